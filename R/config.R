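#' Validated run configuration for the pipeline commands
#'
#' Collects and validates the parameters of one pipeline command before any
#' computation happens.  Thresholds must lie in (0,1), repetition counts
#' must be positive, and referenced input files must exist.
#'
#' @param command one of `"simulate"`, `"derive"`, `"bootstrap"`,
#'   `"score"`, `"validate"`, `"compare"`.
#' @param scans path to a cohort manifest TSV (commands reading scans).
#' @param pattern_dir path to a pattern bundle (scoring/validation).
#' @param pattern_dir_b second pattern bundle (`compare`).
#' @param atlas path to a labeled NIfTI atlas (`compare`, optional for
#'   `validate`).
#' @param out output directory.
#' @param cum_var_threshold,mask_threshold,gmp_group see [derive_config()].
#' @param pc1_only derive the PC1-only pattern variant.
#' @param n_replicates,ci_level bootstrap settings.
#' @param per_camera,reference_group,other_reference_camera scoring
#'   settings (see [score_cohort()]).
#' @param spec a [synthetic_cohort_spec()] for `simulate`, or a list of
#'   overrides for the default spec.
#' @param write_truth write ground truth alongside simulated scans.
#' @param seed integer seed.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(command, scans = NULL, pattern_dir = NULL,
                       pattern_dir_b = NULL, atlas = NULL, out = NULL,
                       cum_var_threshold = 0.5, mask_threshold = 0.35,
                       gmp_group = "all", pc1_only = FALSE,
                       n_replicates = 1000, ci_level = 0.90,
                       per_camera = TRUE, reference_group = "control",
                       other_reference_camera = NULL,
                       spec = NULL, write_truth = FALSE, seed = 1L) {
  commands <- c("simulate", "derive", "bootstrap", "score", "validate",
                "compare")
  if (!command %in% commands) {
    stop_ssm("config", "unknown command '%s' (expected one of: %s)",
             command, paste(commands, collapse = ", "))
  }
  for (nm in c("cum_var_threshold", "mask_threshold", "ci_level")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !(v > 0 && v < 1)) {
      stop_ssm("config", "%s must be a number in (0,1)", nm)
    }
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    stop_ssm("config", "n_replicates must be >= 1")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_ssm("config", "seed must be a single integer")
  }
  needs_scans <- command %in% c("derive", "bootstrap", "score", "validate")
  if (needs_scans) {
    if (is.null(scans)) stop_ssm("config", "command '%s' requires `scans`", command)
    if (!file.exists(scans)) stop_ssm("config", "scans manifest not found: %s", scans)
  }
  needs_pattern <- command %in% c("score", "validate", "compare")
  if (needs_pattern) {
    if (is.null(pattern_dir)) {
      stop_ssm("config", "command '%s' requires `pattern_dir`", command)
    }
    if (!file.exists(file.path(pattern_dir, "pattern.json"))) {
      stop_ssm("config", "pattern bundle not found: %s", pattern_dir)
    }
  }
  if (command == "compare") {
    if (is.null(pattern_dir_b) ||
        !file.exists(file.path(pattern_dir_b, "pattern.json"))) {
      stop_ssm("config", "command 'compare' requires a second pattern bundle")
    }
    if (is.null(atlas) || !file.exists(atlas)) {
      stop_ssm("config", "command 'compare' requires an `atlas` volume")
    }
  }
  if (is.null(out)) stop_ssm("config", "an output directory `out` is required")
  if (command == "simulate") {
    if (is.null(spec)) {
      spec <- synthetic_cohort_spec(seed = as.integer(seed))
    } else if (!inherits(spec, "synthetic_cohort_spec")) {
      spec <- do.call(synthetic_cohort_spec,
                      c(spec, list(seed = as.integer(seed))))
    }
  }
  structure(
    list(command = command, scans = scans, pattern_dir = pattern_dir,
         pattern_dir_b = pattern_dir_b, atlas = atlas, out = out,
         cum_var_threshold = cum_var_threshold,
         mask_threshold = mask_threshold, gmp_group = gmp_group,
         pc1_only = pc1_only, n_replicates = n_replicates,
         ci_level = ci_level, per_camera = per_camera,
         reference_group = reference_group,
         other_reference_camera = other_reference_camera,
         spec = spec, write_truth = write_truth, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Execute one pipeline command
#'
#' Dispatches a validated [run_config()] to the corresponding stage
#' functions, writes the command's artifacts under `config$out`, and drops
#' a `run_manifest.json` (configuration echo, seed, package version, input
#' file hashes, timings) sufficient to reproduce the run.  Inputs are never
#' mutated.
#'
#' @param config a [run_config()].
#' @return A list with the command's primary in-memory result and
#'   `manifest` (the run manifest), invisibly.
#' @export
run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  dcfg <- derive_config(cum_var_threshold = config$cum_var_threshold,
                        mask_threshold = config$mask_threshold,
                        gmp_group = config$gmp_group, seed = config$seed)
  load_scans <- function() {
    m <- read_manifest(config$scans)
    load_volume_set(m$path, m)
  }
  result <- switch(
    config$command,
    simulate = {
      cohort <- generate_cohort(config$spec)
      write_cohort(cohort, config$out, write_truth = config$write_truth)
      cohort
    },
    derive = {
      vs <- load_scans()
      fit <- if (config$pc1_only) derive_pattern_pc1(vs, dcfg)
      else derive_pattern(vs, dcfg)
      write_pattern(fit$pattern, config$out)
      fit
    },
    bootstrap = {
      vs <- load_scans()
      bt <- bootstrap_stability(vs, dcfg, n_replicates = config$n_replicates,
                                ci_level = config$ci_level,
                                seed = config$seed)
      write_bootstrap_maps(bt, config$out)
      bt
    },
    score = {
      vs <- load_scans()
      pattern <- read_pattern(config$pattern_dir)
      sc <- score_cohort(vs, pattern,
                         reference_group = config$reference_group,
                         per_camera = config$per_camera,
                         other_reference_camera = config$other_reference_camera,
                         pattern_id = basename(config$pattern_dir))
      write.table(sc$table, file.path(config$out, "scores.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      sc
    },
    validate = {
      vs <- load_scans()
      pattern <- read_pattern(config$pattern_dir)
      sc <- score_cohort(vs, pattern,
                         reference_group = config$reference_group,
                         per_camera = config$per_camera,
                         other_reference_camera = config$other_reference_camera,
                         pattern_id = basename(config$pattern_dir))
      rep <- discrimination_report(sc)
      jsonlite::write_json(unclass(rep),
                           file.path(config$out, "report.json"),
                           auto_unbox = TRUE, digits = NA)
      write.table(sc$table, file.path(config$out, "scores.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      rep
    },
    compare = {
      pa <- read_pattern(config$pattern_dir)
      pb <- read_pattern(config$pattern_dir_b)
      atlas_img <- RNifti::readNifti(config$atlas)
      labs <- array(as.integer(round(as.vector(atlas_img))),
                    dim = dim(atlas_img))
      present <- sort(setdiff(unique(as.vector(labs)), 0L))
      atl <- voi_atlas(labs, setNames(sprintf("region_%02d", present),
                                      present))
      vs <- if (!is.null(config$scans)) {
        m <- read_manifest(config$scans)
        load_volume_set(m$path, m)
      } else NULL
      rep <- compare_patterns(pa, pb, atl, scored_dataset = vs,
                              other_reference_camera = config$other_reference_camera)
      jsonlite::write_json(unclass(rep),
                           file.path(config$out, "similarity.json"),
                           auto_unbox = TRUE, digits = NA)
      rep
    }
  )
  inputs <- c(config$scans, config$atlas,
              if (!is.null(config$pattern_dir))
                file.path(config$pattern_dir, "pattern.json"),
              if (!is.null(config$pattern_dir_b))
                file.path(config$pattern_dir_b, "pattern.json"))
  manifest <- list(
    command = config$command,
    config = config[setdiff(names(config), "spec")],
    seed = config$seed,
    version = as.character(packageVersion("ssmpca")),
    input_hashes = if (length(inputs)) {
      as.list(tools::md5sum(inputs[file.exists(inputs)]))
    } else list(),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(list(result = result, manifest = manifest))
}
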