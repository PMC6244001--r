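#' Experiment configuration files
#'
#' Experiments are described by a small versioned YAML schema with
#' sections `patch`, `field`, `sampler`, `analysis` and an
#' experiment-specific block; `snr: inf` encodes an infinite
#' signal-to-noise ratio. [read_experiment_config()] parses and validates
#' a file, reporting schema violations field by field;
#' [run_pipeline()] executes the named experiment and writes its outputs
#' plus a JSON metadata record (resolved parameters, seed, package
#' version) and a plain-text log.
#'
#' @param path Path to a YAML configuration file.
#' @return The validated configuration as a named list.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_experiment_config(cfg)
  cfg
}

## "inf" (any case) -> Inf; numbers pass through.
parse_snr <- function(x) {
  if (is.character(x) && tolower(x) %in% c("inf", "infinite")) return(Inf)
  if (is.numeric(x) && x > 0) return(x)
  stop("snr must be a positive number or the string 'inf'")
}

#' @rdname read_experiment_config
#' @param cfg Configuration list.
#' @export
validate_experiment_config <- function(cfg) {
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  need(is.list(cfg), "config: must be a mapping")
  need(!is.null(cfg$experiment) &&
         cfg$experiment %in% c("depth_profile", "resolution", "pial", "trials_pca"),
       "experiment: must be one of depth_profile, resolution, pial, trials_pca")
  need(is.numeric(cfg$seed) && length(cfg$seed) == 1,
       "seed: must be a single integer")
  p <- cfg$patch
  if (!is.null(p)) {
    need(is.null(p$kind) || p$kind %in% c("flat", "variable"),
         "patch.kind: must be 'flat' or 'variable'")
    if (identical(p$kind, "flat"))
      need(is.numeric(p$thickness_mm) && p$thickness_mm > 0,
           "patch.thickness_mm: must be a positive number")
  }
  if (!is.null(cfg$sampler)) {
    need(is.null(cfg$sampler$voxel_size_mm) ||
           (is.numeric(cfg$sampler$voxel_size_mm) && cfg$sampler$voxel_size_mm > 0),
         "sampler.voxel_size_mm: must be a positive number")
    if (!is.null(cfg$sampler$snr))
      tryCatch(parse_snr(cfg$sampler$snr),
               error = function(e) errs <<- c(errs, paste0("sampler.snr: ", conditionMessage(e))))
  }
  if (!is.null(cfg$analysis))
    need(is.null(cfg$analysis$n_depths) ||
           (is.numeric(cfg$analysis$n_depths) && cfg$analysis$n_depths >= 1),
         "analysis.n_depths: must be a positive integer")
  if (length(errs))
    stop("invalid experiment configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}

config_patch <- function(cfg, seed) {
  p <- cfg$patch %||% list()
  kind <- p$kind %||% "variable"
  if (kind == "flat") {
    make_flat_patch(p$thickness_mm %||% 3,
                    p$length_mm %||% 20,
                    resolution_mm = p$resolution_mm %||% 0.01)
  } else {
    make_variable_patch(p$thickness_min_mm %||% 1.7,
                        p$thickness_max_mm %||% 3.7,
                        length_mm = p$length_mm %||% 20,
                        smoothness_mm = p$smoothness_mm %||% 5,
                        seed = p$seed %||% derive_seed(seed, "patch"),
                        resolution_mm = p$resolution_mm %||% 0.01)
  }
}

config_field <- function(cfg, patch) {
  f <- cfg$field %||% list()
  type <- f$type %||% "induced_psf"
  switch(type,
    induced_psf = induced_psf(f$center_depth %||% 0.5,
                              f$fwhm_fraction %||% 0.2,
                              f$peak_amplitude %||% 1),
    pial_rim = pial_boundary_field(f$rim_width_mm %||% 0.2,
                                   f$peak_amplitude %||% 1, patch),
    constant = constant_gm_field(f$value %||% 1),
    stop("field.type: unknown field type '", type, "'")
  )
}

#' Run a configured experiment end to end
#'
#' Executes the experiment named in the configuration (`depth_profile`,
#' `resolution`, `pial` or `trials_pca`), writing tab-separated outputs, a
#' `metadata.json` record and a `run.log` to the output directory. Runs
#' are deterministic given an identical configuration; partially written
#' outputs are removed if a stage fails.
#'
#' @param config Path to a YAML configuration file, or an equivalent list.
#' @param out_dir Output directory (default: `output_dir` from the config,
#'   else a temporary directory).
#' @param seed Optional override of the configured master seed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the paths of the written artifacts and
#'   the main in-memory result.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) read_experiment_config(config) else {
    validate_experiment_config(config); config
  }
  seed <- as.integer(seed %||% cfg$seed)
  out_dir <- out_dir %||% cfg$output_dir %||% tempfile("laminarsim_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log_path <- file.path(out_dir, "run.log")
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  result <- tryCatch({
    say("experiment: %s (seed %d)", cfg$experiment, seed)
    t0 <- proc.time()["elapsed"]
    an <- cfg$analysis %||% list()
    sm <- cfg$sampler %||% list()
    res <- switch(cfg$experiment,
      depth_profile = {
        patch <- config_patch(cfg, seed)
        field <- config_field(cfg, patch)
        grid <- place_grid(patch, sm$voxel_size_mm %||% 0.75,
                           jitter_seed = derive_seed(seed, "jitter"))
        smp <- measure(field, patch, grid, snr = parse_snr(sm$snr %||% "inf"),
                       seed = derive_seed(seed, "noise"))
        prof <- suppressWarnings(
          upsample_and_bin(smp, patch, an$n_depths %||% 30,
                           an$upsample_factor %||% 10))
        if (!is.null(an$normalization) && an$normalization != "none")
          prof <- normalize_profile(prof, an$normalization)
        emit("depth_profile.tsv", function(p) write_depth_profile_tsv(prof, p))
        prof
      },
      resolution = {
        ex <- cfg$resolution %||% list()
        patch <- if (is.null(cfg$patch)) NULL else config_patch(cfg, seed)
        curve <- run_overlap_experiment(
          roi_sizes = unlist(ex$roi_sizes %||% c(24, 100, 1000)),
          snr = parse_snr(sm$snr %||% "inf"),
          n_depths_sampled = ex$n_depths_sampled %||% 21,
          n_realizations = ex$n_realizations %||% 200,
          seed = seed, voxel_size_mm = sm$voxel_size_mm %||% 0.75,
          fwhm_fraction = cfg$field$fwhm_fraction %||% 0.2,
          center_depth = cfg$field$center_depth %||% 0.5,
          patch = patch, upsample_factor = an$upsample_factor %||% 10)
        emit("overlap_curve.tsv", function(p) write_overlap_curve_tsv(curve, p))
        curve
      },
      pial = {
        ex <- cfg$pial %||% list()
        patch <- if (is.null(cfg$patch)) NULL else config_patch(cfg, seed)
        pl <- run_pial_leakage_experiment(
          rim_width_mm = cfg$field$rim_width_mm %||% 0.2,
          peak_amplitude = cfg$field$peak_amplitude %||% 1,
          voxel_sizes_mm = unlist(ex$voxel_sizes_mm %||% c(0.75, 0.125)),
          n_realizations = ex$n_realizations %||% 100,
          n_depths = an$n_depths %||% 21, seed = seed, patch = patch,
          snr = parse_snr(sm$snr %||% "inf"),
          upsample_factor = an$upsample_factor %||% 10)
        for (key in names(pl$profiles)) {
          prof <- pl$profiles[[key]]
          emit(sprintf("pial_profile_%s.tsv", key),
               function(p) write_depth_profile_tsv(prof, p))
        }
        pl
      },
      trials_pca = {
        ex <- cfg$trials %||% list()
        patch <- config_patch(cfg, seed)
        model <- timecourse_model(
          tangential_modulation_amp = ex$tangential_modulation_amp %||% 0.3,
          modulation_seed = derive_seed(seed, "modulation"))
        ts <- simulate_trials(model, patch, ex$n_trials %||% 10,
                              ex$noise_sd %||% 0.2,
                              seed = derive_seed(seed, "trials"),
                              n_depths = ex$n_depths %||% 30,
                              n_x = ex$n_x %||% 40)
        stack <- build_trial_matrix(ts)
        pca <- pca_explained_variance(stack)
        emit("trials.tsv", function(p) write_trial_stack_tsv(stack, p))
        emit("explained_variance.tsv", function(p) write.table(
          data.frame(component = seq_along(pca$explained_variance_pct),
                     explained_variance_pct = pca$explained_variance_pct),
          p, sep = "\t", row.names = FALSE, quote = FALSE))
        emit("pc1_profile.tsv", function(p) write.table(
          data.frame(position_mm = pca$positions, pc1 = pca$components[, 1]),
          p, sep = "\t", row.names = FALSE, quote = FALSE))
        pca
      }
    )
    meta <- list(experiment = cfg$experiment, seed = seed,
                 config = cfg, package_version = as.character(packageVersion("laminarsim")),
                 elapsed_s = round(unname(proc.time()["elapsed"] - t0), 2))
    emit("metadata.json", function(p)
      jsonlite::write_json(meta, p, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, force = TRUE))
    say("done in %.1f s; %d artifact(s) in %s", meta$elapsed_s,
        length(written), out_dir)
    res
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(list(result = result, out_dir = out_dir, files = written))
}
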