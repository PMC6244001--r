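#' Trial matrix of tangential positive-BOLD profiles
#'
#' Builds the matrix fed to the PCA assessment of tangential variability:
#' for each trial, the positive-BOLD window average is computed per depth
#' and distance (via [extract_positive_and_undershoot()] windows) and
#' collapsed over grey-matter depths, giving one tangential profile per
#' trial. Rows are trials, columns are tangential positions.
#'
#' @param trials A `trial_set` from [simulate_trials()], or a list of
#'   `depth x distance x time` arrays sharing one grid (then `times`,
#'   `x` and the stimulus window must be given).
#' @param times,x Time (s) and tangential position (mm) axes (taken from
#'   the `trial_set` when available).
#' @param stimulus_onset_s,stimulus_duration_s Stimulus window (s).
#' @param rise_lag_s Hemodynamic rise lag excluded from the window start.
#' @return A `trial_stack`: `n_trials x n_positions` matrix with
#'   attributes `positions` and `provenance`.
#' @export
build_trial_matrix <- function(trials, times = NULL, x = NULL,
                               stimulus_onset_s = NULL,
                               stimulus_duration_s = NULL,
                               rise_lag_s = 8) {
  if (inherits(trials, "trial_set")) {
    times <- trials$times; x <- trials$x
    stimulus_onset_s <- stimulus_onset_s %||% trials$model$stimulus_onset_s
    stimulus_duration_s <- stimulus_duration_s %||% trials$model$stimulus_duration_s
    arrays <- trials$trials
    provenance <- list(model = trials$model, noise_sd = trials$noise_sd,
                       seed = trials$seed)
  } else {
    arrays <- trials
    provenance <- list()
  }
  if (length(arrays) < 2) stop("at least 2 trials are required")
  dims <- lapply(arrays, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("all trials must share one depth x distance x time grid")
  pos_win <- times >= stimulus_onset_s + rise_lag_s &
    times <= stimulus_onset_s + stimulus_duration_s
  if (!any(pos_win)) stop("positive-BOLD window is outside the sampled times")
  X <- t(vapply(arrays, function(a) {
    colMeans(apply(a[, , pos_win, drop = FALSE], c(1, 2), mean))
  }, numeric(length(x))))
  structure(X, positions = x, provenance = provenance,
            class = c("trial_stack", "matrix"))
}

#' PCA decomposition of a trial stack
#'
#' Column-mean-centred singular value decomposition of the trial matrix
#' (trials as observations, tangential positions as variables). The
#' percent variance explained by component `k` is `100 * s_k^2 / sum s^2`;
#' the first principal component's sign is fixed so that its correlation
#' with the mean tangential profile is non-negative.
#'
#' @param stack A `trial_stack` (or plain matrix, trials in rows).
#' @return A `pca_result`: orthonormal `components` (columns),
#'   `singular_values`, `explained_variance_pct`, the `center` vector and
#'   `positions`.
#' @export
pca_explained_variance <- function(stack) {
  X <- unclass(stack)
  stopifnot(is.matrix(X), nrow(X) >= 2, ncol(X) >= 2)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  if (all(abs(Xc) < 1e-14))
    stop("zero-variance trial stack: explained variance is undefined")
  s <- svd(Xc)
  ev <- 100 * s$d^2 / sum(s$d^2)
  comps <- s$v
  mean_prof <- center
  if (sd(mean_prof) > 0 && !is.na(r1 <- cor(comps[, 1], mean_prof)) && r1 < 0) {
    comps[, 1] <- -comps[, 1]
    s$u[, 1] <- -s$u[, 1]
  } else if (sd(mean_prof) == 0 && sum(comps[, 1]) < 0) {
    comps[, 1] <- -comps[, 1]
  }
  structure(list(components = comps, singular_values = s$d,
                 scores = s$u %*% diag(s$d, nrow = length(s$d)),
                 explained_variance_pct = ev, center = center,
                 positions = attr(stack, "positions")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> explained variance (%):",
      paste(sprintf("%.1f", utils::head(x$explained_variance_pct, 5)),
            collapse = ", "),
      if (length(x$explained_variance_pct) > 5) "..." else "", "\n")
  invisible(x)
}

#' Similarity of the first principal component to a reference profile
#'
#' Pearson correlation between PC1 and a reference tangential profile
#' (e.g. the generator's true tangential modulation, or a single trial).
#'
#' @param result A `pca_result`.
#' @param reference Numeric profile on the same position grid.
#' @return Pearson correlation coefficient.
#' @export
pc1_similarity <- function(result, reference) {
  pc1 <- result$components[, 1]
  if (length(reference) != length(pc1))
    stop("reference must be on the same position grid as PC1")
  if (sd(pc1) == 0 || sd(reference) == 0)
    stop("correlation with a constant profile is undefined")
  cor(pc1, reference)
}

#' Write / read a trial stack as TSV
#'
#' Long format with columns `trial`, `position_mm`, `value`.
#'
#' @param stack A `trial_stack`.
#' @param path File path.
#' @return `write_trial_stack_tsv` returns `path` invisibly;
#'   `read_trial_stack_tsv` returns a `trial_stack`.
#' @export
write_trial_stack_tsv <- function(stack, path) {
  X <- unclass(stack)
  df <- data.frame(trial = rep(seq_len(nrow(X)), ncol(X)),
                   position_mm = rep(attr(stack, "positions"), each = nrow(X)),
                   value = as.vector(X))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_stack_tsv
#' @export
read_trial_stack_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  pos <- sort(unique(df$position_mm))
  trials <- sort(unique(df$trial))
  X <- matrix(NA_real_, length(trials), length(pos))
  X[cbind(match(df$trial, trials), match(df$position_mm, pos))] <- df$value
  structure(X, positions = pos, provenance = list(source = path),
            class = c("trial_stack", "matrix"))
}
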