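make_stack <- function(n_trials = 8, noise_sd = 0.5, seed = 7, n_x = 24,
                       model = timecourse_model()) {
  p <- make_flat_patch(2.5, 20, resolution_mm = 0.05)
  ts <- simulate_trials(model, p, n_trials, noise_sd, seed,
                        n_depths = 10, n_x = n_x)
  list(ts = ts, stack = build_trial_matrix(ts))
}

test_that("trial matrices have trials as rows and honour degenerate generators", {
  m0 <- timecourse_model(trial_gain_sd = 0)
  s <- make_stack(n_trials = 3, noise_sd = 0, model = m0)
  expect_identical(dim(unclass(s$stack)), c(3L, 24L))
  # identical noiseless trials give identical rows
  expect_equal(s$stack[1, ], s$stack[2, ])
  # no tangential modulation and no noise: constant columns and rows
  mflat <- timecourse_model(trial_gain_sd = 0, tangential_modulation_amp = 0)
  sf <- make_stack(n_trials = 3, noise_sd = 0, model = mflat)
  expect_lt(diff(range(unclass(sf$stack))), 1e-12)
  expect_error(build_trial_matrix(list(matrix(1, 2, 2)),
                                  times = 1:2, x = 1:2,
                                  stimulus_onset_s = 0, stimulus_duration_s = 1),
               "at least 2")
  expect_error(
    build_trial_matrix(list(array(1, c(2, 3, 4)), array(1, c(2, 3, 5))),
                       times = 1:4, x = 1:3,
                       stimulus_onset_s = 0, stimulus_duration_s = 2),
    "share one")
})

test_that("trial-stack row means match the noiseless generator within 3 SE", {
  s <- make_stack(n_trials = 10, noise_sd = 0.5, seed = 7)
  noiseless <- make_stack(n_trials = 2, noise_sd = 0, seed = 1,
                          model = timecourse_model(trial_gain_sd = 0))
  truth <- noiseless$stack[1, ]
  est <- colMeans(s$stack)
  se <- apply(unclass(s$stack), 2, sd) / sqrt(10)
  expect_true(all(abs(est - truth) < 3.5 * se + 1e-8))
})

test_that("explained variance matches an eigen-decomposition of the covariance", {
  s <- make_stack(n_trials = 6, noise_sd = 1, seed = 3, n_x = 20)
  pca <- pca_explained_variance(s$stack)
  ev <- eigen(cov(unclass(s$stack)), symmetric = TRUE, only.values = TRUE)$values
  ev <- 100 * ev / sum(ev)
  k <- length(pca$explained_variance_pct)
  expect_equal(pca$explained_variance_pct, ev[seq_len(k)], tolerance = 1e-8)
  expect_equal(sum(pca$explained_variance_pct), 100, tolerance = 1e-10)
  # components orthonormal
  G <- crossprod(pca$components)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
})

test_that("a rank-1 stack loads 100% on the first component", {
  prof <- sin(seq(0, 3, length.out = 15))
  X <- outer(c(1, 2, 3.5, 0.2), prof)
  stack <- structure(X, positions = seq_len(15),
                     class = c("trial_stack", "matrix"))
  pca <- pca_explained_variance(stack)
  expect_equal(pca$explained_variance_pct[1], 100, tolerance = 1e-10)
  expect_error(pca_explained_variance(matrix(1, 4, 5)), "zero-variance")
})

test_that("explained variance is invariant to global rescaling", {
  s <- make_stack(n_trials = 6, noise_sd = 1, seed = 9, n_x = 12)
  pca1 <- pca_explained_variance(s$stack)
  scaled <- structure(unclass(s$stack) * 37, positions = attr(s$stack, "positions"),
                      class = class(s$stack))
  pca2 <- pca_explained_variance(scaled)
  expect_equal(pca1$explained_variance_pct, pca2$explained_variance_pct,
               tolerance = 1e-10)
})

test_that("PC1 sign and similarity conventions hold", {
  s <- make_stack(n_trials = 10, noise_sd = 0.3, seed = 5)
  pca <- pca_explained_variance(s$stack)
  expect_gte(cor(pca$components[, 1], colMeans(s$stack)), 0)
  expect_equal(pc1_similarity(pca, pca$components[, 1]), 1)
  expect_equal(pc1_similarity(pca, -pca$components[, 1]), -1)
  expect_error(pc1_similarity(pca, rep(1, 24)), "constant")
  expect_error(pc1_similarity(pca, 1:5), "position grid")
})

test_that("PC1 recovers the true tangential modulation under moderate noise", {
  s <- make_stack(n_trials = 10, noise_sd = 0.5, seed = 7, n_x = 20)
  pca <- pca_explained_variance(s$stack)
  expect_gt(pc1_similarity(pca, s$ts$tangential_modulation), 0.9)
})

test_that("structured stacks beat matched pure-noise stacks on PC1 variance", {
  m_noise <- timecourse_model(trial_gain_sd = 0, tangential_modulation_amp = 0)
  ev1 <- vapply(1:30, function(i)
    pca_explained_variance(make_stack(8, 1, seed = 100 + i)$stack)$explained_variance_pct[1],
    numeric(1))
  ev0 <- vapply(1:30, function(i)
    pca_explained_variance(make_stack(8, 1, seed = 100 + i, model = m_noise)$stack)$explained_variance_pct[1],
    numeric(1))
  expect_gt(mean(ev1), mean(ev0))
})

test_that("trial stacks round-trip through TSV", {
  s <- make_stack(n_trials = 4, noise_sd = 0.2, seed = 2, n_x = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_stack_tsv(s$stack, path)
  q <- read_trial_stack_tsv(path)
  expect_equal(unclass(q)[, ], unclass(s$stack)[, ], ignore_attr = TRUE)
  expect_equal(attr(q, "positions"), attr(s$stack, "positions"))
})
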