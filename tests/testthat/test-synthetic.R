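# synthetic generator: planted networks, ordinal sampling, paired waves

test_that("make_true_network builds planted networks and latent matrices", {
  # degenerate independence case
  cfg0 <- generator_config(within_weight = 0, between_weight = 0)
  tr0 <- make_true_network(cfg0)
  expect_equal(unclass(tr0$latent_correlation_baseline),
               diag(12), ignore_attr = TRUE)
  expect_true(all(unclass(tr0$true_network_baseline) == 0))

  cfg <- generator_config(within_weight = 0.3, between_weight = 0.02)
  tr <- make_true_network(cfg)
  W <- unclass(tr$true_network_baseline)
  # round trip: precision implied by the network reproduces the latent
  # correlation to numerical accuracy
  R <- stats::cov2cor(solve(diag(12) - W))
  expect_lt(max(abs(R - tr$latent_correlation_baseline)), 1e-10)
  # block structure: items of one block share within_weight
  expect_equal(W["bnss1", "bnss2"], 0.3)
  expect_equal(W["bnss1", "bnss5"], 0.02)
  # follow-up is an element-wise scaling
  expect_equal(unclass(tr$true_network_followup),
               cfg$strength_scale_followup * W, tolerance = 1e-12)
  expect_equal(global_strength(tr$true_network_followup),
               cfg$strength_scale_followup *
                 global_strength(tr$true_network_baseline))
  # latent matrices are valid correlation matrices
  for (R in list(tr$latent_correlation_baseline,
                 tr$latent_correlation_followup)) {
    expect_equal(diag(R), setNames(rep(1, 12), colnames(R)))
    expect_lt(max(abs(R - t(R))), 1e-12)
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config(between_weight = 0.4, within_weight = 0.3),
               "between_weight")
  expect_error(generator_config(subject_dependence = 1), "subject_dependence")
  expect_error(generator_config(thresholds = c(0, 1, 2, 3, 4)), "6 cut-points")
  expect_error(generator_config(thresholds = c(0, 1, 1, 2, 3, 4)),
               "strictly increasing")
  expect_error(generator_config(blocks = list(a = paste0("bnss", 1:3))),
               "partition")
  # non-PD planted precision caught at construction, naming the weights
  bad <- generator_config(within_weight = 0.6, between_weight = 0.25)
  expect_error(make_true_network(bad), "positive definite")
})

test_that("sample_ordinal_panel discretizes a latent Gaussian", {
  R <- diag(3)
  dimnames(R) <- list(c("a", "b", "c"), c("a", "b", "c"))
  # floor case: thresholds far above any plausible draw
  pan <- sample_ordinal_panel(R, 50, thresholds = 10:15, seed = 1)
  expect_true(all(pan$scores == 0L))
  # scores always integers in [0, 6]
  pan2 <- sample_ordinal_panel(R, 500, thresholds = c(-2, -1, 0, 1, 2, 3),
                               seed = 2)
  expect_true(all(pan2$scores %in% 0:6))
  # independent latents give near-zero pairwise correlations
  pan3 <- sample_ordinal_panel(R, 5000,
                               thresholds = c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5),
                               seed = 3)
  C <- cor(pan3$scores)
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
  # non-PD input rejected
  bad <- matrix(1, 2, 2)
  expect_error(sample_ordinal_panel(bad, 50, 10:15), "positive definite")
})

test_that("rank correlations of a large panel recover the latent matrix", {
  cfg <- generator_config(n_subjects = 20000, seed = 11)
  tr <- make_true_network(cfg)
  pan <- sample_ordinal_panel(tr$latent_correlation_baseline, 20000,
                              cfg$thresholds, seed = 12)
  # tetrachoric-style latent-correlation estimates on a mix of
  # within-domain and between-domain pairs
  pairs <- list(c("bnss1", "bnss2"), c("bnss2", "bnss3"),
                c("bnss5", "bnss6"), c("bnss9", "bnss10"),
                c("bnss12", "bnss13"), c("bnss1", "bnss7"),
                c("bnss5", "bnss11"), c("bnss3", "bnss13"))
  for (pr in pairs) {
    rhat <- oracle_tetrachoric(pan$scores[, pr[1]], pan$scores[, pr[2]])
    expect_lt(abs(rhat - tr$latent_correlation_baseline[pr[1], pr[2]]),
              0.03)
  }
})

test_that("make_paired_panel honours dependence, shifts and determinism", {
  # rho = 0: waves statistically independent
  cfg0 <- generator_config(n_subjects = 20000, subject_dependence = 0,
                           strength_scale_followup = 1,
                           mean_shift_followup = 0, seed = 21)
  made0 <- make_paired_panel(cfg0)
  cross <- vapply(seq_len(12), function(j)
    cor(made0$panel$baseline$scores[, j], made0$panel$followup$scores[, j]),
    numeric(1))
  expect_lt(max(abs(cross)), 0.05)

  # negative mean shift lowers every follow-up item mean
  cfg1 <- generator_config(n_subjects = 5000, mean_shift_followup = -0.2,
                           strength_scale_followup = 1, seed = 22)
  made1 <- make_paired_panel(cfg1)
  expect_true(all(colMeans(made1$panel$followup$scores) <=
                    colMeans(made1$panel$baseline$scores)))

  # positive dependence produces positive cross-wave correlations
  cfg2 <- generator_config(n_subjects = 5000, subject_dependence = 0.6,
                           seed = 23)
  made2 <- make_paired_panel(cfg2)
  cross2 <- vapply(seq_len(12), function(j)
    cor(made2$panel$baseline$scores[, j], made2$panel$followup$scores[, j]),
    numeric(1))
  expect_true(all(cross2 > 0.2))

  # determinism: same seed, bit-identical panels
  cfg3 <- generator_config(n_subjects = 200, seed = 24)
  expect_identical(make_paired_panel(cfg3)$panel,
                   make_paired_panel(cfg3)$panel)
})

test_that("unpenalized partial correlations of large latent samples recover the planted network", {
  cfg <- generator_config(seed = 31)
  tr <- make_true_network(cfg)
  set.seed(31)
  X <- matrix(rnorm(50000 * 12), 50000, 12) %*%
    chol(tr$latent_correlation_baseline)
  Theta <- solve(cor(X))
  d <- sqrt(diag(Theta))
  P <- -Theta / outer(d, d)
  diag(P) <- 0
  expect_lt(max(abs(P - unclass(tr$true_network_baseline))), 0.02)
})

test_that("panel CSV round-trips through write and load", {
  made <- planted_panel(n = 80, seed = 41)
  path <- tempfile(fileext = ".csv")
  write_panel_csv(made$panel, path)
  back <- load_paired_panel(path)
  expect_identical(back$baseline$scores, made$panel$baseline$scores)
  expect_identical(back$followup$scores, made$panel$followup$scores)
})
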