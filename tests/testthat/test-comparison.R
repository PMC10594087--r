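# dependent-samples permutation network comparison test

test_that("nct_statistics computes M, S and edge differences", {
  net <- random_signed_network(5)
  id <- nct_statistics(net, net)
  expect_equal(id$M, 0)
  expect_equal(id$S, 0)
  expect_true(all(id$edge_diffs == 0))

  # one-edge case
  W1 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  W2 <- W1
  W1[1, 2] <- W1[2, 1] <- 0.30
  W2[1, 2] <- W2[2, 1] <- 0.10
  st <- nct_statistics(pc_network(W1), pc_network(W2))
  expect_equal(st$M, 0.2)
  expect_equal(st$S, 0.2)

  # S and M identities on random pairs; M = 0 implies S = 0
  set.seed(1)
  for (i in 1:10) {
    n1 <- random_signed_network(6)
    n2 <- random_signed_network(6)
    st <- nct_statistics(n1, n2)
    expect_equal(st$S, abs(global_strength(n1) - global_strength(n2)))
    expect_equal(st$M, max(abs(unclass(n1) - unclass(n2))))
  }
  m2 <- pc_network(unclass(random_signed_network(5)),
                   item_labels = paste0("X", 1:5))
  expect_error(nct_statistics(net, m2), "labels differ")
})

test_that("permute_paired swaps waves per subject", {
  made <- planted_panel(n = 612, seed = 2)
  pair <- made$panel
  pm1 <- permute_paired(pair, seed = 3)
  pm2 <- permute_paired(pair, seed = 3)
  expect_identical(pm1$baseline$scores, pm2$baseline$scores)
  mask <- attr(pm1, "swap_mask")
  # roughly half the subjects swap
  expect_lt(abs(mean(mask) - 0.5), 0.05)
  # swapped subjects carry follow-up rows at baseline
  expect_identical(pm1$baseline$scores[mask, ], pair$followup$scores[mask, ])
  expect_identical(pm1$baseline$scores[!mask, ],
                   pair$baseline$scores[!mask, ])
  # applying the same mask twice restores the original pair
  back <- permute_paired(pm1, swap_mask = mask)
  expect_identical(back$baseline$scores, pair$baseline$scores)
  expect_identical(back$followup$scores, pair$followup$scores)
})

test_that("holm_adjust applies the step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # Holm never exceeds Bonferroni, and dominates the raw p-values
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    h <- holm_adjust(p)
    expect_true(all(h <= pmin(length(p) * p, 1) + 1e-12))
    expect_true(all(h >= p))
  }
})

test_that("identical waves give degenerate null results", {
  made <- planted_panel(n = 150, seed = 5)
  pair <- paired_panel(made$panel$baseline,
                       item_panel(made$panel$baseline$scores,
                                  made$panel$baseline$subject_ids,
                                  made$panel$baseline$item_labels,
                                  "followup"))
  res <- nct_dependent(pair, fast_settings(), B = 50, seed = 6)
  expect_equal(res$M, 0)
  expect_equal(res$S, 0)
  expect_equal(res$p_M, 1)
  expect_equal(res$p_S, 1)
  # p-values bounded below by 1/(B+1), Holm >= raw
  expect_true(all(res$edge_p_raw >= 1 / (res$B + 1)))
  expect_true(all(res$edge_p_holm >= res$edge_p_raw))
})

test_that("nct_dependent is reproducible and reports edges per policy", {
  made <- planted_panel(n = 200, seed = 7)
  r1 <- nct_dependent(made$panel, fast_settings(), B = 30, seed = 8,
                      edge_tests = "all")
  r2 <- nct_dependent(made$panel, fast_settings(), B = 30, seed = 8,
                      edge_tests = "all")
  expect_identical(r1$perm_S, r2$perm_S)
  expect_identical(r1$edge_p_holm, r2$edge_p_holm)
  expect_s3_class(r1, "nct_result")
  expect_equal(nrow(r1$edge_table), 66)
  r3 <- nct_dependent(made$panel, fast_settings(), B = 30, seed = 8,
                      edge_tests = "none")
  expect_null(r3$edge_table)
})

test_that("permutation distribution matches full enumeration for 10 subjects", {
  # brute force: all 2^10 swap masks; sampled: B = 2000 random masks.
  # compared by total variation over 10 equal-probability bins of the
  # enumerated distribution of the global-strength statistic.  A 4-item
  # subset keeps estimation non-degenerate at n = 10 (12 items with 10
  # subjects select empty networks for every mask).
  made <- planted_panel(n = 10, seed = 9, subject_dependence = 0.5)
  keep <- c("bnss1", "bnss2", "bnss3", "bnss5")
  pair <- exclude_items(made$panel,
                        setdiff(made$panel$baseline$item_labels, keep))
  st <- estimator_settings(n_lambdas = 15, gamma = 0)
  stat_for_mask <- function(mask) {
    pm <- permute_paired(pair, swap_mask = mask)
    W1 <- pairnet:::.fit_network_scores(pm$baseline$scores, st)
    W2 <- pairnet:::.fit_network_scores(pm$followup$scores, st)
    abs(sum(abs(W1[upper.tri(W1)])) - sum(abs(W2[upper.tri(W2)])))
  }
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 10)))
  exact <- apply(masks, 1, stat_for_mask)

  set.seed(10)
  B <- 2000
  sampled <- vapply(seq_len(B), function(b)
    stat_for_mask(rbinom(10, 1, 0.5) == 1), numeric(1))

  brk <- unique(quantile(exact, probs = seq(0, 1, by = 0.1)))
  brk[1] <- -Inf
  brk[length(brk)] <- Inf
  pe <- as.numeric(table(cut(exact, brk))) / length(exact)
  ps <- as.numeric(table(cut(sampled, brk))) / B
  tv <- 0.5 * sum(abs(pe - ps))
  expect_lte(tv, 0.05)
})

test_that("global-strength test has power against a weakened follow-up", {
  rej <- logical(12)
  for (i in seq_along(rej)) {
    made <- make_paired_panel(generator_config(
      n_subjects = 612, strength_scale_followup = 0.8,
      mean_shift_followup = -0.2, seed = 400 + i))
    res <- nct_dependent(made$panel, fast_settings(), B = 60,
                         seed = 500 + i)
    rej[i] <- res$p_S < 0.05
  }
  expect_gte(mean(rej), 0.5)
})
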