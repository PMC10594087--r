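# ingestion, item exclusion, nonparanormal transform, correlation input

make_csv <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

test_that("load_panel validates, filters and listwise-deletes", {
  df <- data.frame(subject_id = c("s1", "s2", "s3"), time = "baseline",
                   i1 = c(1L, 2L, 3L), i2 = c(0L, NA, 2L))
  expect_message(pan <- load_panel(make_csv(df), "baseline"), "dropped 1")
  expect_equal(pan$subject_ids, c("s1", "s3"))
  expect_equal(dim(pan), c(2L, 2L))

  # out-of-range score names the cell
  df$i2 <- c(0L, 8L, 2L)
  expect_error(load_panel(make_csv(df), "baseline"), "out of range")
  df$i2 <- c(0L, -1L, 2L)
  expect_error(load_panel(make_csv(df), "baseline"), "out of range")

  # duplicate subjects rejected
  df2 <- data.frame(subject_id = c("s1", "s1"), i1 = c(1L, 2L))
  expect_error(load_panel(make_csv(df2), "baseline"), "duplicate")

  # wide well-formed file passes through with its shape
  set.seed(5)
  wide <- data.frame(subject_id = sprintf("p%03d", 1:612),
                     matrix(sample(0:6, 612 * 13, TRUE), 612, 13))
  pan3 <- load_panel(make_csv(wide), "baseline")
  expect_equal(dim(pan3), c(612L, 13L))

  # tab-delimited input picked up from the extension
  patht <- tempfile(fileext = ".tsv")
  write.table(df2[1, ], patht, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(load_panel(patht, "baseline")$subject_ids, "s1")
})

test_that("exclude_items drops named columns and keeps order", {
  made <- planted_panel(n = 50, seed = 1)
  pan <- made$panel$baseline
  out <- exclude_items(pan, "bnss5")
  expect_equal(out$item_labels, setdiff(pan$item_labels, "bnss5"))
  expect_identical(exclude_items(pan, character()), pan)
  expect_error(exclude_items(pan, "bnss4"), "unknown item")
  # 13-item panel minus the control item leaves 12
  scores <- matrix(sample(0:6, 20 * 13, TRUE), 20, 13,
                   dimnames = list(NULL, paste0("bnss", 1:13)))
  pan13 <- item_panel(scores, time_label = "baseline")
  expect_equal(length(exclude_items(pan13, "bnss4")$item_labels), 12L)
})

test_that("nonparanormal transform is monotone, tie-preserving and near-normal", {
  # strictly increasing input stays monotone; strictly increasing away
  # from the Winsorization boundary (extreme ranks are truncated to
  # [delta_n, 1 - delta_n] by construction, which collapses the most
  # extreme values)
  x <- matrix(seq(0, 1, length.out = 100), ncol = 1)
  z <- nonparanormal_transform(x)
  expect_true(all(diff(z[, 1]) >= 0))
  expect_true(all(diff(z[5:95, 1]) > 0))

  # ties map to identical values
  pan <- item_panel(matrix(c(rep(2L, 5), rep(4L, 7), 0:5), ncol = 1),
                    time_label = "baseline")
  zt <- nonparanormal_transform(pan)
  expect_length(unique(zt[pan$scores == 2L, 1]), 1L)
  expect_length(unique(zt[pan$scores == 4L, 1]), 1L)

  # continuous uniform input: transformed column is close to standard normal
  set.seed(42)
  u <- matrix(runif(1000), ncol = 1)
  zu <- nonparanormal_transform(u)[, 1]
  ks <- suppressWarnings(stats::ks.test(zu, "pnorm"))
  expect_lt(unname(ks$statistic), 0.05)

  # column means near 0 and sds near 1 on ordinal panels
  made <- planted_panel(n = 400, seed = 3)
  Z <- nonparanormal_transform(made$panel$baseline)
  expect_lt(max(abs(colMeans(Z))), 0.1)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 0.15)

  # rank preservation: the transform is nondecreasing in the raw score, so
  # ranks survive up to the Winsorization collapse of rare extreme
  # categories
  raw <- made$panel$baseline$scores[, 1]
  expect_true(all(diff(Z[order(raw), 1]) >= 0))
  expect_gt(cor(raw, Z[, 1], method = "spearman"), 0.999)

  # constant columns are rejected by name
  cpan <- item_panel(cbind(a = rep(3L, 20), b = sample(0:6, 20, TRUE)),
                     time_label = "baseline")
  expect_error(nonparanormal_transform(cpan), "constant column: a")
  expect_error(nonparanormal_transform(matrix(runif(5), ncol = 1)), "n >= 10")
})

test_that("panel_correlation is symmetric, unit-diagonal and sane", {
  set.seed(7)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  X[, 2] <- X[, 1] # identical columns -> r = 1
  C <- panel_correlation(X)
  expect_identical(C, t(C))
  expect_equal(C["a", "b"], 1)
  expect_equal(diag(C), setNames(rep(1, 4), letters[1:4]))

  # independent columns at large n: off-diagonals near 0
  Z <- matrix(rnorm(20000 * 5), 20000, 5)
  C2 <- panel_correlation(Z)
  expect_lt(max(abs(C2[upper.tri(C2)])), 0.05)

  expect_error(panel_correlation(Z[1:2, ]), "at least 3")
  expect_warning(panel_correlation(Z[1:4, ]), "n <= p")
})

test_that("pipeline determinism: same file, identical correlation matrix", {
  made <- planted_panel(n = 60, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_panel_csv(made$panel, path)
  run <- function() {
    pan <- load_panel(path, "baseline")
    panel_correlation(nonparanormal_transform(pan))
  }
  expect_identical(serialize(run(), NULL), serialize(run(), NULL))
})
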