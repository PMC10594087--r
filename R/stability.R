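# Edge-weight accuracy (nonparametric bootstrap) and centrality stability
# (case-dropping bootstrap with the correlation-stability coefficient).

#' Nonparametric bootstrap of edge weights
#'
#' Resamples subjects with replacement `B` times, re-runs the full
#' estimation pipeline (nonparanormal transform, correlation, EBIC-glasso)
#' per resample, and summarizes each edge by its bootstrap mean and
#' percentile interval.
#'
#' @param panel an [item_panel].
#' @param settings an [estimator_settings()].
#' @param B number of bootstrap samples (>= 100 for quantile intervals).
#' @param seed RNG seed.
#' @param probs interval probabilities (default 2.5% / 97.5%).
#' @return An object of class `edge_stability`: a data frame per edge with
#'   `original`, `boot_mean`, `lower`, `upper`, plus fields `B`,
#'   `failed`, `seed`.
#' @export
edge_bootstrap <- function(panel, settings = estimator_settings(),
                           B = 1000L, seed = NULL,
                           probs = c(0.025, 0.975)) {
  stopifnot(inherits(panel, "item_panel"), B >= 2, length(probs) == 2)
  if (B < 100L)
    warning("B < 100: percentile intervals will be coarse", call. = FALSE)
  X <- panel$scores
  n <- nrow(X)
  W0 <- .fit_network_scores(X, settings)
  ne <- sum(upper.tri(W0))
  .set_seed_if(seed)
  boots <- matrix(NA_real_, B, ne)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    Wb <- tryCatch(.fit_network_scores(X[idx, , drop = FALSE], settings),
                   error = function(e) NULL)
    if (is.null(Wb)) failed <- failed + 1L
    else boots[b, ] <- Wb[upper.tri(Wb)]
  }
  if (failed > 0.05 * B)
    stop(sprintf("estimator failed in %d of %d bootstrap samples",
                 failed, B), call. = FALSE)
  ok <- stats::complete.cases(boots)
  qs <- apply(boots[ok, , drop = FALSE], 2L, quantile, probs = probs)
  pairs <- .upper_pairs(colnames(W0))
  edges <- data.frame(pairs,
                      original = W0[upper.tri(W0)],
                      boot_mean = colMeans(boots[ok, , drop = FALSE]),
                      lower = qs[1L, ], upper = qs[2L, ],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, network = pc_network(W0),
                 B = as.integer(B), failed = failed, probs = probs,
                 seed = seed),
            class = "edge_stability")
}

#' @export
print.edge_stability <- function(x, ...) {
  cat(sprintf("<edge_stability> %d edges, B = %d (%d failed)\n",
              nrow(x$edges), x$B, x$failed))
  invisible(x)
}

#' Case-dropping bootstrap of centrality stability
#'
#' For each drop proportion q, draws `B` subsamples without replacement of
#' size `round((1 - q) n)`, re-estimates the network and its centralities,
#' and correlates them with the full-sample centralities.  Proportions
#' whose retained size falls below `p + 5` are skipped with a warning.
#'
#' @param panel an [item_panel].
#' @param settings an [estimator_settings()].
#' @param proportions drop-proportion grid (default 0.1-0.9 by 0.1).
#' @param B subsamples per proportion.
#' @param seed RNG seed.
#' @param indices centrality indices to track.
#' @return An object of class `case_drop`: `draws` (long data frame of
#'   per-draw correlations), `summary` (mean correlation per proportion and
#'   index), `cs` (correlation-stability coefficients at the default 0.7 /
#'   95% rule), plus settings.
#' @export
case_drop_bootstrap <- function(panel, settings = estimator_settings(),
                                proportions = seq(0.1, 0.9, by = 0.1),
                                B = 250L, seed = NULL,
                                indices = c("strength", "closeness",
                                            "betweenness")) {
  stopifnot(inherits(panel, "item_panel"), B >= 1)
  X <- panel$scores
  n <- nrow(X); p <- ncol(X)
  cent <- function(W) {
    net <- pc_network(W)
    tab <- suppressMessages(
      cbind(strength = node_strength(net),
            closeness = closeness_centrality(net),
            betweenness = betweenness_centrality(net)))
    tab[, indices, drop = FALSE]
  }
  C0 <- cent(.fit_network_scores(X, settings))
  .set_seed_if(seed)
  rows <- list()
  for (q in proportions) {
    m <- round((1 - q) * n)
    if (m < p + 5L) {
      warning(sprintf("drop proportion %.2f skipped: retained size %d < %d",
                      q, m, p + 5L), call. = FALSE)
      next
    }
    for (b in seq_len(B)) {
      idx <- sample.int(n, m)
      Wb <- tryCatch(.fit_network_scores(X[idx, , drop = FALSE], settings),
                     error = function(e) NULL)
      if (is.null(Wb)) next
      Cb <- cent(Wb)
      r <- vapply(indices, function(k) {
        if (sd(Cb[, k]) == 0 || sd(C0[, k]) == 0) return(NA_real_)
        cor(C0[, k], Cb[, k])
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(proportion = q, draw = b, index = indices,
                   correlation = unname(r), stringsAsFactors = FALSE)
    }
  }
  draws <- do.call(rbind, rows)
  if (is.null(draws) || nrow(draws) == 0L)
    stop("no usable case-dropping draws", call. = FALSE)
  # NA correlations (constant centrality in a subsample, e.g. an empty
  # re-estimated network) are kept in `draws` but excluded from the means
  agg <- stats::aggregate(list(correlation = draws$correlation),
                          by = list(proportion = draws$proportion,
                                    index = draws$index),
                          FUN = function(v) mean(v, na.rm = TRUE))
  out <- structure(list(draws = draws, summary = agg,
                        proportions = proportions, B = as.integer(B),
                        indices = indices, seed = seed),
                   class = "case_drop")
  out$cs <- cs_coefficient(out)
  out
}

#' Correlation-stability (CS) coefficient
#'
#' For each centrality index, the largest drop proportion at which the
#' correlation with the full-sample centralities stays at or above
#' `r_threshold` in at least `prob` of the draws; 0 when no proportion
#' qualifies.
#'
#' @param result a `case_drop` object.
#' @param r_threshold correlation threshold (default 0.7).
#' @param prob required fraction of draws (default 0.95).
#' @return Named numeric vector of CS coefficients, one per index.
#' @export
cs_coefficient <- function(result, r_threshold = 0.7, prob = 0.95) {
  stopifnot(inherits(result, "case_drop"))
  draws <- result$draws
  vapply(result$indices, function(k) {
    d <- draws[draws$index == k & !is.na(draws$correlation), , drop = FALSE]
    qs <- sort(unique(d$proportion))
    ok <- vapply(qs, function(q) {
      v <- d$correlation[d$proportion == q]
      length(v) > 0 && mean(v >= r_threshold) >= prob
    }, logical(1))
    if (!any(ok)) 0 else max(qs[ok])
  }, numeric(1))
}

#' @export
print.case_drop <- function(x, ...) {
  cat(sprintf("<case_drop> %d proportions x B = %d\n",
              length(unique(x$draws$proportion)), x$B))
  cs <- x$cs
  cat("  CS-coefficients:",
      paste(sprintf("%s = %.2f", names(cs), cs), collapse = ", "), "\n")
  invisible(x)
}
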