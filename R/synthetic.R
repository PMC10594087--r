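# Synthetic paired ordinal panels from a latent Gaussian with a planted
# block-structured partial-correlation network.

.default_item_labels <- function() {
  paste0("bnss", c(1:3, 5:13))
}

.default_blocks <- function() {
  list(anhedonia      = paste0("bnss", 1:3),
       asociality     = paste0("bnss", 5:6),
       avolition      = paste0("bnss", 7:8),
       blunted_affect = paste0("bnss", 9:11),
       alogia         = paste0("bnss", 12:13))
}

# Right-skewed default cut-points on the standard-normal latent: most mass
# on scores 0-3, matching a mild-to-moderate severity profile.
.default_thresholds <- function() c(-0.25, 0.5, 1.1, 1.7, 2.3, 2.9)

#' Configuration for the synthetic paired-panel generator
#'
#' Describes a latent multivariate-normal world with a planted
#' block-structured partial-correlation network: items within the same
#' domain (block) share partial correlation `within_weight`, items in
#' different domains share `between_weight`, the follow-up network equals
#' the baseline network scaled by `strength_scale_followup`, and each
#' subject's latent scores correlate `subject_dependence` across waves.
#' Latent values are discretized into 0-6 scores by per-item cut-points.
#'
#' @param n_subjects number of paired subjects (default 612).
#' @param item_labels ordered item names (default the 12 BNSS negative
#'   symptom items, item 4 excluded).
#' @param blocks named list partitioning `item_labels` into domains.
#' @param within_weight partial correlation inside a block, in (0, 1).
#' @param between_weight partial correlation between blocks, >= 0 and less
#'   than `within_weight`.
#' @param strength_scale_followup multiplicative factor on all true edge
#'   weights at follow-up, in (0, 1].
#' @param subject_dependence latent cross-wave correlation per subject, in
#'   `[0, 1)`.
#' @param thresholds numeric vector of 6 strictly increasing cut-points, or
#'   a p x 6 matrix (one row per item).
#' @param mean_shift_followup per-item latent mean change at follow-up
#'   (scalar recycled, or length-p vector).  Negative values lower item
#'   scores at follow-up.
#' @param block_pair_weights optional data frame with columns `block_a`,
#'   `block_b`, `weight` overriding `between_weight` for specific block
#'   pairs.
#' @param missing_rate fraction of scores set missing (default 0).
#' @param seed RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 612L,
                             item_labels = .default_item_labels(),
                             blocks = .default_blocks(),
                             within_weight = 0.3,
                             between_weight = 0.02,
                             strength_scale_followup = 0.9,
                             subject_dependence = 0.5,
                             thresholds = .default_thresholds(),
                             mean_shift_followup = -0.2,
                             block_pair_weights = NULL,
                             missing_rate = 0,
                             seed = NULL) {
  stopifnot(n_subjects >= 1, within_weight >= 0, within_weight < 1,
            between_weight >= 0, strength_scale_followup > 0,
            strength_scale_followup <= 1, missing_rate >= 0,
            missing_rate < 1)
  # within = between = 0 is the degenerate independence case; otherwise the
  # between-domain coupling must be strictly weaker than the within-domain
  # coupling
  if (between_weight > within_weight ||
      (within_weight > 0 && between_weight >= within_weight))
    stop("between_weight must be smaller than within_weight", call. = FALSE)
  if (subject_dependence < 0 || subject_dependence >= 1)
    stop("subject_dependence must lie in [0, 1)", call. = FALSE)
  p <- length(item_labels)
  blk_items <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(blk_items) || !setequal(blk_items, item_labels))
    stop("blocks must form a partition of item_labels", call. = FALSE)
  thresholds <- .expand_thresholds(thresholds, p, item_labels)
  mean_shift_followup <- rep_len(mean_shift_followup, p)
  if (!is.null(block_pair_weights)) {
    stopifnot(is.data.frame(block_pair_weights),
              all(c("block_a", "block_b", "weight") %in%
                    names(block_pair_weights)),
              all(block_pair_weights$block_a %in% names(blocks)),
              all(block_pair_weights$block_b %in% names(blocks)))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 item_labels = item_labels, blocks = blocks,
                 within_weight = within_weight,
                 between_weight = between_weight,
                 strength_scale_followup = strength_scale_followup,
                 subject_dependence = subject_dependence,
                 thresholds = thresholds,
                 mean_shift_followup = mean_shift_followup,
                 block_pair_weights = block_pair_weights,
                 missing_rate = missing_rate, seed = seed),
            class = "generator_config")
}

.expand_thresholds <- function(thresholds, p, item_labels) {
  if (is.numeric(thresholds) && is.null(dim(thresholds)))
    thresholds <- matrix(thresholds, nrow = p, ncol = length(thresholds),
                         byrow = TRUE)
  thresholds <- as.matrix(thresholds)
  if (ncol(thresholds) != 6L || nrow(thresholds) != p)
    stop("thresholds must provide exactly 6 cut-points per item",
         call. = FALSE)
  if (any(apply(thresholds, 1L, function(z) any(diff(z) <= 0))))
    stop("thresholds must be strictly increasing per item", call. = FALSE)
  rownames(thresholds) <- item_labels
  thresholds
}

#' Build the planted true networks and their latent correlation matrices
#'
#' The planted partial-correlation matrix P has `within_weight` inside
#' blocks and `between_weight` elsewhere; the implied precision matrix is
#' `I - P` (unit diagonal), whose inverse, standardized, gives the latent
#' correlation matrix.  The follow-up network is the baseline network scaled
#' element-wise by `strength_scale_followup`.
#'
#' @param config a [generator_config()].
#' @return An object of class `truth_bundle`: the two true [pc_network]s,
#'   the block partition, and the two latent correlation matrices.
#' @export
make_true_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  labels <- config$item_labels
  p <- length(labels)
  block_of <- setNames(rep(names(config$blocks),
                           lengths(config$blocks)),
                       unlist(config$blocks, use.names = FALSE))[labels]
  P <- matrix(config$between_weight, p, p, dimnames = list(labels, labels))
  if (!is.null(config$block_pair_weights)) {
    for (k in seq_len(nrow(config$block_pair_weights))) {
      ba <- config$block_pair_weights$block_a[k]
      bb <- config$block_pair_weights$block_b[k]
      w <- config$block_pair_weights$weight[k]
      ia <- which(block_of == ba); ib <- which(block_of == bb)
      P[ia, ib] <- w; P[ib, ia] <- w
    }
  }
  same <- outer(block_of, block_of, "==")
  P[same] <- config$within_weight
  diag(P) <- 0

  latent_from_pcor <- function(Pm, tag) {
    Theta <- diag(p) - Pm
    ev <- eigen(Theta, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8)
      stop(sprintf(paste0("implied precision matrix not positive definite ",
                          "(%s network; within_weight=%.3g, ",
                          "between_weight=%.3g)"), tag,
                   config$within_weight, config$between_weight),
           call. = FALSE)
    R <- stats::cov2cor(solve(Theta))
    dimnames(R) <- list(labels, labels)
    (R + t(R)) / 2
  }

  Pf <- config$strength_scale_followup * P
  structure(list(
    true_network_baseline = pc_network(P),
    true_network_followup = pc_network(Pf),
    true_partition = canonicalize(setNames(match(block_of,
                                                 names(config$blocks)),
                                           labels)),
    latent_correlation_baseline = latent_from_pcor(P, "baseline"),
    latent_correlation_followup = latent_from_pcor(Pf, "followup"),
    config = config), class = "truth_bundle")
}

# symmetric matrix square root
.sqrtm <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("latent correlation matrix is not positive definite", call. = FALSE)
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

.discretize <- function(X, thresholds) {
  out <- matrix(0L, nrow(X), ncol(X))
  for (j in seq_len(ncol(X)))
    out[, j] <- findInterval(X[, j], thresholds[j, ])
  out
}

#' Sample one wave of ordinal scores from a latent Gaussian
#'
#' Draws `n` latent vectors from `N(mean_shift, latent_corr)` and
#' discretizes each item by its cut-points into scores 0-6.
#'
#' @param latent_corr positive-definite correlation matrix.
#' @param n number of subjects.
#' @param thresholds 6 cut-points (vector) or p x 6 matrix.
#' @param mean_shift per-item latent mean offset (recycled).
#' @param seed RNG seed.
#' @param time_label wave label for the returned panel.
#' @param subject_ids optional identifiers.
#' @return An [item_panel].
#' @export
sample_ordinal_panel <- function(latent_corr, n, thresholds,
                                 mean_shift = 0, seed = NULL,
                                 time_label = "baseline",
                                 subject_ids = NULL) {
  latent_corr <- .assert_square_labeled(latent_corr, "latent_corr")
  p <- ncol(latent_corr)
  thresholds <- .expand_thresholds(thresholds, p, colnames(latent_corr))
  mean_shift <- rep_len(mean_shift, p)
  A <- .sqrtm(latent_corr) # errors if not PD
  .set_seed_if(seed)
  X <- matrix(rnorm(n * p), n, p) %*% A
  X <- sweep(X, 2L, mean_shift, "+")
  item_panel(.discretize(X, thresholds),
             subject_ids = subject_ids %||% sprintf("S%04d", seq_len(n)),
             item_labels = colnames(latent_corr), time_label = time_label)
}

#' Generate a paired baseline/follow-up panel with known ground truth
#'
#' Baseline and follow-up latents are drawn jointly: with `A`, `B` the
#' symmetric square roots of the two latent correlation matrices and `rho`
#' the subject dependence, `X_b = Z1 A` and
#' `X_f = (rho Z1 + sqrt(1 - rho^2) Z2) B + mean_shift`, so each wave has
#' its own planted network and subjects carry latent dependence across
#' waves.
#'
#' @param config a [generator_config()].
#' @return A list with elements `panel` (a [paired_panel]) and `truth`
#'   (a `truth_bundle`).
#' @export
make_paired_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  truth <- make_true_network(config)
  n <- config$n_subjects
  p <- length(config$item_labels)
  rho <- config$subject_dependence
  A <- .sqrtm(truth$latent_correlation_baseline)
  B <- .sqrtm(truth$latent_correlation_followup)
  .set_seed_if(config$seed)
  Z1 <- matrix(rnorm(n * p), n, p)
  Z2 <- matrix(rnorm(n * p), n, p)
  Xb <- Z1 %*% A
  Xf <- (rho * Z1 + sqrt(1 - rho^2) * Z2) %*% B
  Xf <- sweep(Xf, 2L, config$mean_shift_followup, "+")
  Sb <- .discretize(Xb, config$thresholds)
  Sf <- .discretize(Xf, config$thresholds)
  if (config$missing_rate > 0) {
    Sb[runif(length(Sb)) < config$missing_rate] <- NA_integer_
    Sf[runif(length(Sf)) < config$missing_rate] <- NA_integer_
  }
  ids <- sprintf("S%04d", seq_len(n))
  allow <- config$missing_rate > 0
  pb <- item_panel(Sb, ids, config$item_labels, "baseline", allow_na = allow)
  pf <- item_panel(Sf, ids, config$item_labels, "followup", allow_na = allow)
  list(panel = paired_panel(pb, pf), truth = truth)
}

#' Write a paired panel as a wide CSV
#'
#' Columns: `subject_id`, `time` (baseline/followup), then one integer
#' column per item.
#'
#' @param pair a [paired_panel] (or single [item_panel]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(pair, path) {
  one <- function(panel) {
    data.frame(subject_id = panel$subject_ids, time = panel$time_label,
               as.data.frame(panel$scores), check.names = FALSE,
               stringsAsFactors = FALSE)
  }
  df <- if (inherits(pair, "paired_panel"))
    rbind(one(pair$baseline), one(pair$followup)) else one(pair)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a truth bundle as JSON plus an edge-list TSV
#'
#' @param truth a `truth_bundle` from [make_true_network()].
#' @param json_path,edges_path output files.
#' @return `json_path`, invisibly.
#' @export
write_truth <- function(truth, json_path, edges_path = NULL) {
  W <- .network_weights(truth$true_network_baseline)
  obj <- list(
    item_labels = truth$config$item_labels,
    true_network_baseline = unname(apply(W, 1L, as.numeric, simplify = FALSE)),
    true_network_followup = unname(apply(
      .network_weights(truth$true_network_followup), 1L, as.numeric,
      simplify = FALSE)),
    true_partition = as.integer(truth$true_partition),
    latent_correlation_baseline = unname(apply(
      truth$latent_correlation_baseline, 1L, as.numeric, simplify = FALSE)),
    latent_correlation_followup = unname(apply(
      truth$latent_correlation_followup, 1L, as.numeric, simplify = FALSE)))
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(edges_path)) {
    ed <- .upper_pairs(truth$config$item_labels)
    ed$weight <- W[upper.tri(W)]
    write.table(ed, edges_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
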