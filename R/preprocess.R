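# Panel ingestion, item exclusion, nonparanormal transformation, and the
# correlation input to the network estimator.

.read_delim_auto <- function(path, delim = NULL) {
  if (is.null(delim)) {
    ext <- tolower(tools::file_ext(path))
    delim <- if (ext %in% c("tsv", "txt")) "\t" else ","
  }
  read.csv(path, sep = delim, na.strings = c("", "NA"),
           check.names = FALSE, stringsAsFactors = FALSE)
}

#' Load one wave of an item panel from a delimited file
#'
#' Expects a wide table with a `subject_id` column, optionally a `time`
#' column (rows are filtered to `time_label` when present), and one integer
#' column per item with scores in `[0, 6]`.  Rows with any missing item are
#' dropped (listwise deletion) and the count is reported.
#'
#' @param path CSV/TSV file; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `delim` is given.
#' @param time_label `"baseline"` or `"followup"`.
#' @param delim optional field delimiter override.
#' @return An [item_panel].
#' @export
load_panel <- function(path, time_label = c("baseline", "followup"),
                       delim = NULL) {
  time_label <- match.arg(time_label)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- .read_delim_auto(path, delim)
  if (!"subject_id" %in% names(df))
    stop("input must contain a 'subject_id' column", call. = FALSE)
  if ("time" %in% names(df)) {
    df <- df[df$time == time_label, , drop = FALSE]
    if (nrow(df) == 0L)
      stop("no rows with time == '", time_label, "'", call. = FALSE)
  }
  item_cols <- setdiff(names(df), c("subject_id", "time"))
  if (length(item_cols) == 0L) stop("no item columns found", call. = FALSE)
  scores <- as.matrix(df[, item_cols, drop = FALSE])
  suppressWarnings(storage.mode(scores) <- "double")
  nonint <- which(!is.na(scores) & scores != round(scores), arr.ind = TRUE)
  if (nrow(nonint) > 0L)
    stop(sprintf("non-integer score at row %d, column '%s'",
                 nonint[1L, 1L], item_cols[nonint[1L, 2L]]), call. = FALSE)
  bad <- which(!is.na(scores) & (scores < 0 | scores > 6), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("score out of range [0, 6] at row %d, column '%s'",
                 bad[1L, 1L], item_cols[bad[1L, 2L]]), call. = FALSE)
  keep <- stats::complete.cases(scores)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(sprintf("load_panel: dropped %d of %d rows with missing items",
                    dropped, nrow(scores)))
  item_panel(scores[keep, , drop = FALSE],
             subject_ids = df$subject_id[keep], item_labels = item_cols,
             time_label = time_label)
}

#' Load both waves and keep complete pairs
#'
#' Reads baseline and follow-up waves (from one file with a `time` column,
#' or two files) and intersects subjects so only complete cases across both
#' waves remain, in baseline order.
#'
#' @param path file containing the baseline wave (and, if `path_followup`
#'   is `NULL`, the follow-up wave via its `time` column).
#' @param path_followup optional second file for the follow-up wave.
#' @param delim optional delimiter override.
#' @return A [paired_panel].
#' @export
load_paired_panel <- function(path, path_followup = NULL, delim = NULL) {
  pb <- load_panel(path, "baseline", delim)
  pf <- load_panel(path_followup %||% path, "followup", delim)
  common <- intersect(pb$subject_ids, pf$subject_ids)
  lost <- length(union(pb$subject_ids, pf$subject_ids)) - length(common)
  if (lost > 0L)
    message(sprintf("load_paired_panel: %d subjects without complete data in both waves removed",
                    lost))
  if (length(common) == 0L)
    stop("no subjects present in both waves", call. = FALSE)
  sub <- function(panel) item_panel(
    panel$scores[match(common, panel$subject_ids), , drop = FALSE],
    subject_ids = common, item_labels = panel$item_labels,
    time_label = panel$time_label)
  paired_panel(sub(pb), sub(pf))
}

#' Drop items from a panel
#'
#' Removes the named item columns (e.g. a control item excluded from the
#' network analysis), preserving the order of the remaining items.
#'
#' @param panel an [item_panel] or [paired_panel].
#' @param drop character vector of item names to remove.
#' @return Panel of the same class without the dropped items.
#' @export
exclude_items <- function(panel, drop) {
  if (inherits(panel, "paired_panel"))
    return(paired_panel(exclude_items(panel$baseline, drop),
                        exclude_items(panel$followup, drop)))
  stopifnot(inherits(panel, "item_panel"))
  if (length(drop) == 0L) return(panel)
  unknown <- setdiff(drop, panel$item_labels)
  if (length(unknown) > 0L)
    stop("unknown item(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  keep <- setdiff(panel$item_labels, drop)
  item_panel(panel$scores[, keep, drop = FALSE],
             subject_ids = panel$subject_ids, item_labels = keep,
             time_label = panel$time_label)
}

# core transform on a plain numeric matrix (fast path for bootstraps)
.npn_matrix <- function(X) {
  n <- nrow(X)
  if (n < 10L) stop("nonparanormal transform needs n >= 10", call. = FALSE)
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  small_alphabet <- is.integer(X) && !anyNA(X) && min(X) >= 0L && max(X) <= 6L
  Z <- matrix(0, n, ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (small_alphabet) {
      # mid-ranks of 0-6 scores in O(n) via counts: for score s the average
      # rank is (#below) + (#tied + 1)/2
      tab <- tabulate(x + 1L, 7L)
      if (sum(tab > 0L) < 2L)
        stop("constant column: ", colnames(X)[j] %||% paste0("column ", j),
             " carries no network information", call. = FALSE)
      cum <- cumsum(tab)
      mid <- (cum - tab + (tab + 1) / 2) / n
      zlev <- qnorm(pmin(pmax(mid, delta), 1 - delta))
      z <- zlev[x + 1L]
    } else {
      if (length(unique(x)) < 2L)
        stop("constant column: ", colnames(X)[j] %||% paste0("column ", j),
             " carries no network information", call. = FALSE)
      u <- rank(x, ties.method = "average") / n
      z <- qnorm(pmin(pmax(u, delta), 1 - delta))
    }
    Z[, j] <- z / sd(z)
  }
  Z
}

#' Nonparanormal (rank-based Gaussianizing) transformation
#'
#' Maps each column through its Winsorized mid-rank empirical CDF composed
#' with the standard-normal quantile function: with `u_i = rank_i / n`
#' (average ranks for ties) truncated to `[delta_n, 1 - delta_n]`,
#' `delta_n = 1 / (4 n^{1/4} sqrt(pi log n))`, the transformed value is
#' `qnorm(u_i)`, rescaled to unit column standard deviation.  The transform
#' is monotone per column and assigns tied raw scores identical values.
#'
#' @param panel an [item_panel], or a numeric matrix.
#' @return A numeric matrix of class `npn_matrix` with attribute `source`.
#' @export
nonparanormal_transform <- function(panel) {
  X <- if (inherits(panel, "item_panel")) panel$scores else as.matrix(panel)
  Z <- .npn_matrix(X)
  structure(Z, class = c("npn_matrix", "matrix", "array"), source = panel)
}

#' Pearson correlation matrix of transformed columns
#'
#' Computes the p x p Pearson correlation of the (transformed) columns,
#' symmetrizes, and clips marginally negative eigenvalues to zero (with a
#' message) so the result is positive semi-definite within `1e-8`.
#'
#' @param t a matrix, typically from [nonparanormal_transform()].
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
panel_correlation <- function(t) {
  X <- as.matrix(t)
  if (nrow(X) < 3L) stop("need at least 3 complete rows", call. = FALSE)
  if (nrow(X) <= ncol(X))
    warning("n <= p: correlation matrix is singular; regularized estimation ",
            "is still possible", call. = FALSE)
  C <- cor(X)
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    e <- eigen(C, symmetric = TRUE)
    C <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    C <- stats::cov2cor((C + t(C)) / 2)
    dimnames(C) <- dimnames(cor(X))
    message("panel_correlation: clipped negative eigenvalues to restore PSD")
  }
  diag(C) <- 1
  C
}
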