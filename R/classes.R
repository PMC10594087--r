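# S3 containers: pc_network, item_panel, paired_panel

#' Construct a partial-correlation network
#'
#' A `pc_network` is a symmetric weighted adjacency matrix of partial
#' correlations with zero diagonal and entries in `[-1, 1]`.
#'
#' @param weights p x p symmetric numeric matrix; the diagonal is forced to
#'   zero.  Row/column names are the item labels.
#' @param item_labels optional character vector overriding the dimnames.
#' @return An object of class `pc_network` (a labeled matrix).
#' @export
pc_network <- function(weights, item_labels = NULL) {
  weights <- .assert_square_labeled(weights, "weights")
  if (!is.null(item_labels)) {
    stopifnot(length(item_labels) == nrow(weights))
    dimnames(weights) <- list(item_labels, item_labels)
  }
  if (max(abs(weights - t(weights))) > 1e-10)
    stop("network weights must be symmetric", call. = FALSE)
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (any(abs(weights) > 1 + 1e-8))
    stop("partial correlations must lie in [-1, 1]", call. = FALSE)
  structure(weights, class = c("pc_network", "matrix", "array"))
}

#' @export
print.pc_network <- function(x, ...) {
  p <- nrow(x)
  ne <- sum(x[upper.tri(x)] != 0)
  cat(sprintf("<pc_network> %d nodes, %d edges, global strength %.3f\n",
              p, ne, global_strength(x)))
  invisible(x)
}

.network_weights <- function(net) {
  w <- unclass(net)
  attr(w, "class") <- NULL
  w
}

.as_network <- function(x) {
  if (inherits(x, "pc_network")) x else pc_network(x)
}

#' Construct an item panel
#'
#' One wave of ordinal item responses: an n x p integer matrix of scores in
#' `[0, 6]` (NA allowed only at ingestion), with unique subject identifiers
#' and a wave label.
#'
#' @param scores integer matrix, rows = subjects, columns = items.
#' @param subject_ids character vector of unique identifiers.
#' @param item_labels character vector of item names.
#' @param time_label `"baseline"` or `"followup"`.
#' @param allow_na allow missing scores (ingestion only).
#' @return An object of class `item_panel`.
#' @export
item_panel <- function(scores, subject_ids = rownames(scores),
                       item_labels = colnames(scores),
                       time_label = c("baseline", "followup"),
                       allow_na = FALSE) {
  time_label <- match.arg(time_label)
  scores <- as.matrix(scores)
  if (is.null(subject_ids))
    subject_ids <- sprintf("S%04d", seq_len(nrow(scores)))
  if (is.null(item_labels))
    item_labels <- paste0("item", seq_len(ncol(scores)))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids))
    stop("duplicate subject_id: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(subject_ids) != nrow(scores) ||
      length(item_labels) != ncol(scores))
    stop("scores dimensions must match subject_ids x item_labels",
         call. = FALSE)
  storage.mode(scores) <- "integer"
  bad <- which(!is.na(scores) & (scores < 0L | scores > 6L), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("score out of range [0, 6] at row %d ('%s'), column '%s'",
                 bad[1L, 1L], subject_ids[bad[1L, 1L]],
                 item_labels[bad[1L, 2L]]), call. = FALSE)
  if (!allow_na && anyNA(scores))
    stop("missing scores not allowed after cleaning", call. = FALSE)
  dimnames(scores) <- list(subject_ids, item_labels)
  structure(list(scores = scores, subject_ids = subject_ids,
                 item_labels = item_labels, time_label = time_label),
            class = "item_panel")
}

#' @export
print.item_panel <- function(x, ...) {
  cat(sprintf("<item_panel> %s: %d subjects x %d items\n", x$time_label,
              length(x$subject_ids), length(x$item_labels)))
  invisible(x)
}

#' @export
dim.item_panel <- function(x) dim(x$scores)

#' Construct a paired panel
#'
#' Baseline and follow-up [item_panel]s on identical subjects and items, in
#' identical order (complete cases across both waves).
#'
#' @param baseline,followup [item_panel] objects.
#' @return An object of class `paired_panel`.
#' @export
paired_panel <- function(baseline, followup) {
  stopifnot(inherits(baseline, "item_panel"), inherits(followup, "item_panel"))
  if (!identical(baseline$item_labels, followup$item_labels))
    stop("item labels differ between waves", call. = FALSE)
  if (!identical(baseline$subject_ids, followup$subject_ids))
    stop("subject ids differ between waves (paired panels need complete ",
         "cases across both waves)", call. = FALSE)
  structure(list(baseline = baseline, followup = followup),
            class = "paired_panel")
}

#' @export
print.paired_panel <- function(x, ...) {
  cat(sprintf("<paired_panel> %d subjects x %d items (baseline + followup)\n",
              length(x$baseline$subject_ids), length(x$baseline$item_labels)))
  invisible(x)
}
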