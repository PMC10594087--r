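# shared validators, seed derivation, small helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific child seed from a master seed
#'
#' Deterministically maps a master seed and a stage name to an integer seed
#' below 2^31, so pipeline stages can be re-run independently yet
#' reproducibly.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(master)) %% 2147483647 * 48271 + h * 1009) %%
               2147483647)
}

.assert_square_labeled <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
  if (is.null(rownames(m)) && is.null(colnames(m))) {
    lab <- paste0("V", seq_len(nrow(m)))
    dimnames(m) <- list(lab, lab)
  } else if (is.null(rownames(m))) {
    rownames(m) <- colnames(m)
  } else if (is.null(colnames(m))) {
    colnames(m) <- rownames(m)
  }
  m
}

.upper_pairs <- function(labels) {
  p <- length(labels)
  if (p < 2L) return(data.frame(item_a = character(), item_b = character(),
                                stringsAsFactors = FALSE))
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  data.frame(item_a = labels[idx[, 1L]], item_b = labels[idx[, 2L]],
             stringsAsFactors = FALSE)
}

.set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
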