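# Sparse partial-correlation network estimation: L1-penalized Gaussian
# likelihood over a lambda path, model selection by the extended BIC.

#' Estimator settings
#'
#' @param gamma EBIC hyperparameter controlling sparsity (default 0.5).
#' @param n_lambdas number of penalty values on the log-spaced grid.
#' @param lambda_min_ratio smallest lambda as a fraction of
#'   `lambda_max = max off-diagonal |S|`.
#' @param tol convergence tolerance: maximum absolute parameter change
#'   between sweeps.
#' @param max_sweeps maximum block-coordinate sweeps per fit.
#' @param penalty `"ebicglasso"` (plain L1, the default) or `"adaptive"`
#'   (penalty weights `1/|theta_ij|` taken from the least-penalized plain
#'   fit on the same grid).
#' @return A list of class `estimator_settings`.
#' @export
estimator_settings <- function(gamma = 0.5, n_lambdas = 100L,
                               lambda_min_ratio = 0.01, tol = 1e-6,
                               max_sweeps = 500L,
                               penalty = c("ebicglasso", "adaptive")) {
  penalty <- match.arg(penalty)
  stopifnot(gamma >= 0, n_lambdas >= 1, lambda_min_ratio > 0,
            lambda_min_ratio <= 1, tol > 0, max_sweeps >= 1)
  structure(list(gamma = gamma, n_lambdas = as.integer(n_lambdas),
                 lambda_min_ratio = lambda_min_ratio, tol = tol,
                 max_sweeps = as.integer(max_sweeps), penalty = penalty),
            class = "estimator_settings")
}

.check_corr_input <- function(S) {
  S <- .assert_square_labeled(S, "S")
  if (max(abs(S - t(S))) > 1e-12)
    stop("S must be symmetric (tolerance 1e-12)", call. = FALSE)
  if (max(abs(diag(S) - 1)) > 1e-8)
    stop("S must have unit diagonal", call. = FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("S is not positive semi-definite", call. = FALSE)
  S
}

#' Graphical lasso fit at a single penalty
#'
#' Maximizes `log det(Theta) - trace(S Theta) - lambda * sum_{i != j}
#' |Theta_ij|` (diagonal unpenalized) by block coordinate descent.  With
#' `lambda = 0` the unpenalized maximum-likelihood solution `solve(S)` is
#' returned directly.
#'
#' @param S correlation matrix (symmetric, unit diagonal, PSD).
#' @param lam scalar penalty `lambda >= 0`, or a p x p matrix of per-entry
#'   penalties.
#' @param tol,max_sweeps convergence controls (see [estimator_settings()]).
#' @return The estimated precision matrix `Theta` (symmetric positive
#'   definite), with the partial-correlation network as attribute
#'   `"network"`.
#' @export
glasso_fit <- function(S, lam, tol = 1e-6, max_sweeps = 500L) {
  S <- .check_corr_input(S)
  p <- ncol(S)
  Lam <- if (is.matrix(lam)) lam else matrix(lam, p, p)
  if (any(Lam < 0)) stop("lambda must be nonnegative", call. = FALSE)
  fit <- .glasso_fit_cpp(S, Lam, tol, as.integer(max_sweeps))
  if (!fit$converged)
    stop(sprintf("glasso did not converge in %d sweeps (last change %.3g)",
                 max_sweeps, fit$last_change), call. = FALSE)
  Theta <- fit$theta
  dimnames(Theta) <- dimnames(S)
  net <- fit$pcor
  dimnames(net) <- dimnames(S)
  attr(Theta, "network") <- pc_network(net)
  Theta
}

#' Convert a precision matrix to a partial-correlation network
#'
#' `e_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)` for `i != j`, zero
#' diagonal.
#'
#' @param theta symmetric positive-definite precision matrix.
#' @return A [pc_network].
#' @export
precision_to_partialcorr <- function(theta) {
  theta <- .assert_square_labeled(theta, "theta")
  if (max(abs(theta - t(theta))) > 1e-8)
    stop("theta must be symmetric", call. = FALSE)
  if (any(diag(theta) <= 0))
    stop("theta must have positive diagonal", call. = FALSE)
  d <- sqrt(diag(theta))
  E <- -theta / outer(d, d)
  diag(E) <- 0
  E[abs(E) < 1e-10] <- 0
  pc_network(E)
}

#' Extended Bayesian information criterion
#'
#' `EBIC = -2 loglik + E log n + 4 gamma E log p`, where `E` is the number
#' of (undirected) edges in the model.
#'
#' @param loglik Gaussian log-likelihood of the fitted precision matrix.
#' @param n sample size.
#' @param p number of variables.
#' @param E number of edges.
#' @param gamma EBIC hyperparameter (0 gives the classical BIC penalty).
#' @return The EBIC score (smaller is better).
#' @export
ebic <- function(loglik, n, p, E, gamma = 0.5) {
  stopifnot(is.numeric(loglik), n >= 0, p >= 0, E >= 0, gamma >= 0)
  -2 * loglik + E * log(n) + 4 * gamma * E * log(p)
}

.lambda_grid <- function(S, n_lambdas, lambda_min_ratio) {
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax <= 0) lmax <- 1e-4 # no signal at all; any penalty gives empty
  if (n_lambdas == 1L) return(lmax)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambdas))
}

#' Estimate a sparse partial-correlation network over a penalty path
#'
#' Fits the graphical lasso along a log-spaced lambda grid running from
#' `lambda_max = max off-diagonal |S|` (empty network) down to
#' `lambda_max * lambda_min_ratio`, scores every model by EBIC with
#' hyperparameter `gamma`, and selects the minimizer.  With
#' `penalty = "adaptive"`, per-entry penalty weights `1/|theta_ij|` from
#' the least-penalized plain fit re-weight the path (zero entries get a
#' large finite weight).
#'
#' @param S correlation matrix.
#' @param n sample size behind `S`.
#' @param settings an [estimator_settings()].
#' @inheritParams estimator_settings
#' @return An object of class `regularization_path` with elements
#'   `lambdas`, `loglik`, `nedge`, `ebic`, `thetas` (p x p x L array),
#'   `selected_index`, `network` (the selected [pc_network]), `gamma`, `n`.
#' @export
estimate_network <- function(S, n, settings = NULL, gamma = 0.5,
                             n_lambdas = 100L, lambda_min_ratio = 0.01) {
  if (is.null(settings))
    settings <- estimator_settings(gamma = gamma, n_lambdas = n_lambdas,
                                   lambda_min_ratio = lambda_min_ratio)
  S <- .check_corr_input(S)
  p <- ncol(S)
  if (n < p)
    warning("n < p: estimates rely heavily on regularization", call. = FALSE)
  lambdas <- .lambda_grid(S, settings$n_lambdas, settings$lambda_min_ratio)
  weights <- matrix(1, p, p)
  if (settings$penalty == "adaptive") {
    base <- .glasso_path_cpp(S, n, min(lambdas), weights, settings$gamma,
                             settings$tol, settings$max_sweeps)
    th <- base$thetas[, , 1L]
    weights <- 1 / pmax(abs(th), 1e-10)
    weights <- pmin(weights, 1e10)
    weights <- weights / mean(weights[upper.tri(weights)])
    diag(weights) <- 0
  }
  fit <- .glasso_path_cpp(S, n, lambdas, weights, settings$gamma,
                          settings$tol, settings$max_sweeps)
  if (!any(fit$converged))
    stop("all penalized fits failed to converge", call. = FALSE)
  ok <- which(fit$converged)
  sel <- ok[which.min(fit$ebic[ok])]
  net <- fit$pcors[, , sel]
  dimnames(net) <- dimnames(S)
  structure(list(lambdas = fit$lambdas, loglik = fit$loglik,
                 nedge = as.integer(fit$nedge), ebic = fit$ebic,
                 thetas = fit$thetas, converged = fit$converged,
                 selected_index = sel, network = pc_network(net),
                 gamma = settings$gamma, n = n, settings = settings,
                 item_labels = colnames(S)),
            class = "regularization_path")
}

#' @export
print.regularization_path <- function(x, ...) {
  cat(sprintf(paste0("<regularization_path> %d lambdas, gamma = %.2f; ",
                     "selected lambda = %.4g with %d edges (EBIC %.1f)\n"),
              length(x$lambdas), x$gamma, x$lambdas[x$selected_index],
              x$nedge[x$selected_index], x$ebic[x$selected_index]))
  invisible(x)
}

# one-call pipeline on a raw score matrix: npn -> correlation -> selection.
# Fast path used by bootstraps and the permutation test.
.fit_network_scores <- function(scores, settings) {
  Z <- .npn_matrix(scores)
  S <- cor(Z)
  lambdas <- .lambda_grid(S, settings$n_lambdas, settings$lambda_min_ratio)
  p <- ncol(S)
  weights <- matrix(1, p, p)
  if (settings$penalty == "adaptive") {
    base <- .glasso_path_cpp(S, nrow(scores), min(lambdas), weights,
                             settings$gamma, settings$tol,
                             settings$max_sweeps)
    th <- base$thetas[, , 1L]
    weights <- pmin(1 / pmax(abs(th), 1e-10), 1e10)
    weights <- weights / mean(weights[upper.tri(weights)])
    diag(weights) <- 0
  }
  fit <- .glasso_path_cpp(S, nrow(scores), lambdas, weights, settings$gamma,
                          settings$tol, settings$max_sweeps)
  ok <- which(fit$converged)
  if (length(ok) == 0L) stop("estimator failed", call. = FALSE)
  sel <- ok[which.min(fit$ebic[ok])]
  W <- fit$pcors[, , sel]
  dimnames(W) <- dimnames(S)
  W
}

#' Estimate the selected network directly from an item panel
#'
#' Convenience wrapper running the full pipeline
#' `nonparanormal_transform -> panel_correlation -> estimate_network` and
#' returning the selected network.
#'
#' @param panel an [item_panel].
#' @param settings an [estimator_settings()].
#' @return A [pc_network].
#' @export
fit_panel_network <- function(panel, settings = estimator_settings()) {
  stopifnot(inherits(panel, "item_panel"))
  pc_network(.fit_network_scores(panel$scores, settings))
}

#' Write a network to square CSV, edge-list TSV and GraphML
#'
#' @param net a [pc_network].
#' @param csv_path,tsv_path,graphml_path output files (`NULL` to skip).
#' @return Invisibly, the vector of written paths.
#' @export
write_network_files <- function(net, csv_path = NULL, tsv_path = NULL,
                                graphml_path = NULL) {
  net <- .as_network(net)
  W <- .network_weights(net)
  written <- character()
  if (!is.null(csv_path)) {
    write.csv(as.data.frame(W), csv_path, row.names = TRUE, quote = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(tsv_path)) {
    ed <- .upper_pairs(colnames(W))
    ed$weight <- W[upper.tri(W)]
    ed <- ed[ed$weight != 0, , drop = FALSE]
    write.table(ed, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, tsv_path)
  }
  if (!is.null(graphml_path)) {
    g <- .network_igraph(net, use_abs = FALSE)
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}
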