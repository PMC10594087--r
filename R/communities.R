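# Signed spinglass community detection: Potts Hamiltonian with a signed
# configuration-model null, minimized by simulated annealing, repeated
# across seeds with canonical partition tallying.

# coupling matrix B_ij = (w+ - g+ p+) - (w- - g- p-), zero diagonal;
# H(sigma) = -sum_{i<j} B_ij * delta(sigma_i, sigma_j)
.signed_coupling <- function(net, gamma_pos = 1, gamma_neg = 1) {
  W <- .network_weights(.as_network(net))
  wp <- pmax(W, 0); wn <- pmax(-W, 0)
  diag(wp) <- 0; diag(wn) <- 0
  cfg <- function(w) {
    s <- rowSums(w); m2 <- sum(w)
    if (m2 > 0) outer(s, s) / m2 else matrix(0, nrow(w), ncol(w))
  }
  B <- (wp - gamma_pos * cfg(wp)) - (wn - gamma_neg * cfg(wn))
  diag(B) <- 0
  dimnames(B) <- dimnames(W)
  B
}

#' Signed Potts Hamiltonian of a partition
#'
#' With `w+`/`w-` the positive and negative parts of the edge weights and
#' `p+`/`p-` their configuration-model expectations
#' (`p_ij = s_i s_j / (2m)` from the positive/negative strengths), the
#' energy is
#' `H = -sum_{i<j} [(w+_ij - g+ p+_ij) - (w-_ij - g- p-_ij)] delta(s_i, s_j)`.
#' Lower is better; the all-singletons partition has H = 0.
#'
#' @param net a [pc_network].
#' @param partition integer community labels, one per node (named vectors
#'   are matched by name).
#' @param gamma_pos,gamma_neg resolution parameters for the positive and
#'   negative null models.
#' @return Scalar energy.
#' @export
hamiltonian <- function(net, partition, gamma_pos = 1, gamma_neg = 1) {
  net <- .as_network(net)
  p <- ncol(net)
  if (length(partition) != p)
    stop("partition length must equal the number of nodes", call. = FALSE)
  if (!is.null(names(partition))) {
    if (!setequal(names(partition), colnames(net)))
      stop("partition names do not match network labels", call. = FALSE)
    partition <- partition[colnames(net)]
  }
  B <- .signed_coupling(net, gamma_pos, gamma_neg)
  same <- outer(partition, partition, "==")
  -sum(B[upper.tri(B)][same[upper.tri(same)]])
}

#' Canonicalize a partition
#'
#' Relabels communities by order of first appearance over the node order:
#' the first node's community becomes 1, the next previously unseen
#' community becomes 2, and so on.  Idempotent; two labelings equal up to a
#' label permutation share one canonical form.
#'
#' @param partition integer (or factor/character) community labels.
#' @return Named integer vector of canonical labels.
#' @export
canonicalize <- function(partition) {
  lab <- as.character(partition)
  first <- unique(lab)
  out <- match(lab, first)
  names(out) <- names(partition)
  out
}

#' One spinglass community-detection run
#'
#' Simulated annealing over spin (community) assignments minimizing
#' [hamiltonian()]: single-node relabel proposals with Metropolis
#' acceptance under a geometric cooling schedule; the best partition seen
#' is returned in canonical form.
#'
#' @param net a [pc_network] with at least one nonzero edge.
#' @param seed integer seed for the annealer's own RNG (platform
#'   independent).
#' @param max_communities maximum number of spin states (default p).
#' @param t_start,t_stop,cooling annealing temperature schedule.
#' @param sweeps_per_temp sweeps (p proposals each) per temperature.
#' @param gamma_pos,gamma_neg resolution parameters.
#' @return Named integer vector (canonical partition) with attribute
#'   `"energy"`.
#' @export
spinglass_partition <- function(net, seed = 1L, max_communities = NULL,
                                t_start = 1.0, t_stop = 0.01,
                                cooling = 0.99, sweeps_per_temp = 50L,
                                gamma_pos = 1, gamma_neg = 1) {
  net <- .as_network(net)
  W <- .network_weights(net)
  if (all(W == 0))
    stop("community structure undefined for an empty network", call. = FALSE)
  p <- ncol(W)
  B <- .signed_coupling(net, gamma_pos, gamma_neg)
  res <- .spinglass_runs_cpp(B, 1L, as.integer(seed),
                             as.integer(max_communities %||% p),
                             t_start, t_stop, cooling,
                             as.integer(sweeps_per_temp))
  part <- setNames(as.integer(res$assign[1L, ]), colnames(W))
  attr(part, "energy") <- hamiltonian(net, part, gamma_pos, gamma_neg)
  part
}

#' Tally community structures over repeated stochastic runs
#'
#' Runs [spinglass_partition()] `n_runs` times with derived seeds,
#' canonicalizes every resulting partition, and tallies the frequency of
#' each distinct structure (descending).
#'
#' @inheritParams spinglass_partition
#' @param n_runs number of stochastic runs (the reference workflow uses
#'   10000).
#' @return An object of class `community_tally`: `partitions` (list of
#'   named canonical assignments), `frequencies`, `energies` (exact
#'   Hamiltonian per partition), `counts`, `n_runs`, `seed`.
#' @export
community_tally <- function(net, n_runs = 10000L, seed = 1L,
                            max_communities = NULL, t_start = 1.0,
                            t_stop = 0.01, cooling = 0.99,
                            sweeps_per_temp = 50L, gamma_pos = 1,
                            gamma_neg = 1) {
  stopifnot(n_runs >= 1)
  net <- .as_network(net)
  W <- .network_weights(net)
  if (all(W == 0))
    stop("community structure undefined for an empty network", call. = FALSE)
  p <- ncol(W)
  B <- .signed_coupling(net, gamma_pos, gamma_neg)
  res <- .spinglass_runs_cpp(B, as.integer(n_runs), as.integer(seed),
                             as.integer(max_communities %||% p),
                             t_start, t_stop, cooling,
                             as.integer(sweeps_per_temp))
  keys <- apply(res$assign, 1L, paste, collapse = "-")
  tab <- sort(table(keys), decreasing = TRUE)
  parts <- lapply(names(tab), function(k)
    setNames(as.integer(strsplit(k, "-", fixed = TRUE)[[1L]]), colnames(W)))
  energies <- vapply(parts, function(pt)
    hamiltonian(net, pt, gamma_pos, gamma_neg), numeric(1))
  structure(list(partitions = parts,
                 frequencies = as.numeric(tab) / n_runs,
                 counts = as.integer(tab), energies = energies,
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 item_labels = colnames(W)),
            class = "community_tally")
}

#' @export
print.community_tally <- function(x, ...) {
  cat(sprintf("<community_tally> %d runs, %d distinct structures\n",
              x$n_runs, length(x$partitions)))
  k <- min(5L, length(x$partitions))
  for (i in seq_len(k))
    cat(sprintf("  %5.1f%%  %s communities (H = %.4f)\n",
                100 * x$frequencies[i], max(x$partitions[[i]]),
                x$energies[i]))
  invisible(x)
}

#' Frequency with which two item sets merge into one community
#'
#' @param tally a [community_tally()].
#' @param items_a,items_b disjoint character vectors of item names.
#' @return Fraction of runs in which every item of `items_a` and `items_b`
#'   shares a single community.
#' @export
domain_merge_frequency <- function(tally, items_a, items_b) {
  stopifnot(inherits(tally, "community_tally"))
  if (length(intersect(items_a, items_b)) > 0)
    stop("item sets must be disjoint", call. = FALSE)
  unknown <- setdiff(c(items_a, items_b), tally$item_labels)
  if (length(unknown) > 0)
    stop("unknown item(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  both <- c(items_a, items_b)
  merged <- vapply(tally$partitions, function(pt)
    length(unique(pt[both])) == 1L, logical(1))
  sum(tally$frequencies[merged])
}
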