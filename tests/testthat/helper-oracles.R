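# Independent oracles used to validate the package implementations.
# These deliberately use different algorithms than the package code:
# proximal-gradient (FISTA) maximization for the penalized likelihood,
# exhaustive simple-path enumeration for shortest-path centralities, and
# exhaustive set-partition enumeration for the spinglass energy optimum.

# penalized objective: log det(Theta) - tr(S Theta) - lam * sum_{i!=j} |Theta_ij|
penalized_objective <- function(Theta, S, lam) {
  ld <- determinant(Theta, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  off <- Theta
  diag(off) <- 0
  as.numeric(ld$modulus) - sum(S * Theta) - lam * sum(abs(off))
}

# FISTA maximizer of the penalized objective (proximal gradient with
# backtracking and adaptive restart); diagonal unpenalized.
oracle_glasso <- function(S, lam, iters = 20000, tol = 1e-10) {
  p <- ncol(S)
  Theta <- diag(1 / diag(S), p)
  Y <- Theta
  t_k <- 1
  step <- 1
  obj_old <- penalized_objective(Theta, S, lam)
  prox <- function(M, thr) {
    off <- sign(M) * pmax(abs(M) - thr, 0)
    diag(off) <- diag(M)
    off
  }
  for (i in seq_len(iters)) {
    G <- solve(Y) - S # gradient of the smooth part (ascent direction)
    repeat {
      cand <- prox(Y + step * G, step * lam)
      ev_ok <- min(eigen(cand, symmetric = TRUE,
                         only.values = TRUE)$values) > 1e-12
      if (ev_ok) {
        # backtracking on the smooth part (majorization check)
        diffm <- cand - Y
        lhs <- -(determinant(cand)$modulus) + sum(S * cand)
        rhs <- -(determinant(Y)$modulus) + sum(S * Y) - sum(G * diffm) +
          sum(diffm^2) / (2 * step)
        if (lhs <= rhs + 1e-12) break
      }
      step <- step / 2
      if (step < 1e-12) break
    }
    Theta_new <- cand
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    Y <- Theta_new + ((t_k - 1) / t_new) * (Theta_new - Theta)
    obj_new <- penalized_objective(Theta_new, S, lam)
    if (obj_new < obj_old) { # restart momentum on objective decrease
      Y <- Theta_new
      t_new <- 1
    }
    if (max(abs(Theta_new - Theta)) < tol && i > 10) {
      Theta <- Theta_new
      break
    }
    Theta <- Theta_new
    t_k <- t_new
    obj_old <- max(obj_old, obj_new)
  }
  Theta
}

# random correlation matrix (PD, unit diagonal)
random_corr <- function(p) {
  A <- matrix(rnorm(p * (p + 2)), p + 2, p)
  stats::cov2cor(crossprod(A) / (p + 2))
}

# --- exhaustive shortest-path centralities for small weighted networks ----
# edge lengths 1/|w|; returns distances, closeness (0 when disconnected),
# fractional betweenness.
oracle_centrality <- function(W, tie_tol = 1e-9) {
  p <- ncol(W)
  len <- 1 / abs(W)
  len[W == 0] <- Inf
  dist <- matrix(Inf, p, p)
  diag(dist) <- 0
  btw <- numeric(p)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(v, visited, d) {
      if (v == t) {
        out[[length(out) + 1L]] <<- list(d = d, via = setdiff(visited, c(s, t)))
        return(invisible(NULL))
      }
      for (u in seq_len(p)) {
        if (u %in% visited || !is.finite(len[v, u])) next
        walk(u, c(visited, u), d + len[v, u])
      }
    }
    walk(s, s, 0)
    out
  }
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    ps <- paths_between(s, t)
    if (length(ps) == 0) next
    ds <- vapply(ps, `[[`, numeric(1), "d")
    dmin <- min(ds)
    dist[s, t] <- dist[t, s] <- dmin
    short <- ps[ds <= dmin + tie_tol]
    sigma <- length(short)
    for (sp in short)
      for (v in sp$via) btw[v] <- btw[v] + 1 / sigma
  }
  tot <- rowSums(dist)
  clo <- ifelse(is.finite(tot) & tot > 0, 1 / tot, 0)
  if (p == 1) clo <- 0
  list(dist = dist, closeness = clo, betweenness = btw)
}

# --- all set partitions of p elements (restricted growth strings) ---------
all_partitions <- function(p) {
  out <- list()
  grow <- function(a, mx) {
    i <- length(a) + 1L
    if (i > p) {
      out[[length(out) + 1L]] <<- a
      return(invisible(NULL))
    }
    for (k in seq_len(mx + 1L)) grow(c(a, k), max(mx, k))
  }
  grow(integer(), 0L)
  out
}

# exhaustive minimum of the signed Potts Hamiltonian
oracle_best_partition <- function(net, gamma_pos = 1, gamma_neg = 1) {
  p <- ncol(net)
  parts <- all_partitions(p)
  energies <- vapply(parts, function(pt)
    hamiltonian(net, setNames(pt, colnames(net)), gamma_pos, gamma_neg),
    numeric(1))
  k <- which.min(energies)
  list(partition = parts[[k]], energy = energies[k], all = energies)
}

# --- tetrachoric correlation oracle ---------------------------------------
# consistent latent-correlation estimate for ordinal pairs from a latent
# bivariate normal: dichotomize near the median, then solve
# Phi2(h, k, r) = P(X <= c, Y <= c) for r.
phi2 <- function(h, k, r) {
  if (abs(r) < 1e-12) return(pnorm(h) * pnorm(k))
  f <- function(t) dnorm(t) * pnorm((k - r * t) / sqrt(1 - r^2))
  stats::integrate(f, -Inf, h, rel.tol = 1e-9)$value
}

oracle_tetrachoric <- function(x, y) {
  cuts <- sort(unique(x))
  c1 <- cuts[which.min(abs(vapply(cuts, function(c) mean(x <= c),
                                  numeric(1)) - 0.5))]
  cuts2 <- sort(unique(y))
  c2 <- cuts2[which.min(abs(vapply(cuts2, function(c) mean(y <= c),
                                   numeric(1)) - 0.5))]
  h <- qnorm(mean(x <= c1))
  k <- qnorm(mean(y <= c2))
  p00 <- mean(x <= c1 & y <= c2)
  stats::uniroot(function(r) phi2(h, k, r) - p00, c(-0.99, 0.99),
                 tol = 1e-8)$root
}

# small helper: random signed network with zero diagonal
random_signed_network <- function(p, density = 0.7, wmax = 0.6) {
  W <- matrix(0, p, p)
  ut <- upper.tri(W)
  ne <- sum(ut)
  w <- runif(ne, -wmax, wmax) * (runif(ne) < density)
  W[ut] <- w
  W <- W + t(W)
  lab <- paste0("V", seq_len(p))
  dimnames(W) <- list(lab, lab)
  pc_network(W)
}

# default small estimator settings to keep permutation loops quick in tests
fast_settings <- function() estimator_settings(n_lambdas = 25L)

# planted-panel shorthand
planted_panel <- function(n = 612, seed = 1, ...) {
  make_paired_panel(generator_config(n_subjects = n, seed = seed, ...))
}
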