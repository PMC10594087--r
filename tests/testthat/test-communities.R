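# signed spinglass community detection and partition tallying

two_clique_net <- function(w_within = 0.4, bridge = 0.01) {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- w_within
  W[5:8, 5:8] <- w_within
  diag(W) <- 0
  W[4, 5] <- W[5, 4] <- bridge
  lab <- paste0("n", 1:8)
  dimnames(W) <- list(lab, lab)
  pc_network(W)
}

test_that("hamiltonian obeys its closed-form reductions", {
  net <- random_signed_network(5)
  # all-singletons partition: no co-membership, zero energy
  expect_equal(hamiltonian(net, 1:5), 0)

  # single positive edge, endpoints together, gamma+ = 0: H = -w
  W <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  W[1, 2] <- W[2, 1] <- 0.7
  net2 <- pc_network(W)
  expect_equal(hamiltonian(net2, c(1, 1, 2), gamma_pos = 0), -0.7)
  # with the endpoints apart the edge contributes nothing
  expect_equal(hamiltonian(net2, c(1, 2, 3), gamma_pos = 0), 0)

  expect_error(hamiltonian(net, 1:4), "length")
  expect_error(hamiltonian(net, setNames(1:5, paste0("z", 1:5))), "names")
})

test_that("canonicalize relabels by first appearance and is idempotent", {
  expect_equal(unname(canonicalize(c(2, 2, 1, 3))), c(1, 1, 2, 3))
  expect_equal(unname(canonicalize(c(1, 1, 2, 3))), c(1, 1, 2, 3))
  set.seed(1)
  for (i in 1:20) {
    a <- sample(1:4, 7, replace = TRUE)
    relab <- sample(10:13)[a] # consistent label permutation
    expect_equal(canonicalize(a), canonicalize(relab))
    expect_equal(canonicalize(canonicalize(a)), canonicalize(a))
  }
})

test_that("annealer finds planted structures", {
  # two positive cliques joined by a weak bridge
  net <- two_clique_net()
  hits <- 0
  for (s in 1:100) {
    pt <- spinglass_partition(net, seed = s)
    hits <- hits + identical(as.integer(pt), rep(c(1L, 2L), each = 4L))
  }
  expect_gte(hits, 95)

  # a single all-positive clique stays together
  U <- matrix(0.4, 5, 5)
  diag(U) <- 0
  dimnames(U) <- list(paste0("c", 1:5), paste0("c", 1:5))
  pt <- spinglass_partition(pc_network(U), seed = 1)
  expect_equal(as.integer(pt), rep(1L, 5))

  # positive within, negative between: the two blocks
  W <- matrix(-0.2, 6, 6)
  W[1:3, 1:3] <- 0.4
  W[4:6, 4:6] <- 0.4
  diag(W) <- 0
  dimnames(W) <- list(paste0("s", 1:6), paste0("s", 1:6))
  signed <- pc_network(W)
  hits2 <- 0
  for (s in 1:100) {
    pt <- spinglass_partition(signed, seed = s)
    hits2 <- hits2 + identical(as.integer(pt), rep(c(1L, 2L), each = 3L))
  }
  expect_gte(hits2, 99)

  expect_error(spinglass_partition(pc_network(matrix(0, 3, 3))), "empty")
})

test_that("best annealed energy matches exhaustive enumeration on small nets", {
  set.seed(2)
  ok <- 0
  for (i in 1:20) {
    net <- random_signed_network(sample(4:6, 1))
    or <- oracle_best_partition(net)
    best <- min(vapply(1:20, function(s)
      attr(spinglass_partition(net, seed = s), "energy"), numeric(1)))
    ok <- ok + (best <= or$energy + 1e-9)
  }
  expect_gte(ok, 19)
})

test_that("community_tally counts canonical structures with exact frequencies", {
  net <- two_clique_net(w_within = 0.5, bridge = 0.001)
  tal <- community_tally(net, n_runs = 100, seed = 3)
  expect_equal(sum(tal$frequencies), 1, tolerance = 1e-12)
  expect_equal(sum(tal$counts), 100L)
  # deterministic toy structure: a single entry at frequency 1
  expect_equal(length(tal$partitions), 1L)
  expect_equal(tal$frequencies[1], 1)
  # energies recomputed exactly for each tallied partition
  expect_equal(tal$energies[1], hamiltonian(net, tal$partitions[[1]]))
  # bit-for-bit reproducibility
  tal2 <- community_tally(net, n_runs = 100, seed = 3)
  expect_identical(serialize(tal, NULL), serialize(tal2, NULL))
})

test_that("tallying is invariant to consistent node relabeling", {
  net <- two_clique_net(w_within = 0.45, bridge = 0.02)
  tal <- community_tally(net, n_runs = 50, seed = 4)
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  W <- unclass(net)[perm, perm]
  talp <- community_tally(pc_network(W), n_runs = 50, seed = 4)
  expect_equal(sort(talp$frequencies), sort(tal$frequencies))
})

test_that("domain_merge_frequency weights partitions correctly", {
  net <- two_clique_net()
  tal <- community_tally(net, n_runs = 20, seed = 5)
  # the cliques are always separate communities here
  expect_equal(domain_merge_frequency(tal, paste0("n", 1:4), paste0("n", 5:8)),
               0)
  # within one clique everything is merged
  expect_equal(domain_merge_frequency(tal, c("n1", "n2"), c("n3", "n4")), 1)
  # constructed mixed tally: 60/40 split
  fake <- tal
  fake$partitions <- list(
    setNames(rep(1L, 8), paste0("n", 1:8)),
    setNames(rep(c(1L, 2L), each = 4L), paste0("n", 1:8)))
  fake$frequencies <- c(0.6, 0.4)
  expect_equal(domain_merge_frequency(fake, paste0("n", 1:4),
                                      paste0("n", 5:8)), 0.6)
  expect_error(domain_merge_frequency(tal, "n1", "n1"), "disjoint")
  expect_error(domain_merge_frequency(tal, "n1", "zz"), "unknown")
})
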