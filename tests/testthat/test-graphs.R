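test_that("correlation matrix matches the direct Pearson formula", {
  B <- matrix(c(1, 2, 3, 4, 5,
                2, 1, 4, 3, 6,
                5, 4, 3, 2, 1), 3, byrow = TRUE)
  g <- correlation_matrix(as_betas(B))
  # brute-force covariance / (sigma sigma)
  for (i in 1:3) for (j in 1:3) {
    expected <- if (i == j) 0 else {
      xi <- B[i, ] - mean(B[i, ]); xj <- B[j, ] - mean(B[j, ])
      sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
    expect_equal(g$W[i, j], expected, tolerance = 1e-12)
  }
  expect_equal(g$n_trials, 5)
})

test_that("perfectly (anti)correlated series hit the bounds", {
  x <- rnorm(10)
  g <- correlation_matrix(as_betas(rbind(x, 2 * x + 1, -x)))
  expect_equal(g$W[1, 2], 1)
  expect_equal(g$W[1, 3], -1)
})

test_that("degenerate inputs to correlation_matrix are rejected", {
  expect_error(correlation_matrix(as_betas(matrix(1:4, 2))), "3 trials")
  B <- rbind(rnorm(6), rep(1, 6))
  expect_error(correlation_matrix(as_betas(B)), "zero-variance")
  expect_error(correlation_matrix(as_betas(matrix(rnorm(30), 10)),
                                  max_nodes = 5), "budget")
})

test_that("FDR thresholding implements the BH step-up over unique edges", {
  # 4 nodes, 6 unique edges with chosen p-values; survivors must match an
  # independent enumeration of the step-up rule
  n_tr <- 50
  p_want <- c(0.001, 0.02, 0.04, 0.8, 0.95, 0.99)
  r_want <- r_for_p(p_want, n_tr)
  W <- matrix(0, 4, 4)
  W[1, 2] <- r_want[1]; W[3, 4] <- r_want[2]; W[1, 3] <- r_want[3]
  W[2, 4] <- r_want[4]; W[1, 4] <- r_want[5]; W[2, 3] <- r_want[6]
  W <- W + t(W)
  g <- threshold_fdr(as_graph(W, n_trials = n_tr), q = 0.05)
  surv_oracle <- bh_survivors_oracle(p_want, 0.05)
  expect_equal(g$threshold$n_edges_kept, sum(surv_oracle))
  expect_true((g$W[1, 2] > 0) == surv_oracle[1])
  expect_true((g$W[3, 4] > 0) == surv_oracle[2])
  expect_true((g$W[2, 4] > 0) == surv_oracle[4])
})

test_that("extreme graphs threshold to everything or nothing", {
  W1 <- matrix(0.999, 5, 5); diag(W1) <- 0
  g1 <- threshold_fdr(as_graph(W1, 50))
  expect_equal(g1$threshold$n_edges_kept, 10)
  W2 <- -W1
  expect_warning(g2 <- threshold_fdr(as_graph(W2, 50)), "no edges survive")
  expect_true(all(g2$W == 0))
  expect_error(threshold_fdr(as_graph(W1, 3)), "n_trials")
})

test_that("thresholding is monotone in q", {
  set.seed(12)
  B <- matrix(rnorm(20 * 30), 20)
  g <- correlation_matrix(as_betas(B))
  s1 <- suppressWarnings(threshold_fdr(g, 0.01))$W > 0
  s5 <- suppressWarnings(threshold_fdr(g, 0.05))$W > 0
  expect_true(all(s5[s1]))
})

test_that("parcel averaging is the unweighted member mean", {
  # one voxel per parcel: identity
  B <- matrix(rnorm(3 * 6), 3)
  parc1 <- array(c(2L, 1L, 3L), dim = c(3, 1, 1))
  out1 <- parcel_average(as_betas(B), parc1)
  expect_equal(out1$betas[1, ], B[2, ])
  expect_equal(out1$betas[3, ], B[3, ])
  # two voxels: (a + b) / 2
  parc2 <- array(c(1L, 1L, 2L), dim = c(3, 1, 1))
  out2 <- parcel_average(as_betas(B), parc2)
  expect_equal(out2$betas[1, ], (B[1, ] + B[2, ]) / 2)
  # empty parcel rejected
  parc3 <- array(c(1L, 1L, 3L), dim = c(3, 1, 1))
  expect_error(parcel_average(as_betas(B), parc3), "empty parcel")
})

test_that("two disconnected triangles split into two modules with Q = 0.5", {
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 3] <- W[1, 3] <- W[4, 5] <- W[5, 6] <- W[4, 6] <- 1
  W <- W + t(W)
  part <- louvain_partition(W, n_restarts = 20, rng_seed = 1)
  expect_equal(max(part$membership), 2)
  expect_equal(part$Q, 0.5, tolerance = 1e-12)
  expect_equal(part$membership[1:3], rep(part$membership[1], 3))
})

test_that("a single clique is one module with Q = 0", {
  W <- matrix(1, 4, 4); diag(W) <- 0
  part <- louvain_partition(W, n_restarts = 10, rng_seed = 2)
  expect_equal(max(part$membership), 1)
  expect_equal(part$Q, 0, tolerance = 1e-12)
})

test_that("modularity matches brute-force and igraph evaluations", {
  set.seed(14)
  for (rep in 1:5) {
    W <- random_weighted_graph(12)
    memb <- sample(3, 12, replace = TRUE)
    expect_equal(modularity_q(W, memb), modularity_oracle(W, memb),
                 tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    expect_equal(modularity_q(W, memb),
                 igraph::modularity(g, memb,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-10)
    # gamma sweep against the brute-force oracle
    expect_equal(modularity_q(W, memb, gamma = 1.5),
                 modularity_oracle(W, memb, gamma = 1.5), tolerance = 1e-12)
  }
})

test_that("louvain recovers planted assortative block structure", {
  set.seed(30)
  planted <- rep(1:4, each = 12)
  nmi <- vapply(1:20, function(i) {
    P <- ifelse(outer(planted, planted, "=="), 0.8, 0.05)
    W <- matrix(0, 48, 48)
    ut <- upper.tri(W)
    W[ut] <- as.numeric(runif(sum(ut)) < P[ut])
    W <- W + t(W)
    part <- louvain_partition(W, n_restarts = 10, rng_seed = i)
    igraph::compare(part$membership, planted, method = "nmi")
  }, numeric(1))
  expect_gte(mean(nmi), 0.9)
})

test_that("louvain is deterministic, validates input and beats one module", {
  set.seed(31)
  W <- random_weighted_graph(15)
  p1 <- louvain_partition(W, n_restarts = 5, rng_seed = 3)
  p2 <- louvain_partition(W, n_restarts = 5, rng_seed = 3)
  expect_identical(p1$membership, p2$membership)
  expect_gte(p1$Q, 0)  # never below the single-module baseline
  expect_error(louvain_partition(matrix(0, 3, 3)), "no edges")
  expect_error(louvain_partition(matrix(c(0, -1, -1, 0), 2)), "non-negative")
})

test_that("module propagation assigns each voxel its parcel's module", {
  parc <- array(c(1L, 1L, 1L, 2L, 2L), dim = c(5, 1, 1))
  expect_equal(propagate_modules(c(1L, 2L), parc), c(1, 1, 1, 2, 2))
  expect_equal(propagate_modules(c(1L, 1L), parc), rep(1, 5))
  # relabelling invariance: permute parcel ids with matching permutation
  parc_perm <- array(c(2L, 2L, 2L, 1L, 1L), dim = c(5, 1, 1))
  expect_equal(propagate_modules(c(2L, 1L), parc_perm),
               propagate_modules(c(1L, 2L), parc))
  expect_error(propagate_modules(c(1L), parc), "cover")
})

test_that("participation coefficient matches direct summation examples", {
  # provincial node: all edges inside its own module
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[1, 3] <- W[2, 3] <- 0.7
  W <- W + t(W)
  pc <- participation_coefficient(W, c(1, 1, 1, 2))
  expect_equal(pc[1], 0)
  # unit edges split 2 in-module / 2 to one other module -> 0.5
  W2 <- matrix(0, 5, 5)
  W2[1, 2] <- W2[1, 3] <- W2[1, 4] <- W2[1, 5] <- 1
  W2 <- W2 + t(W2)
  pc2 <- participation_coefficient(W2, c(1, 1, 1, 2, 2))
  expect_equal(pc2[1], 0.5)
  # weighted: strength 3 in-module, 1 to another module -> 0.375
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- 3; W3[1, 3] <- 1
  W3 <- W3 + t(W3)
  pc3 <- participation_coefficient(W3, c(1, 1, 2))
  expect_equal(pc3[1], 1 - (0.75^2 + 0.25^2))
})

test_that("participation coefficient agrees with brute force on random graphs", {
  set.seed(40)
  for (rep in 1:200) {
    n <- sample(3:50, 1)
    W <- random_weighted_graph(n)
    labels <- sample(sample(4, 1), n, replace = TRUE)
    expect_equal(as.numeric(participation_coefficient(W, labels)),
                 pc_oracle(W, labels), tolerance = 1e-12)
  }
})

test_that("participation coefficient invariances and bounds hold", {
  set.seed(41)
  W <- random_weighted_graph(20)
  labels <- sample(3, 20, replace = TRUE)
  pc <- participation_coefficient(W, labels)
  # scale invariance
  expect_equal(as.numeric(participation_coefficient(5.5 * W, labels)),
               as.numeric(pc), tolerance = 1e-12)
  # upper bound 1 - 1/M
  expect_true(all(pc <= 1 - 1 / 3 + 1e-12))
  # zero-strength node convention
  W0 <- W; W0[1, ] <- 0; W0[, 1] <- 0
  expect_equal(participation_coefficient(W0, labels)[1], 0)
  # moving an in-module edge to a previously unconnected module raises PC
  for (rep in 1:20) {
    n <- 8
    Wr <- matrix(0, n, n)
    lab <- c(1, 1, 1, 2, 2, 2, 3, 3)
    Wr[1, 2] <- Wr[1, 3] <- 1   # node 1: in-module edges only
    Wr[4, 5] <- 1
    Wr <- Wr + t(Wr)
    Wm <- Wr
    Wm[1, 3] <- Wm[3, 1] <- 0
    Wm[1, 7] <- Wm[7, 1] <- 1   # move one edge to module 3
    expect_gt(pc_oracle(Wm, lab)[1], pc_oracle(Wr, lab)[1])
    expect_equal(participation_coefficient(Wm, lab)[1], pc_oracle(Wm, lab)[1])
  }
})
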