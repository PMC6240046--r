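make_null_map <- function(n = 12, grid = c(8, 8, 8), seed = 1, smooth = NULL) {
  set.seed(seed)
  D <- matrix(rnorm(n * prod(grid)), n)
  if (!is.null(smooth)) D <- D %*% smooth
  paired_t_map(D, matrix(0, n, prod(grid)), grid = grid)
}

test_that("sub-threshold maps give an empty cluster table", {
  m <- make_null_map(seed = 2)
  m$z <- m$z * 0.01
  res <- cluster_inference(m, z_threshold = 2.33, n_perm = 100, rng_seed = 1)
  expect_equal(nrow(res), 0)
})

test_that("clusters are maximal face-connected components", {
  grid <- c(5, 5, 5)
  z <- rep(0, prod(grid))
  blobA <- c(ind3(1, 1, 1, grid), ind3(2, 1, 1, grid), ind3(2, 2, 1, grid))
  blobB <- c(ind3(4, 4, 4, grid), ind3(5, 5, 5, grid))  # diagonal: separate at 6-conn
  z[blobA] <- c(3, 4, 3.5)
  z[blobB] <- c(3, 3.2)
  m <- make_null_map(grid = grid, seed = 3)
  m$z <- z
  m$perm <- NULL
  res <- cluster_inference(m, z_threshold = 2.33, method = "grf", fwhm = 2)
  expect_equal(nrow(res), 3)
  expect_equal(sort(res$extent), c(1, 1, 3))
  expect_equal(res$extent[1], 3)
  expect_equal(res$peak_stat[1], 4)
  expect_equal(res$peak_index[1], ind3(2, 1, 1, grid))
  # with corner connectivity the diagonal pair merges
  res26 <- cluster_inference(m, z_threshold = 2.33, method = "grf", fwhm = 2,
                             connectivity = 26)
  expect_equal(nrow(res26), 2)
  expect_equal(sort(res26$extent), c(2, 3))
})

test_that("a strong planted activation is detected by permutation inference", {
  grid <- c(12, 12, 12)
  nv <- prod(grid)
  blob <- c(ind3(2:4, 2:4, 2:4, grid),           # 3x3x3 cube
            ind3(5, 2:4, 2, grid))               # face-attached extension

  expect_equal(length(unique(blob)), 30)
  detected <- vapply(1:10, function(i) {
    set.seed(600 + i)
    D <- matrix(rnorm(22 * nv), 22)
    D[, blob] <- D[, blob] + 1.28       # expected group z near 6
    m <- paired_t_map(D, matrix(0, 22, nv), grid = grid)
    res <- cluster_inference(m, z_threshold = 2.33, n_perm = 199,
                             rng_seed = i)
    nrow(res) > 0 && res$extent[1] >= 25 && min(res$p_corrected) < 0.05
  }, logical(1))
  expect_true(all(detected))
})

test_that("permutation corrected p-values are valid under the global null", {
  grid <- c(8, 8, 8)
  S <- smoothing_matrix(grid, fwhm = 2)
  rej <- vapply(1:100, function(i) {
    m <- make_null_map(n = 12, grid = grid, seed = 700 + i, smooth = S)
    res <- cluster_inference(m, z_threshold = 2.33, n_perm = 100,
                             rng_seed = i)
    nrow(res) > 0 && min(res$p_corrected) <= 0.05
  }, logical(1))
  # FWER at or conservatively below ~0.05 (upper binomial bound)
  expect_lte(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 100))
})

test_that("grf approximation gives monotone, in-range cluster p-values", {
  p10 <- grf_p_probe(extent = 10)
  p40 <- grf_p_probe(extent = 40)
  expect_true(p40 < p10)
  expect_true(all(c(p10, p40) > 0 & c(p10, p40) < 1))
})

test_that("BH critical p agrees with step-up enumeration on random vectors", {
  set.seed(60)
  for (i in 1:1000) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(c(1, 2, 3), 1)
    crit <- bh_critical_p(p, 0.05)
    surv <- bh_survivors_oracle(p, 0.05)
    if (!any(surv)) {
      expect_equal(crit, 0)
    } else {
      expect_equal(crit, max(p[surv]))
      expect_identical(p <= crit, surv)
    }
  }
})

test_that("small-volume correction flags the ROI holding a planted effect", {
  grid <- c(10, 10, 10)
  nv <- prod(grid)
  roi1 <- rep(FALSE, nv); roi1[ind3(2:4, 2, 2, grid)] <- TRUE
  roi1[ind3(2:4, 3, 2, grid)] <- TRUE
  roi2 <- rep(FALSE, nv); roi2[ind3(7:9, 7:9, 7, grid)] <- TRUE
  set.seed(61)
  D <- matrix(rnorm(20 * nv), 20)
  D[, which(roi1)] <- D[, which(roi1)] + 1.5
  m <- paired_t_map(D, matrix(0, 20, nv), grid = grid)
  svc <- small_volume_correct(m, list(hit = roi1, miss = roi2),
                              n_perm = 199, rng_seed = 5)
  expect_true(svc$table$significant[svc$table$roi == "hit"])
  expect_false(svc$table$significant[svc$table$roi == "miss"])
  expect_equal(svc$critical_p, bh_critical_p(svc$table$p, 0.05))
  expect_error(small_volume_correct(m, list(bad = rep(FALSE, nv))),
               "empty ROI")
})

test_that("all-null ROIs give critical p = 0 and no significance", {
  expect_equal(bh_critical_p(rep(1, 6), 0.05), 0)
  grid <- c(8, 8, 8)
  m <- make_null_map(n = 10, grid = grid, seed = 77)
  m$z <- m$z * 0.01   # force no clusters anywhere
  rois <- list(a = c(rep(TRUE, 64), rep(FALSE, 448)),
               b = c(rep(FALSE, 448), rep(TRUE, 64)))
  svc <- small_volume_correct(m, rois, n_perm = 100, rng_seed = 1)
  expect_equal(svc$table$p, c(1, 1))
  expect_equal(svc$critical_p, 0)
  expect_false(any(svc$table$significant))
})
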