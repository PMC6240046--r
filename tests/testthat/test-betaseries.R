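test_that("design has one column per trial plus nuisance, DCT and constant", {
  ev <- generate_protocol(protocol_spec(), rng_seed = 1)
  nuis <- matrix(rnorm(attr(ev, "n_scans") * 9), ncol = 9,
                 dimnames = list(NULL, c(paste0("motion_", 1:6),
                                         paste0("compartment_", 1:3))))
  des <- build_design(ev, nuisance = nuis)
  expect_length(des$trial_cols, 75)
  expect_equal(ncol(des$X), 75 + 9 + des$n_dct + 1)
  expect_true(all(paste0("motion_", 1:6) %in% des$labels))
})

test_that("DCT regressor count matches an independent spectral construction", {
  cases <- list(c(209, 2.511, 128), c(100, 2, 128), c(300, 1.5, 100),
                c(64, 3, 60))
  for (cs in cases) {
    n <- cs[1]; tr <- cs[2]; cutoff <- cs[3]
    # independent count: DCT frequencies k/(2T) at or below 1/cutoff
    T_run <- n * tr
    k_oracle <- sum(seq_len(n - 1) / (2 * T_run) <= 1 / cutoff)
    expect_equal(ncol(dct_basis(n, tr, cutoff)), k_oracle)
    expect_equal(k_oracle, floor(2 * T_run / cutoff))
  }
})

test_that("high-pass projection is idempotent", {
  set.seed(3)
  D <- dct_basis(120, 2.5, 128)
  y <- rnorm(120)
  hp <- function(v) v - D %*% crossprod(D, v)   # orthonormal basis
  expect_equal(hp(hp(y)), hp(y), tolerance = 1e-12)
})

test_that("a brief trial's regressor approaches the sampled HRF", {
  ev <- data.frame(onset = 20, duration = 0.05, trial_type = "cue",
                   sound_id = "cue_1", block_index = 1)
  attr(ev, "tr") <- 2; attr(ev, "n_scans") <- 40L
  class(ev) <- c("trial_events", "data.frame")
  des <- build_design(ev, cutoff = 128)
  col <- des$X[, 1]
  ref <- canonical_hrf((0:39) * 2 - 20)
  keep <- ref > 1e-3
  expect_gt(cor(col[keep], ref[keep]), 0.9999)
})

test_that("design construction rejects degenerate inputs", {
  ev <- data.frame(onset = c(10, 10), duration = 5,
                   trial_type = c("cue", "cue"),
                   sound_id = c("a", "b"), block_index = 1)
  attr(ev, "tr") <- 2; attr(ev, "n_scans") <- 60L
  class(ev) <- c("trial_events", "data.frame")
  expect_error(build_design(ev), "identical onsets")
  ev2 <- generate_protocol(small_protocol(), rng_seed = 1)
  expect_error(build_design(ev2, cutoff = 3), "twice the TR")
})

test_that("noiseless coefficients are recovered exactly", {
  ev <- generate_protocol(small_protocol(), rng_seed = 2)
  des <- build_design(ev)
  set.seed(5)
  beta_true <- matrix(rnorm(3 * ncol(des$X)), 3)
  Y <- beta_true %*% t(des$X)
  fit <- fit_betas(Y, des, ar1 = "none")
  expect_equal(fit$betas, beta_true[, des$trial_cols],
               tolerance = 1e-8)
})

test_that("AR(1) estimation reduces to OLS for white noise", {
  ev <- generate_protocol(small_protocol(n_scans = 300), rng_seed = 2)
  des <- build_design(ev)
  set.seed(9)
  Y <- matrix(rnorm(5 * 300, sd = 0.2), 5) +
    matrix(1, 5, 1) %*% t(des$X %*% rep(1, ncol(des$X)))
  f_none <- fit_betas(Y, des, ar1 = "none")
  f_est <- fit_betas(Y, des, ar1 = "estimate")
  expect_lt(max(abs(f_none$betas - f_est$betas)), 1e-2)
  expect_lt(max(abs(f_est$rho)), 0.2)
})

test_that("prewhitened estimator variance matches the closed-form GLS value", {
  ev <- generate_protocol(small_protocol(n_scans = 150), rng_seed = 1)
  des <- build_design(ev)
  X <- des$X
  n <- nrow(X); rho <- 0.5
  V <- rho^abs(outer(seq_len(n), seq_len(n), "-"))
  gls_var <- diag(solve(t(X) %*% solve(V) %*% X))[des$trial_cols]
  set.seed(11)
  innov <- sqrt(1 - rho^2)
  B <- replicate(400, {
    e <- as.numeric(stats::filter(rnorm(n, 0, innov), rho,
                                  method = "recursive"))
    y <- 2 * X[, 1] + e
    suppressWarnings(fit_betas(matrix(y, 1), des, ar1 = "estimate"))$betas[1, ]
  })
  ratio <- apply(B, 1, var) / gls_var
  expect_true(all(ratio > 0.75 & ratio < 1.35))
  expect_equal(mean(B[1, ]), 2, tolerance = 0.05)
})

test_that("rank-deficient designs are rejected with the offending columns", {
  ev <- generate_protocol(small_protocol(), rng_seed = 3)
  nuis <- cbind(dup_a = rep(1, attr(ev, "n_scans")))  # collinear with constant
  des <- build_design(ev, nuisance = nuis)
  expect_error(fit_betas(matrix(rnorm(70), 1), des), "collinear")
  expect_error(fit_betas(matrix(rnorm(50), 1),
                         build_design(generate_protocol(small_protocol(),
                                                        rng_seed = 3))),
               "scans")
})

test_that("condition split is an order-preserving partition", {
  ev <- generate_protocol(protocol_spec(), rng_seed = 4)
  B <- matrix(seq_len(2 * 75), 2)
  bs <- as_betas(B, trial_type = ev$trial_type)
  sp <- split_by_condition(bs, ev)
  expect_equal(ncol(sp$cue$betas), 50)
  expect_equal(ncol(sp$control$betas), 25)
  # union of splits = input, order preserved within condition
  expect_equal(sp$cue$betas, B[, ev$trial_type == "cue"])
  expect_equal(sp$control$betas, B[, ev$trial_type == "control"])
  expect_equal(sort(c(sp$cue$betas[1, ], sp$control$betas[1, ])),
               sort(B[1, ]))
  # all-cue input: control split absent, flagged
  bs2 <- as_betas(B[, 1:10], trial_type = rep("cue", 10))
  expect_warning(sp2 <- split_by_condition(bs2), "no trials")
  expect_null(sp2$control)
  bs3 <- as_betas(B[, 1:4], trial_type = c("cue", "cue", "odd", "cue"))
  expect_error(split_by_condition(bs3), "unknown condition")
})
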