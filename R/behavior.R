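#' Euclidean object-placement error
#'
#' Distance in cm between the true and the placed location; the learning
#' criterion in the emulated task was placement within 4 cm.
#'
#' @param true_xy,placed_xy Numeric length-2 vectors, or 2-column matrices
#'   of coordinates (cm).
#' @return Numeric vector of distances (cm).
#' @export
placement_error <- function(true_xy, placed_xy) {
  a <- rbind(true_xy); b <- rbind(placed_xy)
  stopifnot(ncol(a) == 2, ncol(b) == 2, all(is.finite(a)), all(is.finite(b)))
  unname(sqrt(rowSums((a - b)^2)))
}

#' Simulate per-item placement errors with a planted brain-behavior link
#'
#' Per item, the pre-sleep error is drawn from a normal truncated at 0 (by
#' resampling); the post-sleep error adds a subject-level overnight
#' forgetting term plus item noise, again truncated at 0. Forgetting
#' decreases linearly in the subject's planted network effect
#' (`pc_effects`, the per-subject seed cross-module boost scale), relative
#' to the reference level `pc_reference`, with full weight for cued items
#' and weight `uncued_weight` for uncued items — emulating a negative
#' association between cue-induced network integration and overnight
#' forgetting that extends (more weakly) to uncued material.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param pc_effects Optional per-subject planted effects; defaults to
#'   draws from N(0.25, 0.1) truncated at 0.
#' @param coupling Slope (cm of forgetting per unit planted effect).
#' @param uncued_weight Relative coupling weight for uncued items.
#' @param pc_reference Reference effect level at which forgetting equals
#'   `forgetting_mean`.
#' @param mu1 Mean pre-sleep error (cm).
#' @param sd_item SD of pre-sleep item errors (cm).
#' @param forgetting_mean Mean overnight increase in error (cm).
#' @param sd_subject SD of the subject-level forgetting term (cm).
#' @param sd_change SD of item-level overnight change noise (cm).
#' @param n_items Items per subject (half cued, half uncued).
#' @param rng_seed Integer seed.
#' @return A `data.frame` (class `behavioral_table`): `subject`, `item`,
#'   `cued`, `error_test1`, `error_test2`; attribute `pc_effects` holds the
#'   per-subject planted values.
#' @export
generate_behavior <- function(n_subjects = 22, pc_effects = NULL,
                              coupling = 4, uncued_weight = 0.7,
                              pc_reference = 0.25, mu1 = 2.74,
                              sd_item = 1.5, forgetting_mean = 0.37,
                              sd_subject = 0.15, sd_change = 0.8,
                              n_items = 50, rng_seed = 1) {
  if (n_subjects < 4) stop("need at least 4 subjects")
  if (sd_item < 0 || sd_subject < 0 || sd_change < 0) {
    stop("variance parameters must be non-negative")
  }
  if (n_items %% 2 != 0) stop("n_items must be even (half cued)")
  set.seed(as.integer(rng_seed))
  if (is.null(pc_effects)) {
    pc_effects <- rtrunc0(n_subjects, 0.25, 0.1)
  }
  stopifnot(length(pc_effects) == n_subjects)
  rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    e1 <- rtrunc0(n_items, mu1, sd_item)
    cued <- sample(rep(c(TRUE, FALSE), n_items / 2))
    subj_forget <- forgetting_mean + stats::rnorm(1, 0, sd_subject)
    shift <- subj_forget -
      coupling * (pc_effects[s] - pc_reference) *
      ifelse(cued, 1, uncued_weight)
    e2 <- e1 + shift + stats::rnorm(n_items, 0, sd_change)
    for (iter in 1:100) {
      neg <- e2 < 0
      if (!any(neg)) break
      e2[neg] <- e1[neg] + shift[neg] + stats::rnorm(sum(neg), 0, sd_change)
    }
    e2[e2 < 0] <- 0
    rows[[s]] <- data.frame(subject = s, item = seq_len(n_items),
                            cued = cued, error_test1 = e1, error_test2 = e2)
  }
  out <- do.call(rbind, rows)
  attr(out, "pc_effects") <- pc_effects
  class(out) <- c("behavioral_table", "data.frame")
  out
}

# normal truncated at 0 by resampling (falls back to |x| if stuck)
rtrunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  for (iter in 1:100) {
    neg <- x < 0
    if (!any(neg)) break
    x[neg] <- stats::rnorm(sum(neg), mean, sd)
  }
  abs(x)
}

#' Overnight-forgetting summary statistics
#'
#' Per-subject mean placement errors at both tests and their difference
#' (Test 2 - Test 1; positive = forgetting), overall and split by cueing,
#' plus group-level paired t-tests (two-sided) for overall, cued and uncued
#' forgetting and for the cued-vs-uncued contrast (a two-level
#' within-subject factor, so the paired t is the square root of the
#' equivalent repeated-measures F).
#'
#' @param table A `behavioral_table` (columns `subject`, `cued`,
#'   `error_test1`, `error_test2`).
#' @return A list of class `forgetting_summary`: `per_subject` (data
#'   frame), `group` (list of test results: each `mean`, `sem`, `t`, `df`,
#'   `p`; `cued_vs_uncued` also reports `F = t^2`).
#' @export
forgetting_summary <- function(table) {
  req <- c("subject", "cued", "error_test1", "error_test2")
  stopifnot(all(req %in% names(table)))
  if (anyNA(table[req])) stop("both tests must be present for every item")
  subs <- sort(unique(table$subject))
  per <- lapply(subs, function(s) {
    d <- table[table$subject == s, ]
    if (!any(d$cued) || !all(c(TRUE, FALSE) %in% d$cued)) {
      warning("subject ", s, " lacks items in one cueing condition; excluded")
      return(NULL)
    }
    data.frame(
      subject = s,
      mean_test1 = mean(d$error_test1),
      mean_test2 = mean(d$error_test2),
      delta = mean(d$error_test2 - d$error_test1),
      delta_cued = mean(d$error_test2[d$cued] - d$error_test1[d$cued]),
      delta_uncued = mean(d$error_test2[!d$cued] - d$error_test1[!d$cued]))
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) < 2) stop("need at least 2 complete subjects")
  one <- function(x) {
    n <- length(x)
    if (stats::sd(x) <= 1e-10 * max(1, abs(mean(x)))) {
      return(list(mean = mean(x), sem = 0,
                  t = if (mean(x) == 0) 0 else NA_real_,
                  df = n - 1,
                  p = if (mean(x) == 0) 1 else NA_real_,
                  degenerate = TRUE))
    }
    tt <- stats::t.test(x)
    list(mean = mean(x), sem = stats::sd(x) / sqrt(n),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, degenerate = FALSE)
  }
  grp <- list(overall = one(per$delta),
              cued = one(per$delta_cued),
              uncued = one(per$delta_uncued),
              cued_vs_uncued = one(per$delta_cued - per$delta_uncued))
  grp$cued_vs_uncued$F <- grp$cued_vs_uncued$t^2
  out <- list(per_subject = per, group = grp)
  class(out) <- "forgetting_summary"
  out
}

#' Kendall rank correlation (tau-b) with normal-approximation p
#'
#' Tau-b with tie correction; the two-sided p-value uses the normal
#' approximation for the concordance statistic S with tie-corrected
#' variance and a continuity correction.
#'
#' @param x,y Numeric vectors of equal length (n >= 4), neither constant.
#' @return A list: `tau`, `p`, `S`, `n`.
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 4) stop("need n >= 4")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("constant vector")
  }
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  ut <- upper.tri(dx)
  S <- sum(dx[ut] * dy[ut])
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  # tie-corrected variance of S (Kendall 1970)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- if (S == 0) 0 else (S - sign(S)) / sqrt(varS)
  p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(tau = tau, p = p, S = S, n = n)
}

#' Williams-Hotelling test for two dependent correlations
#'
#' Compares r12 and r13 — the correlations of variables 2 and 3 with the
#' shared variable 1 — on n observations, with df = n - 3:
#' `t = (r12 - r13) * sqrt(((n - 1) * (1 + r23)) /
#'   (2 * ((n - 1)/(n - 3)) * |R| + rbar^2 * (1 - r23)^3))`
#' where `rbar = (r12 + r13)/2` and `|R|` is the determinant of the 3x3
#' correlation matrix.
#'
#' @param r12,r13,r23 Correlations (the triple must form a positive
#'   semi-definite correlation matrix).
#' @param n Sample size (>= 4).
#' @return A list: `t`, `df`, `p` (two-sided).
#' @export
williams_hotelling <- function(r12, r13, r23, n) {
  stopifnot(n >= 4, abs(r12) <= 1, abs(r13) <= 1, abs(r23) <= 1)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < -1e-12) stop("correlation triple is not positive semi-definite")
  detR <- max(detR, 0)
  rbar <- (r12 + r13) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3
  t_stat <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  df <- n - 3
  list(t = t_stat, df = df,
       p = 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE))
}
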