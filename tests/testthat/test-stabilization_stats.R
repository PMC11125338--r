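test_that("repeated-measures ANOVA matches brute-force sums of squares", {
  Y <- matrix(c(3, 5, 4,
                6, 7, 8,
                2, 4, 3,
                5, 6, 7,
                4, 5, 6), 5, 3, byrow = TRUE)
  an <- rm_anova(Y)
  or <- oracle_rm_anova(Y)
  expect_equal(an$F, or$F, tolerance = 1e-10)
  expect_equal(unname(an$ss), c(or$ss_f, or$ss_s, or$ss_e), tolerance = 1e-10)
})

test_that("identical window columns give F = 0, p = 1", {
  Y <- matrix(rep(rnorm(6), 4), 6, 4)
  an <- rm_anova(Y)
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)
})

test_that("with two windows, F equals the squared paired-t statistic", {
  set.seed(31)
  Y <- matrix(rnorm(24), 12, 2)
  an <- rm_anova(Y)
  tt <- oracle_paired_t(Y[, 1], Y[, 2])
  expect_equal(an$F, tt$t^2, tolerance = 1e-10)
})

test_that("ANOVA, epsilon, Mauchly and paired t match independent oracles on random matrices", {
  set.seed(32)
  for (rep in 1:25) {
    n <- sample(8:15, 1)
    k <- sample(3:5, 1)
    Y <- matrix(rnorm(n * k), n, k) +
      outer(rnorm(n, sd = 0.8), rep(1, k)) +
      outer(rep(1, n), rnorm(k))
    an <- rm_anova(Y)
    or <- oracle_rm_anova(Y)
    expect_equal(an$F, or$F, tolerance = 1e-8)
    # epsilon: eigenvalue formula vs the trace formula oracle
    S <- cov(Y)
    Cn <- diag(k) - 1 / k
    St <- Cn %*% S %*% Cn
    eps_tr <- sum(diag(St))^2 / ((k - 1) * sum(St * St))
    expect_equal(an$epsilon, min(max(eps_tr, 1 / (k - 1)), 1), tolerance = 1e-10)
    # cross-check against the multivariate machinery in base R
    ml <- lm(Y ~ 1)
    idata <- data.frame(w = factor(seq_len(k)))
    av <- anova(ml, X = ~1, idata = idata, test = "Spherical")
    mt <- mauchly.test(ml, X = ~1, idata = idata)
    expect_equal(an$mauchly_W, unname(mt$statistic), tolerance = 1e-8)
    # the chi-square series term differs slightly between implementations
    # (textbook 3(k-1)+2 vs base R's 3k+2), so p agrees to ~1e-4 only
    expect_equal(an$mauchly_p, mt$p.value, tolerance = 1e-3)
    expect_equal(an$p_gg, av$`G-G Pr`[1], tolerance = 1e-8)
    # one random pair against t.test and the formula oracle (matrix stores
    # the t of the lower-index-minus-higher-index difference)
    ij <- sort(sample(k, 2))
    pw <- pairwise_paired_tests(Y)
    tt <- t.test(Y[, ij[1]], Y[, ij[2]], paired = TRUE)
    expect_equal(pw$t[ij[1], ij[2]], unname(tt$statistic), tolerance = 1e-8)
    expect_equal(pw$p_raw[ij[1], ij[2]], tt$p.value, tolerance = 1e-8)
    orp <- oracle_paired_t(Y[, ij[1]], Y[, ij[2]])
    expect_equal(pw$t[ij[1], ij[2]], orp$t, tolerance = 1e-8)
  }
})

test_that("epsilon hits its bounds for compound-symmetric and rank-1 covariances", {
  k <- 7
  S_cs <- matrix(0.3, k, k); diag(S_cs) <- 1
  expect_equal(gg_epsilon(S_cs), 1)
  v <- seq_len(k) - mean(seq_len(k))
  S_r1 <- tcrossprod(v)
  expect_equal(gg_epsilon(S_r1), 1 / (k - 1))
  expect_error(gg_epsilon(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("Mauchly test holds its size under sphericity and rejects under AR(1)", {
  set.seed(33)
  n <- 300; k <- 4
  rej <- 0; reps <- 300
  for (i in seq_len(reps)) {
    Y <- matrix(rnorm(n * k), n, k)  # i.i.d. columns: sphericity holds
    rej <- rej + (mauchly_sphericity(Y)$p < 0.05)
  }
  rate <- rej / reps
  expect_gt(rate, 0.02)  # within binomial error of the nominal 5%
  expect_lt(rate, 0.09)

  rho <- 0.9
  Sig <- rho^abs(outer(1:k, 1:k, "-"))
  R <- chol(Sig)
  rej2 <- 0
  for (i in 1:50) {
    Y <- matrix(rnorm(200 * k), 200, k) %*% R
    m <- mauchly_sphericity(Y)
    rej2 <- rej2 + (m$p < 0.05)
    expect_lt(m$W, 1)
  }
  expect_gt(rej2 / 50, 0.9)
})

test_that("pairwise matrix has 21 Bonferroni comparisons for 7 windows", {
  set.seed(34)
  Y <- matrix(rnorm(70), 10, 7)
  pw <- pairwise_paired_tests(Y)
  expect_equal(pw$m, 21)
  expect_true(all(pw$p_adj >= pw$p_raw, na.rm = TRUE))
  expect_true(all(pw$p_adj == pmin(1, 21 * pw$p_raw), na.rm = TRUE))
  expect_equal(pw$p_adj, t(pw$p_adj))
  # identical columns: t = 0, never significant
  Y2 <- cbind(Y[, 1], Y[, 1], Y[, 2])
  pw2 <- pairwise_paired_tests(Y2)
  expect_equal(pw2$t[1, 2], 0)
  expect_equal(pw2$p_adj[1, 2], 1)
  # Bonferroni dominance: adjusted significance is a subset of raw
  sig_raw <- !is.na(pw$p_raw) & pw$p_raw < 0.05
  expect_true(all(which(pw$significant) %in% which(sig_raw)))
})

test_that("untestable pairs count as no difference with a flag", {
  Y <- matrix(rnorm(21), 7, 3)
  Y[2:7, 3] <- NA  # only one complete pair with column 3
  pw <- pairwise_paired_tests(Y)
  expect_true(pw$untestable[1, 3])
  expect_equal(pw$p_adj[1, 3], 1)
  expect_false(pw$significant[1, 3])
})

test_that("the stabilization rule picks the first all-clear window", {
  grid <- build_window_grid(2)
  k <- 7
  an_sig <- structure(list(p = 1e-6), class = "rm_anova")
  mk_tests <- function(sig) {
    structure(list(significant = sig, alpha = 0.05,
                   untestable = matrix(FALSE, k, k)),
              class = "pairwise_tests")
  }
  none <- matrix(FALSE, k, k)
  res <- stabilization_time(mk_tests(none), grid, an_sig)
  expect_equal(res$stabilized_at, 0)

  all_sig <- matrix(TRUE, k, k); diag(all_sig) <- FALSE
  res2 <- stabilization_time(mk_tests(all_sig), grid, an_sig)
  expect_false(res2$stabilized)
  expect_true(is.na(res2$stabilized_at))
  expect_true(all(lengths(res2$plateaus) == 1))

  # windows {8,10,12} mutually n.s.; every (w<=6, w') significant -> 8 s
  sig <- matrix(FALSE, k, k)
  for (i in 1:4) for (j in (i + 1):k) sig[i, j] <- sig[j, i] <- TRUE
  res3 <- stabilization_time(mk_tests(sig), grid, an_sig)
  expect_equal(res3$stabilized_at, 8)

  # ANOVA gate: no overall effect -> stabilized from the first window
  an_ns <- structure(list(p = 0.41), class = "rm_anova")
  res4 <- stabilization_time(mk_tests(all_sig), grid, an_ns)
  expect_equal(res4$stabilized_at, 0)
  expect_false(res4$gate_rejected)
})

test_that("removing evidence never delays stabilization", {
  set.seed(35)
  grid <- build_window_grid(2)
  k <- 7
  an_sig <- structure(list(p = 1e-6), class = "rm_anova")
  for (rep in 1:20) {
    sig <- matrix(FALSE, k, k)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      s <- runif(1) < 0.4
      sig[i, j] <- sig[j, i] <- s
    }
    mk <- function(s) structure(list(significant = s, alpha = 0.05,
                                     untestable = matrix(FALSE, k, k)),
                                class = "pairwise_tests")
    base <- stabilization_time(mk(sig), grid, an_sig)
    on <- which(sig & upper.tri(sig), arr.ind = TRUE)
    if (!nrow(on)) next
    pick <- on[sample(nrow(on), 1), ]
    sig2 <- sig
    sig2[pick[1], pick[2]] <- sig2[pick[2], pick[1]] <- FALSE
    relax <- stabilization_time(mk(sig2), grid, an_sig)
    b <- if (base$stabilized) base$stabilized_at else Inf
    r <- if (relax$stabilized) relax$stabilized_at else Inf
    expect_lte(r, b)
  }
})

test_that("correction shrinks degrees of freedom and epsilon stays in bounds", {
  set.seed(36)
  n <- 40; k <- 7
  Sig <- 0.95^abs(outer(1:k, 1:k, "-"))
  Y <- matrix(rnorm(n * k), n, k) %*% chol(Sig) + outer(rep(1, n), (1:k) / 3)
  an <- rm_anova(Y)
  expect_gte(an$epsilon, 1 / (k - 1))
  expect_lte(an$epsilon, 1)
  expect_true(an$correction_applied)
  expect_lte(an$df1, k - 1)
  expect_lte(an$df2, (n - 1) * (k - 1))
  expect_gte(an$p, an$p_uncorrected)  # GG correction is conservative here
})

test_that("analyze_variable errors informatively", {
  tab <- data.frame(event_id = "e1", variable = "pd", window_start_s = 0,
                    window_len_s = 2, value = 1, is_missing = FALSE)
  expect_error(analyze_variable(tab, "hr"), "does not contain")
  expect_error(analyze_variable(tab, "pd"), "complete units|insufficient")
  expect_error(rm_anova(matrix(rnorm(4), 2, 2)), "3 complete units")
})
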