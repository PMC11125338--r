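#' Assemble a repeated-measures matrix from a feature table
#'
#' Pivots the long-form feature table of one variable into an
#' attempts-by-windows matrix. Complete-case filtering is applied downstream
#' (listwise for the ANOVA, pairwise for the t-tests).
#'
#' @param features Long-form feature table (see [compute_window_features()]).
#' @param variable One of [to_variables()].
#' @param unit `"attempt"` (each takeover is a unit, the default) or
#'   `"driver"` (values first averaged per driver; requires event ids of the
#'   form produced by the generator, `s<study>_d<driver>_...`).
#' @return Numeric matrix with one row per unit and one column per window
#'   start, NA for missing cells; column names are the window starts.
#' @export
build_rm_matrix <- function(features, variable, unit = c("attempt", "driver")) {
  unit <- match.arg(unit)
  f <- features[features$variable == variable, , drop = FALSE]
  if (!nrow(f)) stop("feature table has no rows for variable '", variable, "'",
                     call. = FALSE)
  starts <- sort(unique(f$window_start_s))
  id <- f$event_id
  if (unit == "driver") id <- sub("^(s[0-9]+_d[0-9]+).*$", "\\1", id)
  agg <- stats::aggregate(value ~ id + window_start_s,
                          data = data.frame(id = id,
                                            window_start_s = f$window_start_s,
                                            value = f$value),
                          FUN = mean, na.action = stats::na.pass)
  units <- sort(unique(agg$id))
  M <- matrix(NA_real_, length(units), length(starts),
              dimnames = list(units, as.character(starts)))
  M[cbind(match(agg$id, units), match(agg$window_start_s, starts))] <- agg$value
  M
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance of the within-subject differences is
#' spherical, using the covariance of k-1 orthonormal contrasts and the
#' chi-square approximation to `-(n-1) d log W`.
#'
#' @param Y Complete-case numeric matrix, units x k window levels.
#' @return List with `W`, `p`, `df`, `chisq`; for `k = 2`, `W = 1` and
#'   `p = 1` (sphericity is trivially satisfied).
#' @export
mauchly_sphericity <- function(Y) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("mauchly_sphericity requires complete cases", call. = FALSE)
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2) stop("need at least 2 levels", call. = FALSE)
  if (k == 2) return(list(W = 1, p = 1, df = 0L, chisq = 0))
  if (n <= k) stop("need n > k complete units for the sphericity test", call. = FALSE)
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")  # orthonormal contrasts
  S <- stats::cov(Y)
  Acov <- t(C) %*% S %*% C
  ev <- eigen(Acov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .Machine$double.eps * max(ev))
    stop("degenerate data: contrast covariance is singular", call. = FALSE)
  W <- prod(ev) / (mean(ev))^(k - 1)
  kk <- k - 1                      # dimension of the contrast space
  nu <- n - 1                      # error degrees of freedom
  rho <- 1 - (2 * kk^2 + kk + 2) / (6 * kk * nu)
  z <- -nu * log(W)
  df <- kk * (kk + 1) / 2 - 1
  # Box chi-square series to second order (the standard approximation)
  w2 <- (kk + 2) * (kk - 1) * (kk - 2) * (2 * kk^3 + 6 * kk^2 + 3 * kk + 2) /
    (288 * kk^2 * nu^2 * rho^2)
  p <- stats::pchisq(z * rho, df, lower.tail = FALSE) +
    w2 * (stats::pchisq(z * rho, df + 4, lower.tail = FALSE) -
            stats::pchisq(z * rho, df, lower.tail = FALSE))
  p <- min(max(p, 0), 1)
  list(W = W, p = p, df = df, chisq = z * rho)
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-violation correction factor computed from the double-centered
#' covariance matrix of the window levels:
#' `epsilon = (sum lambda_i)^2 / ((k-1) sum lambda_i^2)` over its eigenvalues,
#' equivalently `tr(S~)^2 / ((k-1) tr(S~^2))`; clipped to
#' `[1/(k-1), 1]`.
#'
#' @param S Symmetric positive semi-definite k x k covariance matrix.
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(S) {
  S <- as.matrix(S)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    stop("covariance matrix must be symmetric", call. = FALSE)
  k <- ncol(S)
  Cn <- diag(k) - 1 / k
  St <- Cn %*% S %*% Cn
  ev <- eigen(St, symmetric = TRUE, only.values = TRUE)$values
  if (sum(ev^2) < .Machine$double.eps) return(1)  # degenerate: no level variance
  eps <- sum(ev)^2 / ((k - 1) * sum(ev^2))
  min(max(eps, 1 / (k - 1)), 1)
}

#' One-factor repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject decomposition of the units x windows matrix into factor,
#' subject and error sums of squares; `F = MS_factor / MS_error`. Sphericity
#' is assessed with Mauchly's test; when it is rejected at `alpha` the
#' Greenhouse-Geisser correction scales both degrees of freedom by epsilon.
#' Both the uncorrected and corrected p-values are always reported.
#'
#' @param Y Numeric matrix, units x k windows; rows with any NA are dropped
#'   (listwise complete-case) and the retained count reported.
#' @param alpha Significance level for the sphericity gate (default 0.05).
#' @return List of class `rm_anova` with `F`, `df1`, `df2`, `p`,
#'   `p_uncorrected`, `p_gg`, `epsilon`, `mauchly_W`, `mauchly_p`,
#'   `correction_applied`, `n_complete`, `k`.
#' @export
rm_anova <- function(Y, alpha = 0.05) {
  Y <- as.matrix(Y)
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  n <- nrow(Y); k <- ncol(Y)
  if (n < 3) stop("insufficient data: need at least 3 complete units", call. = FALSE)
  grand <- mean(Y)
  row_m <- rowMeans(Y); col_m <- colMeans(Y)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_fact <- n * sum((col_m - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_fact
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_f <- ss_fact / df1
  ms_e <- ss_err / df2
  F_stat <- if (ms_e <= 0) {
    if (ss_fact <= 1e-12 * max(ss_tot, 1)) 0 else Inf
  } else ms_f / ms_e
  eps <- gg_epsilon(stats::cov(Y))
  mau <- if (k > 2 && n > k) {
    tryCatch(mauchly_sphericity(Y),
             error = function(e) list(W = NA_real_, p = NA_real_))
  } else list(W = 1, p = 1)
  p_unc <- stats::pf(F_stat, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(F_stat, eps * df1, eps * df2, lower.tail = FALSE)
  corr <- is.finite(mau$p) && mau$p < alpha
  if (F_stat == 0) p_unc <- p_gg <- 1
  structure(list(
    F = F_stat,
    df1 = if (corr) eps * df1 else df1,
    df2 = if (corr) eps * df2 else df2,
    p = if (corr) p_gg else p_unc,
    p_uncorrected = p_unc, p_gg = p_gg, epsilon = eps,
    mauchly_W = mau$W, mauchly_p = mau$p,
    correction_applied = corr, n_complete = n, k = k,
    ss = c(factor = ss_fact, subject = ss_subj, error = ss_err)
  ), class = "rm_anova")
}

#' All-pairs paired t-tests with Bonferroni adjustment
#'
#' Two-sided paired t-tests between every pair of window columns, each on its
#' pairwise-complete rows; p-values are Bonferroni-adjusted by the number of
#' comparisons `m = k (k - 1) / 2` (21 for 7 windows). A pair with fewer than
#' 2 complete rows, or with zero-variance identical differences, is untestable
#' and treated as "no difference observed" (adjusted p = 1) with its cell
#' flagged in `untestable`.
#'
#' @param Y Numeric matrix, units x k windows (NA allowed).
#' @param alpha Significance level (default 0.05).
#' @return List of class `pairwise_tests` with k x k matrices `t`, `p_raw`,
#'   `p_adj`, `n_pairs`, logical `significant` and `untestable`, plus
#'   `m` (number of comparisons) and `alpha`.
#' @export
pairwise_paired_tests <- function(Y, alpha = 0.05) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  if (k < 2) stop("need at least 2 windows", call. = FALSE)
  m <- k * (k - 1) / 2
  tm <- pm <- pa <- matrix(NA_real_, k, k, dimnames = dimnames(Y)[c(2, 2)])
  np <- matrix(0L, k, k, dimnames = dimnames(Y)[c(2, 2)])
  unt <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- Y[, i] - Y[, j]
      d <- d[!is.na(d)]
      np[i, j] <- np[j, i] <- length(d)
      if (length(d) < 2) { unt[i, j] <- unt[j, i] <- TRUE; pa[i, j] <- pa[j, i] <- 1; next }
      s <- stats::sd(d)
      if (s == 0) {
        if (all(d == 0)) { tm[i, j] <- tm[j, i] <- 0; pm[i, j] <- pm[j, i] <- 1 }
        else { tm[i, j] <- tm[j, i] <- Inf * sign(mean(d)); pm[i, j] <- pm[j, i] <- 0 }
      } else {
        tt <- mean(d) / (s / sqrt(length(d)))
        tm[i, j] <- tm[j, i] <- tt
        pm[i, j] <- pm[j, i] <- 2 * stats::pt(-abs(tt), df = length(d) - 1)
      }
      pa[i, j] <- pa[j, i] <- min(1, m * pm[i, j])
    }
  }
  diag(pa) <- 1
  sig <- !is.na(pa) & pa < alpha & !unt
  diag(sig) <- FALSE
  structure(list(t = tm, p_raw = pm, p_adj = pa, n_pairs = np,
                 significant = sig, untestable = unt, m = m, alpha = alpha),
            class = "pairwise_tests")
}

#' Apply the stabilization criterion
#'
#' A variable is stabilized in the first window that shows no significant
#' difference from **all** subsequent windows. The last window has no
#' subsequent windows and is therefore not a candidate; if no candidate
#' qualifies the variable did not stabilize within the horizon. When the
#' overall repeated-measures ANOVA does not reject (p >= alpha), no pairwise
#' differences are confirmed and the variable is stabilized from the first
#' window on. Maximal runs of consecutive windows with no significant internal
#' pair are also reported as transient plateaus (e.g. speed stabilizing,
#' drifting, then stabilizing again).
#'
#' @param tests A `pairwise_tests` object (ignored when the ANOVA gate does
#'   not reject).
#' @param grid The `to_window_grid` the tests were computed on.
#' @param anova The `rm_anova` result for the same matrix.
#' @return List of class `stabilization_result`: `stabilized_at` (window
#'   start in seconds, NA if not stabilized), `stabilized` (logical),
#'   `plateaus` (list of integer window-index runs), `gate_rejected`,
#'   `anova`, `tests`.
#' @export
stabilization_time <- function(tests, grid, anova) {
  starts <- grid$starts
  k <- length(starts)
  gate <- is.finite(anova$p) && anova$p < tests$alpha
  if (!gate) {
    return(structure(list(stabilized_at = starts[1], stabilized = TRUE,
                          plateaus = list(seq_len(k)), gate_rejected = FALSE,
                          anova = anova, tests = tests),
                     class = "stabilization_result"))
  }
  sig <- tests$significant
  if (nrow(sig) != k)
    stop("pairwise test matrix does not match the window grid", call. = FALSE)
  stab_idx <- NA_integer_
  for (w in seq_len(k - 1)) {
    if (!any(sig[w, (w + 1):k])) { stab_idx <- w; break }
  }
  # maximal consecutive runs with no significant pair inside the run
  plateaus <- list()
  w <- 1L
  while (w <= k) {
    e <- w
    while (e < k && !any(sig[w:(e + 1), w:(e + 1)])) e <- e + 1L
    plateaus[[length(plateaus) + 1L]] <- w:e
    w <- e + 1L
  }
  structure(list(
    stabilized_at = if (is.na(stab_idx)) NA_real_ else starts[stab_idx],
    stabilized = !is.na(stab_idx),
    plateaus = plateaus, gate_rejected = TRUE,
    anova = anova, tests = tests
  ), class = "stabilization_result")
}

#' Full stabilization analysis of one variable
#'
#' Assembles the repeated-measures matrix for a variable from the feature
#' table, runs the sphericity test and repeated-measures ANOVA
#' (listwise-complete), then — if the ANOVA rejects — all-pairs
#' Bonferroni-adjusted paired t-tests (pairwise-complete), and applies the
#' stabilization criterion.
#'
#' @param features Long-form feature table.
#' @param variable One of [to_variables()].
#' @param alpha Significance level (default 0.05).
#' @param unit Repeated-measures unit, `"attempt"` (default) or `"driver"`.
#' @return A `stabilization_result` with extra fields `variable`,
#'   `window_len_s`, `n_total`, `n_complete`.
#' @export
analyze_variable <- function(features, variable, alpha = 0.05,
                             unit = c("attempt", "driver")) {
  unit <- match.arg(unit)
  if (!variable %in% unique(features$variable))
    stop("feature table does not contain variable '", variable, "'", call. = FALSE)
  M <- build_rm_matrix(features, variable, unit = unit)
  wl <- unique(features$window_len_s[features$variable == variable])[1]
  starts <- as.numeric(colnames(M))
  step <- if (length(starts) > 1) starts[2] - starts[1] else 2
  grid <- build_window_grid(wl, step = step, horizon = max(starts))
  n_complete <- sum(stats::complete.cases(M))
  if (n_complete < 3)
    stop("insufficient data for variable '", variable,
         "': fewer than 3 complete units", call. = FALSE)
  an <- rm_anova(M, alpha = alpha)
  tests <- pairwise_paired_tests(M, alpha = alpha)
  res <- stabilization_time(tests, grid, an)
  res$variable <- variable
  res$window_len_s <- wl
  res$n_total <- nrow(M)
  res$n_complete <- n_complete
  res
}
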