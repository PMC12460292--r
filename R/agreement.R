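## Measurement-agreement statistics for paired TLS-estimated and
## water-displacement reference volumes: regression-style error metrics,
## Bland-Altman limits of agreement, Lin's concordance correlation, gauge
## repeatability (variance components), and rank tests (Kruskal-Wallis,
## Mann-Whitney) for species-level differences.

#' Conventions for the agreement report
#'
#' Declared once per report and echoed in the output.
#'
#' @param diff_direction direction of the Bland-Altman difference:
#'   `"est_minus_obs"` (default: a negative mean difference means the TLS
#'   estimate underestimates the reference) or `"obs_minus_est"`.
#' @param variance_mode variance denominators for the concordance
#'   correlation: `"population"` (n, default — the convention under which
#'   the concordance estimator is defined) or `"sample"` (n - 1).
#' @param tie_correction apply mid-rank tie corrections in the rank tests
#'   (default TRUE).
#' @return list of class `agreement_conventions`.
#' @export
agreement_conventions <- function(diff_direction = c("est_minus_obs", "obs_minus_est"),
                                  variance_mode = c("population", "sample"),
                                  tie_correction = TRUE) {
  structure(list(diff_direction = match.arg(diff_direction),
                 variance_mode = match.arg(variance_mode),
                 tie_correction = isTRUE(tie_correction)),
            class = "agreement_conventions")
}

.check_paired <- function(observed, estimated) {
  if (length(observed) != length(estimated))
    stop("observed and estimated must have equal length")
  if (length(observed) < 2L) stop("at least 2 paired values required")
  if (!all(is.finite(observed)) || !all(is.finite(estimated)))
    stop("volumes must be finite")
}

#' Regression-style error metrics
#'
#' With x = observed (reference) and y = estimated volumes:
#' R^2 = 1 - sum((y - x)^2) / sum((y - mean(y))^2);
#' RMSE = sqrt(mean((y - x)^2));
#' RE = mean((x - y) / y) (a fraction);
#' Bias = mean(y - x);
#' rRMSE = RMSE / mean(x) * 100 — normalised by the mean *observed* value,
#' in percent.
#'
#' @param observed reference volumes (cm^3), positive.
#' @param estimated TLS-estimated volumes (cm^3), positive.
#' @return list with `r_squared`, `rmse`, `re`, `bias`, `rrmse`, `n`.
#' @export
regression_metrics <- function(observed, estimated) {
  .check_paired(observed, estimated)
  x <- observed; y <- estimated
  n <- length(x)
  if ((var(x) == 0 || var(y) == 0) && !all(x == y))
    stop("zero variance; R-squared undefined")
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum((y - x)^2) / ss_tot else 1
  if (any(y == 0)) stop("zero estimated value; relative error undefined")
  rmse <- sqrt(mean((y - x)^2))
  list(r_squared = r2,
       rmse = rmse,
       re = mean((x - y) / y),
       bias = mean(y - x),
       rrmse = relative_rmse(rmse, mean(x)),
       n = n)
}

#' Relative RMSE in percent
#'
#' rRMSE = RMSE / mean observed x 100. Exposed separately so that a printed
#' RMSE and group mean can be combined directly.
#'
#' @param rmse root mean square error (cm^3).
#' @param mean_observed mean of the reference volumes (cm^3), nonzero.
#' @return rRMSE in percent.
#' @export
relative_rmse <- function(rmse, mean_observed) {
  if (mean_observed == 0) stop("mean observed volume is zero; rRMSE undefined")
  rmse / mean_observed * 100
}

#' Bland-Altman limits of agreement from summary values
#'
#' ULOA = mean difference + 1.96 s, LLOA = mean difference - 1.96 s, where s
#' is the standard deviation of the paired differences.
#'
#' @param mean_diff mean of the differences (cm^3).
#' @param sd_diff standard deviation of the differences (cm^3).
#' @return named vector `c(uloa, lloa)`.
#' @export
loa_limits <- function(mean_diff, sd_diff) {
  c(uloa = mean_diff + 1.96 * sd_diff,
    lloa = mean_diff - 1.96 * sd_diff)
}

#' Bland-Altman analysis of paired volumes
#'
#' Differences are taken per the declared direction (default estimated minus
#' observed); s is their sample (n - 1) standard deviation; the 95% limits of
#' agreement are mean +/- 1.96 s. Per-pair (mean, difference) coordinates are
#' returned for plotting.
#'
#' @inheritParams regression_metrics
#' @param conventions an [agreement_conventions()].
#' @return list with `mean_diff`, `sd_diff`, `uloa`, `lloa`, `n` and a
#'   data.frame `pairs` (columns `mean`, `diff`).
#' @export
bland_altman <- function(observed, estimated,
                         conventions = agreement_conventions()) {
  .check_paired(observed, estimated)
  d <- if (conventions$diff_direction == "est_minus_obs")
    estimated - observed else observed - estimated
  m <- mean(d)
  s <- sd(d)
  lim <- loa_limits(m, s)
  list(mean_diff = m, sd_diff = s,
       uloa = lim[["uloa"]], lloa = lim[["lloa"]],
       n = length(d),
       pairs = data.frame(mean = (observed + estimated) / 2, diff = d))
}

#' Concordance correlation coefficient
#'
#' Lin's coefficient of agreement:
#' rho_c = 2 rho sigma_x sigma_y / (sigma_x^2 + sigma_y^2 + (mu_x - mu_y)^2),
#' combining precision (the correlation rho) with accuracy (the location and
#' scale shift). Population (n) variance denominators by default.
#'
#' @inheritParams bland_altman
#' @return rho_c in [-1, 1]; exactly 1 iff the vectors are identical
#'   elementwise.
#' @export
ccc <- function(observed, estimated, conventions = agreement_conventions()) {
  .check_paired(observed, estimated)
  x <- observed; y <- estimated
  n <- length(x)
  denomf <- if (conventions$variance_mode == "population") n else n - 1
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / denomf
  vy <- sum((y - my)^2) / denomf
  if (vx == 0 || vy == 0) {
    if (all(x == y)) return(1)
    stop("zero variance; concordance correlation undefined")
  }
  sxy <- sum((x - mx) * (y - my)) / denomf
  2 * sxy / (vx + vy + (mx - my)^2)
}

#' Gauge repeatability percentage from replicated measurements
#'
#' One-factor (parts) random-effects variance decomposition of replicated
#' reference measurements: the within-part mean square estimates the
#' repeatability variance of the measurement system, the between-part mean
#' square yields the part-to-part variance (via the mean-square weight n0
#' for unbalanced designs), and GRR% = sigma^2_GRR / sigma^2_total x 100 with
#' sigma^2_GRR the repeatability component (no operator factor is modelled).
#' Negative component estimates are truncated at 0.
#'
#' @param replicates list (one element per part) or matrix (parts x repeats,
#'   NA-padded) of replicate measurements; >= 2 parts, >= 2 repeats each.
#' @return list with `grr_percent`, `sigma2_repeatability`, `sigma2_parts`,
#'   `sigma2_total`.
#' @export
grr <- function(replicates) {
  if (is.matrix(replicates) || is.data.frame(replicates)) {
    replicates <- apply(as.matrix(replicates), 1, function(r) r[!is.na(r)],
                        simplify = FALSE)
  }
  k <- length(replicates)
  if (k < 2L) stop("gauge study needs at least 2 parts")
  ni <- lengths(replicates)
  if (any(ni < 2L)) stop("every part needs at least 2 replicate measurements")
  N <- sum(ni)
  means <- vapply(replicates, mean, 0)
  grand <- sum(ni * means) / N
  ss_within <- sum(vapply(replicates, function(r) sum((r - mean(r))^2), 0))
  ss_between <- sum(ni * (means - grand)^2)
  ms_within <- ss_within / (N - k)
  ms_between <- ss_between / (k - 1)
  n0 <- (N - sum(ni^2) / N) / (k - 1)  # mean-square weight, balanced: n0 = n
  s2_rep <- ms_within
  s2_parts <- max((ms_between - ms_within) / n0, 0)
  s2_tot <- s2_rep + s2_parts
  list(grr_percent = if (s2_tot > 0) 100 * s2_rep / s2_tot else 0,
       sigma2_repeatability = s2_rep,
       sigma2_parts = s2_parts,
       sigma2_total = s2_tot)
}

.midranks <- function(x) rank(x, ties.method = "average")

#' Kruskal-Wallis rank test
#'
#' H = 12 / (N (N + 1)) * sum R_i^2 / n_i - 3 (N + 1) over pooled mid-ranks,
#' divided by the tie-correction factor 1 - sum(t^3 - t) / (N^3 - N) when tie
#' correction is on; p from the chi-squared approximation with k - 1 degrees
#' of freedom. A single group collapses to H = 0.
#'
#' @param groups list of >= 1 numeric vectors, each non-empty; pooled size
#'   >= 3 for the chi-squared approximation to be meaningful.
#' @param conventions an [agreement_conventions()].
#' @return list with `H`, `p`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups, conventions = agreement_conventions()) {
  if (!is.list(groups) || length(groups) < 1L) stop("groups must be a non-empty list")
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  if (length(unique(pooled)) == 1L && length(groups) > 1L)
    stop("all pooled values identical; H undefined (tie correction divides by zero)")
  r <- .midranks(pooled)
  g <- rep(seq_along(groups), lengths(groups))
  Ri <- tapply(r, g, sum)
  ni <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  if (conventions$tie_correction) {
    t <- table(pooled)
    corr <- 1 - sum(t^3 - t) / (N^3 - N)
    if (corr <= 0) stop("degenerate ties; H undefined")
    H <- H / corr
  }
  df <- length(groups) - 1L
  p <- if (df > 0) pchisq(H, df, lower.tail = FALSE) else NA_real_
  list(H = max(H, 0), p = p, df = df, n = N)
}

# exact null distribution of the rank sum of group 1 by enumeration is
# equivalent to the Wilcoxon distribution; use R's dwilcox for U1
.mwu_exact_p <- function(u_min, n1, n2) {
  # two-sided: P(min(U1, U2) <= u_min) under the null
  u <- 0:(n1 * n2)
  dens <- stats::dwilcox(u, n1, n2)
  umin <- pmin(u, n1 * n2 - u)
  sum(dens[umin <= u_min])
}

#' Mann-Whitney U test
#'
#' U = n1 n2 + n1 (n1 + 1) / 2 - R1 with R1 the mid-rank sum of group 1; the
#' reported statistic is min(U, n1 n2 - U). The p value is exact (null
#' distribution of U) when n1 + n2 <= 12 and the pooled data has no ties,
#' otherwise a normal approximation with tie-adjusted variance and
#' continuity correction is used.
#'
#' @param group1,group2 non-empty numeric vectors.
#' @param conventions an [agreement_conventions()].
#' @return list with `U` (min-statistic), `U1` (group-1 statistic), `p`,
#'   `method`.
#' @export
mann_whitney_u <- function(group1, group2,
                           conventions = agreement_conventions()) {
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  n1 <- length(group1); n2 <- length(group2)
  pooled <- c(group1, group2)
  r <- .midranks(pooled)
  R1 <- sum(r[seq_len(n1)])
  U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
  U <- min(U1, n1 * n2 - U1)
  ties <- any(duplicated(pooled))
  if (n1 + n2 <= 12 && !ties) {
    p <- .mwu_exact_p(U, n1, n2)
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    t <- table(pooled)
    tie_term <- if (conventions$tie_correction) sum(t^3 - t) / (N * (N - 1)) else 0
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U1 - mu) - 0.5) / sqrt(sig2)
      z <- max(z, 0)
      p <- 2 * pnorm(z, lower.tail = FALSE)
    }
    p <- min(p, 1)
    method <- "normal_approximation"
  }
  list(U = U, U1 = U1, p = p, method = method)
}
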