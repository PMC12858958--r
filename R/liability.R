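#' Liability threshold for a given prevalence
#'
#' Under the liability-threshold model, disease occurs when a latent
#' standard-normal liability exceeds the threshold `t = qnorm(1 - K)`,
#' where `K` is the disease prevalence (here typically the 5-year case
#' proportion of a cohort subgroup).
#'
#' @param K Prevalence, strictly between 0 and 1.
#' @return The liability threshold `t`.
#' @examples
#' liability_threshold(0.5)   # 0
#' liability_threshold(0.021)
#' @export
liability_threshold <- function(K) {
  if (!is.numeric(K) || any(!is.finite(K)) || any(K <= 0) || any(K >= 1))
    stop("prevalence K must lie strictly in (0, 1)", call. = FALSE)
  stats::qnorm(1 - K)
}

# moments of the standard normal truncated at t: cases are L > t, controls
# L <= t; used by the forward AUC model
.truncnorm_moments <- function(K) {
  t <- liability_threshold(K)
  m1 <- stats::dnorm(t) / K          # E[L | L > t]
  v1 <- 1 + t * m1 - m1^2            # Var[L | L > t]
  m0 <- -stats::dnorm(t) / (1 - K)   # E[L | L <= t]
  v0 <- 1 + t * m0 - m0^2
  list(t = t, m1 = m1, v1 = v1, m0 = m0, v0 = v0)
}

#' Forward liability model: AUC implied by a PGS-liability correlation
#'
#' The PGS Z-score and the liability are modelled as standard bivariate
#' normal with correlation `rho`; cases have liability above the
#' threshold for prevalence `K`. The case and control Z distributions are
#' then normal-mixture projections of truncated normals; the AUC is
#' computed from their truncated-normal means and variances via the
#' binormal formula. The approximation error against direct simulation is
#' below 0.005 AUC across the operating range (see package tests).
#'
#' @param rho PGS-liability correlation, in `[0, 1)`.
#' @param K Prevalence in `(0, 1)`.
#' @return The implied AUC, in `[0.5, 1)`; `rho = 0` gives exactly 0.5.
#' @seealso [rho_from_auc()] for the numerical inverse.
#' @examples
#' auc_from_rho(0, 0.05)    # 0.5
#' auc_from_rho(0.3, 0.05)
#' @export
auc_from_rho <- function(rho, K) {
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(rho < 0) || any(rho >= 1))
    stop("rho must lie in [0, 1)", call. = FALSE)
  mo <- .truncnorm_moments(K)
  num <- rho * (mo$m1 - mo$m0)
  den <- sqrt(rho^2 * (mo$v1 + mo$v0) + 2 * (1 - rho^2))
  stats::pnorm(num / den)
}

#' Invert the forward liability model: correlation from an observed AUC
#'
#' Numerically inverts [auc_from_rho()] by bracketed root finding, so that
#' a subgroup's observed PGS Z-score AUC and case proportion map to the
#' correlation parameter of the liability model. The round trip
#' `auc_from_rho(rho_from_auc(a, K), K)` reproduces `a` to within 1e-6.
#'
#' @param auc Observed AUC, in `[0.5, 1)`. Values below 0.5 are rejected:
#'   the convention is that higher scores mean higher risk.
#' @param K Prevalence in `(0, 1)`.
#' @return The correlation `rho` in `[0, 1)`.
#' @examples
#' rho_from_auc(0.65, 176 / 8291)
#' @export
rho_from_auc <- function(auc, K) {
  if (!is.numeric(auc) || length(auc) != 1L || !is.finite(auc) ||
      auc < 0.5 || auc >= 1)
    stop("auc must lie in [0.5, 1); scores are oriented so that higher ",
         "values mean higher risk", call. = FALSE)
  if (auc == 0.5) return(0)
  stats::uniroot(function(r) auc_from_rho(r, K) - auc,
                 interval = c(0, 1 - 1e-12), tol = 1e-12)$root
}

#' Construct a liability-threshold model
#'
#' Bundles the parameters of the liability-threshold mapping between PGS
#' Z-scores and disease risk: prevalence `K`, threshold `t`, PGS-liability
#' correlation `rho`, the implied AUC, and the standardized case-control
#' mean difference `d = sqrt(2) * qnorm(AUC)` kept for reporting.
#' Supply exactly one of `rho` or `auc`.
#'
#' @param K Prevalence in `(0, 1)`.
#' @param rho PGS-liability correlation in `[0, 1)`, or `NULL`.
#' @param auc Observed AUC in `[0.5, 1)`, or `NULL`.
#' @return An object of class `"liability_model"`: a list with elements
#'   `K`, `t`, `rho`, `auc`, `d`.
#' @examples
#' m <- liability_model(K = 176 / 8291, auc = 0.65)
#' m$rho
#' @export
liability_model <- function(K, rho = NULL, auc = NULL) {
  t <- liability_threshold(K)
  if (is.null(rho) == is.null(auc))
    stop("supply exactly one of rho or auc", call. = FALSE)
  if (is.null(rho)) rho <- rho_from_auc(auc, K)
  auc <- auc_from_rho(rho, K)
  structure(list(K = K, t = t, rho = rho, auc = auc,
                 d = sqrt(2) * stats::qnorm(auc)),
            class = "liability_model")
}

#' @export
print.liability_model <- function(x, ...) {
  cat("Liability-threshold model\n")
  cat(sprintf("  prevalence K : %.6g\n", x$K))
  cat(sprintf("  threshold  t : %.6g\n", x$t))
  cat(sprintf("  correlation  : %.6g\n", x$rho))
  cat(sprintf("  implied AUC  : %.4f\n", x$auc))
  cat(sprintf("  Cohen's d    : %.4f\n", x$d))
  invisible(x)
}

#' Relative risk for an individual PGS Z-score
#'
#' The probability of disease given a Z-score `z` under the liability
#' model is `pnorm((rho * z - t) / sqrt(1 - rho^2))`; dividing by the
#' prevalence gives the relative risk versus the population average. The
#' function is strictly increasing in `z` for `rho > 0` and integrates to
#' 1 against the standard-normal density of `z`.
#'
#' @param z PGS Z-score(s); vectorized.
#' @param model A [liability_model()].
#' @return Relative risk(s), non-negative.
#' @examples
#' m <- liability_model(K = 0.021, rho = 0.23)
#' individual_relative_risk(c(-2, 0, 2), m)
#' @export
individual_relative_risk <- function(z, model) {
  stopifnot(inherits(model, "liability_model"))
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  stats::pnorm((model$rho * z - model$t) / sqrt(1 - model$rho^2)) / model$K
}

# integration bounds for z: the standard-normal mass outside [-8, 8] is
# below 1e-15, far inside the 1e-6 tolerances used downstream
.Z_LIM <- 8

# P(case and Z in [lo, hi]) under the model, by adaptive quadrature
.bin_case_mass <- function(model, lo, hi, abs.tol = 1e-9) {
  lo <- max(lo, -.Z_LIM); hi <- min(hi, .Z_LIM)
  if (hi <= lo) return(0)
  f <- function(z)
    stats::dnorm(z) *
      stats::pnorm((model$rho * z - model$t) / sqrt(1 - model$rho^2))
  res <- tryCatch(
    stats::integrate(f, lo, hi, abs.tol = abs.tol, rel.tol = 1e-10,
                     subdivisions = 400L),
    error = function(e)
      stop("quantile-RR integration failed on [", signif(lo, 4), ", ",
           signif(hi, 4), "]: ", conditionMessage(e), call. = FALSE))
  res$value
}

#' Estimated relative risks by PGS quantile
#'
#' Partitions the standard-normal Z scale into `n_quantiles` bins of equal
#' probability (theoretical normal cut points) and computes, for each bin,
#' the mean disease probability divided by the prevalence:
#' `RR_i = E[P(case | Z) | Z in bin i] / K`, by adaptive numerical
#' integration. The probability-weighted mean of the returned RRs is 1 by
#' construction (checked to 1e-6).
#'
#' @param model A [liability_model()].
#' @param n_quantiles Number of equal-probability bins, at least 2.
#' @param reference Either `"population"` (default; RRs are versus the
#'   population average) or `"middle"` (all RRs divided by the middle
#'   bin's RR, a display convention for dense quantile plots).
#' @return A data frame of class `"quantile_rr"` with columns
#'   `quantile_index`, `z_lower`, `z_upper`, `estimated_rr`.
#' @examples
#' m <- liability_model(K = 0.021, auc = 0.65)
#' quantile_relative_risks(m, 5)
#' @export
quantile_relative_risks <- function(model, n_quantiles,
                                    reference = c("population", "middle")) {
  stopifnot(inherits(model, "liability_model"))
  reference <- match.arg(reference)
  if (!is.numeric(n_quantiles) || length(n_quantiles) != 1L ||
      n_quantiles < 2 || n_quantiles != round(n_quantiles))
    stop("n_quantiles must be an integer >= 2", call. = FALSE)
  n_quantiles <- as.integer(n_quantiles)
  breaks <- stats::qnorm(seq(0, 1, length.out = n_quantiles + 1L))
  p_bin <- 1 / n_quantiles
  rr <- vapply(seq_len(n_quantiles), function(i) {
    .bin_case_mass(model, breaks[i], breaks[i + 1L]) / (p_bin * model$K)
  }, numeric(1))
  wsum <- sum(p_bin * rr)
  if (abs(wsum - 1) > 1e-6)
    stop(sprintf(paste0("quantile RR integration inconsistent: ",
                        "probability-weighted mean %.8f differs from 1"),
                 wsum), call. = FALSE)
  if (reference == "middle") {
    mid <- ceiling(n_quantiles / 2)
    rr <- rr / rr[mid]
  }
  out <- data.frame(quantile_index = seq_len(n_quantiles),
                    z_lower = breaks[-length(breaks)],
                    z_upper = breaks[-1L],
                    estimated_rr = rr)
  class(out) <- c("quantile_rr", "data.frame")
  attr(out, "reference") <- reference
  out
}

#' Observed relative risks by PGS quantile, with Katz confidence intervals
#'
#' Observed relative risk in a bin is the bin's case fraction divided by
#' the overall case fraction, `(x_i / n_i) / (X / N)`. 95% intervals use
#' the Katz log method: `SE(log RR) = sqrt(1/x_i - 1/n_i + 1/X - 1/N)`,
#' with bounds `exp(log RR +/- z * SE)`. Bins with zero cases report
#' `observed_rr = 0` with the interval flagged undefined (`NA`); no
#' continuity correction is applied.
#'
#' Bins are formed either from explicit `breaks` on the Z scale, or as
#' equal-count empirical quantile bins (`n_quantiles`), assigning sorted
#' samples to bins in stable order so ties never straddle a boundary
#' unpredictably.
#'
#' @param z Numeric vector of PGS Z-scores.
#' @param case Logical (or 0/1) vector of case indicators, same length.
#' @param breaks Optional numeric vector of bin boundaries (length
#'   `n_bins + 1`, strictly increasing, spanning the data).
#' @param n_quantiles Number of equal-count bins when `breaks` is absent.
#' @param conf_level Confidence level for the Katz intervals.
#' @return A data frame of class `"quantile_rr"` with columns
#'   `quantile_index`, `z_lower`, `z_upper`, `n_in_bin`, `cases_in_bin`,
#'   `observed_rr`, `ci_lower`, `ci_upper`.
#' @examples
#' set.seed(1)
#' z <- rnorm(2000); case <- runif(2000) < plogis(z - 2)
#' observed_quantile_rr(z, case, n_quantiles = 5)
#' @export
observed_quantile_rr <- function(z, case, breaks = NULL, n_quantiles = NULL,
                                 conf_level = 0.95) {
  stopifnot(length(z) == length(case))
  case <- as.logical(case)
  if (anyNA(z) || anyNA(case)) stop("z and case must be complete", call. = FALSE)
  N <- length(z); X <- sum(case)
  if (X == 0) stop("no cases observed; relative risks undefined", call. = FALSE)
  if (is.null(breaks)) {
    if (is.null(n_quantiles))
      stop("supply breaks or n_quantiles", call. = FALSE)
    q <- as.integer(n_quantiles)
    if (q < 2) stop("n_quantiles must be >= 2", call. = FALSE)
    # equal-count bins: stable assignment by sample order within ties
    ord <- order(z)
    sizes <- rep(N %/% q, q) + c(rep(1L, N %% q), rep(0L, q - N %% q))
    bin <- integer(N)
    bin[ord] <- rep.int(seq_len(q), sizes)
    lo <- tapply(z, bin, min); hi <- tapply(z, bin, max)
  } else {
    if (is.unsorted(breaks, strictly = TRUE))
      stop("breaks must be strictly increasing", call. = FALSE)
    q <- length(breaks) - 1L
    bin <- findInterval(z, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    lo <- breaks[-length(breaks)]; hi <- breaks[-1L]
  }
  x <- vapply(seq_len(q), function(i) sum(case[bin == i]), numeric(1))
  n <- vapply(seq_len(q), function(i) sum(bin == i), numeric(1))
  rr <- ifelse(n > 0, (x / n) / (X / N), NA_real_)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(pmax(1 / x - 1 / n + 1 / X - 1 / N, 0))
  ci_lo <- ifelse(x > 0, exp(log(rr) - zq * se), NA_real_)
  ci_hi <- ifelse(x > 0, exp(log(rr) + zq * se), NA_real_)
  out <- data.frame(quantile_index = seq_len(q),
                    z_lower = as.numeric(lo), z_upper = as.numeric(hi),
                    n_in_bin = as.integer(n), cases_in_bin = as.integer(x),
                    observed_rr = rr, ci_lower = ci_lo, ci_upper = ci_hi)
  class(out) <- c("quantile_rr", "data.frame")
  out
}

#' Relative risk for carriers of a rare variant
#'
#' The fraction of cases among carriers divided by the overall case
#' fraction, used to put PGS quantile risks side by side with published
#' carrier risks for moderate- and high-penetrance genes.
#'
#' @param carrier_cases Number of carriers who are cases.
#' @param carriers Total number of carriers (>= 1).
#' @param total_cases Total cases in the study (>= 1).
#' @param total_n Total study size.
#' @return The carrier relative risk.
#' @examples
#' carrier_relative_risk(10, 20, 100, 1000) # 5
#' @export
carrier_relative_risk <- function(carrier_cases, carriers, total_cases,
                                  total_n) {
  if (carriers < 1 || total_cases < 1 || total_n < 1)
    stop("carriers, total_cases and total_n must be positive", call. = FALSE)
  if (carrier_cases < 0 || carrier_cases > carriers)
    stop("carrier_cases must lie in [0, carriers]", call. = FALSE)
  (carrier_cases / carriers) / (total_cases / total_n)
}
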