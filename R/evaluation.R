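#' Area under the ROC curve (Mann-Whitney with midranks)
#'
#' The probability that a randomly chosen case outscores a randomly
#' chosen control, with ties counted one half: `AUC = U / (n1 * n0)`
#' computed from midranks.
#'
#' @param scores Numeric predictions (higher = more case-like).
#' @param labels Logical (or 0/1) case indicators.
#' @return The AUC in `[0, 1]`.
#' @examples
#' auc(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)) # 0.875
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels))
    stop("scores and labels must be complete", call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("AUC needs at least one case and one control", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Stratified-bootstrap percentile confidence interval for an AUC
#'
#' Cases and controls are resampled separately (stratified bootstrap, so
#' every replicate keeps the observed case/control sizes); the interval
#' is the percentile 2.5/97.5 range of the replicate AUCs. Replicates
#' with an undefined AUC are dropped and counted in the
#' `"n_dropped"` attribute.
#'
#' @param scores,labels As in [auc()].
#' @param B Number of bootstrap replicates (default 2000).
#' @param seed Integer seed; the interval is deterministic given it.
#' @param conf_level Confidence level.
#' @return Named numeric `c(lower, upper)` with attribute `n_dropped`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 2000L, seed = 1L,
                             conf_level = 0.95) {
  labels <- as.logical(labels)
  i1 <- which(labels); i0 <- which(!labels)
  if (length(i1) < 2L || length(i0) < 2L)
    stop("stratified bootstrap needs >= 2 cases and >= 2 controls",
         call. = FALSE)
  s1 <- scores[i1]; s0 <- scores[i0]
  n1 <- length(s1); n0 <- length(s0)
  lab <- c(rep(TRUE, n1), rep(FALSE, n0))
  with_substream(seed, "bootstrap_auc", {
    reps <- vapply(seq_len(B), function(b) {
      x <- c(s1[sample.int(n1, n1, replace = TRUE)],
             s0[sample.int(n0, n0, replace = TRUE)])
      r <- rank(x)
      (sum(r[lab]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
    }, numeric(1))
    dropped <- sum(is.na(reps))
    a <- (1 - conf_level) / 2
    ci <- stats::quantile(reps[!is.na(reps)], c(a, 1 - a), names = FALSE,
                          type = 7)
    structure(c(lower = ci[1], upper = ci[2]), n_dropped = dropped)
  })
}

# placement values: for each case, the fraction of controls it beats
# (ties half); and symmetrically for controls
.placements <- function(scores, labels) {
  s1 <- scores[labels]; s0 <- scores[!labels]
  n1 <- length(s1); n0 <- length(s0)
  r_all <- rank(c(s1, s0))
  r1 <- rank(s1); r0 <- rank(s0)
  V10 <- (r_all[seq_len(n1)] - r1) / n0         # per-case
  V01 <- 1 - (r_all[n1 + seq_len(n0)] - r0) / n1 # per-control
  list(V10 = V10, V01 = V01, auc = mean(V10))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same samples
#' using the DeLong placement-value covariance: the variance of the AUC
#' difference is assembled from the empirical covariance matrices of the
#' per-case and per-control placement values, and the two-sided p-value
#' comes from the normal reference. When the two scores are
#' rank-identical the variance is zero and the comparison is reported as
#' degenerate (`z` and `p` are `NA`) rather than as p = 0.
#'
#' @param scores_a,scores_b Paired score vectors on the same samples.
#' @param labels Case indicators.
#' @return A list with `auc_a`, `auc_b`, `delta_auc`, `se`, `z`,
#'   `p_value`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 < 2L || n0 < 2L)
    stop("DeLong test needs >= 2 cases and >= 2 controls", call. = FALSE)
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  S10 <- stats::cov(cbind(pa$V10, pb$V10))
  S01 <- stats::cov(cbind(pa$V01, pb$V01))
  v <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / n1 +
       (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n0
  delta <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta,
                se = 0, z = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  }
  se <- sqrt(v)
  z <- delta / se
  list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta, se = se,
       z = z, p_value = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Expected/observed calibration ratio
#'
#' `E` is the (design-weighted) sum of predicted risks over the at-risk
#' set and `O` the weighted observed case count; `E/O = 1` indicates
#' calibration-in-the-large. For whole-cohort designs the 95% CI uses
#' the log-normal method with `SE(log E/O) = 1 / sqrt(O)`. For
#' case-cohort designs a stratified bootstrap (sub-cohort members and
#' outside-sub-cohort cases resampled as separate strata) gives robust
#' percentile intervals.
#'
#' @param predicted_risks Predicted absolute risks in `[0, 1]`.
#' @param outcomes Observed case indicators.
#' @param weights Design weights (default 1).
#' @param design `"cohort"` or `"case_cohort"`.
#' @param subcohort Logical vector flagging sub-cohort membership
#'   (required for `design = "case_cohort"`).
#' @param B Bootstrap replicates for the case-cohort interval.
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return A list with `e_over_o`, `ci_lower`, `ci_upper`, `expected`,
#'   `observed`.
#' @export
expected_observed <- function(predicted_risks, outcomes,
                              weights = rep(1, length(outcomes)),
                              design = c("cohort", "case_cohort"),
                              subcohort = NULL, B = 1000L, seed = 1L,
                              conf_level = 0.95) {
  design <- match.arg(design)
  outcomes <- as.logical(outcomes)
  if (any(predicted_risks < 0 | predicted_risks > 1, na.rm = TRUE))
    stop("predicted risks must lie in [0, 1]", call. = FALSE)
  if (anyNA(predicted_risks))
    stop("predicted risks must be complete", call. = FALSE)
  E <- sum(weights * predicted_risks)
  O <- sum(weights * outcomes)
  if (O <= 0)
    stop("no observed cases; E/O undefined", call. = FALSE)
  eo <- E / O
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (design == "cohort") {
    half <- zq / sqrt(O)
    return(list(e_over_o = eo, ci_lower = eo * exp(-half),
                ci_upper = eo * exp(half), expected = E, observed = O))
  }
  if (is.null(subcohort))
    stop("case_cohort design needs the subcohort membership flags",
         call. = FALSE)
  sub_i <- which(subcohort)
  case_i <- which(!subcohort & outcomes)
  reps <- with_substream(seed, "eo_bootstrap", {
    vapply(seq_len(B), function(b) {
      i <- c(sub_i[sample.int(length(sub_i), replace = TRUE)],
             if (length(case_i))
               case_i[sample.int(length(case_i), replace = TRUE)])
      Eb <- sum(weights[i] * predicted_risks[i])
      Ob <- sum(weights[i] * outcomes[i])
      if (Ob > 0) Eb / Ob else NA_real_
    }, numeric(1))
  })
  a <- (1 - conf_level) / 2
  ci <- stats::quantile(reps[!is.na(reps)], c(a, 1 - a), names = FALSE)
  list(e_over_o = eo, ci_lower = ci[1], ci_upper = ci[2],
       expected = E, observed = O)
}

#' Percentage of incident cases captured by top score fractions
#'
#' For each fraction `f`, the score threshold is the empirical
#' `(1 - f)` quantile taken as the `ceiling(f * n)`-th largest score;
#' ties at the boundary are included in the top group. Returns the
#' percentage of incident cases occurring in each top group.
#'
#' @param scores Numeric scores over the full analysis set.
#' @param cases Case indicators.
#' @param top_fractions Fractions of the population, default
#'   `c(0.10, 0.25, 0.50)`.
#' @return A data frame with `top_fraction`, `threshold`,
#'   `pct_cases_captured` (in `[0, 100]`, non-decreasing in the
#'   fraction).
#' @export
case_capture <- function(scores, cases,
                         top_fractions = c(0.10, 0.25, 0.50)) {
  cases <- as.logical(cases)
  stopifnot(length(scores) == length(cases), sum(cases) > 0)
  n <- length(scores)
  srt <- sort(scores, decreasing = TRUE)
  res <- lapply(top_fractions, function(f) {
    stopifnot(f > 0, f <= 1)
    thr <- srt[ceiling(f * n)]
    top <- scores >= thr   # boundary ties included in the top group
    data.frame(top_fraction = f, threshold = thr,
               pct_cases_captured = 100 * sum(cases & top) / sum(cases))
  })
  do.call(rbind, res)
}

#' Stratified discrimination and calibration report
#'
#' Evaluates one or more score columns within user-defined strata,
#' applying the reporting rules of the analysis: prevalent cases are
#' excluded from the incident analysis set (unless
#' `include_prevalent = TRUE`, the sensitivity mode in which prevalent
#' cases are counted as cases); strata with fewer than `min_cases`
#' incident cases are skipped and listed with the reason; each evaluated
#' stratum reports per-score AUCs with stratified-bootstrap CIs, all
#' pairwise DeLong comparisons, and (when a `predicted_risk` style
#' column is among the scores and lies in `[0, 1]`) the E/O calibration
#' ratio.
#'
#' @param cohort A `"cohort_table"` data frame.
#' @param strata Either a column name (each level is a stratum) or a
#'   named list of logical masks over the cohort rows.
#' @param score_cols Character vector of cohort columns to evaluate.
#' @param risk_cols Subset of `score_cols` that are absolute risks, for
#'   which E/O calibration is also computed (default: those named with a
#'   `"risk"` substring).
#' @param min_cases Minimum incident cases for a stratum to be
#'   evaluated (default 10).
#' @param B Bootstrap replicates for AUC CIs.
#' @param seed Integer seed.
#' @param include_prevalent Sensitivity mode: include prevalent cases as
#'   cases instead of excluding them.
#' @return An object of class `"evaluation_report"`: a list with data
#'   frames `auc`, `delong`, `calibration`, `skipped` and the per-stratum
#'   metadata `strata`.
#' @export
stratified_evaluate <- function(cohort, strata, score_cols,
                                risk_cols = grep("risk", score_cols,
                                                 value = TRUE),
                                min_cases = 10L, B = 2000L, seed = 1L,
                                include_prevalent = FALSE) {
  stopifnot(all(score_cols %in% names(cohort)))
  if (is.character(strata) && length(strata) == 1L) {
    lev <- unique(as.character(cohort[[strata]]))
    masks <- lapply(lev, function(l) cohort[[strata]] == l)
    names(masks) <- lev
  } else {
    masks <- strata
    if (is.null(names(masks)) || any(!nzchar(names(masks))))
      stop("strata masks must be named", call. = FALSE)
  }
  prev <- if ("prevalent_case" %in% names(cohort))
    cohort$prevalent_case else rep(FALSE, nrow(cohort))
  auc_rows <- list(); dl_rows <- list(); cal_rows <- list()
  skip_rows <- list(); meta_rows <- list()
  for (s in names(masks)) {
    m <- masks[[s]] & !is.na(masks[[s]])
    if (!include_prevalent) m <- m & !prev
    sub <- cohort[m, , drop = FALSE]
    if (nrow(sub) == 0) {
      skip_rows[[s]] <- data.frame(stratum = s, reason = "empty stratum")
      next
    }
    case <- sub$incident_case_5y | (include_prevalent & sub$prevalent_case)
    n_cases <- sum(case)
    if (n_cases < min_cases) {
      skip_rows[[s]] <- data.frame(stratum = s, reason = sprintf(
        "only %d incident cases (minimum %d)", n_cases, min_cases))
      next
    }
    meta_rows[[s]] <- data.frame(stratum = s, n = nrow(sub),
                                 n_cases = n_cases,
                                 n_controls = sum(!case))
    for (sc in score_cols) {
      ci <- bootstrap_auc_ci(sub[[sc]], case, B = B,
                             seed = substream_seed(seed, paste0(s, sc)))
      auc_rows[[paste(s, sc)]] <- data.frame(
        stratum = s, score = sc, auc = auc(sub[[sc]], case),
        ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
        n_cases = n_cases, n_controls = sum(!case))
    }
    if (length(score_cols) > 1) {
      cmb <- utils::combn(score_cols, 2)
      for (k in seq_len(ncol(cmb))) {
        a <- cmb[1, k]; b <- cmb[2, k]
        dt <- delong_test(sub[[a]], sub[[b]], case)
        dl_rows[[paste(s, a, b)]] <- data.frame(
          stratum = s, score_a = a, score_b = b,
          delta_auc = dt$delta_auc, z = dt$z, p_value = dt$p_value,
          degenerate = dt$degenerate)
      }
    }
    for (rc in intersect(risk_cols, score_cols)) {
      r <- sub[[rc]]
      if (any(r < 0 | r > 1, na.rm = TRUE)) next
      w <- if ("design_weight" %in% names(sub)) sub$design_weight else
        rep(1, nrow(sub))
      is_cc <- "subcohort_member" %in% names(sub) &&
        !anyNA(sub$subcohort_member) && !all(sub$subcohort_member)
      eo <- if (is_cc)
        expected_observed(r, case, w, design = "case_cohort",
                          subcohort = sub$subcohort_member,
                          seed = substream_seed(seed, paste0("eo", s, rc)))
      else expected_observed(r, case, w)
      cal_rows[[paste(s, rc)]] <- data.frame(
        stratum = s, score = rc, e_over_o = eo$e_over_o,
        ci_lower = eo$ci_lower, ci_upper = eo$ci_upper,
        expected = eo$expected, observed = eo$observed)
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, unname(x)) else
    data.frame()
  structure(list(strata = bind(meta_rows), auc = bind(auc_rows),
                 delong = bind(dl_rows), calibration = bind(cal_rows),
                 skipped = bind(skip_rows)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report:", nrow(x$strata), "strata evaluated,",
      nrow(x$skipped), "skipped\n")
  if (nrow(x$auc)) { cat("\nAUC:\n"); print(x$auc, row.names = FALSE) }
  if (nrow(x$calibration)) {
    cat("\nCalibration (E/O):\n"); print(x$calibration, row.names = FALSE)
  }
  if (nrow(x$skipped)) {
    cat("\nSkipped strata:\n"); print(x$skipped, row.names = FALSE)
  }
  invisible(x)
}
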