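#' Construct a population rate table over 5-year age bands
#'
#' Holds piecewise-constant cause-specific hazards per age band: the
#' disease incidence hazard among the event-free and the competing
#' all-cause-minus-disease mortality hazard, both in events per
#' person-year. Bands are half-open `[age_low, age_high)` in whole years
#' and must be contiguous, non-overlapping and sorted.
#'
#' @param age_low,age_high Integer band bounds in years.
#' @param incidence_hazard Disease incidence hazard per band (>= 0).
#' @param other_mortality_hazard Competing mortality hazard per band (>= 0).
#' @param population Optional population count per band.
#' @return A data frame of class `"rate_table"`.
#' @examples
#' rate_table(c(40, 45), c(45, 50), c(0.001, 0.002), c(0.002, 0.003))
#' @export
rate_table <- function(age_low, age_high, incidence_hazard,
                       other_mortality_hazard, population = NULL) {
  n <- length(age_low)
  stopifnot(length(age_high) == n, length(incidence_hazard) == n,
            length(other_mortality_hazard) == n)
  if (any(!is.finite(incidence_hazard)) || any(incidence_hazard < 0) ||
      any(!is.finite(other_mortality_hazard)) ||
      any(other_mortality_hazard < 0))
    stop("hazards must be finite and non-negative", call. = FALSE)
  if (any(age_high <= age_low))
    stop("each band needs age_high > age_low", call. = FALSE)
  o <- order(age_low)
  age_low <- age_low[o]; age_high <- age_high[o]
  incidence_hazard <- incidence_hazard[o]
  other_mortality_hazard <- other_mortality_hazard[o]
  if (n > 1 && any(age_low[-1] != age_high[-n]))
    stop("age bands must be contiguous and non-overlapping", call. = FALSE)
  out <- data.frame(age_low = age_low, age_high = age_high,
                    incidence_hazard = incidence_hazard,
                    other_mortality_hazard = other_mortality_hazard)
  if (!is.null(population)) out$population <- population[o]
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Read / write rate tables as tab-separated text
#'
#' Columns: `age_low`, `age_high`, `incidence_hazard`,
#' `other_mortality_hazard`, optional `population`; one header line;
#' missing values as `NA`. Gzip-compressed files are read transparently.
#'
#' @param path File path.
#' @return `read_rate_table()` returns a [rate_table()];
#'   `write_rate_table()` returns `path` invisibly.
#' @export
read_rate_table <- function(path) {
  d <- utils::read.table(gzfile(path), header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("age_low", "age_high", "incidence_hazard",
            "other_mortality_hazard")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("rate table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rate_table(d$age_low, d$age_high, d$incidence_hazard,
             d$other_mortality_hazard, d$population)
}

#' @rdname read_rate_table
#' @param rates A [rate_table()].
#' @export
write_rate_table <- function(rates, path) {
  stopifnot(inherits(rates, "rate_table"))
  utils::write.table(as.data.frame(rates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# split [start, start + horizon) into sub-intervals at band boundaries;
# errors if any part is uncovered
.rate_intervals <- function(rates, start_age, horizon) {
  end_age <- start_age + horizon
  if (start_age < rates$age_low[1] || end_age > rates$age_high[nrow(rates)])
    stop(sprintf("rate table covers [%g, %g) but [%g, %g) requested; ",
                 rates$age_low[1], rates$age_high[nrow(rates)],
                 start_age, end_age),
         "ages outside the table are never extrapolated", call. = FALSE)
  cuts <- sort(unique(c(start_age, end_age,
                        rates$age_low[rates$age_low > start_age &
                                      rates$age_low < end_age])))
  lo <- cuts[-length(cuts)]; hi <- cuts[-1]
  band <- findInterval(lo, rates$age_low)
  data.frame(lo = lo, hi = hi,
             lc = rates$incidence_hazard[band],
             ld = rates$other_mortality_hazard[band])
}

#' Age-specific absolute risk under competing mortality
#'
#' Cause-specific cumulative incidence over `[start_age, start_age +
#' horizon)` with piecewise-constant hazards: within each sub-interval j
#' of length `D_j`, the contribution is
#' `S_j * lc_j / (lc_j + ld_j) * (1 - exp(-(lc_j + ld_j) * D_j))`,
#' where `S_j` is the probability of being alive and event-free at the
#' start of the sub-interval. Sub-intervals with both hazards zero
#' contribute exactly zero. This is the life-table quantity used for
#' "average population absolute 5-year risk" style calculations, with
#' death as a competing risk.
#'
#' @param rates A [rate_table()] covering the requested interval.
#' @param start_age Age (years) at the start of the horizon; vectorized.
#' @param horizon Length of the risk horizon in years (default 5).
#' @return Absolute risk(s) in `[0, 1]`.
#' @examples
#' rt <- rate_table(0, 100, 0.01, 0)
#' age_specific_risk(rt, 50)   # 1 - exp(-0.05)
#' @export
age_specific_risk <- function(rates, start_age, horizon = 5) {
  stopifnot(inherits(rates, "rate_table"), horizon > 0)
  one <- function(a) {
    iv <- .rate_intervals(rates, a, horizon)
    S <- 1; risk <- 0
    for (j in seq_len(nrow(iv))) {
      tot <- iv$lc[j] + iv$ld[j]
      d <- iv$hi[j] - iv$lo[j]
      if (tot > 0) {
        risk <- risk + S * (iv$lc[j] / tot) * (1 - exp(-tot * d))
        S <- S * exp(-tot * d)
      }
    }
    risk
  }
  vapply(start_age, one, numeric(1))
}

#' Combine an age-specific absolute risk with a PGS relative risk
#'
#' Multiplies the population-average absolute risk by the relative risk,
#' capping at 1 with a warning when the product exceeds certainty (the
#' multiplicative combination is an approximation that can overflow for
#' extreme strata).
#'
#' @param age_risk Absolute risk(s) in `[0, 1]`.
#' @param rr Relative risk(s), non-negative.
#' @return Absolute risk(s) in `[0, 1]`.
#' @examples
#' age_pgs_risk(0.012, 2.5) # 0.03
#' @export
age_pgs_risk <- function(age_risk, rr) {
  if (any(!is.finite(age_risk)) || any(age_risk < 0) || any(age_risk > 1))
    stop("age_risk must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(rr)) || any(rr < 0))
    stop("rr must be non-negative and finite", call. = FALSE)
  out <- age_risk * rr
  if (any(out > 1)) {
    warning(sum(out > 1), " risk value(s) capped at 1", call. = FALSE)
    out <- pmin(out, 1)
  }
  out
}

#' Absolute-risk surface by age band and PGS quantile
#'
#' Evaluates the 5-year absolute risk for every combination of age band
#' and PGS quantile stratum: the band's population-average risk times the
#' stratum's estimated relative risk. A `"population"` stratum (RR = 1)
#' is always included.
#'
#' @param rates A [rate_table()].
#' @param quantile_rrs A `"quantile_rr"` data frame with `estimated_rr`
#'   (from [quantile_relative_risks()]), or any data frame with columns
#'   `stratum` and `rr`.
#' @param ages Vector of band start ages to evaluate.
#' @param horizon Risk horizon in years.
#' @return A data frame of class `"risk_surface"` with columns
#'   `age_band_start`, `stratum`, `rr`, `risk`.
#' @export
risk_surface <- function(rates, quantile_rrs, ages, horizon = 5) {
  if (inherits(quantile_rrs, "quantile_rr")) {
    strata <- data.frame(
      stratum = sprintf("q%d", quantile_rrs$quantile_index),
      rr = quantile_rrs$estimated_rr)
  } else {
    stopifnot(all(c("stratum", "rr") %in% names(quantile_rrs)))
    strata <- quantile_rrs[, c("stratum", "rr")]
  }
  strata <- rbind(data.frame(stratum = "population", rr = 1), strata)
  base <- age_specific_risk(rates, ages, horizon)
  out <- expand.grid(age_band_start = ages, stratum = strata$stratum,
                     stringsAsFactors = FALSE)
  out$rr <- strata$rr[match(out$stratum, strata$stratum)]
  out$risk <- age_pgs_risk(rep(base, times = nrow(strata)), out$rr)
  class(out) <- c("risk_surface", "data.frame")
  out
}

#' Age at which each PGS stratum crosses a risk threshold
#'
#' For each stratum of a [risk_surface()], reports the earliest age band
#' whose absolute risk meets or exceeds `threshold`, and the shift
#' relative to a reference age (e.g. a population screening start age).
#' Strata never reaching the threshold are reported with `NA` crossing
#' age and status `"not reached"`.
#'
#' @param surface A [risk_surface()].
#' @param threshold Risk threshold in `(0, 1)` (e.g. 0.012).
#' @param reference_age Reference age in years (e.g. 50).
#' @return A data frame with columns `stratum`, `crossing_age`,
#'   `shift_years`, `status`.
#' @export
threshold_crossing_age <- function(surface, threshold, reference_age) {
  stopifnot(inherits(surface, "risk_surface"),
            threshold > 0, threshold < 1)
  strata <- unique(surface$stratum)
  res <- lapply(strata, function(s) {
    sub <- surface[surface$stratum == s, ]
    sub <- sub[order(sub$age_band_start), ]
    hit <- which(sub$risk >= threshold)
    if (length(hit) == 0)
      data.frame(stratum = s, crossing_age = NA_real_,
                 shift_years = NA_real_, status = "not reached")
    else {
      a <- sub$age_band_start[hit[1]]
      data.frame(stratum = s, crossing_age = a,
                 shift_years = a - reference_age, status = "reached")
    }
  })
  do.call(rbind, res)
}

#' Proportion of a cohort (and of its cases) above a risk threshold
#'
#' Given per-individual predicted absolute risks, computes the
#' design-weighted fraction of individuals whose predicted risk strictly
#' exceeds the threshold, and the fraction of incident cases occurring in
#' that group.
#'
#' @param cohort A cohort table with columns `predicted_risk`,
#'   `incident_case_5y` and optionally `design_weight`.
#' @param threshold Risk threshold.
#' @return A list with elements `prop_above` and `prop_cases_above`.
#' @export
proportion_above_threshold <- function(cohort, threshold) {
  stopifnot(all(c("predicted_risk", "incident_case_5y") %in% names(cohort)))
  if (anyNA(cohort$predicted_risk))
    stop("predicted_risk must be present for all records", call. = FALSE)
  w <- if ("design_weight" %in% names(cohort)) cohort$design_weight else
    rep(1, nrow(cohort))
  above <- cohort$predicted_risk > threshold
  case <- as.logical(cohort$incident_case_5y)
  list(prop_above = sum(w[above]) / sum(w),
       prop_cases_above = if (sum(w[case]) > 0)
         sum(w[above & case]) / sum(w[case]) else NA_real_)
}
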