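#' Configuration for synthetic cohort generation
#'
#' Collects the parameters of the generative model the downstream
#' analysis assumes: a standard bivariate-normal (Z-score, liability)
#' pair with correlation `rho`, disease defined either by a scalar
#' prevalence `K` (liability mode) or by age-band hazards (event-time
#' mode), an age-band distribution, optional per-group raw-PGS location
#' and scale shifts, and a sub-cohort sampling fraction for case-cohort
#' designs.
#'
#' @param n_individuals Number of individuals to simulate.
#' @param rho PGS-liability correlation in `[0, 1)`.
#' @param prevalence Scalar 5-year case prevalence `K` in `(0, 1)`
#'   (liability mode), or `NULL` when a rate table drives events.
#' @param age_band_weights Named probability vector over band start ages
#'   (names are band starts in years; bands are `[a, a + 5)`); must sum
#'   to 1 within 1e-12.
#' @param group_shifts Data frame with columns `group`, `mean`, `sd`,
#'   `prop`: raw-PGS mean/SD per ancestry-like group and group mixing
#'   proportions. Default: one group, mean 0, SD 1.
#' @param subcohort_fraction Sub-cohort sampling proportion in `(0, 1]`.
#' @param seed Global integer seed; all generators draw from substreams
#'   of it (see [substream_seed()]).
#' @return An object of class `"simulation_config"`.
#' @examples
#' simulation_config(1000, rho = 0.25, prevalence = 0.02, seed = 1)
#' @export
simulation_config <- function(n_individuals, rho, prevalence = NULL,
                              age_band_weights = c(`50` = 1),
                              group_shifts = NULL,
                              subcohort_fraction = 1, seed = 1L) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)", call. = FALSE)
  if (!is.null(prevalence) &&
      (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1))
    stop("prevalence K must lie in (0, 1)", call. = FALSE)
  if (abs(sum(age_band_weights) - 1) > 1e-12)
    stop("age_band_weights must sum to 1", call. = FALSE)
  if (is.null(names(age_band_weights)))
    stop("age_band_weights must be named by band start age", call. = FALSE)
  if (subcohort_fraction <= 0 || subcohort_fraction > 1)
    stop("subcohort_fraction must lie in (0, 1]", call. = FALSE)
  if (is.null(group_shifts))
    group_shifts <- data.frame(group = "ALL", mean = 0, sd = 1, prop = 1)
  stopifnot(all(c("group", "mean", "sd", "prop") %in% names(group_shifts)),
            abs(sum(group_shifts$prop) - 1) < 1e-12,
            all(group_shifts$sd > 0))
  structure(list(n_individuals = as.integer(n_individuals), rho = rho,
                 prevalence = prevalence,
                 age_band_weights = age_band_weights,
                 group_shifts = group_shifts,
                 subcohort_fraction = subcohort_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# shared draw of (group, age band, Z, L) under the bivariate-normal model
.draw_base <- function(config) {
  n <- config$n_individuals
  gs <- config$group_shifts
  grp <- sample(gs$group, n, replace = TRUE, prob = gs$prop)
  band <- as.numeric(sample(names(config$age_band_weights), n,
                            replace = TRUE,
                            prob = config$age_band_weights))
  age <- band + sample(0:4, n, replace = TRUE) # whole years within [a, a+5)
  L <- stats::rnorm(n)
  Z <- config$rho * L + sqrt(1 - config$rho^2) * stats::rnorm(n)
  raw <- gs$mean[match(grp, gs$group)] + gs$sd[match(grp, gs$group)] * Z
  data.frame(sample_id = sprintf("S%06d", seq_len(n)),
             age_at_baseline = age, age_band = band, subgroup = grp,
             raw_score = raw, z_score = Z, liability = L)
}

.finish_cohort <- function(d) {
  d$prevalent_case <- FALSE
  d$screening_history <- NA
  d$subcohort_member <- NA
  d$design_weight <- 1
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' Simulate a cohort under the liability-threshold model
#'
#' Draws `(Z, L)` standard bivariate normal with correlation `rho`; an
#' individual is an incident 5-year case iff `L` exceeds the threshold
#' `qnorm(1 - K)`. This inverts the relative-risk mapping used by the
#' analysis, so empirical quantile relative risks converge to the
#' analytic ones as `n` grows.
#'
#' @param config A [simulation_config()] with scalar `prevalence` set.
#' @return A `"cohort_table"` data frame: one row per individual with
#'   `sample_id`, `age_at_baseline`, `age_band`, `subgroup`, `raw_score`,
#'   `z_score`, `incident_case_5y` and design columns.
#' @examples
#' cfg <- simulation_config(500, rho = 0.3, prevalence = 0.05, seed = 7)
#' head(simulate_liability_cohort(cfg))
#' @export
simulate_liability_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$prevalence))
    stop("liability mode needs a scalar prevalence in the config",
         call. = FALSE)
  t <- liability_threshold(config$prevalence)
  with_substream(config$seed, "liability_cohort", {
    d <- .draw_base(config)
    d$incident_case_5y <- d$liability > t
    d$liability <- NULL
    .finish_cohort(d)
  })
}

#' Simulate a cohort with competing-risk event times
#'
#' Individuals age through the rate table's 5-year bands with competing
#' exponential clocks per band: a disease clock with hazard
#' `incidence_hazard * RR(z)` and a death clock with
#' `other_mortality_hazard`, re-drawn at each band boundary (the
#' piecewise-constant-hazard assumption of the life table). The first
#' clock to ring within the horizon determines the event; otherwise the
#' record is censored at the horizon.
#'
#' @param config A [simulation_config()]; its `rho` drives the Z-scores.
#' @param rates A [rate_table()] covering all simulated ages plus the
#'   horizon.
#' @param horizon_years Follow-up horizon in years (default 5).
#' @param model Optional [liability_model()] supplying the individual
#'   relative-risk multiplier `RR(z)`; when `NULL`, RR is 1 for everyone
#'   and the cohort reproduces the population life table.
#' @return A `"cohort_table"` with additional columns `event_type`
#'   (`"cancer"`, `"death"`, `"censored"`) and `event_age`.
#' @export
simulate_event_time_cohort <- function(config, rates, horizon_years = 5,
                                       model = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(rates, "rate_table"))
  max_start <- max(as.numeric(names(config$age_band_weights))) + 5
  if (max_start + horizon_years - 5 > rates$age_high[nrow(rates)] ||
      min(as.numeric(names(config$age_band_weights))) < rates$age_low[1])
    stop("rate table does not cover the simulated ages plus horizon",
         call. = FALSE)
  with_substream(config$seed, "event_time_cohort", {
    d <- .draw_base(config)
    d$liability <- NULL
    rr <- if (is.null(model)) rep(1, nrow(d)) else
      individual_relative_risk(d$z_score, model)
    n <- nrow(d)
    event_type <- rep("censored", n)
    event_age <- d$age_at_baseline + horizon_years
    for (i in seq_len(n)) {
      a <- d$age_at_baseline[i]
      end <- a + horizon_years
      while (a < end) {
        band <- findInterval(a, rates$age_low)
        seg_end <- min(rates$age_high[band], end)
        lc <- rates$incidence_hazard[band] * rr[i]
        ld <- rates$other_mortality_hazard[band]
        tc <- if (lc > 0) stats::rexp(1, lc) else Inf
        td <- if (ld > 0) stats::rexp(1, ld) else Inf
        tmin <- min(tc, td)
        if (a + tmin < seg_end) {
          event_type[i] <- if (tc < td) "cancer" else "death"
          event_age[i] <- a + tmin
          break
        }
        a <- seg_end
      }
    }
    d$event_type <- event_type
    d$event_age <- event_age
    d$incident_case_5y <- event_type == "cancer"
    .finish_cohort(d)
  })
}

#' Subsample a cohort under a case-cohort design
#'
#' Retains a simple random sub-cohort plus every incident case, with
#' classic case-cohort inverse-probability weights: sub-cohort non-cases
#' get weight `1 / subcohort_fraction`; cases (inside or outside the
#' sub-cohort) contribute as cases with weight 1.
#'
#' @param cohort A `"cohort_table"` with `incident_case_5y`.
#' @param subcohort_fraction Sampling proportion in `(0, 1]`.
#' @param seed Integer seed.
#' @return The retained rows with `subcohort_member` and `design_weight`
#'   filled in.
#' @export
simulate_case_cohort <- function(cohort, subcohort_fraction, seed) {
  stopifnot("incident_case_5y" %in% names(cohort))
  if (subcohort_fraction <= 0 || subcohort_fraction > 1)
    stop("subcohort_fraction must lie in (0, 1]", call. = FALSE)
  with_substream(seed, "case_cohort", {
    n <- nrow(cohort)
    in_sub <- stats::runif(n) < subcohort_fraction
    keep <- in_sub | cohort$incident_case_5y
    out <- cohort[keep, , drop = FALSE]
    out$subcohort_member <- in_sub[keep]
    out$design_weight <- ifelse(out$incident_case_5y, 1,
                                1 / subcohort_fraction)
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Simulate principal-component coordinates for ancestry clusters
#'
#' Draws isotropic Gaussian clusters around five reference centroids in
#' the space of the first four PCs, retaining the true labels so that
#' downstream k-means assignment can be scored against the truth.
#'
#' @param group_sizes Named integer vector of cluster sizes (5 groups).
#' @param centroids 5 x 4 numeric matrix of cluster centres (distinct
#'   rows), rownames giving the group labels.
#' @param sds Per-group isotropic SD (scalar or length 5; 0 allowed).
#' @param seed Integer seed.
#' @return A data frame with `sample_id`, `PC1`..`PC4` and `true_label`.
#' @export
simulate_pc_mixture <- function(group_sizes, centroids, sds, seed) {
  stopifnot(is.matrix(centroids), ncol(centroids) == 4,
            nrow(centroids) == length(group_sizes))
  if (anyDuplicated(centroids) > 0)
    stop("centroids must be distinct", call. = FALSE)
  labels <- rownames(centroids)
  if (is.null(labels)) labels <- names(group_sizes)
  if (is.null(labels)) labels <- paste0("G", seq_len(nrow(centroids)))
  sds <- rep_len(sds, nrow(centroids))
  with_substream(seed, "pc_mixture", {
    rows <- lapply(seq_along(group_sizes), function(g) {
      k <- group_sizes[g]
      m <- matrix(stats::rnorm(k * 4, sd = sds[g]), ncol = 4, byrow = FALSE)
      sweep(m, 2, centroids[g, ], `+`)
    })
    pcs <- do.call(rbind, rows)
    out <- data.frame(sample_id = sprintf("P%06d", seq_len(nrow(pcs))),
                      PC1 = pcs[, 1], PC2 = pcs[, 2],
                      PC3 = pcs[, 3], PC4 = pcs[, 4],
                      true_label = rep(labels, times = group_sizes))
    out
  })
}

#' Simulate genotype dosages and PGS weights with known true scores
#'
#' Variants are independent with minor-allele frequencies drawn uniformly
#' from `maf_range`; dosages follow Hardy-Weinberg binomial sampling.
#' Weights are zero-mean normal. True per-allele average scores are
#' computed by direct summation before any missingness is applied, so
#' scoring code can be checked exactly.
#'
#' @param n_samples,n_variants Matrix dimensions.
#' @param maf_range Interval within `(0, 0.5]`.
#' @param missing_rate Proportion of dosages set missing, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list with `genotypes` (samples x variants matrix, `NA` for
#'   missing), `weights` (a scoring data frame as from
#'   [read_scoring_file()]) and `true_scores`.
#' @export
simulate_genotypes_and_weights <- function(n_samples, n_variants,
                                           maf_range = c(0.05, 0.5),
                                           missing_rate = 0, seed = 1L) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1)
  with_substream(seed, "genotypes", {
    maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
    G <- vapply(seq_len(n_variants),
                function(j) stats::rbinom(n_samples, 2, maf[j]),
                numeric(n_samples))
    G <- matrix(G, nrow = n_samples)
    ids <- sprintf("rs%05d", seq_len(n_variants))
    dimnames(G) <- list(sprintf("S%05d", seq_len(n_samples)), ids)
    w <- stats::rnorm(n_variants)
    weights <- data.frame(variant_id = ids,
                          chromosome = as.character(1 +
                            (seq_len(n_variants) - 1) %% 22),
                          position = seq_len(n_variants) * 1000L,
                          effect_allele = "A", other_allele = "G",
                          weight = w, stringsAsFactors = FALSE)
    class(weights) <- c("variant_weights", "data.frame")
    true_scores <- as.numeric(G %*% w) / (2 * n_variants)
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(G)) < missing_rate, nrow = n_samples)
      G[mask] <- NA_real_
    }
    list(genotypes = G, weights = weights, true_scores = true_scores)
  })
}

#' Printed cohort-subgroup age/case profiles
#'
#' Per-subgroup counts of women not diagnosed (`n_controls`) and
#' diagnosed (`n_cases`) with incident invasive breast cancer within five
#' years of baseline, by 5-year age band, for the five cohort/ancestry
#' subgroups the analysis targets (UK Biobank European, South-Asian and
#' African ancestry; QSkin European; MCCS European). Cells suppressed in
#' the source for confidentiality (counts of five or fewer) are `NA`.
#' These profiles seed the synthetic generator's age-band weights and
#' reduced-scale cohort sizes.
#'
#' @return A data frame with columns `subgroup`, `age_band_start`,
#'   `n_controls`, `n_cases`.
#' @examples
#' p <- cohort_subgroup_profiles()
#' aggregate(n_cases ~ subgroup, p, sum, na.rm = TRUE)
#' @export
cohort_subgroup_profiles <- function() {
  d <- rbind(
    data.frame(subgroup = "UKB-EUR", age_band_start = seq(40, 65, 5),
               n_controls = c(20318, 27873, 33496, 39738, 51773, 36079),
               n_cases = c(181, 367, 421, 575, 915, 624)),
    data.frame(subgroup = "QSkin-EUR", age_band_start = seq(45, 70, 5),
               n_controls = c(981, 1342, 1555, 1750, 1456, 1031),
               n_cases = c(17, 27, 23, 37, 45, 27)),
    data.frame(subgroup = "MCCS-EUR", age_band_start = seq(50, 70, 5),
               n_controls = c(376, 566, 493, 505, 520),
               n_cases = c(34, 35, 40, 48, 37)),
    data.frame(subgroup = "UKB-SAS", age_band_start = seq(40, 65, 5),
               n_controls = c(789, 816, 875, 760, 683, 469),
               n_cases = c(6, 6, 7, 15, NA, NA)),
    data.frame(subgroup = "UKB-AFR", age_band_start = seq(40, 65, 5),
               n_controls = c(886, 1062, 949, 607, 487, 409),
               n_cases = c(NA, 8, 7, NA, NA, NA)))
  d
}

#' Age-band weights for one built-in subgroup profile
#'
#' Normalised total (case + control) counts per band for a subgroup from
#' [cohort_subgroup_profiles()]; suppressed case cells contribute zero
#' cases to the weight.
#'
#' @param subgroup One of `"UKB-EUR"`, `"QSkin-EUR"`, `"MCCS-EUR"`,
#'   `"UKB-SAS"`, `"UKB-AFR"`.
#' @return A named probability vector over band start ages.
#' @export
subgroup_age_band_weights <- function(subgroup) {
  p <- cohort_subgroup_profiles()
  p <- p[p$subgroup == subgroup, ]
  if (nrow(p) == 0)
    stop("unknown subgroup: ", subgroup, call. = FALSE)
  tot <- p$n_controls + ifelse(is.na(p$n_cases), 0, p$n_cases)
  stats::setNames(tot / sum(tot), p$age_band_start)
}
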