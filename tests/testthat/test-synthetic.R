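test_that("substream seeds are label-specific and in integer range", {
  s1 <- substream_seed(42L, "liability")
  s2 <- substream_seed(42L, "genotypes")
  expect_identical(s1, substream_seed(42L, "liability"))
  expect_false(s1 == s2)
  expect_true(is.integer(s1) && s1 >= 0 && s1 < 2^31)
})

test_that("simulation_config validates its invariants", {
  expect_error(simulation_config(10, rho = 1, prevalence = 0.1), "rho")
  expect_error(simulation_config(10, rho = 0.2, prevalence = 1.2),
               "prevalence")
  expect_error(simulation_config(10, rho = 0.2, prevalence = 0.1,
                                 age_band_weights = c(`50` = 0.6,
                                                      `55` = 0.5)),
               "sum to 1")
  expect_error(simulation_config(10, rho = 0.2, prevalence = 0.1,
                                 subcohort_fraction = 0), "subcohort")
})

test_that("liability cohort reproduces prevalence, independence and AUC", {
  # case fraction inside the 99% binomial interval at K = 0.05
  cfg <- simulation_config(1e6, rho = 0, prevalence = 0.05, seed = 11)
  co <- simulate_liability_cohort(cfg)
  ci <- qbinom(c(0.005, 0.995), 1e6, 0.05) / 1e6
  frac <- mean(co$incident_case_5y)
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
  # rho = 0: case and control Z distributions indistinguishable
  co2 <- simulate_liability_cohort(
    simulation_config(1e5, rho = 0, prevalence = 0.5, seed = 12))
  ks <- suppressWarnings(
    ks.test(co2$z_score[co2$incident_case_5y],
            co2$z_score[!co2$incident_case_5y]))
  expect_gt(ks$p.value, 0.01)
  # rho = 0.3: empirical AUC matches the analytic forward model
  co3 <- simulate_liability_cohort(
    simulation_config(1e6, rho = 0.3, prevalence = 0.05, seed = 13))
  expect_lt(abs(empirical_auc(co3$z_score, co3$incident_case_5y) -
                auc_from_rho(0.3, 0.05)), 0.005)
})

test_that("liability cohort is reproducible and carries the design columns", {
  cfg <- simulation_config(500, rho = 0.25, prevalence = 0.02,
                           age_band_weights = c(`50` = 0.5, `55` = 0.5),
                           seed = 21)
  a <- simulate_liability_cohort(cfg)
  b <- simulate_liability_cohort(cfg)
  expect_identical(a, b)
  expect_true(all(c("sample_id", "age_at_baseline", "age_band",
                    "subgroup", "z_score", "incident_case_5y",
                    "prevalent_case", "design_weight") %in% names(a)))
  expect_true(all(a$age_at_baseline >= a$age_band &
                  a$age_at_baseline < a$age_band + 5))
  expect_error(simulate_liability_cohort(
    simulation_config(10, rho = 0.2, seed = 1)), "prevalence")
})

test_that("empirical quantile RRs converge to the analytic ones", {
  rho <- 0.3; K <- 0.05
  co <- simulate_liability_cohort(
    simulation_config(1e6, rho = rho, prevalence = K, seed = 31))
  est <- quantile_relative_risks(liability_model(K, rho = rho), 5)
  obs <- observed_quantile_rr(co$z_score, co$incident_case_5y,
                              n_quantiles = 5)
  for (i in 1:5) {
    se_log <- sqrt(1 / obs$cases_in_bin[i] - 1 / obs$n_in_bin[i] +
                   1 / sum(obs$cases_in_bin) - 1 / sum(obs$n_in_bin))
    expect_lt(abs(log(obs$observed_rr[i]) - log(est$estimated_rr[i])),
              3 * se_log)
  }
})

test_that("event-time cohort: null hazards, closed form, determinism", {
  cfg <- simulation_config(2000, rho = 0, prevalence = NULL,
                           age_band_weights = c(`50` = 1), seed = 41)
  rt0 <- rate_table(40, 80, 0, 0.02)
  co0 <- simulate_event_time_cohort(cfg, rt0)
  expect_equal(sum(co0$incident_case_5y), 0L)
  # constant hazards, single band: cancer fraction near the closed form
  lc <- 0.02; ld <- 0.03; T5 <- 5
  rt <- rate_table(40, 80, lc, ld)
  cfg2 <- simulation_config(2e4, rho = 0, prevalence = NULL,
                            age_band_weights = c(`50` = 1), seed = 42)
  co <- simulate_event_time_cohort(cfg2, rt)
  p_true <- lc / (lc + ld) * (1 - exp(-(lc + ld) * T5))
  se <- sqrt(p_true * (1 - p_true) / 2e4)
  expect_lt(abs(mean(co$incident_case_5y) - p_true), 3 * se)
  expect_identical(co, simulate_event_time_cohort(cfg2, rt))
  expect_error(simulate_event_time_cohort(cfg2, rate_table(50, 54, 0.01, 0)),
               "cover")
})

test_that("event-time cohort with RR = 1 reproduces the life table", {
  rt <- rate_table(c(50, 55), c(55, 60), c(0.004, 0.008), c(0.01, 0.02))
  cfg <- simulation_config(4e4, rho = 0, prevalence = NULL,
                           age_band_weights = c(`50` = 1), seed = 43)
  co <- simulate_event_time_cohort(cfg, rt)
  pred <- vapply(co$age_at_baseline,
                 function(a) age_specific_risk(rt, a), numeric(1))
  p_bar <- mean(pred)
  se <- sqrt(p_bar * (1 - p_bar) / nrow(co))
  expect_lt(abs(mean(co$incident_case_5y) - p_bar), 3 * se)
})

test_that("event-time cohort applies the liability RR multiplier", {
  rt <- rate_table(50, 60, 0.01, 0)
  m <- liability_model(0.05, rho = 0.5)
  cfg <- simulation_config(3e4, rho = 0.5, prevalence = NULL,
                           age_band_weights = c(`50` = 1), seed = 44)
  co <- simulate_event_time_cohort(cfg, rt, model = m)
  top <- co$z_score > quantile(co$z_score, 0.8)
  expect_gt(mean(co$incident_case_5y[top]),
            1.5 * mean(co$incident_case_5y[!top]))
})

test_that("case-cohort subsampling keeps all cases with design weights", {
  co <- simulate_liability_cohort(
    simulation_config(1e5, rho = 0.3, prevalence = 0.03, seed = 51))
  # fraction 1: identity with unit weights
  full <- simulate_case_cohort(co, 1, seed = 52)
  expect_equal(nrow(full), nrow(co))
  expect_true(all(full$design_weight == 1))
  cc <- simulate_case_cohort(co, 0.2, seed = 53)
  expect_true(all(co$sample_id[co$incident_case_5y] %in% cc$sample_id))
  nsub <- sum(cc$subcohort_member)
  ci <- qbinom(c(0.005, 0.995), 1e5, 0.2)
  expect_gte(nsub, ci[1]); expect_lte(nsub, ci[2])
  expect_true(all(cc$design_weight[cc$incident_case_5y] == 1))
  expect_true(all(cc$design_weight[!cc$incident_case_5y] == 5))
  # a case-free cohort reduces to the sub-cohort
  co0 <- co; co0$incident_case_5y <- FALSE
  cc0 <- simulate_case_cohort(co0, 0.2, seed = 54)
  expect_true(all(cc0$subcohort_member))
  expect_error(simulate_case_cohort(co, 0, seed = 1), "subcohort_fraction")
})

test_that("PC mixture generator honours centroids, sds and seed", {
  C <- rbind(EUR = c(0, 0, 0, 0), SAS = c(10, 0, 0, 0),
             AFR = c(0, 10, 0, 0), AMR = c(0, 0, 10, 0),
             EAS = c(0, 0, 0, 10))
  pts <- simulate_pc_mixture(c(EUR = 3, SAS = 2, AFR = 2, AMR = 2,
                               EAS = 2), C, sds = 0, seed = 61)
  expect_equal(unname(as.matrix(pts[1:3, paste0("PC", 1:4)])),
               matrix(0, 3, 4))
  expect_equal(pts$true_label[4], "SAS")
  expect_identical(pts, simulate_pc_mixture(c(EUR = 3, SAS = 2, AFR = 2,
                                              AMR = 2, EAS = 2), C,
                                            sds = 0, seed = 61))
  Cdup <- C; Cdup[2, ] <- Cdup[1, ]
  expect_error(simulate_pc_mixture(rep(2, 5), Cdup, 1, 1), "distinct")
})

test_that("genotype generator: HWE dosages, exact true scores, hand case", {
  g <- simulate_genotypes_and_weights(50, 20, missing_rate = 0, seed = 71)
  expect_true(all(g$genotypes %in% 0:2))
  sc <- compute_scores(g$genotypes, g$weights)
  expect_equal(sc$raw_score, g$true_scores, tolerance = 1e-15)
  # single variant, weight 1, two allele observations: score = dosage / 2
  G <- matrix(c(0, 1, 2), ncol = 1,
              dimnames = list(c("a", "b", "c"), "rs1"))
  w <- data.frame(variant_id = "rs1", chromosome = "1", position = 1L,
                  effect_allele = "A", other_allele = "G", weight = 1)
  expect_equal(compute_scores(G, w)$raw_score, c(0, 0.5, 1))
  expect_identical(simulate_genotypes_and_weights(10, 5, seed = 72),
                   simulate_genotypes_and_weights(10, 5, seed = 72))
  expect_error(simulate_genotypes_and_weights(10, 5, maf_range = c(0, 0.5)))
})

test_that("built-in subgroup profiles match their totals", {
  p <- cohort_subgroup_profiles()
  totals <- aggregate(cbind(n_controls, n_cases) ~ subgroup, p, sum,
                      na.action = na.pass, na.rm = TRUE)
  expect_equal(totals$n_controls[totals$subgroup == "QSkin-EUR"], 8115)
  expect_equal(totals$n_cases[totals$subgroup == "QSkin-EUR"], 176)
  expect_equal(totals$n_controls[totals$subgroup == "UKB-EUR"], 209277)
  expect_equal(totals$n_cases[totals$subgroup == "UKB-EUR"], 3083)
  expect_equal(totals$n_cases[totals$subgroup == "MCCS-EUR"], 194)
  w <- subgroup_age_band_weights("QSkin-EUR")
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_error(subgroup_age_band_weights("nope"), "unknown")
})
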