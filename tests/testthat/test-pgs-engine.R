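write_tmp_scoring <- function(lines, ext = ".txt") {
  p <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("scoring files parse, reject duplicates and bad weights", {
  p <- write_tmp_scoring(c(
    "#pgs_id=TEST", "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
    "rs1\t1\t100\tA\tG\t0.5", "rs2\t2\t200\tC\tT\t-0.25",
    "rs3\t3\t300\tAT\tA\t0.1"))
  w <- read_scoring_file(p)
  expect_equal(nrow(w), 3)
  expect_equal(w$weight, c(0.5, -0.25, 0.1))
  expect_equal(w$effect_allele[3], "AT")   # indels pass through
  dup <- write_tmp_scoring(c("rsID\teffect_allele\tother_allele\teffect_weight",
                             "rs1\tA\tG\t0.5", "rs1\tA\tG\t0.2"))
  expect_error(read_scoring_file(dup), "rs1")
  bad <- write_tmp_scoring(c("rsID\teffect_allele\tother_allele\teffect_weight",
                             "rs1\tA\tG\t0.5", "rs2\tC\tT\tnot_a_number"))
  expect_error(read_scoring_file(bad), "row")
  nomand <- write_tmp_scoring(c("rsID\teffect_allele\teffect_weight",
                                "rs1\tA\t0.5"))
  expect_error(read_scoring_file(nomand), "mandatory")
})

test_that("scoring files round-trip and tolerate commas and gzip", {
  g <- simulate_genotypes_and_weights(5, 8, seed = 1)
  p <- withr::local_tempfile(fileext = ".txt")
  write_scoring_file(g$weights, p)
  expect_equal(as.data.frame(read_scoring_file(p)),
               as.data.frame(g$weights))
  pcsv <- write_tmp_scoring(c("rsID,effect_allele,other_allele,effect_weight",
                              "rs1,A,G,0.5"))
  expect_equal(read_scoring_file(pcsv)$weight, 0.5)
  pgz <- withr::local_tempfile(fileext = ".txt.gz")
  con <- gzfile(pgz, "w")
  writeLines(c("rsID\teffect_allele\tother_allele\teffect_weight",
               "rs1\tA\tG\t0.5"), con)
  close(con)
  expect_equal(read_scoring_file(pgz)$weight, 0.5)
})

test_that("allele harmonization classifies as-is, swap and unmatched", {
  w <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4"),
                  chromosome = c("1", "1", "2", "2"),
                  position = c(100L, 200L, 300L, 400L),
                  effect_allele = c("A", "C", "G", "A"),
                  other_allele = c("G", "T", "T", "C"),
                  weight = c(0.5, -0.25, 0.1, 0.2))
  cv <- data.frame(variant_id = c("rs1", "rs2", "rs9"),
                   chromosome = c("1", "1", "3"),
                   position = c(100L, 200L, 900L),
                   effect_allele = c("A", "T", "A"),
                   other_allele = c("G", "C", "G"))
  h <- harmonize_alleles(w, cv)
  expect_equal(h$report$matched_as_is, 1)
  expect_equal(h$report$matched_swap, 1)
  expect_equal(h$report$unmatched, 2)
  expect_false(h$matched$swapped[h$matched$variant_id == "rs1"])
  expect_true(h$matched$swapped[h$matched$variant_id == "rs2"])
  expect_true(all(c("rs3", "rs4") %in% h$unmatched))
  # a mismatched allele pair is unmatched, not an error
  cv2 <- data.frame(variant_id = "rs1", effect_allele = "A",
                    other_allele = "T")
  expect_equal(harmonize_alleles(w[1, ], cv2)$report$unmatched, 1)
})

test_that("positional fallback matches by chr:pos but skips ambiguous pairs", {
  w <- data.frame(variant_id = c("rsX", "rsY"),
                  chromosome = c("1", "1"), position = c(100L, 200L),
                  effect_allele = c("A", "A"), other_allele = c("G", "T"),
                  weight = c(1, 1))
  cv <- data.frame(variant_id = c("chr1:100", "chr1:200"),
                   chromosome = c("1", "1"), position = c(100L, 200L),
                   effect_allele = c("A", "A"), other_allele = c("G", "T"))
  h <- harmonize_alleles(w, cv)
  expect_equal(h$matched$variant_id, "rsX")   # A/T is strand-ambiguous
  expect_true("rsY" %in% h$unmatched)
})

test_that("raw scores follow the average-per-allele-observation formula", {
  G <- matrix(c(1, 2, 2, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("rs1", "rs2")))
  w <- data.frame(variant_id = c("rs1", "rs2"), chromosome = "1",
                  position = c(1L, 2L), effect_allele = "A",
                  other_allele = "G", weight = c(0.5, -0.25))
  sc <- compute_scores(G, w)
  expect_equal(sc$raw_score, c(0.0, 0.25))   # (0.5-0.5)/4 and (1.0)/4
  expect_equal(sc$n_variants_scored, c(2L, 2L))
})

test_that("scoring equals the brute-force summation oracle exactly", {
  g <- simulate_genotypes_and_weights(40, 25, seed = 81)
  sc <- compute_scores(g$genotypes, g$weights)
  oracle <- numeric(40)
  for (i in 1:40) {
    tot <- 0
    for (j in 1:25) tot <- tot + g$weights$weight[j] * g$genotypes[i, j]
    oracle[i] <- tot / (2 * 25)
  }
  expect_equal(sc$raw_score, oracle, tolerance = 1e-14)
})

test_that("scoring is invariant to allele-swap harmonization", {
  g <- simulate_genotypes_and_weights(30, 10, seed = 82)
  base <- compute_scores(g$genotypes, g$weights)$raw_score
  # cohort metadata with half the variants reported on swapped alleles
  cv <- g$weights[, c("variant_id", "chromosome", "position",
                      "effect_allele", "other_allele")]
  swap_idx <- seq(1, 10, by = 2)
  tmp <- cv$effect_allele[swap_idx]
  cv$effect_allele[swap_idx] <- cv$other_allele[swap_idx]
  cv$other_allele[swap_idx] <- tmp
  Gsw <- g$genotypes
  Gsw[, swap_idx] <- 2 - Gsw[, swap_idx]   # dosages now count the swapped allele
  h <- harmonize_alleles(g$weights, cv)
  expect_equal(h$report$matched_swap, length(swap_idx))
  got <- compute_scores(Gsw, h$matched)$raw_score
  expect_equal(got, base, tolerance = 1e-15)
})

test_that("missing-dosage policies: mean imputation and drop", {
  G <- matrix(c(0, 2, NA, 2, 1, 0), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("rs1", "rs2")))
  w <- data.frame(variant_id = c("rs1", "rs2"), chromosome = "1",
                  position = 1:2, effect_allele = "A", other_allele = "G",
                  weight = c(1, 1))
  mi <- compute_scores(G, w, missing_policy = "mean_impute")
  # rs1 mean dosage over s1,s2 = 1 -> s3 numerator 1 + 0, denominator 4
  expect_equal(mi$raw_score[3], (1 + 0) / 4)
  expect_equal(mi$n_variants_scored, rep(2L, 3))
  dr <- compute_scores(G, w, missing_policy = "drop")
  expect_equal(dr$raw_score[3], 0 / 2)
  expect_equal(dr$n_variants_scored[3], 1L)
  # a sample with no usable variants is flagged, not silently zero
  G2 <- matrix(c(NA_real_, 1), nrow = 2,
               dimnames = list(c("s1", "s2"), "rs1"))
  d2 <- compute_scores(G2, w[1, ], missing_policy = "drop")
  expect_equal(d2$score_flag, c("no_usable_variants", "ok"))
  expect_true(is.na(d2$raw_score[1]))
  expect_error(compute_scores(matrix(3, 1, 1,
                                     dimnames = list("s", "rs1")), w[1, ]),
               "dosages")
})

test_that("within-group standardization pins the n-1 SD convention", {
  r <- data.frame(raw_score = c(1, 2, 3))
  out <- standardize_within_group(r, rep("g", 3))
  expect_equal(out$z_score, c(-1, 0, 1))   # sample SD of 1,2,3 is exactly 1
  # two groups with different means are separately centred
  r2 <- data.frame(raw_score = c(1, 2, 3, 11, 12, 13, 14))
  grp <- c("a", "a", "a", "b", "b", "b", "b")
  out2 <- standardize_within_group(r2, grp)
  for (g in c("a", "b")) {
    expect_equal(mean(out2$z_score[grp == g]), 0, tolerance = 1e-12)
    expect_equal(sd(out2$z_score[grp == g]), 1, tolerance = 1e-12)
  }
  expect_error(standardize_within_group(data.frame(raw_score = 1), "g"),
               ">= 2")
  expect_error(standardize_within_group(data.frame(raw_score = c(2, 2)),
                                        c("g", "g")), "degenerate")
})

test_that("standardization is idempotent and reusable on new samples", {
  set.seed(9)
  r <- data.frame(raw_score = rnorm(50, mean = 3, sd = 2))
  grp <- rep(c("x", "y"), 25)
  once <- standardize_within_group(r, grp)
  twice <- standardize_within_group(data.frame(raw_score = once$z_score),
                                    grp)
  expect_equal(twice$z_score, once$z_score, tolerance = 1e-12)
  st <- attr(once, "group_stats")
  new <- standardize_within_group(data.frame(raw_score = c(3, 5)),
                                  c("x", "x"), stats = st)
  expect_equal(new$z_score, (c(3, 5) - st$mean[st$group == "x"]) /
                 st$sd[st$group == "x"])
  expect_error(standardize_within_group(data.frame(raw_score = 1), "z",
                                        stats = st), "constants")
})

test_that("relatedness pruning removes one member per pair", {
  pr <- prune_relatives(data.frame(a = "A", b = "B"), seed = 5)
  expect_equal(length(pr), 1)
  expect_true(pr %in% c("A", "B"))
  expect_identical(prune_relatives(data.frame(a = "A", b = "B"), seed = 5),
                   pr)
  expect_setequal(prune_relatives(data.frame(), ids = c("A", "B", "C")),
                  c("A", "B", "C"))
  # chain A-B, B-C: exhaustive check that no listed pair survives
  pairs <- data.frame(a = c("A", "B"), b = c("B", "C"))
  for (s in 1:20) {
    kept <- prune_relatives(pairs, seed = s)
    expect_gte(length(kept), 1)
    expect_false(all(c("A", "B") %in% kept))
    expect_false(all(c("B", "C") %in% kept))
  }
})

test_that("super-population assignment recovers well-separated clusters", {
  C <- rbind(EUR = c(0, 0, 0, 0), SAS = c(6, 0, 0, 0),
             AFR = c(0, 6, 0, 0), AMR = c(0, 0, 6, 0),
             EAS = c(0, 0, 0, 6))
  # points exactly at the centroids
  expect_equal(assign_superpopulations(C, C), rownames(C))
  sizes <- c(EUR = 200, SAS = 50, AFR = 50, AMR = 30, EAS = 30)
  pts <- simulate_pc_mixture(sizes, C, sds = 0.3, seed = 91)
  lab <- assign_superpopulations(pts, C)
  expect_equal(mean(lab == pts$true_label), 1)
  # identical points collapse to one label with a warning
  same <- matrix(0, nrow = 10, ncol = 4)
  expect_warning(lab2 <- assign_superpopulations(same, C), "empty cluster")
  expect_equal(length(unique(lab2)), 1)
})

test_that("k-means agrees with the reference Lloyd implementation", {
  C <- rbind(a = c(0, 0, 0, 0), b = c(4, 0, 0, 0), c = c(0, 4, 0, 0),
             d = c(4, 4, 0, 0), e = c(2, 2, 4, 0))
  pts <- simulate_pc_mixture(c(a = 40, b = 40, c = 40, d = 40, e = 40),
                             C, sds = 0.5, seed = 92)
  X <- as.matrix(pts[, paste0("PC", 1:4)])
  ours <- assign_superpopulations(pts, C)
  ref <- stats::kmeans(X, centers = C, algorithm = "Lloyd",
                       iter.max = 100)
  expect_equal(unname(ours), rownames(C)[ref$cluster])
})

test_that("the 3-SD European filter uses an inclusive componentwise rule", {
  mu <- c(0, 0, 0, 0); sd4 <- c(1, 1, 1, 1)
  at_mean <- matrix(0, 1, 4)
  expect_true(eur_3sd_filter(at_mean, mu, sd4))
  off <- matrix(c(3.1, 0, 0, 0), 1, 4)
  expect_false(eur_3sd_filter(off, mu, sd4))
  boundary <- matrix(rep(3, 4), 1, 4)
  expect_true(eur_3sd_filter(boundary, mu, sd4))
  expect_error(eur_3sd_filter(at_mean, mu, c(0, 1, 1, 1)), "positive")
})
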