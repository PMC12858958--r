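#' Read a PGS scoring file
#'
#' Reads a PGS Catalog style scoring file: a header line followed by one
#' row per variant with columns `rsID` (or `variant_id`), `chr_name` (or
#' `chromosome`), `chr_position` (or `position`), `effect_allele`,
#' `other_allele` (or `reference_allele`) and `effect_weight` (or
#' `weight`). Tab- or comma-separated; leading `#` comment lines are
#' skipped; gzip is read transparently. Rows whose weight does not parse
#' as a number are rejected with their row numbers.
#'
#' @param path File path.
#' @return A data frame of class `"variant_weights"` with columns
#'   `variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @export
read_scoring_file <- function(path) {
  lines <- readLines(gzfile(path))
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1L) stop("empty scoring file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  d <- utils::read.table(text = lines, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  alias <- c(rsID = "variant_id", rsid = "variant_id",
             variant_id = "variant_id",
             chr_name = "chromosome", chromosome = "chromosome",
             chr_position = "position", position = "position",
             effect_allele = "effect_allele",
             other_allele = "other_allele",
             reference_allele = "other_allele",
             effect_weight = "weight", weight = "weight")
  hit <- alias[names(d)]
  names(d)[!is.na(hit)] <- hit[!is.na(hit)]
  need <- c("variant_id", "effect_allele", "other_allele", "weight")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("scoring file missing mandatory columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  w <- suppressWarnings(as.numeric(d$weight))
  bad <- which(is.na(w) & !is.na(d$weight))
  if (length(bad))
    stop("unparseable effect weights at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  dup <- d$variant_id[duplicated(d$variant_id)]
  if (length(dup))
    stop("duplicate variant_id in scoring file: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  out <- data.frame(variant_id = d$variant_id,
                    chromosome = if ("chromosome" %in% names(d))
                      d$chromosome else NA_character_,
                    position = if ("position" %in% names(d))
                      as.integer(d$position) else NA_integer_,
                    effect_allele = toupper(d$effect_allele),
                    other_allele = toupper(d$other_allele),
                    weight = w, stringsAsFactors = FALSE)
  if (any(out$effect_allele == out$other_allele))
    stop("effect and other allele identical for: ",
         paste(out$variant_id[out$effect_allele == out$other_allele],
               collapse = ", "), call. = FALSE)
  class(out) <- c("variant_weights", "data.frame")
  out
}

#' @rdname read_scoring_file
#' @param weights A `"variant_weights"` data frame.
#' @export
write_scoring_file <- function(weights, path) {
  d <- as.data.frame(weights)
  names(d)[names(d) == "variant_id"] <- "rsID"
  names(d)[names(d) == "chromosome"] <- "chr_name"
  names(d)[names(d) == "position"] <- "chr_position"
  names(d)[names(d) == "weight"] <- "effect_weight"
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ambiguous (strand-symmetric) allele pairs excluded from positional
# fallback matching
.is_ambiguous_pair <- function(a, b) {
  p <- paste(pmin(a, b), pmax(a, b))
  p %in% c("A T", "C G")
}

#' Harmonize scoring-file alleles against cohort variant metadata
#'
#' Matches each scoring variant to the cohort's variant metadata, first
#' by `variant_id`, then (for ids absent from the cohort) by
#' `(chromosome, position)` with the ambiguous A/T and C/G pairs excluded
#' from the fallback. Each matched variant is classified as matched
#' as-is (alleles identical) or matched-with-swap (effect/other
#' reversed); anything else is unmatched. For swapped variants the
#' scoring convention is to complement the dosage (`d -> 2 - d`), which
#' leaves raw scores identical to scoring the un-swapped data.
#'
#' @param weights A `"variant_weights"` scoring table.
#' @param cohort_variants A data frame with columns `variant_id`,
#'   `effect_allele`, `other_allele` (and optionally `chromosome`,
#'   `position`) describing the variants present in the cohort.
#' @return A list with `matched` (the scoring rows found in the cohort,
#'   with columns `cohort_variant_id` and logical `swapped`), `unmatched`
#'   (variant ids) and `report` (counts of the three classes).
#' @export
harmonize_alleles <- function(weights, cohort_variants) {
  stopifnot(all(c("variant_id", "effect_allele", "other_allele") %in%
                names(cohort_variants)))
  cv <- cohort_variants
  idx <- match(weights$variant_id, cv$variant_id)
  # positional fallback for ids not found
  if (anyNA(idx) && all(c("chromosome", "position") %in% names(cv)) &&
      all(c("chromosome", "position") %in% names(weights))) {
    key_w <- paste(weights$chromosome, weights$position)
    key_c <- paste(cv$chromosome, cv$position)
    fb <- match(key_w, key_c)
    amb <- .is_ambiguous_pair(weights$effect_allele, weights$other_allele)
    use <- is.na(idx) & !is.na(fb) & !amb
    idx[use] <- fb[use]
  }
  status <- rep("unmatched", nrow(weights))
  swapped <- rep(FALSE, nrow(weights))
  found <- !is.na(idx)
  ea <- cv$effect_allele[idx[found]]; oa <- cv$other_allele[idx[found]]
  as_is <- weights$effect_allele[found] == ea &
    weights$other_allele[found] == oa
  swap <- weights$effect_allele[found] == oa &
    weights$other_allele[found] == ea
  status[found][as_is] <- "as_is"
  status[found][swap & !as_is] <- "swap"
  swapped[found][swap & !as_is] <- TRUE
  keep <- status != "unmatched"
  matched <- weights[keep, , drop = FALSE]
  matched$cohort_variant_id <- cv$variant_id[idx[keep]]
  matched$swapped <- swapped[keep]
  rownames(matched) <- NULL
  class(matched) <- c("variant_weights", "data.frame")
  list(matched = matched,
       unmatched = weights$variant_id[!keep],
       report = list(matched_as_is = sum(status == "as_is"),
                     matched_swap = sum(status == "swap"),
                     unmatched = sum(status == "unmatched")))
}

#' Compute raw PGS from dosages and variant weights
#'
#' The raw score is the weighted sum of effect-allele dosages divided by
#' the number of allele observations: `sum_j w_j d_ij / (2 m_i)`, where
#' `m_i` counts the variants usable for sample `i` under the missing
#' policy. With `"mean_impute"` (default) a missing dosage is replaced by
#' twice the effect-allele frequency estimated from non-missing samples
#' and every matched variant counts in the denominator; with `"drop"`
#' the variant is excluded from that sample's numerator and denominator.
#'
#' @param genotypes Samples x variants numeric matrix of dosages in
#'   `[0, 2]`, `NA` for missing; columns named by cohort variant id,
#'   rows by sample id.
#' @param weights A `"variant_weights"` table, optionally carrying the
#'   `cohort_variant_id`/`swapped` columns from [harmonize_alleles()]
#'   (swapped variants are scored on the complemented dosage `2 - d`).
#' @param missing_policy `"mean_impute"` or `"drop"`.
#' @return A data frame of class `"pgs_result"` with `sample_id`,
#'   `raw_score`, `n_variants_scored` and `score_flag` (`"ok"` or
#'   `"no_usable_variants"`; flagged samples carry `NA` scores rather
#'   than a silent zero).
#' @export
compute_scores <- function(genotypes, weights,
                           missing_policy = c("mean_impute", "drop")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is.matrix(genotypes))
  if (any(genotypes < 0 | genotypes > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  col_id <- if ("cohort_variant_id" %in% names(weights))
    weights$cohort_variant_id else weights$variant_id
  j <- match(col_id, colnames(genotypes))
  if (anyNA(j))
    stop("variants absent from the genotype matrix: ",
         paste(col_id[is.na(j)], collapse = ", "), call. = FALSE)
  if (length(j) < 1L) stop("no matched variants to score", call. = FALSE)
  D <- genotypes[, j, drop = FALSE]
  if ("swapped" %in% names(weights) && any(weights$swapped))
    D[, weights$swapped] <- 2 - D[, weights$swapped]
  w <- weights$weight
  if (missing_policy == "mean_impute") {
    eaf2 <- colMeans(D, na.rm = TRUE)          # 2 * effect-allele freq
    for (k in which(colSums(is.na(D)) > 0)) {
      if (is.nan(eaf2[k]))
        stop("variant ", colnames(D)[k],
             " has no non-missing dosages to impute from", call. = FALSE)
      D[is.na(D[, k]), k] <- eaf2[k]
    }
    m <- rep(ncol(D), nrow(D))
    num <- as.numeric(D %*% w)
  } else {
    obs <- !is.na(D)
    m <- rowSums(obs)
    D0 <- D; D0[!obs] <- 0
    num <- as.numeric(D0 %*% w)
  }
  flag <- ifelse(m > 0, "ok", "no_usable_variants")
  raw <- ifelse(m > 0, num / (2 * m), NA_real_)
  out <- data.frame(sample_id = rownames(genotypes) %||%
                      sprintf("S%05d", seq_len(nrow(genotypes))),
                    raw_score = raw,
                    n_variants_scored = as.integer(m),
                    score_flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("pgs_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize raw PGS within subgroups
#'
#' Converts raw scores to Z-scores with mean 0 and SD 1 within each
#' subgroup, using the sample (n - 1) SD. The per-group means and SDs
#' are returned (as attribute `"group_stats"`) so the same
#' standardization can be applied to new samples; pass them back via
#' `stats` to reuse a reference standardization.
#'
#' @param results A `"pgs_result"` data frame (or any data frame with
#'   `raw_score`).
#' @param group Vector of subgroup labels, one per row.
#' @param stats Optional data frame `(group, mean, sd)` from a previous
#'   call; when supplied, groups are standardized with these constants.
#' @return The input with columns `subgroup` and `z_score` added;
#'   attribute `"group_stats"` carries the constants used.
#' @export
standardize_within_group <- function(results, group, stats = NULL) {
  stopifnot("raw_score" %in% names(results),
            length(group) == nrow(results))
  if (is.null(stats)) {
    gs <- lapply(split(results$raw_score, group), function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2L)
        stop("standardization needs >= 2 scored members per group",
             call. = FALSE)
      s <- stats::sd(x)   # sample SD, n - 1 denominator
      if (s == 0)
        stop("degenerate group: constant raw scores", call. = FALSE)
      c(mean = mean(x), sd = s)
    })
    stats <- data.frame(group = names(gs),
                        mean = vapply(gs, `[[`, numeric(1), "mean"),
                        sd = vapply(gs, `[[`, numeric(1), "sd"),
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  i <- match(as.character(group), stats$group)
  if (anyNA(i))
    stop("groups without standardization constants: ",
         paste(unique(group[is.na(i)]), collapse = ", "), call. = FALSE)
  results$subgroup <- as.character(group)
  results$z_score <- (results$raw_score - stats$mean[i]) / stats$sd[i]
  attr(results, "group_stats") <- stats
  results
}

#' Prune one random member from each related pair
#'
#' Given a list of related id pairs (e.g. first- or second-degree
#' relatives), removes one uniformly chosen member per pair, processing
#' pairs in input order and skipping pairs already broken by an earlier
#' removal. The retained set contains no listed pair; the choice is
#' deterministic under the seed.
#'
#' @param pairs Data frame (or 2-column matrix) of id pairs.
#' @param ids Optional vector of all ids; defaults to the ids appearing
#'   in `pairs`.
#' @param seed Integer seed.
#' @return Character vector of retained ids.
#' @export
prune_relatives <- function(pairs, ids = NULL, seed = 1L) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) > 0 && ncol(pairs) < 2)
    stop("pairs needs two columns", call. = FALSE)
  all_ids <- unique(c(if (!is.null(ids)) as.character(ids),
                      if (nrow(pairs) > 0)
                        c(as.character(pairs[[1]]),
                          as.character(pairs[[2]]))))
  if (nrow(pairs) == 0) return(all_ids)
  with_substream(seed, "prune_relatives", {
    removed <- character(0)
    for (r in seq_len(nrow(pairs))) {
      a <- as.character(pairs[[1]][r]); b <- as.character(pairs[[2]][r])
      if (a %in% removed || b %in% removed) next
      removed <- c(removed, sample(c(a, b), 1L))
    }
    setdiff(all_ids, removed)
  })
}

#' Assign samples to super-populations by k-means from reference centroids
#'
#' Runs Lloyd's algorithm (Euclidean distance in the 4-PC space,
#' convergence when assignments stabilize or after 100 iterations)
#' initialized at the supplied reference centroids, making the
#' assignment deterministic. If a cluster empties, its centroid is kept
#' fixed and a warning is emitted; samples are always labeled by their
#' final nearest centroid.
#'
#' @param coords Data frame with columns `PC1`..`PC4` (and optionally
#'   `sample_id`), or a numeric matrix with 4 columns.
#' @param reference_centroids 5 x 4 numeric matrix; rownames are the
#'   super-population labels.
#' @return Character vector of labels, one per sample.
#' @export
assign_superpopulations <- function(coords, reference_centroids) {
  X <- if (is.data.frame(coords))
    as.matrix(coords[, c("PC1", "PC2", "PC3", "PC4")]) else as.matrix(coords)
  stopifnot(ncol(X) == 4, nrow(reference_centroids) == 5,
            ncol(reference_centroids) == 4)
  C <- as.matrix(reference_centroids)
  labels <- rownames(C) %||% paste0("K", 1:5)
  assign_nearest <- function(C) {
    d2 <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * X %*% t(C)
    max.col(-d2, ties.method = "first")
  }
  cl <- assign_nearest(C)
  warned <- FALSE
  for (it in seq_len(100L)) {
    for (k in 1:5) {
      if (any(cl == k)) C[k, ] <- colMeans(X[cl == k, , drop = FALSE])
      else if (!warned) { warning("empty cluster during k-means; centroid ",
                                  labels[k], " kept fixed", call. = FALSE)
                          warned <- TRUE }
    }
    new_cl <- assign_nearest(C)
    if (all(new_cl == cl)) break
    cl <- new_cl
  }
  if (length(unique(cl)) < 5 && !warned)
    warning("empty cluster after k-means convergence", call. = FALSE)
  labels[cl]
}

#' Flag samples within 3 SD of a reference European PC mean
#'
#' `TRUE` iff every one of the four PC coordinates lies within three
#' reference standard deviations of the reference mean (inclusive
#' boundary).
#'
#' @param coords As in [assign_superpopulations()].
#' @param eur_mean,eur_sd Numeric length-4 reference mean and SD;
#'   `eur_sd` strictly positive.
#' @return Logical vector, one per sample.
#' @export
eur_3sd_filter <- function(coords, eur_mean, eur_sd) {
  X <- if (is.data.frame(coords))
    as.matrix(coords[, c("PC1", "PC2", "PC3", "PC4")]) else as.matrix(coords)
  stopifnot(length(eur_mean) == 4, length(eur_sd) == 4)
  if (any(eur_sd <= 0)) stop("eur_sd must be strictly positive", call. = FALSE)
  dev <- abs(sweep(X, 2, eur_mean)) <= rep(3 * eur_sd, each = nrow(X))
  rowSums(dev) == 4L
}
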