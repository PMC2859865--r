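#' Is a sire-steer genotype pair a Mendelian (heritability) error?
#'
#' For a biallelic marker in a parent-child duo, the only configuration
#' impossible under Mendelian transmission is a pair of opposite homozygotes
#' (`AA` vs `BB`); a deletion on the transmitted haplotype produces exactly
#' this signature when the hemizygous genotypes are called as homozygotes.
#' Both genotypes must be called; pre-filter `NC` pairs.
#'
#' @param sire_genotype,steer_genotype vectors of calls in `AA`, `AB`, `BB`.
#' @return logical vector, `TRUE` where the duo is impossible.
#' @export
mendel_error <- function(sire_genotype, steer_genotype) {
  ok <- c("AA", "AB", "BB")
  if (!all(sire_genotype %in% ok) || !all(steer_genotype %in% ok)) {
    stop("mendel_error requires called genotypes (no NC); pre-filter pairs")
  }
  (sire_genotype == "AA" & steer_genotype == "BB") |
    (sire_genotype == "BB" & steer_genotype == "AA")
}

#' Per-marker parent-child heritability error frequencies
#'
#' For each marker, counts opposite-homozygote errors over the informative
#' duos (both genotypes called) and reports the error frequency. Markers with
#' no informative duo get a missing frequency.
#'
#' @param table an [intensity_table()] containing both duo members.
#' @param pairs pedigree data.frame (`sire_id`, `steer_id`).
#' @param markers optional subset of marker ids (default: all markers).
#' @return data.frame: `marker_id`, `n_pairs_informative`, `n_errors`,
#'   `pc_error_freq`.
#' @export
pc_error_frequencies <- function(table, pairs, markers = NULL) {
  stopifnot(inherits(table, "intensity_table"),
            all(c("sire_id", "steer_id") %in% names(pairs)))
  ids <- unique(c(pairs$sire_id, pairs$steer_id))
  missing_ids <- setdiff(ids, table$samples)
  if (length(missing_ids) > 0L) {
    stop("pedigree sample(s) absent from table: ",
         paste(missing_ids, collapse = ", "))
  }
  mk <- if (is.null(markers)) table$markers$marker_id else markers
  g_sire <- table$genotype[mk, pairs$sire_id, drop = FALSE]
  g_steer <- table$genotype[mk, pairs$steer_id, drop = FALSE]
  informative <- g_sire != "NC" & g_steer != "NC"
  err <- informative &
    ((g_sire == "AA" & g_steer == "BB") | (g_sire == "BB" & g_steer == "AA"))
  n_inf <- rowSums(informative)
  n_err <- rowSums(err)
  data.frame(marker_id = mk,
             n_pairs_informative = n_inf,
             n_errors = n_err,
             pc_error_freq = ifelse(n_inf > 0L, n_err / n_inf, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-duo heritability concordance (pair QC)
#'
#' Overall genotype concordance of each sire-steer duo across all markers
#' (1 minus the opposite-homozygote error rate over informative markers),
#' used to confirm the parent-child relationship before the marker-level
#' screen.
#'
#' @param table an [intensity_table()].
#' @param pairs pedigree data.frame.
#' @return `pairs` with added `n_informative`, `n_errors`, `concordance`.
#' @export
pair_concordance <- function(table, pairs) {
  stopifnot(inherits(table, "intensity_table"))
  res <- pairs
  res$n_informative <- 0L; res$n_errors <- 0L; res$concordance <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    gs <- table$genotype[, pairs$sire_id[i]]
    gt <- table$genotype[, pairs$steer_id[i]]
    inf <- gs != "NC" & gt != "NC"
    ne <- sum(mendel_error(gs[inf], gt[inf]))
    res$n_informative[i] <- sum(inf)
    res$n_errors[i] <- ne
    res$concordance[i] <- if (sum(inf) > 0L) 1 - ne / sum(inf) else NA_real_
  }
  res
}

#' Select deletion-polymorphism candidate markers by P-C error frequency
#'
#' Markers whose heritability error frequency exceeds the threshold. The
#' default comparison is strict (`> 3%`); set `strict = FALSE` for an
#' inclusive `>=` rule.
#'
#' @param stats data.frame from [pc_error_frequencies()].
#' @param threshold error-frequency cutoff (default 0.03).
#' @param strict strict (`>`) vs inclusive (`>=`) comparison.
#' @return character vector of candidate marker ids.
#' @export
select_candidates <- function(stats, threshold = 0.03, strict = TRUE) {
  f <- stats$pc_error_freq
  keep <- !is.na(f) & if (strict) f > threshold else f >= threshold
  stats$marker_id[keep]
}

#' Parameters of the six-genotype cluster classifier
#'
#' @param baf_lo,baf_hi BAF cutoffs separating the A-side, heterozygous and
#'   B-side clusters (defaults 0.15 / 0.85).
#' @param c0,c1 intensity-tier cutoffs relative to the diploid homozygote
#'   median `m`: null below `c0*m`, hemizygous in `[c0*m, c1*m)`, diploid
#'   above (defaults 0.15 / 0.70).
#' @param min_hemi minimum hemizygous samples at a BAF extreme for cluster
#'   evidence (default 3).
#' @param min_called minimum samples with both BAF and R present (default 10).
#' @return list of class `sixgeno_params`.
#' @export
sixgeno_params <- function(baf_lo = 0.15, baf_hi = 0.85, c0 = 0.15,
                           c1 = 0.70, min_hemi = 3L, min_called = 10L) {
  stopifnot(baf_lo < baf_hi, c0 < c1, c0 > 0, min_hemi >= 1L)
  structure(list(baf_lo = baf_lo, baf_hi = baf_hi, c0 = c0, c1 = c1,
                 min_hemi = as.integer(min_hemi),
                 min_called = as.integer(min_called)),
            class = "sixgeno_params")
}

#' Classify samples at one marker into six copy-aware genotypes
#'
#' Automates the genoplot inspection of a candidate deletion marker: samples
#' are partitioned by allelic intensity (BAF near 0 / near 1/2 / near 1) and
#' by total-intensity tier relative to the median R of diploid-tier
#' homozygotes (`m`, seeded from the upper decile of R so that a deletion
#' carried by most samples does not drag the reference down): below `c0*m`
#' is the null-copy cluster (`-/-`), between
#' `c0*m` and `c1*m` the hemizygous clusters (`A/-`, `B/-`), above the
#' diploid clusters (`AA`, `AB`, `BB`). `cluster_evidence` is `TRUE` when a
#' hemizygous tier of at least `min_hemi` samples sits at a BAF extreme -
#' i.e. the genoplot would show the six-cluster pattern of a common deletion
#' polymorphism.
#'
#' @param table an [intensity_table()] with `r_total` present at the marker.
#' @param marker_id marker to classify.
#' @param params a [sixgeno_params()].
#' @return list with `calls` (named character vector per sample, levels
#'   `AA`, `AB`, `BB`, `A/-`, `B/-`, `-/-`; `NA` where unclassifiable),
#'   `cluster_evidence` (logical, `NA` if too few called samples) and the
#'   diploid reference intensity `m`.
#' @export
classify_six_genotypes <- function(table, marker_id,
                                   params = sixgeno_params()) {
  stopifnot(inherits(table, "intensity_table"),
            inherits(params, "sixgeno_params"))
  if (!marker_id %in% table$markers$marker_id) {
    stop("unknown marker: ", marker_id)
  }
  baf <- table$baf[marker_id, ]
  r <- table$r_total[marker_id, ]
  calls <- setNames(rep(NA_character_, length(r)), table$samples)
  usable <- !is.na(baf) & !is.na(r)
  if (sum(usable) < params$min_called) {
    return(list(calls = calls, cluster_evidence = NA, m = NA_real_))
  }
  b <- baf[usable]; rr <- r[usable]
  side <- ifelse(b <= params$baf_lo, "A",
                 ifelse(b >= params$baf_hi, "B", "mid"))
  # anchor the diploid tier on the upper decile of R rather than the median:
  # at a common deletion the hemizygous cluster can hold most samples, but
  # the top of the intensity distribution stays diploid
  m0 <- unname(quantile(rr, 0.9, type = 7))
  dip0 <- rr >= params$c1 * m0
  hom0 <- side != "mid"
  m <- if (any(dip0 & hom0)) median(rr[dip0 & hom0]) else
    if (any(dip0)) median(rr[dip0]) else m0
  tier <- ifelse(rr < params$c0 * m, "null",
                 ifelse(rr < params$c1 * m, "hemi", "diploid"))
  cl <- character(length(rr))
  cl[tier == "null"] <- "-/-"
  cl[tier == "hemi" & side == "A"] <- "A/-"
  cl[tier == "hemi" & side == "B"] <- "B/-"
  # mid-BAF signal at hemizygous intensity has no single-allele explanation;
  # called as the diploid heterozygote
  cl[tier == "hemi" & side == "mid"] <- "AB"
  cl[tier == "diploid"] <- c(A = "AA", mid = "AB", B = "BB")[
    side[tier == "diploid"]]
  calls[usable] <- cl
  n_hemi_extreme <- sum(tier == "hemi" & side != "mid")
  list(calls = calls,
       cluster_evidence = n_hemi_extreme >= params$min_hemi,
       m = m)
}

#' Pairwise intensity-ratio scan between a target and a reference sample
#'
#' Screens every marker for `|log2(R_target / R_reference)|` at or beyond the
#' threshold; the classic BeadStudio paired-sample inspection
#' (`log2(R_sub/R_ref) <= -1.5` or `>= 1.5`). Markers with missing R in
#' either sample are skipped. Negative-ratio hits indicate loss in the
#' target, positive-ratio hits gain.
#'
#' @param table an [intensity_table()] with the R layer populated.
#' @param target_sample,reference_sample distinct sample ids; the reference
#'   should be a QC-passing, low-noise sample.
#' @param threshold absolute log2-ratio cutoff (default 1.5, inclusive).
#' @return data.frame: `marker_id`, `chromosome`, `position`,
#'   `target_sample`, `reference_sample`, `log2_ratio`, `direction`.
#' @export
pairwise_scan <- function(table, target_sample, reference_sample,
                          threshold = 1.5) {
  stopifnot(inherits(table, "intensity_table"), threshold > 0)
  if (identical(target_sample, reference_sample)) {
    stop("target and reference sample must differ")
  }
  for (s in c(target_sample, reference_sample)) {
    if (!s %in% table$samples) stop("unknown sample id: ", s)
  }
  r_t <- table$r_total[, target_sample]
  r_r <- table$r_total[, reference_sample]
  ratio <- log2(r_t / r_r)
  hit <- which(!is.na(ratio) & abs(ratio) >= threshold)
  data.frame(marker_id = table$markers$marker_id[hit],
             chromosome = table$markers$chromosome[hit],
             position = table$markers$position[hit],
             target_sample = rep(target_sample, length(hit)),
             reference_sample = rep(reference_sample, length(hit)),
             log2_ratio = unname(ratio[hit]),
             direction = ifelse(ratio[hit] < 0, "loss", "gain"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Choose the pairwise-scan reference sample
#'
#' The QC-passing sample with the lowest LRR noise.
#'
#' @param qc data.frame from [compute_sample_qc()].
#' @param sd_threshold QC cutoff handed to [filter_samples()].
#' @return a sample id.
#' @export
choose_reference_sample <- function(qc, sd_threshold = 0.30) {
  pass <- filter_samples(qc, sd_threshold)
  if (length(pass) == 0L) stop("no sample passes QC")
  sub <- qc[qc$sample_id %in% pass, ]
  sub$sample_id[which.min(sub$sd_lrr)]
}

#' Markers with deletion-side pairwise hits across a set of target samples
#'
#' Runs [pairwise_scan()] of each target against one reference and collects
#' the union of markers hit on the loss side (`log2 ratio <= -threshold`);
#' gain-side hits are recorded by the scan but excluded from the deletion
#' catalogue.
#'
#' @param table an [intensity_table()].
#' @param target_samples samples to scan.
#' @param reference_sample the reference sample id.
#' @param threshold absolute log2-ratio cutoff (default 1.5).
#' @param min_targets report a marker once at least this many targets hit it
#'   (default 1).
#' @return character vector of marker ids.
#' @export
pairwise_deletion_markers <- function(table, target_samples, reference_sample,
                                      threshold = 1.5, min_targets = 1L) {
  hits <- lapply(setdiff(target_samples, reference_sample), function(s) {
    h <- pairwise_scan(table, s, reference_sample, threshold)
    unique(h$marker_id[h$direction == "loss"])
  })
  tab <- base::table(unlist(hits))
  names(tab)[tab >= min_targets]
}

#' Merge deletion-polymorphism catalogues from the two discovery methods
#'
#' Set union of the heritability-screen and pairwise-scan marker lists, with
#' per-marker provenance and a both-methods flag; the union size obeys
#' inclusion-exclusion (`|A| + |B| - |A n B|`). Optional per-marker
#' statistics (P-C error frequency, cluster evidence, HWE p, missing rate)
#' are joined onto the catalogue when supplied.
#'
#' @param heritability_markers,pairwise_markers character vectors of marker
#'   ids.
#' @param stats optional data.frame from [pc_error_frequencies()].
#' @param cluster_evidence optional named logical vector by marker id.
#' @param hwe_p,missing_rate optional named numeric vectors by marker id.
#' @return data.frame: `marker_id`, `methods`, `both_methods`, plus any
#'   joined statistics columns.
#' @export
merge_methods <- function(heritability_markers, pairwise_markers,
                          stats = NULL, cluster_evidence = NULL,
                          hwe_p = NULL, missing_rate = NULL) {
  a <- unique(as.character(heritability_markers))
  b <- unique(as.character(pairwise_markers))
  all_mk <- union(a, b)
  in_a <- all_mk %in% a; in_b <- all_mk %in% b
  out <- data.frame(
    marker_id = all_mk,
    methods = ifelse(in_a & in_b, "heritability,pairwise",
                     ifelse(in_a, "heritability", "pairwise")),
    both_methods = in_a & in_b,
    stringsAsFactors = FALSE)
  if (!is.null(stats)) {
    out$pc_error_freq <- stats$pc_error_freq[match(all_mk, stats$marker_id)]
  }
  if (!is.null(cluster_evidence)) {
    out$cluster_evidence <- unname(cluster_evidence[all_mk])
  }
  if (!is.null(hwe_p)) out$hwe_p <- unname(hwe_p[all_mk])
  if (!is.null(missing_rate)) out$missing_rate <- unname(missing_rate[all_mk])
  out
}

#' One-degree-of-freedom Hardy-Weinberg chi-square test
#'
#' Compares observed genotype counts with Hardy-Weinberg expectations at the
#' observed allele frequency. A deletion segregating at a marker inflates
#' homozygote counts, so HWE deviation is an ancillary deletion flag.
#'
#' @param n_aa,n_ab,n_bb non-negative genotype counts.
#' @return list with `chi2` and `p` (both `NA` for a monomorphic marker).
#' @export
marker_hwe_chi2 <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(list(chi2 = NA_real_, p = NA_real_))
  p <- (2 * n_bb + n_ab) / (2 * n)  # B allele frequency
  if (p == 0 || p == 1) return(list(chi2 = NA_real_, p = NA_real_))
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((c(n_aa, n_ab, n_bb) - expected)^2 / expected)
  list(chi2 = chi2, p = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Missing genotype rate at a marker
#'
#' @param genotypes character vector of calls at one marker.
#' @return fraction of `NC` calls.
#' @export
marker_missing_rate <- function(genotypes) {
  if (length(genotypes) == 0L) return(NA_real_)
  mean(genotypes == "NC")
}

#' Export a deletion-polymorphism catalogue as TSV
#'
#' @param catalogue data.frame from [merge_methods()].
#' @param map optional marker map to add chromosome/position columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_delpoly_catalogue <- function(catalogue, path, map = NULL) {
  out <- catalogue
  if (!is.null(map)) {
    i <- match(out$marker_id, map$marker_id)
    out <- cbind(out[, "marker_id", drop = FALSE],
                 chromosome = map$chromosome[i], position = map$position[i],
                 out[, setdiff(names(out), "marker_id"), drop = FALSE])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
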