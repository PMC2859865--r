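#' Aggregate CNV calls into CNV regions (CNVRs)
#'
#' Calls on the same chromosome that overlap by at least one shared position
#' are grouped by transitive closure; each group becomes one region spanning
#' `min(start)..max(end)` of its member calls. Regions are disjoint and
#' sorted by (chromosome, start). Every call belongs to exactly one region.
#'
#' @param calls call data.frame (see [call_cnvs()]).
#' @return data.frame of regions: `region_id`, `chromosome`, `start`, `end`,
#'   `n_cnvs`, `n_gain`, `n_loss`, `type`, plus a list column
#'   `member_calls` holding each region's member-call data.frame.
#' @export
build_cnvrs <- function(calls) {
  if (nrow(calls) == 0L) {
    out <- data.frame(region_id = character(), chromosome = integer(),
                      start = integer(), end = integer(), n_cnvs = integer(),
                      n_gain = integer(), n_loss = integer(),
                      type = character(), stringsAsFactors = FALSE)
    out$member_calls <- list()
    return(out)
  }
  regions <- list()
  for (chr in sort(unique(calls$chromosome))) {
    sub <- calls[calls$chromosome == chr, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start, end = sub$end)
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)
    hits <- IRanges::findOverlaps(ir, merged, minoverlap = 1L)
    grp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    for (g in seq_along(merged)) {
      members <- sub[grp == g, , drop = FALSE]
      regions[[length(regions) + 1L]] <- list(
        chromosome = chr,
        start = min(members$start), end = max(members$end),
        members = members)
    }
  }
  out <- data.frame(
    chromosome = vapply(regions, `[[`, integer(1L), "chromosome"),
    start = vapply(regions, `[[`, numeric(1L), "start"),
    end = vapply(regions, `[[`, numeric(1L), "end"),
    stringsAsFactors = FALSE)
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  ord <- order(vapply(regions, `[[`, integer(1L), "chromosome"),
               vapply(regions, `[[`, numeric(1L), "start"))
  regions <- regions[ord]
  rownames(out) <- NULL
  out$region_id <- sprintf("chr%d:%d-%d", out$chromosome,
                           as.integer(out$start), as.integer(out$end))
  out$member_calls <- lapply(regions, `[[`, "members")
  out$n_cnvs <- vapply(out$member_calls, nrow, integer(1L))
  out$n_gain <- vapply(out$member_calls,
                       function(m) sum(m$copy_state > 2L), integer(1L))
  out$n_loss <- vapply(out$member_calls,
                       function(m) sum(m$copy_state < 2L), integer(1L))
  out$type <- vapply(seq_len(nrow(out)),
                     function(i) classify_type(out[i, ]), character(1L))
  out[, c("region_id", "chromosome", "start", "end", "n_cnvs", "n_gain",
          "n_loss", "type", "member_calls")]
}

#' Length of a region or call interval
#'
#' Reporting convention: `end - start`, matching printed region coordinates
#' (e.g. chr15:1836732-2039483 has length 202,751 bp).
#'
#' @param region one-row region/call data.frame, or any data.frame with
#'   `start` and `end` columns (vectorized).
#' @return integer length(s) in bp.
#' @export
region_length <- function(region) {
  as.integer(region$end - region$start)
}

#' CNV frequency of a region
#'
#' Member-call count over the number of genotyped samples (rounded to three
#' decimals in exported tables; returned here at full precision).
#'
#' @param region one-row region data.frame (or any with `n_cnvs`).
#' @param n_samples cohort size (>= 1).
#' @param distinct_carriers count each carrier sample once instead of each
#'   member call (not the reporting default).
#' @return frequency in (0, 1\].
#' @export
cnvr_frequency <- function(region, n_samples, distinct_carriers = FALSE) {
  if (length(n_samples) != 1L || is.na(n_samples) || n_samples < 1L) {
    stop("n_samples must be a positive integer")
  }
  num <- if (distinct_carriers && !is.null(region$member_calls)) {
    vapply(region$member_calls,
           function(m) length(unique(m$sample_id)), integer(1L))
  } else {
    region$n_cnvs
  }
  num / n_samples
}

#' Classify a region as gain-only, loss-only or mixed
#'
#' @param region one-row region data.frame with a `member_calls` list column
#'   (or `n_gain`/`n_loss` counts).
#' @return one of `"gain_only"`, `"loss_only"`, `"mixed"`.
#' @export
classify_type <- function(region) {
  if (!is.null(region$member_calls)) {
    states <- region$member_calls[[1L]]$copy_state
    n_gain <- sum(states > 2L); n_loss <- sum(states < 2L)
  } else {
    n_gain <- region$n_gain; n_loss <- region$n_loss
  }
  if (n_gain + n_loss == 0L) stop("region has no member calls")
  if (n_loss == 0L) "gain_only" else if (n_gain == 0L) "loss_only" else "mixed"
}

#' Annotate regions with overlapping genes
#'
#' A gene is listed for a region when its interval shares at least one
#' position with the region span (both in the package's 1-based convention;
#' see [read_gene_bed()] - a gene abutting the region end does not overlap).
#' Genes are deduplicated per region.
#'
#' @param regions region data.frame from [build_cnvrs()].
#' @param genes data.frame with `gene_id`, `chromosome`, `start`, `end`.
#' @return `regions` with list column `genes` and count column `n_genes`.
#' @export
annotate_genes <- function(regions, genes) {
  if (nrow(regions) == 0L) {
    regions$genes <- list(); regions$n_genes <- integer()
    return(regions)
  }
  gr_reg <- GenomicRanges::GRanges(
    seqnames = regions$chromosome,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end))
  regions$genes <- replicate(nrow(regions), character(), simplify = FALSE)
  if (nrow(genes) > 0L) {
    gr_gen <- GenomicRanges::GRanges(
      seqnames = genes$chromosome,
      ranges = IRanges::IRanges(start = genes$start, end = genes$end))
    hits <- GenomicRanges::findOverlaps(gr_reg, gr_gen, minoverlap = 1L)
    for (i in unique(S4Vectors::queryHits(hits))) {
      g <- genes$gene_id[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]]
      regions$genes[[i]] <- sort(unique(g))
    }
  }
  regions$n_genes <- vapply(regions$genes, length, integer(1L))
  regions
}

#' Cohort-level summary of a CNV call set and its regions
#'
#' The derived statistics of a discovery cohort: counts, per-sample means,
#' size distributions (kb, length convention `end - start`), gain/loss split
#' and their ratio, common-region counts at strict frequency thresholds
#' (> 1%, > 2.5%, > 5%) and the number of distinct genes in annotated
#' regions. Means, sizes and the ratio are reported rounded to one decimal;
#' an all-gain or empty call set yields an `NA` ratio rather than an error.
#'
#' @param calls call data.frame.
#' @param regions region data.frame from [build_cnvrs()] (optionally gene
#'   annotated).
#' @param n_samples cohort size.
#' @return one-row data.frame (class `callset_summary`).
#' @export
summarize_callset <- function(calls, regions, n_samples) {
  stopifnot(n_samples >= 1L)
  sizes_kb <- function(x) if (nrow(x) == 0L) numeric() else
    (x$end - x$start) / 1000
  n_gain <- sum(calls$copy_state > 2L)
  n_loss <- sum(calls$copy_state < 2L)
  freq <- if (nrow(regions) > 0L) regions$n_cnvs / n_samples else numeric()
  n_genes <- if ("genes" %in% names(regions)) {
    length(unique(unlist(regions$genes)))
  } else NA_integer_
  out <- data.frame(
    n_cnvs = nrow(calls),
    mean_per_sample = round(nrow(calls) / n_samples, 1L),
    mean_size_kb = round(mean(sizes_kb(calls)), 1L),
    median_size_kb = round(median(sizes_kb(calls)), 1L),
    n_gain = n_gain, n_loss = n_loss,
    loss_gain_ratio = if (n_gain == 0L) NA_real_ else
      round(n_loss / n_gain, 1L),
    n_cnvrs = nrow(regions),
    mean_cnvrs_per_sample = round(nrow(regions) / n_samples, 1L),
    mean_cnvr_size_kb = round(mean(sizes_kb(regions)), 1L),
    median_cnvr_size_kb = round(median(sizes_kb(regions)), 1L),
    n_common_1pct = sum(freq > 0.01),
    n_common_2_5pct = sum(freq > 0.025),
    n_common_5pct = sum(freq > 0.05),
    n_genes = n_genes)
  if (nrow(calls) == 0L) {
    out$mean_size_kb <- out$median_size_kb <- 0
  }
  if (nrow(regions) == 0L) {
    out$mean_cnvr_size_kb <- out$median_cnvr_size_kb <- 0
  }
  class(out) <- c("callset_summary", class(out))
  out
}

#' Export CNV regions as a publication-style TSV
#'
#' Columns follow the common-region table layout: `CNV region` (coordinate
#' label), `Length (bp)`, `No. of CNVs`, `Frequency` (3 decimals),
#' `No. of genes`, `Genes`.
#'
#' @param regions (annotated) region data.frame.
#' @param n_samples cohort size used for the frequency column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cnvr_table <- function(regions, n_samples, path) {
  out <- data.frame(
    `CNV region` = regions$region_id,
    `Length (bp)` = region_length(regions),
    `No. of CNVs` = regions$n_cnvs,
    Frequency = sprintf("%.3f", regions$n_cnvs / n_samples),
    `No. of genes` = if ("n_genes" %in% names(regions)) regions$n_genes else 0L,
    Genes = if ("genes" %in% names(regions)) {
      vapply(regions$genes, paste, character(1L), collapse = ", ")
    } else "",
    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
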