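#' Validate and sort a marker map
#'
#' A marker map is a `data.frame` with columns `marker_id`, `chromosome`
#' (integer autosome index) and `position` (1-based bp, as printed by the
#' genotyping software). Markers are sorted by (chromosome, position).
#'
#' @param markers data.frame with columns `marker_id`, `chromosome`,
#'   `position`.
#' @param n_chromosomes number of autosomes accepted (default 29, the bovine
#'   autosome count).
#' @return the validated map, sorted by (chromosome, position).
#' @export
as_marker_map <- function(markers, n_chromosomes = 29L) {
  stopifnot(is.data.frame(markers))
  need <- c("marker_id", "chromosome", "position")
  miss <- setdiff(need, names(markers))
  if (length(miss) > 0L) {
    stop("marker map is missing column(s): ", paste(miss, collapse = ", "))
  }
  markers$marker_id <- as.character(markers$marker_id)
  markers$chromosome <- as.integer(markers$chromosome)
  markers$position <- as.integer(markers$position)
  if (anyNA(markers$chromosome) ||
      any(markers$chromosome < 1L | markers$chromosome > n_chromosomes)) {
    stop("chromosome must be an integer in 1..", n_chromosomes)
  }
  if (anyNA(markers$position) || any(markers$position < 1L)) {
    stop("position must be a positive 1-based integer")
  }
  if (anyDuplicated(markers$marker_id)) {
    stop("duplicate marker_id in marker map")
  }
  markers <- markers[order(markers$chromosome, markers$position), , drop = FALSE]
  rownames(markers) <- NULL
  markers
}

#' Construct an intensity table
#'
#' The central container of the package: per-marker genomic coordinates plus
#' four marker x sample layers holding log R ratio (LRR), B allele frequency
#' (BAF), total signal intensity R, and the called genotype. Matrices are
#' oriented markers in rows, samples in columns, with dimnames set to marker
#' and sample identifiers.
#'
#' @param markers marker map (see [as_marker_map()]).
#' @param lrr,baf,r_total numeric matrices (markers x samples); `NA` encodes a
#'   missing measurement. BAF must lie in \[0, 1\] and R must be positive
#'   where present.
#' @param genotype character matrix of calls in `AA`, `AB`, `BB`, `NC`.
#' @return an object of class `intensity_table`.
#' @export
intensity_table <- function(markers, lrr, baf, r_total, genotype) {
  markers <- as_marker_map(markers)
  samples <- colnames(lrr)
  if (is.null(samples)) stop("lrr must have sample ids as column names")
  dims <- dim(lrr)
  for (layer in list(baf = baf, r_total = r_total, genotype = genotype)) {
    if (!identical(dim(layer), dims)) {
      stop("all layers must share dimensions markers x samples")
    }
  }
  if (nrow(lrr) != nrow(markers)) {
    stop("layer row count does not match the marker map")
  }
  idx <- match(markers$marker_id, rownames(lrr))
  if (anyNA(idx)) stop("layer rownames must carry marker ids")
  reorder <- function(m) m[idx, , drop = FALSE]
  lrr <- reorder(lrr); baf <- reorder(baf)
  r_total <- reorder(r_total); genotype <- reorder(genotype)
  if (any(baf < 0 | baf > 1, na.rm = TRUE)) {
    stop("BAF values must lie in [0, 1]")
  }
  if (any(r_total <= 0, na.rm = TRUE)) {
    stop("r_total values must be positive where present")
  }
  bad <- setdiff(unique(as.vector(genotype)), c("AA", "AB", "BB", "NC", NA))
  if (length(bad) > 0L) {
    stop("invalid genotype token(s): ", paste(bad, collapse = ", "))
  }
  genotype[is.na(genotype)] <- "NC"
  structure(
    list(markers = markers, samples = samples,
         lrr = lrr, baf = baf, r_total = r_total, genotype = genotype),
    class = "intensity_table"
  )
}

#' @export
print.intensity_table <- function(x, ...) {
  cat("intensity_table:", nrow(x$markers), "markers x",
      length(x$samples), "samples\n")
  cat("  chromosomes:", paste(range(x$markers$chromosome), collapse = "-"),
      " missing LRR:", sum(is.na(x$lrr)), "\n")
  invisible(x)
}

#' Number of markers / samples in an intensity table
#' @param x an `intensity_table`.
#' @return integer count.
#' @export
n_markers <- function(x) nrow(x$markers)

#' @rdname n_markers
#' @export
n_samples <- function(x) length(x$samples)

#' Subset an intensity table by samples and/or markers
#'
#' @param x an `intensity_table`.
#' @param samples character vector of sample ids to keep (default all).
#' @param markers character vector of marker ids to keep (default all).
#' @return a new `intensity_table`.
#' @export
subset_table <- function(x, samples = NULL, markers = NULL) {
  stopifnot(inherits(x, "intensity_table"))
  si <- if (is.null(samples)) seq_along(x$samples) else {
    i <- match(samples, x$samples)
    if (anyNA(i)) stop("unknown sample id(s): ",
                       paste(samples[is.na(i)], collapse = ", "))
    i
  }
  mi <- if (is.null(markers)) seq_len(nrow(x$markers)) else {
    i <- match(markers, x$markers$marker_id)
    if (anyNA(i)) stop("unknown marker id(s): ",
                       paste(markers[is.na(i)], collapse = ", "))
    sort(i)
  }
  intensity_table(
    x$markers[mi, , drop = FALSE],
    x$lrr[mi, si, drop = FALSE], x$baf[mi, si, drop = FALSE],
    x$r_total[mi, si, drop = FALSE], x$genotype[mi, si, drop = FALSE]
  )
}
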