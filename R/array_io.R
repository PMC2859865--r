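#' Read a Final-Report-like intensity/genotype export
#'
#' Parses the tab-separated per-sample-per-marker dialect produced by array
#' genotyping software ("Final Report" exports): one row per (marker, sample)
#' with the header columns `SNP Name`, `Sample ID`, `Chr`, `Position`,
#' `Log R Ratio`, `B Allele Freq`, `GType` and optionally `R` (total signal
#' intensity). Empty numeric fields become missing values; an empty or `--`
#' genotype becomes `NC`. Malformed numeric fields, BAF outside \[0, 1\],
#' non-positive R, and unknown chromosome tokens are rejected with the
#' offending line number.
#'
#' @param path path to the TSV file.
#' @param n_chromosomes accepted autosome range (default 29).
#' @return an [intensity_table()].
#' @export
read_final_report <- function(path, n_chromosomes = 29L) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  need <- c("SNP Name", "Sample ID", "Chr", "Position",
            "Log R Ratio", "B Allele Freq", "GType")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("final report is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop("final report contains no data rows")
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1

  parse_num <- function(txt, what, allow_missing = TRUE) {
    txt <- trimws(txt)
    missing <- txt == "" | txt == "NA" | txt == "NaN"
    out <- suppressWarnings(as.numeric(txt))
    bad <- is.na(out) & !missing
    if (any(bad)) {
      stop("malformed ", what, " value '", txt[bad][1L],
           "' at line ", line_no[bad][1L])
    }
    out[missing] <- NA_real_
    if (!allow_missing && anyNA(out)) {
      stop("missing ", what, " at line ", line_no[is.na(out)][1L])
    }
    out
  }

  chr_txt <- sub("^chr", "", trimws(raw$Chr), ignore.case = TRUE)
  chrom <- suppressWarnings(as.integer(chr_txt))
  bad_chr <- is.na(chrom) | chrom < 1L | chrom > n_chromosomes
  if (any(bad_chr)) {
    stop("unknown chromosome token '", raw$Chr[bad_chr][1L],
         "' at line ", line_no[bad_chr][1L])
  }
  pos <- parse_num(raw$Position, "Position", allow_missing = FALSE)
  lrr <- parse_num(raw$`Log R Ratio`, "Log R Ratio")
  baf <- parse_num(raw$`B Allele Freq`, "B Allele Freq")
  bad_baf <- !is.na(baf) & (baf < 0 | baf > 1)
  if (any(bad_baf)) {
    stop("B Allele Freq ", baf[bad_baf][1L], " outside [0, 1] at line ",
         line_no[bad_baf][1L])
  }
  r_tot <- if ("R" %in% names(raw)) parse_num(raw$R, "R") else
    rep(NA_real_, nrow(raw))
  bad_r <- !is.na(r_tot) & r_tot <= 0
  if (any(bad_r)) {
    stop("non-positive R at line ", line_no[bad_r][1L])
  }
  gtype <- trimws(raw$GType)
  gtype[gtype %in% c("", "--", "NC")] <- "NC"
  bad_g <- !(gtype %in% c("AA", "AB", "BB", "NC"))
  if (any(bad_g)) {
    stop("invalid genotype token '", gtype[bad_g][1L],
         "' at line ", line_no[bad_g][1L])
  }

  marker_id <- trimws(raw$`SNP Name`)
  sample_id <- trimws(raw$`Sample ID`)
  key <- paste(marker_id, sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (marker, sample) row at line ",
         line_no[duplicated(key)][1L])
  }
  first <- !duplicated(marker_id)
  markers <- data.frame(marker_id = marker_id[first],
                        chromosome = chrom[first],
                        position = as.integer(pos[first]),
                        stringsAsFactors = FALSE)
  # a marker must map to a single locus
  locus <- paste(chrom, pos)[match(marker_id, marker_id[first])]
  if (any(locus != paste(chrom, pos))) {
    i <- which(locus != paste(chrom, pos))[1L]
    stop("marker ", marker_id[i], " has conflicting coordinates at line ",
         line_no[i])
  }
  markers <- as_marker_map(markers, n_chromosomes)
  samples <- unique(sample_id)

  shape <- function(values, fill) {
    m <- matrix(fill, nrow = nrow(markers), ncol = length(samples),
                dimnames = list(markers$marker_id, samples))
    m[cbind(match(marker_id, markers$marker_id),
            match(sample_id, samples))] <- values
    m
  }
  intensity_table(markers,
                  lrr = shape(lrr, NA_real_),
                  baf = shape(baf, NA_real_),
                  r_total = shape(r_tot, NA_real_),
                  genotype = shape(gtype, "NC"))
}

#' Write an intensity table as a Final-Report-like TSV
#'
#' Inverse of [read_final_report()]: one row per (marker, sample), markers in
#' map order, numeric values at full precision so a write/read round trip
#' reproduces the table.
#'
#' @param x an `intensity_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_final_report <- function(x, path) {
  stopifnot(inherits(x, "intensity_table"))
  nm <- nrow(x$markers); ns <- length(x$samples)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.10g", v))
  out <- data.frame(
    `SNP Name` = rep(x$markers$marker_id, times = ns),
    `Sample ID` = rep(x$samples, each = nm),
    Chr = rep(x$markers$chromosome, times = ns),
    Position = rep(x$markers$position, times = ns),
    `Log R Ratio` = fmt(as.vector(x$lrr)),
    `B Allele Freq` = fmt(as.vector(x$baf)),
    GType = as.vector(x$genotype),
    R = fmt(as.vector(x$r_total)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample quality control statistics
#'
#' For each sample, the standard deviation of its non-missing LRR values
#' (population SD, dividing by n — a deterministic reporting choice) and the
#' genotype call rate (called genotypes / total markers).
#'
#' @param x an `intensity_table`.
#' @return data.frame with columns `sample_id`, `sd_lrr`, `call_rate`.
#' @export
compute_sample_qc <- function(x) {
  stopifnot(inherits(x, "intensity_table"))
  if (n_markers(x) == 0L || n_samples(x) == 0L) stop("empty intensity table")
  sd_pop <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_real_)
    sqrt(mean((v - mean(v))^2))
  }
  sd_lrr <- apply(x$lrr, 2L, sd_pop)
  if (anyNA(sd_lrr)) {
    stop("sample(s) with no non-missing LRR: ",
         paste(x$samples[is.na(sd_lrr)], collapse = ", "))
  }
  call_rate <- colMeans(x$genotype != "NC")
  data.frame(sample_id = x$samples, sd_lrr = unname(sd_lrr),
             call_rate = unname(call_rate), stringsAsFactors = FALSE)
}

#' Select high-quality samples by LRR noise
#'
#' Retains samples whose LRR standard deviation is strictly below the
#' threshold (the `SD of LRR < 0.30` rule; the boundary value itself is
#' excluded).
#'
#' @param qc data.frame from [compute_sample_qc()].
#' @param sd_threshold strict upper bound on `sd_lrr` (default 0.30).
#' @return character vector of retained sample ids (possibly empty).
#' @export
filter_samples <- function(qc, sd_threshold = 0.30) {
  stopifnot(is.data.frame(qc), nrow(qc) > 0L,
            all(c("sample_id", "sd_lrr") %in% names(qc)))
  qc$sample_id[qc$sd_lrr < sd_threshold]
}

#' Read a sire-steer pedigree file
#'
#' Two-column headerless TSV: `sire_id <tab> steer_id`, one duo per line.
#' Each steer may appear at most once; a self-pair is rejected.
#'
#' @param path path to the pedigree TSV.
#' @return data.frame with columns `sire_id`, `steer_id` (zero rows for an
#'   empty file).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(sire_id = character(), steer_id = character(),
                      stringsAsFactors = FALSE))
  }
  ped <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(ped) < 2L) stop("pedigree file must have two tab-separated columns")
  ped <- data.frame(sire_id = trimws(ped[[1L]]), steer_id = trimws(ped[[2L]]),
                    stringsAsFactors = FALSE)
  if (any(ped$sire_id == ped$steer_id)) {
    stop("pedigree pair with identical sire and steer id: ",
         ped$sire_id[ped$sire_id == ped$steer_id][1L])
  }
  if (anyDuplicated(ped$steer_id)) {
    stop("steer appears in more than one pair: ",
         ped$steer_id[duplicated(ped$steer_id)][1L])
  }
  ped
}

#' Write a pedigree file
#' @param pairs data.frame with columns `sire_id`, `steer_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pairs, path) {
  stopifnot(all(c("sire_id", "steer_id") %in% names(pairs)))
  write.table(pairs[, c("sire_id", "steer_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export intervals as BED
#'
#' Internal coordinates are 1-based positions with interval length given by
#' `end - start`; on export the start is shifted down by one so the file is
#' standard 0-based half-open BED (an internal interval \[101, 200\] becomes
#' the BED line `start=100 end=200`).
#'
#' @param intervals data.frame with columns `chromosome`, `start`, `end` and
#'   optionally `name` (or a column named by `name_col`).
#' @param path output path.
#' @param name_col optional column used for the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  stopifnot(all(c("chromosome", "start", "end") %in% names(intervals)))
  bed <- data.frame(chrom = paste0("chr", intervals$chromosome),
                    start = as.integer(intervals$start) - 1L,
                    end = as.integer(intervals$end),
                    stringsAsFactors = FALSE)
  if (!is.null(name_col)) bed$name <- intervals[[name_col]]
  else if ("name" %in% names(intervals)) bed$name <- intervals$name
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotation intervals from a BED file
#'
#' Converts the 0-based half-open BED records to the package's internal
#' 1-based convention (`start = bed_start + 1`, `end = bed_end`, so that
#' length remains `end - start + 1` positions and a gene abutting a region
#' end does not overlap it).
#'
#' @param path BED file with at least chrom, start, end and a name column.
#' @return data.frame with columns `gene_id`, `chromosome`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(gene_id = character(), chromosome = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  bed <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(bed) < 4L) stop("gene BED needs chrom, start, end, name columns")
  data.frame(
    gene_id = trimws(bed[[4L]]),
    chromosome = as.integer(sub("^chr", "", trimws(bed[[1L]]),
                                ignore.case = TRUE)),
    start = as.integer(bed[[2L]]) + 1L,
    end = as.integer(bed[[3L]]),
    stringsAsFactors = FALSE
  )
}
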