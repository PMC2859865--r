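#' Mean delta-CT of a qPCR replicate set
#'
#' The internal-control CT is subtracted from the target CT per replicate
#' and the three per-replicate differences are averaged. (Averaging the
#' per-replicate differences equals differencing the replicate means for
#' equal replicate counts; the per-replicate form is used for clarity.)
#'
#' @param ct_target,ct_reference numeric vectors of exactly three positive
#'   CT cycles each.
#' @return the mean delta-CT, in cycles.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (length(ct_target) != 3L || length(ct_reference) != 3L) {
    stop("exactly three replicates are required for target and reference")
  }
  if (anyNA(ct_target) || anyNA(ct_reference)) {
    stop("missing CT replicate")
  }
  if (any(ct_target <= 0) || any(ct_reference <= 0)) {
    stop("CT values must be positive")
  }
  mean(ct_target - ct_reference)
}

#' Copy number from delta-CT values by the comparative CT method
#'
#' `ddCT = dCT_sample - dCT_calibrator` against a designated two-copy
#' calibrator sample, and `copy number = 2 * 2^(-ddCT)`; each cycle of delay
#' halves the inferred copy number. The rounded copy is the nearest
#' non-negative integer.
#'
#' @param delta_ct_sample,delta_ct_calibrator mean delta-CT values.
#' @return data.frame: `delta_ct`, `delta_delta_ct`, `copy_number`,
#'   `rounded_copy`.
#' @export
copy_number <- function(delta_ct_sample, delta_ct_calibrator) {
  ddct <- delta_ct_sample - delta_ct_calibrator
  cn <- 2 * 2^(-ddct)
  data.frame(delta_ct = delta_ct_sample, delta_delta_ct = ddct,
             copy_number = cn, rounded_copy = as.integer(floor(cn + 0.5)))
}

#' Estimate copy numbers for a table of qPCR assays
#'
#' Computes each sample's mean delta-CT, normalizes against the calibrator
#' sample (which must be present and is expected to carry two copies), and
#' applies the comparative CT formula.
#'
#' @param assays data.frame with columns `sample_id`, `ct_target_1..3`,
#'   `ct_reference_1..3` (as written by [simulate_qpcr()] or read from an
#'   assay TSV).
#' @param calibrator_sample sample id of the two-copy calibrator.
#' @return data.frame: `sample_id`, `delta_ct`, `delta_delta_ct`,
#'   `copy_number`, `rounded_copy`.
#' @export
estimate_copy_numbers <- function(assays, calibrator_sample) {
  need <- c("sample_id", paste0("ct_target_", 1:3),
            paste0("ct_reference_", 1:3))
  miss <- setdiff(need, names(assays))
  if (length(miss) > 0L) {
    stop("assay table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!calibrator_sample %in% assays$sample_id) {
    stop("calibrator sample ", calibrator_sample, " not in assay table")
  }
  dct <- vapply(seq_len(nrow(assays)), function(i) {
    delta_ct(as.numeric(assays[i, paste0("ct_target_", 1:3)]),
             as.numeric(assays[i, paste0("ct_reference_", 1:3)]))
  }, numeric(1L))
  dct_cal <- dct[match(calibrator_sample, assays$sample_id)]
  out <- copy_number(dct, dct_cal)
  cbind(data.frame(sample_id = assays$sample_id, stringsAsFactors = FALSE),
        out)
}

#' Concordance of qPCR copy estimates with expected copy classes
#'
#' Fraction of samples whose rounded qPCR copy number equals the expected
#' integer copy class (from a genoplot classification or a simulation truth
#' table), over the samples present in both inputs.
#'
#' @param estimates data.frame from [estimate_copy_numbers()].
#' @param expected data.frame with `sample_id` and `expected_copy`, or a
#'   named vector of integer classes.
#' @return fraction concordant in \[0, 1\].
#' @export
concordance_with_expected <- function(estimates, expected) {
  if (!is.data.frame(expected)) {
    expected <- data.frame(sample_id = names(expected),
                           expected_copy = as.integer(expected),
                           stringsAsFactors = FALSE)
  }
  common <- intersect(estimates$sample_id, expected$sample_id)
  if (length(common) == 0L) {
    stop("no samples shared between estimates and expected classes")
  }
  est <- estimates$rounded_copy[match(common, estimates$sample_id)]
  exp_ <- expected$expected_copy[match(common, expected$sample_id)]
  mean(est == exp_)
}

#' Read / write qPCR assay TSV files
#'
#' Assay tables have one row per sample with three target and three
#' internal-control CT replicates.
#'
#' @param path file path.
#' @return `read_qpcr_assays`: the assay data.frame.
#' @export
read_qpcr_assays <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_qpcr_assays
#' @param assays assay data.frame.
#' @export
write_qpcr_assays <- function(assays, path) {
  write.table(assays, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
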