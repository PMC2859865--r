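#' Parameters of the LRR/BAF hidden Markov CNV caller
#'
#' The caller decodes, per sample and chromosome, a hidden copy-state
#' sequence over the four states 0 (null), 1 (hemizygous loss), 2 (diploid),
#' 3 (single gain). Emissions combine a Gaussian LRR term (state means
#' `lrr_means`, shared SD `lrr_sd`) with a BAF mixture: each state's allelic
#' clusters (state 2 at 0, 1/2, 1; state 1 at 0, 1; state 3 at 0, 1/3, 2/3,
#' 1; state 0 uniform) weighted binomially by the population frequency of the
#' B allele (`pfb`), with Gaussian cluster width `baf_sd` and a small uniform
#' outlier mass. Transitions are distance dependent: the probability of
#' leaving the diploid state over a gap of `g` bp is `p0 * exp(-g / d0)`,
#' split evenly over the three CNV states; a CNV state returns to diploid
#' with probability `return_prob` and switches directly to another CNV state
#' with probability `switch_eps` each.
#'
#' @param lrr_means LRR emission means for states 0..3.
#' @param lrr_sd shared LRR emission SD.
#' @param baf_sd BAF cluster SD.
#' @param pfb population frequency of the B allele used for cluster weights
#'   (scalar or per-marker vector; default 0.5).
#' @param outlier_mass uniform BAF outlier mixture weight.
#' @param p0 diploid-exit probability at zero gap.
#' @param d0 exponential decay length of the exit probability, bp.
#' @param return_prob per-step probability a CNV state returns to diploid
#'   (sets the expected event length in markers to ~1/return_prob).
#' @param switch_eps per-step probability of a direct CNV-to-CNV state switch.
#' @param min_markers minimum markers per reported call.
#' @return list of class `caller_params`.
#' @export
caller_params <- function(lrr_means = c(-3.0, -0.66, 0.0, 0.40),
                          lrr_sd = 0.20,
                          baf_sd = 0.05,
                          pfb = 0.5,
                          outlier_mass = 0.01,
                          p0 = 0.01,
                          d0 = 1e5,
                          return_prob = 0.2,
                          switch_eps = 1e-4,
                          min_markers = 3L) {
  stopifnot(length(lrr_means) == 4L, lrr_sd > 0, baf_sd > 0,
            p0 > 0, p0 < 1, d0 > 0, return_prob > 0,
            return_prob + 2 * switch_eps < 1, min_markers >= 1L)
  structure(list(lrr_means = lrr_means, lrr_sd = lrr_sd, baf_sd = baf_sd,
                 pfb = pfb, outlier_mass = outlier_mass, p0 = p0, d0 = d0,
                 return_prob = return_prob, switch_eps = switch_eps,
                 min_markers = as.integer(min_markers)),
            class = "caller_params")
}

# BAF mixture log density for one state; baf and pfb are vectors
baf_loglik <- function(baf, state, pfb, baf_sd, outlier_mass) {
  n <- length(baf)
  if (state == 0L) return(rep(0, n))  # uniform on [0,1]: log density 0
  centres <- switch(as.character(state),
                    "1" = c(0, 1), "2" = c(0, 0.5, 1),
                    "3" = c(0, 1 / 3, 2 / 3, 1))
  k <- length(centres) - 1L
  dens <- rep(0, n)
  for (j in seq_along(centres)) {
    w <- choose(k, j - 1L) * pfb^(j - 1L) * (1 - pfb)^(k - j + 1L)
    dens <- dens + w * dnorm(baf, centres[j], baf_sd)
  }
  log((1 - outlier_mass) * dens + outlier_mass)
}

# per-marker emission log-likelihood matrix (markers x 4 states); missing
# observations contribute nothing
hmm_emission <- function(lrr, baf, params) {
  n <- length(lrr)
  pfb <- rep(params$pfb, length.out = n)
  em <- matrix(0, n, 4L)
  for (s in 0:3) {
    ll <- dnorm(lrr, params$lrr_means[s + 1L], params$lrr_sd, log = TRUE)
    ll[is.na(ll)] <- 0
    bl <- baf_loglik(baf, s, pfb, params$baf_sd, params$outlier_mass)
    bl[is.na(bl)] <- 0
    em[, s + 1L] <- ll + bl
  }
  em
}

# 4x4 log transition matrix for one inter-marker gap
hmm_transition <- function(gap, params) {
  p <- params$p0 * exp(-gap / params$d0)
  q <- params$return_prob; e <- params$switch_eps
  tm <- matrix(e, 4L, 4L)
  tm[3L, ] <- p / 3; tm[3L, 3L] <- 1 - p       # from diploid
  for (s in c(1L, 2L, 4L)) {
    tm[s, 3L] <- q
    tm[s, s] <- 1 - q - 2 * e
  }
  log(tm)
}

# initial state log-probabilities: diploid prior 1 - p0
hmm_init <- function(params) {
  log(c(params$p0 / 3, params$p0 / 3, 1 - params$p0, params$p0 / 3))
}

# Viterbi decoding for one sample on one chromosome; ties resolve to the
# lowest copy state (first index). Returns integer states in 0..3.
viterbi_decode <- function(lrr, baf, positions, params) {
  n <- length(lrr)
  em <- hmm_emission(lrr, baf, params)
  delta <- hmm_init(params) + em[1L, ]
  back <- matrix(0L, n, 4L)
  if (n > 1L) {
    for (i in 2:n) {
      tm <- hmm_transition(positions[i] - positions[i - 1L], params)
      cand <- delta + tm            # rows: from, cols: to
      back[i, ] <- apply(cand, 2L, which.max)  # first max = lowest state
      delta <- cand[cbind(back[i, ], 1:4)] + em[i, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) for (i in n:2) path[i - 1L] <- back[i, path[i]]
  path - 1L
}

#' Call per-sample CNV segments from LRR/BAF signal
#'
#' Runs the four-state Viterbi decoder (see [caller_params()]) over each
#' sample and chromosome and reports maximal runs of a constant non-diploid
#' state spanning at least `min_markers` markers. Call boundaries are the
#' positions of the first and last marker of the run; a call never spans a
#' chromosome boundary.
#'
#' @param table an [intensity_table()] (QC-passing samples).
#' @param map marker map; must equal the table's map and be sorted.
#' @param params a [caller_params()].
#' @param samples optional subset of sample ids to call.
#' @return data.frame of calls: `sample_id`, `chromosome`, `start`, `end`,
#'   `copy_state`, `n_markers`, `mean_lrr`.
#' @export
call_cnvs <- function(table, map = table$markers, params = caller_params(),
                      samples = table$samples) {
  stopifnot(inherits(table, "intensity_table"),
            inherits(params, "caller_params"))
  if (!identical(map$marker_id, table$markers$marker_id)) {
    stop("map does not match the table's marker map")
  }
  if (is.unsorted(order(map$chromosome, map$position))) {
    stop("marker map must be sorted by (chromosome, position)")
  }
  out <- list()
  for (chr in unique(map$chromosome)) {
    rows <- which(map$chromosome == chr)
    pos <- map$position[rows]
    if (is.unsorted(pos)) stop("marker map must be sorted within chromosome")
    for (sm in samples) {
      path <- viterbi_decode(table$lrr[rows, sm], table$baf[rows, sm],
                             pos, params)
      r <- rle(path)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      keep <- r$values != 2L & r$lengths >= params$min_markers
      if (!any(keep)) next
      for (k in which(keep)) {
        i1 <- rows[starts[k]]; i2 <- rows[ends[k]]
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sm, chromosome = chr,
          start = map$position[i1], end = map$position[i2],
          copy_state = r$values[k], n_markers = r$lengths[k],
          mean_lrr = mean(table$lrr[i1:i2, sm], na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_calls <- function() {
  data.frame(sample_id = character(), chromosome = integer(),
             start = integer(), end = integer(), copy_state = integer(),
             n_markers = integer(), mean_lrr = numeric(),
             stringsAsFactors = FALSE)
}

#' Concordance between two CNV call sets
#'
#' The fraction of calls in `a` that overlap (by at least one shared
#' position, same sample, same chromosome) any call in `b`.
#'
#' @param a,b call data.frames as returned by [call_cnvs()].
#' @return a real in \[0, 1\] (`NaN` for an empty `a`).
#' @export
compare_callsets <- function(a, b) {
  if (nrow(a) == 0L) return(NaN)
  hit <- vapply(seq_len(nrow(a)), function(i) {
    any(b$sample_id == a$sample_id[i] & b$chromosome == a$chromosome[i] &
          b$start <= a$end[i] & b$end >= a$start[i])
  }, logical(1L))
  mean(hit)
}

#' Filter CNV calls by marker support and length
#'
#' Retains calls with at least `min_markers` markers and spanning at least
#' `min_length_bp` (length convention `end - start`); order preserving.
#'
#' @param calls call data.frame.
#' @param min_markers,min_length_bp non-negative minima (0 = no filter).
#' @return the filtered call data.frame.
#' @export
filter_calls <- function(calls, min_markers = 0L, min_length_bp = 0L) {
  if (min_markers < 0L || min_length_bp < 0L) {
    stop("filter minima must be non-negative")
  }
  calls[calls$n_markers >= min_markers &
          (calls$end - calls$start) >= min_length_bp, , drop = FALSE]
}

#' Export CNV calls as TSV
#' @param calls call data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
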