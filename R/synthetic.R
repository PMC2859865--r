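#' Simulation configuration for a synthetic SNP-array cohort
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design the package targets: a 29-autosome bovine genome assayed on a
#' 54,001-marker BeadChip with ~51.5 kb mean marker spacing, and a half-sib
#' cohort of 248 steers produced from 17 sires (265 animals). Steers are
#' assigned to sires round-robin, so `n_steers` need not be divisible by
#' `n_sires`.
#'
#' LRR emission means per copy state (0, 1, 2, 3 copies) follow the
#' conventional SNP-array signal model (-3.0, -0.66, 0.0, +0.40 log2 units);
#' total intensity R scales linearly with copy number around `r_base` for the
#' diploid state, so hemizygous samples sit at half intensity and null
#' samples near the baseline.
#'
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @param n_sires,n_steers pedigree size (defaults 17 and 248).
#' @param steers_per_sire optional convenience; when given, overrides
#'   `n_steers` with `n_sires * steers_per_sire`.
#' @param n_chromosomes number of autosomes (default 29).
#' @param chromosome_length_bp modelled chromosome length (default 120 Mb,
#'   on the scale of the larger bovine autosomes, leaving headroom for the
#'   random marker spacing).
#' @param n_markers total markers across the genome (default 54,001).
#' @param mean_spacing_bp mean inter-marker gap; gaps are exponential
#'   (right-skewed, so the median gap falls below the mean, default 51,500).
#' @param allele_freq_range B allele frequencies are drawn uniformly from
#'   this interval (default \[0.05, 0.95\]).
#' @param lrr_means LRR emission means for copy states 0..3.
#' @param lrr_noise_sd,baf_noise_sd Gaussian noise SDs for LRR and BAF.
#' @param r_base diploid mean of total intensity R; `r_noise_sd` its noise;
#'   `r_null_mean` the residual signal of zero-copy samples.
#' @param geno_error_rate probability a called genotype is replaced by a
#'   random other call (baseline genotyping error).
#' @param nc_rate probability a genotype is reported as no-call (`NC`).
#' @param null_genotype what the genotype caller reports for zero-copy
#'   samples: `"NC"` (default) or `"random_hom"`.
#' @param event_specs list of [cnv_event()] specifications to embed.
#' @param qpcr_base_ct,qpcr_ref_ct baseline CT of the target assay on a
#'   2-copy template and of the internal-control gene.
#' @param qpcr_ct_noise_sd per-replicate CT noise SD.
#' @param qpcr_ct_ceiling CT reported for non-amplification (zero copies).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_sires = 17L,
                       n_steers = 248L,
                       steers_per_sire = NULL,
                       n_chromosomes = 29L,
                       chromosome_length_bp = 1.2e8,
                       n_markers = 54001L,
                       mean_spacing_bp = 51500,
                       allele_freq_range = c(0.05, 0.95),
                       lrr_means = c(-3.0, -0.66, 0.0, 0.40),
                       lrr_noise_sd = 0.15,
                       baf_noise_sd = 0.03,
                       r_base = 2.0,
                       r_noise_sd = 0.10,
                       r_null_mean = 0.05,
                       geno_error_rate = 0.001,
                       nc_rate = 0.0043,
                       null_genotype = c("NC", "random_hom"),
                       event_specs = list(),
                       qpcr_base_ct = 25,
                       qpcr_ref_ct = 25,
                       qpcr_ct_noise_sd = 0.1,
                       qpcr_ct_ceiling = 40) {
  if (!is.null(steers_per_sire)) n_steers <- n_sires * steers_per_sire
  null_genotype <- match.arg(null_genotype)
  cfg <- list(seed = as.integer(seed), n_sires = as.integer(n_sires),
              n_steers = as.integer(n_steers),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_bp = chromosome_length_bp,
              n_markers = as.integer(n_markers),
              mean_spacing_bp = mean_spacing_bp,
              allele_freq_range = allele_freq_range,
              lrr_means = lrr_means, lrr_noise_sd = lrr_noise_sd,
              baf_noise_sd = baf_noise_sd, r_base = r_base,
              r_noise_sd = r_noise_sd, r_null_mean = r_null_mean,
              geno_error_rate = geno_error_rate, nc_rate = nc_rate,
              null_genotype = null_genotype, event_specs = event_specs,
              qpcr_base_ct = qpcr_base_ct, qpcr_ref_ct = qpcr_ref_ct,
              qpcr_ct_noise_sd = qpcr_ct_noise_sd,
              qpcr_ct_ceiling = qpcr_ct_ceiling)
  stopifnot(cfg$n_markers >= 1L, cfg$mean_spacing_bp > 0,
            cfg$n_sires >= 1L, cfg$n_steers >= 0L,
            cfg$n_chromosomes >= 1L, length(cfg$lrr_means) == 4L,
            cfg$lrr_noise_sd > 0, cfg$baf_noise_sd > 0, cfg$r_base > 0,
            cfg$geno_error_rate >= 0, cfg$geno_error_rate < 1,
            cfg$nc_rate >= 0, cfg$nc_rate < 1)
  for (ev in cfg$event_specs) {
    if (!inherits(ev, "cnv_event")) stop("event_specs must be cnv_event objects")
    if (ev$chromosome > cfg$n_chromosomes) {
      stop("event chromosome ", ev$chromosome, " outside the simulated genome")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Specify a CNV event to embed in the synthetic cohort
#'
#' A copy-number allele segregating in the population: a deletion allele
#' (`copy_state` 0 or 1; carriers are hemizygous, homozygous carriers null)
#' or a duplication allele (`copy_state` 3). `population_frequency` is the
#' haplotype (allele) frequency. When `inherited = TRUE` the allele follows
#' Mendelian transmission: each sire haplotype carries it with probability
#' `population_frequency`, the steer receives one sire haplotype (probability
#' 1/2 per haplotype, drawn once per event so the deletion stays contiguous)
#' plus an independent population (dam) haplotype. With `inherited = FALSE`
#' carrier haplotypes are drawn independently per animal.
#'
#' @param chromosome autosome index.
#' @param start,end event span in bp (1-based; `end > start`).
#' @param copy_state 0, 1 (deletion allele) or 3 (duplication allele).
#' @param population_frequency allele frequency in (0, 1].
#' @param inherited logical; Mendelian transmission (default `TRUE`).
#' @return a list of class `cnv_event`.
#' @export
cnv_event <- function(chromosome, start, end, copy_state,
                      population_frequency, inherited = TRUE) {
  stopifnot(end > start, copy_state %in% c(0L, 1L, 3L),
            population_frequency > 0, population_frequency <= 1,
            chromosome >= 1L)
  structure(list(chromosome = as.integer(chromosome), start = start,
                 end = end, copy_state = as.integer(copy_state),
                 population_frequency = population_frequency,
                 inherited = isTRUE(inherited)),
            class = "cnv_event")
}

#' Simulate a marker map with exponential inter-marker spacing
#'
#' Markers are distributed as evenly as possible across chromosomes; within a
#' chromosome, gaps are drawn from an exponential distribution with the
#' configured mean (right-skewed, so the empirical median spacing falls below
#' the mean, as on real BeadChips), rounded to at least 1 bp.
#'
#' @param config a [sim_config()].
#' @return a marker map data.frame (`marker_id`, `chromosome`, `position`).
#' @export
simulate_marker_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  per_chr <- rep(config$n_markers %/% config$n_chromosomes,
                 config$n_chromosomes)
  extra <- config$n_markers %% config$n_chromosomes
  if (extra > 0L) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  maps <- vector("list", config$n_chromosomes)
  for (chr in seq_len(config$n_chromosomes)) {
    n <- per_chr[chr]
    if (n == 0L) next
    gaps <- pmax(1, round(rexp(n, rate = 1 / config$mean_spacing_bp)))
    pos <- cumsum(gaps)
    if (pos[n] > config$chromosome_length_bp) {
      stop("chromosome ", chr, " too short (", config$chromosome_length_bp,
           " bp) for ", n, " markers at mean spacing ",
           config$mean_spacing_bp)
    }
    maps[[chr]] <- data.frame(
      marker_id = sprintf("SNP%02d_%05d", chr, seq_len(n)),
      chromosome = chr, position = as.integer(pos),
      stringsAsFactors = FALSE)
  }
  as_marker_map(do.call(rbind, maps), config$n_chromosomes)
}

# markers covered by an event span
event_marker_rows <- function(map, ev) {
  which(map$chromosome == ev$chromosome &
          map$position >= ev$start & map$position <= ev$end)
}

#' Simulate pedigree genotypes with embedded copy-number alleles
#'
#' Sire genotypes are drawn in Hardy-Weinberg proportions from per-marker B
#' allele frequencies; each steer inherits one sire haplotype and one
#' independent population (dam) haplotype. Inside a deletion-carrying
#' haplotype the deleted allele is absent: hemizygous animals are reported as
#' the homozygote of the remaining allele (A/- as `AA`, B/- as `BB`), and
#' zero-copy animals as `NC` (or a random homozygote, per
#' `config$null_genotype`). Deletions on a transmitted sire haplotype thereby
#' create opposite-homozygote parent-child pairs, the Mendelian-inconsistency
#' signature downstream screening exploits.
#'
#' @param config a [sim_config()].
#' @param map marker map from [simulate_marker_map()].
#' @return list with `genotype` (marker x sample character matrix) and
#'   `truth`, a truth table carrying the copy-number matrix (`copy`), the B
#'   allele copy count (`b_count`), per-carrier event intervals (`events`),
#'   per-marker allele frequencies, the pedigree and the map.
#' @export
simulate_pedigree_genotypes <- function(config, map) {
  stopifnot(inherits(config, "sim_config"))
  map <- as_marker_map(map, config$n_chromosomes)
  set.seed(config$seed + 202L)

  sires <- sprintf("SIRE%02d", seq_len(config$n_sires))
  steers <- sprintf("STEER%03d", seq_len(config$n_steers))
  samples <- c(sires, steers)
  sire_of <- rep(seq_len(config$n_sires), length.out = config$n_steers)
  pedigree <- data.frame(sire_id = sires[sire_of], steer_id = steers,
                         stringsAsFactors = FALSE)

  M <- nrow(map); nsi <- config$n_sires; nst <- config$n_steers
  p <- runif(M, config$allele_freq_range[1L], config$allele_freq_range[2L])

  # haplotype B-allele indicators
  sire_h1 <- matrix(rbinom(M * nsi, 1L, p), nrow = M)
  sire_h2 <- matrix(rbinom(M * nsi, 1L, p), nrow = M)
  trans <- matrix(sample(c(1L, 2L), M * nst, replace = TRUE), nrow = M)
  dam <- matrix(rbinom(M * nst, 1L, p), nrow = M)

  # copy-number allele carrier indicators per haplotype
  zero_si <- matrix(0L, M, nsi); zero_st <- matrix(0L, M, nst)
  sire_d1 <- zero_si; sire_d2 <- zero_si
  steer_dp <- zero_st; steer_dm <- zero_st  # paternal / maternal (dam)
  gain <- rep(FALSE, M)
  covered <- rep(FALSE, M)
  events_acc <- list()

  for (ev in config$event_specs) {
    rows <- event_marker_rows(map, ev)
    if (length(rows) == 0L) {
      stop("event ", ev$chromosome, ":", ev$start, "-", ev$end,
           " spans no markers")
    }
    if (any(covered[rows])) stop("event specs may not overlap on markers")
    covered[rows] <- TRUE
    f <- ev$population_frequency
    is_gain <- ev$copy_state == 3L
    gain[rows] <- is_gain

    d1 <- rbinom(nsi, 1L, f); d2 <- rbinom(nsi, 1L, f)
    if (is_gain) d2[d1 == 1L] <- 0L  # one extra copy at most (state ceiling 3)
    sire_d1[rows, ] <- rep(d1, each = length(rows))
    sire_d2[rows, ] <- rep(d2, each = length(rows))

    if (ev$inherited) {
      te <- sample(c(1L, 2L), nst, replace = TRUE)
      trans[rows, ] <- rep(te, each = length(rows))
      dp <- ifelse(te == 1L, d1[sire_of], d2[sire_of])
    } else {
      dp <- rbinom(nst, 1L, f)
    }
    dm <- rbinom(nst, 1L, f)
    if (is_gain) dm[dp == 1L] <- 0L
    steer_dp[rows, ] <- rep(dp, each = length(rows))
    steer_dm[rows, ] <- rep(dm, each = length(rows))

    span <- range(map$position[rows])
    carrier <- c(d1 + d2, dp + dm) > 0L
    if (any(carrier)) {
      events_acc[[length(events_acc) + 1L]] <- data.frame(
        sample_id = samples[carrier], chromosome = ev$chromosome,
        start = ev$start, end = ev$end,
        marker_start = span[1L], marker_end = span[2L],
        n_markers = length(rows),
        copy_state = if (is_gain) 3L else
          ifelse((c(d1 + d2, dp + dm)[carrier]) >= 2L, 0L, 1L),
        stringsAsFactors = FALSE)
    }
  }

  # transmitted sire allele per steer marker (steer_dp was already filled per
  # event: from the transmitted haplotype when inherited, independently when not)
  pat <- matrix(0L, M, nst)
  for (j in seq_len(nst)) {
    s <- sire_of[j]
    pat[, j] <- ifelse(trans[, j] == 1L, sire_h1[, s], sire_h2[, s])
  }

  sign_mult <- ifelse(gain, 1L, -1L)  # gains add copies, deletions remove
  copy_s <- 2L + sign_mult * (sire_d1 + sire_d2)
  copy_t <- 2L + sign_mult * (steer_dp + steer_dm)
  # B allele copies: deleted haplotypes contribute nothing, duplicated twice.
  # sign_mult (length M) recycles down the columns of the carrier matrices.
  hap_w <- function(d) 1L + d * sign_mult
  b_s <- sire_h1 * hap_w(sire_d1) + sire_h2 * hap_w(sire_d2)
  b_t <- pat * hap_w(steer_dp) + dam * hap_w(steer_dm)

  copy <- cbind(copy_s, copy_t)
  bcnt <- cbind(b_s, b_t)
  dimnames(copy) <- dimnames(bcnt) <- list(map$marker_id, samples)

  geno <- genotype_from_copy(copy, bcnt, config)

  events <- if (length(events_acc) > 0L) do.call(rbind, events_acc) else
    data.frame(sample_id = character(), chromosome = integer(),
               start = numeric(), end = numeric(), marker_start = integer(),
               marker_end = integer(), n_markers = integer(),
               copy_state = integer(), stringsAsFactors = FALSE)

  truth <- list(copy = copy, b_count = bcnt, events = events,
                allele_freq = setNames(p, map$marker_id),
                pedigree = pedigree, map = map)
  list(genotype = geno, truth = truth)
}

# reported genotype given true copy number and B allele copies, with
# baseline no-call and miscall rates applied
genotype_from_copy <- function(copy, bcnt, config) {
  geno <- matrix("NC", nrow(copy), ncol(copy), dimnames = dimnames(copy))
  geno[copy == 2L & bcnt == 0L] <- "AA"
  geno[copy == 2L & bcnt == 1L] <- "AB"
  geno[copy == 2L & bcnt == 2L] <- "BB"
  # hemizygous: homozygote of the remaining allele
  geno[copy == 1L & bcnt == 0L] <- "AA"
  geno[copy == 1L & bcnt == 1L] <- "BB"
  # duplication: any mixed allele count is called heterozygous
  geno[copy == 3L] <- c("AA", "AB", "AB", "BB")[bcnt[copy == 3L] + 1L]
  if (config$null_genotype == "random_hom") {
    nul <- copy == 0L
    geno[nul] <- sample(c("AA", "BB"), sum(nul), replace = TRUE)
  }
  called <- geno != "NC"
  err <- called & matrix(runif(length(geno)) < config$geno_error_rate,
                         nrow(geno))
  if (any(err)) {
    swap <- function(g) vapply(g, function(v)
      sample(setdiff(c("AA", "AB", "BB"), v), 1L), character(1L))
    geno[err] <- swap(geno[err])
  }
  nc <- matrix(runif(length(geno)) < config$nc_rate, nrow(geno))
  geno[nc] <- "NC"
  geno
}

#' Simulate LRR/BAF/R intensities from a copy-number truth table
#'
#' LRR is Gaussian around the configured per-state mean; BAF clusters at the
#' true allelic ratio (0/1 for hemizygous samples - the heterozygote cluster
#' disappears under deletion - 0, 1/3, 2/3, 1 under duplication, uniform
#' noise at zero copies); total intensity R scales with copy number so
#' hemizygous samples sit at reduced R.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [simulate_pedigree_genotypes()].
#' @param genotypes reported genotype matrix from the same call.
#' @return an [intensity_table()].
#' @export
simulate_intensities <- function(config, truth, genotypes) {
  stopifnot(inherits(config, "sim_config"))
  copy <- truth$copy
  if (!all(copy %in% 0:3)) stop("unknown copy state in truth table")
  set.seed(config$seed + 303L)
  M <- nrow(copy); S <- ncol(copy)
  mu <- matrix(config$lrr_means[copy + 1L], M, S)
  lrr <- mu + matrix(rnorm(M * S, sd = config$lrr_noise_sd), M, S)
  centre <- ifelse(copy == 0L, NA_real_, truth$b_count / pmax(copy, 1L))
  baf <- centre + matrix(rnorm(M * S, sd = config$baf_noise_sd), M, S)
  baf[copy == 0L] <- runif(sum(copy == 0L))
  baf <- pmin(pmax(baf, 0), 1)
  mu_r <- ifelse(copy == 0L, config$r_null_mean, config$r_base * copy / 2)
  r <- pmax(mu_r + matrix(rnorm(M * S, sd = config$r_noise_sd), M, S), 0.01)
  dimnames(lrr) <- dimnames(baf) <- dimnames(r) <- dimnames(copy)
  intensity_table(truth$map, lrr, baf, r, genotypes)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper chaining [simulate_marker_map()],
#' [simulate_pedigree_genotypes()] and [simulate_intensities()].
#'
#' @param config a [sim_config()].
#' @return list with `table` (an `intensity_table`), `map`, `pedigree`,
#'   `truth` and `config`.
#' @export
simulate_cohort <- function(config) {
  map <- simulate_marker_map(config)
  g <- simulate_pedigree_genotypes(config, map)
  table <- simulate_intensities(config, g$truth, g$genotype)
  list(table = table, map = map, pedigree = g$truth$pedigree,
       truth = g$truth, config = config)
}

#' Simulate TaqMan qPCR CT replicates at one marker
#'
#' The target assay amplifies within the tested locus and is co-amplified
#' with an internal-control gene measured on the same plate. Per replicate,
#' `CT_target = base_ct - log2(copy/2) + noise` and
#' `CT_reference = ref_ct + noise`; three replicates each. Zero-copy samples
#' do not amplify and are reported at the CT ceiling.
#'
#' @param truth truth table from [simulate_pedigree_genotypes()].
#' @param sample_ids samples to assay.
#' @param marker_id marker whose locus the assay targets.
#' @param config a [sim_config()].
#' @return data.frame with columns `sample_id`, `marker_id`,
#'   `ct_target_1..3`, `ct_reference_1..3`, `true_copy`.
#' @export
simulate_qpcr <- function(truth, sample_ids, marker_id, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!marker_id %in% rownames(truth$copy)) {
    stop("unknown marker: ", marker_id)
  }
  i <- match(sample_ids, colnames(truth$copy))
  if (anyNA(i)) stop("unknown sample id(s): ",
                     paste(sample_ids[is.na(i)], collapse = ", "))
  set.seed((config$seed + 404L + sum(utf8ToInt(marker_id))) %% .Machine$integer.max)
  copy <- truth$copy[marker_id, i]
  n <- length(i)
  tgt <- matrix(config$qpcr_base_ct - log2(pmax(copy, 1L) / 2), n, 3L) +
    matrix(rnorm(3L * n, sd = config$qpcr_ct_noise_sd), n, 3L)
  tgt[copy == 0L, ] <- config$qpcr_ct_ceiling
  ref <- matrix(config$qpcr_ref_ct, n, 3L) +
    matrix(rnorm(3L * n, sd = config$qpcr_ct_noise_sd), n, 3L)
  out <- data.frame(sample_id = sample_ids, marker_id = marker_id,
                    stringsAsFactors = FALSE)
  out[paste0("ct_target_", 1:3)] <- as.data.frame(tgt)
  out[paste0("ct_reference_", 1:3)] <- as.data.frame(ref)
  out$true_copy <- as.integer(copy)
  out
}

#' Write the copy-number truth table as TSV
#' @param truth truth table from [simulate_pedigree_genotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  long <- data.frame(marker_id = rep(rownames(truth$copy),
                                     ncol(truth$copy)),
                     sample_id = rep(colnames(truth$copy),
                                     each = nrow(truth$copy)),
                     copy = as.vector(truth$copy),
                     stringsAsFactors = FALSE)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of embedded events recovered by a call set
#'
#' A per-carrier truth event counts as recovered when some call of the same
#' sample on the same chromosome overlaps the event's marker span and agrees
#' in gain/loss direction.
#'
#' @param calls call data.frame from [call_cnvs()].
#' @param truth_events the `events` component of a truth table.
#' @param min_markers only score events spanning at least this many markers.
#' @return recovered fraction (`NA` when no event qualifies).
#' @export
event_recovery <- function(calls, truth_events, min_markers = 1L) {
  ev <- truth_events[truth_events$n_markers >= min_markers, , drop = FALSE]
  if (nrow(ev) == 0L) return(NA_real_)
  hit <- vapply(seq_len(nrow(ev)), function(i) {
    any(calls$sample_id == ev$sample_id[i] &
          calls$chromosome == ev$chromosome[i] &
          calls$start <= ev$marker_end[i] &
          calls$end >= ev$marker_start[i] &
          sign(calls$copy_state - 2L) == sign(ev$copy_state[i] - 2L))
  }, logical(1L))
  mean(hit)
}
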