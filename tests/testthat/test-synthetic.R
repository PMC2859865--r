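test_that("generator output is reproducible for a fixed seed", {
  cfg <- sim_config(seed = 99L, n_sires = 4L, n_steers = 8L,
                    n_chromosomes = 2L, chromosome_length_bp = 8e6,
                    n_markers = 60L,
                    event_specs = list(cnv_event(1L, 1e5, 2e6, 1L, 0.3)))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$map, b$map)
  expect_identical(a$table$lrr, b$table$lrr)
  expect_identical(a$table$baf, b$table$baf)
  expect_identical(a$table$genotype, b$table$genotype)
  expect_identical(a$truth$copy, b$truth$copy)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("marker spacing is right-skewed with the configured mean", {
  cfg <- sim_config(seed = 3L, n_chromosomes = 1L, n_markers = 1001L,
                    chromosome_length_bp = 2e8)
  map <- simulate_marker_map(cfg)
  gaps <- diff(map$position)
  expect_equal(length(gaps), 1000L)
  expect_lt(abs(mean(gaps) - 51500) / 51500, 0.10)
  # exponential gaps: empirical median below the mean
  expect_lt(median(gaps), mean(gaps))
  # too-short chromosome is refused
  short <- sim_config(seed = 3L, n_chromosomes = 1L, n_markers = 1001L,
                      chromosome_length_bp = 1e6)
  expect_error(simulate_marker_map(short), "too short")
})

test_that("event specs are validated against the map", {
  cfg <- sim_config(seed = 5L, n_chromosomes = 1L, n_markers = 20L,
                    chromosome_length_bp = 5e6,
                    event_specs = list(cnv_event(1L, 1L, 10L, 1L, 0.5)))
  map <- simulate_marker_map(cfg)
  # the 10 bp event covers no marker
  expect_error(simulate_pedigree_genotypes(cfg, map), "spans no markers")
  expect_error(cnv_event(1L, 100L, 50L, 1L, 0.5))   # end <= start
  expect_error(cnv_event(1L, 1L, 10L, 2L, 0.5))     # diploid is not an event
})

test_that("hemizygous genotypes collapse to the remaining-allele homozygote", {
  copy <- matrix(c(2L, 2L, 2L, 1L, 1L, 0L, 3L, 3L),
                 nrow = 8, dimnames = list(paste0("m", 1:8), "s"))
  bcnt <- matrix(c(0L, 1L, 2L, 0L, 1L, 0L, 1L, 3L), nrow = 8,
                 dimnames = dimnames(copy))
  cfg <- sim_config(seed = 1L, geno_error_rate = 0, nc_rate = 0)
  set.seed(1)
  g <- bovicnv:::genotype_from_copy(copy, bcnt, cfg)
  expect_identical(as.vector(g),
                   c("AA", "AB", "BB", "AA", "BB", "NC", "AB", "BB"))
  cfg2 <- sim_config(seed = 1L, geno_error_rate = 0, nc_rate = 0,
                     null_genotype = "random_hom")
  set.seed(1)
  g2 <- bovicnv:::genotype_from_copy(copy, bcnt, cfg2)
  expect_true(g2[6L] %in% c("AA", "BB"))
})

test_that("event-free error-free data shows no Mendelian errors", {
  cfg <- sim_config(seed = 21L, n_sires = 10L, n_steers = 30L,
                    n_chromosomes = 1L, chromosome_length_bp = 6e6,
                    n_markers = 80L, geno_error_rate = 0, nc_rate = 0)
  coh <- simulate_cohort(cfg)
  st <- pc_error_frequencies(coh$table, coh$pedigree)
  expect_true(all(st$n_errors == 0L))
  expect_true(all(st$pc_error_freq == 0))
})

test_that("deletion-induced P-C error rates match the enumeration oracle", {
  duo <- duo_cohort()
  st <- pc_error_frequencies(duo$table, duo$pedigree)
  for (ev in duo$config$event_specs) {
    rows <- which(duo$map$position >= ev$start & duo$map$position <= ev$end)
    for (r in rows) {
      mk <- duo$map$marker_id[r]
      p <- unname(duo$truth$allele_freq[mk])
      oracle <- enum_pc_error(ev$population_frequency, p)
      s <- st[st$marker_id == mk, ]
      expected <- s$n_pairs_informative * oracle$p_err_informative
      se <- sqrt(s$n_pairs_informative * oracle$p_err_informative *
                   (1 - oracle$p_err_informative))
      expect_lte(abs(s$n_errors - expected), 3 * se + 1e-9)
    }
  }
  # outside the events nothing is flagged (error-free configuration)
  in_event <- rep(FALSE, nrow(duo$map))
  for (ev in duo$config$event_specs) {
    in_event <- in_event | (duo$map$position >= ev$start &
                              duo$map$position <= ev$end)
  }
  expect_true(all(st$pc_error_freq[!in_event] == 0))
})

test_that("opposite-homozygote duos arise inside transmitted deletions", {
  duo <- duo_cohort()
  ev <- duo$config$event_specs[[2L]]  # 35% deletion
  rows <- which(duo$map$position >= ev$start & duo$map$position <= ev$end)
  mk <- duo$map$marker_id[rows[1L]]
  gs <- duo$table$genotype[mk, duo$pedigree$sire_id]
  gt <- duo$table$genotype[mk, duo$pedigree$steer_id]
  inf <- gs != "NC" & gt != "NC"
  expect_gt(sum(mendel_error(gs[inf], gt[inf])), 0L)
})

test_that("intensity emissions follow the copy-state signal model", {
  coh <- cnv_cohort()
  cfg <- coh$config
  copy <- coh$truth$copy
  # mean LRR over hemizygous entries within 3 SE of the configured mean
  hemi <- copy == 1L
  n1 <- sum(hemi)
  expect_gt(n1, 50L)
  se <- cfg$lrr_noise_sd / sqrt(n1)
  expect_lt(abs(mean(coh$table$lrr[hemi]) - cfg$lrr_means[2L]), 3 * se)
  # heterozygote BAF cluster present at diploid entries, absent under
  # hemizygous deletion
  baf1 <- coh$table$baf[hemi]
  expect_equal(sum(baf1 > 0.35 & baf1 < 0.65), 0L)
  dip_ab <- copy == 2L & coh$truth$b_count == 1L
  expect_gt(mean(coh$table$baf[dip_ab] > 0.35 & coh$table$baf[dip_ab] < 0.65),
            0.99)
  # duplicated samples show intermediate clusters at 1/3 and 2/3
  dup_ab <- copy == 3L & coh$truth$b_count %in% c(1L, 2L)
  expect_gt(mean(abs(coh$table$baf[dup_ab] - 1 / 3) < 0.12 |
                   abs(coh$table$baf[dup_ab] - 2 / 3) < 0.12), 0.99)
  # total intensity drops to half for hemizygous, near zero for null
  expect_lt(abs(mean(coh$table$r_total[hemi]) - cfg$r_base / 2), 0.05)
})

test_that("every embedded event is conserved in the truth table", {
  coh <- cnv_cohort()
  ev <- coh$truth$events
  expect_true(all(ev$n_markers >= 1L))
  # each spec'd event contributed carriers, and carrier copy states are
  # consistent with the copy matrix
  for (spec in coh$config$event_specs) {
    sub <- ev[ev$chromosome == spec$chromosome & ev$start == spec$start, ]
    expect_gt(nrow(sub), 0L)
    for (i in seq_len(nrow(sub))) {
      mk <- coh$map$marker_id[coh$map$chromosome == sub$chromosome[i] &
                                coh$map$position >= sub$marker_start[i] &
                                coh$map$position <= sub$marker_end[i]]
      states <- coh$truth$copy[mk, sub$sample_id[i]]
      expect_true(all(states == sub$copy_state[i]))
    }
  }
})

test_that("qPCR simulation encodes copy number in CT at the expected scale", {
  duo <- duo_cohort()
  cfg0 <- duo$config
  ev <- cfg0$event_specs[[1L]]
  mk <- duo$map$marker_id[duo$map$position >= ev$start][1L]
  # noise-free: recovered copy number is exact
  cfg <- duo$config; cfg$qpcr_ct_noise_sd <- 1e-12
  ids <- colnames(duo$truth$copy)[1:40]
  assays <- simulate_qpcr(duo$truth, ids, mk, cfg)
  cal <- assays$sample_id[assays$true_copy == 2L][1L]
  est <- estimate_copy_numbers(assays, cal)
  expect_equal(est$copy_number[assays$true_copy > 0L],
               assays$true_copy[assays$true_copy > 0L], tolerance = 1e-6)
  expect_equal(est$rounded_copy, assays$true_copy)
  # a hemizygous sample lags the 2-copy calibrator by one cycle
  hemi <- which(assays$true_copy == 1L)[1L]
  expect_equal(est$delta_delta_ct[hemi], 1, tolerance = 1e-6)
  # three replicates each, ceiling CT for null samples
  expect_true(all(grepl("^ct_", names(assays)[3:8])))
  nulls <- assays$true_copy == 0L
  if (any(nulls)) {
    expect_true(all(assays[nulls, paste0("ct_target_", 1:3)] ==
                      cfg$qpcr_ct_ceiling))
  }
})
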