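# Fixtures built in code at test time.

# Tiny deterministic 5-marker x 3-sample intensity table.
small_table <- function() {
  markers <- data.frame(
    marker_id = paste0("M", 1:5),
    chromosome = c(1L, 1L, 1L, 2L, 2L),
    position = c(100L, 200L, 300L, 150L, 400L))
  samples <- c("S1", "S2", "S3")
  dn <- list(markers$marker_id, samples)
  lrr <- matrix(c(0.01, -0.02, 0.03, 0.00, -0.01,
                  -0.30, 0.30, -0.30, 0.30, -0.30,
                  0.10, NA, 0.05, -0.05, 0.02),
                nrow = 5, dimnames = dn)
  baf <- matrix(c(0.00, 0.50, 1.00, 0.49, 0.02,
                  0.98, 0.51, 0.01, 0.97, 0.50,
                  0.00, 1.00, 0.52, NA, 0.03),
                nrow = 5, dimnames = dn)
  r <- matrix(c(2.0, 1.9, 2.1, 2.0, 2.2,
                1.0, 2.0, 2.1, 1.8, 2.0,
                0.05, 2.0, 1.9, NA, 2.1),
              nrow = 5, dimnames = dn)
  geno <- matrix(c("AA", "AB", "BB", "AB", "AA",
                   "BB", "AB", "AA", "BB", "AB",
                   "AA", "BB", "AB", "NC", "AA"),
                 nrow = 5, dimnames = dn)
  intensity_table(markers, lrr, baf, r, geno)
}

# Call-set row constructor.
make_call <- function(sample_id, chromosome, start, end, copy_state,
                      n_markers = 5L, mean_lrr = NA_real_) {
  data.frame(sample_id = sample_id, chromosome = chromosome,
             start = start, end = end, copy_state = copy_state,
             n_markers = n_markers, mean_lrr = mean_lrr,
             stringsAsFactors = FALSE)
}

# One shared synthetic cohort with embedded events, reused by the caller,
# deletion-screen and acceptance tests (built once per session).
.fixtures <- new.env(parent = emptyenv())

cnv_cohort <- function() {
  if (!is.null(.fixtures$coh)) return(.fixtures$coh)
  base <- sim_config(seed = 42L, n_sires = 20L, n_steers = 80L,
                     n_chromosomes = 2L, chromosome_length_bp = 1.5e7,
                     n_markers = 400L, geno_error_rate = 0.001,
                     nc_rate = 0.0043)
  map <- simulate_marker_map(base)
  p1 <- map$position[map$chromosome == 1L]
  p2 <- map$position[map$chromosome == 2L]
  events <- list(
    cnv_event(1L, p1[40], p1[46], 1L, 0.20),   # 7-marker deletion
    cnv_event(1L, p1[120], p1[126], 1L, 0.10), # 7-marker rarer deletion
    cnv_event(2L, p2[60], p2[66], 3L, 0.20),   # 7-marker duplication
    cnv_event(2L, p2[150], p2[155], 1L, 0.20)) # 6-marker deletion
  cfg <- sim_config(seed = 42L, n_sires = 20L, n_steers = 80L,
                    n_chromosomes = 2L, chromosome_length_bp = 1.5e7,
                    n_markers = 400L, geno_error_rate = 0.001,
                    nc_rate = 0.0043, event_specs = events)
  coh <- simulate_cohort(cfg)
  coh$calls <- call_cnvs(coh$table)
  .fixtures$coh <- coh
  coh
}

# Cohort of unrelated duos (one steer per sire) for Mendelian-rate checks
# where binomial independence across pairs is needed.
duo_cohort <- function() {
  if (!is.null(.fixtures$duo)) return(.fixtures$duo)
  base <- sim_config(seed = 7L, n_sires = 200L, n_steers = 200L,
                     n_chromosomes = 1L, chromosome_length_bp = 6e6,
                     n_markers = 80L, geno_error_rate = 0,
                     nc_rate = 0)
  map <- simulate_marker_map(base)
  pos <- map$position
  events <- list(cnv_event(1L, pos[20], pos[22], 1L, 0.20),
                 cnv_event(1L, pos[50], pos[51], 1L, 0.35))
  cfg <- sim_config(seed = 7L, n_sires = 200L, n_steers = 200L,
                    n_chromosomes = 1L, chromosome_length_bp = 6e6,
                    n_markers = 80L, geno_error_rate = 0,
                    nc_rate = 0, event_specs = events)
  g <- simulate_pedigree_genotypes(cfg, map)
  tab <- simulate_intensities(cfg, g$truth, g$genotype)
  .fixtures$duo <- list(table = tab, map = map,
                        pedigree = g$truth$pedigree, truth = g$truth,
                        config = cfg)
  .fixtures$duo
}
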