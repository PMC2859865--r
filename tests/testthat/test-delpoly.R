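test_that("only opposite homozygotes are Mendelian errors for a duo", {
  expect_true(mendel_error("BB", "AA"))
  expect_true(mendel_error("AA", "BB"))
  expect_false(mendel_error("AA", "AA"))
  expect_false(mendel_error("AA", "AB"))
  # a heterozygous parent is compatible with every offspring genotype
  expect_false(any(mendel_error(rep("AB", 3), c("AA", "AB", "BB"))))
  expect_error(mendel_error("NC", "AA"), "pre-filter")
})

test_that("per-marker error frequencies count errors over informative duos", {
  # 156 duos at one marker: 9 opposite-homozygote errors
  n <- 156L
  markers <- data.frame(marker_id = c("mA", "mB"), chromosome = 1L,
                        position = c(100L, 200L))
  sires <- sprintf("sire%03d", 1:n); steers <- sprintf("steer%03d", 1:n)
  geno <- matrix("AB", nrow = 2L, ncol = 2L * n,
                 dimnames = list(markers$marker_id, c(sires, steers)))
  geno["mA", sires] <- "BB"
  geno["mA", steers] <- c(rep("AA", 9L), rep("BB", n - 9L))
  geno["mB", ] <- "NC"
  zeros <- matrix(0, 2L, 2L * n, dimnames = dimnames(geno))
  tab <- intensity_table(markers, zeros, zeros + 0.5, zeros + 2, geno)
  pairs <- data.frame(sire_id = sires, steer_id = steers)
  st <- pc_error_frequencies(tab, pairs)
  a <- st[st$marker_id == "mA", ]
  expect_equal(a$n_pairs_informative, 156L)
  expect_equal(a$n_errors, 9L)
  expect_equal(a$pc_error_freq, 9 / 156)
  # all-NC marker: missing frequency
  b <- st[st$marker_id == "mB", ]
  expect_equal(b$n_pairs_informative, 0L)
  expect_true(is.na(b$pc_error_freq))
  # candidate selection: 9/156 = 5.8% passes the 3% screen
  expect_identical(select_candidates(st), "mA")
  # duo-level concordance reflects the 9 errors
  pc <- pair_concordance(tab, pairs)
  expect_equal(sum(pc$n_errors), 9L)
  expect_equal(pc$concordance[1L], 0)  # first 9 duos: 1 informative, 1 error
})

test_that("candidate threshold is strict by default, inclusive on request", {
  st <- data.frame(marker_id = c("a", "b", "c", "d"),
                   pc_error_freq = c(0.058, 0.03, 0.029, NA))
  expect_identical(select_candidates(st), "a")
  expect_identical(select_candidates(st, strict = FALSE), c("a", "b"))
  expect_identical(select_candidates(st[0, ]), character())
})

test_that("six-genotype classifier reproduces simulation truth", {
  coh <- cnv_cohort()
  ev <- coh$config$event_specs[[1L]]  # 20% deletion
  mks <- coh$map$marker_id[coh$map$chromosome == ev$chromosome &
                             coh$map$position >= ev$start &
                             coh$map$position <= ev$end]
  agree <- vapply(mks, function(mk) {
    cl <- classify_six_genotypes(coh$table, mk)
    expect_true(cl$cluster_evidence)
    copy <- coh$truth$copy[mk, ]
    b <- coh$truth$b_count[mk, ]
    want <- ifelse(copy == 0L, "-/-",
            ifelse(copy == 1L, ifelse(b == 0L, "A/-", "B/-"),
                   c("AA", "AB", "BB")[b + 1L]))
    mean(cl$calls == want, na.rm = TRUE)
  }, numeric(1L))
  expect_true(all(agree >= 0.95))
  # null-copy samples land in the bottom cluster
  mk <- mks[1L]
  nulls <- names(which(coh$truth$copy[mk, ] == 0L))
  if (length(nulls) > 0L) {
    cl <- classify_six_genotypes(coh$table, mk)
    expect_true(all(cl$calls[nulls] == "-/-"))
  }
})

test_that("an all-diploid marker shows no hemizygous cluster evidence", {
  coh <- cnv_cohort()
  clean <- coh$map$marker_id[coh$map$chromosome == 1L][1L]
  cl <- classify_six_genotypes(coh$table, clean)
  expect_false(cl$cluster_evidence)
  expect_true(all(cl$calls %in% c("AA", "AB", "BB"), na.rm = TRUE))
  # too few usable samples: missing classification
  few <- subset_table(coh$table, samples = coh$table$samples[1:5])
  cl2 <- classify_six_genotypes(few, clean)
  expect_true(is.na(cl2$cluster_evidence))
  expect_true(all(is.na(cl2$calls)))
})

test_that("pairwise scan flags markers at the log2 ratio threshold", {
  markers <- data.frame(marker_id = paste0("m", 1:4), chromosome = 1L,
                        position = c(10L, 20L, 30L, 40L))
  dn <- list(markers$marker_id, c("tgt", "ref"))
  r <- matrix(c(1.0, 2.0, 4.0, NA,
                3.2, 2.0, 2.0, 2.0), ncol = 2L, dimnames = dn)
  zero <- matrix(0, 4L, 2L, dimnames = dn)
  tab <- intensity_table(markers, zero, zero + 0.5, r,
                         matrix("AA", 4L, 2L, dimnames = dn))
  hits <- pairwise_scan(tab, "tgt", "ref")
  # log2(1.0/3.2) = -1.678 -> hit; equal R -> 0; log2(4/2) = 1 -> below 1.5
  expect_identical(hits$marker_id, "m1")
  expect_equal(hits$log2_ratio, log2(1 / 3.2), tolerance = 1e-9)
  expect_identical(hits$direction, "loss")
  # exactly +/-1.5 is inside the inspection range
  r2 <- r; r2["m2", "tgt"] <- 2 * 2^1.5
  tab2 <- intensity_table(markers, zero, zero + 0.5, r2,
                          matrix("AA", 4L, 2L, dimnames = dn))
  h2 <- pairwise_scan(tab2, "tgt", "ref")
  expect_true("m2" %in% h2$marker_id)
  expect_identical(h2$direction[h2$marker_id == "m2"], "gain")
  expect_error(pairwise_scan(tab, "tgt", "tgt"), "must differ")
})

test_that("pairwise scan is symmetric under swapping target and reference", {
  coh <- cnv_cohort()
  s <- coh$table$samples[1:2]
  fwd <- pairwise_scan(coh$table, s[1L], s[2L], threshold = 0.8)
  rev <- pairwise_scan(coh$table, s[2L], s[1L], threshold = 0.8)
  expect_identical(fwd$marker_id, rev$marker_id)
  expect_equal(fwd$log2_ratio, -rev$log2_ratio, tolerance = 1e-12)
})

test_that("null-copy carriers drive pairwise deletion discovery", {
  coh <- cnv_cohort()
  qc <- compute_sample_qc(coh$table)
  ref <- choose_reference_sample(qc)
  expect_equal(qc$sd_lrr[qc$sample_id == ref], min(qc$sd_lrr))
  mks <- pairwise_deletion_markers(coh$table, coh$table$samples, ref)
  ev <- coh$config$event_specs[[1L]]
  in_ev <- coh$map$marker_id[coh$map$chromosome == ev$chromosome &
                               coh$map$position >= ev$start &
                               coh$map$position <= ev$end]
  # the 20% deletion has homozygous (null) carriers at ~4%: its markers are hit
  expect_true(any(in_ev %in% mks))
  has_null <- apply(coh$truth$copy[mks, , drop = FALSE] == 0L, 1L, any)
  expect_true(all(has_null))
})

test_that("catalogue merge obeys inclusion-exclusion with provenance flags", {
  a <- sprintf("h%03d", 1:351)
  b <- c(sprintf("h%03d", 1:95), sprintf("p%03d", 1:97))
  merged <- merge_methods(a, b)
  expect_equal(nrow(merged), 448L)
  expect_equal(sum(merged$both_methods), 95L)
  expect_identical(sort(unique(merged$methods[merged$both_methods])),
                   "heritability,pairwise")
  # disjoint inputs add, identical inputs collapse
  expect_equal(nrow(merge_methods(c("x", "y"), c("z"))), 3L)
  m_eq <- merge_methods(c("x", "y"), c("y", "x"))
  expect_equal(nrow(m_eq), 2L)
  expect_true(all(m_eq$both_methods))
  # randomized inclusion-exclusion identity
  set.seed(5)
  for (case in 1:15) {
    univ <- sprintf("mk%04d", 1:400)
    aa <- sample(univ, sample(0:300, 1L))
    bb <- sample(univ, sample(0:300, 1L))
    m <- merge_methods(aa, bb)
    expect_equal(nrow(m), length(aa) + length(bb) -
                   length(intersect(aa, bb)))
    expect_equal(sum(m$both_methods), length(intersect(aa, bb)))
  }
})

test_that("HWE chi-square and missing-rate flags behave as closed forms", {
  h <- marker_hwe_chi2(25L, 50L, 25L)
  expect_equal(h$chi2, 0, tolerance = 1e-12)
  expect_equal(h$p, 1, tolerance = 1e-12)
  h2 <- marker_hwe_chi2(50L, 0L, 50L)
  expect_equal(h2$chi2, 100, tolerance = 1e-9)
  expect_lt(h2$p, 1e-20)
  expect_true(is.na(marker_hwe_chi2(100L, 0L, 0L)$p))
  expect_equal(marker_missing_rate(c(rep("AA", 12L), rep("NC", 3L))), 0.2)
})
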