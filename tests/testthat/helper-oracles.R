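# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check.

# Transitive-closure interval union: connected components of the pairwise
# overlap graph (>= 1 shared position), computed by label propagation.
brute_force_regions <- function(calls) {
  out <- list()
  for (chr in sort(unique(calls$chromosome))) {
    iv <- calls[calls$chromosome == chr, , drop = FALSE]
    n <- nrow(iv)
    adj <- outer(seq_len(n), seq_len(n), function(i, j) {
      iv$start[i] <= iv$end[j] & iv$start[j] <= iv$end[i]
    })
    comp <- seq_len(n)
    repeat {
      nxt <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
      if (identical(nxt, comp)) break
      comp <- nxt
    }
    for (g in sort(unique(comp))) {
      m <- iv[comp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr, start = min(m$start), end = max(m$end),
        n_cnvs = nrow(m))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Exhaustive maximization over all 4^n state sequences, using the model's
# own emission/transition terms but none of the Viterbi recursion.
exhaustive_decode <- function(lrr, baf, positions, params) {
  n <- length(lrr)
  stopifnot(n <= 12L)
  em <- bovicnv:::hmm_emission(lrr, baf, params)
  init <- bovicnv:::hmm_init(params)
  tms <- lapply(seq_len(max(n - 1L, 0L)), function(i) {
    bovicnv:::hmm_transition(positions[i + 1L] - positions[i], params)
  })
  grid <- as.matrix(expand.grid(rep(list(1:4), n)))
  score <- init[grid[, 1L]] + em[cbind(1L, grid[, 1L])]
  if (n > 1L) {
    for (i in 2:n) {
      score <- score + tms[[i - 1L]][cbind(grid[, i - 1L], grid[, i])] +
        em[cbind(i, grid[, i])]
    }
  }
  list(path = grid[which.max(score), ] - 1L, logp = max(score))
}

# Exact parent-child error probability at a marker inside a deletion
# segregating at haplotype frequency f, with B allele frequency p: full
# enumeration over sire haplotype pair, transmitted haplotype and dam
# haplotype. Returns the error probability conditional on both genotypes
# being called, for the generator's default "-/- reported NC" convention.
enum_pc_error <- function(f, p) {
  hap <- c("D", "A", "B")
  pr <- c(f, (1 - f) * (1 - p), (1 - f) * p)
  geno <- function(h1, h2) {
    nd <- (h1 == "D") + (h2 == "D")
    if (nd == 2L) return("NC")
    if (nd == 1L) {
      rem <- if (h1 == "D") h2 else h1
      return(if (rem == "A") "AA" else "BB")
    }
    if (h1 == h2) (if (h1 == "A") "AA" else "BB") else "AB"
  }
  p_err <- 0; p_inf <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:2) for (l in 1:3) {
    prob <- pr[i] * pr[j] * 0.5 * pr[l]
    if (prob == 0) next
    gs <- geno(hap[i], hap[j])
    gc <- geno(hap[c(i, j)][k], hap[l])
    if (gs != "NC" && gc != "NC") {
      p_inf <- p_inf + prob
      if ((gs == "AA" && gc == "BB") || (gs == "BB" && gc == "AA")) {
        p_err <- p_err + prob
      }
    }
  }
  list(p_err_informative = p_err / p_inf, p_informative = p_inf)
}
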