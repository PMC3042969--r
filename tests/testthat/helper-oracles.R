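# Independent brute-force oracles used across the tests.

# Enumerate all gamete combinations for a marker-QTL-marker triple and return
# the conditional QTL-genotype distribution given each flanking-marker class.
# Female gametes: the two intact parental haplotypes (achiasmate) or the same
# recombinant distribution as the male (chiasmate). Male gametes: all 8
# allele triples with no-interference probabilities.
enumerate_cond_probs <- function(design, r1, r2) {
  male <- list(); k <- 0
  for (x1 in 0:1) for (xq in 0:1) for (x2 in 0:1) {
    p <- 0.5 *
      (if (x1 != xq) r1 else 1 - r1) *
      (if (xq != x2) r2 else 1 - r2)
    k <- k + 1
    male[[k]] <- list(h = c(x1, xq, x2), p = p)
  }
  female <- if (design == "achiasmate") {
    list(list(h = c(0, 0, 0), p = 0.5), list(h = c(1, 1, 1), p = 0.5))
  } else male
  joint <- array(0, dim = c(3, 3, 3))  # left geno+1, right geno+1, qtl geno+1
  for (f in female) for (m in male) {
    g <- f$h + m$h
    joint[g[1] + 1, g[3] + 1, g[2] + 1] <-
      joint[g[1] + 1, g[3] + 1, g[2] + 1] + f$p * m$p
  }
  out <- list()
  for (gl in 0:2) for (gr in 0:2) {
    tot <- sum(joint[gl + 1, gr + 1, ])
    out[[paste(gl, gr)]] <- if (tot > 0) {
      # order pQQ (geno 2), pQq, pqq
      rev(joint[gl + 1, gr + 1, ]) / tot
    } else rep(NA_real_, 3)
  }
  out
}

# small two-chromosome map for fast scan tests
small_map <- function() grid_map(n_chrom = 2, n_markers = 6, spacing_cM = 10)

# a population carrying one strong additive QTL, quick to map
one_qtl_pop <- function(n = 250, seed = 99, a = 4, d = 1, var_e = 4) {
  map <- small_map()
  qtls <- data.frame(id = "Q1", chrom = "C1", pos_cM = 23, a = a, d = d)
  cfg <- scenario_config(map, qtls, n = n, mu = 0, var_e = var_e)
  simulate_f2(cfg, seed = seed)
}
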