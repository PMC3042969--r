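#' Conditional QTL-genotype probabilities given flanking markers
#'
#' For a putative QTL `Q` lying between two flanking markers `M+` (left) and
#' `M-` (right), these functions return `P(QQ)`, `P(Qq)` and `P(qq)` given the
#' observed flanking-marker genotype class, for the two F2 meiosis designs:
#'
#' * **achiasmate** — the female parent transmits one of her two parental
#'   haplotypes intact (no crossing-over in female meiosis, as in silkworm),
#'   while the male gamete recombines freely with no interference;
#' * **chiasmate** — the standard F2 design in which both gametes recombine.
#'
#' `r1` is the recombination fraction between `M+` and `Q`, `r2` between `Q`
#' and `M-`. The marker-interval fraction is `r = r1(1-r2) + r2(1-r1)` under
#' no interference. Under the achiasmate design the flanking classes
#' `(MM, mm)` and `(mm, MM)` cannot occur for linked markers (the female
#' haplotype is intact, so the two marker alleles she transmits are always in
#' coupling); requesting them is an error distinct from a missing-data error.
#'
#' @param left,right Integer genotype codes of the left and right flanking
#'   markers: 2 = MM, 1 = Mm, 0 = mm. Vectors are recycled to a common length.
#'   Missing values are not allowed here (see [expected_marker_coeffs()] for
#'   missing-data handling).
#' @param r1,r2 Scalar recombination fractions in `[0, 0.5]` for the two
#'   sub-intervals.
#' @return A numeric matrix with one row per individual and columns
#'   `pQQ`, `pQq`, `pqq` summing to 1.
#' @references The achiasmate table can be derived by enumerating the two
#'   intact female haplotypes against the four male gamete classes; see the
#'   package vignette for the derivation and a numerical cross-check.
#' @examples
#' cond_prob_achiasmate(2, 2, 0.05, 0.05)
#' cond_prob_chiasmate(2, 0, 0.05, 0.05)
#' @export
cond_prob_achiasmate <- function(left, right, r1, r2) {
  check_flank(left, right, r1, r2)
  n <- max(length(left), length(right))
  left <- rep_len(as.integer(left), n); right <- rep_len(as.integer(right), n)
  if (any(left == 2L & right == 0L) || any(left == 0L & right == 2L)) {
    stop("achiasmate-impossible genotype class (MM,mm)/(mm,MM): female haplotypes are intact",
         call. = FALSE)
  }
  tab <- achiasmate_table(r1, r2)
  tab[(2L - left) * 3L + (3L - right), , drop = FALSE]
}

#' @rdname cond_prob_achiasmate
#' @export
cond_prob_chiasmate <- function(left, right, r1, r2) {
  check_flank(left, right, r1, r2)
  n <- max(length(left), length(right))
  left <- rep_len(as.integer(left), n); right <- rep_len(as.integer(right), n)
  tab <- chiasmate_table(r1, r2)
  tab[(2L - left) * 3L + (3L - right), , drop = FALSE]
}

check_flank <- function(left, right, r1, r2) {
  if (any(is.na(left)) || any(is.na(right))) {
    stop("missing flanking-marker genotype", call. = FALSE)
  }
  if (!all(left %in% 0:2) || !all(right %in% 0:2)) {
    stop("marker genotypes must be coded 2 (MM), 1 (Mm) or 0 (mm)", call. = FALSE)
  }
  stopifnot(length(r1) == 1L, length(r2) == 1L)
  if (is.na(r1) || is.na(r2) || r1 < 0 || r2 < 0 || r1 > 0.5 || r2 > 0.5) {
    stop("recombination fractions must lie in [0, 0.5]", call. = FALSE)
  }
}

# 9 x 3 lookup table, rows ordered (MM,Mm,mm) x (MM,Mm,mm) row-major;
# achiasmate-impossible classes hold NA and are guarded by the caller
achiasmate_table <- function(r1, r2) {
  s1 <- 1 - r1; s2 <- 1 - r2
  r <- r1 * s2 + r2 * s1; s <- 1 - r
  # degenerate fully linked triple: point masses
  if (r == 0) {
    tab <- matrix(NA_real_, 9, 3)
    tab[idx33(1, 1), ] <- c(1, 0, 0)
    tab[idx33(2, 2), ] <- c(0, 1, 0)
    tab[idx33(3, 3), ] <- c(0, 0, 1)
    colnames(tab) <- c("pQQ", "pQq", "pqq")
    return(tab)
  }
  tab <- rbind(
    c(s1 * s2 / s,       r1 * r2 / s,  0),            # (MM,MM)
    c(s1 * r2 / r,       r1 * s2 / r,  0),            # (MM,Mm)
    c(NA, NA, NA),                                    # (MM,mm) infeasible
    c(r1 * s2 / r,       s1 * r2 / r,  0),            # (Mm,MM)
    c(r1 * r2 / (2 * s), s1 * s2 / s,  r1 * r2 / (2 * s)), # (Mm,Mm)
    c(0,                 s1 * r2 / r,  r1 * s2 / r),  # (Mm,mm)
    c(NA, NA, NA),                                    # (mm,MM) infeasible
    c(0,                 r1 * s2 / r,  s1 * r2 / r),  # (mm,Mm)
    c(0,                 r1 * r2 / s,  s1 * s2 / s)   # (mm,mm)
  )
  colnames(tab) <- c("pQQ", "pQq", "pqq")
  tab
}

chiasmate_table <- function(r1, r2) {
  s1 <- 1 - r1; s2 <- 1 - r2
  r <- r1 * s2 + r2 * s1; s <- 1 - r
  if (r == 0) {
    tab <- matrix(NA_real_, 9, 3)
    tab[idx33(1, 1), ] <- c(1, 0, 0)
    tab[idx33(2, 2), ] <- c(0, 1, 0)
    tab[idx33(3, 3), ] <- c(0, 0, 1)
    colnames(tab) <- c("pQQ", "pQq", "pqq")
    return(tab)
  }
  g11 <- s1 * s2; g10 <- s1 * r2; g01 <- r1 * s2; g00 <- r1 * r2
  tab <- rbind(
    c(g11^2,     2 * g11 * g00,           g00^2)     / s^2,         # (MM,MM)
    c(g11 * g10, g11 * g01 + g00 * g10,   g00 * g01) / (s * r),     # (MM,Mm)
    c(g10^2,     2 * g10 * g01,           g01^2)     / r^2,         # (MM,mm)
    c(g11 * g01, g11 * g10 + g00 * g01,   g00 * g10) / (s * r),     # (Mm,MM)
    c(2 * g11 * g00, g11^2 + g00^2 + g10^2 + g01^2, 2 * g11 * g00) / (s^2 + r^2), # (Mm,Mm)
    c(g00 * g10, g11 * g10 + g00 * g01,   g11 * g01) / (s * r),     # (Mm,mm)
    c(g01^2,     2 * g10 * g01,           g10^2)     / r^2,         # (mm,MM)
    c(g00 * g01, g11 * g01 + g00 * g10,   g11 * g10) / (s * r),     # (mm,Mm)
    c(g00^2,     2 * g11 * g00,           g11^2)     / s^2          # (mm,mm)
  )
  colnames(tab) <- c("pQQ", "pQq", "pqq")
  tab
}

idx33 <- function(i, j) (i - 1L) * 3L + j

# conditional probabilities given a single flanking marker at recombination r1
single_flank_probs <- function(design, g, r1) {
  s1 <- 1 - r1
  tab <- if (design == "achiasmate") {
    rbind(c(s1, r1, 0),
          c(r1 / 2, s1, r1 / 2),
          c(0, r1, s1))
  } else {
    rbind(c(s1^2, 2 * s1 * r1, r1^2),
          c(s1 * r1, s1^2 + r1^2, s1 * r1),
          c(r1^2, 2 * s1 * r1, s1^2))
  }
  colnames(tab) <- c("pQQ", "pQq", "pqq")
  tab[3L - as.integer(g), , drop = FALSE]
}

#' Expected additive and dominance coefficients from genotype probabilities
#'
#' Maps genotype probabilities to the expected coefficients of the additive
#' and dominance effects under the coding `a`: +1 (QQ), 0 (Qq), -1 (qq) and
#' `d`: +0.5 (Qq), -0.5 (homozygotes):
#' `xA = P(QQ) - P(qq)` and `xD = 0.5 P(Qq) - 0.5 (P(QQ) + P(qq))`.
#'
#' @param probs Matrix with columns `pQQ`, `pQq`, `pqq` (rows are
#'   individuals), as returned by [cond_prob_achiasmate()] or
#'   [cond_prob_chiasmate()].
#' @return A matrix with columns `xA` (in `[-1, 1]`) and `xD`
#'   (in `[-0.5, 0.5]`).
#' @export
qtl_coefficients <- function(probs) {
  probs <- rbind(probs)
  cbind(xA = probs[, "pQQ"] - probs[, "pqq"],
        xD = 0.5 * probs[, "pQq"] - 0.5 * (probs[, "pQQ"] + probs[, "pqq"]))
}

#' Epistatic coefficient products for a pair of loci
#'
#' The coefficients of the four digenic epistatic effects are the products of
#' the two loci's additive/dominance coefficients:
#' `xAA = xA_i xA_j`, `xAD = xA_i xD_j`, `xDA = xD_i xA_j`, `xDD = xD_i xD_j`.
#'
#' @param ci,cj Coefficient matrices (columns `xA`, `xD`) for locus i and j.
#' @return Matrix with columns `xAA`, `xAD`, `xDA`, `xDD`.
#' @export
epistasis_coefficients <- function(ci, cj) {
  ci <- rbind(ci); cj <- rbind(cj)
  cbind(xAA = ci[, "xA"] * cj[, "xA"],
        xAD = ci[, "xA"] * cj[, "xD"],
        xDA = ci[, "xD"] * cj[, "xA"],
        xDD = ci[, "xD"] * cj[, "xD"])
}
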