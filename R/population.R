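#' Construct an F2 cross population
#'
#' Bundles a genetic map, a marker-genotype matrix, per-individual sex labels
#' and phenotypes into a single validated object used by all scanning and
#' estimation functions.
#'
#' @param map A [genetic_map()].
#' @param geno Integer matrix, individuals x markers, coded 2 (MM), 1 (Mm),
#'   0 (mm) or `NA` (missing). Column names must match `map$marker`.
#' @param sex Integer vector of sex labels, exactly the two levels 1 and 2.
#' @param y Numeric phenotype vector.
#' @param design Meiosis design of the cross: `"achiasmate"` (silkworm-type
#'   F2: no crossing-over in the female parent) or `"chiasmate"`.
#' @param truth Optional list recording simulation truth (QTL genotypes,
#'   realized random effects); kept for test harnesses.
#' @return An object of class `cross_pop`.
#' @export
cross_pop <- function(map, geno, sex, y, design = c("achiasmate", "chiasmate"),
                      truth = NULL) {
  design <- match.arg(design)
  validate_map(map)
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)) || !identical(colnames(geno), map$marker)) {
    stop("genotype matrix columns must match the map's markers (same order)",
         call. = FALSE)
  }
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype code at individual %d, marker %s (must be 2, 1, 0 or NA)",
                 w[1], colnames(geno)[w[2]]), call. = FALSE)
  }
  sex <- as.integer(sex)
  if (!all(sex %in% 1:2) || length(sex) != nrow(geno)) {
    stop("sex must be a vector of 1/2 labels, one per individual", call. = FALSE)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(geno)) {
    stop("phenotype length must equal the number of individuals", call. = FALSE)
  }
  structure(list(map = map, geno = geno, sex = sex, y = y,
                 design = design, truth = truth),
            class = "cross_pop")
}

#' @export
print.cross_pop <- function(x, ...) {
  cat(sprintf("F2 cross population (%s design)\n", x$design))
  cat(sprintf("  %d individuals (%d / %d by sex), %d markers on %d chromosomes\n",
              nrow(x$geno), sum(x$sex == 1), sum(x$sex == 2),
              ncol(x$geno), length(unique(x$map$chrom))))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Observed or expected marker-effect coefficients
#'
#' Returns the per-individual additive and dominance coefficients of a marker
#' used in the background-marker models: `zA` takes 1, 0, -1 for MM, Mm, mm
#' and `zD` takes -0.5 for homozygotes and +0.5 for the heterozygote. When a
#' genotype is missing, its coefficients are replaced by their conditional
#' expectation given the nearest non-missing flanking markers on the same
#' chromosome, using the design-appropriate transition structure (achiasmate
#' or chiasmate). An individual with no informative marker on the chromosome
#' receives the marginal F2 (1:2:1) expectation `(0, 0)` with a warning.
#'
#' @param pop A [cross_pop()].
#' @param marker_id Marker name present in the map.
#' @return Matrix with columns `zA`, `zD`, one row per individual.
#' @export
expected_marker_coeffs <- function(pop, marker_id) {
  j <- match(marker_id, pop$map$marker)
  if (is.na(j)) stop(sprintf("unknown marker '%s'", marker_id), call. = FALSE)
  g <- pop$geno[, j]
  out <- cbind(zA = ifelse(g == 2L, 1, ifelse(g == 1L, 0, -1)),
               zD = ifelse(g == 1L, 0.5, -0.5))
  miss <- which(is.na(g))
  if (length(miss)) {
    probs <- locus_probs(pop, pop$map$chrom[j], pop$map$pos_cM[j],
                         individuals = miss, exclude_marker = j,
                         design = pop$design, warn_uninformative = TRUE)
    cf <- qtl_coefficients(probs)
    out[miss, 1] <- cf[, "xA"]
    out[miss, 2] <- cf[, "xD"]
  }
  out
}

# Conditional genotype probabilities at an arbitrary chromosome position for
# a set of individuals, conditioning on the nearest non-missing flanking
# markers (fast path; full multipoint conditioning is not needed for the
# complete-genotype populations produced by the simulator).
locus_probs <- function(pop, chrom, pos_cM, individuals = seq_len(nrow(pop$geno)),
                        exclude_marker = NA_integer_, design = pop$design,
                        warn_uninformative = FALSE) {
  midx <- which(pop$map$chrom == chrom)
  if (!length(midx)) stop(sprintf("unknown chromosome '%s'", chrom), call. = FALSE)
  mpos <- pop$map$pos_cM[midx]
  g <- pop$geno[individuals, midx, drop = FALSE]
  if (!is.na(exclude_marker)) g[, midx == exclude_marker] <- NA_integer_

  obs <- !is.na(g)
  leftc <- sweep(obs, 2, mpos <= pos_cM, "&")   # observed markers at/left of pos
  rightc <- sweep(obs, 2, mpos >= pos_cM, "&")
  li <- apply(leftc, 1, function(z) if (any(z)) max(which(z)) else NA_integer_)
  ri <- apply(rightc, 1, function(z) if (any(z)) min(which(z)) else NA_integer_)

  n <- length(individuals)
  probs <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("pQQ", "pQq", "pqq")))
  key <- paste(li, ri)
  for (k in unique(key)) {
    rows <- which(key == k)
    l <- li[rows[1]]; r <- ri[rows[1]]
    if (is.na(l) && is.na(r)) {
      if (warn_uninformative) {
        warning("individual(s) with no informative marker on chromosome ",
                chrom, "; using marginal 1:2:1 expectation", call. = FALSE)
      }
      probs[rows, ] <- matrix(c(0.25, 0.5, 0.25), length(rows), 3, byrow = TRUE)
    } else if (is.na(r) || (!is.na(l) && l == r)) {
      # single (or coincident) informative flank on the left
      r1 <- map_to_recomb(abs(pos_cM - mpos[l]))
      if (r1 == 0) {
        probs[rows, ] <- point_mass(g[rows, l])
      } else {
        probs[rows, ] <- single_flank_probs(design, g[rows, l], r1)
      }
    } else if (is.na(l)) {
      r1 <- map_to_recomb(abs(mpos[r] - pos_cM))
      if (r1 == 0) {
        probs[rows, ] <- point_mass(g[rows, r])
      } else {
        probs[rows, ] <- single_flank_probs(design, g[rows, r], r1)
      }
    } else {
      r1 <- map_to_recomb(pos_cM - mpos[l])
      r2 <- map_to_recomb(mpos[r] - pos_cM)
      fun <- if (design == "achiasmate") cond_prob_achiasmate else cond_prob_chiasmate
      probs[rows, ] <- fun(g[rows, l], g[rows, r], r1, r2)
    }
  }
  probs
}

point_mass <- function(g) {
  out <- matrix(0, length(g), 3, dimnames = list(NULL, c("pQQ", "pQq", "pqq")))
  out[cbind(seq_along(g), 3L - as.integer(g))] <- 1
  out
}

#' Expected QTL-effect coefficients at a genome position
#'
#' Computes the per-individual expected additive and dominance coefficients
#' `(xA, xD)` of a putative QTL at `pos_cM` on `chrom`, conditioning on the
#' nearest non-missing flanking markers under the requested meiosis design.
#' This is the coefficient engine behind the genome scans.
#'
#' @inheritParams expected_marker_coeffs
#' @param chrom Chromosome id.
#' @param pos_cM Position in cM.
#' @param design Probability backend: `"achiasmate"` or `"chiasmate"`.
#'   Defaults to the population's own design.
#' @return Matrix with columns `xA`, `xD`.
#' @export
qtl_coeffs_at <- function(pop, chrom, pos_cM, design = pop$design) {
  qtl_coefficients(locus_probs(pop, chrom, pos_cM, design = design))
}
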