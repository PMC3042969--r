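## Genome-scan machinery: background-marker selection, 1D main-effect scan,
## interval-pair selection, 2D epistasis scan and full-model assembly.
## All stage tests are Eq-style partial F tests against permutation
## thresholds (95th percentile of the per-permutation maximum F).

sex_indicator <- function(sex) {
  cbind(sex1 = as.numeric(sex == 1L), sex2 = as.numeric(sex == 2L))
}

# per-marker additive/dominance coefficient matrices with expectation-imputed
# missing genotypes
marker_zmats <- function(pop) {
  g <- pop$geno
  zA <- (g - 1)
  zD <- ifelse(g == 1L, 0.5, -0.5)
  for (j in which(colSums(is.na(g)) > 0)) {
    z <- expected_marker_coeffs(pop, pop$map$marker[j])
    zA[, j] <- z[, "zA"]
    zD[, j] <- z[, "zD"]
  }
  list(zA = zA, zD = zD)
}

# n x 2k matrix: each column of M split by sex level
per_sex <- function(M, sx) {
  M <- cbind(M)
  out <- matrix(0, nrow(M), 2 * ncol(M))
  for (j in seq_len(ncol(M))) {
    out[, 2 * j - 1] <- M[, j] * sx[, 1]
    out[, 2 * j]     <- M[, j] * sx[, 2]
  }
  cn <- colnames(M)
  if (!is.null(cn)) colnames(out) <- paste0(rep(cn, each = 2), c("_s1", "_s2"))
  out
}

# 8 per-sex main-effect columns of a marker interval (model-3 terms)
interval_term <- function(z, sx, li, ri) {
  per_sex(cbind(aR = z$zA[, ri], dR = z$zD[, ri],
                aL = z$zA[, li], dL = z$zD[, li]), sx)
}

# 16 per-sex epistatic columns of an interval pair (model-6 terms):
# products of the two right markers and of the two left markers
pair_term <- function(z, sx, iv1, iv2) {
  pr <- cbind(aa = z$zA[, iv1["ri"]] * z$zA[, iv2["ri"]],
              ad = z$zA[, iv1["ri"]] * z$zD[, iv2["ri"]],
              da = z$zD[, iv1["ri"]] * z$zA[, iv2["ri"]],
              dd = z$zD[, iv1["ri"]] * z$zD[, iv2["ri"]])
  pl <- cbind(aa = z$zA[, iv1["li"]] * z$zA[, iv2["li"]],
              ad = z$zA[, iv1["li"]] * z$zD[, iv2["li"]],
              da = z$zD[, iv1["li"]] * z$zA[, iv2["li"]],
              dd = z$zD[, iv1["li"]] * z$zD[, iv2["li"]])
  cbind(per_sex(pr, sx), per_sex(pl, sx))
}

# Batched partial-F evaluation. Qred_list: orthonormal reduced bases per
# conditioning pattern; pat: pattern index per test; E_list: extra-term
# orthonormal bases per test (already orthogonalized against their pattern).
# Y: n x K response matrix. Returns tests x K matrix of F statistics.
batch_F <- function(Y, Qred_list, pat, E_list) {
  Y <- cbind(Y)
  n <- nrow(Y); K <- ncol(Y)
  ssy <- colSums(Y^2)
  ssred <- lapply(Qred_list, function(Q) {
    if (ncol(Q) == 0) rep(0, K) else colSums(crossprod(Q, Y)^2)
  })
  df1 <- vapply(E_list, ncol, 1L)
  B <- do.call(cbind, E_list)
  CP2 <- crossprod(B, Y)^2
  ends <- cumsum(df1); starts <- ends - df1 + 1L
  Fm <- matrix(NA_real_, length(E_list), K)
  for (j in seq_along(E_list)) {
    if (df1[j] == 0) { Fm[j, ] <- 0; next }
    ssx <- if (df1[j] == 1) CP2[starts[j], ] else
      colSums(CP2[starts[j]:ends[j], , drop = FALSE])
    rr <- ncol(Qred_list[[pat[j]]])
    df2 <- n - rr - df1[j]
    sse <- pmax(ssy - ssred[[pat[j]]] - ssx, 0)
    Fm[j, ] <- (ssx / df1[j]) / pmax(sse / df2, .Machine$double.eps)
  }
  Fm
}

perm_matrix <- function(y, n_perm, seed) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_perm), function(i) y[sample.int(length(y))],
         numeric(length(y)))
}

# permutation threshold: (1-alpha) quantile of the per-permutation max F
perm_threshold <- function(y, Qred_list, pat, E_list, n_perm, alpha, seed) {
  Yp <- perm_matrix(y, n_perm, seed)
  Fp <- batch_F(Yp, Qred_list, pat, E_list)
  unname(stats::quantile(apply(Fp, 2, max), 1 - alpha))
}

# backward elimination over a list of term matrices: repeatedly drop the
# term with the lowest conditional F below `threshold`, never dropping the
# term with the highest marginal F; returns indices kept
stepwise_eliminate <- function(y, X0, terms, threshold, marginal_F) {
  keep <- seq_along(terms)
  protect <- which.max(marginal_F)
  # keep the joint design well below n: drop weakest terms outright when the
  # candidate set is too large to fit jointly
  cols <- vapply(terms, ncol, 1L)
  cap_cols <- length(y) - ncol(X0) - 30L
  if (sum(cols) > cap_cols) {
    ord <- order(marginal_F, decreasing = TRUE)
    keep <- sort(ord[cumsum(cols[ord]) <= cap_cols])
    if (!(protect %in% keep)) keep <- sort(c(protect, keep[-length(keep)]))
  }
  repeat {
    if (length(keep) <= 1) break
    condF <- vapply(seq_along(keep), function(i) {
      oth <- do.call(cbind, terms[keep[-i]])
      h <- henderson3_extra_ss(y, cbind(X0, oth, terms[[keep[i]]]), cbind(X0, oth))
      df1 <- h$rank_full - h$rank_reduced
      if (df1 == 0) return(0)  # fully collinear with the other terms
      df2 <- length(y) - h$rank_full
      (h$ssr_extra / df1) / max(h$sse / df2, .Machine$double.eps)
    }, numeric(1))
    condF[keep == protect] <- Inf
    worst <- which.min(condF)
    if (condF[worst] >= threshold) break
    keep <- keep[-worst]
  }
  keep
}

#' Select background marker intervals
#'
#' Tests every pair of adjacent markers for association with the phenotype
#' using the per-sex additive/dominance marker model, retains the intervals
#' whose partial F exceeds a permutation threshold, and removes redundant
#' ("ghost") intervals by backward stepwise elimination. The retained
#' intervals provide the background-control terms of the subsequent genome
#' scans, in the spirit of composite interval mapping.
#'
#' @param pop A [cross_pop()].
#' @param alpha Genome-wise significance level.
#' @param n_perm Number of phenotype permutations for the threshold.
#' @param seed Integer seed for the permutations.
#' @return List with `intervals` (all intervals with their F), `threshold`,
#'   `selected` (row indices into `intervals`), `alpha`, `seed`.
#' @export
select_background_markers <- function(pop, alpha = 0.05, n_perm = 1000,
                                      seed = NULL) {
  ivs <- map_intervals(pop$map)
  if (!nrow(ivs)) stop("at least two markers per chromosome are required", call. = FALSE)
  z <- marker_zmats(pop)
  sx <- sex_indicator(pop$sex)
  X0 <- sx
  li <- match(ivs$left, pop$map$marker)
  ri <- match(ivs$right, pop$map$marker)
  terms <- lapply(seq_len(nrow(ivs)), function(t) interval_term(z, sx, li[t], ri[t]))
  Q0 <- orth_basis(X0)
  E_list <- lapply(terms, function(Tm) extra_basis(Q0, Tm))
  Fobs <- drop(batch_F(pop$y, list(Q0), rep(1L, length(E_list)), E_list))
  thr <- perm_threshold(pop$y, list(Q0), rep(1L, length(E_list)), E_list,
                        n_perm, alpha, seed)
  sel <- which(Fobs > thr)
  if (length(sel) > 1) {
    kept <- stepwise_eliminate(pop$y, X0, terms[sel], thr, Fobs[sel])
    sel <- sel[kept]
  }
  ivs$F <- Fobs
  list(intervals = ivs, threshold = thr, selected = sel,
       alpha = alpha, n_perm = n_perm, seed = seed)
}

# scan grid within given intervals
scan_grid <- function(ivs, rows, step_cM) {
  do.call(rbind, lapply(rows, function(t) {
    pos <- seq(ivs$left_pos[t], ivs$right_pos[t], by = step_cM)
    if (pos[length(pos)] < ivs$right_pos[t]) pos <- c(pos, ivs$right_pos[t])
    data.frame(chrom = ivs$chrom[t], pos_cM = pos, interval = ivs$interval[t])
  }))
}

#' One-dimensional genome scan for main-effect QTLs
#'
#' Walks a cM grid over the genome, testing at each position the four
#' per-sex QTL terms whose coefficients come from the conditional
#' QTL-genotype probabilities of the requested design backend. The reduced
#' model contains the sex means and the selected background intervals'
#' marker terms; background intervals lying within `window_cM` of the
#' tested position are dropped from the conditioning set so the background
#' cannot absorb the tested QTL (the composite-interval-mapping exclusion
#' window). Peaks above the permutation threshold are reported after
#' stepwise elimination of false peaks. With `scope = "selected"` the walk
#' is confined to the selected background intervals instead.
#'
#' @param pop A [cross_pop()].
#' @param background Result of [select_background_markers()].
#' @param design Conditional-probability backend (`"achiasmate"` or
#'   `"chiasmate"`); defaults to the population's design.
#' @param step_cM Walk step in cM.
#' @param alpha Genome-wise significance level.
#' @param n_perm Permutations for the threshold.
#' @param seed Integer seed.
#' @param window_cM Background-exclusion window around the tested position.
#' @param scope Walk the whole genome (default) or only the selected
#'   background intervals.
#' @return List with `profile` (chrom, pos_cM, F, threshold), `threshold`,
#'   `detected` (one row per QTL: position, flanking interval, F, per-sex
#'   scan-stage effect estimates `a1`, `a2`, `d1`, `d2`).
#' @export
scan_main <- function(pop, background, design = pop$design, step_cM = 1,
                      alpha = 0.05, n_perm = 1000, seed = NULL,
                      window_cM = 10, scope = c("genome", "selected")) {
  scope <- match.arg(scope)
  ivs <- background$intervals
  sel <- background$selected
  z <- marker_zmats(pop)
  sx <- sex_indicator(pop$sex)
  X0 <- sx
  li <- match(ivs$left, pop$map$marker)
  ri <- match(ivs$right, pop$map$marker)
  bg_terms <- lapply(sel, function(t) interval_term(z, sx, li[t], ri[t]))
  names(bg_terms) <- as.character(sel)

  scan_rows <- if (scope == "selected" && length(sel)) sel else seq_len(nrow(ivs))
  grid <- scan_grid(ivs, scan_rows, step_cM)
  grid <- grid[!duplicated(grid[c("chrom", "pos_cM")]), , drop = FALSE]

  # conditioning pattern = which background intervals fall inside the
  # exclusion window of the tested position
  drop_set <- function(chrom, pos) {
    if (!length(sel)) return(integer())
    which(ivs$chrom[sel] == chrom &
            ivs$left_pos[sel] - window_cM <= pos &
            ivs$right_pos[sel] + window_cM >= pos)
  }
  drops <- lapply(seq_len(nrow(grid)), function(i)
    drop_set(grid$chrom[i], grid$pos_cM[i]))
  keys <- vapply(drops, function(d) paste(d, collapse = ","), character(1))
  ukeys <- unique(keys)
  pat <- match(keys, ukeys)
  Qred_list <- lapply(ukeys, function(k) {
    dr <- if (nzchar(k)) as.integer(strsplit(k, ",")[[1]]) else integer()
    Xr <- cbind(X0, do.call(cbind, c(list(NULL), bg_terms[setdiff(seq_along(sel), dr)])))
    orth_basis(Xr)
  })

  coeffs <- lapply(seq_len(nrow(grid)), function(i) {
    per_sex(qtl_coeffs_at(pop, grid$chrom[i], grid$pos_cM[i], design = design), sx)
  })
  E_list <- lapply(seq_len(nrow(grid)), function(i) {
    extra_basis(Qred_list[[pat[i]]], coeffs[[i]])
  })
  Fobs <- drop(batch_F(pop$y, Qred_list, pat, E_list))
  thr <- perm_threshold(pop$y, Qred_list, pat, E_list, n_perm, alpha, seed)
  grid$F <- Fobs

  detected <- call_peaks(grid, ivs, thr)
  if (nrow(detected) > 1) {
    det_terms <- lapply(detected$grid_row, function(i) coeffs[[i]])
    kept <- stepwise_eliminate(pop$y, X0, det_terms, thr, detected$F)
    detected <- detected[kept, , drop = FALSE]
  }
  # scan-stage per-sex effect estimates at each detected position
  if (nrow(detected)) {
    est <- t(vapply(seq_len(nrow(detected)), function(k) {
      i <- detected$grid_row[k]
      Xr <- cbind(X0, do.call(cbind, c(list(NULL),
                   bg_terms[setdiff(seq_along(sel), drops[[i]])])))
      cf <- stats::lm.fit(cbind(Xr, coeffs[[i]]), pop$y)$coefficients
      m <- length(cf)
      cf[(m - 3):m]
    }, numeric(4)))
    colnames(est) <- c("a1", "a2", "d1", "d2")
    detected <- cbind(detected, est)
  }
  list(profile = grid[c("chrom", "pos_cM", "interval", "F")], threshold = thr,
       detected = detected, step_cM = step_cM, alpha = alpha,
       n_perm = n_perm, seed = seed, design = design, window_cM = window_cM,
       scope = scope)
}

# peak calling: strict local maxima above threshold, separated from any
# higher retained peak by at least one marker-interval width
call_peaks <- function(grid, ivs, threshold) {
  out <- data.frame(chrom = character(), pos_cM = numeric(), interval = integer(),
                    F = numeric(), grid_row = integer(), stringsAsFactors = FALSE)
  cand <- which(grid$F > threshold)
  if (!length(cand)) return(out)
  ord <- cand[order(grid$F[cand], decreasing = TRUE)]
  for (i in ord) {
    sep <- ivs$right_pos[match(grid$interval[i], ivs$interval)] -
      ivs$left_pos[match(grid$interval[i], ivs$interval)]
    if (nrow(out)) {
      same <- out$chrom == grid$chrom[i]
      if (any(same & abs(out$pos_cM - grid$pos_cM[i]) < sep)) next
    }
    out <- rbind(out, data.frame(chrom = grid$chrom[i], pos_cM = grid$pos_cM[i],
                                 interval = grid$interval[i], F = grid$F[i],
                                 grid_row = i, stringsAsFactors = FALSE))
  }
  out[order(out$chrom, out$pos_cM), , drop = FALSE]
}

#' Select candidate interval pairs for the epistasis scan
#'
#' Tests the sixteen per-sex epistatic marker terms (additive-additive,
#' additive-dominance, dominance-additive and dominance-dominance products
#' of the two right and of the two left markers, split by sex) of every pair
#' of marker intervals, with the background intervals' main-effect terms
#' included in the conditioning set. Pairs exceeding the permutation
#' threshold are retained and pruned by stepwise elimination.
#'
#' @inheritParams scan_main
#' @return List with `pairs` (interval index pairs and their F),
#'   `threshold`, `selected` (row indices), `alpha`, `seed`.
#' @export
select_interval_pairs <- function(pop, background, alpha = 0.05,
                                  n_perm = 1000, seed = NULL) {
  ivs <- background$intervals
  sel <- background$selected
  z <- marker_zmats(pop)
  sx <- sex_indicator(pop$sex)
  X0 <- sx
  li <- match(ivs$left, pop$map$marker)
  ri <- match(ivs$right, pop$map$marker)
  bg <- do.call(cbind, c(list(NULL), lapply(sel, function(t)
    interval_term(z, sx, li[t], ri[t]))))
  Qred <- orth_basis(cbind(X0, bg))

  nIV <- nrow(ivs)
  prs <- which(upper.tri(matrix(TRUE, nIV, nIV)), arr.ind = TRUE)
  pairs <- data.frame(iv1 = prs[, "row"], iv2 = prs[, "col"])
  mk <- function(t) c(li = li[t], ri = ri[t])
  terms <- lapply(seq_len(nrow(pairs)), function(k)
    pair_term(z, sx, mk(pairs$iv1[k]), mk(pairs$iv2[k])))
  E_list <- lapply(terms, function(Tm) extra_basis(Qred, Tm))
  Fobs <- drop(batch_F(pop$y, list(Qred), rep(1L, length(E_list)), E_list))
  thr <- perm_threshold(pop$y, list(Qred), rep(1L, length(E_list)), E_list,
                        n_perm, alpha, seed)
  selp <- which(Fobs > thr)
  if (length(selp) > 1) {
    kept <- stepwise_eliminate(pop$y, cbind(X0, bg), terms[selp], thr, Fobs[selp])
    selp <- selp[kept]
  }
  pairs$F <- Fobs
  list(pairs = pairs, threshold = thr, selected = selp,
       alpha = alpha, n_perm = n_perm, seed = seed)
}

#' Two-dimensional scan for epistatic QTL pairs
#'
#' Walks a two-dimensional cM grid over each selected interval pair, testing
#' the four per-sex epistatic effects of the putative QTL pair. Coefficients
#' are products of the two positions' expected additive/dominance
#' coefficients under the design backend. The conditioning set holds the sex
#' means, the main effects of the QTLs detected in the one-dimensional scan
#' and the marker-epistasis terms of the *other* selected pairs.
#'
#' @inheritParams scan_main
#' @param pairs Result of [select_interval_pairs()].
#' @param main Result of [scan_main()].
#' @return List with `detected` (one row per epistatic pair: the two
#'   positions, F, per-sex effect estimates), `threshold`, `profile`.
#' @export
scan_epistasis <- function(pop, background, pairs, main, design = pop$design,
                           step_cM = 2, alpha = 0.05, n_perm = 1000,
                           seed = NULL) {
  ivs <- background$intervals
  selp <- pairs$selected
  empty <- data.frame(chrom_i = character(), pos_i = numeric(),
                      chrom_j = character(), pos_j = numeric(), F = numeric())
  if (!length(selp)) {
    return(list(detected = empty, threshold = NA_real_, profile = NULL,
                alpha = alpha, n_perm = n_perm, seed = seed))
  }
  z <- marker_zmats(pop)
  sx <- sex_indicator(pop$sex)
  X0 <- sx
  li <- match(ivs$left, pop$map$marker)
  ri <- match(ivs$right, pop$map$marker)
  mains <- do.call(cbind, c(list(NULL),
    lapply(seq_len(nrow(main$detected)), function(k)
      per_sex(qtl_coeffs_at(pop, main$detected$chrom[k], main$detected$pos_cM[k],
                            design = design), sx))))
  mk <- function(t) c(li = li[t], ri = ri[t])
  pair_marker_terms <- lapply(selp, function(k)
    pair_term(z, sx, mk(pairs$pairs$iv1[k]), mk(pairs$pairs$iv2[k])))

  # per tested pair: conditioning excludes its own marker-epistasis term
  Qred_list <- lapply(seq_along(selp), function(pidx) {
    oth <- do.call(cbind, c(list(NULL), pair_marker_terms[-pidx]))
    orth_basis(cbind(X0, mains, oth))
  })

  grids <- list(); E_list <- list(); pat <- integer(); cells <- list()
  for (pidx in seq_along(selp)) {
    k <- selp[pidx]
    t1 <- pairs$pairs$iv1[k]; t2 <- pairs$pairs$iv2[k]
    g1 <- scan_grid(ivs, t1, step_cM); g2 <- scan_grid(ivs, t2, step_cM)
    c1 <- lapply(seq_len(nrow(g1)), function(i)
      qtl_coeffs_at(pop, g1$chrom[i], g1$pos_cM[i], design = design))
    c2 <- lapply(seq_len(nrow(g2)), function(j)
      qtl_coeffs_at(pop, g2$chrom[j], g2$pos_cM[j], design = design))
    for (i in seq_len(nrow(g1))) for (j in seq_len(nrow(g2))) {
      # a locus cannot be epistatic with itself: skip coincident positions
      if (g1$chrom[i] == g2$chrom[j] && abs(g1$pos_cM[i] - g2$pos_cM[j]) < 1e-9) next
      X <- per_sex(epistasis_coefficients(c1[[i]], c2[[j]]), sx)
      E_list[[length(E_list) + 1L]] <- extra_basis(Qred_list[[pidx]], X)
      pat <- c(pat, pidx)
      cells[[length(cells) + 1L]] <- data.frame(
        pair = k, chrom_i = g1$chrom[i], pos_i = g1$pos_cM[i],
        chrom_j = g2$chrom[j], pos_j = g2$pos_cM[j], stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cells)
  Fobs <- drop(batch_F(pop$y, Qred_list, pat, E_list))
  thr <- perm_threshold(pop$y, Qred_list, pat, E_list, n_perm, alpha, seed)
  cells$F <- Fobs

  det <- do.call(rbind, lapply(unique(cells$pair), function(k) {
    sub <- cells[cells$pair == k, , drop = FALSE]
    best <- which.max(sub$F)
    if (sub$F[best] > thr) sub[best, , drop = FALSE] else NULL
  }))
  if (is.null(det)) det <- cbind(pair = integer(), empty)

  # stepwise elimination among detected epistases
  if (nrow(det) > 1) {
    cond_base <- cbind(X0, mains)
    det_terms <- lapply(seq_len(nrow(det)), function(k) {
      ci <- qtl_coeffs_at(pop, det$chrom_i[k], det$pos_i[k], design = design)
      cj <- qtl_coeffs_at(pop, det$chrom_j[k], det$pos_j[k], design = design)
      per_sex(epistasis_coefficients(ci, cj), sx)
    })
    kept <- stepwise_eliminate(pop$y, cond_base, det_terms, thr, det$F)
    det <- det[kept, , drop = FALSE]
  }
  if (nrow(det)) {
    est <- t(vapply(seq_len(nrow(det)), function(k) {
      ci <- qtl_coeffs_at(pop, det$chrom_i[k], det$pos_i[k], design = design)
      cj <- qtl_coeffs_at(pop, det$chrom_j[k], det$pos_j[k], design = design)
      X <- per_sex(epistasis_coefficients(ci, cj), sx)
      cf <- stats::lm.fit(cbind(X0, mains, X), pop$y)$coefficients
      m <- length(cf)
      cf[(m - 7):m]
    }, numeric(8)))
    colnames(est) <- c("aa1", "aa2", "ad1", "ad2", "da1", "da2", "dd1", "dd2")
    det <- cbind(det, est)
  }
  list(detected = det, threshold = thr, profile = cells,
       step_cM = step_cM, alpha = alpha, n_perm = n_perm, seed = seed,
       design = design)
}

#' Assemble the full mixed-model design from scan detections
#'
#' Builds the fixed and random design matrices of the full genetic model:
#' fixed effects are the population mean, each detected QTL's additive and
#' dominance effects and each detected pair's four epistatic effects;
#' random terms are the sex effect and the sex interactions of every
#' additive, dominance and epistatic effect (coefficients are products of
#' the genetic coefficients and sex indicators).
#'
#' @inheritParams scan_main
#' @param main Result of [scan_main()].
#' @param epi Result of [scan_epistasis()] or `NULL`.
#' @return List with `X` (fixed design), `U_list` (named random-term
#'   matrices) and `meta` (detection bookkeeping).
#' @export
assemble_full_model <- function(pop, main, epi = NULL, design = pop$design) {
  sx <- sex_indicator(pop$sex)
  n <- nrow(pop$geno)
  det <- main$detected
  nq <- if (is.null(det)) 0L else nrow(det)
  dete <- if (!is.null(epi)) epi$detected else NULL
  np <- if (is.null(dete)) 0L else nrow(dete)

  X <- matrix(1, n, 1, dimnames = list(NULL, "mu"))
  cf <- vector("list", nq)
  if (nq) {
    for (k in seq_len(nq)) {
      cf[[k]] <- qtl_coeffs_at(pop, det$chrom[k], det$pos_cM[k], design = design)
      cols <- cf[[k]]
      colnames(cols) <- paste0(c("a_", "d_"), "Q", k)
      X <- cbind(X, cols)
    }
  }
  ep_cf <- vector("list", np)
  if (np) {
    for (l in seq_len(np)) {
      ci <- qtl_coeffs_at(pop, dete$chrom_i[l], dete$pos_i[l], design = design)
      cj <- qtl_coeffs_at(pop, dete$chrom_j[l], dete$pos_j[l], design = design)
      ep_cf[[l]] <- epistasis_coefficients(ci, cj)
      cols <- ep_cf[[l]]
      colnames(cols) <- paste0(c("aa_", "ad_", "da_", "dd_"), "E", l)
      X <- cbind(X, cols)
    }
  }

  U_list <- list(S = sx)
  colnames(U_list$S) <- c("S1", "S2")
  if (nq) {
    AS <- do.call(cbind, lapply(seq_len(nq), function(k) {
      m <- per_sex(cf[[k]][, "xA", drop = FALSE], sx)
      colnames(m) <- paste0("AS", c(1, 2), "_Q", k); m
    }))
    DS <- do.call(cbind, lapply(seq_len(nq), function(k) {
      m <- per_sex(cf[[k]][, "xD", drop = FALSE], sx)
      colnames(m) <- paste0("DS", c(1, 2), "_Q", k); m
    }))
    U_list$AS <- AS; U_list$DS <- DS
  }
  if (np) {
    for (nm in c("AA", "AD", "DA", "DD")) {
      col <- paste0("x", nm)
      U <- do.call(cbind, lapply(seq_len(np), function(l) {
        m <- per_sex(ep_cf[[l]][, col, drop = FALSE], sx)
        colnames(m) <- paste0(nm, "S", c(1, 2), "_E", l); m
      }))
      U_list[[paste0(nm, "S")]] <- U
    }
  }
  list(X = X, U_list = U_list,
       meta = list(main = det, epi = dete, design = design))
}

#' Run the full QTL-mapping pipeline
#'
#' Orchestrates background-marker selection, the one-dimensional main-effect
#' scan, interval-pair selection and the two-dimensional epistasis scan
#' (model variants I and II), assembles the full mixed model from the
#' detections and estimates all genetic and QTL-by-sex interaction effects
#' by REML/GLS/AUP-initialized Gibbs sampling.
#'
#' Model variants:
#' * `"I"`  — achiasmate conditional-probability backend, with epistasis;
#' * `"II"` — chiasmate backend (the standard F2 model), with epistasis;
#' * `"III"` — achiasmate backend, epistasis stages skipped.
#'
#' @param pop A [cross_pop()].
#' @param variant Model variant, `"I"`, `"II"` or `"III"`.
#' @param step_cM Scan walk step.
#' @param alpha Genome-wise significance level per stage.
#' @param n_perm Permutations per stage threshold.
#' @param gibbs_iter,burn_in Gibbs chain length and burn-in.
#' @param seed Integer seed; per-stage seeds are derived from it.
#' @param fit Logical: run the full-model Gibbs estimation?
#' @return List with the stage results (`background`, `main`, `pairs`,
#'   `epistasis`), the assembled `model` and the `fit` report.
#' @export
map_qtl <- function(pop, variant = c("I", "II", "III"), step_cM = 1,
                    alpha = 0.05, n_perm = 1000, gibbs_iter = 11000,
                    burn_in = 1000, seed = 1, fit = TRUE) {
  variant <- match.arg(variant)
  backend <- if (variant == "II") "chiasmate" else "achiasmate"
  with_epi <- variant != "III"
  sd <- function(k) (seed * 7L + k) %% .Machine$integer.max

  bg <- select_background_markers(pop, alpha, n_perm, seed = sd(1))
  main <- scan_main(pop, bg, design = backend, step_cM = step_cM,
                    alpha = alpha, n_perm = n_perm, seed = sd(2))
  prs <- NULL; epi <- NULL
  if (with_epi) {
    prs <- select_interval_pairs(pop, bg, alpha, n_perm, seed = sd(3))
    epi <- scan_epistasis(pop, bg, prs, main, design = backend,
                          step_cM = max(step_cM, 2), alpha = alpha,
                          n_perm = n_perm, seed = sd(4))
  }
  model <- assemble_full_model(pop, main, epi, design = backend)
  fit_rep <- NULL
  if (fit) {
    init <- tryCatch(fit_mixed_model(pop$y, model$X, model$U_list),
                     error = function(e) NULL)
    fit_rep <- gibbs_estimate(pop$y, model$X, model$U_list, init = init,
                              n_iter = gibbs_iter, burn_in = burn_in,
                              seed = sd(5))
  }
  list(variant = variant, background = bg, main = main, pairs = prs,
       epistasis = epi, model = model, fit = fit_rep, seed = seed)
}
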