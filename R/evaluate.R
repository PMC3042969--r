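#' Achiasmate-vs-chiasmate coefficient differences
#'
#' Quantifies how much the expected QTL-effect coefficients of the standard
#' chiasmate F2 model deviate from the correct achiasmate ones. With the
#' marker-interval recombination fraction `r` held fixed, the QTL position
#' is swept across the interval: `r1` runs over an interior grid in `(0, r)`
#' and `r2` is derived from the no-interference identity
#' `r = r1 (1 - r2) + r2 (1 - r1)`. At each grid point and for each of the
#' seven achiasmate-feasible flanking-marker classes the absolute difference
#' `D = |x_a - x_c|` and the relative difference `R = |x_a - x_c| / |x_a|`
#' are computed for both the additive and the dominance coefficient
#' (relative differences are undefined and skipped where the achiasmate
#' coefficient is zero).
#'
#' @param r Marker-interval recombination fraction in (0, 0.5).
#' @param grid_points Number of interior grid points for `r1` (at least
#'   100). The endpoints 0 and `r` are excluded: both models degenerate to
#'   the same point masses there and relative differences are undefined.
#' @return A `coeff_diff` object: `curves` (long data frame with columns
#'   `r1`, `class`, `coef`, `metric`, `value`) and `summary` (max/min of
#'   each metric over classes and grid).
#' @examples
#' d <- coefficient_difference(0.09, grid_points = 200)
#' d$summary
#' @export
coefficient_difference <- function(r, grid_points = 1000) {
  if (length(r) != 1 || is.na(r) || r <= 0 || r >= 0.5) {
    stop("r must lie in (0, 0.5)", call. = FALSE)
  }
  if (grid_points < 100) stop("grid_points must be at least 100", call. = FALSE)
  classes <- rbind(c(2, 2), c(2, 1), c(1, 2), c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  cl_lab <- apply(classes, 1, paste, collapse = "/")
  r1g <- r * seq_len(grid_points) / (grid_points + 1)
  # the absolute-difference extrema sit at the exact interval midpoint
  # (r1 = r2); include it so the envelope maxima are not grid-limited
  r1g <- sort(unique(c(r1g, (1 - sqrt(1 - 2 * r)) / 2)))
  res <- vector("list", length(r1g))
  for (i in seq_along(r1g)) {
    r1 <- r1g[i]
    r2 <- (r - r1) / (1 - 2 * r1)
    ca <- qtl_coefficients(cond_prob_achiasmate(classes[, 1], classes[, 2], r1, r2))
    cc <- qtl_coefficients(cond_prob_chiasmate(classes[, 1], classes[, 2], r1, r2))
    dA <- abs(ca[, "xA"] - cc[, "xA"]); dD <- abs(ca[, "xD"] - cc[, "xD"])
    rA <- ifelse(abs(ca[, "xA"]) > 1e-12, dA / abs(ca[, "xA"]), NA_real_)
    rD <- ifelse(abs(ca[, "xD"]) > 1e-12, dD / abs(ca[, "xD"]), NA_real_)
    res[[i]] <- data.frame(r1 = r1, class = rep(cl_lab, 4),
                           coef = rep(rep(c("additive", "dominance"), each = 7), 2),
                           metric = rep(c("absolute", "relative"), each = 14),
                           value = c(dA, dD, rA, rD), stringsAsFactors = FALSE)
  }
  curves <- do.call(rbind, res)
  smax <- function(coef, metric) {
    v <- curves$value[curves$coef == coef & curves$metric == metric]
    max(v, na.rm = TRUE)
  }
  smin <- function(coef, metric) {
    v <- curves$value[curves$coef == coef & curves$metric == metric]
    min(v, na.rm = TRUE)
  }
  summary <- data.frame(
    coef = rep(c("additive", "dominance"), 2),
    metric = rep(c("absolute", "relative"), each = 2),
    max = c(smax("additive", "absolute"), smax("dominance", "absolute"),
            smax("additive", "relative"), smax("dominance", "relative")),
    min = c(smin("additive", "absolute"), smin("dominance", "absolute"),
            smin("additive", "relative"), smin("dominance", "relative")))
  structure(list(r = r, grid_points = grid_points, curves = curves,
                 summary = summary),
            class = "coeff_diff")
}

#' @export
print.coeff_diff <- function(x, ...) {
  cat(sprintf("Achiasmate vs chiasmate coefficient differences (r = %.3f, %d grid points)\n",
              x$r, x$grid_points))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Match detected QTLs to a true architecture
#'
#' Greedy matching by descending F statistic: each detection is matched to
#' the nearest not-yet-matched true QTL on the same chromosome within
#' `window_cM`; detections left unmatched are false positives.
#'
#' @param truth Data frame of true QTLs with columns `chrom`, `pos_cM` (and
#'   optionally `id`).
#' @param detections Data frame with columns `chrom`, `pos_cM`, `F`.
#' @param window_cM Maximum matching distance in cM.
#' @return `detections` with added columns `matched` (logical) and
#'   `true_id` (matched truth row id or `NA`).
#' @export
match_detections <- function(truth, detections, window_cM = 10) {
  if (window_cM <= 0) stop("window_cM must be positive", call. = FALSE)
  det <- detections
  det$matched <- FALSE
  det$true_id <- NA_character_
  if (!nrow(det)) return(det)
  tid <- if ("id" %in% names(truth)) as.character(truth$id) else
    as.character(seq_len(nrow(truth)))
  taken <- rep(FALSE, nrow(truth))
  for (i in order(det$F, decreasing = TRUE)) {
    d <- ifelse(truth$chrom == det$chrom[i] & !taken,
                abs(truth$pos_cM - det$pos_cM[i]), Inf)
    j <- which.min(d)
    if (length(j) && d[j] <= window_cM) {
      det$matched[i] <- TRUE
      det$true_id[i] <- tid[j]
      taken[j] <- TRUE
    }
  }
  det
}

#' Monte Carlo evaluation of the mapping pipeline
#'
#' Repeatedly simulates populations from a scenario, runs the full mapping
#' pipeline under one or more model variants on the *same* simulated data
#' sets, and summarizes detection power, false discovery rate and the bias
#' and spread of position and effect estimates per true QTL and epistatic
#' pair.
#'
#' @param cfg A [scenario_config()], e.g. [silkworm_scenario()].
#' @param variants Character vector of model variants (see [map_qtl()]).
#' @param n_reps Number of simulation replicates.
#' @param seed Base seed; replicate seeds are derived from it.
#' @param n_perm Permutations per threshold.
#' @param step_cM Scan step.
#' @param gibbs_iter,burn_in Gibbs chain settings for the full-model fit.
#' @param window_cM Matching window for power/FDR bookkeeping.
#' @return A `simulation_report`: per-variant `qtl` table (power, position
#'   bias/SD, additive and dominance effect bias/SD), `epistasis` table
#'   (power per true pair), `fdr` table (pooled over replicates, with a
#'   binomial Monte-Carlo standard error), and the run settings.
#' @export
run_simulation_study <- function(cfg, variants = c("I", "II"), n_reps = 50,
                                 seed = 1, n_perm = 200, step_cM = 1,
                                 gibbs_iter = 2000, burn_in = 500,
                                 window_cM = 10) {
  stopifnot(n_reps >= 1)
  truth <- cfg$qtls[cfg$qtls$a != 0 | cfg$qtls$d != 0, , drop = FALSE]
  ep <- cfg$epistases
  recs <- list(); eprecs <- list()
  for (rep in seq_len(n_reps)) {
    pop <- simulate_f2(cfg, seed = (seed * 1009L + rep) %% .Machine$integer.max)
    for (v in variants) {
      res <- tryCatch(
        map_qtl(pop, variant = v, step_cM = step_cM, alpha = 0.05,
                n_perm = n_perm, gibbs_iter = gibbs_iter, burn_in = burn_in,
                seed = (seed * 31L + rep) %% .Machine$integer.max),
        error = function(e) {
          warning(sprintf("replicate %d variant %s failed: %s", rep, v,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(res)) next
      det <- res$main$detected
      if (nrow(det)) {
        det <- match_detections(truth, det, window_cM)
        est <- full_model_estimates(res)
        det$a_est <- est$a; det$d_est <- est$d
      } else {
        det$matched <- logical(); det$true_id <- character()
        det$a_est <- numeric(); det$d_est <- numeric()
      }
      det$rep <- rep; det$variant <- v
      recs[[length(recs) + 1L]] <- det
      if (!is.null(res$epistasis) && nrow(res$epistasis$detected) && !is.null(ep)) {
        de <- res$epistasis$detected
        de$rep <- rep; de$variant <- v
        de$true_pair <- vapply(seq_len(nrow(de)), function(k)
          match_epi_pair(cfg, de[k, ], window_cM), character(1))
        eprecs[[length(eprecs) + 1L]] <- de
      }
    }
  }
  all_det <- if (length(recs)) do.call(rbind, recs) else NULL
  all_epi <- if (length(eprecs)) do.call(rbind, eprecs) else NULL

  qtl_tab <- do.call(rbind, lapply(variants, function(v) {
    do.call(rbind, lapply(seq_len(nrow(truth)), function(k) {
      id <- as.character(truth$id[k])
      sub <- all_det[!is.null(all_det) & all_det$variant == v &
                       all_det$true_id %in% id, , drop = FALSE]
      nhit <- length(unique(sub$rep))
      data.frame(variant = v, id = id, chrom = truth$chrom[k],
                 pos = truth$pos_cM[k], a = truth$a[k], d = truth$d[k],
                 power = nhit / n_reps,
                 pos_bias = mean(sub$pos_cM) - truth$pos_cM[k],
                 pos_sd = stats::sd(sub$pos_cM),
                 a_est = mean(sub$a_est), a_sd = stats::sd(sub$a_est),
                 d_est = mean(sub$d_est), d_sd = stats::sd(sub$d_est),
                 stringsAsFactors = FALSE)
    }))
  }))
  fdr_tab <- do.call(rbind, lapply(variants, function(v) {
    sub <- all_det[!is.null(all_det) & all_det$variant == v, , drop = FALSE]
    nd <- nrow(sub); nf <- sum(!sub$matched)
    fdr <- if (nd) nf / nd else NA_real_
    data.frame(variant = v, detections = nd, false = nf, fdr = fdr,
               fdr_se = if (nd) sqrt(fdr * (1 - fdr) / nd) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  epi_tab <- if (!is.null(ep)) do.call(rbind, lapply(variants, function(v) {
    do.call(rbind, lapply(seq_len(nrow(ep)), function(l) {
      id <- as.character(ep$id[l])
      sub <- if (is.null(all_epi)) NULL else
        all_epi[all_epi$variant == v & all_epi$true_pair %in% id, , drop = FALSE]
      data.frame(variant = v, id = id,
                 power = if (is.null(sub)) 0 else length(unique(sub$rep)) / n_reps,
                 stringsAsFactors = FALSE)
    }))
  })) else NULL
  structure(list(qtl = qtl_tab, epistasis = epi_tab, fdr = fdr_tab,
                 detections = all_det, epi_detections = all_epi,
                 settings = list(variants = variants, n_reps = n_reps,
                                 seed = seed, n_perm = n_perm,
                                 step_cM = step_cM, gibbs_iter = gibbs_iter,
                                 window_cM = window_cM)),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf("Simulation study: %d replicates, variants %s\n\nPer-QTL summary:\n",
              x$settings$n_reps, paste(x$settings$variants, collapse = ", ")))
  print(x$qtl, digits = 3, row.names = FALSE)
  cat("\nFalse discovery rate:\n")
  print(x$fdr, digits = 3, row.names = FALSE)
  invisible(x)
}

# pull pooled (sexes combined) additive/dominance posterior means per
# detected QTL from the full-model fit, in detection order
full_model_estimates <- function(res) {
  det <- res$main$detected
  nq <- nrow(det)
  out <- list(a = rep(NA_real_, nq), d = rep(NA_real_, nq))
  if (!is.null(res$fit)) {
    fx <- res$fit$fixed
    for (k in seq_len(nq)) {
      out$a[k] <- fx$mean[fx$term == paste0("a_Q", k)]
      out$d[k] <- fx$mean[fx$term == paste0("d_Q", k)]
    }
  }
  out
}

# identify which true epistatic pair a detected pair corresponds to
match_epi_pair <- function(cfg, de, window_cM) {
  ep <- cfg$epistases
  q <- cfg$qtls
  for (l in seq_len(nrow(ep))) {
    qi <- q[q$id == ep$qtl_i[l], ]; qj <- q[q$id == ep$qtl_j[l], ]
    direct <- de$chrom_i == qi$chrom && abs(de$pos_i - qi$pos_cM) <= window_cM &&
      de$chrom_j == qj$chrom && abs(de$pos_j - qj$pos_cM) <= window_cM
    swapped <- de$chrom_i == qj$chrom && abs(de$pos_i - qj$pos_cM) <= window_cM &&
      de$chrom_j == qi$chrom && abs(de$pos_j - qi$pos_cM) <= window_cM
    if (direct || swapped) return(as.character(ep$id[l]))
  }
  NA_character_
}
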