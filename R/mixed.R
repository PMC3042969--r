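## Linear-model engine: Henderson III extra sums of squares, partial F,
## REML variance components, GLS fixed effects, AUP random-effect prediction
## and Gibbs sampling for posterior effect distributions.

RANK_TOL <- 1e-10  # relative tolerance of the pivoted rank computation

# orthonormal basis of the column space of X (n x rank), pivoted QR
orth_basis <- function(X) {
  if (is.null(X) || ncol(X) == 0) return(matrix(0, nrow(X), 0))
  qr_ <- qr(X, LAPACK = TRUE)
  d <- abs(diag(qr_$qr))
  rank <- sum(d > RANK_TOL * max(d, .Machine$double.eps))
  if (rank == 0) return(matrix(0, nrow(X), 0))
  qr.Q(qr_)[, seq_len(rank), drop = FALSE]
}

# basis of the part of `extra` orthogonal to the columns of Qred; columns
# whose residual is numerically zero relative to their original norm are
# dropped before the rank computation
extra_basis <- function(Qred, extra) {
  E <- extra - Qred %*% crossprod(Qred, extra)
  keep <- sqrt(colSums(E^2)) > 1e-8 * pmax(sqrt(colSums(extra^2)), 1)
  orth_basis(E[, keep, drop = FALSE])
}

#' Henderson III extra sum of squares
#'
#' Decomposes the phenotypic sum of squares into the extra sum of squares
#' attributable to the columns of `X_full` beyond those of `X_reduced`
#' (`SSR(Q|M) = y' (P_full - P_reduced) y`) and the full-model residual
#' (`SSE = y'(I - P_full) y`), with projectors computed through pivoted
#' orthogonal decompositions so that rank-deficient designs are handled.
#'
#' @param y Response vector.
#' @param X_full Full design matrix (must contain the reduced columns'
#'   span).
#' @param X_reduced Reduced design matrix (may have zero columns).
#' @return List with `ssr_extra`, `sse`, `rank_full`, `rank_reduced`.
#' @export
henderson3_extra_ss <- function(y, X_full, X_reduced) {
  y <- as.numeric(y)
  n <- length(y)
  Qr <- orth_basis(X_reduced)
  Qe <- extra_basis(Qr, X_full)
  rank_full <- ncol(Qr) + ncol(Qe)
  if (n <= rank_full) stop("degenerate design: n <= rank(X_full)", call. = FALSE)
  fr <- crossprod(Qr, y); fe <- crossprod(Qe, y)
  ssr_extra <- sum(fe^2)
  sse <- sum(y^2) - sum(fr^2) - ssr_extra
  list(ssr_extra = max(ssr_extra, 0), sse = max(sse, 0),
       rank_full = rank_full, rank_reduced = ncol(Qr))
}

#' Partial F statistic for nested designs
#'
#' The F statistic of the extra sum of squares of `X_full` over `X_reduced`:
#' `F = [SSR(Q|M)/df1] / [SSE/df2]` with `df1 = rank(X_full) -
#' rank(X_reduced)` and `df2 = n - rank(X_full)`. Equivalent to the
#' two-least-squares-fits nested-model F test; the extra sum of squares is
#' computed by the Henderson III quadratic-form decomposition.
#'
#' @inheritParams henderson3_extra_ss
#' @return List with `F`, `df1`, `df2`, `ssr_extra`, `sse`, `pvalue`.
#' @export
partial_f <- function(y, X_full, X_reduced) {
  h <- henderson3_extra_ss(y, X_full, X_reduced)
  df1 <- h$rank_full - h$rank_reduced
  df2 <- length(y) - h$rank_full
  if (df1 == 0) stop("undefined test: no extra degrees of freedom", call. = FALSE)
  denom <- h$sse / df2
  Fv <- if (denom <= .Machine$double.eps * sum(y^2)) Inf else (h$ssr_extra / df1) / denom
  list(F = Fv, df1 = df1, df2 = df2, ssr_extra = h$ssr_extra, sse = h$sse,
       pvalue = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

# V = sigma2_e I + sum_u sigma2_u U_u U_u'
build_V <- function(n, U_list, sigma2) {
  V <- diag(sigma2[length(sigma2)], n)
  for (u in seq_along(U_list)) {
    if (sigma2[u] > 0) V <- V + sigma2[u] * tcrossprod(U_list[[u]])
  }
  V
}

#' REML estimation of variance components
#'
#' Maximizes the restricted log-likelihood of the mixed model
#' `y = X b + sum_u U_u e_u + e`, `e_u ~ N(0, sigma2_u I)`, over the
#' log-variances using quasi-Newton optimization. Estimates are constrained
#' non-negative by the log parameterization; components driven to the lower
#' boundary are reported as (numerically) zero.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix.
#' @param U_list Named list of random-term coefficient matrices.
#' @param start Optional starting variances (one per random term plus the
#'   residual, in that order).
#' @return List with `sigma2` (named vector, residual last), `logLik`,
#'   `converged` and `counts`. Non-convergence is flagged, not an error.
#' @export
reml_components <- function(y, X, U_list, start = NULL) {
  y <- as.numeric(y); n <- length(y)
  if (!length(U_list)) stop("at least one random term is required", call. = FALSE)
  Qx <- orth_basis(X)
  if (n <= ncol(Qx)) stop("degenerate design: n <= rank(X)", call. = FALSE)
  r <- length(U_list)
  vy <- stats::var(y)
  if (is.null(start)) start <- rep(vy / (r + 1), r + 1)
  lb <- log(vy) - 25
  th0 <- pmax(log(start), lb + 1)
  G_list <- lapply(U_list, tcrossprod)

  # objective and analytic score share one evaluation, cached by parameter
  cache <- new.env(parent = emptyenv())
  evaluate <- function(th) {
    if (!is.null(cache$th) && identical(th, cache$th)) return(invisible())
    sigma2 <- exp(th)
    V <- diag(sigma2[r + 1], n)
    for (u in seq_len(r)) V <- V + sigma2[u] * G_list[[u]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) { cache$th <- th; cache$f <- 1e10; cache$g <- rep(0, r + 1); return(invisible()) }
    Vi <- chol2inv(ch)
    Vi_X <- Vi %*% Qx
    XtViX <- crossprod(Qx, Vi_X)
    ch2 <- chol(XtViX)
    W <- backsolve(ch2, forwardsolve(t(ch2), t(Vi_X)))
    P <- Vi - Vi_X %*% W
    Py <- drop(P %*% y)
    f <- 0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) + sum(y * Py))
    g <- numeric(r + 1)
    for (u in seq_len(r)) {
      g[u] <- 0.5 * sigma2[u] * (sum(P * G_list[[u]]) - drop(crossprod(Py, G_list[[u]] %*% Py)))
    }
    g[r + 1] <- 0.5 * sigma2[r + 1] * (sum(diag(P)) - sum(Py^2))
    cache$th <- th; cache$f <- f; cache$g <- g
    invisible()
  }
  fn <- function(th) { evaluate(th); cache$f }
  gr <- function(th) { evaluate(th); cache$g }
  fit <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                      lower = lb, upper = log(vy) + 12,
                      control = list(maxit = 200))
  sigma2 <- exp(fit$par)
  sigma2[fit$par <= lb + 1e-6] <- 0
  names(sigma2) <- c(names(U_list), "residual")
  list(sigma2 = sigma2, logLik = -fit$value, converged = fit$convergence == 0,
       counts = fit$counts)
}

#' Generalized least squares for the fixed effects
#'
#' Solves the generalized normal equations `X' V^-1 X b = X' V^-1 y`;
#' rank-deficient `X` is handled through the pseudo-inverse of the
#' generalized cross-product, and a near-singular `V` falls back to a
#' ridge-stabilized solve with a warning.
#'
#' @param y Response vector.
#' @param X Fixed design matrix (columns should be named).
#' @param V Phenotypic covariance matrix.
#' @return List with `b` (estimates), `cov` (their covariance) and `se`.
#' @export
gls_fixed <- function(y, X, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular V: using ridge-stabilized solve", call. = FALSE)
    ch <- chol(V + diag(1e-8 * mean(diag(V)), n))
  }
  Wy <- forwardsolve(t(ch), y)
  WX <- forwardsolve(t(ch), X)
  XtX <- crossprod(WX)
  sv <- svd(XtX)
  pos <- sv$d > RANK_TOL * max(sv$d)
  XtXi <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  b <- drop(XtXi %*% crossprod(WX, Wy))
  names(b) <- colnames(X)
  list(b = b, cov = XtXi, se = sqrt(pmax(diag(XtXi), 0)))
}

#' Adjusted unbiased prediction (AUP) of random effects
#'
#' Starts from the BLUP-type predictor `e_u = sigma2_u U_u' V^-1 (y - X b)`
#' and applies the adjusted-unbiased scaling: within each term the predicted
#' levels are centred and rescaled so that their empirical variance matches
#' the estimated variance component. Predictions of a two-level term
#' therefore sum to zero by construction.
#'
#' @param y Response vector.
#' @param X Fixed design matrix.
#' @param U_list Named list of random-term coefficient matrices.
#' @param V Phenotypic covariance.
#' @param sigma2 Variance components (random terms then residual), e.g. from
#'   [reml_components()].
#' @param b Optional fixed-effect estimates; computed by [gls_fixed()] if
#'   missing.
#' @return Named list of predicted random-effect vectors.
#' @export
aup_random <- function(y, X, U_list, V, sigma2, b = NULL) {
  if (is.null(b)) b <- gls_fixed(y, X, V)$b
  resid <- y - X %*% b
  ch <- chol(V)
  Vi_r <- backsolve(ch, forwardsolve(t(ch), resid))
  out <- vector("list", length(U_list))
  names(out) <- names(U_list)
  for (u in seq_along(U_list)) {
    e <- drop(sigma2[u] * crossprod(U_list[[u]], Vi_r))
    q <- length(e)
    if (q > 1) {
      e <- e - mean(e)
      s <- stats::sd(e)
      if (s > 0 && sigma2[u] > 0) e <- e * sqrt(sigma2[u]) / s
    }
    out[[u]] <- e
  }
  out
}

#' Gibbs sampling for the mixed model
#'
#' Samples the joint posterior of the fixed effects, random effects and
#' variance components of `y = X b + sum_u U_u e_u + e` under a flat prior
#' on `b` and weakly informative scaled-inverse-chi-square priors on the
#' variances. Conditionals are normal for effects and scaled-inverse-
#' chi-square for variances. Each effect is summarized by its posterior mean
#' and SD, and tested by `t = mean/SD` against a Student-t reference.
#'
#' The package's random terms are all sex-structured: their levels come in
#' pairs (one level per sex) constrained to sum to zero, which also keeps
#' the sampler identified against the fixed intercept. With
#' `zero_sum = TRUE` (the default) each sampled random-effect vector is
#' projected onto that constraint (consecutive level pairs for
#' even-dimensional terms, the global mean otherwise) and the variance
#' conditionals use the correspondingly reduced degrees of freedom.
#'
#' @param y Response vector.
#' @param X Fixed design matrix with named columns.
#' @param U_list Named list of random-term coefficient matrices.
#' @param init List with elements `b`, `e` (list), `sigma2`, typically from
#'   REML/GLS/AUP (see [fit_mixed_model()]); missing parts are filled with
#'   neutral defaults.
#' @param n_iter,burn_in Chain length and burn-in (`n_iter > burn_in`).
#' @param seed Integer seed for reproducible chains.
#' @param prior_nu,prior_s2 Scaled-inverse-chi-square hyperparameters shared
#'   by all variance components (weakly informative defaults).
#' @param zero_sum Constrain random-effect levels to sum to zero within sex
#'   pairs (see Details).
#' @return A `fit_report` list: `fixed` (data frame with mean, sd, t,
#'   pvalue, significant), `random` (data frame per level),
#'   `variance_components`, `diagnostics`.
#' @export
gibbs_estimate <- function(y, X, U_list, init = NULL, n_iter = 11000,
                           burn_in = 1000, seed = NULL,
                           prior_nu = 0.002, prior_s2 = 1, zero_sum = TRUE) {
  stopifnot(n_iter > burn_in)
  if (!is.null(seed)) set.seed(seed)
  y <- as.numeric(y); n <- length(y)
  p <- ncol(X)
  r <- length(U_list)
  qs <- vapply(U_list, ncol, 1L)
  vy <- stats::var(y)
  cap <- 1e6 * vy  # divergence guard on variance samples

  b <- if (!is.null(init$b)) init$b else rep(0, p)
  e <- if (!is.null(init$e)) init$e else lapply(U_list, function(U) rep(0, ncol(U)))
  sigma2 <- if (!is.null(init$sigma2)) pmax(init$sigma2, 1e-6 * vy) else
    rep(vy / (r + 1), r + 1)

  # precompute fixed-effect solve (X may be rank deficient -> pseudo-inverse)
  sv <- svd(crossprod(X))
  pos <- sv$d > RANK_TOL * max(sv$d)
  XtXi <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  XtXi_h <- sweep(sv$v[, pos, drop = FALSE], 2, sqrt(sv$d[pos]), "/")
  UtU <- lapply(U_list, crossprod)
  blocks <- lapply(U_list, function(U) {
    q <- ncol(U)
    if (!zero_sum) return(NULL)
    if (q %% 2 == 0) split(seq_len(q), rep(seq_len(q / 2), each = 2)) else
      list(seq_len(q))
  })
  free_df <- if (zero_sum) qs - vapply(blocks, length, 0L) else qs
  free_df <- pmax(free_df, 1L)

  keep <- n_iter - burn_in
  sum_b <- rep(0, p); ssq_b <- rep(0, p)
  sum_e <- lapply(qs, numeric); ssq_e <- lapply(qs, numeric)
  sum_v <- rep(0, r + 1); ssq_v <- rep(0, r + 1)
  capped <- FALSE

  for (it in seq_len(n_iter)) {
    # fixed effects | rest
    resid_f <- y
    for (u in seq_len(r)) resid_f <- resid_f - U_list[[u]] %*% e[[u]]
    bhat <- XtXi %*% crossprod(X, resid_f)
    b <- drop(bhat + sqrt(sigma2[r + 1]) * (XtXi_h %*% rnorm(sum(pos))))
    base <- y - X %*% b
    # random effects | rest (blockwise per term)
    for (u in seq_len(r)) {
      resid_u <- base
      for (v in seq_len(r)) if (v != u) resid_u <- resid_u - U_list[[v]] %*% e[[v]]
      Prec <- UtU[[u]] / sigma2[r + 1] + diag(1 / sigma2[u], qs[u])
      chP <- chol(Prec)
      mu_u <- backsolve(chP, forwardsolve(t(chP), crossprod(U_list[[u]], resid_u) / sigma2[r + 1]))
      e[[u]] <- drop(mu_u + backsolve(chP, rnorm(qs[u])))
      if (!is.null(blocks[[u]])) {
        for (blk in blocks[[u]]) e[[u]][blk] <- e[[u]][blk] - mean(e[[u]][blk])
      }
      # variance of term u | e_u
      ssu <- sum(e[[u]]^2)
      sigma2[u] <- (prior_nu * prior_s2 + ssu) /
        stats::rchisq(1, df = prior_nu + free_df[u])
      if (sigma2[u] > cap) { sigma2[u] <- cap; capped <- TRUE }
    }
    # residual variance
    resid <- base
    for (u in seq_len(r)) resid <- resid - U_list[[u]] %*% e[[u]]
    sigma2[r + 1] <- (prior_nu * prior_s2 + sum(resid^2)) /
      stats::rchisq(1, df = prior_nu + n)
    if (sigma2[r + 1] > cap) { sigma2[r + 1] <- cap; capped <- TRUE }

    if (it > burn_in) {
      sum_b <- sum_b + b; ssq_b <- ssq_b + b^2
      for (u in seq_len(r)) {
        sum_e[[u]] <- sum_e[[u]] + e[[u]]; ssq_e[[u]] <- ssq_e[[u]] + e[[u]]^2
      }
      sum_v <- sum_v + sigma2; ssq_v <- ssq_v + sigma2^2
    }
  }

  post <- function(s, ss) {
    m <- s / keep
    sd <- sqrt(pmax(ss / keep - m^2, 0) * keep / (keep - 1))
    list(mean = m, sd = sd)
  }
  pb <- post(sum_b, ssq_b)
  tdf <- n - sum(pos)
  tval <- ifelse(pb$sd > 0, pb$mean / pb$sd, Inf * sign(pb$mean))
  fixed <- data.frame(term = colnames(X), mean = pb$mean, sd = pb$sd, t = tval,
                      pvalue = 2 * stats::pt(-abs(tval), df = tdf),
                      stringsAsFactors = FALSE)
  fixed$significant <- fixed$pvalue < 0.05

  random <- do.call(rbind, lapply(seq_len(r), function(u) {
    pe <- post(sum_e[[u]], ssq_e[[u]])
    lv <- colnames(U_list[[u]])
    if (is.null(lv)) lv <- paste0(names(U_list)[u], seq_len(qs[u]))
    tv <- ifelse(pe$sd > 0, pe$mean / pe$sd, 0)
    data.frame(term = names(U_list)[u], level = lv, mean = pe$mean, sd = pe$sd,
               t = tv, pvalue = 2 * stats::pt(-abs(tv), df = tdf),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(random)) random$significant <- random$pvalue < 0.05
  pv <- post(sum_v, ssq_v)
  vc <- data.frame(term = c(names(U_list), "residual"),
                   mean = pv$mean, sd = pv$sd, stringsAsFactors = FALSE)
  structure(list(fixed = fixed, random = random, variance_components = vc,
                 diagnostics = list(n_iter = n_iter, burn_in = burn_in,
                                    seed = seed, capped = capped)),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Mixed-model fit (Gibbs posterior summaries)\n\nFixed effects:\n")
  print(x$fixed, digits = 3, row.names = FALSE)
  cat("\nVariance components:\n")
  print(x$variance_components, digits = 3, row.names = FALSE)
  invisible(x)
}

#' REML + GLS + AUP fit, used to initialize the Gibbs sampler
#'
#' Convenience wrapper running [reml_components()], [gls_fixed()] and
#' [aup_random()] and returning an `init` list suitable for
#' [gibbs_estimate()].
#'
#' @inheritParams reml_components
#' @return List with `b`, `e`, `sigma2`, `reml`.
#' @export
fit_mixed_model <- function(y, X, U_list) {
  reml <- reml_components(y, X, U_list)
  V <- build_V(length(y), U_list, reml$sigma2)
  g <- gls_fixed(y, X, V)
  e <- aup_random(y, X, U_list, V, reml$sigma2, b = g$b)
  list(b = g$b, e = e, sigma2 = reml$sigma2, reml = reml)
}
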