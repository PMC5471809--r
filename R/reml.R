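# restricted log-likelihood of y = 1*mu + a + e, V = va*G + ve*I, in the
# eigenbasis of G: lam_i = va*d_i + ve. Constant terms dropped.
reml_loglik_uni <- function(va, ve, d, y_t, x_t) {
  lam <- va * d + ve
  if (any(lam <= 0)) return(-Inf)
  xvx <- sum(x_t^2 / lam)
  xvy <- sum(x_t * y_t / lam)
  yvy <- sum(y_t^2 / lam)
  ypy <- yvy - xvy^2 / xvx
  -0.5 * (sum(log(lam)) + log(xvx) + ypy)
}

#' Univariate REML variance components on a genomic relationship matrix
#'
#' Fits the animal model `y = 1*mu + a + e` with `V(a) = G * sigma_a2` and
#' `V(e) = I * sigma_e2` by restricted maximum likelihood. The likelihood
#' is diagonalized by a single eigendecomposition of `G`, then the
#' variance ratio is maximized exactly on the profiled restricted
#' likelihood (grid bracketing + golden-section refinement), so each
#' candidate ratio costs O(n). Heritability is
#' `h2 = sigma_a2 / (sigma_a2 + sigma_e2)`; standard errors come from the
#' observed information of the restricted likelihood (delta method for
#' `h2`).
#'
#' @param y_adj An [adjust_phenotypes()] result (or any data frame with
#'   `id` and `y_adj`).
#' @param grm A [build_grm()] result covering the phenotyped IDs.
#' @return Object of class `varcomp`; see [tidy.varcomp()] and
#'   [glance.varcomp()].
#' @examples
#' cfg <- sim_config(n_individuals = 150, n_chromosomes = 1,
#'                   snps_per_chrom = 200, n_qtl = 20, target_h2 = 0.5)
#' g <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(g, cfg)
#' fit <- reml_univariate(adjust_phenotypes(sim$traits, "y"), build_grm(g))
#' glance(fit)
#' @export
reml_univariate <- function(y_adj, grm) {
  stopifnot(inherits(grm, "grm_matrix"))
  idx <- align_ids(y_adj$id, grm$ids, "GRM")
  y <- y_adj$y_adj
  n <- length(y)
  if (n < 30) stop("need at least 30 phenotyped individuals", call. = FALSE)

  ev <- grm_eigen(grm$G[idx, idx, drop = FALSE])
  U <- ev$vectors
  d <- ev$values
  y_t <- drop(crossprod(U, y))
  x_t <- drop(crossprod(U, rep(1, n)))
  vp <- var(y)

  # profile REML over log variance ratio delta = va/ve
  prof <- function(log_delta) {
    delta <- exp(log_delta)
    lam0 <- delta * d + 1
    xvx <- sum(x_t^2 / lam0)
    xvy <- sum(x_t * y_t / lam0)
    ypy <- sum(y_t^2 / lam0) - xvy^2 / xvx
    ve <- ypy / (n - 1)
    -0.5 * (sum(log(lam0)) + (n - 1) * log(ve) + log(xvx) + (n - 1))
  }
  grid <- seq(-10, 10, length.out = 81)
  vals <- vapply(grid, prof, numeric(1))
  best <- which.max(vals)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- optimise(prof, c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  boundary <- opt$maximum <= -10 + 1e-6 || opt$maximum >= 10 - 1e-6

  lam0 <- delta * d + 1
  xvx <- sum(x_t^2 / lam0)
  xvy <- sum(x_t * y_t / lam0)
  ypy <- sum(y_t^2 / lam0) - xvy^2 / xvx
  ve <- ypy / (n - 1)
  va <- delta * ve
  floor_v <- 1e-8 * vp
  va <- max(va, floor_v)
  ve <- max(ve, floor_v)
  h2 <- va / (va + ve)
  mu <- xvy / xvx

  ll <- function(theta) reml_loglik_uni(theta[1], theta[2], d, y_t, x_t)
  se <- se_from_loglik(ll, c(va, ve))
  # delta method for h2 = va/(va+ve)
  h2_se <- NA_real_
  H <- tryCatch(num_hessian(ll, c(va, ve)), error = function(e) NULL)
  if (!is.null(H)) {
    covm <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(covm)) {
      grad <- c(ve, -va) / (va + ve)^2
      v <- drop(t(grad) %*% covm %*% grad)
      if (is.finite(v) && v > 0) h2_se <- sqrt(v)
    }
  }

  structure(list(
    traits = attr(y_adj, "trait") %||% "y",
    sigma_a2 = va, sigma_e2 = ve, h2 = h2, mu = mu,
    se = c(sigma_a2 = se[1], sigma_e2 = se[2], h2 = h2_se),
    loglik = ll(c(va, ve)), n = n,
    converged = !boundary,
    eigen = ev, perm = idx, y_t = y_t, x_t = x_t
  ), class = "varcomp")
}

# -2 * restricted log-likelihood for two traits in the eigenbasis of G;
# A, E are the 2x2 genetic / residual covariance matrices
reml_neg2ll_biv <- function(A, E, d, Y_t, x_t) {
  v11 <- A[1, 1] * d + E[1, 1]
  v12 <- A[1, 2] * d + E[1, 2]
  v22 <- A[2, 2] * d + E[2, 2]
  det_i <- v11 * v22 - v12^2
  if (any(det_i <= 0)) return(Inf)
  i11 <- v22 / det_i; i12 <- -v12 / det_i; i22 <- v11 / det_i
  x2 <- x_t^2
  # X'V^{-1}X (2x2), X = blockdiag(1, 1) transformed
  a11 <- sum(x2 * i11); a12 <- sum(x2 * i12); a22 <- sum(x2 * i22)
  b1 <- sum(x_t * (i11 * Y_t[, 1] + i12 * Y_t[, 2]))
  b2 <- sum(x_t * (i12 * Y_t[, 1] + i22 * Y_t[, 2]))
  det_a <- a11 * a22 - a12^2
  if (det_a <= 0) return(Inf)
  mu1 <- (a22 * b1 - a12 * b2) / det_a
  mu2 <- (a11 * b2 - a12 * b1) / det_a
  r1 <- Y_t[, 1] - x_t * mu1
  r2 <- Y_t[, 2] - x_t * mu2
  quad <- sum(i11 * r1^2 + 2 * i12 * r1 * r2 + i22 * r2^2)
  sum(log(det_i)) + log(det_a) + quad
}

#' Bivariate REML for genetic correlation
#'
#' Pairwise bivariate animal model for two traits sharing the genomic
#' relationship matrix: genetic effects have covariance `A (x) G` and
#' residuals `E (x) I`, with `A`, `E` the 2x2 trait covariance matrices.
#' The restricted likelihood is evaluated in the eigenbasis of `G` (2x2
#' blocks per eigenvalue) and maximized over a log-Cholesky
#' parameterisation of `(A, E)` by Nelder-Mead, started from the
#' univariate fits. The genetic correlation is
#' `r_g = sigma_a12 / sqrt(sigma_a1^2 * sigma_a2^2)` (clamped to
#' `[-1, 1]`), and the phenotypic correlation comes from the summed
#' components.
#'
#' @param y1,y2 [adjust_phenotypes()] results for the two traits;
#'   individuals present in both (and in the GRM) are analyzed.
#' @param grm A [build_grm()] result.
#' @return Object of class `varcomp` with bivariate fields
#'   (`sigma_a12`, `r_g`, `r_p`, per-trait `h2`).
#' @export
reml_bivariate <- function(y1, y2, grm) {
  stopifnot(inherits(grm, "grm_matrix"))
  common <- intersect(intersect(y1$id, y2$id), grm$ids)
  if (length(common) < 30)
    stop("need at least 30 individuals phenotyped for both traits",
         call. = FALSE)
  v1 <- y1$y_adj[match(common, y1$id)]
  v2 <- y2$y_adj[match(common, y2$id)]
  idx <- match(common, grm$ids)
  n <- length(common)

  ev <- grm_eigen(grm$G[idx, idx, drop = FALSE])
  U <- ev$vectors
  d <- ev$values
  Y_t <- crossprod(U, cbind(v1, v2))
  x_t <- drop(crossprod(U, rep(1, n)))

  # starting values from univariate fits
  sub1 <- y1[match(common, y1$id), ]; attr(sub1, "trait") <- attr(y1, "trait")
  sub2 <- y2[match(common, y2$id), ]; attr(sub2, "trait") <- attr(y2, "trait")
  f1 <- reml_univariate(sub1, grm)
  f2 <- reml_univariate(sub2, grm)
  start_cov_a <- 0.5 * sqrt(f1$sigma_a2 * f2$sigma_a2)
  start_cov_e <- 0.5 * cor(v1, v2) * sqrt(f1$sigma_e2 * f2$sigma_e2)

  chol_par <- function(S) {
    L <- t(chol(S))
    c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  }
  par_chol <- function(p) {
    L <- matrix(c(exp(p[1]), p[2], 0, exp(p[3])), 2, 2)
    tcrossprod(L)
  }
  make_psd <- function(a1, a12, a2) {
    S <- matrix(c(a1, a12, a12, a2), 2, 2)
    if (a12^2 >= 0.98 * a1 * a2) S[1, 2] <- S[2, 1] <- sign(a12) * 0.9 * sqrt(a1 * a2)
    S
  }
  start <- c(chol_par(make_psd(f1$sigma_a2, start_cov_a, f2$sigma_a2)),
             chol_par(make_psd(f1$sigma_e2, start_cov_e, f2$sigma_e2)))

  obj <- function(p) {
    reml_neg2ll_biv(par_chol(p[1:3]), par_chol(p[4:6]), d, Y_t, x_t)
  }
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-12))
  opt <- optim(opt$par, obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-12))
  A <- par_chol(opt$par[1:3])
  E <- par_chol(opt$par[4:6])

  r_g <- A[1, 2] / sqrt(A[1, 1] * A[2, 2])
  if (abs(r_g) > 1) {
    if (abs(r_g) < 1.01)
      warning("genetic correlation overshoot clamped to [-1, 1]", call. = FALSE)
    r_g <- sign(r_g) * 1
  }
  P <- A + E
  r_p <- P[1, 2] / sqrt(P[1, 1] * P[2, 2])

  theta <- c(A[1, 1], A[1, 2], A[2, 2], E[1, 1], E[1, 2], E[2, 2])
  ll <- function(th) {
    Am <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2)
    Em <- matrix(c(th[4], th[5], th[5], th[6]), 2, 2)
    -0.5 * reml_neg2ll_biv(Am, Em, d, Y_t, x_t)
  }
  se <- se_from_loglik(ll, theta)

  structure(list(
    traits = c(attr(y1, "trait") %||% "y1", attr(y2, "trait") %||% "y2"),
    A = A, E = E,
    sigma_a2 = c(A[1, 1], A[2, 2]), sigma_a12 = A[1, 2],
    sigma_e2 = c(E[1, 1], E[2, 2]), sigma_e12 = E[1, 2],
    h2 = c(A[1, 1] / (A[1, 1] + E[1, 1]), A[2, 2] / (A[2, 2] + E[2, 2])),
    r_g = r_g, r_p = r_p,
    se = setNames(se, c("sigma_a2_1", "sigma_a12", "sigma_a2_2",
                        "sigma_e2_1", "sigma_e12", "sigma_e2_2")),
    loglik = -0.5 * opt$value, n = n,
    converged = opt$convergence == 0
  ), class = c("varcomp_biv", "varcomp"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Heritability from a variance-component pair
#'
#' `h2 = sigma_a2 / (sigma_a2 + sigma_e2)`.
#'
#' @param sigma_a2 Additive genetic variance.
#' @param sigma_e2 Residual variance.
#' @return Numeric heritability.
#' @examples
#' heritability(0.0694, 0.0599)  # 0.54 at 2 dp
#' @export
heritability <- function(sigma_a2, sigma_e2) {
  stopifnot(sigma_a2 >= 0, sigma_e2 >= 0, sigma_a2 + sigma_e2 > 0)
  sigma_a2 / (sigma_a2 + sigma_e2)
}

#' @export
print.varcomp <- function(x, ...) {
  if (inherits(x, "varcomp_biv")) {
    cat("<varcomp bivariate> traits ", paste(x$traits, collapse = " / "),
        ": h2 = (", round(x$h2[1], 3), ", ", round(x$h2[2], 3),
        "), r_g = ", round(x$r_g, 3), ", r_p = ", round(x$r_p, 3), "\n",
        sep = "")
  } else {
    cat("<varcomp> trait ", x$traits, ": sigma_a2 = ", signif(x$sigma_a2, 4),
        ", sigma_e2 = ", signif(x$sigma_e2, 4), ", h2 = ", round(x$h2, 3),
        "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a variance-component fit
#'
#' @param x A `varcomp` object.
#' @param ... Unused.
#' @return Tibble with one row per estimated component (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.varcomp <- function(x, ...) {
  if (inherits(x, "varcomp_biv")) {
    tibble::tibble(
      term = c("sigma_a2_1", "sigma_a12", "sigma_a2_2",
               "sigma_e2_1", "sigma_e12", "sigma_e2_2",
               "h2_1", "h2_2", "r_g", "r_p"),
      estimate = c(x$sigma_a2[1], x$sigma_a12, x$sigma_a2[2],
                   x$sigma_e2[1], x$sigma_e12, x$sigma_e2[2],
                   x$h2, x$r_g, x$r_p),
      std.error = c(unname(x$se), rep(NA_real_, 4)))
  } else {
    tibble::tibble(
      term = c("sigma_a2", "sigma_e2", "h2"),
      estimate = c(x$sigma_a2, x$sigma_e2, x$h2),
      std.error = unname(x$se))
  }
}

#' One-row summary of a variance-component fit
#'
#' @param x A `varcomp` object.
#' @param ... Unused.
#' @return One-row tibble (`h2` or `r_g` and companions, `logLik`, `n`,
#'   `converged`).
#' @export
glance.varcomp <- function(x, ...) {
  if (inherits(x, "varcomp_biv")) {
    tibble::tibble(h2_1 = x$h2[1], h2_2 = x$h2[2], r_g = x$r_g, r_p = x$r_p,
                   logLik = x$loglik, n = x$n, converged = x$converged)
  } else {
    tibble::tibble(h2 = x$h2, sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2,
                   logLik = x$loglik, n = x$n, converged = x$converged)
  }
}
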