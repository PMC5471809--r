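# central-difference Hessian of a scalar function; step scaled per coordinate
num_hessian <- function(f, x, rel_step = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x), 1) * rel_step
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# standard errors from the observed information of a log-likelihood
se_from_loglik <- function(loglik, theta) {
  H <- tryCatch(num_hessian(loglik, theta), error = function(e) NULL)
  if (is.null(H)) return(rep(NA_real_, length(theta)))
  info <- -H
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) return(rep(NA_real_, length(theta)))
  d <- diag(cov)
  d[!is.finite(d) | d <= 0] <- NA_real_
  sqrt(d)
}

align_ids <- function(target_ids, have_ids, what) {
  idx <- match(target_ids, have_ids)
  if (anyNA(idx))
    stop("alignment error: ", what, " missing ", sum(is.na(idx)), " id(s)",
         call. = FALSE)
  idx
}
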