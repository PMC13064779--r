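## Independent brute-force oracles: dense-grid numerical integration,
## written without reference to the package's quadrature code paths.

## Trapezoid-style marginal loglik for a unidimensional 2PL:
## sum_i log sum_t w(t) prod_j p_j(t)^y (1-p_j(t))^(1-y), y matrix n x J.
oracle_loglik_uni <- function(y, slope, intercept, npts = 20001) {
  tg <- seq(-10, 10, length.out = npts)
  w <- dnorm(tg)
  w <- w / sum(w)
  sum(apply(y, 1L, function(r) {
    p <- plogis(outer(slope, tg) + intercept)
    ll <- colSums(r * log(p) + (1 - r) * log(1 - p), na.rm = TRUE)
    log(sum(exp(ll) * w))
  }))
}

## Dense 2-D grid marginal loglik for a one-domain bifactor toy:
## latents (theta0, theta_s) independent standard normal.
oracle_loglik_bifactor1 <- function(y, a0, as_, intercept, npts = 501) {
  tg <- seq(-8, 8, length.out = npts)
  w <- dnorm(tg)
  w <- w / sum(w)
  sum(apply(y, 1L, function(r) {
    tot <- 0
    for (qi in seq_along(tg)) {
      p <- plogis(outer(as_, tg) + a0 * tg[qi] + intercept)
      ll <- colSums(r * log(p) + (1 - r) * log(1 - p), na.rm = TRUE)
      tot <- tot + w[qi] * sum(exp(ll) * w)
    }
    log(tot)
  }))
}

## Dense 2-D grid marginal loglik for a 2-factor correlated toy; item j
## loads slope[j] on factor dom[j] (1 or 2), latent corr rho.
oracle_loglik_corr2 <- function(y, slope, intercept, dom, rho, npts = 501) {
  tg <- seq(-8, 8, length.out = npts)
  dens <- function(x, yv) {
    exp(-(x^2 - 2 * rho * x * yv + yv^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
  }
  W <- outer(tg, tg, dens)
  W <- W / sum(W)
  sum(apply(y, 1L, function(r) {
    tot <- 0
    for (qi in seq_along(tg)) {
      th <- rbind(tg[qi], tg)[dom, , drop = FALSE]   # J x npts
      p <- plogis(th * slope + intercept)
      ll <- colSums(r * log(p) + (1 - r) * log(1 - p), na.rm = TRUE)
      tot <- tot + sum(exp(ll) * W[qi, ])
    }
    log(tot)
  }))
}

## Dense-grid posterior mean of theta for the one-domain testlet model with
## item parameters and testlet SD fixed: posterior over (theta, gamma).
oracle_testlet_eap <- function(yrow, a, b, sigma_d, npts = 401) {
  tg <- seq(-8, 8, length.out = npts)
  gg <- seq(-8 * max(sigma_d, 0.05), 8 * max(sigma_d, 0.05),
            length.out = npts)
  wt <- dnorm(tg)
  wg <- dnorm(gg, 0, sigma_d)
  post <- matrix(0, npts, npts)
  for (qi in seq_along(tg)) {
    pm <- plogis(vapply(gg, function(g) a * (tg[qi] - b - g),
                        numeric(length(a))))   # items x gamma grid
    ll <- colSums(yrow * log(pm) + (1 - yrow) * log(1 - pm), na.rm = TRUE)
    post[qi, ] <- wt[qi] * wg * exp(ll)
  }
  sum(rowSums(post) * tg) / sum(post)
}

## Dense-grid GRM marginal loglik; pars: list of list(a, b) per item.
oracle_grm_loglik <- function(y, pars, npts = 20001) {
  tg <- seq(-10, 10, length.out = npts)
  w <- dnorm(tg)
  w <- w / sum(w)
  sum(apply(cbind(seq_len(nrow(y))), 1L, function(i) {
    ll <- rep(0, length(tg))
    for (j in seq_along(pars)) {
      k <- y[i, j]
      if (is.na(k)) next
      cum <- cbind(1, plogis(outer(tg, pars[[j]]$b,
                                   function(t, bb) pars[[j]]$a * (t - bb))), 0)
      pr <- cum[, k + 1L] - cum[, k + 2L]
      ll <- ll + log(pr)
    }
    log(sum(exp(ll) * w))
  }))
}

## Dense-grid GRM EAP for one person.
oracle_grm_eap <- function(yrow, pars, npts = 20001) {
  tg <- seq(-10, 10, length.out = npts)
  w <- dnorm(tg)
  ll <- rep(0, length(tg))
  for (j in seq_along(pars)) {
    k <- yrow[j]
    if (is.na(k)) next
    cum <- cbind(1, plogis(outer(tg, pars[[j]]$b,
                                 function(t, bb) pars[[j]]$a * (t - bb))), 0)
    ll <- ll + log(cum[, k + 1L] - cum[, k + 2L])
  }
  post <- w * exp(ll)
  sum(post * tg) / sum(post)
}

## Batch-means Monte Carlo standard error of a chain's mean.
mcse_batch <- function(x, n_batch = 30L) {
  nb <- min(n_batch, floor(length(x) / 10))
  bm <- colMeans(matrix(x[seq_len(nb * floor(length(x) / nb))],
                        nrow = floor(length(x) / nb)))
  sd(bm) / sqrt(nb)
}

## Tibble wrapper for a plain response matrix.
as_resp_tbl <- function(y) {
  if (is.null(rownames(y))) rownames(y) <- sprintf("p%03d", seq_len(nrow(y)))
  if (is.null(colnames(y))) colnames(y) <- sprintf("i%02d", seq_len(ncol(y)))
  dplyr::bind_cols(tibble::tibble(person_id = rownames(y)),
                   tibble::as_tibble(as.data.frame(y)))
}
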