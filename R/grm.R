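## Graded response model (ordinal IRT) for the 10-item clinician severity
## scale: category probabilities, marginal-ML fitting by EM with
## Gauss-Hermite quadrature, information-matrix standard errors, and EAP
## person scores with posterior SDs.

#' Graded-response category probabilities
#'
#' Cumulative-logit model: `P(Y >= k) = plogis(a * (theta - b_k))` with
#' `P(Y >= 0) = 1` and `P(Y >= K) = 0`; category probabilities are the
#' successive differences and always sum to one.
#'
#' @param a Item discrimination (> 0).
#' @param thresholds Ordered category thresholds `b_1 <= ... <= b_{K-1}`.
#' @param theta Vector of latent trait values.
#' @return Matrix `length(theta)` x `K` of category probabilities.
#' @export
#' @examples
#' grm_category_probs(1, c(-1, 0, 1, 2), 0)
grm_category_probs <- function(a, thresholds, theta) {
  if (a <= 0) abort("discrimination a must be positive")
  if (is.unsorted(thresholds)) abort("thresholds must be non-decreasing")
  cum <- cbind(1, plogis(outer(theta, thresholds, function(t, b) a * (t - b))), 0)
  pr <- cum[, -ncol(cum), drop = FALSE] - cum[, -1, drop = FALSE]
  colnames(pr) <- paste0("k", seq_len(ncol(pr)) - 1L)
  pr
}

#' Fit a graded response model
#'
#' Marginal maximum likelihood by EM with Gauss-Hermite quadrature over a
#' standard-normal latent trait. Cells coded `NA` (scale not administered)
#' are skipped in the likelihood. Rating categories never observed for an
#' item are merged downward onto the next lower observed category, with the
#' remapping recorded on the result; items with fewer than two observed
#' categories are dropped with a warning. Standard errors come from the
#' outer-product (BHHH) estimate of the observed information of the
#' marginal likelihood.
#'
#' @param sev Severity tibble (`person_id` + ordinal item columns).
#' @param nodes Number of quadrature nodes (default 41).
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param se Compute standard errors (default TRUE).
#' @return An object of class `ocd_grm`: list with `items` (tibble of `a`,
#'   `se_a`, `b1`-`b4` and their SEs), `loglik`, `npar`, `AIC`, `BIC`,
#'   `n_persons`, `converged`, `iterations`, `remap`.
#' @export
fit_grm <- function(sev, nodes = 41L, max_iter = 500L, tol = 1e-5,
                    se = TRUE) {
  m <- resp_matrix(sev)
  keep <- vapply(seq_len(ncol(m)), function(j) {
    length(unique(m[!is.na(m[, j]), j])) >= 2L
  }, logical(1))
  if (!all(keep)) {
    warn(paste0("dropping item(s) with < 2 observed categories: ",
                paste(colnames(m)[!keep], collapse = ", ")))
    m <- m[, keep, drop = FALSE]
  }
  if (ncol(m) == 0L) abort("no fittable items")
  coll <- collapse_categories(m)
  y <- coll$y                      # collapsed 0-based categories, NA kept
  ncat <- coll$ncat
  gh <- gh_normal(nodes)
  J <- ncol(y)
  ## starting values: a = 1, thresholds from marginal cumulative proportions
  pars <- lapply(seq_len(J), function(j) {
    v <- y[!is.na(y[, j]), j]
    pg <- vapply(seq_len(ncat[j] - 1L),
                 function(k) mean(v >= k), numeric(1))
    pg <- pmin(pmax(pg, 1e-3), 1 - 1e-3)
    list(a = 1, b = sort(-qlogis(pg)))
  })
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    es <- grm_estep(y, pars, gh)
    if (es$loglik < ll_old - 1e-8) {
      warn("EM step decreased the marginal log-likelihood")
    }
    if (abs(es$loglik - ll_old) < tol || iter >= max_iter) {
      converged <- abs(es$loglik - ll_old) < tol
      ll <- es$loglik
      break
    }
    ll_old <- es$loglik
    for (j in seq_len(J)) {
      r <- vapply(seq_len(ncat[j]) - 1L, function(k) {
        colSums(es$post[which(y[, j] == k), , drop = FALSE])
      }, numeric(length(gh$x)))           # Q x K expected counts
      pars[[j]] <- grm_mstep_item(t(r), pars[[j]], gh$x)
    }
  }
  npar <- sum(ncat)                       # a + (ncat-1) thresholds per item
  items <- purrr::map2_dfr(pars, seq_len(J), function(p, j) {
    b <- rep(NA_real_, 4L)
    b[seq_along(p$b)] <- p$b
    tibble::tibble(item_id = colnames(y)[j], a = p$a,
                   b1 = b[1], b2 = b[2], b3 = b[3], b4 = b[4])
  })
  fit <- structure(list(items = items, pars = pars, ncat = ncat,
                        remap = coll$remap, loglik = ll, npar = npar,
                        AIC = -2 * ll + 2 * npar,
                        BIC = -2 * ll + npar * log(nrow(y)),
                        n_persons = nrow(y), converged = converged,
                        iterations = iter, nodes = nodes,
                        item_ids = colnames(y)),
                   class = "ocd_grm")
  if (se) fit <- add_grm_ses(fit, y, gh)
  fit
}

## Merge unobserved categories downward; returns collapsed matrix, number
## of categories per item, and the value remapping per item.
collapse_categories <- function(m) {
  remap <- list()
  y <- m
  ncat <- integer(ncol(m))
  for (j in seq_len(ncol(m))) {
    obs <- sort(unique(m[!is.na(m[, j]), j]))
    v <- m[, j]
    cj <- findInterval(v, obs) - 1L
    cj[!is.na(cj) & cj < 0L] <- 0L
    y[, j] <- cj
    ncat[j] <- length(obs)
    remap[[colnames(m)[j]]] <- setNames(seq_along(obs) - 1L,
                                        as.character(obs))
  }
  list(y = y, ncat = ncat, remap = remap)
}

## E-step: person x node posterior weights and total marginal loglik.
grm_estep <- function(y, pars, gh) {
  n <- nrow(y); Q <- length(gh$x)
  ll <- matrix(0, n, Q)
  for (j in seq_along(pars)) {
    lp <- log(clamp_p(grm_category_probs(pars[[j]]$a, pars[[j]]$b, gh$x)))
    obs <- which(!is.na(y[, j]))
    ll[obs, ] <- ll[obs, ] + t(lp[, y[obs, j] + 1L, drop = FALSE])
  }
  lw <- sweep(ll, 2L, log(gh$w), "+")
  li <- row_logsumexp(lw)
  post <- exp(lw - li)
  list(post = post, loglik = sum(li))
}

## M-step for one item: maximise expected complete-data loglik over
## (log a, b1, log-increments) given K x Q expected category counts.
grm_mstep_item <- function(r, par0, xq) {
  K <- nrow(r)
  enc <- function(p) c(log(p$a), p$b[1],
                       if (K > 2) log(pmax(diff(p$b), 1e-6)))
  dec <- function(v) list(a = exp(v[1]),
                          b = cumsum(c(v[2], if (K > 2) exp(v[3:K]))))
  obj <- function(v) {
    p <- dec(v)
    lp <- log(clamp_p(grm_category_probs(p$a, p$b, xq)))
    -sum(r * t(lp))
  }
  res <- optim(enc(par0), obj, method = "BFGS",
               control = list(maxit = 100, reltol = 1e-10))
  dec(res$par)
}

#' Marginal log-likelihood of a graded response model at given parameters
#'
#' Evaluates the quadrature marginal log-likelihood of ordinal data under a
#' standard-normal latent trait at fixed item parameters; used for
#' goodness-of-fit checks and cross-validation against independent
#' integration.
#'
#' @param sev Severity tibble.
#' @param bank Parameter tibble with `item_id`, `a`, `b1`-`b4` (trailing
#'   thresholds may be `NA` for items with fewer categories).
#' @param nodes Quadrature nodes.
#' @return Total marginal log-likelihood (scalar).
#' @export
grm_loglik <- function(sev, bank, nodes = 101L) {
  m <- resp_matrix(sev)
  m <- m[, bank$item_id, drop = FALSE]
  gh <- gh_normal(nodes)
  pars <- purrr::map(seq_len(nrow(bank)), function(j) {
    b <- as.numeric(bank[j, c("b1", "b2", "b3", "b4")])
    list(a = bank$a[j], b = b[!is.na(b)])
  })
  grm_estep(m, pars, gh)$loglik
}

#' EAP person scores from a graded response model
#'
#' Expected a posteriori latent severity for each person under a standard
#' normal prior, with the posterior SD as the score's standard error.
#' Persons with no administered item receive the prior mean 0 with SD 1 and
#' are flagged.
#'
#' @param fit An `ocd_grm` fit (or a parameter tibble as in [grm_loglik()]).
#' @param sev Severity tibble to score.
#' @param nodes Quadrature nodes.
#' @return Tibble with `person_id`, `score`, `se`, `n_observed`,
#'   `prior_fallback`.
#' @export
eap_scores <- function(fit, sev, nodes = 101L) {
  m <- resp_matrix(sev)
  if (inherits(fit, "ocd_grm")) {
    pars <- fit$pars
    ids <- fit$item_ids
    m <- m[, ids, drop = FALSE]
    ## apply the training-time category remapping
    for (j in seq_along(ids)) {
      obs <- as.numeric(names(fit$remap[[ids[j]]]))
      cj <- findInterval(m[, j], obs) - 1L
      cj[!is.na(cj) & cj < 0L] <- 0L
      m[, j] <- cj
    }
  } else {
    pars <- purrr::map(seq_len(nrow(fit)), function(j) {
      b <- as.numeric(fit[j, c("b1", "b2", "b3", "b4")])
      list(a = fit$a[j], b = b[!is.na(b)])
    })
    m <- m[, fit$item_id, drop = FALSE]
  }
  gh <- gh_normal(nodes)
  es <- grm_estep(m, pars, gh)
  mu <- as.numeric(es$post %*% gh$x)
  sd_ <- sqrt(pmax(as.numeric(es$post %*% gh$x^2) - mu^2, 0))
  none <- rowSums(!is.na(m)) == 0
  mu[none] <- 0
  sd_[none] <- 1
  tibble::tibble(person_id = rownames(m), score = mu, se = sd_,
                 n_observed = rowSums(!is.na(m)), prior_fallback = none)
}

## BHHH standard errors: outer product of per-person numerical score
## vectors with respect to the natural item parameters.
add_grm_ses <- function(fit, y, gh) {
  pars <- fit$pars
  J <- length(pars)
  per_person_ll <- function(pars_) {
    n <- nrow(y); Q <- length(gh$x)
    ll <- matrix(0, n, Q)
    for (j in seq_len(J)) {
      lp <- log(clamp_p(grm_category_probs(pars_[[j]]$a, pars_[[j]]$b, gh$x)))
      obs <- which(!is.na(y[, j]))
      ll[obs, ] <- ll[obs, ] + t(lp[, y[obs, j] + 1L, drop = FALSE])
    }
    row_logsumexp(sweep(ll, 2L, log(gh$w), "+"))
  }
  ## parameter layout: per item (a, b_1..b_{K-1})
  layout <- purrr::map(seq_len(J), function(j) {
    c(a = NA_real_, setNames(pars[[j]]$b,
                             paste0("b", seq_along(pars[[j]]$b))))
  })
  npar <- sum(lengths(layout))
  h <- 1e-5
  base_ll <- per_person_ll(pars)
  scores <- matrix(0, nrow(y), npar)
  idx <- 0L
  for (j in seq_len(J)) {
    for (k in seq_len(1L + length(pars[[j]]$b))) {
      idx <- idx + 1L
      up <- pars; dn <- pars
      if (k == 1L) {
        up[[j]]$a <- pars[[j]]$a + h; dn[[j]]$a <- pars[[j]]$a - h
      } else {
        up[[j]]$b[k - 1L] <- pars[[j]]$b[k - 1L] + h
        dn[[j]]$b[k - 1L] <- pars[[j]]$b[k - 1L] - h
        up[[j]]$b <- sort(up[[j]]$b); dn[[j]]$b <- sort(dn[[j]]$b)
      }
      scores[, idx] <- (per_person_ll(up) - per_person_ll(dn)) / (2 * h)
    }
  }
  info <- crossprod(scores)
  se_all <- rep(NA_real_, npar)
  ok <- tryCatch({
    se_all <- sqrt(diag(solve(info)))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) warn("information matrix singular; SEs unavailable")
  idx <- 0L
  items <- fit$items
  se_cols <- matrix(NA_real_, J, 5L)
  for (j in seq_len(J)) {
    kk <- 1L + length(pars[[j]]$b)
    se_cols[j, seq_len(kk)] <- se_all[idx + seq_len(kk)]
    idx <- idx + kk
  }
  items$se_a <- se_cols[, 1]
  items$se_b1 <- se_cols[, 2]; items$se_b2 <- se_cols[, 3]
  items$se_b3 <- se_cols[, 4]; items$se_b4 <- se_cols[, 5]
  fit$items <- items
  fit
}

#' @export
print.ocd_grm <- function(x, ...) {
  cat("Graded response model:", length(x$pars), "items,",
      x$n_persons, "persons\n")
  cat(sprintf("  loglik %.2f | AIC %.1f | BIC %.1f | %s in %d iterations\n",
              x$loglik, x$AIC, x$BIC,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
tidy.ocd_grm <- function(x, ...) x$items

#' @export
glance.ocd_grm <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, npar = x$npar, AIC = x$AIC, BIC = x$BIC,
                 n_persons = x$n_persons, converged = x$converged,
                 iterations = x$iterations)
}
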