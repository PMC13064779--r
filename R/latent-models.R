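## Marginal maximum likelihood fitting and comparison of three latent
## structures for binary symptom data: unidimensional 2PL, correlated
## five-factor, and hierarchical bifactor. Estimation is deterministic
## EM with Gauss-Hermite quadrature (dimension-reduced per-domain 2-D
## integrals for the bifactor model; a full transformed grid for the
## correlated model), so fits are exactly reproducible.

#' Latent model specification
#'
#' @param structure One of `"unidimensional"`, `"correlated"` (five
#'   correlated domain factors) or `"bifactor"` (general factor plus
#'   orthogonal domain-specific factors).
#' @param nodes_general Quadrature nodes for the general/single factor.
#' @param nodes_specific Nodes per domain-specific factor (bifactor).
#' @param nodes_correlated Nodes per dimension of the full correlated grid;
#'   the grid has `nodes_correlated^5` points, so this is the accuracy/cost
#'   switch for the correlated model.
#' @param max_iter,tol EM iteration cap and absolute tolerance on the
#'   marginal log-likelihood change.
#' @param ridge Ridge penalty applied to slope/intercept of degenerate
#'   (all-0 or all-1) items only; keeps their estimates bounded.
#' @param equal_slopes Constrain all items to share one discrimination
#'   (Rasch-like; unidimensional structure only).
#' @param drop_domain Optional domain name whose specific factor is removed
#'   (its items load on the general factor only); used by
#'   [leave_one_domain_out()].
#' @param loading_threshold Standardized specific loading above which an
#'   item is counted as retaining a salient domain relationship.
#' @return A list of class `ocd_model_spec`.
#' @export
model_spec <- function(structure = c("unidimensional", "correlated",
                                     "bifactor"),
                       nodes_general = 21L, nodes_specific = 15L,
                       nodes_correlated = 5L, max_iter = 500L, tol = 1e-4,
                       ridge = 1e-3, equal_slopes = FALSE,
                       drop_domain = NULL, loading_threshold = 0.35) {
  structure_ <- match.arg(structure)
  if (equal_slopes && structure_ != "unidimensional") {
    abort("equal_slopes is only meaningful for the unidimensional structure")
  }
  structure(list(structure = structure_,
                 nodes_general = as.integer(nodes_general),
                 nodes_specific = as.integer(nodes_specific),
                 nodes_correlated = as.integer(nodes_correlated),
                 max_iter = as.integer(max_iter), tol = tol, ridge = ridge,
                 equal_slopes = equal_slopes, drop_domain = drop_domain,
                 loading_threshold = loading_threshold),
            class = "ocd_model_spec")
}

## -- quadrature scaffolding --------------------------------------------------

## Bifactor/unidimensional scaffold: item blocks per domain with per-domain
## (general x specific) grids; a domain without a specific factor uses the
## general nodes only.
build_quad <- function(spec, map, item_ids) {
  gh0 <- gh_normal(spec$nodes_general)
  ghs <- gh_normal(spec$nodes_specific)
  if (spec$structure == "unidimensional") {
    doms <- list(list(domain = "all", items = item_ids, specific = FALSE))
  } else {
    doms <- purrr::map(unique(map$domain), function(d) {
      list(domain = d, items = map$item_id[map$domain == d],
           specific = spec$structure == "bifactor" &&
             !identical(d, spec$drop_domain))
    })
  }
  list(gh0 = gh0, ghs = ghs, doms = doms)
}

## Dense correlated grid: standard-normal z-grid transformed by chol(Sigma).
corr_grid <- function(spec, n_dim) {
  gh <- gh_normal(spec$nodes_correlated)
  Z <- as.matrix(expand.grid(rep(list(gh$x), n_dim)))
  lw <- rowSums(log(matrix(gh$w[as.matrix(expand.grid(
    rep(list(seq_along(gh$w)), n_dim)))], nrow(Z), n_dim)))
  list(Z = Z, logw = lw)
}

## -- E-step engines ----------------------------------------------------------

## Unidimensional / bifactor E-step with per-domain dimension reduction.
## pars: tibble item_id, domain, slope_general, slope_specific, intercept.
## Returns loglik plus, if counts = TRUE, per-domain expected count
## matrices for the M-step.
estep_bifactor <- function(Y1, Y0, pars, quad, counts = FALSE) {
  n <- nrow(Y1)
  gx0 <- quad$gh0$x; lw0 <- log(quad$gh0$w)
  gxs <- quad$ghs$x; lws <- log(quad$ghs$w)
  Q0 <- length(gx0); Qs <- length(gxs)
  blocks <- list()
  B <- matrix(0, n, Q0)          # sum over domains of log L_d(i, q)
  for (d in seq_along(quad$doms)) {
    dd <- quad$doms[[d]]
    jj <- match(dd$items, colnames(Y1))
    a0 <- pars$slope_general[jj]; as_ <- pars$slope_specific[jj]
    cc <- pars$intercept[jj]
    if (dd$specific) {
      ## linear predictor on the (q, s) grid, columns grouped by q
      lin <- outer(a0, gx0)[, rep(seq_len(Q0), each = Qs), drop = FALSE] +
        outer(as_, gxs)[, rep(seq_len(Qs), times = Q0), drop = FALSE] + cc
    } else {
      lin <- outer(a0, gx0) + cc
    }
    lp <- log(clamp_p(plogis(lin))); l1p <- log(clamp_p(1 - plogis(lin)))
    A <- Y1[, jj, drop = FALSE] %*% lp + Y0[, jj, drop = FALSE] %*% l1p
    if (dd$specific) {
      Bd <- vapply(seq_len(Q0), function(q) {
        row_logsumexp(sweep(A[, (q - 1L) * Qs + seq_len(Qs), drop = FALSE],
                            2L, lws, "+"))
      }, numeric(n))
    } else {
      Bd <- A
    }
    B <- B + Bd
    blocks[[d]] <- list(dd = dd, jj = jj, A = A, Bd = Bd)
  }
  lM <- sweep(B, 2L, lw0, "+")
  li <- row_logsumexp(lM)
  out <- list(loglik = sum(li))
  if (!counts) return(out)
  out$blocks <- purrr::map(blocks, function(bl) {
    dd <- bl$dd
    if (dd$specific) {
      ## joint posterior over (q, s) for this domain's items
      base <- (B - bl$Bd + rep(lw0, each = n)) - li    # n x Q0
      lpost <- base[, rep(seq_len(Q0), each = Qs), drop = FALSE] +
        bl$A + rep(rep(lws, times = Q0), each = n)
      post <- exp(lpost)
      X <- cbind(general = gx0[rep(seq_len(Q0), each = Qs)],
                 specific = gxs[rep(seq_len(Qs), times = Q0)],
                 intercept = 1)
    } else {
      post <- exp(sweep(B, 2L, lw0, "+") - li)                # n x Q0
      X <- cbind(general = gx0, intercept = 1)
    }
    r1 <- crossprod(Y1[, bl$jj, drop = FALSE], post)
    n01 <- crossprod(Y1[, bl$jj, drop = FALSE] +
                       Y0[, bl$jj, drop = FALSE], post)
    list(items = dd$items, jj = bl$jj, specific = dd$specific,
         X = X, r1 = r1, n01 = n01, post = post)
  })
  out
}

## Correlated-factor E-step on a dense transformed grid.
estep_correlated <- function(Y1, Y0, pars, corr, grid, d_idx,
                             counts = FALSE) {
  R <- chol_psd(corr)                            # upper: corr = R'R
  Theta <- grid$Z %*% R                          # nodes x D, cov = R'R
  th_item <- Theta[, d_idx, drop = FALSE]        # nodes x J
  lin <- t(th_item) * pars$slope_specific + pars$intercept   # J x nodes
  lp <- log(clamp_p(plogis(lin))); l1p <- log(clamp_p(1 - plogis(lin)))
  A <- Y1 %*% lp + Y0 %*% l1p                    # n x nodes
  lM <- sweep(A, 2L, grid$logw, "+")
  li <- row_logsumexp(lM)
  out <- list(loglik = sum(li))
  if (!counts) return(out)
  post <- exp(lM - li)
  out$post <- post
  out$Theta <- Theta
  out$r1 <- crossprod(Y1, post)
  out$n01 <- crossprod(Y1 + Y0, post)
  out
}

chol_psd <- function(S) {
  tryCatch(chol(S), error = function(e) {
    chol(S + diag(1e-6, nrow(S)))
  })
}

## Damped Newton for a weighted logistic M-step (expected successes r1 of
## n01 trials at design rows X); concave objective, ridge optional.
newton_logit <- function(X, r1, n01, beta0, ridge = 0) {
  beta <- beta0
  for (it in seq_len(60)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    g <- drop(crossprod(X, r1 - n01 * p)) - ridge * beta
    W <- n01 * p * (1 - p)
    H <- crossprod(X, X * W) + diag(ridge + 1e-10, ncol(X))
    step <- tryCatch(drop(solve(H, g)), error = function(e) rep(0, ncol(X)))
    mx <- max(abs(step))
    if (mx > 2) step <- step * (2 / mx)
    beta <- beta + step
    beta <- pmin(pmax(beta, -25), 25)
    if (mx < 1e-9) break
  }
  beta
}

## -- public operations -------------------------------------------------------

#' Marginal log-likelihood of a latent structure at given item parameters
#'
#' Evaluates `sum_i log integral prod_j P(y_ij | latents) phi(latents)
#' d latents` by Gauss-Hermite quadrature under the structure in `spec`,
#' at fixed item parameters. Missing cells are skipped in the conditional
#' likelihood product.
#'
#' @param data Checklist tibble (`person_id` + 0/1 item columns).
#' @param pars Parameter tibble with columns `item_id`, `domain`,
#'   `slope_general`, `slope_specific`, `intercept` (unused slopes may be
#'   `NA`/0).
#' @param spec A [model_spec()].
#' @param map Domain map (required for correlated/bifactor structures).
#' @param corr Factor correlation matrix (correlated structure only;
#'   defaults to identity).
#' @return Total marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(data, pars, spec, map = NULL, corr = NULL) {
  if (any(!is.finite(pars$intercept))) abort("non-finite parameter")
  if (spec$structure != "unidimensional" && is.null(map)) {
    abort("domain map required for this structure")
  }
  if (spec$structure != "correlated" &&
      any(!is.finite(pars$slope_general))) {
    abort("non-finite parameter")
  }
  m <- resp_matrix(data)
  pars <- pars[match(colnames(m), pars$item_id), , drop = FALSE]
  if (anyNA(pars$item_id)) abort("pars must cover every item column")
  ind <- bern_indicators(m)
  if (spec$structure == "correlated") {
    doms <- unique(map$domain)
    d_idx <- match(map$domain[match(colnames(m), map$item_id)], doms)
    if (is.null(corr)) corr <- diag(length(doms))
    grid <- corr_grid(spec, length(doms))
    if (!all(is.finite(pars$slope_specific))) abort("non-finite slopes")
    return(estep_correlated(ind$y1, ind$y0, pars, corr, grid,
                            d_idx)$loglik)
  }
  pars$slope_specific[is.na(pars$slope_specific)] <- 0
  quad <- build_quad(spec, map, colnames(m))
  estep_bifactor(ind$y1, ind$y0, pars, quad)$loglik
}

#' Fit a latent structure model by marginal maximum likelihood
#'
#' EM estimation of the specified structure on binary checklist data. The
#' E-step integrates the latent factors on Gauss-Hermite grids (per-domain
#' two-dimensional grids for the bifactor model); the M-step solves one
#' small weighted logistic regression per item by damped Newton, plus a
#' latent-correlation update for the correlated model. Starting values are
#' fixed (intercepts at the logit of the item endorsement rate, slopes at
#' 1), so the fit is deterministic. Items endorsed by nobody or everybody
#' get a weak ridge penalty and a warning; the ridge strength is recorded
#' on the result.
#'
#' @param data Checklist tibble.
#' @param map Domain map tibble (required unless unidimensional).
#' @param spec A [model_spec()].
#' @return An object of class `ocd_cfa` with elements `pars` (tibble of
#'   slopes/intercepts), `corr` (correlated structure), `loglik`, `npar`,
#'   `AIC`, `BIC`, `n_persons`, `converged`, `iterations`, `ascent_ok`,
#'   `degenerate_items`, `spec`.
#' @export
fit_latent_model <- function(data, map = NULL, spec = model_spec()) {
  m <- resp_matrix(data)
  if (spec$structure != "unidimensional") {
    if (is.null(map)) abort("domain map required for this structure")
    if (!all(colnames(m) %in% map$item_id)) {
      abort("domain map must cover every item")
    }
  }
  ind <- bern_indicators(m)
  Y1 <- ind$y1; Y0 <- ind$y0
  n <- nrow(m); J <- ncol(m)
  rate <- colSums(Y1) / pmax(colSums(Y1 + Y0), 1)
  degen <- rate <= 0 | rate >= 1
  if (any(degen)) {
    warn(paste0("degenerate item(s) (no 0s or no 1s observed), ",
                "ridge-penalised: ",
                paste(colnames(m)[degen], collapse = ", ")))
  }
  ridge_j <- ifelse(degen, spec$ridge, 0)
  doms <- if (is.null(map)) "all" else unique(map$domain)
  dom_of <- if (is.null(map)) rep("all", J) else
    map$domain[match(colnames(m), map$item_id)]
  pars <- tibble::tibble(
    item_id = colnames(m), domain = dom_of,
    slope_general = if (spec$structure == "correlated") NA_real_ else 1,
    slope_specific = dplyr::case_when(
      spec$structure == "unidimensional" ~ 0,
      spec$structure == "bifactor" ~ 1,
      TRUE ~ 1),
    intercept = qlogis(pmin(pmax(rate, 0.02), 0.98))
  )
  if (spec$structure == "bifactor" && !is.null(spec$drop_domain)) {
    pars$slope_specific[dom_of == spec$drop_domain] <- 0
  }
  corr <- if (spec$structure == "correlated") diag(length(doms)) else NULL
  quad <- if (spec$structure != "correlated")
    build_quad(spec, map, colnames(m)) else NULL
  grid <- if (spec$structure == "correlated")
    corr_grid(spec, length(doms)) else NULL
  d_idx <- match(dom_of, doms)

  ll_old <- -Inf
  ll_best <- -Inf
  best <- NULL
  ascent_ok <- TRUE
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (spec$structure == "correlated") {
      es <- estep_correlated(Y1, Y0, pars, corr, grid, d_idx, counts = TRUE)
    } else {
      es <- estep_bifactor(Y1, Y0, pars, quad, counts = TRUE)
    }
    if (es$loglik < ll_old - 1e-6) ascent_ok <- FALSE
    if (es$loglik > ll_best) {
      ll_best <- es$loglik
      best <- list(pars = pars, corr = corr)
    }
    ## the correlated model's quadrature grid moves with the correlation
    ## update, so its discretised objective can stall in a small
    ## oscillation; fall back to the best iterate when that happens
    if (es$loglik < ll_best - max(1, 100 * spec$tol)) {
      pars <- best$pars
      corr <- best$corr
      ll <- ll_best
      converged <- TRUE
      break
    }
    if (abs(es$loglik - ll_old) < spec$tol || iter >= spec$max_iter) {
      converged <- abs(es$loglik - ll_old) < spec$tol
      ll <- es$loglik
      if (ll_best > ll) {
        pars <- best$pars
        corr <- best$corr
        ll <- ll_best
      }
      break
    }
    ll_old <- es$loglik
    ## M-step
    if (spec$structure == "correlated") {
      for (j in seq_len(J)) {
        X <- cbind(es$Theta[, d_idx[j]], 1)
        b <- newton_logit(X, es$r1[j, ], es$n01[j, ],
                          c(pars$slope_specific[j], pars$intercept[j]),
                          ridge = ridge_j[j])
        pars$slope_specific[j] <- b[1]; pars$intercept[j] <- b[2]
      }
      ## correlation update from the posterior second moment, standardised
      ## (factor variances stay fixed at 1 for identification). Because
      ## the quadrature grid moves with the correlation, the moment update
      ## alone can reduce the discretised likelihood; backtrack to the
      ## largest damped step that does not.
      g <- colSums(es$post)
      S <- crossprod(es$Theta, es$Theta * g) / n
      sdd <- sqrt(pmax(diag(S), 1e-8))
      corr_new <- S / tcrossprod(sdd)
      diag(corr_new) <- 1
      for (lam in c(1, 0.5, 0.25)) {
        cand <- (1 - lam) * corr + lam * corr_new
        llc <- estep_correlated(Y1, Y0, pars, cand, grid, d_idx)$loglik
        if (llc >= es$loglik) {
          corr <- cand
          break
        }
      }
      ## sign convention: positive slopes on average per factor
      for (d in seq_along(doms)) {
        jj <- which(d_idx == d)
        if (mean(pars$slope_specific[jj]) < 0) {
          pars$slope_specific[jj] <- -pars$slope_specific[jj]
          corr[d, -d] <- -corr[d, -d]; corr[-d, d] <- -corr[-d, d]
        }
      }
    } else if (spec$equal_slopes) {
      bl <- es$blocks[[1]]
      pars <- mstep_equal_slopes(pars, bl)
    } else {
      for (bl in es$blocks) {
        for (k in seq_along(bl$items)) {
          j <- bl$jj[k]
          if (bl$specific) {
            beta0 <- c(pars$slope_general[j], pars$slope_specific[j],
                       pars$intercept[j])
            b <- newton_logit(bl$X, bl$r1[k, ], bl$n01[k, ], beta0,
                              ridge = ridge_j[j])
            pars$slope_general[j] <- b[1]
            pars$slope_specific[j] <- b[2]
            pars$intercept[j] <- b[3]
          } else {
            beta0 <- c(pars$slope_general[j], pars$intercept[j])
            b <- newton_logit(bl$X, bl$r1[k, ], bl$n01[k, ], beta0,
                              ridge = ridge_j[j])
            pars$slope_general[j] <- b[1]
            pars$intercept[j] <- b[2]
          }
        }
        ## orient each specific factor positively (sign indeterminacy)
        if (bl$specific) {
          jj <- bl$jj
          if (mean(pars$slope_specific[jj]) < 0) {
            pars$slope_specific[jj] <- -pars$slope_specific[jj]
          }
        }
      }
    }
  }
  npar <- switch(spec$structure,
    unidimensional = if (spec$equal_slopes) J + 1L else 2L * J,
    correlated = 2L * J + length(doms) * (length(doms) - 1L) / 2L,
    bifactor = 3L * J - (if (is.null(spec$drop_domain)) 0L else
                           sum(dom_of == spec$drop_domain)))
  structure(list(pars = pars, corr = corr, loglik = ll, npar = npar,
                 AIC = -2 * ll + 2 * npar, BIC = -2 * ll + npar * log(n),
                 n_persons = n, converged = converged, iterations = iter,
                 ascent_ok = ascent_ok,
                 degenerate_items = colnames(m)[degen],
                 ridge = spec$ridge, spec = spec,
                 item_ids = colnames(m)),
            class = "ocd_cfa")
}

## Equal-slope (Rasch-like) M-step: coordinate ascent between the shared
## slope and the per-item intercepts.
mstep_equal_slopes <- function(pars, bl) {
  a <- pars$slope_general[1]
  cc <- pars$intercept
  x <- bl$X[, "general"]
  for (sweep_i in seq_len(8)) {
    for (k in seq_along(bl$jj)) {
      j <- bl$jj[k]
      p <- plogis(a * x + cc[j])
      g <- sum(bl$r1[k, ] - bl$n01[k, ] * p)
      h <- sum(bl$n01[k, ] * p * (1 - p))
      cc[j] <- cc[j] + g / (h + 1e-10)
    }
    num <- 0; den <- 0
    for (k in seq_along(bl$jj)) {
      j <- bl$jj[k]
      p <- plogis(a * x + cc[j])
      num <- num + sum((bl$r1[k, ] - bl$n01[k, ] * p) * x)
      den <- den + sum(bl$n01[k, ] * p * (1 - p) * x^2)
    }
    a <- a + num / (den + 1e-10)
  }
  pars$slope_general <- a
  pars$intercept <- cc
  pars
}

#' Compare fitted latent models
#'
#' Builds the model-comparison table: log-likelihood, parameter count, AIC,
#' BIC, differences to the best model, and chi-square likelihood-ratio
#' tests for nested pairs (the unidimensional model is nested in the
#' bifactor model; an ablated bifactor model is nested in the full one).
#'
#' @param fits Named list of `ocd_cfa` fits on the same data.
#' @return Tibble with one row per model: `model`, `structure`, `loglik`,
#'   `npar`, `AIC`, `BIC`, `dAIC`, `dBIC`, and for models nested in a
#'   larger fitted model, `lrt_stat`, `lrt_df`, `lrt_p` against the
#'   smallest encompassing model in the list.
#' @export
compare_models <- function(fits) {
  if (is.null(names(fits))) {
    names(fits) <- purrr::map_chr(fits, function(f) f$spec$structure)
  }
  np <- unique(purrr::map_int(fits, "n_persons"))
  if (length(np) != 1L) abort("all fits must be on the same data")
  tab <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(model = nm, structure = f$spec$structure,
                   loglik = f$loglik, npar = f$npar, AIC = f$AIC,
                   BIC = f$BIC)
  })
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$dBIC <- tab$BIC - min(tab$BIC)
  lrt <- purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    encl <- which(purrr::map_lgl(seq_len(nrow(tab)), function(j) {
      nested_in(fits[[i]], fits[[j]]) && j != i
    }))
    if (!length(encl)) {
      return(tibble::tibble(lrt_stat = NA_real_, lrt_df = NA_integer_,
                            lrt_p = NA_real_, lrt_vs = NA_character_))
    }
    j <- encl[which.min(tab$npar[encl])]
    stat <- max(0, -2 * (tab$loglik[i] - tab$loglik[j]))
    df <- tab$npar[j] - tab$npar[i]
    tibble::tibble(lrt_stat = stat, lrt_df = as.integer(df),
                   lrt_p = if (df > 0) {
                     pchisq(stat, df, lower.tail = FALSE)
                   } else if (stat < 1e-8) 1 else NA_real_,
                   lrt_vs = tab$model[j])
  })
  dplyr::bind_cols(tab, lrt)
}

## Is fit_small nested in fit_big?
nested_in <- function(small, big) {
  if (small$npar > big$npar) return(FALSE)
  s1 <- small$spec$structure; s2 <- big$spec$structure
  (s1 == "unidimensional" && s2 == "bifactor") ||
    (s1 == "bifactor" && s2 == "bifactor" &&
       !is.null(small$spec$drop_domain) && is.null(big$spec$drop_domain)) ||
    (s1 == s2 && small$npar == big$npar)
}

#' Leave-one-domain-out ablation of the bifactor model
#'
#' Refits the hierarchical bifactor model five times, each time removing
#' one domain's specific factor (its items keep their general-factor
#' loadings), and reports the log-likelihood drop and the likelihood-ratio
#' test of each ablated model against the full model. The ranking of drops
#' orders the domains by their independent contribution beyond the general
#' OCD dimension.
#'
#' @param data Checklist tibble.
#' @param map Domain map.
#' @param spec A bifactor [model_spec()].
#' @return Tibble: `domain_dropped`, `loglik`, `loglik_drop`, `lrt_stat`,
#'   `lrt_df`, `lrt_p`, `rank` (1 = largest drop). The full-model fit is
#'   attached as attribute `full_fit`.
#' @export
leave_one_domain_out <- function(data, map, spec = model_spec("bifactor")) {
  if (spec$structure != "bifactor") abort("spec must be bifactor")
  full <- fit_latent_model(data, map, spec)
  doms <- unique(map$domain)
  tab <- purrr::map_dfr(doms, function(d) {
    sp <- spec
    sp$drop_domain <- d
    f <- fit_latent_model(data, map, sp)
    df <- sum(map$domain == d)
    stat <- max(0, 2 * (full$loglik - f$loglik))
    tibble::tibble(domain_dropped = d, loglik = f$loglik,
                   loglik_drop = full$loglik - f$loglik,
                   lrt_stat = stat, lrt_df = df,
                   lrt_p = pchisq(stat, df, lower.tail = FALSE))
  })
  tab$rank <- rank(-tab$loglik_drop, ties.method = "first")
  attr(tab, "full_fit") <- full
  tab
}

#' Standardized factor loadings of a fitted model
#'
#' Converts logit slopes to standardized loadings on the normal-ogive
#' metric: `lambda_k = (a_k / 1.702) / sqrt(1 + sum_k (a_k / 1.702)^2)`.
#' The communality is the sum of squared loadings.
#'
#' @param fit An `ocd_cfa` fit.
#' @return Tibble: `item_id`, `domain`, `lambda_general`,
#'   `lambda_specific`, `communality`, `retained` (specific loading at or
#'   above the spec's threshold).
#' @export
standardized_loadings <- function(fit) {
  D <- 1.702
  p <- fit$pars
  ag <- ifelse(is.na(p$slope_general), 0, p$slope_general) / D
  as_ <- ifelse(is.na(p$slope_specific), 0, p$slope_specific) / D
  denom <- sqrt(1 + ag^2 + as_^2)
  lg <- ag / denom
  ls <- as_ / denom
  tibble::tibble(item_id = p$item_id, domain = p$domain,
                 lambda_general = lg, lambda_specific = ls,
                 communality = lg^2 + ls^2,
                 retained = abs(ls) >= fit$spec$loading_threshold)
}

#' EAP person scores from a fitted binary latent model
#'
#' Posterior mean and SD of the general latent trait given each person's
#' response pattern, by quadrature. For the bifactor structure the
#' domain-specific factors are integrated out, so the score targets the
#' common OCD dimension.
#'
#' @param fit An `ocd_cfa` fit (unidimensional or bifactor).
#' @param data Checklist tibble to score.
#' @param nodes Quadrature nodes for the general factor.
#' @return Tibble `person_id`, `score`, `se`, `n_endorsed`, `all_zero`.
#' @export
score_persons_eap <- function(fit, data, nodes = 61L) {
  if (fit$spec$structure == "correlated") {
    abort(paste0("EAP scoring of the correlated model is not supported; ",
                 "use the unidimensional or bifactor structure"))
  }
  m <- resp_matrix(data)
  m <- m[, fit$item_ids, drop = FALSE]
  ## equal-slope models make the sum score sufficient; score through it so
  ## persons with equal counts get exactly equal posteriors
  if (fit$spec$structure == "unidimensional" && !anyNA(m) &&
      length(unique(fit$pars$slope_general)) == 1L) {
    gh <- gh_normal(nodes)
    a1 <- fit$pars$slope_general[1]
    const_q <- colSums(log1p(exp(outer(fit$pars$intercept, a1 * gh$x, "+"))))
    S <- rowSums(m)
    su <- sort(unique(S))
    lk <- outer(su, a1 * gh$x) -
      matrix(const_q, length(su), nodes, byrow = TRUE) +
      matrix(log(gh$w), length(su), nodes, byrow = TRUE)
    li <- row_logsumexp(lk)
    post <- exp(lk - li)
    mu_u <- as.numeric(post %*% gh$x)
    sd_u <- sqrt(pmax(as.numeric(post %*% gh$x^2) - mu_u^2, 0))
    k <- match(S, su)
    return(tibble::tibble(person_id = rownames(m), score = mu_u[k],
                          se = sd_u[k], n_endorsed = S, all_zero = S == 0))
  }
  ind <- bern_indicators(m)
  spec <- fit$spec
  spec$nodes_general <- as.integer(nodes)
  map <- tibble::tibble(item_id = fit$pars$item_id,
                        domain = fit$pars$domain)
  quad <- build_quad(spec, map, colnames(m))
  gx0 <- quad$gh0$x; lw0 <- log(quad$gh0$w)
  n <- nrow(m)
  B <- matrix(0, n, length(gx0))
  for (dd in quad$doms) {
    jj <- match(dd$items, colnames(m))
    a0 <- fit$pars$slope_general[jj]
    as_ <- fit$pars$slope_specific[jj]
    cc <- fit$pars$intercept[jj]
    if (dd$specific) {
      gxs <- quad$ghs$x; lws <- log(quad$ghs$w)
      Qs <- length(gxs); Q0 <- length(gx0)
      lin <- outer(a0, gx0)[, rep(seq_len(Q0), each = Qs), drop = FALSE] +
        outer(as_, gxs)[, rep(seq_len(Qs), times = Q0), drop = FALSE] + cc
      lp <- log(clamp_p(plogis(lin)))
      l1p <- log(clamp_p(1 - plogis(lin)))
      A <- ind$y1[, jj, drop = FALSE] %*% lp +
        ind$y0[, jj, drop = FALSE] %*% l1p
      Bd <- vapply(seq_len(Q0), function(q) {
        row_logsumexp(sweep(A[, (q - 1L) * Qs + seq_len(Qs), drop = FALSE],
                            2L, lws, "+"))
      }, numeric(n))
    } else {
      lin <- outer(a0, gx0) + cc
      lp <- log(clamp_p(plogis(lin)))
      l1p <- log(clamp_p(1 - plogis(lin)))
      Bd <- ind$y1[, jj, drop = FALSE] %*% lp +
        ind$y0[, jj, drop = FALSE] %*% l1p
    }
    B <- B + Bd
  }
  lpost <- sweep(B, 2L, lw0, "+")
  li <- row_logsumexp(lpost)
  post <- exp(lpost - li)
  mu <- as.numeric(post %*% gx0)
  sd_ <- sqrt(pmax(as.numeric(post %*% gx0^2) - mu^2, 0))
  tibble::tibble(person_id = rownames(m), score = mu, se = sd_,
                 n_endorsed = rowSums(m == 1, na.rm = TRUE),
                 all_zero = rowSums(m == 1, na.rm = TRUE) == 0)
}

#' @export
print.ocd_cfa <- function(x, ...) {
  cat("Latent structure fit:", x$spec$structure, "\n")
  cat(sprintf("  %d persons, %d items | loglik %.2f | AIC %.1f | BIC %.1f\n",
              x$n_persons, nrow(x$pars), x$loglik, x$AIC, x$BIC))
  cat(sprintf("  %s in %d EM iterations\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
tidy.ocd_cfa <- function(x, ...) x$pars

#' @export
glance.ocd_cfa <- function(x, ...) {
  tibble::tibble(structure = x$spec$structure, loglik = x$loglik,
                 npar = x$npar, AIC = x$AIC, BIC = x$BIC,
                 n_persons = x$n_persons, converged = x$converged,
                 iterations = x$iterations, ascent_ok = x$ascent_ok)
}

#' Plot a model comparison table
#'
#' @param object Tibble from [compare_models()].
#' @param ... Unused.
#' @return A ggplot bar chart of AIC and BIC differences to the best model.
#' @export
plot_model_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("model", "dAIC", "dBIC")],
                              c("dAIC", "dBIC"),
                              names_to = "index", values_to = "delta")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$delta,
                                     fill = .data$index)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "difference to best model",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
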