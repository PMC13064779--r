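## Latent-structure comparison for ordinal severity items: the graded
## (cumulative-logit) counterpart of the binary structure fits, so the
## 10-item clinician scale can be checked for a single primary dimension
## against 2-factor and hierarchical alternatives. The scale is small, so
## every structure is integrated on a full Gauss-Hermite product grid.

#' Default obsession/compulsion grouping of the severity items
#'
#' The conventional halves of the 10-item scale: the first five ratings
#' (time, interference, distress, resistance, control for obsessions) form
#' one group, the second five (the compulsion counterparts) the other. The
#' split is configurable in [fit_graded_structure()] because alternative
#' partitions (e.g. a resistance/control grouping) are also discussed in
#' the literature.
#'
#' @param item_ids Character vector of the scale's item ids, in order.
#' @return Tibble `item_id`, `group`.
#' @export
severity_groups <- function(item_ids) {
  n <- length(item_ids)
  tibble::tibble(item_id = item_ids,
                 group = rep(c("obsessions", "compulsions"),
                             c(ceiling(n / 2), floor(n / 2))))
}

#' Fit a latent structure to ordinal severity items
#'
#' Marginal maximum likelihood for graded (cumulative-logit) items under
#' one of three structures: a single severity dimension
#' (`"unidimensional"`), two correlated group factors (`"correlated"`), or
#' a hierarchical/bifactor structure with a general severity dimension
#' plus orthogonal group factors (`"bifactor"`). Category probabilities
#' are `P(Y >= k) = logistic(a' theta + c_k)` with ordered intercepts.
#' Estimation is EM on a full Gauss-Hermite product grid (1, 2 or 3
#' dimensions), with the group-factor correlation updated by a damped,
#' backtracking moment step as in the binary engine.
#'
#' @param sev Severity tibble (`person_id` + ordinal item columns; `NA`
#'   cells are skipped).
#' @param groups Item grouping tibble (`item_id`, `group`); default
#'   [severity_groups()] on the data's columns.
#' @param structure One of `"unidimensional"`, `"correlated"`,
#'   `"bifactor"`.
#' @param nodes Quadrature nodes per dimension.
#' @param max_iter,tol EM iteration cap and absolute loglik tolerance.
#' @return Object of class `ocd_graded_cfa`: `pars` (per item: slopes per
#'   dimension and ordered cumulative intercepts), `corr` (correlated
#'   structure), `loglik`,
#'   `npar`, `AIC`, `BIC`, `n_persons`, `converged`, `iterations`,
#'   `ascent_ok`.
#' @export
fit_graded_structure <- function(sev, groups = NULL,
                                 structure = c("unidimensional",
                                               "correlated", "bifactor"),
                                 nodes = 11L, max_iter = 200L, tol = 1e-4) {
  structure_ <- match.arg(structure)
  m <- resp_matrix(sev)
  if (is.null(groups)) groups <- severity_groups(colnames(m))
  if (!all(colnames(m) %in% groups$item_id)) {
    abort("groups must cover every item")
  }
  coll <- collapse_categories(m)
  y <- coll$y
  ncat <- coll$ncat
  grp <- groups$group[match(colnames(m), groups$item_id)]
  grp_lv <- unique(grp)
  n <- nrow(y); J <- ncol(y)
  gh <- gh_normal(nodes)

  ## latent dimension layout: column 1 = general/single factor; for the
  ## correlated structure the columns are the group factors themselves
  n_dim <- switch(structure_, unidimensional = 1L,
                  correlated = length(grp_lv),
                  bifactor = 1L + length(grp_lv))
  Z <- as.matrix(expand.grid(rep(list(gh$x), n_dim)))
  logw <- rowSums(matrix(log(gh$w)[as.matrix(expand.grid(
    rep(list(seq_along(gh$w)), n_dim)))], nrow(Z), n_dim))
  ## which latent columns load on item j
  dims_of <- function(j) {
    g <- match(grp[j], grp_lv)
    switch(structure_, unidimensional = 1L, correlated = g,
           bifactor = c(1L, 1L + g))
  }
  corr <- if (structure_ == "correlated") diag(length(grp_lv)) else NULL

  ## starting values: unit slope on each loaded dimension (specifics 0.5),
  ## thresholds from marginal cumulative proportions
  pars <- lapply(seq_len(J), function(j) {
    v <- y[!is.na(y[, j]), j]
    pg <- pmin(pmax(vapply(seq_len(ncat[j] - 1L), function(k) mean(v >= k),
                           numeric(1)), 1e-3), 1 - 1e-3)
    nd <- length(dims_of(j))
    list(a = c(1, rep(0.5, nd - 1L)), c = sort(qlogis(pg), decreasing = TRUE))
  })

  theta_nodes <- function(corr_) {
    if (structure_ == "correlated") Z %*% chol_psd(corr_) else Z
  }
  estep <- function(pars_, corr_) {
    Theta <- theta_nodes(corr_)
    ll <- matrix(0, n, nrow(Z))
    for (j in seq_len(J)) {
      eta <- Theta[, dims_of(j), drop = FALSE] %*% pars_[[j]]$a
      cum <- cbind(1, plogis(outer(drop(eta), pars_[[j]]$c, "+")), 0)
      lp <- t(log(clamp_p(cum[, -ncol(cum), drop = FALSE] -
                            cum[, -1, drop = FALSE])))   # K x nodes
      obs <- which(!is.na(y[, j]))
      ll[obs, ] <- ll[obs, ] + lp[y[obs, j] + 1L, , drop = FALSE]
    }
    lw <- sweep(ll, 2L, logw, "+")
    li <- row_logsumexp(lw)
    list(loglik = sum(li), post = exp(lw - li), Theta = Theta)
  }

  ll_old <- -Inf; ll <- NA_real_
  ascent_ok <- TRUE; converged <- FALSE; iter <- 0L
  repeat {
    iter <- iter + 1L
    es <- estep(pars, corr)
    if (es$loglik < ll_old - 1e-6) ascent_ok <- FALSE
    if (abs(es$loglik - ll_old) < tol || iter >= max_iter) {
      converged <- abs(es$loglik - ll_old) < tol
      ll <- es$loglik
      break
    }
    ll_old <- es$loglik
    for (j in seq_len(J)) {
      X <- es$Theta[, dims_of(j), drop = FALSE]
      r <- vapply(seq_len(ncat[j]) - 1L, function(k) {
        colSums(es$post[which(y[, j] == k), , drop = FALSE])
      }, numeric(nrow(Z)))                  # nodes x K
      pars[[j]] <- graded_mstep_item(t(r), pars[[j]], X)
    }
    if (structure_ == "correlated") {
      g <- colSums(es$post)
      S <- crossprod(es$Theta, es$Theta * g) / n
      sdd <- sqrt(pmax(diag(S), 1e-8))
      corr_new <- S / tcrossprod(sdd); diag(corr_new) <- 1
      for (lam in c(1, 0.5, 0.25)) {
        cand <- (1 - lam) * corr + lam * corr_new
        if (estep(pars, cand)$loglik >= es$loglik) {
          corr <- cand
          break
        }
      }
    }
  }
  npar <- sum(vapply(seq_len(J), function(j) {
    length(pars[[j]]$a) + ncat[j] - 1L
  }, integer(1))) + if (structure_ == "correlated")
    length(grp_lv) * (length(grp_lv) - 1L) / 2L else 0L
  ptab <- purrr::map_dfr(seq_len(J), function(j) {
    a <- pars[[j]]$a
    tibble::tibble(item_id = colnames(y)[j], group = grp[j],
                   slope_general = if (structure_ == "correlated")
                     NA_real_ else a[1],
                   slope_specific = if (structure_ == "correlated") a[1]
                   else if (length(a) > 1) a[2] else 0,
                   intercepts = list(pars[[j]]$c))
  })
  structure(list(pars = ptab, raw_pars = pars, corr = corr, loglik = ll,
                 npar = npar, AIC = -2 * ll + 2 * npar,
                 BIC = -2 * ll + npar * log(n), n_persons = n,
                 structure = structure_, converged = converged,
                 iterations = iter, ascent_ok = ascent_ok,
                 remap = coll$remap),
            class = "ocd_graded_cfa")
}

## One graded item's M-step: slopes plus decreasing cumulative intercepts,
## optimised on an unconstrained transform.
graded_mstep_item <- function(r, par0, X) {
  K <- nrow(r)
  nd <- ncol(X)
  enc <- function(p) c(p$a, p$c[1],
                       if (K > 2) log(pmax(-diff(p$c), 1e-6)))
  dec <- function(v) list(a = v[seq_len(nd)],
                          c = cumsum(c(v[nd + 1],
                                       if (K > 2) -exp(v[(nd + 2):(nd + K - 1)]))))
  obj <- function(v) {
    p <- dec(v)
    eta <- drop(X %*% p$a)
    cum <- cbind(1, plogis(outer(eta, p$c, "+")), 0)
    lp <- log(clamp_p(cum[, -ncol(cum), drop = FALSE] -
                        cum[, -1, drop = FALSE]))
    -sum(r * t(lp))
  }
  res <- optim(enc(par0), obj, method = "BFGS",
               control = list(maxit = 80, reltol = 1e-9))
  dec(res$par)
}

#' @export
print.ocd_graded_cfa <- function(x, ...) {
  cat("Graded latent structure fit:", x$structure, "\n")
  cat(sprintf("  %d persons, %d items | loglik %.2f | AIC %.1f | BIC %.1f\n",
              x$n_persons, nrow(x$pars), x$loglik, x$AIC, x$BIC))
  invisible(x)
}

#' @export
glance.ocd_graded_cfa <- function(x, ...) {
  tibble::tibble(structure = x$structure, loglik = x$loglik, npar = x$npar,
                 AIC = x$AIC, BIC = x$BIC, n_persons = x$n_persons,
                 converged = x$converged, iterations = x$iterations,
                 ascent_ok = x$ascent_ok)
}

#' @export
tidy.ocd_graded_cfa <- function(x, ...) x$pars
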