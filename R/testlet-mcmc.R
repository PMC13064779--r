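## Bayesian estimation of the 2PL testlet response model by
## Metropolis-within-Gibbs MCMC: multi-chain running, Gelman-Rubin
## convergence checking, item parameter summaries and person propensity
## scores with posterior SEs.

#' MCMC configuration for the testlet model
#'
#' Defaults follow the production settings the model is documented with:
#' 40 000 iterations per chain, the first 10 000 discarded as burn-in, two
#' chains with overdispersed starting values, and a potential scale
#' reduction factor below 1.2 required of every monitored item parameter
#' before inferences are drawn. Tests and examples use far shorter chains.
#'
#' @param n_iter Iterations per chain.
#' @param burn_in Burn-in iterations discarded (must be < `n_iter`).
#' @param n_chains Number of chains (>= 2, for convergence checking).
#' @param threshold PSRF convergence threshold (> 1).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param prior_a_sd Prior SD of log discrimination, `log a ~ N(0, sd^2)`.
#' @param prior_b_sd Prior SD of item severity, `b ~ N(0, sd^2)`.
#' @param sigma_prior Shape and rate of the Inverse-Gamma prior on the
#'   testlet variances.
#' @param sigma_fixed Optional fixed per-domain testlet SDs (a single value
#'   is recycled); `0` collapses a domain to the plain 2PL and `NULL`
#'   (default) estimates all variances.
#' @param update_items Sample item parameters (set `FALSE` to hold them at
#'   their initial values, e.g. for oracle checks of the person posterior).
#' @param target_accept Robbins-Monro target acceptance rate for the
#'   adaptive random-walk proposals (adaptation runs during burn-in only,
#'   preserving detailed balance afterwards).
#' @return List of class `ocd_mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 40000L, burn_in = 10000L, n_chains = 2L,
                        threshold = 1.2, thin = 1L, prior_a_sd = 1,
                        prior_b_sd = 2, sigma_prior = c(shape = 2, rate = 1),
                        sigma_fixed = NULL, update_items = TRUE,
                        target_accept = 0.44) {
  if (burn_in >= n_iter) abort("burn_in must be smaller than n_iter")
  if (n_chains < 2L) abort("convergence checking requires >= 2 chains")
  if (threshold <= 1) abort("threshold must exceed 1")
  if (thin < 1L) abort("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), threshold = threshold,
                 thin = as.integer(thin), prior_a_sd = prior_a_sd,
                 prior_b_sd = prior_b_sd, sigma_prior = sigma_prior,
                 sigma_fixed = sigma_fixed, update_items = update_items,
                 target_accept = target_accept),
            class = "ocd_mcmc_config")
}

#' Run one MCMC chain for the testlet model
#'
#' A Metropolis-within-Gibbs sweep updates, in order, person propensities
#' (random walk), testlet effects (random walk per domain), a
#' likelihood-invariant joint recentering of each person's propensity and
#' testlet effects (exact Gibbs draw), item slope/severity pairs (joint
#' random walk on `(log a, b)`), and the testlet variances (conjugate
#' inverse-gamma draw). Proposal scales adapt during burn-in only. Given a
#' seed the returned draws are bit-identical across runs.
#'
#' @param data Checklist tibble.
#' @param map Domain map tibble.
#' @param config An [mcmc_config()].
#' @param seed Integer seed for the chain.
#' @param chain_index 1-based chain number; sets the sign of the
#'   overdispersed `log a` start (alternating by chain).
#' @param init Optional named list overriding starting values (`theta`,
#'   `a`, `b`, `sigma`, `gamma`).
#' @return List with matrices of retained draws (`theta`, `a`, `b`,
#'   `sigma` as SDs, `gamma`), acceptance rates and the seed.
#' @export
run_chain <- function(data, map, config = mcmc_config(), seed = 1L,
                      chain_index = 1L, init = NULL) {
  if (ncol(data) < 2L) abort("data must contain at least one item")
  if (nrow(data) == 0L) abort("data must contain at least one person")
  m <- resp_matrix(data)
  check_domain_map(map, strict = FALSE)
  if (!all(colnames(m) %in% map$item_id)) {
    abort("domain map must cover every item")
  }
  doms <- unique(map$domain[match(colnames(m), map$item_id)])
  dom0 <- match(map$domain[match(colnames(m), map$item_id)], doms) - 1L
  n <- nrow(m); J <- ncol(m); D <- length(doms)
  sfix <- config$sigma_fixed
  if (!is.null(sfix)) sfix <- rep_len(sfix, D)
  sigma_zero <- if (is.null(sfix)) rep(FALSE, D) else sfix == 0
  update_sigma <- is.null(sfix)

  set.seed(seed)
  ## overdispersed starts: theta ~ N(0, 2^2), log a ~ N(+/-0.5, 0.5^2)
  ## with sign alternating by chain index, b ~ N(0, 1)
  theta0 <- rnorm(n, 0, 2)
  la_mu <- if (chain_index %% 2L == 1L) 0.5 else -0.5
  a0 <- exp(rnorm(J, la_mu, 0.5))
  b0 <- rnorm(J, 0, 1)
  sig0 <- if (is.null(sfix)) rep(1, D) else pmax(sfix, 1e-8)^2
  gamma0 <- matrix(0, n, D)
  for (d in seq_len(D)) {
    if (!sigma_zero[d]) gamma0[, d] <- rnorm(n, 0, sqrt(sig0[d]))
  }
  if (!is.null(init)) {
    if (!is.null(init$theta)) theta0 <- init$theta
    if (!is.null(init$a)) a0 <- init$a
    if (!is.null(init$b)) b0 <- init$b
    if (!is.null(init$sigma)) sig0 <- pmax(init$sigma, 1e-8)^2
    if (!is.null(init$gamma)) gamma0 <- init$gamma
  }
  ym <- m
  storage.mode(ym) <- "integer"
  out <- .testlet_sampler(ym, dom0, config$n_iter, config$burn_in,
                          config$thin, theta0, gamma0, a0, b0, sig0,
                          sigma_zero, config$update_items, update_sigma,
                          config$prior_a_sd, config$prior_b_sd,
                          config$sigma_prior[["shape"]],
                          config$sigma_prior[["rate"]],
                          config$target_accept)
  colnames(out$theta) <- rownames(m)
  colnames(out$a) <- colnames(m)
  colnames(out$b) <- colnames(m)
  colnames(out$sigma) <- doms
  colnames(out$gamma) <- paste(rep(doms, each = n), rep(rownames(m), D),
                               sep = ".")
  out$seed <- seed
  out$chain_index <- chain_index
  out
}

#' Run the full multi-chain testlet MCMC
#'
#' Runs `config$n_chains` chains with distinct seeds and overdispersed
#' starting values and assembles the posterior draws. Convergence is *not*
#' asserted here; check it with [convergence()] before summarising.
#'
#' @inheritParams run_chain
#' @param seed Base seed; per-chain seeds are derived deterministically.
#' @param init Optional starting-value override applied to every chain.
#' @return Object of class `ocd_testlet_post`: per-chain draw matrices,
#'   the configuration, ids, and an `all_zero` person flag.
#' @export
run_mcmc <- function(data, map, config = mcmc_config(), seed = 1L,
                     init = NULL) {
  chains <- purrr::map(seq_len(config$n_chains), function(cc) {
    run_chain(data, map, config, seed = derive_seed(seed, 100L + cc),
              chain_index = cc, init = init)
  })
  m <- resp_matrix(data)
  structure(list(chains = chains, config = config,
                 item_ids = colnames(m), person_ids = rownames(m),
                 domains = colnames(chains[[1]]$sigma),
                 map = map, seed = seed,
                 all_zero = rowSums(m == 1, na.rm = TRUE) == 0),
            class = "ocd_testlet_post")
}

#' Potential scale reduction factor
#'
#' Gelman-Rubin convergence diagnostic from parallel chains:
#' `sqrt(((n - 1) / n * W + B / n) / W)` with `W` the mean within-chain
#' variance and `B/n` the variance of the chain means. Identical chains
#' give `sqrt((n - 1) / n) <= 1`; chains exploring different regions give
#' values well above 1.
#'
#' @param draws Matrix of draws, one column per chain.
#' @return Scalar PSRF.
#' @export
psrf <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) abort("PSRF needs >= 2 chains")
  n <- nrow(draws)
  W <- mean(apply(draws, 2L, var))
  Bn <- var(colMeans(draws))
  if (W <= 0) return(if (Bn <= 0) sqrt((n - 1) / n) else Inf)
  sqrt(((n - 1) / n * W + Bn) / W)
}

#' Multi-chain convergence report for a testlet posterior
#'
#' Computes the PSRF for every monitored parameter (item discriminations,
#' item severities and the per-domain testlet SDs — person propensities
#' are not monitored) and summarises the item-parameter PSRFs at their
#' 50th and 97.5th percentiles. The run passes when every monitored PSRF
#' is below the configured threshold.
#'
#' @param post An `ocd_testlet_post`.
#' @param threshold PSRF threshold (default from the run's configuration).
#' @return Object of class `ocd_convergence`: tibble `params` (parameter,
#'   psrf), `q50`, `q975`, `pass`, `threshold`.
#' @export
convergence <- function(post, threshold = post$config$threshold) {
  lens <- unique(purrr::map_int(post$chains, function(ch) nrow(ch$a)))
  if (length(lens) != 1L) abort("chains must have equal length")
  pull <- function(block, k) {
    vapply(post$chains, function(ch) ch[[block]][, k], numeric(lens))
  }
  items <- purrr::map_dfr(c("a", "b"), function(bl) {
    tibble::tibble(
      parameter = paste0(bl, "[", post$item_ids, "]"),
      block = bl,
      psrf = vapply(seq_along(post$item_ids),
                    function(k) psrf(pull(bl, k)), numeric(1)))
  })
  est_sigma <- is.null(post$config$sigma_fixed)
  sig <- if (est_sigma) tibble::tibble(
    parameter = paste0("sigma[", post$domains, "]"), block = "sigma",
    psrf = vapply(seq_along(post$domains),
                  function(k) psrf(pull("sigma", k)), numeric(1))
  ) else NULL
  mon <- if (post$config$update_items) dplyr::bind_rows(items, sig) else sig
  if (is.null(mon) || nrow(mon) == 0L) {
    mon <- tibble::tibble(parameter = character(), block = character(),
                          psrf = numeric())
  }
  item_psrf <- items$psrf[rep(post$config$update_items, nrow(items))]
  structure(list(params = mon,
                 q50 = if (length(item_psrf))
                   unname(quantile(item_psrf, 0.5)) else NA_real_,
                 q975 = if (length(item_psrf))
                   unname(quantile(item_psrf, 0.975)) else NA_real_,
                 pass = all(mon$psrf < threshold),
                 threshold = threshold),
            class = "ocd_convergence")
}

#' @export
print.ocd_convergence <- function(x, ...) {
  cat(sprintf("Convergence (PSRF < %.2f): %s\n", x$threshold,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  item-parameter PSRF quantiles: 50th = %.2f, 97.5th = %.2f\n",
              x$q50, x$q975))
  invisible(x)
}

check_gate <- function(post, override) {
  conv <- convergence(post)
  if (!conv$pass && !override) {
    abort(paste0("chains have not converged (max PSRF ",
                 sprintf("%.3f", max(conv$params$psrf)),
                 " >= ", post$config$threshold,
                 "); rerun longer or pass override = TRUE"))
  }
  if (!conv$pass && override) {
    warn("summarising despite failed convergence check (override = TRUE)")
  }
  conv
}

#' Posterior item parameter table
#'
#' Pooled-chain posterior means and SDs of each item's discrimination
#' (slope) and severity, in the style of a published item-parameter table.
#' Refuses to summarise before the convergence check passes unless
#' `override = TRUE`.
#'
#' @param post An `ocd_testlet_post`.
#' @param sort_by_b Sort items by posterior mean severity.
#' @param override Summarise even if convergence failed (logged warning).
#' @return Tibble: `item_id`, `domain`, `a_mean`, `a_sd`, `b_mean`, `b_sd`.
#' @export
summarize_items <- function(post, sort_by_b = FALSE, override = FALSE) {
  check_gate(post, override)
  a_all <- do.call(rbind, purrr::map(post$chains, "a"))
  b_all <- do.call(rbind, purrr::map(post$chains, "b"))
  out <- tibble::tibble(
    item_id = post$item_ids,
    domain = post$map$domain[match(post$item_ids, post$map$item_id)],
    a_mean = colMeans(a_all), a_sd = apply(a_all, 2L, sd),
    b_mean = colMeans(b_all), b_sd = apply(b_all, 2L, sd))
  if (sort_by_b) out <- dplyr::arrange(out, .data$b_mean)
  out
}

#' Posterior testlet-SD table
#'
#' @inheritParams summarize_items
#' @return Tibble: `domain`, `sigma_mean`, `sigma_sd` (posterior mean and
#'   SD of each domain's testlet effect SD).
#' @export
summarize_testlets <- function(post, override = FALSE) {
  check_gate(post, override)
  s_all <- do.call(rbind, purrr::map(post$chains, "sigma"))
  tibble::tibble(domain = post$domains, sigma_mean = colMeans(s_all),
                 sigma_sd = apply(s_all, 2L, sd))
}

#' Posterior person propensity scores
#'
#' Posterior mean and SD of each person's latent OCD propensity (population
#' scale mean 0, SD 1). Persons endorsing no symptom are flagged: the data
#' cannot rank-order them further, so their scores cluster at the low end
#' with wide posterior SDs.
#'
#' @inheritParams summarize_items
#' @return Tibble: `person_id`, `score`, `se`, `all_zero`.
#' @export
score_persons <- function(post, override = FALSE) {
  check_gate(post, override)
  th <- do.call(rbind, purrr::map(post$chains, "theta"))
  tibble::tibble(person_id = post$person_ids, score = colMeans(th),
                 se = apply(th, 2L, sd), all_zero = post$all_zero)
}

#' @export
print.ocd_testlet_post <- function(x, ...) {
  cat(sprintf("Testlet model posterior: %d persons x %d items, %d chains x %d kept draws\n",
              length(x$person_ids), length(x$item_ids), length(x$chains),
              nrow(x$chains[[1]]$a)))
  invisible(x)
}

#' @export
tidy.ocd_testlet_post <- function(x, ...) {
  summarize_items(x, override = TRUE)
}

#' @export
glance.ocd_testlet_post <- function(x, ...) {
  conv <- convergence(x)
  tibble::tibble(n_persons = length(x$person_ids),
                 n_items = length(x$item_ids),
                 n_chains = length(x$chains),
                 n_draws = nrow(x$chains[[1]]$a) * length(x$chains),
                 psrf_q50 = conv$q50, psrf_q975 = conv$q975,
                 converged = conv$pass)
}

#' Item characteristic curves from a testlet posterior
#'
#' @param object An `ocd_testlet_post`.
#' @param items Item ids to display (default: 4 spanning the severity
#'   range).
#' @param ... Unused.
#' @return A ggplot of endorsement probability against propensity.
#' @export
autoplot.ocd_testlet_post <- function(object, items = NULL, ...) {
  tab <- summarize_items(object, override = TRUE)
  if (is.null(items)) {
    tab <- dplyr::arrange(tab, .data$b_mean)
    items <- tab$item_id[unique(round(seq(1, nrow(tab), length.out = 4)))]
  }
  tab <- tab[tab$item_id %in% items, ]
  grid_df <- tidyr::expand_grid(item_id = tab$item_id,
                                theta = seq(-3, 3, by = 0.05))
  grid_df <- dplyr::left_join(grid_df, tab, by = "item_id")
  grid_df$p <- plogis(grid_df$a_mean * (grid_df$theta - grid_df$b_mean))
  ggplot2::ggplot(grid_df, ggplot2::aes(x = .data$theta, y = .data$p,
                                        colour = .data$item_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "OCD propensity (SD units)",
                  y = "endorsement probability", colour = "item") +
    ggplot2::theme_minimal()
}
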