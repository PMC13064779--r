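## Sampler correctness: determinism, bookkeeping, convergence diagnostics,
## and agreement with dense-grid posteriors on tiny instances. Full-scale
## parameter recovery lives in test-acceptance.R.

tiny_study <- function(n = 30, n_items = 6, seed = 1, sd_d = 0.8) {
  set.seed(seed)
  items <- tibble::tibble(item_id = sprintf("i%02d", seq_len(n_items)),
                          domain = rep(c("taboo", "contamination"),
                                       length.out = n_items),
                          a = runif(n_items, 0.8, 2),
                          b = runif(n_items, -0.5, 1.2))
  persons <- draw_persons(sim_config(n_persons = n, unaffected_frac = 0,
                                     testlet_sd = sd_d, seed = seed + 1))
  resp <- simulate_testlet_responses(
    list(items = items,
         testlet_sd = c(taboo = sd_d, contamination = sd_d)),
    persons, seed = seed + 2)
  list(resp = resp, map = items[, c("item_id", "domain")], items = items,
       persons = persons)
}

test_that("chains are bit-identical under a fixed seed and configs validate", {
  st <- tiny_study()
  cfg <- mcmc_config(n_iter = 300, burn_in = 100)
  c1 <- run_chain(st$resp, st$map, cfg, seed = 5)
  c2 <- run_chain(st$resp, st$map, cfg, seed = 5)
  expect_identical(c1$a, c2$a)
  expect_identical(c1$theta, c2$theta)
  expect_identical(c1$gamma, c2$gamma)
  expect_error(mcmc_config(n_chains = 1), ">= 2 chains")
  expect_error(mcmc_config(n_iter = 100, burn_in = 100), "smaller")
  expect_error(mcmc_config(threshold = 0.9), "exceed 1")
  expect_error(run_chain(st$resp[, 1, drop = FALSE], st$map, cfg),
               "at least one item")
})

test_that("posterior bookkeeping returns the configured number of draws", {
  st <- tiny_study(n = 50)
  cfg <- mcmc_config(n_iter = 2000, burn_in = 500)
  post <- run_mcmc(st$resp, st$map, cfg, seed = 7)
  expect_length(post$chains, 2L)
  for (ch in post$chains) {
    expect_equal(nrow(ch$a), 1500L)
    expect_equal(ncol(ch$theta), 50L)
    expect_equal(ncol(ch$gamma), 100L)
  }
  cfg5 <- mcmc_config(n_iter = 2000, burn_in = 500, thin = 5)
  post5 <- run_mcmc(st$resp, st$map, cfg5, seed = 7)
  expect_equal(nrow(post5$chains[[1]]$b), 300L)
  ## full posterior run is reproducible end to end
  post_b <- run_mcmc(st$resp, st$map, cfg, seed = 7)
  expect_identical(post$chains[[2]]$b, post_b$chains[[2]]$b)
})

test_that("PSRF separates identical chains from separated chains", {
  set.seed(8)
  x <- rnorm(1000)
  expect_equal(psrf(cbind(x, x)), sqrt(999 / 1000))
  expect_lte(psrf(cbind(x, x)), 1)
  far <- cbind(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  expect_gt(psrf(far), 1.2)
  expect_error(psrf(matrix(x, ncol = 1)), ">= 2 chains")
})

test_that("convergence reports quantiles over item parameters and gates summaries", {
  st <- tiny_study(n = 60)
  post <- run_mcmc(st$resp, st$map,
                   mcmc_config(n_iter = 1200, burn_in = 400), seed = 9)
  cv <- convergence(post)
  expect_true(all(is.finite(cv$params$psrf)))
  expect_gte(cv$q975, cv$q50)
  expect_equal(cv$pass, all(cv$params$psrf < 1.2))
  ## separated fake chains must fail the gate
  bad <- post
  for (k in seq_along(bad$chains)) {
    bad$chains[[k]]$a <- bad$chains[[k]]$a + (k - 1) * 10
  }
  expect_false(convergence(bad)$pass)
  expect_error(summarize_items(bad), "not converged")
  expect_warning(it <- summarize_items(bad, override = TRUE), "override")
  expect_equal(nrow(it), 6L)
})

test_that("posterior propensity means match a dense-grid Bayes oracle on a tiny instance", {
  ## 4 persons x 3 items, one domain, item parameters and testlet SD fixed
  a <- c(1.2, 0.9, 1.6); b <- c(-0.3, 0.4, 0.9); sd_d <- 0.8
  y <- matrix(c(1, 1, 1,
                0, 0, 0,
                1, 0, 1,
                0, 1, 0), 4, 3, byrow = TRUE,
              dimnames = list(paste0("p", 1:4), paste0("i", 1:3)))
  dat <- as_resp_tbl(y)
  map <- tibble::tibble(item_id = colnames(y), domain = "taboo")
  cfg <- mcmc_config(n_iter = 6000, burn_in = 1000, sigma_fixed = sd_d,
                     update_items = FALSE)
  post <- run_mcmc(dat, map, cfg, seed = 11,
                   init = list(a = a, b = b))
  th <- do.call(rbind, purrr::map(post$chains, "theta"))
  for (i in 1:4) {
    oracle <- oracle_testlet_eap(y[i, ], a, b, sd_d)
    mc_se <- mcse_batch(th[, i])
    expect_lt(abs(mean(th[, i]) - oracle), 3 * max(mc_se, 0.01))
  }
  ## monotone scoring: the all-endorsing person outranks the all-zero one
  expect_gt(mean(th[, 1]), mean(th[, 2]))
})

test_that("with zero testlet variance the sampler agrees with marginal-ML 2PL", {
  set.seed(12)
  items <- tibble::tibble(item_id = sprintf("i%02d", 1:15), domain = "taboo",
                          a = runif(15, 0.8, 2), b = runif(15, -0.8, 1.5))
  persons <- draw_persons(sim_config(n_persons = 1000, unaffected_frac = 0,
                                     testlet_sd = 0, seed = 13))
  resp <- simulate_testlet_responses(list(items = items,
                                          testlet_sd = c(taboo = 0)),
                                     persons, seed = 14)
  map <- items[, c("item_id", "domain")]
  post <- run_mcmc(resp, map,
                   mcmc_config(n_iter = 3000, burn_in = 1000,
                               sigma_fixed = 0), seed = 15)
  it <- summarize_items(post, override = TRUE) |> suppressWarnings()
  f <- fit_latent_model(resp, spec = model_spec("unidimensional",
                                                tol = 1e-4))
  b_ml <- -f$pars$intercept / f$pars$slope_general
  expect_true(all(abs(it$b_mean - b_ml) <= 2.5 * it$b_sd))
})

test_that("person scores respect exchangeability and endorsement ordering", {
  st <- tiny_study(n = 40, seed = 16)
  m <- as.matrix(st$resp[, -1])
  m[1, ] <- m[2, ]              # two persons share a response row
  m[3, ] <- 1                   # endorses everything
  m[4, ] <- 0                   # endorses nothing
  dat <- as_resp_tbl(m)
  post <- run_mcmc(dat, st$map, mcmc_config(n_iter = 4000, burn_in = 1000),
                   seed = 17)
  sc <- score_persons(post, override = TRUE) |> suppressWarnings()
  expect_lt(abs(sc$score[1] - sc$score[2]), 0.15)
  expect_gt(sc$score[3], mean(sc$score))
  expect_lt(sc$score[4], mean(sc$score))
  expect_true(sc$all_zero[4])
  expect_false(sc$all_zero[3])
})
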