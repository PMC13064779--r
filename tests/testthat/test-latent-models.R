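## Small closed-form cases and properties of the marginal-ML engines.
## Heavier simulation studies live in test-acceptance.R.

toy_pars <- function(items, domain = "all", ag, as_ = 0, cc) {
  tibble::tibble(item_id = items, domain = domain, slope_general = ag,
                 slope_specific = as_, intercept = cc)
}

test_that("single-item symmetric cases have closed-form marginal likelihoods", {
  dat <- as_resp_tbl(matrix(1, 1, 1, dimnames = list("p1", "i1")))
  pars <- toy_pars("i1", ag = 1, cc = 0)
  ll <- marginal_loglik(dat, pars, model_spec("unidimensional",
                                              nodes_general = 61))
  expect_equal(ll, log(0.5), tolerance = 1e-9)
  ## zero slopes: likelihood is Bernoulli(1/2) per observed cell
  set.seed(31)
  y <- matrix(rbinom(12, 1, 0.5), 4, 3)
  dat2 <- as_resp_tbl(y)
  pars2 <- toy_pars(colnames(dat2)[-1], ag = 0, cc = 0)
  ll2 <- marginal_loglik(dat2, pars2, model_spec("unidimensional"))
  expect_equal(ll2, 12 * log(0.5), tolerance = 1e-9)
  expect_error(marginal_loglik(dat2, dplyr::mutate(pars2, intercept = NaN),
                               model_spec("unidimensional")), "non-finite")
})

test_that("quadrature marginal loglik matches dense-grid brute force on random toys", {
  set.seed(32)
  y <- matrix(rbinom(12, 1, 0.5), 4, 3,
              dimnames = list(paste0("p", 1:4), paste0("i", 1:3)))
  y[2, 3] <- NA
  dat <- as_resp_tbl(y)
  a <- runif(3, 0.5, 2); cc <- runif(3, -1, 1)
  ## unidimensional
  ll_u <- marginal_loglik(dat, toy_pars(colnames(y), ag = a, cc = cc),
                          model_spec("unidimensional", nodes_general = 101))
  expect_equal(ll_u, oracle_loglik_uni(y, a, cc),
               tolerance = 1e-6)
  ## bifactor with one domain (2 latent dimensions)
  as_ <- runif(3, 0.3, 1)
  map1 <- tibble::tibble(item_id = colnames(y), domain = "taboo")
  ll_b <- marginal_loglik(dat, toy_pars(colnames(y), domain = "taboo",
                                        ag = a, as_ = as_, cc = cc),
                          model_spec("bifactor", nodes_general = 61,
                                     nodes_specific = 61), map = map1)
  expect_equal(ll_b, oracle_loglik_bifactor1(y, a, as_, cc),
               tolerance = 1e-6)
  ## two correlated factors
  map2 <- tibble::tibble(item_id = colnames(y),
                         domain = c("taboo", "taboo", "contamination"))
  rho <- 0.55
  corr <- matrix(c(1, rho, rho, 1), 2)
  ll_c <- marginal_loglik(dat, toy_pars(colnames(y),
                                        domain = map2$domain,
                                        ag = NA, as_ = a, cc = cc),
                          model_spec("correlated", nodes_correlated = 61),
                          map = map2, corr = corr)
  expect_equal(ll_c, oracle_loglik_corr2(y, a, cc, c(1, 1, 2), rho),
               tolerance = 1e-6)
})

test_that("EM ascends the likelihood and the bifactor fit nests the unidimensional one", {
  set.seed(33)
  items <- tibble::tibble(item_id = sprintf("i%02d", 1:10),
                          domain = rep(c("taboo", "contamination"), each = 5),
                          a = runif(10, 0.8, 2), b = runif(10, -0.5, 1))
  persons <- draw_persons(sim_config(n_persons = 500, unaffected_frac = 0,
                                     testlet_sd = 0.7, seed = 34))
  resp <- simulate_testlet_responses(
    list(items = items, testlet_sd = c(taboo = 0.7, contamination = 0.7)),
    persons, seed = 35)
  map <- items[, c("item_id", "domain")]
  fu <- fit_latent_model(resp, map, model_spec("unidimensional", tol = 1e-5))
  fb <- fit_latent_model(resp, map, model_spec("bifactor", tol = 1e-5))
  fc <- fit_latent_model(resp, map, model_spec("correlated", tol = 1e-4,
                                               nodes_correlated = 15))
  expect_true(fu$ascent_ok)
  expect_true(fb$ascent_ok)
  expect_true(fc$ascent_ok)
  expect_gte(fb$loglik, fu$loglik - 1e-4)
  ## fit indices are internally consistent
  for (f in list(fu, fb, fc)) {
    expect_equal(f$AIC, -2 * f$loglik + 2 * f$npar)
    expect_equal(f$BIC, -2 * f$loglik + f$npar * log(f$n_persons))
  }
  ## doubling quadrature nodes barely moves the loglik on a standard
  ## 300-person fixture
  sub <- resp[1:300, ]
  ll_dense <- marginal_loglik(sub, fu$pars,
                              model_spec("unidimensional",
                                         nodes_general = 42))
  expect_lt(abs(ll_dense - marginal_loglik(
    sub, fu$pars, model_spec("unidimensional", nodes_general = 21))), 0.01)
})

test_that("unidimensional 2PL recovers generating parameters across seeds", {
  cors_a <- cors_b <- numeric(5)
  for (s in 1:5) {
    set.seed(40 + s)
    items <- tibble::tibble(item_id = sprintf("i%02d", 1:20),
                            domain = "taboo",
                            a = runif(20, 0.8, 2.5), b = runif(20, -1, 2))
    persons <- draw_persons(sim_config(n_persons = 2000,
                                       unaffected_frac = 0,
                                       testlet_sd = 0, seed = 50 + s))
    resp <- simulate_testlet_responses(
      list(items = items, testlet_sd = c(taboo = 0)), persons,
      seed = 60 + s)
    f <- fit_latent_model(resp, spec = model_spec("unidimensional",
                                                  tol = 1e-4))
    b_hat <- -f$pars$intercept / f$pars$slope_general
    cors_a[s] <- cor(items$a, f$pars$slope_general)
    cors_b[s] <- cor(items$b, b_hat)
  }
  expect_true(all(cors_b >= 0.95))
  expect_true(all(cors_a >= 0.85))
})

test_that("degenerate items are ridge-penalised, flagged and bounded", {
  set.seed(70)
  y <- matrix(rbinom(200, 1, 0.5), 50, 4)
  y[, 4] <- 0   # endorsed by nobody
  dat <- as_resp_tbl(y)
  expect_warning(f <- fit_latent_model(dat, spec = model_spec("unidimensional")),
                 "degenerate")
  expect_equal(f$degenerate_items, colnames(dat)[5])
  expect_true(all(is.finite(f$pars$slope_general)) &&
                all(abs(f$pars$intercept) <= 25))
})

test_that("model comparison tables carry deltas and chi-square LRTs", {
  fake <- function(structure, loglik, npar, drop = NULL) {
    structure(list(spec = model_spec(structure, drop_domain = drop),
                   loglik = loglik, npar = npar,
                   AIC = -2 * loglik + 2 * npar,
                   BIC = -2 * loglik + npar * log(100), n_persons = 100L),
              class = "ocd_cfa")
  }
  ## straight AIC difference
  tab <- compare_models(list(m1 = fake("unidimensional", -55, 5),
                             m2 = fake("unidimensional", -50, 5)))
  expect_equal(tab$dAIC, c(10, 0))
  ## identical fits: statistic 0, p = 1
  tab_id <- compare_models(list(m1 = fake("unidimensional", -50, 5),
                                m2 = fake("unidimensional", -50, 5)))
  expect_equal(tab_id$lrt_stat, c(0, 0))
  expect_equal(tab_id$lrt_p, c(1, 1))
  ## -2 delta loglik = 3.84 on 1 df sits at the 5% point
  tab2 <- compare_models(list(small = fake("unidimensional", -51.92, 10),
                              big = fake("bifactor", -50, 11)))
  expect_equal(tab2$lrt_stat[1], 3.84)
  expect_equal(tab2$lrt_p[1], 0.05, tolerance = 1e-3)
  expect_error(compare_models(list(
    a = fake("unidimensional", -5, 2),
    b = structure(list(spec = model_spec(), loglik = -5, npar = 2,
                       AIC = 0, BIC = 0, n_persons = 99L),
                  class = "ocd_cfa"))), "same data")
})

test_that("standardized loadings follow the normal-metric conversion", {
  fake_fit <- structure(
    list(pars = tibble::tibble(item_id = c("i1", "i2", "i3"),
                               domain = "taboo",
                               slope_general = c(1.702, 0, 1.702),
                               slope_specific = c(0, 0, 1.702),
                               intercept = 0),
         spec = model_spec("bifactor")), class = "ocd_cfa")
  lt <- standardized_loadings(fake_fit)
  expect_equal(lt$lambda_general[1], 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(lt$lambda_general[2], 0)
  expect_equal(lt$lambda_general[3], 0.577, tolerance = 1e-3)
  expect_equal(lt$lambda_specific[3], 0.577, tolerance = 1e-3)
  expect_equal(lt$communality[3], 0.667, tolerance = 1e-3)
  expect_true(all(abs(c(lt$lambda_general, lt$lambda_specific)) < 1))
  expect_true(all(lt$communality < 1))
})

test_that("leave-one-domain-out pinpoints the domain carrying specific variance", {
  set.seed(80)
  map <- tibble::tibble(item_id = sprintf("i%02d", 1:15),
                        domain = rep(c("taboo", "contamination",
                                       "hoarding"), each = 5))
  loads <- tibble::tibble(item_id = map$item_id, domain = map$domain,
                          slope_general = runif(15, 0.8, 1.8),
                          slope_specific = ifelse(map$domain ==
                                                    "contamination", 1.3, 0),
                          intercept = runif(15, -1, 0.5))
  resp <- simulate_bifactor_responses(loads, n_persons = 700, seed = 81)
  spec <- model_spec("bifactor", nodes_general = 15, nodes_specific = 9,
                     tol = 1e-3)
  tab <- leave_one_domain_out(resp, map, spec)
  expect_equal(tab$domain_dropped[tab$rank == 1], "contamination")
  full <- attr(tab, "full_fit")
  expect_true(all(tab$loglik <= full$loglik + 1e-4))
})

test_that("EAP scores rise with added endorsements and flag all-zero rows", {
  set.seed(90)
  items <- tibble::tibble(item_id = sprintf("i%02d", 1:12), domain = "taboo",
                          a = runif(12, 0.8, 2), b = runif(12, -0.5, 1.5))
  persons <- draw_persons(sim_config(n_persons = 400, unaffected_frac = 0,
                                     testlet_sd = 0, seed = 91))
  resp <- simulate_testlet_responses(list(items = items,
                                          testlet_sd = c(taboo = 0)),
                                     persons, seed = 92)
  f <- fit_latent_model(resp, spec = model_spec("unidimensional"))
  sc <- score_persons_eap(f, resp)
  expect_true(all(sc$se > 0))
  expect_true(all(sc$all_zero == (sc$n_endorsed == 0)))
  ## flipping one 0 to 1 for a person never lowers the score
  m <- as.matrix(resp[, -1])
  i <- which(rowSums(m) == 5)[1]
  j <- which(m[i, ] == 0)[1]
  m2 <- m
  m2[i, j] <- 1
  sc2 <- score_persons_eap(f, as_resp_tbl(m2))
  expect_gt(sc2$score[i], sc$score[i])
})
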