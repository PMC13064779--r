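test_that("category probabilities telescope to one and match direct evaluation", {
  pr <- grm_category_probs(1, c(-1, 0, 1, 2), 0)
  expect_equal(as.numeric(pr), c(0.2689, 0.2311, 0.2311, 0.1497, 0.1192),
               tolerance = 1e-3)
  th <- seq(-6, 6, by = 0.1)
  prs <- grm_category_probs(1.7, c(-0.5, 0.3, 1.1, 2.4), th)
  expect_true(all(abs(rowSums(prs) - 1) < 1e-12))
  expect_true(all(prs >= 0))
  ## cumulative symmetry: P(Y >= 2) = 1/2 exactly at theta = b2
  pr2 <- grm_category_probs(50, c(-1, 0.4, 1, 2), 0.4)
  expect_equal(sum(pr2[, 3:5]), 0.5, tolerance = 1e-9)
  expect_error(grm_category_probs(1, c(1, 0), 0), "non-decreasing")
  expect_error(grm_category_probs(-1, c(0, 1), 0), "positive")
})

test_that("fitted marginal loglik and EAP match dense-grid oracles on a toy", {
  y <- matrix(c(0, 2, 4,
                1, 1, 0,
                3, NA, 2), 3, 3, byrow = TRUE,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
  sev <- as_resp_tbl(y)
  bank <- tibble::tibble(item_id = paste0("s", 1:3),
                         a = c(1.2, 0.8, 1.6),
                         b1 = c(-1, -0.5, -1.2), b2 = c(-0.2, 0.2, -0.1),
                         b3 = c(0.8, 1.0, 0.7), b4 = c(1.9, 2.2, 1.6))
  pars <- purrr::map(1:3, function(j) {
    list(a = bank$a[j], b = as.numeric(bank[j, c("b1", "b2", "b3", "b4")]))
  })
  ll <- grm_loglik(sev, bank, nodes = 101)
  expect_equal(ll, oracle_grm_loglik(y, pars), tolerance = 1e-6)
  sc <- eap_scores(bank, sev, nodes = 151)
  for (i in 1:3) {
    expect_equal(sc$score[i], oracle_grm_eap(y[i, ], pars),
                 tolerance = 1e-6)
  }
})

test_that("random ratings yield near-zero discrimination with large uncertainty", {
  set.seed(101)
  y <- matrix(sample(0:4, 300 * 3, replace = TRUE), 300, 3)
  colnames(y) <- paste0("s", 1:3)
  ## at a ~ 0 the thresholds stop being identified, so the information
  ## matrix degenerates — that is the flag
  expect_warning(f <- fit_grm(as_resp_tbl(y)), "singular|SEs")
  expect_true(all(f$items$a < 0.35))
  expect_true(all(is.na(f$items$se_a) |
                    f$items$se_a / f$items$a > 0.5 | f$items$a < 0.1))
})

test_that("items with a single observed category are dropped with a warning", {
  y <- cbind(s1 = rep(2L, 40), s2 = sample(0:4, 40, replace = TRUE))
  expect_warning(f <- fit_grm(as_resp_tbl(y), se = FALSE),
                 "< 2 observed")
  expect_equal(f$items$item_id, "s2")
})

test_that("unobserved internal categories are merged downward with a recorded remap", {
  set.seed(102)
  y <- matrix(sample(c(0L, 1L, 4L), 200 * 2, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2)), 200, 2)
  colnames(y) <- c("s1", "s2")
  f <- fit_grm(as_resp_tbl(y))
  expect_equal(f$ncat, c(3L, 3L))
  expect_equal(unname(f$remap$s1[c("0", "1", "4")]), 0:2)
  expect_true(all(is.na(f$items$b3)) && all(is.na(f$items$b4)))
  ## scoring applies the same remap without error
  sc <- eap_scores(f, as_resp_tbl(y))
  expect_true(all(is.finite(sc$score)))
})

test_that("EAP is monotone in any single rating and falls back to the prior", {
  bank <- default_severity_bank()[1:2, ]
  ## exhaustive 2-item toy: raising one rating never lowers the EAP
  grid_y <- expand.grid(y1 = 0:4, y2 = 0:4)
  sev <- as_resp_tbl(as.matrix(grid_y))
  names(sev)[-1] <- bank$item_id
  sc <- eap_scores(bank, sev)
  em <- matrix(sc$score, 5, 5)      # rows y1, cols y2
  expect_true(all(apply(em, 2, diff) > 0))
  expect_true(all(apply(em, 1, diff) > 0))
  ## all-zero row sits below the prior mean; all-missing gets the prior
  miss <- as_resp_tbl(matrix(NA_integer_, 1, 2))
  names(miss)[-1] <- bank$item_id
  sc0 <- eap_scores(bank, miss)
  expect_equal(sc0$score, 0)
  expect_equal(sc0$se, 1)
  expect_true(sc0$prior_fallback)
  expect_lt(em[1, 1], 0)
})

test_that("tidiers expose the item table and fit indices", {
  set.seed(103)
  bank <- default_severity_bank()
  sev <- simulate_severity(bank, rnorm(300), seed = 104)
  f <- fit_grm(sev, se = FALSE)
  expect_equal(nrow(tidy(f)), 10L)
  g <- glance(f)
  expect_equal(g$AIC, -2 * g$loglik + 2 * f$npar)
  expect_true(g$converged)
})

test_that("graded structure comparison nests the unidimensional model in the hierarchical one", {
  set.seed(120)
  bank <- default_severity_bank()
  n <- 600
  eta <- rnorm(n)
  u_obs <- rnorm(n, 0, 0.6)
  u_comp <- rnorm(n, 0, 0.6)
  sev_o <- simulate_severity(bank[1:5, ], eta + u_obs, seed = 121)
  sev_c <- simulate_severity(bank[6:10, ], eta + u_comp, seed = 122)
  sev <- dplyr::bind_cols(sev_o, sev_c[, -1])
  fu <- fit_graded_structure(sev, structure = "unidimensional",
                             nodes = 21, tol = 1e-3)
  fb <- fit_graded_structure(sev, structure = "bifactor", nodes = 9,
                             tol = 1e-2)
  fc <- fit_graded_structure(sev, structure = "correlated", nodes = 15,
                             tol = 1e-3)
  expect_true(fu$ascent_ok && fb$ascent_ok && fc$ascent_ok)
  expect_gte(fb$loglik, fu$loglik - 1e-4)
  expect_gt(fb$npar, fu$npar)
  ## the two group factors should correlate strongly but imperfectly
  expect_gt(fc$corr[1, 2], 0.5)
  expect_lt(fc$corr[1, 2], 0.999)
  for (f in list(fu, fb, fc)) {
    expect_equal(f$AIC, -2 * f$loglik + 2 * f$npar)
  }
})
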