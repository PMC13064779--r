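test_that("item bank draws are deterministic and respect collapsed ranges", {
  cfg <- sim_config(seed = 4)
  b1 <- draw_item_bank(cfg)
  b2 <- draw_item_bank(cfg)
  expect_identical(b1, b2)
  cfg2 <- sim_config(a_range = c(1.78, 1.78), b_range = c(0.55, 0.55))
  bk <- draw_item_bank(cfg2)
  expect_true(all(bk$items$a == 1.78) && all(bk$items$b == 0.55))
  expect_equal(nrow(bk$items), 64L)
  expect_equal(unname(table(bk$items$domain)[unique(bk$items$domain)]),
               c(16L, 13L, 15L, 2L, 18L), ignore_attr = TRUE)
  expect_error(sim_config(n_persons = 0), "positive")
  expect_error(sim_config(a_range = c(-1, 2)), "a_range")
})

test_that("the testlet response function has its logistic symmetries", {
  expect_equal(irf_testlet(2.75, 0.85, 0, 0.85), 0.5)
  expect_equal(irf_testlet(1.78, 0.55, 0, 1.55), plogis(1.78))
  for (a in c(0.5, 1.3, 4)) {
    expect_equal(irf_testlet(a, 0.7, 1.1 - 0.7, 1.1), 0.5)
  }
  expect_error(irf_testlet(-1, 0, 0, 0), "positive")
  ## endorsement strictly decreasing in b at fixed a, theta
  bs <- seq(-3, 3, by = 0.1)
  expect_true(all(diff(irf_testlet(1.5, bs, 0, 0.3)) < 0))
})

test_that("marginal endorsement is one half at the symmetric points", {
  ## a = 0: items carry no information, endorsement rate 1/2
  persons <- draw_persons(sim_config(n_persons = 4000, unaffected_frac = 0,
                                     seed = 8))
  bank0 <- list(items = tibble::tibble(item_id = paste0("i", 1:4),
                                       domain = "taboo", a = 1e-12, b = 0),
                testlet_sd = c(taboo = 0.5))
  r <- simulate_testlet_responses(bank0, persons, seed = 9)
  rates <- colMeans(as.matrix(r[, -1]))
  expect_true(all(abs(rates - 0.5) < 3 * sqrt(0.25 / 4000)))
  ## single item a=1, b=0, sigma=0, theta ~ N(0,1): theta-marginal is 1/2
  persons2 <- draw_persons(sim_config(n_persons = 50000, unaffected_frac = 0,
                                      seed = 10))
  bank1 <- list(items = tibble::tibble(item_id = "i1", domain = "taboo",
                                       a = 1, b = 0),
                testlet_sd = c(taboo = 0))
  r2 <- simulate_testlet_responses(bank1, persons2, seed = 11)
  expect_lt(abs(mean(r2[[2]]) - 0.5), 3 * sqrt(0.25 / 50000))
})

test_that("zero testlet variance reduces the simulation to a plain 2PL", {
  n <- 50000
  set.seed(12)
  items <- tibble::tibble(item_id = paste0("i", 1:6),
                          domain = rep(c("taboo", "contamination"), each = 3),
                          a = runif(6, 0.7, 2), b = runif(6, -0.5, 1.5))
  persons <- draw_persons(sim_config(n_persons = n, unaffected_frac = 0,
                                     testlet_sd = 0, seed = 13))
  r_t <- simulate_testlet_responses(list(items = items,
                                         testlet_sd = c(taboo = 0, contamination = 0)),
                                    persons, seed = 14)
  loads <- tibble::tibble(item_id = items$item_id, domain = items$domain,
                          slope_general = items$a, slope_specific = 0,
                          intercept = -items$a * items$b)
  r_b <- simulate_bifactor_responses(loads, theta0 = persons$theta, seed = 15)
  se <- sqrt(0.25 / n)
  expect_true(all(abs(colMeans(as.matrix(r_t[, -1])) -
                        colMeans(as.matrix(r_b[, -1]))) < 3 * 2 * se))
})

test_that("the testlet parameterisation of the bifactor model reproduces the testlet distribution", {
  ## slope_general = a, slope_specific = a * sd_d, intercept = -a b
  n <- 50000
  sd_d <- 0.8
  items <- tibble::tibble(item_id = paste0("i", 1:4), domain = "taboo",
                          a = c(0.8, 1.2, 1.6, 2.0),
                          b = c(0.2, 0.6, 1.0, 1.4))
  persons <- draw_persons(sim_config(n_persons = n, unaffected_frac = 0,
                                     testlet_sd = sd_d, seed = 16))
  r_t <- simulate_testlet_responses(list(items = items,
                                         testlet_sd = c(taboo = sd_d)),
                                    persons, seed = 17)
  loads <- tibble::tibble(item_id = items$item_id, domain = items$domain,
                          slope_general = items$a,
                          slope_specific = items$a * sd_d,
                          intercept = -items$a * items$b)
  r_b <- simulate_bifactor_responses(loads, n_persons = n, seed = 18)
  mt <- as.matrix(r_t[, -1]); mb <- as.matrix(r_b[, -1])
  se <- sqrt(0.25 / n)
  expect_true(all(abs(colMeans(mt) - colMeans(mb)) < 3 * 2 * se))
  ## within-domain pairwise 2x2 association agrees between the two routes
  for (pair in list(c(1, 2), c(2, 4), c(1, 3))) {
    p11_t <- mean(mt[, pair[1]] & mt[, pair[2]])
    p11_b <- mean(mb[, pair[1]] & mb[, pair[2]])
    expect_lt(abs(p11_t - p11_b), 3 * 2 * sqrt(0.25 / n))
  }
})

test_that("severity categories follow graded-response probabilities", {
  pr <- grm_category_probs(1, c(-1, 0, 1, 2), 0)
  expect_equal(as.numeric(pr),
               c(0.2689, 0.2311, 0.2311, 0.1497, 0.1192), tolerance = 1e-3)
  expect_equal(sum(pr), 1)
  bank <- tibble::tibble(item_id = "s1", a = 1, b1 = -1, b2 = 0, b3 = 1,
                         b4 = 2)
  sev <- simulate_severity(bank, rep(0, 20000), seed = 19)
  emp <- tabulate(sev$s1 + 1L, 5L) / 20000
  expect_true(all(abs(emp - as.numeric(pr)) <
                    3 * sqrt(as.numeric(pr) * (1 - as.numeric(pr)) / 20000)))
  ## eta -> +inf pushes every rating to the top category
  sev_hi <- simulate_severity(bank, rep(50, 50), seed = 20)
  expect_true(all(sev_hi$s1 == 4L))
  expect_error(simulate_severity(dplyr::mutate(bank, b2 = -2), 0),
               "non-decreasing")
})

test_that("positive testlet SD induces extra within-domain association", {
  n <- 50000
  items <- tibble::tibble(item_id = paste0("i", 1:4),
                          domain = rep(c("taboo", "contamination"), each = 2),
                          a = 1.4, b = 0.5)
  persons <- draw_persons(sim_config(n_persons = n, unaffected_frac = 0,
                                     testlet_sd = 1.0, seed = 21))
  r <- as.matrix(simulate_testlet_responses(
    list(items = items, testlet_sd = c(taboo = 1, contamination = 1)),
    persons, seed = 22)[, -1])
  or_of <- function(x, y) {
    t11 <- sum(x & y); t00 <- sum(!x & !y)
    t10 <- sum(x & !y); t01 <- sum(!x & y)
    (t11 * t00) / (t10 * t01)
  }
  or_within <- or_of(r[, 1], r[, 2])
  or_cross <- or_of(r[, 1], r[, 3])
  expect_gt(or_within, or_cross)
})

test_that("the unaffected stratum yields roughly a quarter symptom-free persons", {
  st <- simulate_study(sim_config(n_persons = 4000, seed = 23))
  zero <- mean(rowSums(as.matrix(st$resp[, -1]) == 1) == 0)
  expect_gt(zero, 0.18)
  expect_lt(zero, 0.33)
  ## correlated severity trait: severity sum rises with theta
  sym <- rowSums(as.matrix(st$sev[, -1])) |> suppressWarnings()
  obs <- !is.na(sym)
  expect_gt(cor(st$truth$persons$theta[obs], sym[obs],
                method = "spearman"), 0.5)
})

test_that("fixtures are written deterministically and reject degenerate configs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(n_persons = 25, seed = 24)
  f1 <- make_fixture(cfg, d1)
  f2 <- make_fixture(cfg, d2)
  for (nm in c("resp", "sev", "flags", "map")) {
    expect_identical(readLines(f1$files[[nm]]), readLines(f2$files[[nm]]))
  }
  expect_true(file.exists(f1$files[["truth"]]))
  expect_error(sim_config(n_persons = 0))
})
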