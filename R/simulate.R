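## Synthetic-data generator: persons, item banks, checklist responses under
## testlet or bifactor response models, and correlated ordinal severity
## ratings. Every downstream stage is testable against this module's known
## truth without access-restricted clinical data.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design the package targets: 999 persons of whom 37.5% are
#' unaffected relatives, a 64-item checklist partitioned into five symptom
#' domains (16/13/15/2/18 items), discriminations uniform on 0.5-3,
#' symptom severities uniform on 0.3-2.7 (the published symptom-severity
#' range is 0.54-2.65), moderate testlet dependence within each domain, and
#' a clinician severity scale whose latent trait correlates 0.8 with the
#' checklist trait.
#'
#' @param n_persons Number of simulated persons.
#' @param domain_sizes Named integer vector of items per domain (5 domains).
#' @param a_range Range of item discriminations (logit slope units).
#' @param b_range Range of item severities (latent-trait units; endorsement
#'   probability is 0.5 at `theta = b` for an average person).
#' @param testlet_sd Per-domain SD of the person-by-domain testlet effects
#'   (length 5, recycled); 0 collapses the model to a plain 2PL.
#' @param severity_bank Tibble of graded-response parameters for the 10
#'   severity items (`item_id`, `a`, `b1`-`b4`); default
#'   [default_severity_bank()].
#' @param latent_cor Correlation between the checklist trait and the
#'   severity trait, in \[-1, 1\].
#' @param unaffected_frac Fraction of persons drawn from a low-propensity
#'   stratum emulating unaffected relatives (0 disables the mixture).
#' @param unaffected_shift Downward shift (latent SD units) of that stratum.
#' @param scaling Logistic scaling constant D (1 by default; 1.702 gives
#'   normal-ogive-comparable slopes).
#' @param seed Integer seed recorded with the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 999L,
                       domain_sizes = c(doubt_checking = 16L,
                                        contamination = 13L,
                                        symmetry_ordering = 15L,
                                        hoarding = 2L,
                                        taboo = 18L),
                       a_range = c(0.5, 3.0),
                       b_range = c(0.3, 2.7),
                       testlet_sd = 0.75,
                       severity_bank = default_severity_bank(),
                       latent_cor = 0.8,
                       unaffected_frac = 0.375,
                       unaffected_shift = 3.5,
                       scaling = 1,
                       seed = 1L) {
  if (n_persons < 1) abort("n_persons must be positive")
  if (length(domain_sizes) != 5L || any(domain_sizes < 1)) {
    abort("domain_sizes must give a positive count for each of 5 domains")
  }
  if (is.null(names(domain_sizes))) names(domain_sizes) <- DOMAINS
  if (diff(a_range) < 0 || a_range[1] <= 0) abort("invalid a_range")
  if (diff(b_range) < 0) abort("invalid b_range")
  testlet_sd <- rep_len(testlet_sd, 5L)
  if (any(testlet_sd < 0)) abort("testlet_sd must be non-negative")
  if (abs(latent_cor) > 1) abort("latent_cor must lie in [-1, 1]")
  check_severity_bank(severity_bank)
  structure(list(n_persons = as.integer(n_persons),
                 domain_sizes = domain_sizes, a_range = a_range,
                 b_range = b_range, testlet_sd = testlet_sd,
                 severity_bank = severity_bank, latent_cor = latent_cor,
                 unaffected_frac = unaffected_frac,
                 unaffected_shift = unaffected_shift,
                 scaling = scaling, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default graded-response item bank for the 10-item severity scale
#'
#' Discrimination and four ordered rating thresholds for each of the ten
#' clinician rating items (time, interference, distress, resistance,
#' control; obsessions and compulsions each). Values are anchored to
#' published item parameters for this instrument where available; the
#' remaining entries (interference and control discriminations, the
#' distress and control threshold sets) are synthetic values interpolated
#' to mirror their printed counterparts, so the bank as a whole is a
#' realistic stand-in, not a reproduction.
#'
#' @return Tibble with columns `item_id`, `a`, `b1`, `b2`, `b3`, `b4`.
#' @export
default_severity_bank <- function() {
  tibble::tribble(
    ~item_id,            ~a,   ~b1,   ~b2,  ~b3,  ~b4,
    "time_obs",          3.19, -0.52, 1.73, 3.20, 4.46,
    "interference_obs",  2.55, -0.09, 1.02, 2.28, 3.92,
    "distress_obs",      3.10, -0.15, 1.05, 2.35, 3.95,
    "resistance_obs",    1.59, -0.21, 0.59, 1.59, 2.15,
    "control_obs",       1.85, -0.30, 0.55, 1.55, 2.10,
    "time_comp",         2.94, -0.62, 2.01, 3.66, 5.25,
    "interference_comp", 2.45, -0.16, 1.20, 2.56, 4.25,
    "distress_comp",     2.90, -0.20, 1.10, 2.45, 4.05,
    "resistance_comp",   1.42, -0.53, 0.51, 1.50, 2.02,
    "control_comp",      1.70, -0.45, 0.50, 1.45, 2.00
  )
}

check_severity_bank <- function(bank) {
  need <- c("item_id", "a", "b1", "b2", "b3", "b4")
  if (!all(need %in% names(bank))) {
    abort("severity bank needs columns item_id, a, b1-b4")
  }
  if (any(bank$a <= 0)) abort("severity discriminations must be positive")
  th <- as.matrix(bank[, c("b1", "b2", "b3", "b4")])
  if (any(t(apply(th, 1L, diff)) < 0)) {
    abort("severity thresholds must be non-decreasing within item")
  }
  invisible(bank)
}

#' Draw a synthetic checklist item bank
#'
#' Discriminations and severities are drawn uniformly over the configured
#' ranges; items are laid out in domain blocks following
#' `config$domain_sizes`. Collapsing a range to a point gives every item
#' that value.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (defaults to `config$seed`).
#' @return List with `items` (tibble `item_id`, `domain`, `a`, `b`) and
#'   `testlet_sd` (named per-domain vector).
#' @export
draw_item_bank <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n_items <- sum(config$domain_sizes)
  items <- tibble::tibble(
    item_id = sprintf("y%02d", seq_len(n_items)),
    domain = rep(names(config$domain_sizes), config$domain_sizes),
    a = runif(n_items, config$a_range[1], config$a_range[2]),
    b = runif(n_items, config$b_range[1], config$b_range[2])
  )
  list(items = items,
       testlet_sd = setNames(config$testlet_sd, names(config$domain_sizes)))
}

#' Draw person-level latent quantities
#'
#' The general OCD propensity `theta` is standard normal for affected
#' persons; an optional unaffected stratum is shifted downward to produce
#' realistic all-zero checklist rows. Testlet effects `gamma` are drawn
#' independently per person and domain with the configured SDs, and the
#' severity trait `eta` correlates `latent_cor` with `theta`.
#'
#' @inheritParams draw_item_bank
#' @return Tibble with `person_id`, `affected`, `theta`, `eta` and one
#'   `gamma_<domain>` column per domain.
#' @export
draw_persons <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_persons
  affected <- runif(n) >= config$unaffected_frac
  theta <- rnorm(n) - ifelse(affected, 0, config$unaffected_shift)
  eta <- config$latent_cor * theta +
    sqrt(1 - config$latent_cor^2) * rnorm(n)
  gam <- vapply(config$testlet_sd, function(s) rnorm(n, 0, s), numeric(n))
  if (n == 1L) gam <- matrix(gam, nrow = 1L)
  colnames(gam) <- paste0("gamma_", names(config$domain_sizes))
  dplyr::bind_cols(
    tibble::tibble(person_id = sprintf("p%04d", seq_len(n)),
                   affected = affected, theta = theta, eta = eta),
    tibble::as_tibble(gam)
  )
}

#' Testlet item response function
#'
#' Endorsement probability `plogis(D * a * (theta - b - gamma))`: the
#' standard two-parameter logistic curve with a person-by-domain testlet
#' effect subtracted from the propensity.
#'
#' @param a Discrimination (> 0).
#' @param b Item severity.
#' @param gamma Testlet effect.
#' @param theta Person propensity.
#' @param scaling Logistic scaling constant D.
#' @return Endorsement probability in (0, 1).
#' @export
irf_testlet <- function(a, b, gamma, theta, scaling = 1) {
  if (any(a <= 0)) abort("discrimination a must be positive")
  plogis(scaling * a * (theta - b - gamma))
}

#' Simulate checklist responses under the testlet model
#'
#' Bernoulli draws with `P(y = 1) = plogis(D a_j (theta_i - b_j -
#' gamma_{i, d(j)}))`.
#'
#' @param bank Item bank as from [draw_item_bank()].
#' @param persons Person tibble as from [draw_persons()].
#' @param seed Optional seed.
#' @param scaling Logistic scaling constant D.
#' @return Checklist tibble (`person_id` + one 0/1 column per item).
#' @export
simulate_testlet_responses <- function(bank, persons, seed = NULL,
                                       scaling = 1) {
  if (!is.null(seed)) set.seed(seed)
  items <- bank$items
  gam <- as.matrix(persons[, paste0("gamma_", unique(items$domain)),
                           drop = FALSE])
  d_idx <- match(items$domain, unique(items$domain))
  eta <- outer(persons$theta, rep(1, nrow(items)))
  eta <- sweep(eta - gam[, d_idx, drop = FALSE], 2L, items$b, "-")
  p <- plogis(scaling * sweep(eta, 2L, items$a, "*"))
  y <- matrix(rbinom(length(p), 1L, p), nrow = nrow(p))
  colnames(y) <- items$item_id
  rownames(y) <- persons$person_id
  matrix_to_tbl(y)
}

#' Simulate checklist responses under a bifactor model
#'
#' Every item loads on a general factor and on exactly one domain-specific
#' factor, all latent factors independent standard normal:
#' `P(y = 1) = plogis(slope_general * theta0 + slope_specific * theta_d +
#' intercept)`. With the testlet parameterisation (`slope_general = a_j`,
#' `slope_specific = a_j * sd_d`, `intercept = -a_j * b_j`) this reproduces
#' the marginal distribution of [simulate_testlet_responses()].
#'
#' @param loadings Tibble with columns `item_id`, `domain`,
#'   `slope_general`, `slope_specific`, `intercept`.
#' @param n_persons Number of persons to draw (ignored when `theta0` given).
#' @param theta0 Optional general-factor scores.
#' @param theta_spec Optional matrix of specific-factor scores (persons x
#'   domains, columns named by domain).
#' @param seed Optional seed.
#' @return Checklist tibble.
#' @export
simulate_bifactor_responses <- function(loadings, n_persons = NULL,
                                        theta0 = NULL, theta_spec = NULL,
                                        seed = NULL) {
  if (anyDuplicated(loadings$item_id)) {
    abort("each item may load on exactly one specific domain")
  }
  if (!is.null(seed)) set.seed(seed)
  doms <- unique(loadings$domain)
  if (is.null(theta0)) theta0 <- rnorm(n_persons)
  n <- length(theta0)
  if (is.null(theta_spec)) {
    theta_spec <- matrix(rnorm(n * length(doms)), n, length(doms),
                         dimnames = list(NULL, doms))
  }
  d_idx <- match(loadings$domain, colnames(theta_spec))
  lin <- outer(theta0, loadings$slope_general) +
    sweep(theta_spec[, d_idx, drop = FALSE], 2L,
          loadings$slope_specific, "*")
  lin <- sweep(lin, 2L, loadings$intercept, "+")
  p <- plogis(lin)
  y <- matrix(rbinom(length(p), 1L, p), nrow = n)
  colnames(y) <- loadings$item_id
  rownames(y) <- sprintf("p%04d", seq_len(n))
  matrix_to_tbl(y)
}

#' Simulate clinician severity ratings under a graded response model
#'
#' Ordinal 0-4 ratings with cumulative endorsement
#' `P(Y >= k) = plogis(a (eta - b_k))`; category probabilities are the
#' successive differences.
#'
#' @param bank Severity item bank (see [default_severity_bank()]).
#' @param eta Person severity traits.
#' @param person_ids Optional ids (defaults to `p0001`...).
#' @param seed Optional seed.
#' @return Severity tibble (`person_id` + one 0-4 column per item).
#' @export
simulate_severity <- function(bank, eta, person_ids = NULL, seed = NULL) {
  check_severity_bank(bank)
  if (!is.null(seed)) set.seed(seed)
  n <- length(eta)
  if (is.null(person_ids)) person_ids <- sprintf("p%04d", seq_len(n))
  y <- vapply(seq_len(nrow(bank)), function(j) {
    pr <- grm_category_probs(bank$a[j],
                             as.numeric(bank[j, c("b1", "b2", "b3", "b4")]),
                             eta)
    cp <- t(apply(pr, 1L, cumsum))  # P(Y <= k), columns k = 0..4
    u <- runif(n)
    as.integer(rowSums(u >= cp[, 1:4, drop = FALSE]))
  }, integer(n))
  if (n == 1L) y <- matrix(y, nrow = 1L)
  colnames(y) <- bank$item_id
  rownames(y) <- person_ids
  matrix_to_tbl(y)
}

#' Simulate a complete synthetic study
#'
#' Draws an item bank and persons, generates checklist responses under the
#' testlet model and severity ratings under the graded response model, and
#' applies the design rule that the severity scale is administered only to
#' symptomatic or affected persons (others are left not-administered, to be
#' filled by [impute_zero_severity()]).
#'
#' @inheritParams draw_item_bank
#' @return List with `resp`, `sev`, `flags`, `map` tibbles and `truth`
#'   (item bank, persons, config).
#' @export
simulate_study <- function(config = sim_config(), seed = config$seed) {
  bank <- draw_item_bank(config, seed = derive_seed(seed, 1L))
  persons <- draw_persons(config, seed = derive_seed(seed, 2L))
  resp <- simulate_testlet_responses(bank, persons,
                                     seed = derive_seed(seed, 3L),
                                     scaling = config$scaling)
  sev <- simulate_severity(config$severity_bank, persons$eta,
                           person_ids = persons$person_id,
                           seed = derive_seed(seed, 4L))
  ## severity scale not administered to unaffected, symptom-free persons
  m <- resp_matrix(resp)
  administer <- persons$affected | rowSums(m == 1, na.rm = TRUE) > 0
  sev[!administer, -1] <- NA_integer_
  flags <- tibble::tibble(person_id = persons$person_id,
                          affected = persons$affected)
  map <- tibble::tibble(item_id = bank$items$item_id,
                        domain = bank$items$domain)
  list(resp = resp, sev = sev, flags = flags, map = map,
       truth = list(bank = bank, persons = persons, config = config,
                    seed = seed))
}

#' Write a synthetic study to disk
#'
#' Writes `responses.csv`, `severity.csv`, `flags.csv`, `domain_map.csv`
#' and a machine-readable `truth.json` (all generating parameters plus the
#' seed) into `out_dir`, so parameter-recovery analyses can run from files
#' alone. Re-running with the same configuration reproduces the files
#' byte-for-byte.
#'
#' @inheritParams draw_item_bank
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the file manifest and the truth record.
#' @export
make_fixture <- function(config = sim_config(), out_dir,
                         seed = config$seed) {
  study <- simulate_study(config, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("responses.csv", "severity.csv",
                                "flags.csv", "domain_map.csv", "truth.json"))
  names(paths) <- c("resp", "sev", "flags", "map", "truth")
  write_responses(study$resp, paths["resp"])
  write_responses(study$sev, paths["sev"])
  readr::write_csv(dplyr::mutate(study$flags,
                                 affected = as.integer(.data$affected)),
                   paths["flags"])
  readr::write_csv(study$map, paths["map"])
  truth <- list(seed = seed,
                config = unclass(config[setdiff(names(config),
                                                "severity_bank")]),
                severity_bank = study$truth$config$severity_bank,
                items = study$truth$bank$items,
                testlet_sd = as.list(study$truth$bank$testlet_sd),
                persons = study$truth$persons)
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(files = paths, truth = study$truth))
}
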