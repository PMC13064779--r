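## Internal helpers shared across modules.

## Convert a person x item tibble (first column person_id) to an integer
## matrix with person ids as rownames. NAs preserved.
resp_matrix <- function(data) {
  stopifnot(is.data.frame(data), ncol(data) >= 2)
  ids <- as.character(data[[1]])
  m <- as.matrix(data[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_tbl <- function(m, id_col = "person_id") {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
}

## Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

## Gauss-Hermite nodes/weights transformed for a standard-normal density:
## integral f(t) dnorm(t) dt ~ sum w_q f(x_q).
gh_normal <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x * sqrt(2), w = gh$w / sqrt(pi))
}

## Bernoulli log-likelihood pieces for a person x item 0/1 matrix with NAs:
## returns indicator matrices with NA -> 0 so that
## loglik(person, node) = Y1 %*% log(p) + Y0 %*% log(1 - p).
bern_indicators <- function(y) {
  y1 <- y
  y1[is.na(y1)] <- 0
  y0 <- 1 - y
  y0[is.na(y0)] <- 0
  list(y1 = y1, y0 = y0)
}

## Deterministic per-stage seed derivation, kept inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 999983 * k) %% 2147483629)
}

is_binaryish <- function(x) all(is.na(x) | x %in% c(0, 1))

## Clamp probabilities away from 0/1 for log safety.
clamp_p <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)
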