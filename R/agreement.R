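## Agreement between the two scoring routes (checklist-derived propensity
## vs clinician-severity-derived score): rank correlation and Bland-Altman
## analysis with joint posterior standard errors.

#' Spearman rank correlation
#'
#' Average-rank tie handling; a constant vector has no rank order, so it is
#' signalled as an error rather than silently returning `NA`.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3L) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("rank correlation undefined: constant input vector")
  }
  cor(x, y, method = "spearman")
}

#' Bland-Altman agreement between two scored measures
#'
#' With no gold standard, each person's two score estimates are compared on
#' the scale of their joint uncertainty: the difference
#' `estimate_1 - estimate_2` is plotted against the common mean, and a
#' person *agrees* when the absolute difference is within `z` times the
#' joint standard error `sqrt(SE_1^2 + SE_2^2)`.
#'
#' @param scores1 Tibble of the first measure's scores (`person_id`,
#'   `score`, `se`), e.g. checklist-derived propensities.
#' @param scores2 Tibble of the second measure's scores, e.g.
#'   severity-derived scores.
#' @param z Confidence multiplier (default 1.96, a 95% region).
#' @return Object of class `ocd_agreement`: `records` tibble (per person:
#'   estimates, SEs, `common_mean`, `difference`, `joint_se`, `agree`,
#'   `degenerate`), `summary` one-row tibble (`n`, `n_excluded`,
#'   `percent_agree`, `spearman`, `z`), and the flagged disagreements.
#' @export
bland_altman <- function(scores1, scores2, z = 1.96) {
  common <- intersect(scores1$person_id, scores2$person_id)
  n_excluded <- length(union(scores1$person_id, scores2$person_id)) -
    length(common)
  s1 <- scores1[match(common, scores1$person_id), ]
  s2 <- scores2[match(common, scores2$person_id), ]
  joint <- sqrt(s1$se^2 + s2$se^2)
  degenerate <- joint == 0
  if (any(degenerate)) {
    warn(paste0(sum(degenerate),
                " person(s) with zero SE on both measures; agreement ",
                "degenerates to exact equality for them"))
  }
  diff_ <- s1$score - s2$score
  rec <- tibble::tibble(
    person_id = common,
    estimate_1 = s1$score, se_1 = s1$se,
    estimate_2 = s2$score, se_2 = s2$se,
    common_mean = (s1$score + s2$score) / 2,
    difference = diff_,
    joint_se = joint,
    agree = ifelse(degenerate, diff_ == 0, abs(diff_) <= z * joint),
    degenerate = degenerate)
  summary <- tibble::tibble(
    n = nrow(rec), n_excluded = n_excluded,
    percent_agree = 100 * mean(rec$agree),
    spearman = if (nrow(rec) >= 3L && sd(rec$estimate_1) > 0 &&
                   sd(rec$estimate_2) > 0)
      spearman_rho(rec$estimate_1, rec$estimate_2) else NA_real_,
    z = z)
  structure(list(records = rec, summary = summary,
                 disagreements = rec[!rec$agree, ]),
            class = "ocd_agreement")
}

#' @export
print.ocd_agreement <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Bland-Altman agreement: %.1f%% of %d persons within %.2f joint SEs\n",
              s$percent_agree, s$n, s$z))
  if (!is.na(s$spearman)) {
    cat(sprintf("  Spearman rank correlation of estimates: %.3f\n",
                s$spearman))
  }
  invisible(x)
}

#' @export
tidy.ocd_agreement <- function(x, ...) x$records

#' @export
glance.ocd_agreement <- function(x, ...) x$summary

#' Bland-Altman plot
#'
#' Differences against common means, disagreeing persons highlighted, with
#' the per-person `z * joint SE` band.
#'
#' @param object An `ocd_agreement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocd_agreement <- function(object, ...) {
  rec <- object$records
  z <- object$summary$z
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$common_mean,
                                    y = .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$agree), alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey30",
                                            `FALSE` = "red")) +
    ggplot2::labs(x = "common mean of the two estimates",
                  y = "difference (measure 1 - measure 2)",
                  colour = sprintf("within %.2f joint SE", z)) +
    ggplot2::theme_minimal()
}

#' Rank-preservation check of model scores against raw symptom counts
#'
#' Spearman correlation between model-derived person scores and the raw
#' number of endorsed symptoms. Under an equal-slope (Rasch-like) model
#' the sum score is sufficient, so the correlation is exactly 1; slope
#' variation and testlet effects lower it slightly.
#'
#' @param scores Person score tibble (`person_id`, `score`).
#' @param resp Checklist tibble.
#' @return Spearman's rho.
#' @export
score_vs_raw_rank_check <- function(scores, resp) {
  m <- resp_matrix(resp)
  raw <- rowSums(m == 1, na.rm = TRUE)
  raw <- raw[match(scores$person_id, rownames(m))]
  if (anyNA(raw)) abort("scores contain persons absent from the checklist")
  spearman_rho(scores$score, raw)
}
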