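## Reading, writing, validating and summarising the four study inputs:
## lifetime symptom checklist (binary), symptom -> domain map, clinician
## severity ratings (ordinal 0-4), and lifetime diagnosis flags.

#' Read a lifetime symptom checklist
#'
#' Reads a delimited file holding one row per person: a `person_id` column
#' followed by one column per checklist item, each cell 0 (symptom never
#' present), 1 (present at some point over the lifetime) or empty/`NA`
#' (not assessed). Missing cells are kept missing — absence of assessment is
#' never coerced to absence of the symptom.
#'
#' @param path Path to a comma-separated file with a header row; the first
#'   column is the person identifier.
#' @return A tibble with a character `person_id` column and integer item
#'   columns containing 0, 1 or `NA`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("person_id,y1,y2", "p1,0,1", "p2,1,"), tf)
#' read_responses(tf)
read_responses <- function(path) {
  raw <- read_chr_csv(path)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate person id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  items <- parse_coded_cells(raw[, -1, drop = FALSE], allowed = c("0", "1"),
                             what = "symptom")
  dplyr::bind_cols(tibble::tibble(person_id = as.character(ids)), items)
}

#' Read clinician severity ratings
#'
#' Reads a delimited file of ordinal clinician ratings, one row per person
#' and one column per rating item, each cell an integer 0-4 or empty/`NA`
#' when the scale was not administered.
#'
#' @inheritParams read_responses
#' @return A tibble with `person_id` plus integer rating columns (0-4 or
#'   `NA`).
#' @export
read_severity <- function(path) {
  raw <- read_chr_csv(path)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate person id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  items <- parse_coded_cells(raw[, -1, drop = FALSE],
                             allowed = as.character(0:4), what = "rating")
  dplyr::bind_cols(tibble::tibble(person_id = as.character(ids)), items)
}

#' Read an item-to-domain map
#'
#' The map assigns every checklist item to exactly one of the five lifetime
#' symptom domains (doubt/checking, contamination, symmetry/ordering,
#' hoarding, taboo). In strict mode all five domains must be present.
#'
#' @param path Two-column delimited file: `item_id`, `domain`.
#' @param strict Require all five canonical domains (default `TRUE`); toy
#'   maps for small examples may use fewer with `strict = FALSE`.
#' @return A tibble with columns `item_id` and `domain`.
#' @export
read_domain_map <- function(path, strict = TRUE) {
  raw <- read_chr_csv(path)
  if (ncol(raw) < 2) abort("domain map needs two columns: item_id, domain")
  map <- tibble::tibble(item_id = as.character(raw[[1]]),
                        domain = as.character(raw[[2]]))
  check_domain_map(map, strict = strict)
  map
}

check_domain_map <- function(map, strict = TRUE) {
  bad <- setdiff(unique(map$domain), DOMAINS)
  if (length(bad)) {
    abort(paste0("unknown domain label(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(map$item_id)) {
    abort(paste0("item(s) mapped more than once: ",
                 paste(unique(map$item_id[duplicated(map$item_id)]),
                       collapse = ", ")))
  }
  if (strict && !setequal(unique(map$domain), DOMAINS)) {
    abort("strict mode requires all 5 domains present in the map")
  }
  invisible(map)
}

#' Default 64-item domain map
#'
#' A synthetic stand-in assignment of 64 generic checklist items
#' (`y01`-`y64`) to the five domains, with domain sizes 16 (doubt/checking),
#' 13 (contamination), 15 (symmetry/ordering), 2 (hoarding) and 18 (taboo).
#' The three sizes 16/15/18 follow the instrument's published domain scales;
#' contamination = 13 and hoarding = 2 complete the 64-item partition
#' (hoarding is the obsession + compulsion item pair). The true item-level
#' assignment of the clinical instrument is not reproduced here; supply your
#' own map file for real data.
#'
#' @return A 64-row tibble with columns `item_id`, `domain`.
#' @export
default_domain_map <- function() {
  sizes <- c(doubt_checking = 16L, contamination = 13L,
             symmetry_ordering = 15L, hoarding = 2L, taboo = 18L)
  tibble::tibble(
    item_id = sprintf("y%02d", seq_len(sum(sizes))),
    domain = rep(names(sizes), sizes)
  )
}

#' Read lifetime diagnosis flags
#'
#' @param path Two-column delimited file: `person_id`, `affected` (0/1 or
#'   TRUE/FALSE).
#' @return A tibble with `person_id` (character) and `affected` (logical).
#' @export
read_flags <- function(path) {
  raw <- read_chr_csv(path)
  if (ncol(raw) < 2) abort("flags file needs two columns: person_id, affected")
  val <- tolower(as.character(raw[[2]]))
  ok <- val %in% c("0", "1", "true", "false")
  if (!all(ok)) {
    abort(paste0("unparseable flag for person ", raw[[1]][which(!ok)[1]]))
  }
  tibble::tibble(person_id = as.character(raw[[1]]),
                 affected = val %in% c("1", "true"))
}

#' Write checklist or severity tables
#'
#' Writes a person-by-item tibble back to comma-separated text with missing
#' cells left empty, so that a write/read cycle reproduces the data
#' cell-for-cell.
#'
#' @param data Tibble as returned by [read_responses()] or [read_severity()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Apply the zero-severity assignment rule
#'
#' Persons with no lifetime OCD diagnosis who report none of the checklist
#' symptoms, and whose severity scale was not administered, are assigned
#' severity ratings of 0 on all items. Rows of affected persons, persons
#' endorsing any symptom, or persons with any observed rating are left
#' untouched, so genuine missingness is retained.
#'
#' @param sev Severity tibble ([read_severity()] layout).
#' @param resp Checklist tibble ([read_responses()] layout).
#' @param flags Diagnosis flags tibble ([read_flags()] layout).
#' @return The severity tibble with qualifying rows replaced by zeros. The
#'   number of imputed rows is attached as attribute `n_imputed` and their
#'   ids as `imputed_persons`.
#' @export
impute_zero_severity <- function(sev, resp, flags) {
  if (!setequal(sev$person_id, resp$person_id) ||
      !setequal(sev$person_id, flags$person_id)) {
    abort("person ids of severity, checklist and flags must coincide")
  }
  rm_ <- resp_matrix(resp)[sev$person_id, , drop = FALSE]
  sm <- resp_matrix(sev)
  aff <- flags$affected[match(sev$person_id, flags$person_id)]
  no_symptom <- rowSums(rm_ == 1, na.rm = TRUE) == 0
  not_admin <- rowSums(!is.na(sm)) == 0
  target <- !aff & no_symptom & not_admin
  out <- sev
  if (any(target)) {
    out[target, -1] <- 0L
  }
  attr(out, "n_imputed") <- sum(target)
  attr(out, "imputed_persons") <- sev$person_id[target]
  out
}

#' Summarise lifetime symptom patterns
#'
#' Computes how heterogeneous the reported lifetime symptom patterns are:
#' the proportion of persons endorsing at least one symptom, the number of
#' distinct response patterns among those symptomatic persons, the
#' proportion of symptomatic persons whose pattern is unique to them, and
#' the most frequent patterns.
#'
#' @param resp Checklist tibble.
#' @param top Number of most frequent symptomatic patterns to return.
#' @return One-row tibble with columns `n_persons`, `prop_symptomatic`,
#'   `n_distinct_patterns`, `prop_unique_pattern` and a list-column
#'   `top_patterns` (tibble of pattern string and count).
#' @export
symptom_pattern_summary <- function(resp, top = 5L) {
  m <- resp_matrix(resp)
  symptomatic <- rowSums(m == 1, na.rm = TRUE) > 0
  pat <- apply(m[symptomatic, , drop = FALSE], 1L, function(r) {
    paste(ifelse(is.na(r), "N", r), collapse = "")
  })
  tab <- sort(table(pat), decreasing = TRUE)
  n_sym <- sum(symptomatic)
  tibble::tibble(
    n_persons = nrow(m),
    prop_symptomatic = mean(symptomatic),
    n_distinct_patterns = length(tab),
    prop_unique_pattern = if (n_sym == 0) NA_real_ else
      sum(tab == 1) / n_sym,
    top_patterns = list(tibble::tibble(
      pattern = names(head(tab, top)),
      count = as.integer(head(tab, top))
    ))
  )
}

#' Validate a study data set
#'
#' Cross-checks the checklist, domain map, severity ratings and diagnosis
#' flags for dimension mismatches, id mismatches and out-of-range values,
#' and reports per-item endorsement rates. Problems are collected into a
#' report rather than raised, so all issues surface at once.
#'
#' @param resp Checklist tibble.
#' @param map Domain map tibble.
#' @param sev Optional severity tibble.
#' @param flags Optional flags tibble.
#' @param strict Enforce the full-scale layout (5 domains, 10 rating items).
#' @return An object of class `ocd_validation`: list with `pass` (logical),
#'   `issues` (tibble of `level`, `message`) and `endorsement` (tibble of
#'   per-item endorsement rates).
#' @export
validate_dataset <- function(resp, map, sev = NULL, flags = NULL,
                             strict = TRUE) {
  issues <- list()
  note <- function(level, msg) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(level = level,
                                                     message = msg)
  }
  m <- resp_matrix(resp)
  if (anyDuplicated(rownames(m))) note("error", "duplicate person ids in checklist")
  if (!all(apply(m, 2L, is_binaryish))) {
    bad <- colnames(m)[!apply(m, 2L, is_binaryish)]
    note("error", paste0("non-binary checklist entries in item(s): ",
                         paste(bad, collapse = ", ")))
  }
  tryCatch(check_domain_map(map, strict = strict),
           error = function(e) note("error", conditionMessage(e)))
  extra_map <- setdiff(map$item_id, colnames(m))
  extra_dat <- setdiff(colnames(m), map$item_id)
  if (length(extra_map)) {
    note("error", paste0("item(s) in map but not in checklist: ",
                         paste(extra_map, collapse = ", ")))
  }
  if (length(extra_dat)) {
    note("error", paste0("item(s) in checklist but not in map: ",
                         paste(extra_dat, collapse = ", ")))
  }
  if (!is.null(sev)) {
    sm <- resp_matrix(sev)
    if (strict && ncol(sm) != 10L) {
      note("error", paste0("severity matrix has ", ncol(sm),
                           " columns; expected 10"))
    }
    if (!all(is.na(sm) | (sm %in% 0:4))) {
      note("error", "severity entries outside 0-4")
    }
    if (!setequal(rownames(sm), rownames(m))) {
      note("error", "person ids of severity and checklist differ")
    }
  }
  if (!is.null(flags)) {
    if (!all(rownames(m) %in% flags$person_id)) {
      note("error", "diagnosis flag missing for some checklist persons")
    }
  }
  endorse <- tibble::tibble(
    item_id = colnames(m),
    n_observed = colSums(!is.na(m)),
    endorsement_rate = colMeans(m == 1, na.rm = TRUE)
  )
  if (any(endorse$n_observed == 0)) {
    note("warning", "item(s) with no observed responses")
  }
  issues <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(level = character(), message = character())
  structure(list(pass = !any(issues$level == "error"),
                 issues = issues, endorsement = endorse),
            class = "ocd_validation")
}

#' @export
print.ocd_validation <- function(x, ...) {
  cat("Data set validation:", if (x$pass) "PASS" else "FAIL", "\n")
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues))) {
      cat(sprintf("  [%s] %s\n", x$issues$level[i], x$issues$message[i]))
    }
  } else {
    cat("  no issues found\n")
  }
  invisible(x)
}

## -- internal parsing helpers ------------------------------------------------

read_chr_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = character())
}

## Validate and convert character cells to integer with explicit missing
## marker; errors name the offending row and column.
parse_coded_cells <- function(df, allowed, what) {
  out <- purrr::imap(df, function(col, nm) {
    col <- trimws(col)
    miss <- is.na(col) | col == "" | col == "NA"
    bad <- !miss & !(col %in% allowed)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("unparseable %s value '%s' at row %d, column '%s'",
                    what, col[i], i, nm))
    }
    v <- rep(NA_integer_, length(col))
    v[!miss] <- as.integer(col[!miss])
    v
  })
  tibble::as_tibble(out)
}
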