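#' Read a raw admixture-event table
#'
#' Reads the TSV of per-individual dated admixture inferences. Each record
#' carries a category — a single two-source event, a single multiway event,
#' or two dated pulses — and up to two sub-events
#' (`date1/source1a/source1b/fraction1`, `date2/...`). For single-event
#' records the second block may be empty.
#'
#' @param path TSV with header columns `individual`, `category`, `date1`,
#'   `source1a`, `source1b`, `fraction1`, `date2`, `source2a`, `source2b`,
#'   `fraction2`.
#' @return Tibble of raw records.
#' @export
read_admixture_events <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    individual = readr::col_character(),
    category = readr::col_character(),
    date1 = readr::col_double(), source1a = readr::col_character(),
    source1b = readr::col_character(), fraction1 = readr::col_double(),
    date2 = readr::col_double(), source2a = readr::col_character(),
    source2b = readr::col_character(), fraction2 = readr::col_double()),
    progress = FALSE)
}

event_categories <- c("one-date-two-sources", "one-date-multiway",
                      "multiple-dates")

#' Simplify complex admixture records into two-source single-date events
#'
#' Single two-source records pass through as one event. Records describing a
#' multiway pulse or two dated pulses are emitted as two two-source
#' single-date events each, every event keeping its best-guess source labels
#' and the ancestry fraction attributed to its sources.
#'
#' @param raw Raw record tibble (see [read_admixture_events()]).
#' @return Event tibble: `individual`, `event` (1 or 2), `date`, `source1`,
#'   `source2`, `fraction`, `category`.
#' @export
simplify_events <- function(raw) {
  bad <- setdiff(unique(raw$category), event_categories)
  if (length(bad)) {
    abort(paste0("unknown event category: ", paste(bad, collapse = ", ")))
  }
  first <- raw |>
    dplyr::transmute(individual = .data$individual, event = 1L,
                     date = .data$date1, source1 = .data$source1a,
                     source2 = .data$source1b, fraction = .data$fraction1,
                     category = .data$category)
  second <- raw |>
    dplyr::filter(.data$category != "one-date-two-sources") |>
    dplyr::transmute(individual = .data$individual, event = 2L,
                     date = dplyr::if_else(.data$category == "multiple-dates",
                                           .data$date2, .data$date1),
                     source1 = .data$source2a, source2 = .data$source2b,
                     fraction = .data$fraction2, category = .data$category)
  dplyr::bind_rows(first, second) |>
    dplyr::arrange(.data$individual, .data$event)
}

#' Convert an admixture date in generations to a calendar year
#'
#' `y = reference_birth_year - generation_years * (g + 1)`: with the default
#' mean birth year 1990 and a 28-year generation time, `g = 0` gives 1962.
#'
#' @param g Admixture date(s) in generations (non-negative).
#' @param generation_years Years per generation.
#' @param reference_birth_year Mean birth year of the sampled cohort.
#' @return Calendar year(s).
#' @export
generations_to_year <- function(g, generation_years = 28,
                                reference_birth_year = 1990) {
  if (any(g < 0)) abort("generations must be non-negative")
  reference_birth_year - generation_years * (g + 1)
}

#' Filter admixture events before date comparisons
#'
#' Applies the standard exclusions: events dated exactly 1 generation
#' (frequently an artefact interpreted as no admixture), events whose
#' source-ancestry fraction is at or below `min_ancestry`, and events dated
#' at or beyond `max_generations` (pre-colonial). Optionally restricts to
#' one event per individual: records inferred as two dated pulses are
#' dropped entirely and, for multiway records, only the stronger-fraction
#' event is kept. Order is preserved and the filter is idempotent.
#'
#' @param events Simplified event tibble (see [simplify_events()]).
#' @param drop_date_one Drop events with `date == 1`.
#' @param min_ancestry Events with `fraction <= min_ancestry` are dropped.
#' @param max_generations Events with `date >= max_generations` are dropped.
#' @param one_per_individual Apply the one-event-per-individual restriction.
#' @return Filtered event tibble.
#' @export
filter_events <- function(events, drop_date_one = TRUE, min_ancestry = 0.05,
                          max_generations = 30, one_per_individual = FALSE) {
  out <- events
  if (one_per_individual) {
    out <- out |>
      dplyr::filter(.data$category != "multiple-dates") |>
      dplyr::group_by(.data$individual) |>
      dplyr::filter(.data$category != "one-date-multiway" |
                      .data$fraction == max(.data$fraction)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$individual) |>
      dplyr::slice_head(n = 1) |>
      dplyr::ungroup()
  }
  out |>
    dplyr::filter(!(drop_date_one & .data$date == 1),
                  .data$fraction > min_ancestry,
                  .data$date < max_generations)
}

#' Attach geographic labels to event sources
#'
#' Maps each event's source-cluster labels through a surrogate-to-group
#' mapping (e.g. fine clusters to the regional labels used for date
#' comparisons).
#'
#' @param events Event tibble.
#' @param mapping Data frame with `surrogate`, `group` columns (see
#'   [read_group_mapping()]).
#' @return Events with added `label1`, `label2` columns.
#' @export
label_events <- function(events, mapping) {
  lk <- setNames(mapping$group, mapping$surrogate)
  events |>
    dplyr::mutate(label1 = unname(lk[.data$source1]),
                  label2 = unname(lk[.data$source2]))
}

#' One-sided rank-sum comparison of admixture-date distributions
#'
#' Wilcoxon rank-sum (Mann-Whitney U) test of whether the dates in
#' `dates_a` are skewed toward more recent (numerically smaller) values
#' than those in `dates_b`. Uses midranks for ties; the p-value is exact by
#' enumeration when `length(a) + length(b) <= 12` with no ties, otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param dates_a,dates_b Numeric date vectors (generations), non-empty.
#' @param alternative `"a_more_recent"` (default) tests whether A is
#'   shifted toward smaller dates; `"a_older"` the mirror.
#' @param exact `NULL` (default) chooses the exact p-value automatically as
#'   described above; `TRUE`/`FALSE` force one mode (exact is unavailable
#'   with ties).
#' @return One-row tibble: `statistic` (U for the first sample), `p_value`,
#'   `n_a`, `n_b`, `method`.
#' @export
compare_admixture_dates <- function(dates_a, dates_b,
                                    alternative = c("a_more_recent",
                                                    "a_older"),
                                    exact = NULL) {
  alternative <- match.arg(alternative)
  if (!length(dates_a) || !length(dates_b)) {
    abort("both date samples must be non-empty")
  }
  ties <- anyDuplicated(c(dates_a, dates_b)) > 0
  if (is.null(exact)) {
    exact <- (length(dates_a) + length(dates_b) <= 12) && !ties
  } else if (exact && ties) {
    abort("exact p-values are unavailable with tied dates")
  }
  alt <- if (alternative == "a_more_recent") "less" else "greater"
  wt <- suppressWarnings(
    wilcox.test(dates_a, dates_b, alternative = alt, exact = exact,
                correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(dates_a), n_b = length(dates_b),
                 method = if (exact) "exact" else "normal approximation")
}
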