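# Unwrap the structured record from any of the shapes analytics accept:
# a bare record, a gold label, an extraction result, or a store row / list
# wrapping a `record`.
as_record <- function(x) {
  if (inherits(x, "gold_label")) return(x$gold_record)
  if (inherits(x, "extraction_result")) return(x$record)
  if (inherits(x, "structured_record")) return(x)
  if (is.list(x) && !is.null(x$record)) return(x$record)
  x
}

# Collect (province, prefecture) unit names from records or stories.
unit_names <- function(items, level, basis) {
  get_one <- function(x) {
    if (basis == "event_location") {
      rec <- as_record(x)
      loc <- if (is.null(rec)) NULL else record_field(rec, "event_location")
      if (is.null(loc)) return(NA_character_)
      if (level == "province") loc$province else loc$prefecture %||%
        NA_character_
    } else {
      if (level == "province") x$source_province %||% NA_character_ else
        x$source_prefecture %||% NA_character_
    }
  }
  vapply(items, get_one, character(1))
}

#' Geographic coverage report
#'
#' How many distinct gazetteer units (provinces or prefecture-level
#' divisions) are touched by a set of located items, either by where the
#' injury event occurred or by where the media source sits. Location names
#' not in the gazetteer are counted as uncovered and returned for audit.
#'
#' @param items List of [structured_record()]s, [gold_label()]s,
#'   `extraction_result`s (basis `"event_location"`) or [media_story()]s
#'   (basis `"media_source_location"`).
#' @param gaz Gazetteer.
#' @param level `"province"` or `"prefecture"`.
#' @param basis `"event_location"` or `"media_source_location"`.
#' @return A `coverage_report` list: `level`, `basis`, `covered`, `total`,
#'   `percent` (two decimals, half-up), `per_unit` (tibble of unit counts)
#'   and `unknown` (names not found in the gazetteer).
#' @export
geographic_coverage <- function(items, gaz = load_gazetteer(),
                                level = c("province", "prefecture"),
                                basis = c("event_location",
                                          "media_source_location")) {
  level <- match.arg(level)
  basis <- match.arg(basis)
  universe <- if (level == "province") gaz$provinces$name else
    gaz$prefectures$name
  names_seen <- unit_names(items, level, basis)
  names_seen <- names_seen[!is.na(names_seen)]
  known <- names_seen[names_seen %in% universe]
  unknown <- unique(names_seen[!names_seen %in% universe])
  covered <- length(unique(known))
  total <- length(universe)
  per_unit <- if (length(known)) {
    tb <- table(known)
    tibble::tibble(unit = names(tb), n = as.integer(tb))
  } else {
    tibble::tibble(unit = character(0), n = integer(0))
  }
  structure(list(
    level = level, basis = basis, covered = covered, total = total,
    percent = round_half_up(100 * covered / max(total, 1), 2),
    per_unit = dplyr::arrange(per_unit, dplyr::desc(.data$n), .data$unit),
    unknown = unknown
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage: %d of %d %ss (%0.2f%%), basis %s>\n",
              x$covered, x$total, x$level, x$percent, x$basis))
  invisible(x)
}

#' Share of records stating the event location
#'
#' @param records List of [structured_record()]s or [gold_label()]s.
#' @return Percentage of records with a non-missing `event_location`, two
#'   decimals, rounded half-up.
#' @export
location_reporting_share <- function(records) {
  if (length(records) == 0) abort("`records` must be non-empty.")
  has_loc <- vapply(records, function(x) {
    rec <- as_record(x)
    !is.null(rec) && record_has(rec, "event_location")
  }, logical(1))
  round_half_up(100 * sum(has_loc) / length(records), 2)
}

#' Ranked dictionary-term frequencies
#'
#' Counts occurrences of every dictionary term (including variants,
#' credited to the parent term) in the chosen scope of a corpus -- the
#' word-cloud data table. Ties are broken lexicographically.
#'
#' @param stories List of [media_story()] objects.
#' @param dict Keyword dictionary.
#' @param scope `"body"` or `"title"`.
#' @param top_k Number of terms to keep (default 100).
#' @return A tibble `term`, `chapter`, `count`, sorted by decreasing count.
#' @export
keyword_frequencies <- function(stories, dict,
                                scope = c("body", "title"), top_k = 100) {
  scope <- match.arg(scope)
  if (length(stories) == 0) abort("`stories` must be non-empty.")
  texts <- vapply(stories, story_text, character(1), scope = scope)
  counts <- purrr::map_dfr(seq_len(nrow(dict)), function(i) {
    forms <- c(dict$term[i], dict$variants[[i]])
    n <- sum(vapply(forms, function(f) {
      sum(stringr::str_count(texts, stringr::regex(
        paste0("\\b", regex_escape(f), "\\b"), ignore_case = TRUE)))
    }, numeric(1)))
    tibble::tibble(term = dict$term[i], chapter = dict$chapter[i], count = n)
  })
  counts <- counts |>
    dplyr::filter(.data$count > 0) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$term)
  utils::head(counts, max(top_k, 0))
}

record_signal_date <- function(x, date_basis) {
  rec <- as_record(x)
  ed <- if (is.null(rec)) NULL else record_field(rec, "event_date")
  if (!is.null(ed) && date_basis == "event") {
    return(event_date_as_date(ed))
  }
  pd <- if (is.list(x) && !is.null(x$publication_date)) {
    as.Date(x$publication_date)
  } else NULL
  if (date_basis == "publication" && !is.null(pd)) return(pd)
  if (!is.null(ed)) return(event_date_as_date(ed))
  pd %||% as.Date(NA)
}

record_product <- function(x) {
  rec <- as_record(x)
  if (is.null(rec)) NULL else record_field(rec, "product_name")
}

#' First-signal detection for a product term
#'
#' Finds the earliest dated record matching the product term and counts the
#' confirming cases in the `w` days after it: the signal is confirmed when
#' at least `k` further matching records fall inside that window. The date
#' basis is the event date when present, falling back to the publication
#' date.
#'
#' @param records List of [structured_record()]s, [gold_label()]s or
#'   `extraction_result`s (optionally each wrapped with a
#'   `publication_date`).
#' @param product_term Product term, matched case-insensitively against the
#'   extracted product name.
#' @param k Confirmation threshold (matching cases within the window).
#' @param w Confirmation window, days.
#' @param date_basis `"event"` or `"publication"`.
#' @return A `signal_report` list: `product_term`, `first_detection_date`
#'   (`NA` when nothing matches), `confirming_case_count`, `confirmed`,
#'   `window_days`, `threshold`, and an empty `lead_time_days` slot to be
#'   filled by [lead_time()].
#' @export
detect_first_signal <- function(records, product_term, k = 10, w = 61,
                                date_basis = c("event", "publication")) {
  date_basis <- match.arg(date_basis)
  prods <- lapply(records, record_product)
  match_i <- which(vapply(prods, function(p) {
    !is.null(p) && stringr::str_detect(
      tolower(p), stringr::fixed(tolower(product_term)))
  }, logical(1)))
  if (length(match_i) == 0) {
    return(structure(list(product_term = product_term,
                          first_detection_date = as.Date(NA),
                          confirming_case_count = 0L, confirmed = FALSE,
                          window_days = w, threshold = k,
                          reference_dates = list(),
                          lead_time_days = list()),
                     class = "signal_report"))
  }
  dates <- as.Date(vapply(records[match_i], function(x)
    format(record_signal_date(x, date_basis)), character(1)))
  ord <- order(dates)
  first <- dates[ord][1]
  rest <- dates[-ord[1]]
  confirming <- sum(!is.na(rest) & rest > first & rest <= first + w)
  # ties at the first date also confirm the burst
  confirming <- confirming + sum(!is.na(rest) & rest == first)
  structure(list(product_term = product_term,
                 first_detection_date = first,
                 confirming_case_count = as.integer(confirming),
                 confirmed = confirming >= k,
                 window_days = w, threshold = k,
                 reference_dates = list(), lead_time_days = list()),
            class = "signal_report")
}

#' Lead time against reference dates
#'
#' For each named reference date (first research-literature publication,
#' official recall announcement, ...) computes the signed day count by
#' which the media-derived first detection precedes it: positive means the
#' media signal came first.
#'
#' @param signal A `signal_report` with a non-missing detection date.
#' @param references Named list/vector of reference dates.
#' @return The `signal_report` with `reference_dates` and `lead_time_days`
#'   filled in.
#' @export
lead_time <- function(signal, references) {
  if (is.na(signal$first_detection_date)) {
    abort("Signal has no first detection date; cannot compute lead times.")
  }
  refs <- lapply(references, as.Date)
  signal$reference_dates <- refs
  signal$lead_time_days <- lapply(refs, function(d)
    as.integer(d - signal$first_detection_date))
  signal
}

#' @export
print.signal_report <- function(x, ...) {
  cat(sprintf("<signal '%s': first %s, %d confirming in %dd, confirmed=%s>\n",
              x$product_term,
              ifelse(is.na(x$first_detection_date), "NA",
                     format(x$first_detection_date)),
              x$confirming_case_count, x$window_days, x$confirmed))
  for (nm in names(x$lead_time_days)) {
    cat(sprintf("  lead vs %s: %d days\n", nm, x$lead_time_days[[nm]]))
  }
  invisible(x)
}

#' Trend series over structured records
#'
#' Case counts per group (product, province or external cause) and time bin
#' (month or year), zero-filled so bins are contiguous over the span of the
#' series.
#'
#' @param records List of records/labels/results with dates.
#' @param group_by `"product_name"`, `"event_province"` or
#'   `"external_cause"`.
#' @param bin `"month"` or `"year"`.
#' @param date_basis `"event"` or `"publication"`.
#' @return A tibble `group`, `bin`, `count`.
#' @export
build_trend_series <- function(records,
                               group_by = c("product_name",
                                            "event_province",
                                            "external_cause"),
                               bin = c("month", "year"),
                               date_basis = c("event", "publication")) {
  group_by <- match.arg(group_by)
  bin <- match.arg(bin)
  date_basis <- match.arg(date_basis)
  rows <- purrr::map_dfr(records, function(x) {
    rec <- as_record(x)
    if (is.null(rec)) return(NULL)
    g <- if (group_by == "event_province") {
      loc <- record_field(rec, "event_location")
      if (is.null(loc)) NULL else loc$province
    } else {
      record_field(rec, group_by)
    }
    d <- record_signal_date(x, date_basis)
    if (is.null(g) || is.na(d)) return(NULL)
    tibble::tibble(group = g, date = d)
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(group = character(0), bin = character(0),
                          count = integer(0)))
  }
  fmt <- if (bin == "month") "%Y-%m" else "%Y"
  rows$bin <- format(rows$date, fmt)
  span <- range(rows$date)
  bins <- if (bin == "month") {
    unique(format(seq(as.Date(format(span[1], "%Y-%m-01")), span[2],
                      by = "month"), fmt))
  } else {
    as.character(seq(as.integer(format(span[1], "%Y")),
                     as.integer(format(span[2], "%Y"))))
  }
  tidyr::expand_grid(group = sort(unique(rows$group)), bin = bins) |>
    dplyr::left_join(dplyr::count(rows, .data$group, .data$bin),
                     by = c("group", "bin")) |>
    dplyr::mutate(count = as.integer(tidyr::replace_na(.data$n, 0L))) |>
    dplyr::select("group", "bin", "count")
}
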