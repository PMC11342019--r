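#' The 34 structured leaf fields
#'
#' The platform extracts 29 structured variables from each eligible story;
#' two of them (injury outcome and etiological factors) are split into four
#' and three sub-variables respectively, giving 34 leaf fields. Each leaf
#' field has a typed value and a default set of extraction strategies
#' (regular expression, gazetteer entity recognition, keyword + relation
#' pattern).
#'
#' @return A tibble with columns `id` (variable numbering, e.g. `"8.1"`),
#'   `field` (machine name), `label` (human-readable name), `type` (one of
#'   `date`, `location`, `categorical`, `text`, `count`, `age`, `enum`,
#'   `boolean`, `temperature`), and `strategies` (list column of strategy
#'   names in priority order).
#' @export
leaf_fields <- function() {
  if (!is.null(.iw_cache$leaf_fields)) return(.iw_cache$leaf_fields)
  f <- function(id, field, label, type, strategies) {
    tibble::tibble(id = id, field = field, label = label, type = type,
                   strategies = list(strategies))
  }
  re <- "regex"; en <- "entity"; kd <- "keyword_dependency"
  dplyr::bind_rows(
    f("1", "event_date", "Date the injury event occurred", "date", c(re, en, kd)),
    f("2", "event_location", "Geographic location of the injury event", "location", c(en, kd)),
    f("3", "place_type", "Type of place where the event occurred", "categorical", kd),
    f("4", "injury_nature", "Nature (type) of injury", "categorical", kd),
    f("5", "body_part", "Body part injured", "categorical", kd),
    f("6", "external_cause", "External cause of injury", "categorical", kd),
    f("7", "clinical_diagnosis", "Clinical diagnosis of injury", "text", c(re, kd)),
    f("8.1", "deaths_total", "Number of deaths", "count", c(re, kd)),
    f("8.2", "injured_total", "Number of injured persons", "count", c(re, kd)),
    f("8.3", "child_deaths", "Number of child deaths", "count", c(re, kd)),
    f("8.4", "injured_children", "Number of injured children", "count", c(re, kd)),
    f("9", "product_count", "Number of involved products", "count", kd),
    f("10", "product_name", "Product name", "text", kd),
    f("11", "product_brand", "Brand name of product", "text", kd),
    f("12", "product_characteristics", "Characteristics of product", "text", kd),
    f("13", "product_type", "Type of product", "categorical", kd),
    f("14", "disposition", "Disposition of the product", "categorical", kd),
    f("15", "children_involved", "Number of involved children", "count", re),
    f("16", "child_age", "Age of injured child", "age", re),
    f("17", "child_sex", "Sex of injured child", "enum", kd),
    f("18", "child_activity", "Activity of child as injury happened", "text", kd),
    f("19", "supervisor_count", "Number of supervisors", "count", re),
    f("20", "supervisor_age", "Age of supervisor", "age", re),
    f("21", "supervisor_sex", "Sex of supervisor", "enum", kd),
    f("22", "supervisor_relation", "Supervisor of the injured child", "categorical", kd),
    f("23", "supervisor_present", "Supervisor physically with the child", "boolean", kd),
    f("24.1", "etiology_human", "Human-related etiological factor", "categorical", kd),
    f("24.2", "etiology_product", "Product-related etiological factor", "categorical", kd),
    f("24.3", "etiology_detail", "Detailed etiological factor", "text", kd),
    f("25", "weather", "Weather conditions", "text", kd),
    f("26", "air_quality", "Air quality", "text", kd),
    f("27", "temperature", "Temperature", "temperature", kd),
    f("28", "other_environment", "Other adverse environmental conditions", "text", c(re, kd)),
    f("29", "preventive_measure", "Product-related preventive measure", "text", c(re, kd))
  ) -> out
  .iw_cache$leaf_fields <- out
  .iw_cache$field_types <- stats::setNames(out$type, out$field)
  out
}

leaf_field_names <- function() leaf_fields()$field

field_type <- function(field) {
  if (is.null(.iw_cache$field_types)) leaf_fields()
  t <- .iw_cache$field_types[[field]]
  if (is.null(t)) abort(sprintf("Unknown leaf field: %s", field))
  t
}

#' Construct a media story
#'
#' One raw story as delivered by ingestion: title, body, publication
#' date-time, source metadata and URL. Title and body must be non-empty and
#' the publication date-time parseable.
#'
#' @param story_id Unique identifier within a corpus.
#' @param title,body Story text.
#' @param publication_datetime `"YYYY-MM-DD HH:MM:SS"` (or date-only) string.
#' @param source_name Outlet or account name.
#' @param source_kind `"news_website"` or `"social_media_account"`.
#' @param url Story URL.
#' @param source_province,source_prefecture Administrative location of the
#'   media source, or `NULL` when unknown.
#' @return A `media_story` object (named list).
#' @export
media_story <- function(story_id, title, body, publication_datetime,
                        source_name, source_kind = "news_website", url,
                        source_province = NULL, source_prefecture = NULL) {
  assert_string(story_id, "story_id")
  assert_string(title, "title")
  assert_string(body, "body")
  assert_string(url, "url")
  if (!source_kind %in% c("news_website", "social_media_account")) {
    abort("`source_kind` must be 'news_website' or 'social_media_account'.")
  }
  dt <- tryCatch(as.POSIXct(publication_datetime, tz = "UTC"),
                 error = function(e) NA)
  if (is.na(dt)) abort("`publication_datetime` is not parseable.")
  structure(list(
    story_id = story_id, title = title, body = body,
    publication_datetime = format(dt, "%Y-%m-%d %H:%M:%S"),
    source_name = source_name, source_kind = source_kind, url = url,
    source_province = source_province, source_prefecture = source_prefecture
  ), class = "media_story")
}

story_pub_date <- function(story) {
  as.Date(substr(story$publication_datetime, 1, 10))
}

story_text <- function(story, scope = c("title_body", "title", "body")) {
  scope <- match.arg(scope)
  switch(scope,
         title = story$title,
         body = story$body,
         title_body = paste(story$title, story$body))
}

#' Construct a structured injury record
#'
#' A structured record holds values for any subset of the 34 leaf fields
#' (see [leaf_fields()]); a field that a story does not state is simply
#' absent -- "not stated" is never encoded as zero. `event_date` is an
#' ISO-8601 string whose length encodes its precision (`"2015"`,
#' `"2015-09"`, `"2015-09-14"`); `event_location` is a list with `province`
#' and optional `prefecture`.
#'
#' @param ... Named leaf-field values.
#' @return A `structured_record` object.
#' @export
structured_record <- function(...) {
  vals <- list(...)
  if (length(vals) == 1 && is.null(names(vals)) && is.list(vals[[1]])) {
    vals <- vals[[1]]
  }
  vals <- vals[!vapply(vals, is.null, logical(1))]
  unknown <- setdiff(names(vals), leaf_field_names())
  if (length(unknown)) {
    abort(sprintf("Unknown leaf field(s): %s", paste(unknown, collapse = ", ")))
  }
  structure(vals, class = "structured_record")
}

record_field <- function(record, field) {
  if (field %in% names(record)) record[[field]] else NULL
}

record_has <- function(record, field) {
  !is.null(record_field(record, field))
}

event_date_precision <- function(x) {
  switch(as.character(nchar(x)), "4" = "year", "7" = "month", "10" = "day",
         abort(sprintf("Malformed event date: %s", x)))
}

event_date_as_date <- function(x) {
  as.Date(switch(event_date_precision(x),
                 year = paste0(x, "-01-01"),
                 month = paste0(x, "-01"),
                 day = x))
}

#' Validate a structured record
#'
#' Checks the field-level invariants: counts are non-negative integers,
#' child deaths/injuries never exceed the corresponding totals, the child
#' age lies in the configured range, dates are well formed and (for eligible
#' records) not earlier than the platform's start date.
#'
#' @param record A [structured_record()].
#' @param child_age_range Inclusive age range defining "child", in years.
#' @param min_event_date Earliest admissible event date.
#' @return A character vector of violation descriptions; empty when the
#'   record is valid. Violations are returned, never raised.
#' @export
validate_record <- function(record, child_age_range = c(0, 17),
                            min_event_date = as.Date("2010-01-01")) {
  v <- character(0)
  note <- function(msg) v <<- c(v, msg)
  count_fields <- c("deaths_total", "injured_total", "child_deaths",
                    "injured_children", "product_count", "children_involved",
                    "supervisor_count")
  for (f in count_fields) {
    x <- record_field(record, f)
    if (!is.null(x) && (!is.numeric(x) || is.na(x) || x < 0 || x != trunc(x))) {
      note(sprintf("%s: must be a non-negative integer", f))
    }
  }
  dt <- record_field(record, "deaths_total")
  cd <- record_field(record, "child_deaths")
  if (!is.null(dt) && !is.null(cd) && is.numeric(dt) && is.numeric(cd) &&
      cd > dt) {
    note("child_deaths: exceeds deaths_total")
  }
  it <- record_field(record, "injured_total")
  ic <- record_field(record, "injured_children")
  if (!is.null(it) && !is.null(ic) && is.numeric(it) && is.numeric(ic) &&
      ic > it) {
    note("injured_children: exceeds injured_total")
  }
  age <- record_field(record, "child_age")
  if (!is.null(age) &&
      (!is.numeric(age) || age < child_age_range[1] || age > child_age_range[2])) {
    note(sprintf("child_age: outside configured child age range [%d, %d]",
                 child_age_range[1], child_age_range[2]))
  }
  ed <- record_field(record, "event_date")
  if (!is.null(ed)) {
    ok <- tryCatch({
      d <- event_date_as_date(ed)
      if (d < min_event_date) note(sprintf("event_date: earlier than %s",
                                           format(min_event_date)))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) note("event_date: malformed (expect YYYY, YYYY-MM or YYYY-MM-DD)")
  }
  loc <- record_field(record, "event_location")
  if (!is.null(loc) && (!is.list(loc) || is.null(loc$province))) {
    note("event_location: must carry at least a province")
  }
  sp <- record_field(record, "supervisor_present")
  if (!is.null(sp) && !is.logical(sp)) note("supervisor_present: must be logical")
  v
}

# Flatten a record to one scalar value per leaf field (for CSV export).
record_to_row <- function(record) {
  out <- lapply(leaf_field_names(), function(f) {
    x <- record_field(record, f)
    if (is.null(x)) return(NA_character_)
    if (f == "event_location") {
      return(paste(c(x$province, x$prefecture), collapse = "|"))
    }
    as.character(x)
  })
  names(out) <- leaf_field_names()
  out
}

record_from_row <- function(row) {
  vals <- list()
  for (f in leaf_field_names()) {
    x <- row[[f]]
    if (is.null(x) || length(x) == 0 || is.na(x) || identical(x, "")) next
    vals[[f]] <- switch(field_type(f),
      count = as.integer(x),
      age = as.numeric(x),
      boolean = as.logical(x),
      location = {
        parts <- strsplit(x, "|", fixed = TRUE)[[1]]
        loc <- list(province = parts[1])
        if (length(parts) > 1) loc$prefecture <- parts[2]
        loc
      },
      as.character(x))
  }
  structured_record(vals)
}

# JSON-ready representation and its inverse (round-trip exact).
record_to_json_list <- function(record) {
  unclass(record)
}

record_from_json_list <- function(x) {
  vals <- list()
  for (f in names(x)) {
    if (is.null(x[[f]])) next
    vals[[f]] <- switch(field_type(f),
      count = as.integer(x[[f]]),
      age = as.numeric(x[[f]]),
      boolean = as.logical(x[[f]]),
      location = x[[f]],
      as.character(x[[f]]))
  }
  structured_record(vals)
}

#' Construct a gold label
#'
#' Links a story to its manual adjudication: eligible stories carry a gold
#' structured record, ineligible stories carry none.
#'
#' @param story_id Story identifier.
#' @param eligible Logical.
#' @param gold_record A [structured_record()] when eligible, else `NULL`.
#' @return A `gold_label` object.
#' @export
gold_label <- function(story_id, eligible, gold_record = NULL) {
  assert_string(story_id, "story_id")
  if (!is.logical(eligible) || length(eligible) != 1 || is.na(eligible)) {
    abort("`eligible` must be TRUE or FALSE.")
  }
  if (eligible && is.null(gold_record)) {
    abort("Eligible labels must carry a gold_record.")
  }
  if (!eligible && !is.null(gold_record)) {
    abort("Ineligible labels must not carry a gold_record.")
  }
  structure(list(story_id = story_id, eligible = eligible,
                 gold_record = gold_record), class = "gold_label")
}

#' Load the six-chapter keyword dictionary
#'
#' The keyword dictionary drives candidate search, filtering and categorical
#' extraction. It has exactly six chapters -- child, product, injury,
#' environment, activity, other -- the first three of which must be
#' non-empty. Terms may carry variant spellings and must be unique within a
#' chapter.
#'
#' @param path JSON file mapping chapter name to a list of terms (strings or
#'   `{"term": ..., "variants": [...]}` objects). Defaults to the dictionary
#'   shipped with the package (an English-pack stand-in).
#' @return A `keyword_dictionary`: a tibble with columns `chapter`, `term`,
#'   `variants` (list column).
#' @export
load_keyword_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "keyword_dictionary_en.json",
                                package = "injurywatch")
  if (!file.exists(path)) abort(sprintf("Dictionary file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  required <- c("child", "product", "injury", "environment", "activity", "other")
  missing_ch <- setdiff(required, names(raw))
  if (length(missing_ch)) {
    abort(sprintf("Dictionary is missing required chapter(s): %s",
                  paste(missing_ch, collapse = ", ")))
  }
  extra <- setdiff(names(raw), required)
  if (length(extra)) {
    abort(sprintf("Dictionary has unknown chapter(s): %s",
                  paste(extra, collapse = ", ")))
  }
  rows <- purrr::map_dfr(required, function(ch) {
    entries <- raw[[ch]]
    if (length(entries) == 0) {
      return(tibble::tibble(chapter = character(0), term = character(0),
                            variants = list()))
    }
    terms <- vapply(entries, function(e) {
      if (is.character(e)) e else e$term
    }, character(1))
    variants <- lapply(entries, function(e) {
      if (is.character(e)) character(0) else unlist(e$variants) %||% character(0)
    })
    tibble::tibble(chapter = ch, term = terms, variants = variants)
  })
  dups <- rows |>
    dplyr::count(.data$chapter, .data$term) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dups)) {
    abort(sprintf("Duplicate term(s) within a chapter: %s",
                  paste(sprintf("%s/%s", dups$chapter, dups$term),
                        collapse = ", ")))
  }
  for (ch in c("child", "product", "injury")) {
    if (!any(rows$chapter == ch)) {
      abort(sprintf("Chapter '%s' must not be empty.", ch))
    }
  }
  structure(rows, class = c("keyword_dictionary", class(rows)))
}

# All surface forms (term + variants) for one or more chapters.
dictionary_terms <- function(dict, chapters = NULL) {
  rows <- if (is.null(chapters)) dict else dict[dict$chapter %in% chapters, ]
  unique(c(rows$term, unlist(rows$variants)))
}

#' Load the administrative gazetteer
#'
#' A two-level gazetteer of mainland-China administrative divisions:
#' provinces with nested prefecture-level units. The shipped default carries
#' the 31 real province names and codes with 333 synthetic prefecture names
#' (the platform's real gazetteer is not redistributable); totals match the
#' real administrative geography.
#'
#' @param path JSON file with a `provinces` array of
#'   `{name, code, prefectures}` objects. Defaults to the shipped file.
#' @return A `gazetteer`: list with `provinces` (tibble `name`, `code`),
#'   `prefectures` (tibble `name`, `province`), and counts `n_provinces`,
#'   `n_prefectures`.
#' @export
load_gazetteer <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gazetteer_cn_synthetic.json",
                                package = "injurywatch")
  if (!file.exists(path)) abort(sprintf("Gazetteer file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  provs <- raw$provinces
  if (length(provs) == 0) abort("Gazetteer file lists no provinces.")
  pnames <- vapply(provs, function(p) p$name, character(1))
  if (anyDuplicated(pnames)) {
    abort(sprintf("Duplicate province name(s): %s",
                  paste(unique(pnames[duplicated(pnames)]), collapse = ", ")))
  }
  pcodes <- vapply(provs, function(p) p$code %||% NA_character_, character(1))
  pref <- purrr::map_dfr(provs, function(p) {
    prefs <- unlist(p$prefectures) %||% character(0)
    tibble::tibble(name = as.character(prefs), province = p$name)
  })
  if (nrow(pref)) {
    dup <- pref |>
      dplyr::count(.data$province, .data$name) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup)) {
      abort(sprintf("Duplicate prefecture name(s) within a province: %s",
                    paste(dup$name, collapse = ", ")))
    }
  }
  structure(list(
    provinces = tibble::tibble(name = pnames, code = pcodes),
    prefectures = pref,
    n_provinces = length(pnames),
    n_prefectures = nrow(pref),
    # precompiled name-alternation regexes (entity matching hot path)
    province_rx = terms_regex(pnames),
    prefecture_rx = if (nrow(pref)) terms_regex(pref$name) else NULL
  ), class = "gazetteer")
}

#' @export
print.gazetteer <- function(x, ...) {
  cat(sprintf("<gazetteer: %d provinces, %d prefecture-level units>\n",
              x$n_provinces, x$n_prefectures))
  invisible(x)
}

#' Look up the province of a prefecture-level unit
#'
#' @param gaz A [load_gazetteer()] object.
#' @param prefecture Prefecture name.
#' @return The province name, or `NULL` when the prefecture is unknown.
#' @export
gazetteer_province_of <- function(gaz, prefecture) {
  i <- match(prefecture, gaz$prefectures$name)
  if (is.na(i)) NULL else gaz$prefectures$province[i]
}

#' Read and write story corpora
#'
#' Stories are interchanged as JSON-lines, one story per line.
#'
#' @param stories List of [media_story()] objects.
#' @param path File path.
#' @return `read_stories()` returns a list of `media_story` objects.
#' @export
write_stories <- function(stories, path) {
  write_jsonl(lapply(stories, unclass), path)
}

#' @rdname write_stories
#' @export
read_stories <- function(path) {
  lapply(read_jsonl(path), function(x) {
    media_story(x$story_id, x$title, x$body, x$publication_datetime,
                x$source_name, x$source_kind, x$url,
                x$source_province, x$source_prefecture)
  })
}

#' Read and write gold labels
#'
#' @param labels List of [gold_label()] objects.
#' @param path File path.
#' @return `read_gold_labels()` returns a list of `gold_label` objects.
#' @export
write_gold_labels <- function(labels, path) {
  write_jsonl(lapply(labels, function(l) {
    list(story_id = l$story_id, eligible = l$eligible,
         gold_record = if (is.null(l$gold_record)) NULL else
           record_to_json_list(l$gold_record))
  }), path)
}

#' @rdname write_stories
#' @export
read_gold_labels <- function(path) {
  lapply(read_jsonl(path), function(x) {
    gold_label(x$story_id, isTRUE(x$eligible),
               if (is.null(x$gold_record)) NULL else
                 record_from_json_list(x$gold_record))
  })
}
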