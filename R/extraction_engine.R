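# Number-token alternation used inside numeric patterns (digits or number
# words; normalised to digits on conversion).
num_token_rx <- function() {
  paste0("(?:\\d+|", paste(names(number_words()), collapse = "|"), ")")
}

#' Default strategy routing
#'
#' Which extraction strategies are enabled for each leaf field, in priority
#' order. The default mirrors the published per-variable strategy
#' assignment: for example, the event date uses all three strategies, child
#' sex only keyword + relation patterns, supervisor age only regular
#' expressions. Under conflict the earlier strategy in the list wins
#' (regex > entity > keyword_dependency).
#'
#' @return Named list: leaf field -> character vector of strategies.
#' @export
default_strategy_routing <- function() {
  lf <- leaf_fields()
  stats::setNames(lf$strategies, lf$field)
}

#' Default extraction pattern rules
#'
#' Builds the rule inventory behind the three strategy families:
#' `regex` rules capture numeric and free-text slots with syntactic
#' anchors; `entity` rules recognise dates and gazetteer place names;
#' `keyword_dependency` rules fire only when a dictionary keyword occurs in
#' its configured relation (trigger phrase / governance window), never on
#' bare keyword presence. "Dependency syntactic parsing" is realised as
#' these configurable relation patterns; a parser-backed relation provider
#' can be plugged in by supplying a different rule set.
#'
#' @param dict Keyword dictionary (reserved for custom vocabularies).
#' @param catalog Product catalog supplying the product-name vocabulary.
#' @param pack Language pack supplying codebooks, months and number words.
#' @return Named list: leaf field -> list of rules.
#' @export
default_extraction_patterns <- function(dict = load_keyword_dictionary(),
                                        catalog = default_product_catalog(),
                                        pack = default_language_pack()) {
  cb <- pack$codebook
  num <- num_token_rx()
  rx <- function(pattern, convert = "text", ignore_case = TRUE) {
    list(strategy = "regex", kind = "capture", pattern = pattern,
         convert = convert, ignore_case = ignore_case)
  }
  kd_kw <- function(pattern, vocab, map = NULL) {
    list(strategy = "keyword_dependency", kind = "kw", pattern = pattern,
         vocab = vocab, map = map, ignore_case = TRUE,
         compiled = compile_kw_pattern(pattern, vocab))
  }
  kd_cap <- function(pattern, convert = "text", ignore_case = TRUE) {
    list(strategy = "keyword_dependency", kind = "capture",
         pattern = pattern, convert = convert, ignore_case = ignore_case)
  }
  verbs <- cb$external_cause$verb
  cause_map <- stats::setNames(cb$external_cause$category, verbs)
  mech_verbs <- c(verbs, "ingested", "was injured by", "injured by")
  list(
    event_date = list(
      rx("\\b(\\d{4}-\\d{2}-\\d{2})\\b", convert = "iso_date"),
      list(strategy = "entity", kind = "date")),
    event_location = list(
      list(strategy = "entity", kind = "location")),
    place_type = list(
      kd_kw("took place at (?:the |a |an )?{kw}", cb$place_type)),
    injury_nature = list(
      kd_kw("suffered (?:a |an )?{kw}", cb$injury_nature)),
    body_part = list(
      kd_kw("affected the {kw}", cb$body_part)),
    external_cause = list(
      kd_kw("(?:boy|girl|child) {kw}", verbs, map = cause_map)),
    clinical_diagnosis = list(
      rx("gave a diagnosis of ([a-z ]+)\\."),
      kd_cap("gave a diagnosis of ([a-z ]+)\\.")),
    deaths_total = list(
      rx(sprintf("claimed (%s) li(?:fe|ves) in total", num),
         convert = "count")),
    injured_total = list(
      rx(sprintf("altogether (%s) (?:person was|people were) injured", num),
         convert = "count")),
    child_deaths = list(
      rx(sprintf("(%s) of the deaths (?:was|were)", num), convert = "count"),
      rx(sprintf("(%s) died\\b", num), convert = "count")),
    injured_children = list(
      rx(sprintf("(%s) child(?:ren)? (?:was|were) injured", num),
         convert = "count")),
    product_count = list(
      kd_cap(sprintf("(%s) units? of the product", num), convert = "count")),
    product_name = list(
      kd_kw(sprintf("(?:%s) (?:the |a |an )?{kw}",
                    paste(mech_verbs, collapse = "|")),
            catalog$name)),
    product_brand = list(
      kd_cap("under the brand ([A-Z][A-Za-z0-9-]*)", ignore_case = FALSE)),
    product_characteristics = list(
      kd_cap("described as ([a-z ,-]+)\\.")),
    product_type = list(
      kd_kw("classed as (?:a |an )?{kw}", cb$product_type)),
    disposition = list(
      kd_kw("was subsequently {kw}", cb$disposition)),
    children_involved = list(
      rx(sprintf("involved (%s) child(?:ren)?", num), convert = "count")),
    child_age = list(
      rx(sprintf("(%s)-year-old (?:boy|girl|child)", num),
         convert = "count")),
    child_sex = list(
      kd_kw("(?:[a-z0-9]+-year-old|young) {kw}", names(cb$child_sex),
            map = cb$child_sex)),
    child_activity = list(
      kd_cap("was ([a-z ]+?) at the time\\.")),
    supervisor_count = list(
      rx(sprintf("accompanied by (%s) adult supervisor", num),
         convert = "count")),
    supervisor_age = list(
      rx(paste0("(\\d+)-year-old (?:",
                paste(c(cb$supervisor_relation, "caregiver", "supervisor"),
                      collapse = "|"), ")"),
         convert = "count")),
    supervisor_sex = list(
      kd_kw("supervisor was a {kw}", names(cb$supervisor_sex),
            map = cb$supervisor_sex)),
    supervisor_relation = list(
      kd_kw("(?:his|her|the|their) (?:\\d+-year-old )?{kw} was",
            cb$supervisor_relation)),
    supervisor_present = list(
      kd_kw(paste0("(?:", paste(c(cb$supervisor_relation, "caregiver",
                                  "supervisor"), collapse = "|"),
                   ") was {kw}"),
            names(cb$supervisor_present), map = cb$supervisor_present)),
    etiology_human = list(
      kd_kw("attributed the event to {kw}", cb$etiology_human)),
    etiology_product = list(
      kd_kw("{kw} in the product", cb$etiology_product)),
    etiology_detail = list(
      kd_cap("in detail, ([a-z ,-]+)\\.")),
    weather = list(
      kd_cap("weather at the time was ([a-z ]+)\\.")),
    air_quality = list(
      kd_cap("air quality that day was ([a-z ]+)\\.")),
    temperature = list(
      kd_cap("temperature was (-?\\d+ degrees celsius)",
             convert = "span_text")),
    other_environment = list(
      rx("conditions included ([a-z ,-]+)\\."),
      kd_cap("conditions included ([a-z ,-]+)\\.")),
    preventive_measure = list(
      rx("advised that ([a-z ,-]+)\\."),
      kd_cap("advised that ([a-z ,-]+)\\."))
  )
}

compile_kw_pattern <- function(pattern, vocab) {
  vocab <- vocab[order(-nchar(vocab))]
  alt <- paste0("(", paste(vapply(vocab, regex_escape, character(1)),
                           collapse = "|"), ")")
  sub("{kw}", alt, pattern, fixed = TRUE)
}

convert_value <- function(raw, convert) {
  switch(convert %||% "text",
    count = {
      v <- parse_number_token(raw)
      if (is.na(v)) NULL else as.integer(v)
    },
    iso_date = raw,
    span_text = raw,
    text = stringr::str_squish(raw))
}

# Run one rule against the text; returns list(value, span) or NULL.
run_rule <- function(text, rule, gaz = NULL, pack = NULL) {
  if (rule$kind == "date") return(entity_date(text, pack))
  if (rule$kind == "location") return(entity_location(text, gaz))
  pattern <- rule$pattern
  if (rule$kind == "kw") {
    pattern <- rule$compiled %||% compile_kw_pattern(rule$pattern,
                                                     rule$vocab)
  }
  m <- stringr::str_match(text, stringr::regex(
    pattern, ignore_case = isTRUE(rule$ignore_case)))
  if (is.na(m[1, 1])) return(NULL)
  if (rule$kind == "kw") {
    kw_raw <- m[1, 2]
    canon <- rule$vocab[match(tolower(kw_raw), tolower(rule$vocab))]
    value <- if (!is.null(rule$map)) unname(rule$map[[canon]]) else canon
    return(list(value = value, span = m[1, 1]))
  }
  raw <- if (ncol(m) >= 2 && !is.na(m[1, 2])) m[1, 2] else m[1, 1]
  value <- convert_value(raw, rule$convert)
  if (is.null(value)) return(NULL)
  list(value = value, span = m[1, 1])
}

entity_date <- function(text, pack) {
  months <- pack$months
  malt <- paste(months, collapse = "|")
  m <- stringr::str_match(text, stringr::regex(
    sprintf("\\bon (\\d{1,2}) (%s) (\\d{4})", malt), ignore_case = TRUE))
  if (!is.na(m[1, 1])) {
    mo <- match(tolower(m[1, 3]), tolower(months))
    return(list(value = sprintf("%s-%02d-%02d", m[1, 4], mo,
                                as.integer(m[1, 2])), span = m[1, 1]))
  }
  m <- stringr::str_match(text, stringr::regex(
    sprintf("\\bin (%s) (\\d{4})", malt), ignore_case = TRUE))
  if (!is.na(m[1, 1])) {
    mo <- match(tolower(m[1, 2]), tolower(months))
    return(list(value = sprintf("%s-%02d", m[1, 3], mo), span = m[1, 1]))
  }
  m <- stringr::str_match(text, "\\bin ((?:19|20)\\d{2})\\b")
  if (!is.na(m[1, 1])) return(list(value = m[1, 2], span = m[1, 1]))
  NULL
}

entity_location <- function(text, gaz) {
  if (nrow(gaz$prefectures) > 0) {
    prx <- gaz$prefecture_rx %||% terms_regex(gaz$prefectures$name)
    m <- regmatches(text, regexpr(prx, text, perl = TRUE))
    if (length(m)) {
      pref <- m[1]
      return(list(value = list(province = gazetteer_province_of(gaz, pref),
                               prefecture = pref), span = pref))
    }
  }
  vrx <- gaz$province_rx %||% terms_regex(gaz$provinces$name)
  m <- regmatches(text, regexpr(vrx, text, perl = TRUE))
  if (length(m)) {
    return(list(value = list(province = m[1]), span = m[1]))
  }
  NULL
}

# Strict typed equality between two extracted/gold values of one field;
# used for conflict detection (precision-aware comparison for scoring lives
# in values_match_gold()).
values_identical <- function(field, a, b) {
  type <- field_type(field)
  if (type == "location") {
    return(identical(a$province, b$province) &&
             identical(a$prefecture %||% NA_character_,
                       b$prefecture %||% NA_character_))
  }
  if (type %in% c("count", "age")) return(isTRUE(a == b))
  if (type == "boolean") return(identical(a, b))
  identical(stringr::str_squish(tolower(as.character(a))),
            stringr::str_squish(tolower(as.character(b))))
}

#' Extract a numeric field with regular expressions
#'
#' Applies the field's regex rules to the text and returns the first match
#' converted to a number; number words of the active language pack are
#' normalised to digits.
#'
#' @param text Story text.
#' @param field A numeric-typed leaf field (count, age).
#' @param patterns Rule inventory, see [default_extraction_patterns()].
#' @return Integer value, or `NULL` when no rule matches.
#' @export
extract_numeric_regex <- function(text, field,
                                  patterns = default_extraction_patterns()) {
  if (!field_type(field) %in% c("count", "age")) {
    abort(sprintf("Field '%s' is not numeric-typed.", field))
  }
  rules <- purrr::keep(patterns[[field]] %||% list(),
                       function(r) r$strategy == "regex")
  if (length(rules) == 0) {
    abort(sprintf("No regex rules configured for field '%s'.", field))
  }
  for (r in rules) {
    hit <- run_rule(text, r)
    if (!is.null(hit)) return(hit$value)
  }
  NULL
}

#' Extract date and place entities
#'
#' Recognises the event date (day, month or year precision, encoded in the
#' ISO string length) and the event location, resolved against the
#' gazetteer at the most specific level found (a prefecture hit implies its
#' province).
#'
#' @param text Story text.
#' @param gaz Gazetteer.
#' @param pack Language pack (month names).
#' @return A partial [structured_record()] with `event_date` and/or
#'   `event_location` when recognised.
#' @export
extract_entities <- function(text, gaz = load_gazetteer(),
                             pack = default_language_pack()) {
  vals <- list()
  d <- entity_date(text, pack)
  if (!is.null(d)) vals$event_date <- d$value
  l <- entity_location(text, gaz)
  if (!is.null(l)) vals$event_location <- l$value
  structured_record(vals)
}

#' Extract a field with keyword + relation patterns
#'
#' A value is returned only when a vocabulary keyword matches *and* its
#' configured relation pattern (trigger phrase within the pattern window)
#' is satisfied; bare keyword presence never fires.
#'
#' @param text Story text.
#' @param field Leaf field routed to this strategy.
#' @param patterns Rule inventory.
#' @return The extracted value, or `NULL`.
#' @export
extract_keyword_dependency <- function(text, field,
                                       patterns =
                                         default_extraction_patterns()) {
  rules <- purrr::keep(patterns[[field]] %||% list(),
                       function(r) r$strategy == "keyword_dependency")
  for (r in rules) {
    hit <- run_rule(text, r)
    if (!is.null(hit)) return(hit$value)
  }
  NULL
}

#' Resolve competing strategy outputs for one field
#'
#' When all candidates agree (or only one strategy fired) the value is
#' taken as-is; on disagreement the value from the highest-priority enabled
#' strategy in the routing order wins and the conflict is reported so the
#' decision can be audited.
#'
#' @param candidates Named list strategy -> value (only enabled strategies).
#' @param routing Strategy routing, see [default_strategy_routing()].
#' @param field Leaf field name.
#' @return `list(value = <value or NULL>, conflict = <NULL or list>)`.
#' @export
resolve_strategy_conflicts <- function(candidates, routing, field) {
  candidates <- candidates[!vapply(candidates, is.null, logical(1))]
  if (length(candidates) == 0) return(list(value = NULL, conflict = NULL))
  order_ <- intersect(routing[[field]], names(candidates))
  candidates <- candidates[order_]
  first <- candidates[[1]]
  agree <- all(vapply(candidates, function(v)
    values_identical(field, first, v), logical(1)))
  if (agree) return(list(value = first, conflict = NULL))
  list(value = first,
       conflict = list(field = field, values = candidates))
}

#' Extract the full structured record from one story
#'
#' Runs every enabled strategy for each of the 34 leaf fields, resolves
#' conflicts by routing priority, and returns the record together with
#' per-field provenance (strategy, matched span, confidence tier) and any
#' conflicts. Extraction is deterministic and never raises on content:
#' fields that no rule matches are left missing.
#'
#' @param story A [media_story()] (normally one that passed eligibility).
#' @param dict Keyword dictionary.
#' @param gaz Gazetteer.
#' @param routing Strategy routing.
#' @param patterns Rule inventory.
#' @param pack Language pack.
#' @return An `extraction_result`: list with `story_id`, `record`,
#'   `provenance` (field -> list(strategy, span, tier)), `conflicts` and
#'   `violations` (from [validate_record()]).
#' @export
extract_record <- function(story, dict = load_keyword_dictionary(),
                           gaz = load_gazetteer(),
                           routing = default_strategy_routing(),
                           patterns = NULL,
                           pack = default_language_pack()) {
  patterns <- patterns %||% default_extraction_patterns(dict = dict,
                                                        pack = pack)
  text <- story_text(story)
  record_vals <- list()
  provenance <- list()
  conflicts <- list()
  tiers <- c("high", "medium", "low")
  for (field in leaf_field_names()) {
    enabled <- routing[[field]] %||% character(0)
    rules <- patterns[[field]] %||% list()
    candidates <- list()
    spans <- list()
    for (strategy in enabled) {
      srules <- purrr::keep(rules, function(r) r$strategy == strategy)
      for (r in srules) {
        hit <- run_rule(text, r, gaz = gaz, pack = pack)
        if (!is.null(hit)) {
          candidates[[strategy]] <- hit$value
          spans[[strategy]] <- hit$span
          break
        }
      }
    }
    res <- resolve_strategy_conflicts(candidates, routing, field)
    if (!is.null(res$value)) {
      record_vals[[field]] <- res$value
      win <- intersect(routing[[field]], names(candidates))[1]
      provenance[[field]] <- list(
        strategy = win, span = spans[[win]],
        tier = tiers[min(match(win, routing[[field]]), 3)])
    }
    if (!is.null(res$conflict)) {
      conflicts <- c(conflicts, list(res$conflict))
    }
  }
  record <- structured_record(record_vals)
  structure(list(story_id = story$story_id, record = record,
                 provenance = provenance, conflicts = conflicts,
                 violations = validate_record(record)),
            class = "extraction_result")
}

#' Extract records for a corpus
#'
#' Convenience wrapper building the pattern inventory once and running
#' [extract_record()] over a story list.
#'
#' @inheritParams extract_record
#' @param stories List of [media_story()] objects.
#' @param catalog Product catalog for the product-name vocabulary.
#' @return List of `extraction_result` objects.
#' @export
extract_corpus <- function(stories, dict = load_keyword_dictionary(),
                           gaz = load_gazetteer(),
                           routing = default_strategy_routing(),
                           catalog = default_product_catalog(),
                           pack = default_language_pack()) {
  patterns <- default_extraction_patterns(dict = dict, catalog = catalog,
                                          pack = pack)
  lapply(stories, extract_record, dict = dict, gaz = gaz, routing = routing,
         patterns = patterns, pack = pack)
}
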