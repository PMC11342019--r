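# Build a case-insensitive alternation regex over literal terms (longest
# first, word-bounded).
terms_regex <- function(terms) {
  terms <- terms[order(-nchar(terms))]
  paste0("\\b(?:", paste(vapply(terms, regex_escape, character(1)),
                         collapse = "|"), ")\\b")
}

chapter_hit <- function(texts, dict, chapter) {
  terms <- dictionary_terms(dict, chapter)
  if (length(terms) == 0) return(rep(FALSE, length(texts)))
  stringr::str_detect(texts, stringr::regex(terms_regex(terms),
                                            ignore_case = TRUE))
}

#' Keyword candidate search
#'
#' Retrieves candidate stories from a raw corpus with the dictionary-driven
#' rule: a story is a candidate when its title or body contains at least one
#' term from each of the three defining chapters -- child, product and
#' injury. The environment, activity and other chapters do not gate
#' candidacy.
#'
#' @param stories List of [media_story()] objects.
#' @param dict A [load_keyword_dictionary()] dictionary.
#' @return Candidate `story_id`s, ordered by publication date-time then
#'   story id.
#' @export
keyword_candidate_search <- function(stories, dict) {
  if (length(stories) == 0) return(character(0))
  texts <- vapply(stories, story_text, character(1))
  hit <- chapter_hit(texts, dict, "child") &
    chapter_hit(texts, dict, "product") &
    chapter_hit(texts, dict, "injury")
  ids <- vapply(stories, `[[`, character(1), "story_id")
  pubs <- vapply(stories, `[[`, character(1), "publication_datetime")
  keep <- which(hit)
  keep <- keep[order(pubs[keep], ids[keep])]
  ids[keep]
}

#' Default eligibility-filter rules
#'
#' @param child_age_range Inclusive child age range, years.
#' @param min_publication_date Earliest admissible publication date;
#'   stories published before 2010 are excluded because older stories are
#'   not consistently available online.
#' @param enabled Character vector of enabled rules among `fictional`,
#'   `jurisdiction`, `language`, `child`, `product`, `date`, `topical`.
#' @return A filter-rule configuration list.
#' @export
default_filter_rules <- function(child_age_range = c(0, 17),
                                 min_publication_date = as.Date("2010-01-01"),
                                 enabled = c("fictional", "jurisdiction",
                                             "language", "child", "product",
                                             "date", "topical")) {
  list(child_age_range = child_age_range,
       min_publication_date = as.Date(min_publication_date),
       enabled = enabled)
}

#' Apply the eligibility filter to one story
#'
#' A story is eligible when every enabled rule passes: the event is real
#' (no fiction markers), located in the configured jurisdiction, written in
#' the active language pack's script, involves a child and a consumer
#' product, was published on or after the platform start date, and is not a
#' purely topical (legal or educational commentary) piece. Extraction hints,
#' when available, sharpen the child/jurisdiction checks.
#'
#' @param story A [media_story()].
#' @param hints Optional partial [structured_record()] of extracted values.
#' @param rules A [default_filter_rules()] configuration.
#' @param dict Keyword dictionary.
#' @param gaz Gazetteer.
#' @param pack Language pack.
#' @return `list(eligible = <logical>, reasons = <character>)`; `reasons`
#'   names every failed rule.
#' @export
apply_eligibility_filter <- function(story, hints = NULL,
                                     rules = default_filter_rules(),
                                     dict = load_keyword_dictionary(),
                                     gaz = load_gazetteer(),
                                     pack = default_language_pack()) {
  text <- story_text(story)
  reasons <- character(0)
  on_rule <- function(r) r %in% rules$enabled
  if (on_rule("fictional") &&
      stringr::str_detect(text, stringr::regex(
        terms_regex(pack$fiction_markers), ignore_case = TRUE))) {
    reasons <- c(reasons, "fictional")
  }
  if (on_rule("topical") &&
      stringr::str_detect(text, stringr::regex(
        terms_regex(pack$topical_markers), ignore_case = TRUE))) {
    reasons <- c(reasons, "topical")
  }
  if (on_rule("jurisdiction")) {
    prov <- if (!is.null(hints)) {
      loc <- record_field(hints, "event_location")
      if (!is.null(loc)) loc$province else NULL
    }
    if (!is.null(prov) && !prov %in% gaz$provinces$name) {
      reasons <- c(reasons, "outside_jurisdiction")
    }
  }
  if (on_rule("language")) {
    letters_all <- stringr::str_count(text, "[[:alpha:]]")
    letters_pack <- stringr::str_count(text, pack$script_regex)
    if (letters_all > 0 && letters_pack / letters_all < 0.5) {
      reasons <- c(reasons, "language_mismatch")
    }
  }
  if (on_rule("child")) {
    age <- if (!is.null(hints)) record_field(hints, "child_age") else NULL
    child_ok <- if (!is.null(age)) {
      age >= rules$child_age_range[1] && age <= rules$child_age_range[2]
    } else {
      any(chapter_hit(text, dict, "child"))
    }
    if (!child_ok) reasons <- c(reasons, "no_child")
  }
  if (on_rule("product")) {
    prod_ok <- (!is.null(hints) && record_has(hints, "product_name")) ||
      any(chapter_hit(text, dict, "product"))
    if (!prod_ok) reasons <- c(reasons, "no_product")
  }
  if (on_rule("date") &&
      story_pub_date(story) < rules$min_publication_date) {
    reasons <- c(reasons, "pre_start_date")
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}

normalise_title <- function(x) {
  x <- tolower(x)
  x <- stringr::str_replace_all(x, "[^a-z0-9 ]", " ")
  stringr::str_squish(x)
}

token_shingles <- function(text, k = 3) {
  toks <- stringr::str_split_1(stringr::str_squish(tolower(
    stringr::str_replace_all(text, "[^[:alnum:] ]", " "))), " ")
  toks <- toks[nzchar(toks)]
  if (length(toks) < k) return(paste(toks, collapse = " "))
  vapply(seq_len(length(toks) - k + 1),
         function(i) paste(toks[i:(i + k - 1)], collapse = " "),
         character(1))
}

shingle_jaccard <- function(a, b) {
  sa <- unique(a); sb <- unique(b)
  u <- length(union(sa, sb))
  if (u == 0) return(1)
  length(intersect(sa, sb)) / u
}

#' Deduplicate a story corpus
#'
#' Collapses exact-URL duplicates and near-duplicates (equal normalised
#' title and token-shingle Jaccard body similarity at or above the
#' threshold), keeping the earliest-published story of each cluster as the
#' representative. The operation is idempotent.
#'
#' @param stories List of [media_story()] objects.
#' @param threshold Jaccard similarity threshold for near-duplicate bodies.
#' @param shingle Token shingle length.
#' @return `list(kept = <stories>, clusters = <list of story_id vectors>)`;
#'   clusters only lists groups of size two or more.
#' @export
deduplicate_stories <- function(stories, threshold = 0.9, shingle = 3) {
  n <- length(stories)
  if (n == 0) return(list(kept = stories, clusters = list()))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  urls <- vapply(stories, `[[`, character(1), "url")
  for (grp in split(seq_len(n), urls)) {
    if (length(grp) > 1) for (j in grp[-1]) union_(grp[1], j)
  }
  titles <- normalise_title(vapply(stories, `[[`, character(1), "title"))
  bodies <- lapply(stories, function(s) token_shingles(s$body, shingle))
  for (grp in split(seq_len(n), titles)) {
    if (length(grp) < 2) next
    for (a in seq_along(grp)) {
      for (b in seq_len(a - 1L)) {
        i <- grp[a]; j <- grp[b]
        if (find(i) == find(j)) next
        if (shingle_jaccard(bodies[[i]], bodies[[j]]) >= threshold) {
          union_(i, j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  pubs <- vapply(stories, `[[`, character(1), "publication_datetime")
  ids <- vapply(stories, `[[`, character(1), "story_id")
  kept_idx <- integer(0)
  clusters <- list()
  for (grp in split(seq_len(n), roots)) {
    rep_i <- grp[order(pubs[grp], ids[grp])][1]
    kept_idx <- c(kept_idx, rep_i)
    if (length(grp) > 1) clusters <- c(clusters, list(ids[sort(grp)]))
  }
  kept_idx <- sort(kept_idx)
  list(kept = stories[kept_idx], clusters = clusters)
}
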