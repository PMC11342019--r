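#' Load the reference per-variable extraction performance table
#'
#' A transcription of a published manual-validation study of the extraction
#' strategy suite on 1000 product-related child-injury media stories: for
#' each of the 34 leaf fields, the number of evaluated stories including the
#' variable, the extraction rate (%) and the extraction accuracy (%).
#' Five variables that none of the evaluated stories mentioned carry `NA`.
#'
#' @return A tibble with columns `variable_id`, `variable`, `n_including`,
#'   `extraction_rate`, `accuracy`.
#' @export
load_reference_evaluation <- function() {
  path <- system.file("extdata", "reference_extraction_performance.csv",
                      package = "injurywatch")
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "integer",
                                 "numeric", "numeric")) |>
    tibble::as_tibble()
}

# Precision-aware, type-aware match of an extracted value against the gold
# value. Dates are compared at the gold record's precision; counts exactly;
# text case/whitespace-normalised; locations on province and, when the gold
# states one, prefecture.
values_match_gold <- function(field, extracted, gold) {
  type <- field_type(field)
  if (type == "date") {
    k <- nchar(gold)
    return(nchar(extracted) >= k && substr(extracted, 1, k) == gold)
  }
  if (type == "location") {
    if (!identical(extracted$province, gold$province)) return(FALSE)
    if (is.null(gold$prefecture)) return(TRUE)
    return(identical(extracted$prefecture, gold$prefecture))
  }
  values_identical(field, extracted, gold)
}

align_results_gold <- function(results, gold) {
  rid <- vapply(results, `[[`, character(1), "story_id")
  gid <- vapply(gold, `[[`, character(1), "story_id")
  idx <- match(rid, gid)
  if (anyNA(idx) || length(rid) != length(gid)) {
    abort("`results` and `gold` are not aligned on story_id.")
  }
  gold[idx]
}

#' Per-field extraction rate
#'
#' Share of evaluated stories for which the extractor returned a
#' non-missing value for the field. Both denominator conventions are
#' supported: `"all"` divides by all evaluated stories (the default);
#' `"including"` divides by the stories whose gold record states the field.
#'
#' @param results List of `extraction_result` objects.
#' @param gold List of [gold_label()] objects covering the same stories.
#' @param field Leaf field name.
#' @param denominator `"all"` or `"including"`.
#' @return Percentage in `[0, 100]`, or `NA` when the chosen denominator
#'   is zero (rate not calculable).
#' @export
compute_extraction_rate <- function(results, gold, field,
                                    denominator = c("all", "including")) {
  denominator <- match.arg(denominator)
  if (length(results) == 0) abort("No results to evaluate.")
  gold <- align_results_gold(results, gold)
  extracted <- vapply(results, function(r) record_has(r$record, field),
                      logical(1))
  if (denominator == "all") {
    den <- length(results)
  } else {
    den <- sum(vapply(gold, function(g) !is.null(g$gold_record) &&
                        record_has(g$gold_record, field), logical(1)))
  }
  if (den == 0) return(NA_real_)
  100 * sum(extracted) / den
}

#' Per-field extraction accuracy
#'
#' Share of stories whose extracted value matches the gold value under
#' field-typed comparison (dates at the gold precision, counts exactly,
#' text normalised). `basis = "including"` (default) scores over stories
#' whose gold record states the field -- a missing extraction counts as a
#' miss; `basis = "extracted"` scores only over stories with a non-missing
#' extraction.
#'
#' @inheritParams compute_extraction_rate
#' @param basis `"including"` or `"extracted"`.
#' @return Percentage, or `NA` when the basis set is empty.
#' @export
compute_extraction_accuracy <- function(results, gold, field,
                                        basis = c("including", "extracted")) {
  basis <- match.arg(basis)
  if (length(results) == 0) abort("No results to evaluate.")
  gold <- align_results_gold(results, gold)
  gold_vals <- lapply(gold, function(g)
    if (is.null(g$gold_record)) NULL else record_field(g$gold_record, field))
  ext_vals <- lapply(results, function(r) record_field(r$record, field))
  if (basis == "including") {
    in_scope <- which(!vapply(gold_vals, is.null, logical(1)))
  } else {
    in_scope <- which(!vapply(ext_vals, is.null, logical(1)))
  }
  if (length(in_scope) == 0) return(NA_real_)
  hits <- vapply(in_scope, function(i) {
    e <- ext_vals[[i]]; g <- gold_vals[[i]]
    if (is.null(e) || is.null(g)) return(FALSE)
    values_match_gold(field, e, g)
  }, logical(1))
  100 * sum(hits) / length(in_scope)
}

#' Full per-variable evaluation table
#'
#' One row per leaf field: stories including the variable, extraction rate
#' and extraction accuracy, in the layout of the published validation
#' table.
#'
#' @inheritParams compute_extraction_rate
#' @inheritParams compute_extraction_accuracy
#' @return A tibble with columns `variable_id`, `variable`, `n_including`,
#'   `extraction_rate`, `accuracy`.
#' @export
evaluation_table <- function(results, gold,
                             denominator = c("all", "including"),
                             basis = c("including", "extracted")) {
  denominator <- match.arg(denominator)
  basis <- match.arg(basis)
  lf <- leaf_fields()
  gold_al <- align_results_gold(results, gold)
  purrr::map_dfr(seq_len(nrow(lf)), function(i) {
    field <- lf$field[i]
    n_inc <- sum(vapply(gold_al, function(g) !is.null(g$gold_record) &&
                          record_has(g$gold_record, field), logical(1)))
    tibble::tibble(
      variable_id = lf$id[i],
      variable = lf$label[i],
      n_including = n_inc,
      extraction_rate = compute_extraction_rate(results, gold, field,
                                                denominator),
      accuracy = compute_extraction_accuracy(results, gold, field, basis))
  })
}

#' Band summary of an evaluation table
#'
#' Summarises per-variable extraction rates into the reporting bands used
#' for the platform's headline results: rates above 95%, rates in the
#' middle band (50--95%, with the observed min/max), rates below 50%, and
#' rates not calculable; plus the count of variables with accuracy above
#' 70% and the list of exceptions at or below 70%.
#'
#' @param rows A tibble as returned by [evaluation_table()] or
#'   [load_reference_evaluation()].
#' @return A list with `n_rate_over_95`, `n_rate_mid_band`,
#'   `mid_band_range`, `n_rate_under_50`, `n_rate_not_calculable`,
#'   `n_accuracy_over_70`, `accuracy_exceptions` (tibble of variables with
#'   accuracy <= 70).
#' @export
summarize_evaluation_table <- function(rows) {
  if (nrow(rows) == 0) {
    return(list(n_rate_over_95 = 0L, n_rate_mid_band = 0L,
                mid_band_range = c(NA_real_, NA_real_),
                n_rate_under_50 = 0L, n_rate_not_calculable = 0L,
                n_accuracy_over_70 = 0L,
                accuracy_exceptions = rows))
  }
  rate <- rows$extraction_rate
  acc <- rows$accuracy
  mid <- !is.na(rate) & rate >= 50 & rate <= 95
  list(
    n_rate_over_95 = sum(!is.na(rate) & rate > 95),
    n_rate_mid_band = sum(mid),
    mid_band_range = if (any(mid)) range(rate[mid]) else
      c(NA_real_, NA_real_),
    n_rate_under_50 = sum(!is.na(rate) & rate < 50),
    n_rate_not_calculable = sum(is.na(rate)),
    n_accuracy_over_70 = sum(!is.na(acc) & acc > 70),
    accuracy_exceptions = rows[!is.na(acc) & acc <= 70,
                               c("variable_id", "variable", "accuracy")]
  )
}
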