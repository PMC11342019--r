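#' @importFrom rlang %||% abort warn
#' @importFrom stats runif
NULL

# package-local memo cache (leaf-field table, compiled patterns)
.iw_cache <- new.env(parent = emptyenv())

#' Round half away from zero
#'
#' The rounding convention used for reported percentages (base `round()`
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

assert_string <- function(x, what) {
  if (!is_string(x) || !nzchar(x)) {
    abort(sprintf("`%s` must be a non-empty string.", what))
  }
  invisible(x)
}

#' Read and write JSON-lines files
#'
#' One JSON object per line, UTF-8. Used for corpora, gold labels, extraction
#' results and store collections.
#'
#' @param x A list of records (each a named list).
#' @param path File path.
#' @return `read_jsonl()` returns a list of named lists; `write_jsonl()`
#'   returns `path` invisibly.
#' @export
write_jsonl <- function(x, path) {
  lines <- vapply(x, function(rec) {
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                  digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
}

# Parse a line tolerantly; returns NULL on malformed JSON.
parse_jsonl_line <- function(line) {
  tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
           error = function(e) NULL)
}

# English number words 0-20 plus tens; extraction normalises these to digits.
number_words <- function() {
  c(zero = 0, one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
    seven = 7, eight = 8, nine = 9, ten = 10, eleven = 11, twelve = 12,
    thirteen = 13, fourteen = 14, fifteen = 15, sixteen = 16, seventeen = 17,
    eighteen = 18, nineteen = 19, twenty = 20, thirty = 30, forty = 40,
    fifty = 50, sixty = 60, seventy = 70, eighty = 80, ninety = 90)
}

parse_number_token <- function(tok) {
  tok <- tolower(trimws(tok))
  if (grepl("^-?[0-9]+$", tok)) return(as.integer(tok))
  nw <- number_words()
  if (tok %in% names(nw)) return(as.integer(nw[[tok]]))
  NA_integer_
}

number_to_word <- function(n) {
  nw <- number_words()
  hit <- names(nw)[match(n, nw)]
  if (is.na(hit)) as.character(n) else hit
}

# Regex-escape a literal term.
regex_escape <- function(x) {
  gsub("([.\\\\+*?\\[\\]^$(){}=!<>|:#-])", "\\\\\\1", x, perl = TRUE)
}
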