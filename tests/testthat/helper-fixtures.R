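# Shared fixtures for the test suite. Everything is built in code; nothing
# is read from outside the package.

toy_story <- function(id = "S1", title = "Local news update",
                      body = "Body text.", pub = "2018-04-02 08:00:00",
                      url = paste0("https://example.org/", id),
                      source_name = "Test Outlet",
                      source_province = NULL, source_prefecture = NULL) {
  media_story(story_id = id, title = title, body = body,
              publication_datetime = pub, source_name = source_name,
              url = url, source_province = source_province,
              source_prefecture = source_prefecture)
}

toy_gazetteer_file <- function(provinces) {
  # provinces: named list province -> character vector of prefectures
  path <- tempfile(fileext = ".json")
  payload <- list(provinces = purrr::imap(provinces, function(prefs, nm) {
    list(name = nm, code = "00", prefectures = as.list(prefs))
  }))
  names(payload$provinces) <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  path
}

toy_dictionary_file <- function(chapters) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(chapters, path, auto_unbox = TRUE)
  path
}

full_chapters <- function() {
  list(child = list("child", "boy"), product = list("magnet", "kettle"),
       injury = list("injured", "burn"),
       environment = list("home"), activity = list("playing"),
       other = list("recall"))
}

# Small eligible/ineligible corpus with known structure.
small_bundle <- function(n = 60, seed = 42, noise = 0, ...) {
  generate_corpus(scenario_config(n_stories = n, eligible_fraction = 0.5,
                                  seed = seed, noise = noise, ...))
}

eligible_split <- function(bundle) {
  elig <- vapply(bundle$labels, function(l) l$eligible, logical(1))
  list(stories = bundle$stories[elig], labels = bundle$labels[elig])
}
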