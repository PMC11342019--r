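patterns <- default_extraction_patterns()
gaz <- load_gazetteer()

test_that("numeric regex extraction normalises number words and ages", {
  txt <- "Altogether three people were injured. Three children were injured, one died."
  expect_equal(extract_numeric_regex(txt, "injured_children", patterns), 3L)
  expect_equal(extract_numeric_regex(txt, "child_deaths", patterns), 1L)
  expect_equal(extract_numeric_regex(txt, "injured_total", patterns), 3L)
  expect_equal(extract_numeric_regex("a 5-year-old boy fell", "child_age",
                                     patterns), 5L)
  expect_null(extract_numeric_regex("no numeric phrase here", "child_age",
                                    patterns))
  expect_error(extract_numeric_regex(txt, "product_name", patterns),
               "numeric")
})

test_that("entity extraction resolves dates by precision and places by level", {
  pref <- gaz$prefectures$name[1]
  prov <- gaz$prefectures$province[1]
  rec <- extract_entities(sprintf(
    "On 14 September 2015 in %s, %s, a child was hurt.", pref, prov), gaz)
  expect_equal(rec$event_date, "2015-09-14")
  expect_equal(rec$event_location$province, prov)
  expect_equal(rec$event_location$prefecture, pref)

  rec <- extract_entities(sprintf("It happened in %s in June 2019.", prov),
                          gaz)
  expect_equal(rec$event_date, "2019-06")
  expect_equal(rec$event_location$province, prov)
  expect_null(rec$event_location$prefecture)

  rec <- extract_entities("The event took place in 2015.", gaz)
  expect_equal(rec$event_date, "2015")

  rec <- extract_entities("No date and no place.", gaz)
  expect_null(rec$event_date)
  expect_null(rec$event_location)
})

test_that("keyword+relation extraction needs the relation, not the keyword", {
  txt <- "the boy swallowed magnetic beads"
  expect_equal(extract_keyword_dependency(txt, "product_name", patterns),
               "magnetic beads")
  expect_equal(extract_keyword_dependency(txt, "external_cause", patterns),
               "foreign-body ingestion")
  # bare keyword presence without the injury relation does not fire
  ad <- "magnetic beads were on sale this week"
  expect_null(extract_keyword_dependency(ad, "product_name", patterns))
  expect_null(extract_keyword_dependency(ad, "external_cause", patterns))
  # supervisor relation and presence from one clause
  sup <- "his mother was in another room"
  expect_equal(extract_keyword_dependency(sup, "supervisor_relation",
                                          patterns), "mother")
  expect_false(extract_keyword_dependency(sup, "supervisor_present",
                                          patterns))
})

test_that("conflicts resolve by routing priority and are recorded", {
  routing <- default_strategy_routing()
  r <- resolve_strategy_conflicts(list(regex = 3L), routing, "deaths_total")
  expect_equal(r$value, 3L)
  expect_null(r$conflict)
  r <- resolve_strategy_conflicts(list(regex = 3L, keyword_dependency = 2L),
                                  routing, "deaths_total")
  expect_equal(r$value, 3L)
  expect_equal(r$conflict$field, "deaths_total")
  r <- resolve_strategy_conflicts(list(), routing, "deaths_total")
  expect_null(r$value)
  # agreement is not a conflict
  r <- resolve_strategy_conflicts(list(regex = 2L, keyword_dependency = 2L),
                                  routing, "deaths_total")
  expect_null(r$conflict)
})

test_that("full-record extraction recovers a noise-free gold record", {
  b <- small_bundle(n = 30, seed = 61)
  es <- eligible_split(b)
  res <- extract_corpus(es$stories)
  for (i in seq_along(res)) {
    gold <- es$labels[[i]]$gold_record
    rec <- res[[i]]$record
    for (f in names(gold)) {
      expect_true(injurywatch:::values_match_gold(f, rec[[f]], gold[[f]]),
                  label = sprintf("story %s field %s", res[[i]]$story_id, f))
    }
  }
})

test_that("extraction is deterministic and fails soft on empty text", {
  b <- small_bundle(n = 10, seed = 4)
  s <- eligible_split(b)$stories[[1]]
  r1 <- extract_record(s, patterns = patterns, gaz = gaz)
  r2 <- extract_record(s, patterns = patterns, gaz = gaz)
  expect_identical(r1, r2)
  empty <- toy_story("E", body = " ")
  r <- extract_record(empty, patterns = patterns, gaz = gaz)
  expect_length(names(r$record), 0)
  expect_length(r$conflicts, 0)
})

test_that("contradictory strategy outputs populate the conflict log", {
  s <- toy_story("C", body = paste(
    "The injury event occurred on 14 September 2015.",
    "Records filed list 2015-09-20 as the processing date."))
  r <- extract_record(s, patterns = patterns, gaz = gaz)
  expect_equal(r$record$event_date, "2015-09-20")  # regex outranks entity
  expect_length(r$conflicts, 1)
  expect_equal(r$conflicts[[1]]$field, "event_date")
  expect_equal(r$provenance$event_date$strategy, "regex")
})

test_that("provenance covers every extracted field and honours routing", {
  b <- small_bundle(n = 40, seed = 19)
  es <- eligible_split(b)
  routing <- default_strategy_routing()
  res <- extract_corpus(es$stories)
  for (r in res) {
    expect_setequal(names(r$provenance), names(r$record))
    for (f in names(r$provenance)) {
      expect_true(r$provenance[[f]]$strategy %in% routing[[f]],
                  label = sprintf("field %s via %s", f,
                                  r$provenance[[f]]$strategy))
    }
  }
})

test_that("disabling a strategy in the routing silences its fields", {
  b <- small_bundle(n = 20, seed = 37)
  es <- eligible_split(b)
  routing <- default_strategy_routing()
  routing$event_location <- character(0)       # disable all strategies
  routing$child_age <- "keyword_dependency"    # no kd rule exists for age
  res <- lapply(es$stories, extract_record, routing = routing,
                patterns = patterns, gaz = gaz)
  for (r in res) {
    expect_false(record_has(r$record, "event_location"))
    expect_false(record_has(r$record, "child_age"))
  }
})

test_that("per-field accuracy degrades monotonically over a noise grid", {
  grid <- c(0, 0.1, 0.2, 0.4)
  acc <- vapply(grid, function(noise) {
    b <- generate_corpus(scenario_config(n_stories = 120,
                                         eligible_fraction = 0.5,
                                         seed = 29, noise = noise))
    es <- eligible_split(b)
    res <- extract_corpus(es$stories)
    tab <- evaluation_table(res, es$labels, basis = "including")
    mean(tab$accuracy, na.rm = TRUE)
  }, numeric(1))
  expect_equal(acc[1], 100)
  expect_true(all(diff(acc) <= 0))
})
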