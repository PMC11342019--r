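gaz <- load_gazetteer()

rec_at <- function(prov, pref = NULL, date = "2018-05-01",
                   product = "magnetic beads") {
  structured_record(event_location = c(list(province = prov),
                                       if (!is.null(pref))
                                         list(prefecture = pref)),
                    event_date = date, product_name = product)
}

test_that("coverage counts distinct gazetteer units and rounds half-up", {
  prefs <- gaz$prefectures
  records <- lapply(prefs$name[1:311], function(p)
    rec_at(gazetteer_province_of(gaz, p), p))
  cov <- geographic_coverage(records, gaz, level = "prefecture")
  expect_equal(cov$covered, 311)
  expect_equal(cov$total, 333)
  expect_equal(cov$percent, 93.39)
  cov324 <- geographic_coverage(
    lapply(prefs$name[1:324], function(p)
      rec_at(gazetteer_province_of(gaz, p), p)),
    gaz, level = "prefecture")
  expect_equal(cov324$percent, 97.30)
  expect_equal(geographic_coverage(list(), gaz,
                                   level = "prefecture")$percent, 0)
})

test_that("unknown locations count as uncovered and are reported", {
  records <- list(rec_at("Nowhere Province", "Ghost Town"),
                  rec_at(gaz$prefectures$province[1],
                         gaz$prefectures$name[1]))
  cov <- geographic_coverage(records, gaz, level = "prefecture")
  expect_equal(cov$covered, 1)
  expect_true("Ghost Town" %in% cov$unknown)
})

test_that("coverage is monotone non-decreasing as records are added", {
  prefs <- gaz$prefectures$name
  withr::with_seed(10, {
    pool <- sample(prefs, 60, replace = TRUE)
  })
  pcts <- vapply(c(10, 30, 60), function(k) {
    recs <- lapply(pool[1:k], function(p)
      rec_at(gazetteer_province_of(gaz, p), p))
    geographic_coverage(recs, gaz, level = "prefecture")$percent
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("source-location coverage reads story metadata", {
  b <- small_bundle(n = 40, seed = 41)
  cov <- geographic_coverage(b$stories, gaz, level = "province",
                             basis = "media_source_location")
  expect_gt(cov$covered, 0)
  expect_equal(cov$total, 31)
})

test_that("location reporting share matches direct arithmetic", {
  recs <- list(rec_at("Hunan"), structured_record(child_age = 1),
               structured_record(child_age = 2))
  expect_equal(location_reporting_share(recs), 33.33)
  expect_equal(location_reporting_share(list(rec_at("Hunan"))), 100)
  # the published aggregate: 30 538 located of 35 275 stories
  expect_equal(round_half_up(100 * 30538 / 35275, 2), 86.57)
  expect_error(location_reporting_share(list()), "non-empty")
})

test_that("keyword frequencies match a hand-counted toy corpus", {
  dict <- load_keyword_dictionary(toy_dictionary_file(full_chapters()))
  stories <- list(
    toy_story("A", body = "A boy and a boy saw a magnet. The magnet hurt."),
    toy_story("B", body = "The kettle burn injured the boy."),
    toy_story("C", body = "Nothing here."))
  freq <- keyword_frequencies(stories, dict, scope = "body", top_k = 100)
  expect_equal(freq$term[1], "boy")       # 3 occurrences
  expect_equal(freq$count[1], 3)
  expect_equal(freq$count[freq$term == "magnet"], 2)
  expect_equal(freq$count[freq$term == "kettle"], 1)
  # ties break lexicographically; truncation at top_k
  expect_equal(keyword_frequencies(stories, dict, top_k = 0)$term,
               character(0))
  one <- keyword_frequencies(list(toy_story("D", body = "a magnet")),
                             dict, top_k = 5)
  expect_equal(one$term, "magnet")
  expect_equal(one$count, 1)
})

test_that("first-signal detection recovers an injected emergence exactly", {
  ev <- list(product = "magnetic beads", first_date = "2015-09-14",
             burst_size = 10, burst_window_days = 61)
  b <- generate_corpus(scenario_config(n_stories = 100, seed = 3,
                                       emergence_events = list(ev)))
  sig <- detect_first_signal(b$labels, "magnetic beads", k = 10, w = 61)
  expect_equal(sig$first_detection_date, as.Date("2015-09-14"))
  expect_true(sig$confirmed)
  expect_gte(sig$confirming_case_count, 10)
})

test_that("signal confirmation tracks the threshold and empty inputs", {
  recs <- list(rec_at("Hunan", date = "2019-01-01"))
  sig <- detect_first_signal(recs, "magnetic beads", k = 10, w = 61)
  expect_equal(sig$first_detection_date, as.Date("2019-01-01"))
  expect_false(sig$confirmed)
  none <- detect_first_signal(recs, "hoverboard", k = 1, w = 30)
  expect_true(is.na(none$first_detection_date))
  expect_false(none$confirmed)
})

test_that("signal recovery holds over randomised emergence scenarios", {
  withr::with_seed(202, {
    scenarios <- lapply(1:20, function(i) {
      list(product = sprintf("novelty gadget %02d", i),
           first_date = format(as.Date("2012-01-01") +
                                 sample.int(3000, 1)),
           burst_size = sample(0:15, 1), burst_window_days = 61)
    })
  })
  for (ev in scenarios) {
    b <- generate_corpus(scenario_config(
      n_stories = 30, seed = 71 + ev$burst_size,
      emergence_events = list(ev)))
    sig <- detect_first_signal(b$labels, ev$product, k = 10, w = 61)
    expect_equal(sig$first_detection_date, as.Date(ev$first_date))
    expect_equal(sig$confirmed, ev$burst_size >= 10,
                 label = sprintf("burst %d", ev$burst_size))
  }
})

test_that("lead times reproduce calendar arithmetic and antisymmetry", {
  sig <- detect_first_signal(list(rec_at("Hunan", date = "2015-09-14")),
                             "magnetic beads", k = 1, w = 61)
  sig <- lead_time(sig, list(literature = "2016-11-25",
                             recall = "2020-12-18",
                             same_day = "2015-09-14"))
  expect_equal(sig$lead_time_days$recall, 1922L)
  expect_equal(sig$lead_time_days$same_day, 0L)
  sig2 <- detect_first_signal(list(rec_at("Hunan", date = "2016-07-03",
                                          product = "electric balance scooter")),
                              "balance scooter", k = 1, w = 61)
  sig2 <- lead_time(sig2, list(recall = "2019-08-02"))
  expect_equal(sig2$lead_time_days$recall, 1125L)
  # antisymmetry under swapping the two dates
  swapped <- detect_first_signal(list(rec_at("Hunan", date = "2019-08-02",
                                             product = "electric balance scooter")),
                                 "balance scooter", k = 1, w = 61)
  swapped <- lead_time(swapped, list(recall = "2016-07-03"))
  expect_equal(swapped$lead_time_days$recall, -1125L)
  none <- detect_first_signal(list(), "x", k = 1, w = 1)
  expect_error(lead_time(none, list(a = "2020-01-01")), "no first detection")
})

test_that("trend series conserve counts and zero-fill contiguous bins", {
  recs <- c(
    lapply(1:3, function(i) rec_at("Hunan", date = "2018-05-10")),
    list(rec_at("Hunan", date = "2018-07-02")))
  tr <- build_trend_series(recs, group_by = "product_name", bin = "month")
  expect_equal(sum(tr$count), 4)
  expect_equal(tr$bin, c("2018-05", "2018-06", "2018-07"))
  expect_equal(tr$count, c(3L, 0L, 1L))
  tr_y <- build_trend_series(c(recs, list(rec_at("Hunan",
                                                 date = "2019-01-01"))),
                             group_by = "event_province", bin = "year")
  expect_equal(sum(tr_y$count), 5)
  expect_equal(tr_y$bin, c("2018", "2019"))
})

test_that("a hand-built 12-record fixture tallies correctly by group", {
  recs <- c(
    lapply(1:5, function(i) rec_at("Hunan", date = "2020-01-15",
                                   product = "crib")),
    lapply(1:4, function(i) rec_at("Hebei", date = "2020-02-10",
                                   product = "crib")),
    lapply(1:3, function(i) rec_at("Hunan", date = "2020-02-20",
                                   product = "stroller")))
  tr <- build_trend_series(recs, group_by = "event_province", bin = "month")
  expect_equal(tr$count[tr$group == "Hunan" & tr$bin == "2020-01"], 5L)
  expect_equal(tr$count[tr$group == "Hunan" & tr$bin == "2020-02"], 3L)
  expect_equal(tr$count[tr$group == "Hebei" & tr$bin == "2020-02"], 4L)
  expect_equal(tr$count[tr$group == "Hebei" & tr$bin == "2020-01"], 0L)
  expect_equal(sum(tr$count), 12)
})
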