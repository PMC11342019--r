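dict <- load_keyword_dictionary(toy_dictionary_file(full_chapters()))

test_that("candidate rule requires a term from each defining chapter", {
  hit <- toy_story("S1", body = "A boy was injured by a magnet at home.")
  miss1 <- toy_story("S2", body = "A magnet was on sale.")     # no child/injury
  miss2 <- toy_story("S3", body = "Nothing relevant here at all.")
  partial <- toy_story("S4", body = "A boy was injured while running.") # no product
  ids <- keyword_candidate_search(list(hit, miss1, miss2, partial), dict)
  expect_equal(ids, "S1")
})

test_that("a hand-enumerated toy corpus returns exactly its candidates", {
  mk <- function(id, body, pub) toy_story(id, body = body, pub = pub)
  stories <- list(
    mk("A", "The boy was injured by a kettle burn.", "2015-03-01"),
    mk("B", "A child swallowed a magnet and was injured.", "2014-01-01"),
    mk("C", "Kettle discount this weekend.", "2015-05-01"),
    mk("D", "A boy burned his hand, no product involved.", "2015-06-01"),
    mk("E", "A magnet injured a child at the park.", "2013-08-09"),
    mk("F", "Stock market news.", "2016-01-01"),
    mk("G", "Injured worker sues kettle factory.", "2015-02-01"), # no child
    mk("H", "Child plays with magnet happily.", "2015-04-01"),    # no injury
    mk("I", "A burn injury: a child and a faulty kettle.", "2012-01-01"),
    mk("J", "Weather report.", "2015-07-01"))
  ids <- keyword_candidate_search(stories, dict)
  # exactly the four satisfying stories, ordered by publication then id
  expect_equal(ids, c("I", "E", "B", "A"))
})

test_that("eligibility filter passes a well-formed story and names failures", {
  gaz <- load_gazetteer()
  ok <- toy_story("S1",
    body = "A young boy was injured by a magnet at home in Hunan.")
  res <- apply_eligibility_filter(ok, dict = dict, gaz = gaz)
  expect_true(res$eligible)
  expect_length(res$reasons, 0)

  fictional <- toy_story("S2",
    body = "In the movie a boy is injured by a magnet.")
  res <- apply_eligibility_filter(fictional, dict = dict, gaz = gaz)
  expect_false(res$eligible)
  expect_true("fictional" %in% res$reasons)

  old <- toy_story("S3", body = "A boy was injured by a magnet.",
                   pub = "2008-05-01 10:00:00")
  res <- apply_eligibility_filter(old, dict = dict, gaz = gaz)
  expect_false(res$eligible)
  expect_true("pre_start_date" %in% res$reasons)

  adult <- toy_story("S4", body = "A man was injured by a magnet.")
  res <- apply_eligibility_filter(adult, dict = dict, gaz = gaz)
  expect_true("no_child" %in% res$reasons)

  legal <- toy_story("S5",
    body = "The lawsuit over the boy injured by a magnet continues.")
  res <- apply_eligibility_filter(legal, dict = dict, gaz = gaz)
  expect_true("topical" %in% res$reasons)
})

test_that("extraction hints sharpen the child and jurisdiction rules", {
  gaz <- load_gazetteer()
  s <- toy_story("S1", body = "A young boy was injured by a magnet.")
  hints_adult <- structured_record(child_age = 35)
  res <- apply_eligibility_filter(s, hints = hints_adult, dict = dict,
                                  gaz = gaz)
  expect_true("no_child" %in% res$reasons)
  hints_abroad <- structured_record(
    event_location = list(province = "Atlantis"))
  res <- apply_eligibility_filter(s, hints = hints_abroad, dict = dict,
                                  gaz = gaz)
  expect_true("outside_jurisdiction" %in% res$reasons)
})

test_that("filter is monotone: removing a failure trigger never hurts", {
  gaz <- load_gazetteer()
  # build stories from subsets of failure triggers; eligibility must be
  # monotone non-increasing in the trigger set
  base <- "A young boy was injured by a magnet at home."
  triggers <- list(
    fictional = "It happened in a movie.",
    topical = "A lawsuit followed.")
  subsets <- expand.grid(f = c(FALSE, TRUE), t = c(FALSE, TRUE))
  for (i in seq_len(nrow(subsets))) {
    for (j in seq_len(nrow(subsets))) {
      # j's trigger set contained in i's
      if (all(!(unlist(subsets[j, ]) & !unlist(subsets[i, ])))) {
        body_i <- paste(c(base, unlist(triggers)[unlist(subsets[i, ])]),
                        collapse = " ")
        body_j <- paste(c(base, unlist(triggers)[unlist(subsets[j, ])]),
                        collapse = " ")
        ei <- apply_eligibility_filter(toy_story("X", body = body_i),
                                       dict = dict, gaz = gaz)$eligible
        ej <- apply_eligibility_filter(toy_story("X", body = body_j),
                                       dict = dict, gaz = gaz)$eligible
        expect_true(ej >= ei)
      }
    }
  }
})

test_that("candidate search recall is total on clean synthetic corpora", {
  b <- small_bundle(n = 120, seed = 55)
  ids <- keyword_candidate_search(b$stories, load_keyword_dictionary())
  elig_ids <- vapply(Filter(function(l) l$eligible, b$labels), `[[`,
                     character(1), "story_id")
  expect_true(all(elig_ids %in% ids))
})

test_that("exact URL duplicates collapse to the earliest story", {
  a <- toy_story("A", body = "Same story.", pub = "2015-01-02",
                 url = "https://x/1")
  b <- toy_story("B", body = "Same story.", pub = "2015-01-01",
                 url = "https://x/1")
  r <- deduplicate_stories(list(a, b))
  expect_length(r$kept, 1)
  expect_equal(r$kept[[1]]$story_id, "B")
  expect_equal(r$clusters, list(c("A", "B")))
})

test_that("near-duplicates cluster on title equality and body similarity", {
  body <- paste(rep("a boy was injured by a kettle at home today", 4),
                collapse = " ")
  a <- toy_story("A", title = "Boy injured", body = body,
                 pub = "2015-01-05", url = "https://x/a")
  b <- toy_story("B", title = "Boy Injured!", body = body,
                 pub = "2015-01-03", url = "https://y/b")
  c <- toy_story("C", title = "Boy injured",
                 body = "completely different text about something else",
                 pub = "2015-01-04", url = "https://z/c")
  r <- deduplicate_stories(list(a, b, c))
  expect_length(r$kept, 2)
  expect_true("B" %in% vapply(r$kept, `[[`, character(1), "story_id"))
  expect_equal(r$clusters, list(c("A", "B")))
})

test_that("dedup is the identity on a distinct corpus and idempotent", {
  b <- small_bundle(n = 30, seed = 77)
  # make the stories fully distinct by heavily id-stamping the bodies
  stories <- lapply(b$stories, function(s) {
    s$body <- paste(s$body,
                    paste(rep(paste("ref", s$story_id), 20), collapse = " "))
    s
  })
  r1 <- deduplicate_stories(stories)
  expect_length(r1$kept, length(stories))
  expect_length(r1$clusters, 0)
  r2 <- deduplicate_stories(r1$kept)
  expect_identical(lapply(r2$kept, unclass), lapply(r1$kept, unclass))
})

test_that("dedup is idempotent on randomised corpora with planted dups", {
  for (seed in 1:3) {
    b <- small_bundle(n = 40, seed = seed)
    stories <- b$stories
    dup_idx <- withr::with_seed(seed, sample(length(stories), 5))
    extra <- lapply(seq_along(dup_idx), function(k) {
      s <- stories[[dup_idx[k]]]
      s$story_id <- paste0("DUP", k)
      s  # same URL: exact duplicate
    })
    all_stories <- c(stories, extra)
    r1 <- deduplicate_stories(all_stories)
    r2 <- deduplicate_stories(r1$kept)
    expect_identical(lapply(r2$kept, unclass), lapply(r1$kept, unclass))
    expect_length(r2$clusters, 0)
  }
})
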