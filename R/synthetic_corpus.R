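#' Default per-field presence rates
#'
#' Probability that an eligible story states each leaf field. The defaults
#' follow the published per-variable inclusion counts of a manual validation
#' of 1000 product-related child-injury stories (shipped as
#' `reference_extraction_performance.csv`): rate = stories including the
#' variable / 1000, with 0 for the five variables that none of the evaluated
#' stories mentioned.
#'
#' @return A named numeric vector over the 34 leaf fields.
#' @export
default_presence_rates <- function() {
  ref <- load_reference_evaluation()
  lf <- leaf_fields()
  rate <- ref$n_including[match(lf$id, ref$variable_id)] / 1000
  rate[is.na(rate)] <- 0
  stats::setNames(rate, lf$field)
}

#' Scenario configuration for the synthetic corpus generator
#'
#' Describes the study conditions a generated corpus emulates: corpus size,
#' eligible share, per-field presence rates, geographic mixture over
#' provinces, date range (stories from 2010 onwards), the product catalog,
#' optional product-emergence events, the distractor-phrasing noise level
#' and the seed.
#'
#' @param n_stories Number of stories.
#' @param eligible_fraction Share of eligible stories; the eligible count is
#'   allocated exactly as `round(n_stories * eligible_fraction)` and then
#'   shuffled, so counts are deterministic.
#' @param presence_rates Named probability vector over leaf fields; see
#'   [default_presence_rates()].
#' @param geo_weights Named non-negative weights over gazetteer provinces;
#'   default is proportional to 1 + the province's prefecture count.
#' @param date_range Character or Date length-2; start must be on or after
#'   2010-01-01.
#' @param product_catalog Tibble `name`, `type`; see
#'   [default_product_catalog()].
#' @param emergence_events List of
#'   `list(product, type, first_date, burst_size, burst_window_days)`
#'   describing a product whose first story appears at a set date followed
#'   by a burst of cases. Emergence products are withheld from the base
#'   corpus so that the injected story is genuinely the first.
#' @param noise Probability, per story and field, that the field's
#'   realisation is replaced by distractor phrasing the pattern rules cannot
#'   match. Corruption draws are coupled across noise levels (same seed
#'   implies nested corruption sets), so extraction accuracy is monotone in
#'   `noise`.
#' @param seed Integer seed; identical configs generate byte-identical
#'   corpora.
#' @param child_age_range Inclusive child age range in years.
#' @param gazetteer Optional [load_gazetteer()] object (default shipped
#'   file).
#' @param language_pack Optional [default_language_pack()] object.
#' @return A validated `scenario_config` object.
#' @export
scenario_config <- function(n_stories = 200, eligible_fraction = 0.5,
                            presence_rates = default_presence_rates(),
                            geo_weights = NULL,
                            date_range = c("2010-01-01", "2023-12-31"),
                            product_catalog = default_product_catalog(),
                            emergence_events = list(),
                            noise = 0, seed = 1L,
                            child_age_range = c(0, 17),
                            gazetteer = NULL, language_pack = NULL) {
  cfg <- structure(list(
    n_stories = as.integer(n_stories),
    eligible_fraction = eligible_fraction,
    presence_rates = presence_rates,
    geo_weights = geo_weights,
    date_range = as.character(as.Date(date_range)),
    product_catalog = product_catalog,
    emergence_events = emergence_events,
    noise = noise, seed = as.integer(seed),
    child_age_range = child_age_range,
    gazetteer = gazetteer, language_pack = language_pack
  ), class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  if (is.na(cfg$n_stories) || cfg$n_stories < 0) {
    abort("`n_stories` must be a non-negative count.")
  }
  if (cfg$eligible_fraction < 0 || cfg$eligible_fraction > 1) {
    abort("`eligible_fraction` must lie in [0, 1].")
  }
  if (any(cfg$presence_rates < 0 | cfg$presence_rates > 1)) {
    abort("`presence_rates` must lie in [0, 1].")
  }
  miss <- setdiff(leaf_field_names(), names(cfg$presence_rates))
  if (length(miss)) {
    abort(sprintf("`presence_rates` missing field(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (cfg$noise < 0 || cfg$noise > 1) abort("`noise` must lie in [0, 1].")
  dr <- as.Date(cfg$date_range)
  if (dr[1] > dr[2]) abort("`date_range` must be ordered.")
  if (dr[1] < as.Date("2010-01-01")) {
    abort("`date_range` must start on or after 2010-01-01.")
  }
  for (ev in cfg$emergence_events) {
    if ((ev$burst_size %||% 0) < 0) abort("`burst_size` must be >= 0.")
  }
  invisible(cfg)
}

# Fields whose generated numbers may be rendered as number words.
.word_renderable <- c("deaths_total", "injured_total", "child_deaths",
                      "injured_children", "product_count",
                      "children_involved", "supervisor_count", "child_age")

# Draw the full latent plan for one eligible story. RNG consumption is
# fixed (all latent values drawn before presence masking) so that plans are
# reproducible and independent of the noise level.
make_eligible_plan <- function(cfg, gaz, pack, catalog, presence,
                               fixed_product = NULL, fixed_event_date = NULL) {
  cb <- pack$codebook
  prod_i <- sample.int(nrow(catalog), 1)
  product <- fixed_product %||% catalog$name[prod_i]
  ptype <- catalog$type[match(product, catalog$name)]
  provs <- gaz$provinces$name
  w <- cfg$geo_weights
  if (is.null(w)) {
    npref <- vapply(provs, function(p) sum(gaz$prefectures$province == p),
                    integer(1))
    w <- npref + 1
  } else {
    w <- w[provs]
    w[is.na(w)] <- 0
  }
  prov <- sample(provs, 1, prob = w)
  prefs <- gaz$prefectures$name[gaz$prefectures$province == prov]
  pref <- if (length(prefs)) sample(prefs, 1) else NULL
  dr <- as.Date(cfg$date_range)
  d <- dr[1] + sample.int(as.integer(dr[2] - dr[1]) + 1L, 1L) - 1L
  prec <- sample(c("day", "month", "year"), 1, prob = c(0.8, 0.1, 0.1))
  if (!is.null(fixed_event_date)) {
    d <- as.Date(fixed_event_date)
    prec <- "day"
  }
  event_date <- switch(prec, day = format(d, "%Y-%m-%d"),
                       month = format(d, "%Y-%m"), year = format(d, "%Y"))
  u <- runif(length(leaf_field_names()))
  present <- stats::setNames(u < presence[leaf_field_names()],
                             leaf_field_names())
  deaths <- sample(1:3, 1)
  child_deaths <- sample.int(deaths, 1)
  injured <- sample(1:6, 1)
  injured_children <- sample.int(injured, 1)
  age_lo <- max(1L, cfg$child_age_range[1])
  vals <- list(
    event_date = event_date,
    event_location = c(list(province = prov),
                       if (!is.null(pref)) list(prefecture = pref)),
    place_type = sample(cb$place_type, 1),
    injury_nature = sample(cb$injury_nature, 1),
    body_part = sample(cb$body_part, 1),
    external_cause = cb$external_cause$category[
      sample.int(nrow(cb$external_cause), 1)],
    clinical_diagnosis = sample(cb$clinical_diagnosis, 1),
    deaths_total = deaths,
    injured_total = injured,
    child_deaths = child_deaths,
    injured_children = injured_children,
    product_count = sample(1:5, 1),
    product_name = product,
    product_brand = sample(cb$product_brand, 1),
    product_characteristics = sample(cb$product_characteristics, 1),
    product_type = ptype,
    disposition = sample(cb$disposition, 1),
    children_involved = sample(1:4, 1),
    child_age = sample(age_lo:cfg$child_age_range[2], 1),
    child_sex = sample(unname(cb$child_sex), 1),
    supervisor_count = sample(1:3, 1),
    supervisor_age = sample(22:70, 1),
    supervisor_sex = sample(unname(cb$supervisor_sex), 1),
    supervisor_relation = sample(cb$supervisor_relation, 1),
    supervisor_present = unname(sample(cb$supervisor_present, 1)),
    etiology_human = sample(cb$etiology_human, 1),
    etiology_product = sample(cb$etiology_product, 1),
    etiology_detail = sample(cb$etiology_detail, 1),
    weather = sample(cb$weather, 1),
    air_quality = sample(cb$air_quality, 1),
    temperature = sprintf("%d degrees Celsius", sample(-10:38, 1)),
    other_environment = sample(cb$other_environment, 1),
    preventive_measure = sample(cb$preventive_measure, 1)
  )
  as_word <- stats::setNames(runif(length(.word_renderable)) < 0.5,
                             .word_renderable)
  gold <- structured_record(vals[names(present)[present]])
  pub_lag <- sample(0:3, 1)
  pub_date <- min(max(d + pub_lag, dr[1]), dr[2] + 3)
  pub_time <- sprintf("%02d:%02d:%02d", sample(0:23, 1), sample(0:59, 1),
                      sample(0:59, 1))
  src <- make_source(gaz, prov)
  list(kind = "eligible", gold = gold, values = vals, present = present,
       as_word = as_word, product = product,
       publication_datetime = paste(format(pub_date), pub_time), source = src)
}

make_source <- function(gaz, event_prov = NULL) {
  kinds <- c("news_website", "social_media_account")
  kind <- sample(kinds, 1, prob = c(0.7, 0.3))
  outlets <- c("Fast News", "Provincial Daily", "City Evening Post",
               "Metro Channel", "Safety Watch Account", "Parent Voice")
  prov <- if (!is.null(event_prov) && runif(1) < 0.8) event_prov else
    sample(gaz$provinces$name, 1)
  prefs <- gaz$prefectures$name[gaz$prefectures$province == prov]
  pref <- if (length(prefs)) sample(prefs, 1) else NULL
  list(name = paste(prov, sample(outlets, 1)), kind = kind,
       province = prov, prefecture = pref)
}

make_distractor_plan <- function(cfg, gaz, pack, catalog) {
  cb <- pack$codebook
  type <- sample(c("fictional", "adult_injury", "product_ad",
                   "legal_commentary"), 1)
  product <- catalog$name[sample.int(nrow(catalog), 1)]
  place <- sample(cb$place_type, 1)
  adult_age <- sample(25:60, 1)
  marker <- switch(type,
    fictional = sample(pack$fiction_markers[c(1, 2)], 1),
    legal_commentary = sample(c("lawsuit", "court"), 1),
    NA_character_)
  dr <- as.Date(cfg$date_range)
  pub_date <- dr[1] + sample.int(as.integer(dr[2] - dr[1]) + 1L, 1L) - 1L
  pub_time <- sprintf("%02d:%02d:%02d", sample(0:23, 1), sample(0:59, 1),
                      sample(0:59, 1))
  src <- make_source(gaz)
  list(kind = type, product = product, place = place, adult_age = adult_age,
       marker = marker, publication_datetime = paste(format(pub_date), pub_time),
       source = src)
}

an_article <- function(x) {
  if (grepl("^[aeiou]", tolower(x))) paste("an", x) else paste("a", x)
}

render_num <- function(n, as_word) {
  if (isTRUE(as_word) && n >= 0 && n <= 20) number_to_word(n) else
    as.character(n)
}

cap1 <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

date_sentence <- function(iso, pack) {
  switch(event_date_precision(iso),
    day = {
      d <- as.Date(iso)
      sprintf("The injury event occurred on %d %s %d.",
              as.integer(format(d, "%d")),
              pack$months[as.integer(format(d, "%m"))],
              as.integer(format(d, "%Y")))
    },
    month = {
      y <- as.integer(substr(iso, 1, 4)); m <- as.integer(substr(iso, 6, 7))
      sprintf("The injury event occurred in %s %d.", pack$months[m], y)
    },
    year = sprintf("The injury event occurred in %s.", iso))
}

# Assemble the text of one eligible story from its plan; `corrupt` marks
# fields whose realisation is suppressed (distractor phrasing).
build_eligible_text <- function(plan, corrupt, pack, cause_table) {
  v <- plan$values
  show <- function(f) isTRUE(plan$present[[f]]) && !isTRUE(corrupt[[f]])
  num <- function(f) render_num(v[[f]], plan$as_word[[f]])
  s <- character(0)
  if (show("event_date")) s <- c(s, date_sentence(v$event_date, pack))
  if (show("event_location")) {
    loc <- v$event_location
    s <- c(s, if (!is.null(loc$prefecture)) {
      sprintf("It happened in %s, %s.", loc$prefecture, loc$province)
    } else sprintf("It happened in %s.", loc$province))
  }
  subject <- paste0("The ",
    if (show("child_age")) paste0(num("child_age"), "-year-old ")
    else if (show("child_sex")) "young ",
    if (show("child_sex")) names(pack$codebook$child_sex)[
      match(v$child_sex, pack$codebook$child_sex)] else "child")
  verb <- if (show("external_cause")) {
    cause_table$verb[match(v$external_cause, cause_table$category)]
  } else "was injured by"
  object <- if (show("product_name")) paste("the", v$product_name) else
    "a household product"
  s <- c(s, paste0(subject, " ", verb, " ", object, "."))
  if (show("place_type")) {
    s <- c(s, sprintf("The incident took place at the %s.", v$place_type))
  }
  if (show("injury_nature")) {
    s <- c(s, sprintf("The child suffered %s.", an_article(v$injury_nature)))
  }
  if (show("body_part")) {
    s <- c(s, sprintf("The injury affected the %s.", v$body_part))
  }
  if (show("clinical_diagnosis")) {
    s <- c(s, sprintf("Clinicians gave a diagnosis of %s.",
                      v$clinical_diagnosis))
  }
  if (show("deaths_total")) {
    s <- c(s, sprintf("The incident claimed %s %s in total.",
                      num("deaths_total"),
                      if (v$deaths_total == 1) "life" else "lives"))
  }
  if (show("injured_total")) {
    s <- c(s, sprintf("Altogether %s %s injured.", num("injured_total"),
                      if (v$injured_total == 1) "person was" else
                        "people were"))
  }
  if (show("child_deaths")) {
    s <- c(s, if (v$child_deaths == 1) {
      sprintf("%s of the deaths was a child.", cap1(num("child_deaths")))
    } else {
      sprintf("%s of the deaths were children.", cap1(num("child_deaths")))
    })
  }
  if (show("injured_children")) {
    s <- c(s, if (v$injured_children == 1) {
      sprintf("%s child was injured.", cap1(num("injured_children")))
    } else {
      sprintf("%s children were injured.", cap1(num("injured_children")))
    })
  }
  if (show("product_count")) {
    s <- c(s, if (v$product_count == 1) {
      sprintf("%s unit of the product was involved.",
              cap1(num("product_count")))
    } else {
      sprintf("%s units of the product were involved.",
              cap1(num("product_count")))
    })
  }
  if (show("product_brand")) {
    s <- c(s, sprintf("The product was sold under the brand %s.",
                      v$product_brand))
  }
  if (show("product_characteristics")) {
    s <- c(s, sprintf("The product was described as %s.",
                      v$product_characteristics))
  }
  if (show("product_type")) {
    s <- c(s, sprintf("The item is classed as %s.",
                      an_article(v$product_type)))
  }
  if (show("disposition")) {
    s <- c(s, sprintf("The product was subsequently %s.", v$disposition))
  }
  if (show("children_involved")) {
    s <- c(s, sprintf("The incident involved %s %s.",
                      num("children_involved"),
                      if (v$children_involved == 1) "child" else "children"))
  }
  if (show("child_activity")) {
    s <- c(s, sprintf("The child was %s at the time.", v$child_activity))
  }
  if (show("supervisor_count")) {
    s <- c(s, sprintf("The children were accompanied by %s adult %s.",
                      num("supervisor_count"),
                      if (v$supervisor_count == 1) "supervisor" else
                        "supervisors"))
  }
  if (show("supervisor_age") || show("supervisor_relation") ||
      show("supervisor_present")) {
    subj <- paste0("The ",
      if (show("supervisor_age")) paste0(v$supervisor_age, "-year-old "),
      if (show("supervisor_relation")) v$supervisor_relation else "caregiver")
    pred <- if (show("supervisor_present")) {
      phr <- names(pack$codebook$supervisor_present)[
        match(v$supervisor_present, pack$codebook$supervisor_present)]
      sprintf("was %s.", phr)
    } else "was reportedly nearby."
    s <- c(s, paste(subj, pred))
  }
  if (show("supervisor_sex")) {
    s <- c(s, sprintf("The supervisor was a %s.",
                      names(pack$codebook$supervisor_sex)[
                        match(v$supervisor_sex,
                              pack$codebook$supervisor_sex)]))
  }
  if (show("etiology_human")) {
    s <- c(s, sprintf("Investigators attributed the event to %s.",
                      v$etiology_human))
  }
  if (show("etiology_product")) {
    s <- c(s, sprintf("%s in the product was identified.",
                      cap1(an_article(v$etiology_product))))
  }
  if (show("etiology_detail")) {
    s <- c(s, sprintf("In detail, %s.", v$etiology_detail))
  }
  if (show("weather")) {
    s <- c(s, sprintf("Weather at the time was %s.", v$weather))
  }
  if (show("air_quality")) {
    s <- c(s, sprintf("Air quality that day was %s.", v$air_quality))
  }
  if (show("temperature")) {
    s <- c(s, sprintf("The temperature was %s.", v$temperature))
  }
  if (show("other_environment")) {
    s <- c(s, sprintf("Other adverse conditions included %s.",
                      v$other_environment))
  }
  if (show("preventive_measure")) {
    s <- c(s, sprintf("Experts advised that %s.", v$preventive_measure))
  }
  s <- c(s, "Local hospital staff treated the case.")
  list(title = "Child injured in product-related incident",
       body = paste(s, collapse = " "))
}

build_distractor_text <- function(plan) {
  switch(plan$kind,
    fictional = list(
      title = "Film review: action and spectacle",
      body = sprintf(paste(
        "In the new action %s, a young boy is injured by the %s during a",
        "dramatic scene. Critics praised the %s for its realism."),
        plan$marker, plan$product, plan$marker)),
    adult_injury = list(
      title = "Man injured at home",
      body = sprintf(paste(
        "A %d-year-old man was injured by the %s at the %s on Tuesday.",
        "He was treated at the local hospital and released."),
        plan$adult_age, plan$product, plan$place)),
    product_ad = list(
      title = sprintf("Big savings on %s", plan$product),
      body = sprintf(paste(
        "New %s on sale this week at the %s. A perfect gift idea for",
        "creative family fun. Visit our store for discounts."),
        plan$product, plan$place)),
    legal_commentary = list(
      title = "Court weighs product liability case",
      body = sprintf(paste(
        "The %s heard closing arguments in the lawsuit over compensation",
        "after a boy was injured by the %s last year. The ruling will focus",
        "on liability questions."),
        plan$marker, plan$product)))
}

#' Generate a synthetic media-story corpus with ground truth
#'
#' Produces a mixed corpus of eligible product-related child-injury stories
#' and ineligible distractors (fictional events, adult injuries, product
#' advertisements, legal commentary), standing in for a live crawler feed.
#' Eligible stories are realised from slot-filling templates so that every
#' present gold field appears verbatim in the text; the aligned gold labels
#' carry the embedded [structured_record()]s.
#'
#' @param config A [scenario_config()].
#' @return A `corpus_bundle`: list with `stories` (list of
#'   [media_story()]), `labels` (list of [gold_label()] aligned by
#'   `story_id`) and `config`.
#' @export
generate_corpus <- function(config) {
  validate_scenario_config(config)
  gaz <- config$gazetteer %||% load_gazetteer()
  pack <- config$language_pack %||% default_language_pack()
  n <- config$n_stories
  n_elig <- as.integer(round_half_up(n * config$eligible_fraction, 0))
  emergence_products <- vapply(config$emergence_events,
                               function(e) e$product, character(1))
  base_catalog <- config$product_catalog[
    !config$product_catalog$name %in% emergence_products, , drop = FALSE]
  if (n > 0 && nrow(base_catalog) == 0) {
    abort("Product catalog is empty after withholding emergence products.")
  }
  bundle <- structure(list(stories = list(), labels = list(),
                           config = config), class = "corpus_bundle")
  if (n > 0) {
    plans <- withr::with_seed(config$seed, {
      pl <- vector("list", n)
      for (i in seq_len(n_elig)) {
        pl[[i]] <- make_eligible_plan(config, gaz, pack, base_catalog,
                                      config$presence_rates)
      }
      if (n > n_elig) {
        for (i in (n_elig + 1):n) {
          pl[[i]] <- make_distractor_plan(config, gaz, pack, base_catalog)
        }
      }
      perm <- sample.int(n)
      list(plans = pl, perm = perm)
    })
    nf <- length(leaf_field_names())
    umat <- withr::with_seed(config$seed + 1L,
                             matrix(runif(max(n_elig, 1) * nf), ncol = nf))
    colnames(umat) <- leaf_field_names()
    cause_table <- pack$codebook$external_cause
    stories <- vector("list", n)
    labels <- vector("list", n)
    for (pos in seq_len(n)) {
      i <- plans$perm[pos]
      plan <- plans$plans[[i]]
      id <- sprintf("S%06d", pos)
      if (plan$kind == "eligible") {
        corrupt <- umat[i, ] < config$noise
        txt <- build_eligible_text(plan, corrupt, pack, cause_table)
        labels[[pos]] <- gold_label(id, TRUE, plan$gold)
      } else {
        txt <- build_distractor_text(plan)
        labels[[pos]] <- gold_label(id, FALSE)
      }
      stories[[pos]] <- media_story(
        story_id = id, title = txt$title, body = txt$body,
        publication_datetime = plan$publication_datetime,
        source_name = plan$source$name, source_kind = plan$source$kind,
        url = paste0("https://news.example/", id),
        source_province = plan$source$province,
        source_prefecture = plan$source$prefecture)
    }
    bundle$stories <- stories
    bundle$labels <- labels
  }
  for (ev in config$emergence_events) {
    bundle <- inject_emergence_scenario(bundle, ev)
  }
  bundle
}

#' @export
print.corpus_bundle <- function(x, ...) {
  n_elig <- sum(vapply(x$labels, function(l) l$eligible, logical(1)))
  cat(sprintf("<corpus_bundle: %d stories (%d eligible), seed %d>\n",
              length(x$stories), n_elig, x$config$seed))
  invisible(x)
}

#' Inject a product-emergence scenario into a corpus
#'
#' Adds one eligible story whose event date is exactly `first_date`,
#' followed by `burst_size` further eligible stories of the same product
#' uniformly dated within `burst_window_days` after it -- the first-signal
#' pattern that early-detection analytics are meant to recover. Errors if a
#' story of that product already exists earlier than `first_date`.
#'
#' @param bundle A `corpus_bundle`.
#' @param event `list(product, type, first_date, burst_size,
#'   burst_window_days)`; `type` defaults to `"toy"` for products not in the
#'   catalog.
#' @return The augmented `corpus_bundle`.
#' @export
inject_emergence_scenario <- function(bundle, event) {
  cfg <- bundle$config
  gaz <- cfg$gazetteer %||% load_gazetteer()
  pack <- cfg$language_pack %||% default_language_pack()
  first_date <- as.Date(event$first_date)
  burst <- as.integer(event$burst_size %||% 0L)
  window <- as.integer(event$burst_window_days %||% 61L)
  if (burst < 0) abort("`burst_size` must be >= 0.")
  dr <- as.Date(cfg$date_range)
  if (first_date < dr[1] || first_date > dr[2]) {
    abort("`first_date` lies outside the scenario date_range.")
  }
  catalog <- cfg$product_catalog
  if (!event$product %in% catalog$name) {
    catalog <- dplyr::bind_rows(
      catalog, tibble::tibble(name = event$product,
                              type = event$type %||% "toy"))
  }
  for (l in bundle$labels) {
    if (!l$eligible) next
    if (identical(record_field(l$gold_record, "product_name"),
                  event$product)) {
      ed <- record_field(l$gold_record, "event_date")
      d <- if (!is.null(ed)) event_date_as_date(ed) else
        story_pub_date(bundle$stories[[match(
          l$story_id, vapply(bundle$stories, `[[`, "", "story_id"))]])
      if (d < first_date) {
        abort(sprintf(
          "A story of product '%s' already exists earlier than %s.",
          event$product, format(first_date)))
      }
    }
  }
  sub_seed <- cfg$seed + 1000L +
    (sum(utf8ToInt(event$product)) %% 10000L)
  presence <- cfg$presence_rates
  presence[c("event_date", "product_name")] <- 1
  n0 <- length(bundle$stories)
  new_items <- withr::with_seed(sub_seed, {
    dates <- c(first_date,
               if (burst > 0) first_date + sample.int(window, burst,
                                                      replace = TRUE))
    lapply(seq_along(dates), function(j) {
      plan <- make_eligible_plan(cfg, gaz, pack, catalog, presence,
                                 fixed_product = event$product,
                                 fixed_event_date = dates[j])
      id <- sprintf("S%06d", n0 + j)
      txt <- build_eligible_text(
        plan, stats::setNames(rep(FALSE, length(leaf_field_names())),
                              leaf_field_names()),
        pack, pack$codebook$external_cause)
      list(story = media_story(
        story_id = id, title = txt$title, body = txt$body,
        publication_datetime = plan$publication_datetime,
        source_name = plan$source$name, source_kind = plan$source$kind,
        url = paste0("https://news.example/", id),
        source_province = plan$source$province,
        source_prefecture = plan$source$prefecture),
        label = gold_label(id, TRUE, plan$gold))
    })
  })
  bundle$stories <- c(bundle$stories, lapply(new_items, `[[`, "story"))
  bundle$labels <- c(bundle$labels, lapply(new_items, `[[`, "label"))
  bundle
}

#' Write a corpus bundle to disk
#'
#' Emits `stories.jsonl`, `gold_labels.jsonl` and `scenario.json` into a
#' directory.
#'
#' @param bundle A `corpus_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stories(bundle$stories, file.path(dir, "stories.jsonl"))
  write_gold_labels(bundle$labels, file.path(dir, "gold_labels.jsonl"))
  cfg <- bundle$config
  cfg_json <- list(
    n_stories = cfg$n_stories, eligible_fraction = cfg$eligible_fraction,
    presence_rates = as.list(cfg$presence_rates),
    date_range = cfg$date_range, noise = cfg$noise, seed = cfg$seed,
    child_age_range = cfg$child_age_range,
    product_catalog = purrr::map2(cfg$product_catalog$name,
                                  cfg$product_catalog$type,
                                  function(n, t) list(name = n, type = t)),
    emergence_events = cfg$emergence_events
  )
  jsonlite::write_json(cfg_json, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
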