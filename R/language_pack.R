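#' The default language pack
#'
#' Story generation and extraction are scoped to a language pack: the month
#' names, number words, fiction/topical marker lists, script test and
#' codebooks used by the slot-filling templates and the pattern rules. A
#' simple English pack ships by default; a pack for a language without word
#' delimiters would additionally supply a segmenter hook.
#'
#' @return A named list with the pack's components.
#' @export
default_language_pack <- function() {
  list(
    name = "en",
    script_regex = "[A-Za-z]",
    months = month.name,
    fiction_markers = c("movie", "film", "video game", "drama series",
                        "novel", "cartoon episode"),
    topical_markers = c("lawsuit", "court", "compensation", "liability",
                        "verdict", "safety lecture"),
    codebook = default_codebook()
  )
}

# Categorical codebooks shared by the generator templates and the default
# keyword+relation extraction rules. The external-cause categories carry the
# mechanism verb phrase that realises them in narrative text.
default_codebook <- function() {
  causes <- tibble::tibble(
    category = c("foreign-body ingestion", "fall from product",
                 "burn contact", "electric shock", "blunt impact",
                 "entrapment", "laceration", "strangulation"),
    verb = c("swallowed", "fell from", "was burned by", "was shocked by",
             "was struck by", "became trapped in", "was cut by",
             "was strangled by")
  )
  list(
    place_type = c("home", "kindergarten", "school", "playground", "park",
                   "mall", "supermarket", "balcony"),
    injury_nature = c("fracture", "burn", "laceration wound", "poisoning",
                      "asphyxia", "contusion", "internal injury"),
    body_part = c("head", "abdomen", "arm", "leg", "chest", "eye", "hand",
                  "finger"),
    external_cause = causes,
    product_type = c("toy", "nursery equipment", "appliance", "ride-on",
                     "recreational equipment", "furniture", "household tool"),
    disposition = c("recalled", "removed from sale",
                    "placed under investigation", "left on the market"),
    child_sex = c(boy = "male", girl = "female"),
    supervisor_sex = c(man = "male", woman = "female"),
    supervisor_relation = c("mother", "father", "grandmother", "grandfather",
                            "aunt", "uncle", "teacher", "nanny"),
    supervisor_present = c("right beside the child" = TRUE,
                           "watching the child closely" = TRUE,
                           "in another room" = FALSE,
                           "absent from the scene" = FALSE),
    clinical_diagnosis = c("intestinal perforation", "second degree burns",
                           "acute poisoning", "a compound fracture"),
    child_activity = c("playing with the product", "climbing on furniture",
                       "riding in the yard", "eating lunch", "taking a bath"),
    product_brand = c("Acme", "Brightco", "Lumina", "Kidsun"),
    product_characteristics = c("small and shiny", "brightly coloured",
                                "foldable and lightweight",
                                "equipped with strong magnets"),
    etiology_human = c("inadequate supervision", "improper use",
                       "improper storage", "risky play"),
    etiology_product = c("design defect", "manufacturing defect",
                         "missing warning label", "substandard material"),
    etiology_detail = c("the locking mechanism failed under light pressure",
                        "the magnets detached from the frame",
                        "the charger overheated during use",
                        "the guard rail gave way"),
    weather = c("light rain", "heavy snow", "clear skies", "strong wind"),
    air_quality = c("good", "moderate", "heavily polluted"),
    other_environment = c("a slippery floor", "poor lighting",
                          "a crowded room", "an unfenced balcony"),
    preventive_measure = c("small parts be kept away from infants",
                           "window guards be installed",
                           "chargers be unplugged after use",
                           "children be supervised near water")
  )
}

#' The default consumer-product catalog
#'
#' Products sampled by the synthetic generator, each with its product-type
#' category. Names coincide with product-chapter dictionary terms so that
#' candidate search always sees the product facet.
#'
#' @return A tibble with columns `name` and `type`.
#' @export
default_product_catalog <- function() {
  tibble::tibble(
    name = c("magnetic beads", "electric balance scooter", "button battery",
             "crib", "stroller", "trampoline", "electric kettle", "bunk bed",
             "laser pointer", "toy dart gun"),
    type = c("toy", "ride-on", "appliance", "nursery equipment",
             "nursery equipment", "recreational equipment", "appliance",
             "furniture", "toy", "toy")
  )
}
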