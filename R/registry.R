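#' Attribute specification
#'
#' Describes one ordered behavioral attribute of the diary: its kind
#' (which controls how thresholds are rendered in recommendation
#' statements), units, and the noun phrase used in statements.
#'
#' @param attribute_id unique identifier (used as a diary column name).
#' @param kind one of `"time_of_day"`, `"duration_minutes"`,
#'   `"quantity"`, `"ordinal"`.
#' @param units unit string appended to quantity/ordinal thresholds
#'   (e.g. `"mg"`); durations always render as minutes.
#' @param phrase_noun noun phrase for statements (e.g. `"bed time"`,
#'   `"dosage of Lyrica"`).
#' @param le_phrase,ge_phrase comparative phrases for the two rule
#'   directions; defaults depend on `kind` ("no later than"/"no earlier
#'   than" for clock times, "no more than"/"at least" otherwise).
#' @return an object of class `attribute_spec`.
#' @export
attribute_spec <- function(attribute_id, kind, units = "",
                           phrase_noun = attribute_id,
                           le_phrase = NULL, ge_phrase = NULL) {
  kind <- match.arg(kind, c("time_of_day", "duration_minutes",
                            "quantity", "ordinal"))
  if (is.null(le_phrase))
    le_phrase <- if (kind == "time_of_day") "no later than" else "no more than"
  if (is.null(ge_phrase))
    ge_phrase <- if (kind == "time_of_day") "no earlier than" else "at least"
  structure(list(attribute_id = attribute_id, kind = kind, units = units,
                 phrase_noun = phrase_noun, le_phrase = le_phrase,
                 ge_phrase = ge_phrase),
            class = "attribute_spec")
}

#' Default diary registry
#'
#' The original diary catalog: nine 0-10 symptom outcomes (pain,
#' stiffness, fatigue, concentration problems, memory problems, feeling
#' anxious, feeling depressed, gastrointestinal problems, sleep
#' difficulties) and a core set of behavioral attributes covering sleep,
#' rest and self-care. Personal inputs (medications, therapies, foods)
#' are added with [register_attribute()].
#'
#' @return a `diary_registry`: list with `symptoms` (named character
#'   vector mapping symptom id to its statement phrase) and `attributes`
#'   (named list of [attribute_spec()]s).
#' @export
default_registry <- function() {
  symptoms <- c(pain = "pain",
                stiffness = "stiffness",
                fatigue = "fatigue",
                concentration_problems = "concentration",
                memory_problems = "memory",
                feeling_anxious = "anxiety",
                feeling_depressed = "mood",
                gastrointestinal_problems = "digestion",
                sleep_difficulties = "sleep")
  attrs <- list(
    attribute_spec("bed_time", "time_of_day", phrase_noun = "bed time"),
    attribute_spec("wake_time", "time_of_day", phrase_noun = "wake-up time"),
    attribute_spec("nap_minutes", "duration_minutes",
                   phrase_noun = "daytime napping"),
    attribute_spec("exercise_minutes", "duration_minutes",
                   phrase_noun = "exercise"),
    attribute_spec("yoga_minutes", "duration_minutes", phrase_noun = "yoga"))
  names(attrs) <- vapply(attrs, `[[`, "", "attribute_id")
  structure(list(symptoms = symptoms, attributes = attrs),
            class = "diary_registry")
}

#' Add or replace an attribute in a registry
#'
#' @param registry a `diary_registry`.
#' @param spec an [attribute_spec()].
#' @return the updated registry.
#' @export
register_attribute <- function(registry, spec) {
  stopifnot(inherits(registry, "diary_registry"),
            inherits(spec, "attribute_spec"))
  registry$attributes[[spec$attribute_id]] <- spec
  registry
}

#' Read a registry from a YAML or JSON configuration file
#'
#' The file holds `symptoms` (mapping of symptom id to phrase) and
#' `attributes` (list of attribute_spec fields).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `diary_registry`.
#' @export
read_registry <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  symptoms <- unlist(cfg$symptoms)
  attrs <- lapply(cfg$attributes, function(a)
    attribute_spec(a$attribute_id, a$kind,
                   units = a$units %||% "",
                   phrase_noun = a$phrase_noun %||% a$attribute_id,
                   le_phrase = a$le_phrase, ge_phrase = a$ge_phrase))
  names(attrs) <- vapply(attrs, `[[`, "", "attribute_id")
  structure(list(symptoms = symptoms, attributes = attrs),
            class = "diary_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
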