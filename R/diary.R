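#' Validate one raw diary record into a smartlog
#'
#' Checks a raw field map (e.g. one CSV row) against the registry:
#' symptom ratings must be integers in 0-10, attribute ids must be
#' registered, clock-time attributes given as `"HH:MM"` strings are
#' encoded onto the hours-after-noon scale. Missing ratings and
#' attributes are kept as absent (`NA`), never imputed.
#'
#' @param raw named list with `user_id`, `date` (Date or ISO-8601
#'   string) and any subset of registered symptom/attribute fields.
#' @param registry a `diary_registry` (default [default_registry()]).
#' @return a `smartlog`: list with `user_id`, `date`, `ratings` (named
#'   numeric over registered symptoms) and `attributes` (named numeric,
#'   clock times encoded).
#' @export
validate_entry <- function(raw, registry = default_registry()) {
  if (is.null(raw$user_id) || is.null(raw$date))
    stop("record needs user_id and date")
  date <- as.Date(raw$date)
  if (is.na(date)) stop("unparseable date: ", raw$date)
  fields <- setdiff(names(raw), c("user_id", "date"))
  sym_ids <- names(registry$symptoms)
  attr_ids <- names(registry$attributes)
  unknown <- setdiff(fields, c(sym_ids, attr_ids))
  if (length(unknown))
    stop("unknown field(s) not in registry: ", paste(unknown, collapse = ", "))

  ratings <- setNames(rep(NA_real_, length(sym_ids)), sym_ids)
  for (s in intersect(fields, sym_ids)) {
    v <- raw[[s]]
    if (is.null(v) || is.na(v)) next
    v <- as.numeric(v)
    if (is.na(v) || v < 0 || v > 10 || v != round(v))
      stop("rating out of range (0-10 integer) for ", s, ": ", raw[[s]])
    ratings[s] <- v
  }
  attributes <- setNames(rep(NA_real_, length(attr_ids)), attr_ids)
  for (a in intersect(fields, attr_ids)) {
    v <- raw[[a]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) next
    spec <- registry$attributes[[a]]
    if (spec$kind == "time_of_day" && is.character(v))
      v <- encode_time_of_day(v)
    v <- as.numeric(v)
    if (is.na(v)) stop("unparseable value for attribute ", a, ": ", raw[[a]])
    attributes[a] <- v
  }
  structure(list(user_id = as.character(raw$user_id), date = date,
                 ratings = ratings, attributes = attributes),
            class = "smartlog")
}

#' Assemble a user record
#'
#' Bundles a user's diary logs, FIQ administrations and issued profile
#' statements. Log dates must be unique and are sorted strictly
#' increasing; the first FIQ is flagged as baseline.
#'
#' @param user_id user identifier.
#' @param logs data frame with a `date` column (Date) plus numeric
#'   symptom and attribute columns (one row per diary day), or a list
#'   of `smartlog`s.
#' @param fiq list of [fiq_response()] objects, ordered by time.
#' @param profiles list of issued `profile_statement`s.
#' @param registry the `diary_registry` the columns belong to.
#' @return an object of class `user_record`.
#' @export
user_record <- function(user_id, logs, fiq = list(), profiles = list(),
                        registry = default_registry()) {
  if (is.list(logs) && !is.data.frame(logs) &&
      all(vapply(logs, inherits, TRUE, "smartlog"))) {
    logs <- do.call(rbind, lapply(logs, function(l)
      data.frame(date = l$date, as.list(l$ratings), as.list(l$attributes),
                 check.names = FALSE)))
  }
  stopifnot(is.data.frame(logs), "date" %in% names(logs))
  logs$date <- as.Date(logs$date)
  if (anyDuplicated(logs$date))
    stop("duplicate diary entry: at most one log per user per date (user ",
         user_id, ")")
  logs <- logs[order(logs$date), , drop = FALSE]
  rownames(logs) <- NULL
  if (length(fiq)) {
    ord <- order(vapply(fiq, function(f) as.numeric(f$administered_at), 0))
    fiq <- fiq[ord]
    fiq[[1]]$is_baseline <- TRUE
  }
  structure(list(user_id = as.character(user_id), logs = logs, fiq = fiq,
                 profiles = profiles, registry = registry),
            class = "user_record")
}

#' @export
print.user_record <- function(x, ...) {
  cat("<user_record>", x$user_id, "-", nrow(x$logs), "logs,",
      length(x$fiq), "FIQ administrations,",
      length(x$profiles), "profile statements\n")
  invisible(x)
}

#' Extract same-day paired attribute/symptom series
#'
#' Returns the paired vectors (attribute value on date d, symptom
#' rating on date d) used by the cutpoint engine, dropping any day on
#' which either value is missing. Order follows the diary dates.
#'
#' @param user a `user_record`.
#' @param attribute_id,symptom_id registered ids.
#' @return list with `x` (attribute values), `rating` (0-10 ratings)
#'   and `date`.
#' @export
extract_paired_series <- function(user, attribute_id, symptom_id) {
  stopifnot(inherits(user, "user_record"))
  if (!attribute_id %in% names(user$registry$attributes))
    stop("unknown attribute id: ", attribute_id)
  if (!symptom_id %in% names(user$registry$symptoms))
    stop("unknown symptom id: ", symptom_id)
  logs <- user$logs
  x <- if (attribute_id %in% names(logs)) logs[[attribute_id]]
       else rep(NA_real_, nrow(logs))
  y <- if (symptom_id %in% names(logs)) logs[[symptom_id]]
       else rep(NA_real_, nrow(logs))
  keep <- !is.na(x) & !is.na(y)
  list(x = as.numeric(x[keep]), rating = as.numeric(y[keep]),
       date = logs$date[keep])
}
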