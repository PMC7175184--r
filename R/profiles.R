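#' Minimum-data gate for profile generation
#'
#' Recommendation statements are only generated once a user has
#' accumulated enough diary entries; the default gate is 22 completed
#' logs.
#'
#' @param user a `user_record`.
#' @param min_logs minimum completed logs (default 22).
#' @return logical.
#' @export
eligible_for_profiles <- function(user, min_logs = 22) {
  stopifnot(inherits(user, "user_record"))
  nrow(user$logs) >= min_logs
}

#' Scan a user's diary for significant cutpoint rules
#'
#' Iterates every registered (attribute, symptom) pair with sufficient
#' paired data, dichotomizes the ratings, fits the maximum-accuracy
#' cutpoint rule and attaches a permutation p-value. Pairs with a
#' degenerate outcome (constant ratings) or too few members in either
#' class are skipped. Significant models (p <= alpha) are returned
#' sorted by ascending p then descending ESS.
#'
#' @param user a `user_record`.
#' @param alpha per-test significance level (default 0.05). Pairwise
#'   tests are not corrected for multiplicity by default; set
#'   `sidak = TRUE` for a Sidak-adjusted per-test level.
#' @param min_logs eligibility gate (default 22); an ineligible user is
#'   an error.
#' @param min_per_class minimum class size per [fit_cutpoint_model()].
#' @param method,reps permutation settings per [permutation_p_value()].
#' @param seed integer seed controlling Monte Carlo permutations; the
#'   scan is deterministic given `(data, seed)`. The RNG state is
#'   restored on exit when a seed is supplied.
#' @param sidak apply a Sidak multiplicity adjustment across the pairs
#'   actually tested.
#' @return list of significant `cutpoint_model`s (possibly empty).
#' @export
discover_associations <- function(user, alpha = 0.05, min_logs = 22,
                                  min_per_class = 5, method = "auto",
                                  reps = 10000, seed = NULL,
                                  sidak = FALSE) {
  stopifnot(inherits(user, "user_record"))
  if (!eligible_for_profiles(user, min_logs))
    stop("user ", user$user_id, " has fewer than ", min_logs,
         " completed logs; profile generation is gated")
  run <- function() .scan_pairs(user$logs, user$registry, alpha,
                                min_per_class, method, reps, sidak)
  models <- if (is.null(seed)) run() else .with_seed(seed, run())
  for (i in seq_along(models)) models[[i]]$user_id <- user$user_id
  models
}

# Core pair scan over wide log columns (data frame or named list of
# aligned vectors). Separated from the user_record wrapper so the
# simulator can call it cheaply on growing data; model objects are
# materialized only for pairs that clear the significance level.
.scan_pairs <- function(logs, registry, alpha, min_per_class, method,
                        reps, sidak = FALSE) {
  attrs <- intersect(names(registry$attributes), names(logs))
  syms <- intersect(names(registry$symptoms), names(logs))
  hits <- list()
  n_tested <- 0L
  for (a in attrs) {
    xa <- logs[[a]]
    for (s in syms) {
      ys <- logs[[s]]
      keep <- !is.na(xa) & !is.na(ys)
      n <- sum(keep)
      if (n < 2 * min_per_class) next
      x <- xa[keep]; y <- ys[keep]
      med <- stats::median(y)
      improved <- y < med
      n1 <- sum(improved)
      if (n1 < min_per_class || n - n1 < min_per_class) next
      ord <- order(x, method = "radix")
      xs <- x[ord]
      bounds <- which(diff(xs) > 0)
      if (!length(bounds)) next
      lab <- as.integer(improved[ord])
      fit <- oda_fit_cpp(lab, bounds)
      exact_ok <- choose(n, n1) <= .EXACT_BOUND
      p <- if (method == "exact" || (method == "auto" && exact_ok))
        oda_perm_exact_cpp(lab, bounds, fit$mean_sensitivity)
      else oda_perm_mc_cpp(lab, bounds, fit$mean_sensitivity,
                           as.integer(reps), early_h = 30L)
      n_tested <- n_tested + 1L
      hits[[length(hits) + 1]] <-
        list(a = a, s = s, p = p, fit = fit,
             bounds = bounds, xs = xs, n = n, n1 = n1)
    }
  }
  if (!n_tested) return(list())
  level <- if (sidak) 1 - (1 - alpha)^(1 / n_tested) else alpha
  sig <- Filter(function(h) h$p <= level, hits)
  if (!length(sig)) return(list())
  models <- lapply(sig, function(h) {
    b <- h$fit$bound_index
    cut_lo <- h$xs[h$bounds[b]]
    cut_hi <- h$xs[h$bounds[b] + 1]
    structure(list(
      attribute_id = h$a, symptom_id = h$s,
      direction = if (h$fit$direction == 0) "le_improves" else "ge_improves",
      cutpoint = (cut_lo + cut_hi) / 2,
      cut_lo = cut_lo, cut_hi = cut_hi,
      sens_improved = h$fit$sens_improved,
      sens_not_improved = h$fit$sens_not_improved,
      mean_sensitivity = h$fit$mean_sensitivity,
      ess = max(0, min(100,
                       100 * (h$fit$mean_sensitivity - 0.5) / 0.5)),
      n_pairs = h$n, n_improved = h$n1, n_not_improved = h$n - h$n1,
      p_value = h$p, alpha = level, significant = TRUE),
      class = "cutpoint_model")
  })
  ord <- order(vapply(models, `[[`, 0, "p_value"),
               -vapply(models, `[[`, 0, "ess"))
  models[ord]
}

# Threshold a statement quotes: the observed attribute value on the
# favorable side of the cutpoint, so recommendations name realizable
# behaviors rather than midpoints.
.statement_threshold <- function(model) {
  if (model$direction == "le_improves") model$cut_lo else model$cut_hi
}

.format_threshold <- function(value, spec) {
  switch(spec$kind,
         time_of_day = format_time_of_day(value),
         duration_minutes = paste0(format(value), " minutes"),
         quantity = trimws(paste(format(value), spec$units)),
         ordinal = trimws(paste(format(value), spec$units)))
}

#' Render a significant model as a recommendation statement
#'
#' Produces the natural-language statement
#' `"My {symptom} will improve if my {noun} is {phrase} {threshold}"`,
#' e.g. `"My pain will improve if my bed time is no later than
#' 9:40 pm"`. The phrase comes from the attribute's registry entry
#' (`le_phrase` for `le_improves` rules, `ge_phrase` for
#' `ge_improves`), and the threshold is formatted by attribute kind
#' (clock time, minutes, or quantity with units) at the observed value
#' on the favorable side of the cutpoint.
#'
#' @param model a significant `cutpoint_model` (rendering a
#'   non-significant model is refused).
#' @param registry the `diary_registry` holding the attribute spec and
#'   symptom phrase.
#' @param issued_at timestamp recorded on the statement.
#' @return object of class `profile_statement` with fields `text`,
#'   `key` (symptom/attribute/direction identity used for duplicate
#'   suppression), `model`, `issued_at`, `user_id`.
#' @export
render_statement <- function(model, registry = default_registry(),
                             issued_at = Sys.Date()) {
  stopifnot(inherits(model, "cutpoint_model"))
  if (!isTRUE(model$significant))
    stop("refusing to render a non-significant model")
  spec <- registry$attributes[[model$attribute_id]]
  if (is.null(spec)) stop("unregistered attribute: ", model$attribute_id)
  phrase_sym <- registry$symptoms[[model$symptom_id]]
  if (is.null(phrase_sym)) stop("unregistered symptom: ", model$symptom_id)
  phrase <- if (model$direction == "le_improves") spec$le_phrase
            else spec$ge_phrase
  thr <- .format_threshold(.statement_threshold(model), spec)
  text <- sprintf("My %s will improve if my %s is %s %s",
                  phrase_sym, spec$phrase_noun, phrase, thr)
  structure(list(text = text,
                 key = paste(model$symptom_id, model$attribute_id,
                             model$direction, sep = "|"),
                 model = model,
                 issued_at = as.Date(issued_at),
                 user_id = model$user_id %||% NA_character_),
            class = "profile_statement")
}

#' @export
print.profile_statement <- function(x, ...) {
  cat(sprintf("[%s] %s\n", format(x$issued_at), x$text))
  invisible(x)
}

#' Merge newly discovered models into an issued-profile set
#'
#' Applies the duplicate-suppression convention: a statement matching a
#' previously issued one in (symptom, attribute, direction) replaces it
#' (threshold refreshed, original issue date kept) without increasing
#' the cumulative count; a new identity appends. Cumulative profile
#' counts are therefore non-decreasing over time.
#'
#' @param issued list of previously issued `profile_statement`s.
#' @param models list of significant `cutpoint_model`s.
#' @param registry the `diary_registry` used for rendering.
#' @param issued_at issue date for newly appearing statements.
#' @return updated list of `profile_statement`s.
#' @export
issue_profiles <- function(issued, models, registry = default_registry(),
                           issued_at = Sys.Date()) {
  keys <- vapply(issued, `[[`, "", "key")
  for (m in models) {
    st <- render_statement(m, registry, issued_at)
    hit <- match(st$key, keys)
    if (is.na(hit)) {
      issued[[length(issued) + 1]] <- st
      keys <- c(keys, st$key)
    } else {
      st$issued_at <- issued[[hit]]$issued_at  # first-issue date is kept
      issued[[hit]] <- st
    }
  }
  issued
}
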