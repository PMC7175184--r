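#' Construct an FIQ administration
#'
#' One administration of the Fibromyalgia Impact Questionnaire: 11
#' physical-functioning items on a 0-3 Likert scale (missing allowed),
#' days felt good and days of missed work (each 0-7), and seven visual
#' analog scales (work difficulty, pain, fatigue, morning tiredness,
#' stiffness, anxiety, depression) marked in 10 increments (0-10).
#'
#' @param physical_items numeric vector of 11 values in 0-3 (NA allowed).
#' @param feel_good_days days felt good in the past week, 0-7.
#' @param missed_work_days days unable to work because of symptoms, 0-7.
#' @param vas numeric vector of 7 values in 0-10, in the order work
#'   difficulty, pain, fatigue, morning tiredness, stiffness, anxiety,
#'   depression.
#' @param works_outside_home if `FALSE`, the two work-related items
#'   (missed work, work difficulty) are skipped and the total rescaled.
#' @param administered_at Date of administration.
#' @param is_baseline whether this is the baseline administration.
#' @return object of class `fiq_response`.
#' @export
fiq_response <- function(physical_items, feel_good_days, missed_work_days,
                         vas, works_outside_home = TRUE,
                         administered_at = Sys.Date(), is_baseline = FALSE) {
  physical_items <- as.numeric(physical_items)
  vas <- as.numeric(vas)
  if (length(physical_items) != 11)
    stop("physical_items must have 11 values")
  if (length(vas) != 7) stop("vas must have 7 values")
  chk <- function(v, lo, hi, what) {
    if (any(!is.na(v) & (v < lo | v > hi)))
      stop(what, " out of range [", lo, ", ", hi, "]")
  }
  chk(physical_items, 0, 3, "physical item")
  chk(feel_good_days, 0, 7, "feel_good_days")
  chk(missed_work_days, 0, 7, "missed_work_days")
  chk(vas, 0, 10, "VAS item")
  structure(list(physical_items = physical_items,
                 feel_good_days = as.numeric(feel_good_days),
                 missed_work_days = as.numeric(missed_work_days),
                 vas = vas,
                 works_outside_home = isTRUE(works_outside_home),
                 administered_at = as.Date(administered_at),
                 is_baseline = isTRUE(is_baseline)),
            class = "fiq_response")
}

#' Score an FIQ administration to its 0-100 total
#'
#' Each subscale is first normalized to 0-10: the physical subscale is
#' the mean of answered items times 10/3; feel-good days map to
#' `(7 - days) * 10/7` (more good days, less impact); missed-work days
#' to `days * 10/7`; the seven VAS items are used directly. The total
#' is the sum of available subscales rescaled to 0-100 by
#' `100 / (10 * n_valid)`, so skipped items (e.g. the work pair for
#' respondents not working outside the home) rescale rather than
#' penalize.
#'
#' @param resp an [fiq_response()].
#' @return object of class `fiq_score`: list with `total` (0-100),
#'   `subscores` (named, length 10, NA where unavailable) and
#'   `n_valid_subscales`.
#' @export
score_fiq <- function(resp) {
  stopifnot(inherits(resp, "fiq_response"))
  phys <- if (all(is.na(resp$physical_items))) NA_real_
          else mean(resp$physical_items, na.rm = TRUE) * 10 / 3
  feel <- if (is.na(resp$feel_good_days)) NA_real_
          else (7 - resp$feel_good_days) * 10 / 7
  miss <- if (is.na(resp$missed_work_days)) NA_real_
          else resp$missed_work_days * 10 / 7
  vas <- resp$vas
  if (!resp$works_outside_home) {
    miss <- NA_real_
    vas[1] <- NA_real_  # work difficulty
  }
  sub <- c(physical = phys, feel_good = feel, missed_work = miss,
           work_difficulty = vas[1], pain = vas[2], fatigue = vas[3],
           morning_tiredness = vas[4], stiffness = vas[5],
           anxiety = vas[6], depression = vas[7])
  n_valid <- sum(!is.na(sub))
  if (n_valid == 0) stop("unscorable FIQ: all subscales missing")
  total <- sum(sub, na.rm = TRUE) * 100 / (10 * n_valid)
  structure(list(total = total, subscores = sub,
                 n_valid_subscales = n_valid),
            class = "fiq_score")
}

#' Classify an FIQ total into a severity band
#'
#' Bands follow the established severity criteria for the instrument:
#' totals of 38 or less are mild impact, above 38 up to 58 moderate,
#' above 58 severe.
#'
#' @param score numeric FIQ total(s) in 0-100.
#' @return character vector in `{"mild","moderate","severe"}`.
#' @export
classify_severity <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 100))
    stop("FIQ score out of range [0, 100]")
  ifelse(score <= 38, "mild", ifelse(score <= 58, "moderate", "severe"))
}

#' Percent drop between two mean scores
#'
#' `100 * (baseline - followup) / baseline`; positive values are
#' improvement (lower impact at follow-up).
#'
#' @param baseline_mean,followup_mean mean scores, baseline > 0.
#' @return percent drop (full precision; round for display).
#' @export
percent_drop <- function(baseline_mean, followup_mean) {
  if (any(baseline_mean <= 0)) stop("percent drop undefined for baseline <= 0")
  100 * (baseline_mean - followup_mean) / baseline_mean
}
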