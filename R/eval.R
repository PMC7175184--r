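#' Cumulative use indices at a time point
#'
#' Counts a user's completed diary logs and distinct issued profile
#' statements with timestamps at or before `t` — the two indices of
#' program use recorded alongside each FIQ administration.
#'
#' @param user a `user_record`.
#' @param t a Date.
#' @return named numeric: `cum_logs`, `cum_profiles`.
#' @export
use_indices_at <- function(user, t) {
  stopifnot(inherits(user, "user_record"))
  t <- as.Date(t)
  cum_logs <- sum(user$logs$date <= t)
  cum_profiles <- if (length(user$profiles))
    sum(vapply(user$profiles, function(p) as.Date(p$issued_at) <= t, TRUE))
  else 0L
  c(cum_logs = cum_logs, cum_profiles = cum_profiles)
}

#' Build the pooled FIQ-by-use table
#'
#' One row per FIQ administration across all users, carrying the FIQ
#' total and the cumulative use indices at its timestamp. Baseline
#' rows are included by default; users with no FIQ at all are excluded
#' with a warning.
#'
#' @param users list of `user_record`s.
#' @param include_baseline keep baseline administrations (default TRUE).
#' @return data frame of class `pooled_table` with columns `user_id`,
#'   `fiq_date`, `fiq_score`, `cum_logs`, `cum_profiles`,
#'   `is_baseline`.
#' @export
build_pooled_table <- function(users, include_baseline = TRUE) {
  rows <- lapply(users, function(u) {
    if (!length(u$fiq)) {
      warning("user ", u$user_id, " has no FIQ administrations; excluded")
      return(NULL)
    }
    do.call(rbind, lapply(u$fiq, function(f) {
      idx <- use_indices_at(u, f$administered_at)
      data.frame(user_id = u$user_id,
                 fiq_date = as.Date(f$administered_at),
                 fiq_score = score_fiq(f)$total,
                 cum_logs = unname(idx["cum_logs"]),
                 cum_profiles = unname(idx["cum_profiles"]),
                 is_baseline = isTRUE(f$is_baseline))
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no FIQ administrations in cohort")
  if (!include_baseline) out <- out[!out$is_baseline, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pooled_table", "data.frame")
  out
}

# Merge-sort discordance (inversion) count of y after sorting by
# (x, y); within x-tie groups y is sorted, so tied-x pairs contribute
# no inversions and the count equals the number of discordant pairs.
.count_inversions <- function(v) {
  n <- length(v)
  if (n < 2) return(list(v = v, inv = 0))
  mid <- n %/% 2
  L <- .count_inversions(v[seq_len(mid)])
  R <- .count_inversions(v[(mid + 1):n])
  inv <- L$inv + R$inv
  nl <- length(L$v); nr <- length(R$v)
  merged <- numeric(n); i <- 1L; j <- 1L
  for (k in seq_len(n)) {
    if (i <= nl && (j > nr || L$v[i] <= R$v[j])) {
      merged[k] <- L$v[i]; i <- i + 1L
    } else {
      merged[k] <- R$v[j]; j <- j + 1L
      inv <- inv + (nl - i + 1)
    }
  }
  list(v = merged, inv = inv)
}

#' Kendall tau-b with tie correction
#'
#' Rank correlation for ordinal association in the presence of ties:
#' `tau_b = (C - D) / sqrt((n0 - t_x)(n0 - t_y))` with
#' `n0 = n(n-1)/2` and `t_x = sum t(t-1)/2` over tied groups of `x`
#' (likewise `t_y`). `C - D` is obtained by a merge-sort discordance
#' count (O(n log n)). The two-tailed p-value uses the tie-adjusted
#' normal approximation for the variance of `C - D`.
#'
#' @param x,y numeric/ordinal vectors of equal length `>= 2`; an
#'   all-tied `x` or `y` leaves tau undefined and is an error.
#' @return object of class `tau_result`: `tau_b`, `p_value` (two-
#'   tailed), `n_concordant`, `n_discordant`, `ties_x`, `ties_y`, `n`.
#' @export
kendall_tau_b <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(n == length(y), n >= 2, !anyNA(x), !anyNA(y))
  tx <- table(x); ty <- table(y)
  if (length(tx) < 2 || length(ty) < 2)
    stop("tau-b undefined: all values of x or y are tied")
  o <- order(x, y)
  dis <- .count_inversions(y[o])$inv
  n0 <- n * (n - 1) / 2
  t_x <- sum(tx * (tx - 1) / 2)
  t_y <- sum(ty * (ty - 1) / 2)
  txy <- table(paste(x, y, sep = "\r"))
  t_xy <- sum(txy * (txy - 1) / 2)
  # pairs tied on neither axis: concordant + discordant
  S <- n0 - t_x - t_y + t_xy - 2 * dis            # C - D
  con <- (S + (n0 - t_x - t_y + t_xy)) / 2
  tau <- S / sqrt((n0 - t_x) * (n0 - t_y))
  # tie-adjusted variance of C - D
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  v <- (v0 - vt - vu) / 18 + v1 + v2
  z <- if (v > 0) S / sqrt(v) else 0
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(tau_b = tau, p_value = p, z = z,
                 n_concordant = con, n_discordant = dis,
                 ties_x = unname(t_x), ties_y = unname(t_y), n = n),
            class = "tau_result")
}

#' @export
print.tau_result <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.3f (n = %d, two-tailed p = %s)\n",
              x$tau_b, x$n, format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Classify a user's total diary use into tiers
#'
#' Fewer than 22 total logs falls below the inclusion criterion; 22-47
#' logs is moderate use; 48 or more is heavy use.
#'
#' @param total_logs non-negative integer vector.
#' @return character vector in
#'   `{"below_criteria","moderate","heavy"}`.
#' @export
classify_user_use <- function(total_logs) {
  stopifnot(all(total_logs >= 0))
  ifelse(total_logs < 22, "below_criteria",
         ifelse(total_logs < 48, "moderate", "heavy"))
}

#' Follow-up mean FIQ for a high-use subgroup
#'
#' Selects users whose final cumulative use index reaches `threshold`
#' and averages their follow-up (non-baseline) FIQ scores.
#'
#' @param table a `pooled_table` from [build_pooled_table()].
#' @param index `"logs"` or `"profiles"`.
#' @param threshold minimum final cumulative index.
#' @return list with `mean_score` (NA if the subgroup is empty),
#'   `n_users`, `fraction_of_sample`.
#' @export
subgroup_followup_mean <- function(table, index = c("logs", "profiles"),
                                   threshold) {
  index <- match.arg(index)
  stopifnot(nrow(table) > 0)
  col <- paste0("cum_", index)
  finals <- tapply(table[[col]], table$user_id, max)
  sel_users <- names(finals)[finals >= threshold]
  rows <- table$user_id %in% sel_users & !table$is_baseline
  list(mean_score = if (any(rows)) mean(table$fiq_score[rows]) else NA_real_,
       n_users = length(sel_users),
       fraction_of_sample = length(sel_users) / length(finals))
}

#' Use-tier summary of a pooled cohort
#'
#' Per-tier user counts, mean total logs, and tau-b style layout
#' companion: a compact summary mirroring the evaluation's reporting.
#'
#' @param users list of `user_record`s.
#' @return data frame with one row per tier.
#' @export
tier_summary <- function(users) {
  totals <- vapply(users, function(u) nrow(u$logs), 0)
  tier <- classify_user_use(totals)
  out <- do.call(rbind, lapply(c("below_criteria", "moderate", "heavy"),
    function(tr) data.frame(tier = tr, n_users = sum(tier == tr),
                            mean_logs = if (any(tier == tr))
                              mean(totals[tier == tr]) else NA_real_)))
  rownames(out) <- NULL
  out
}
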