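# Independent oracles used across the suite. Deliberately naive and
# separate from the package's code paths.

# Brute-force cutpoint scorer: every (midpoint, direction) rule scored
# by direct sensitivity arithmetic; ties resolved by scanning cutpoints
# ascending, "le" before "ge", keeping the first strict improvement.
oracle_fit <- function(x, improved) {
  u <- sort(unique(x))
  cands <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (cut in cands) {
    for (dir in c("le", "ge")) {
      pred_imp <- if (dir == "le") x <= cut else x >= cut
      s1 <- mean(pred_imp[improved])
      s0 <- mean(!pred_imp[!improved])
      m <- (s1 + s0) / 2
      if (is.null(best) || m > best$m + 1e-12)
        best <- list(m = m, cut = cut, dir = dir, s1 = s1, s0 = s0)
    }
  }
  best
}

# Full-enumeration permutation p-value via the brute-force scorer
# (tiny n only).
oracle_exact_p <- function(x, improved) {
  n <- length(x)
  n1 <- sum(improved)
  obs <- oracle_fit(x, improved)$m
  combos <- utils::combn(n, n1)
  hits <- 0
  for (j in seq_len(ncol(combos))) {
    lab <- rep(FALSE, n)
    lab[combos[, j]] <- TRUE
    if (oracle_fit(x, lab)$m >= obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(combos)
}

# O(n^2) pair-counting Kendall tau-b oracle.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx * dy > 0) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Test-only inverse of render_statement().
parse_statement <- function(text) {
  m <- regmatches(text, regexec(
    "^My (.+) will improve if my (.+) is (no later than|no earlier than|no more than|at least) (.+)$",
    text))[[1]]
  if (length(m) != 5) return(NULL)
  list(symptom_phrase = m[2], noun = m[3], phrase = m[4], threshold = m[5])
}

# Compact fixture builders -------------------------------------------------

make_logs <- function(dates, ...) {
  data.frame(date = as.Date(dates), ..., check.names = FALSE)
}

make_fiq <- function(date, vas_level = 5, feel_good = 3, missed = 2,
                     phys = rep(2, 11), is_baseline = FALSE) {
  fiq_response(phys, feel_good, missed, rep(vas_level, 7),
               administered_at = as.Date(date), is_baseline = is_baseline)
}

# A user with a strong planted bedtime -> pain rule over n days.
make_planted_user <- function(n = 60, threshold = 10, effect = 3,
                              noise_sd = 1.5, seed = 1) {
  set.seed(seed)
  bed <- rnorm(n, 10, 1.5)
  pain <- pmin(10, pmax(0, round(3.5 + effect * (bed > threshold) +
                                   rnorm(n, 0, noise_sd))))
  stiffness <- pmin(10, pmax(0, round(rnorm(n, 5, 1.5))))
  logs <- make_logs(as.Date("2015-01-01") + seq_len(n) - 1,
                    bed_time = bed, pain = pain, stiffness = stiffness)
  user_record("planted", logs)
}
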