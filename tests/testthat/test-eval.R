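fixture_user <- function(id, n_logs, fiq_dates, fiq_level = 5,
                         profile_dates = as.Date(character(0))) {
  logs <- make_logs(as.Date("2015-01-01") + seq_len(n_logs) - 1,
                    pain = rep(c(2, 7), length.out = n_logs))
  profs <- lapply(profile_dates, function(d)
    structure(list(text = "t", key = paste0("k", format(d)),
                   model = NULL, issued_at = as.Date(d), user_id = id),
              class = "profile_statement"))
  fiq <- lapply(seq_along(fiq_dates), function(i)
    make_fiq(fiq_dates[i], vas_level = fiq_level, is_baseline = i == 1))
  user_record(id, logs, fiq = fiq, profiles = profs)
}

test_that("use indices count logs and profiles up to a time point", {
  u <- fixture_user("u1", 30, c("2015-01-01", "2015-02-09"),
                    profile_dates = as.Date(c("2015-01-25", "2015-02-01",
                                              "2015-02-05")))
  expect_equal(use_indices_at(u, as.Date("2014-12-31")),
               c(cum_logs = 0, cum_profiles = 0))
  expect_equal(use_indices_at(u, as.Date("2015-02-09")),
               c(cum_logs = 30, cum_profiles = 3))
  expect_equal(use_indices_at(u, as.Date("2016-01-01")),
               c(cum_logs = 30, cum_profiles = 3))
  expect_equal(use_indices_at(u, as.Date("2015-01-26")),
               c(cum_logs = 26, cum_profiles = 1))
})

test_that("the pooled table reconstructs the study's row arithmetic", {
  # 76 included users: 46 moderate averaging 2.54 follow-ups (117 total)
  # and 30 heavy averaging 4.97 (149 total) -> 266 follow-ups + 76
  # baselines = 342 rows
  fu_mod <- c(rep(3, 25), rep(2, 21))     # sums to 117
  fu_heavy <- c(rep(5, 29), 4)            # sums to 149
  users <- c(
    lapply(seq_along(fu_mod), function(i)
      fixture_user(sprintf("m%02d", i), 30,
                   as.Date("2015-01-01") + 30 * (0:fu_mod[i]))),
    lapply(seq_along(fu_heavy), function(i)
      fixture_user(sprintf("h%02d", i), 60,
                   as.Date("2015-01-01") + 30 * (0:fu_heavy[i]))))
  tab <- build_pooled_table(users)
  expect_equal(nrow(tab), 342)
  expect_equal(sum(tab$is_baseline), 76)
  expect_equal(nrow(build_pooled_table(users, include_baseline = FALSE)),
               266)
  # cumulative indices are non-decreasing within user
  for (uid in unique(tab$user_id)) {
    rows <- tab[tab$user_id == uid, ]
    expect_true(all(diff(rows$cum_logs) >= 0))
    expect_true(all(diff(rows$cum_profiles) >= 0))
  }
})

test_that("a single user with baseline and two follow-ups gives 3 rows", {
  u <- fixture_user("solo", 10, c("2015-01-01", "2015-01-31", "2015-03-02"))
  expect_equal(nrow(build_pooled_table(list(u))), 3)
  u0 <- user_record("nofiq", make_logs("2015-01-01", pain = 3))
  expect_warning(tab <- build_pooled_table(list(u, u0)), "no FIQ")
  expect_equal(nrow(tab), 3)
})

test_that("tau-b equals the pair-counting oracle on tied random vectors", {
  expect_equal(kendall_tau_b(1:10, 1:10)$tau_b, 1)
  expect_equal(kendall_tau_b(1:10, 10:1)$tau_b, -1)
  set.seed(33)
  for (i in 1:120) {
    n <- sample(5:50, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    r <- kendall_tau_b(x, y)
    expect_equal(r$tau_b, oracle_tau_b(x, y), tolerance = 1e-12)
    # independent library cross-check of the coefficient
    expect_equal(r$tau_b, cor(x, y, method = "kendall"), tolerance = 1e-12)
  }
  expect_error(kendall_tau_b(rep(1, 5), 1:5), "undefined")
})

test_that("tau-b is antisymmetric and monotone-transform invariant", {
  set.seed(44)
  x <- sample(1:8, 40, replace = TRUE)
  y <- sample(1:8, 40, replace = TRUE)
  r <- kendall_tau_b(x, y)
  expect_equal(kendall_tau_b(x, -y)$tau_b, -r$tau_b)
  expect_equal(kendall_tau_b(exp(x), y^3)$tau_b, r$tau_b)
  # p-value agrees with the tie-adjusted normal approximation in
  # stats::cor.test
  expect_equal(r$p_value,
               suppressWarnings(cor.test(x, y, method = "kendall")$p.value),
               tolerance = 1e-9)
})

test_that("use tiers split at 22 and 48 logs", {
  expect_equal(classify_user_use(c(0, 21, 22, 47, 48, 200)),
               c("below_criteria", "below_criteria", "moderate",
                 "moderate", "heavy", "heavy"))
})

test_that("subgroup follow-up means select on final cumulative index", {
  users <- list(fixture_user("a", 70, c("2015-01-01", "2015-03-20"),
                             fiq_level = 4),
                fixture_user("b", 30, c("2015-01-01", "2015-02-01"),
                             fiq_level = 8))
  tab <- build_pooled_table(users)
  hi <- subgroup_followup_mean(tab, "logs", 61)
  expect_equal(hi$n_users, 1)
  expect_equal(hi$fraction_of_sample, 0.5)
  all_users <- subgroup_followup_mean(tab, "logs", 0)
  expect_equal(all_users$n_users, 2)
  expect_equal(all_users$mean_score,
               mean(tab$fiq_score[!tab$is_baseline]))
  none <- subgroup_followup_mean(tab, "logs", 1000)
  expect_equal(none$n_users, 0)
  expect_true(is.na(none$mean_score))
})
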