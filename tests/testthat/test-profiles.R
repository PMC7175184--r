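sig_model <- function(attribute_id, symptom_id, direction, cut_lo, cut_hi,
                      p = 0.01) {
  structure(list(attribute_id = attribute_id, symptom_id = symptom_id,
                 direction = direction, cutpoint = (cut_lo + cut_hi) / 2,
                 cut_lo = cut_lo, cut_hi = cut_hi,
                 sens_improved = 0.9, sens_not_improved = 0.9,
                 mean_sensitivity = 0.9, ess = 80, n_pairs = 30,
                 n_improved = 15, n_not_improved = 15,
                 p_value = p, alpha = 0.05, significant = p <= 0.05),
            class = "cutpoint_model")
}

test_that("the 22-log gate controls eligibility", {
  mk <- function(n) user_record("u", make_logs(
    as.Date("2015-01-01") + seq_len(n) - 1,
    pain = rep(c(2, 7), length.out = n)))
  expect_false(eligible_for_profiles(mk(21)))
  expect_true(eligible_for_profiles(mk(22)))
  expect_false(eligible_for_profiles(
    user_record("u0", make_logs(as.Date(character(0))))))
  expect_error(discover_associations(mk(21)), "gated")
})

test_that("statements render in the canonical template", {
  reg <- register_attribute(default_registry(),
                            attribute_spec("lyrica_mg", "quantity",
                                           units = "mg",
                                           phrase_noun = "dosage of Lyrica"))
  st1 <- render_statement(
    sig_model("bed_time", "pain", "le_improves", 9 + 40 / 60, 10.2), reg)
  expect_equal(st1$text,
               "My pain will improve if my bed time is no later than 9:40 pm")
  st2 <- render_statement(
    sig_model("lyrica_mg", "fatigue", "le_improves", 50, 75), reg)
  expect_equal(st2$text,
    "My fatigue will improve if my dosage of Lyrica is no more than 50 mg")
  st3 <- render_statement(
    sig_model("yoga_minutes", "sleep_difficulties", "ge_improves", 10, 20),
    reg)
  expect_equal(st3$text,
               "My sleep will improve if my yoga is at least 20 minutes")
})

test_that("rendering refuses non-significant or unregistered models", {
  m <- sig_model("bed_time", "pain", "le_improves", 9, 10, p = 0.2)
  expect_error(render_statement(m), "non-significant")
  expect_error(render_statement(
    sig_model("unknown_attr", "pain", "le_improves", 1, 2)), "unregistered")
})

test_that("generated statements parse back to their models", {
  reg <- default_registry()
  set.seed(21)
  for (i in 1:25) {
    a <- sample(names(reg$attributes), 1)
    s <- sample(names(reg$symptoms), 1)
    dir <- sample(c("le_improves", "ge_improves"), 1)
    lo <- round(runif(1, 1, 12), 2)
    st <- render_statement(sig_model(a, s, dir, lo, lo + 1), reg)
    parsed <- parse_statement(st$text)
    expect_false(is.null(parsed))
    expect_equal(parsed$symptom_phrase, unname(reg$symptoms[s]))
    expect_equal(parsed$noun, reg$attributes[[a]]$phrase_noun)
    spec <- reg$attributes[[a]]
    expect_equal(parsed$phrase,
                 if (dir == "le_improves") spec$le_phrase else spec$ge_phrase)
  }
})

test_that("duplicate statements update in place without inflating counts", {
  reg <- default_registry()
  issued <- issue_profiles(list(),
                           list(sig_model("bed_time", "pain",
                                          "le_improves", 9.5, 10)),
                           reg, as.Date("2015-02-01"))
  expect_length(issued, 1)
  # same identity, refreshed threshold: replaced, count unchanged,
  # first-issue date kept
  issued2 <- issue_profiles(issued,
                            list(sig_model("bed_time", "pain",
                                           "le_improves", 9.8, 10.4)),
                            reg, as.Date("2015-03-01"))
  expect_length(issued2, 1)
  expect_equal(issued2[[1]]$issued_at, as.Date("2015-02-01"))
  expect_equal(issued2[[1]]$model$cut_lo, 9.8)
  # a new identity increments the count
  issued3 <- issue_profiles(issued2,
                            list(sig_model("yoga_minutes",
                                           "sleep_difficulties",
                                           "ge_improves", 15, 20)),
                            reg, as.Date("2015-03-01"))
  expect_length(issued3, 2)
})

test_that("discovery finds a planted rule and is seed-reproducible", {
  u <- make_planted_user(n = 60, seed = 3)
  models <- discover_associations(u, seed = 17, reps = 2000)
  expect_gte(length(models), 1)
  top <- models[[1]]
  expect_equal(top$attribute_id, "bed_time")
  expect_equal(top$symptom_id, "pain")
  expect_equal(top$direction, "le_improves")
  # byte-identical rerun under the same seed
  models2 <- discover_associations(u, seed = 17, reps = 2000)
  expect_identical(models, models2)
  # p-values ascending, ESS descending within ties
  ps <- vapply(models, `[[`, 0, "p_value")
  expect_true(all(diff(ps) >= 0))
})

test_that("constant symptoms yield no models rather than errors", {
  n <- 30
  logs <- make_logs(as.Date("2015-01-01") + seq_len(n) - 1,
                    bed_time = rnorm(n, 10, 1), pain = rep(5, n))
  u <- user_record("flat", logs)
  expect_length(discover_associations(u, seed = 1, reps = 500), 0)
})
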