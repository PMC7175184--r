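test_that("validate_entry accepts in-range records and encodes clock times", {
  log <- validate_entry(list(user_id = "u1", date = "2015-03-02",
                             pain = 7, bed_time = "21:40"))
  expect_s3_class(log, "smartlog")
  expect_equal(unname(log$ratings["pain"]), 7)
  expect_equal(unname(log$attributes["bed_time"]), 9 + 40 / 60)
  expect_true(is.na(log$ratings["fatigue"]))  # absent, not imputed
})

test_that("validate_entry rejects out-of-range ratings and unknown fields", {
  expect_error(validate_entry(list(user_id = "u1", date = "2015-03-02",
                                   pain = 11)), "out of range")
  expect_error(validate_entry(list(user_id = "u1", date = "2015-03-02",
                                   pain = 2.5)), "out of range")
  expect_error(validate_entry(list(user_id = "u1", date = "2015-03-02",
                                   caffeine = 3)), "unknown field")
  expect_error(validate_entry(list(user_id = "u1")), "date")
})

test_that("duplicate user-date entries are rejected", {
  logs <- make_logs(c("2015-01-01", "2015-01-01"), pain = c(3, 4))
  expect_error(user_record("u1", logs), "duplicate")
})

test_that("clock-time encoding is anchored at noon and inverts to the minute", {
  expect_equal(encode_time_of_day("21:40"), 9 + 40 / 60)
  expect_equal(encode_time_of_day("12:00"), 0)
  expect_equal(encode_time_of_day("02:00"), 14)
  expect_error(encode_time_of_day("25:00"), "malformed")
  expect_error(encode_time_of_day("9.40pm"), "malformed")

  # format . encode is identity over a grid of minutes
  h <- (0:(24 * 60 - 1)) / 60
  fmt <- format_time_of_day(h)
  expect_equal(encode_time_of_day(sub(" am| pm", "", sapply(
    strsplit(fmt, " "), function(p) {
      hm <- as.numeric(strsplit(p[1], ":")[[1]])
      hh <- hm[1] %% 12 + if (p[2] == "pm") 12 else 0
      sprintf("%02d:%02d", hh, hm[2])
    }))), h)
  expect_equal(format_time_of_day(9 + 40 / 60), "9:40 pm")
  expect_equal(format_time_of_day(14), "2:00 am")
  # strictly monotone over the 24-h window
  expect_true(all(diff(encode_time_of_day(
    sprintf("%02d:%02d", c(12:23, 0:11), 30))) > 0))
})

test_that("paired series pair same-day values and drop missing days", {
  logs <- make_logs(as.Date("2015-01-01") + 0:4,
                    bed_time = c(9.5, NA, 10.5, 11, 8),
                    pain = c(3, 4, NA, 7, 2))
  u <- user_record("u1", logs)
  ps <- extract_paired_series(u, "bed_time", "pain")
  expect_equal(ps$x, c(9.5, 11, 8))
  expect_equal(ps$rating, c(3, 7, 2))
  expect_equal(ps$date, as.Date(c("2015-01-01", "2015-01-04", "2015-01-05")))
  expect_lte(length(ps$x), nrow(logs))

  empty <- user_record("u2", make_logs(as.Date(character(0))))
  expect_length(extract_paired_series(empty, "bed_time", "pain")$x, 0)
  expect_error(extract_paired_series(u, "nope", "pain"), "unknown attribute")
  expect_error(extract_paired_series(u, "bed_time", "nope"), "unknown symptom")
})

test_that("registries are extensible and loadable from config files", {
  reg <- register_attribute(default_registry(),
                            attribute_spec("lyrica_mg", "quantity",
                                           units = "mg",
                                           phrase_noun = "dosage of Lyrica"))
  expect_true("lyrica_mg" %in% names(reg$attributes))
  expect_equal(reg$attributes$lyrica_mg$le_phrase, "no more than")

  cfg <- list(symptoms = list(pain = "pain"),
              attributes = list(list(attribute_id = "bed_time",
                                     kind = "time_of_day",
                                     phrase_noun = "bed time")))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  reg2 <- read_registry(path)
  expect_equal(names(reg2$attributes), "bed_time")
  expect_equal(reg2$attributes$bed_time$le_phrase, "no later than")
})
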