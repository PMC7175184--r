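# File dialects: UTF-8 CSV, ISO-8601 dates, empty string as the NA
# token. Diary rows are one user-date each; clock-time attributes are
# stored on the numeric hours-after-noon scale but "HH:MM" strings are
# accepted on input. Profiles travel as JSON-lines (append-friendly).

.FIQ_COLS <- c("user_id", "administered_at", paste0("phys_", 1:11),
               "feel_good_days", "missed_work_days",
               "vas_work", "vas_pain", "vas_fatigue", "vas_morning",
               "vas_stiffness", "vas_anxiety", "vas_depression",
               "works_outside_home")

#' Write diary logs for a set of users to CSV
#'
#' @param users list of `user_record`s.
#' @param path output path.
#' @export
write_diary_csv <- function(users, path) {
  rows <- do.call(rbind, lapply(users, function(u) {
    df <- u$logs
    cbind(data.frame(user_id = u$user_id,
                     date = format(df$date, "%Y-%m-%d")),
          df[setdiff(names(df), "date")])
  }))
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write FIQ administrations for a set of users to CSV
#'
#' @inheritParams write_diary_csv
#' @export
write_fiq_csv <- function(users, path) {
  rows <- do.call(rbind, lapply(users, function(u) {
    if (!length(u$fiq)) return(NULL)
    do.call(rbind, lapply(u$fiq, function(f) {
      df <- data.frame(user_id = u$user_id,
                       administered_at = format(f$administered_at, "%Y-%m-%d"))
      df[paste0("phys_", 1:11)] <- as.list(f$physical_items)
      df$feel_good_days <- f$feel_good_days
      df$missed_work_days <- f$missed_work_days
      df[.FIQ_COLS[16:22]] <- as.list(f$vas)
      df$works_outside_home <- f$works_outside_home
      df
    }))
  }))
  if (is.null(rows)) rows <- as.data.frame(
    setNames(rep(list(character(0)), length(.FIQ_COLS)), .FIQ_COLS))
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write issued profile statements as JSON-lines
#'
#' One JSON object per line with the statement text, issue date and
#' the full fitted-model record.
#'
#' @inheritParams write_diary_csv
#' @export
write_profiles_jsonl <- function(users, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (u in users) for (p in u$profiles) {
    m <- p$model
    rec <- list(user_id = u$user_id, issued_at = format(p$issued_at),
                text = p$text, key = p$key,
                attribute_id = m$attribute_id, symptom_id = m$symptom_id,
                direction = m$direction, cutpoint = m$cutpoint,
                cut_lo = m$cut_lo, cut_hi = m$cut_hi,
                sens_improved = m$sens_improved,
                sens_not_improved = m$sens_not_improved,
                mean_sensitivity = m$mean_sensitivity, ess = m$ess,
                n_pairs = m$n_pairs, p_value = m$p_value,
                alpha = m$alpha, significant = m$significant)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read user records from diary and FIQ files
#'
#' Parses and validates the documented CSV dialects into
#' `user_record`s. Row-level validation failures are collected and
#' reported together with their line numbers; unknown diary columns
#' are a schema error naming the offending columns.
#'
#' @param diary_csv path to the diary CSV.
#' @param fiq_csv optional path to the FIQ CSV; an empty file yields
#'   users with zero FIQs and a warning.
#' @param profiles_jsonl optional path to a profiles JSON-lines file.
#' @param registry a `diary_registry`.
#' @return named list of `user_record`s.
#' @export
read_user_records <- function(diary_csv, fiq_csv = NULL,
                              profiles_jsonl = NULL,
                              registry = default_registry()) {
  df <- read.csv(diary_csv, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("user_id", "date")
  if (!all(needed %in% names(df)))
    stop("diary schema error: missing column(s) ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  known <- c(needed, names(registry$symptoms), names(registry$attributes))
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    stop("diary schema error: unknown column(s) not in registry: ",
         paste(unknown, collapse = ", "))
  errors <- character(0)
  logs_by_user <- list()
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(validate_entry(as.list(df[i, , drop = FALSE]), registry),
                    error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      errors <- c(errors, sprintf("row %d: %s", i + 1L, rec))  # +1 header
      next
    }
    uid <- rec$user_id
    logs_by_user[[uid]] <- c(logs_by_user[[uid]], list(rec))
  }
  if (length(errors))
    stop("diary validation failed:\n", paste(errors, collapse = "\n"))

  fiq_by_user <- list()
  if (!is.null(fiq_csv)) {
    fdf <- read.csv(fiq_csv, stringsAsFactors = FALSE, check.names = FALSE)
    if (!nrow(fdf)) {
      warning("FIQ file is empty; users loaded with zero FIQs")
    } else {
      miss <- setdiff(.FIQ_COLS, names(fdf))
      if (length(miss))
        stop("FIQ schema error: missing column(s) ",
             paste(miss, collapse = ", "))
      for (i in seq_len(nrow(fdf))) {
        r <- fdf[i, ]
        resp <- fiq_response(
          physical_items = as.numeric(r[paste0("phys_", 1:11)]),
          feel_good_days = r$feel_good_days,
          missed_work_days = r$missed_work_days,
          vas = as.numeric(r[.FIQ_COLS[16:22]]),
          works_outside_home = as.logical(r$works_outside_home),
          administered_at = as.Date(r$administered_at))
        uid <- as.character(r$user_id)
        fiq_by_user[[uid]] <- c(fiq_by_user[[uid]], list(resp))
      }
    }
  }

  prof_by_user <- list()
  if (!is.null(profiles_jsonl)) {
    lines <- readLines(profiles_jsonl, encoding = "UTF-8")
    for (ln in lines[nzchar(lines)]) {
      rec <- jsonlite::fromJSON(ln)
      m <- structure(rec[c("attribute_id", "symptom_id", "direction",
                           "cutpoint", "cut_lo", "cut_hi",
                           "sens_improved", "sens_not_improved",
                           "mean_sensitivity", "ess", "n_pairs",
                           "p_value", "alpha", "significant")],
                     class = "cutpoint_model")
      st <- structure(list(text = rec$text, key = rec$key, model = m,
                           issued_at = as.Date(rec$issued_at),
                           user_id = rec$user_id),
                      class = "profile_statement")
      uid <- as.character(rec$user_id)
      prof_by_user[[uid]] <- c(prof_by_user[[uid]], list(st))
    }
  }

  uids <- unique(c(names(logs_by_user), names(fiq_by_user)))
  out <- lapply(uids, function(uid)
    user_record(uid, logs_by_user[[uid]] %||%
                  data.frame(date = as.Date(character(0))),
                fiq = fiq_by_user[[uid]] %||% list(),
                profiles = prof_by_user[[uid]] %||% list(),
                registry = registry))
  names(out) <- uids
  out
}

#' Run the end-to-end pipeline
#'
#' Executes (optionally) cohort simulation, per-user association
#' discovery, profile issuance, and longitudinal evaluation, writing
#' all artifacts plus a run manifest to `out_dir`. Re-running with the
#' same configuration and seed reproduces byte-identical primary
#' outputs and the same manifest hash.
#'
#' @param config list (or path to a YAML file) with fields:
#'   `seed` (required), `out_dir`, and either `simulate` (a list of
#'   [cohort_params()] arguments) or `diary_csv`/`fiq_csv` paths;
#'   optional `alpha`, `min_logs`, `perm` (list with `method`, `reps`).
#' @return invisibly, a list with the users, discovered models, pooled
#'   table, tau results and manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed))
    stop("config error: a seed is required (Monte Carlo permutations)")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- config$alpha %||% 0.05
  min_logs <- config$min_logs %||% 22
  method <- config$perm$method %||% "auto"
  reps <- config$perm$reps %||% 10000
  registry <- if (!is.null(config$registry)) read_registry(config$registry)
              else default_registry()

  if (!is.null(config$simulate)) {
    pars <- do.call(cohort_params,
                    modifyList(config$simulate, list(seed = config$seed)))
    cohort <- simulate_cohort(pars)
    users <- cohort$users
    write_diary_csv(users, file.path(out_dir, "diary.csv"))
    write_fiq_csv(users, file.path(out_dir, "fiq.csv"))
    jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    users <- read_user_records(config$diary_csv, config$fiq_csv,
                               config$profiles_jsonl, registry)
    # discover and issue profiles for eligible users
    seeds <- .with_seed(config$seed,
                        sample.int(2^31 - 2, length(users)))
    for (i in seq_along(users)) {
      u <- users[[i]]
      if (!eligible_for_profiles(u, min_logs)) next
      models <- discover_associations(u, alpha = alpha,
                                      min_logs = min_logs,
                                      method = method, reps = reps,
                                      seed = seeds[i])
      last <- max(u$logs$date)
      users[[i]]$profiles <- issue_profiles(u$profiles, models,
                                            u$registry, last)
    }
  }
  write_profiles_jsonl(users, file.path(out_dir, "profiles.jsonl"))

  pooled <- build_pooled_table(users)
  write.csv(pooled, file.path(out_dir, "pooled.csv"), row.names = FALSE)
  tau <- list(
    cum_logs = unclass(kendall_tau_b(pooled$cum_logs, pooled$fiq_score)),
    cum_profiles = if (length(unique(pooled$cum_profiles)) > 1)
      unclass(kendall_tau_b(pooled$cum_profiles, pooled$fiq_score))
    else NULL)
  jsonlite::write_json(tau, file.path(out_dir, "tau.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(seed = config$seed,
                   package = "nof1oda",
                   version = as.character(utils::packageVersion("nof1oda")),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   n_users = length(users),
                   n_fiq_rows = nrow(pooled))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(users = users, pooled = pooled, tau = tau,
                 manifest = manifest))
}
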