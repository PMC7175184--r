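#' Dichotomize a symptom rating series
#'
#' Splits a 0-10 rating series into two classes for cutpoint modelling:
#' a day is labelled *improved* when its rating falls strictly below
#' the series median; days at or above the median (including ties at
#' the median) are *not improved*. The split is scale-free and tends
#' to balance the classes.
#'
#' @param ratings integer vector of 0-10 ratings (at least two distinct
#'   values required).
#' @return list with `improved` (logical vector aligned to input),
#'   `n_improved`, `n_not_improved`, `median`.
#' @export
dichotomize_outcome <- function(ratings) {
  ratings <- as.numeric(ratings)
  if (length(unique(ratings[!is.na(ratings)])) < 2)
    stop("degenerate outcome: fewer than two distinct rating values")
  med <- stats::median(ratings)
  improved <- ratings < med
  list(improved = improved,
       n_improved = sum(improved),
       n_not_improved = sum(!improved),
       median = med)
}

#' Candidate cutpoints of an ordered attribute
#'
#' Midpoints between consecutive distinct sorted values; `k` distinct
#' values yield `k - 1` candidates.
#'
#' @param x numeric attribute values (at least two distinct).
#' @return numeric vector of candidate cutpoints.
#' @export
enumerate_cutpoints <- function(x) {
  u <- sort(unique(as.numeric(x)))
  if (length(u) < 2)
    stop("no candidate cutpoints: fewer than two distinct attribute values")
  (u[-1] + u[-length(u)]) / 2
}

# Shared preparation for the C++ core: labels aligned to sorted x and
# the 1-based boundary positions between distinct sorted values.
.oda_prep <- function(x, improved) {
  ord <- order(x)
  xs <- x[ord]
  list(lab = as.integer(improved[ord]),
       bounds = as.integer(which(diff(xs) > 0)),
       xs = xs)
}

#' Fit the maximum-accuracy cutpoint model
#'
#' Exhaustively scores every candidate cutpoint in both directions
#' (*le*: improvement predicted when the attribute is at or below the
#' cut; *ge*: the mirror) and returns the rule maximizing the mean of
#' the two per-class sensitivities (class-balanced accuracy, the
#' weighted ODA objective). Ties are broken toward the smaller cutpoint
#' and, at the same cutpoint, toward the *le* direction. The effect
#' strength for sensitivity is `ESS = 100 * (mean_sens - 0.5) / 0.5`.
#'
#' @param x numeric attribute values.
#' @param improved logical class labels aligned to `x` (TRUE =
#'   improved), e.g. from [dichotomize_outcome()].
#' @param min_per_class minimum members required in each class
#'   (default 5); below it no model is attempted.
#' @param attribute_id,symptom_id optional ids carried on the model.
#' @return object of class `cutpoint_model` with fields `direction`
#'   (`"le_improves"`/`"ge_improves"`), `cutpoint`, `cut_lo`/`cut_hi`
#'   (the observed values bracketing it), per-class sensitivities,
#'   `mean_sensitivity`, `ess`, `n_pairs`; `p_value`/`significant` are
#'   `NA` until [permutation_p_value()] is attached.
#' @export
fit_cutpoint_model <- function(x, improved, min_per_class = 5,
                               attribute_id = NA_character_,
                               symptom_id = NA_character_) {
  x <- as.numeric(x)
  improved <- as.logical(improved)
  stopifnot(length(x) == length(improved), !anyNA(x), !anyNA(improved))
  n1 <- sum(improved); n0 <- sum(!improved)
  if (n1 < min_per_class || n0 < min_per_class)
    stop("insufficient class size: need at least ", min_per_class,
         " per class (got ", n1, " improved, ", n0, " not improved)")
  if (length(unique(x)) < 2)
    stop("no candidate cutpoints: fewer than two distinct attribute values")
  prep <- .oda_prep(x, improved)
  fit <- oda_fit_cpp(prep$lab, prep$bounds)
  b <- fit$bound_index
  cut_lo <- prep$xs[prep$bounds[b]]
  cut_hi <- prep$xs[prep$bounds[b] + 1]
  structure(list(
    attribute_id = attribute_id, symptom_id = symptom_id,
    direction = if (fit$direction == 0) "le_improves" else "ge_improves",
    cutpoint = (cut_lo + cut_hi) / 2,
    cut_lo = cut_lo, cut_hi = cut_hi,
    sens_improved = fit$sens_improved,
    sens_not_improved = fit$sens_not_improved,
    mean_sensitivity = fit$mean_sensitivity,
    ess = max(0, min(100, 100 * (fit$mean_sensitivity - 0.5) / 0.5)),
    n_pairs = length(x), n_improved = n1, n_not_improved = n0,
    p_value = NA_real_, alpha = NA_real_, significant = NA),
    class = "cutpoint_model")
}

#' @export
print.cutpoint_model <- function(x, ...) {
  cat(sprintf(
    "<cutpoint_model> %s ~ %s %s %.4g | mean sens %.3f, ESS %.1f, n %d, p %s\n",
    x$symptom_id, x$attribute_id,
    if (x$direction == "le_improves") "<=" else ">=",
    x$cutpoint, x$mean_sensitivity, x$ess, x$n_pairs,
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3)))
  invisible(x)
}

# enumeration bound for the exact permutation method
.EXACT_BOUND <- 200000

#' Permutation p-value for a cutpoint model
#'
#' The test statistic is the best achievable mean sensitivity over all
#' cutpoint rules. The p-value is the proportion of class-label
#' assignments (preserving class sizes) whose best statistic reaches
#' the observed one. `"exact"` enumerates all distinct assignments and
#' is allowed when `choose(n, n_improved) <= 200000`; `"monte_carlo"`
#' resamples label permutations (p includes the observed arrangement in
#' numerator and denominator, so p is never 0). `"auto"` picks exact
#' when feasible.
#'
#' @param x numeric attribute values.
#' @param improved logical class labels aligned to `x`.
#' @param method `"auto"`, `"exact"` or `"monte_carlo"`.
#' @param reps Monte Carlo replicates (default 10000).
#' @param seed optional integer; when given, the RNG state is set for
#'   the call and restored afterwards, making the result a pure
#'   function of `(x, improved, method, reps, seed)`.
#' @return p-value in (0, 1].
#' @export
permutation_p_value <- function(x, improved,
                                method = c("auto", "exact", "monte_carlo"),
                                reps = 10000, seed = NULL) {
  method <- match.arg(method)
  x <- as.numeric(x)
  improved <- as.logical(improved)
  n <- length(x); n1 <- sum(improved)
  stopifnot(n == length(improved), n1 > 0, n1 < n)
  feasible <- choose(n, n1) <= .EXACT_BOUND
  if (method == "exact" && !feasible)
    stop("exact method too large: choose(n, n_improved) exceeds ",
         .EXACT_BOUND, "; use monte_carlo")
  if (method == "auto") method <- if (feasible) "exact" else "monte_carlo"
  prep <- .oda_prep(x, improved)
  obs <- oda_fit_cpp(prep$lab, prep$bounds)$mean_sensitivity
  if (method == "exact")
    return(oda_perm_exact_cpp(prep$lab, prep$bounds, obs))
  run <- function() oda_perm_mc_cpp(prep$lab, prep$bounds, obs, as.integer(reps))
  if (is.null(seed)) run() else .with_seed(seed, run())
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Fit and test one attribute-symptom cutpoint model
#'
#' Convenience wrapper: dichotomize the ratings, fit the
#' maximum-accuracy rule, attach a permutation p-value, and flag
#' significance at `alpha`.
#'
#' @inheritParams fit_cutpoint_model
#' @inheritParams permutation_p_value
#' @param ratings 0-10 symptom ratings paired with `x`.
#' @param alpha per-test significance level (default 0.05).
#' @return a `cutpoint_model` with `p_value` and `significant` filled.
#' @export
oda_test <- function(x, ratings, alpha = 0.05, min_per_class = 5,
                     method = "auto", reps = 10000, seed = NULL,
                     attribute_id = NA_character_,
                     symptom_id = NA_character_) {
  labels <- dichotomize_outcome(ratings)
  model <- fit_cutpoint_model(x, labels$improved, min_per_class,
                              attribute_id = attribute_id,
                              symptom_id = symptom_id)
  model$p_value <- permutation_p_value(x, labels$improved, method = method,
                                       reps = reps, seed = seed)
  model$alpha <- alpha
  model$significant <- model$p_value <= alpha
  model
}
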