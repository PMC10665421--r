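# Cohort resampling: effect-size statistics and the two trial-simulation
# procedures. Algorithm A searches a fixed avatar population for a pair of
# disjoint trial cohorts that differ significantly (two-sample t-test) and
# relevantly (|Cohen's d| above a threshold) in one anthropometric
# parameter. Algorithm B tabulates, over a large metadata-only population,
# the mean number of cohort-pair draws needed until such a pair occurs, as
# a function of trial size and d threshold.

# draw k of n without replacement; hash algorithm avoids the O(n)
# permutation buffer, which dominates when n is a 10^5..10^6 population
draw_idx <- function(n, k) {
  if (2L * k <= n) sample.int(n, k, useHash = TRUE) else sample.int(n, k)
}

# pooled two-sample statistics from raw samples; sp2 may be 0
pair_stats <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  v1 <- sum((x - m1)^2) / (n1 - 1)
  v2 <- sum((y - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  list(n1 = n1, n2 = n2, m1 = m1, m2 = m2, s1 = sqrt(v1), s2 = sqrt(v2),
       sp = sqrt(sp2))
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_p` with
#' `s_p = sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`. Thresholding in
#' the cohort algorithms uses the magnitude `|d|`.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return Signed Cohen's d.
#' @export
#' @examples
#' cohens_d(c(1, 2, 3), c(4, 5, 6)) # -3
cohens_d <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  s <- pair_stats(x, y)
  if (s$sp == 0) stop("pooled standard deviation is zero", call. = FALSE)
  (s$m1 - s$m2) / s$sp
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with `n1 + n2 - 2` degrees of freedom and two-sided
#' p-value. The identity `t = d * sqrt(n1 n2 / (n1 + n2))` with Cohen's d
#' holds exactly (for equal sizes n per group, `t = d * sqrt(n / 2)`),
#' which is why a d threshold translates into a t threshold in the cohort
#' algorithms. A Welch variant is available for sensitivity checks.
#'
#' @param x,y numeric samples, each of size >= 2, pooled SD > 0.
#' @param welch if `TRUE`, use the Welch statistic and
#'   Welch-Satterthwaite degrees of freedom instead.
#' @return A list with `t`, `p`, `df`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  s <- pair_stats(x, y)
  if (welch) {
    se2 <- s$s1^2 / s$n1 + s$s2^2 / s$n2
    if (se2 == 0) stop("zero variance in both samples", call. = FALSE)
    t <- (s$m1 - s$m2) / sqrt(se2)
    df <- se2^2 / (s$s1^4 / (s$n1^2 * (s$n1 - 1)) +
                     s$s2^4 / (s$n2^2 * (s$n2 - 1)))
  } else {
    if (s$sp == 0) stop("pooled standard deviation is zero", call. = FALSE)
    t <- (s$m1 - s$m2) / (s$sp * sqrt(1 / s$n1 + 1 / s$n2))
    df <- s$n1 + s$n2 - 2
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df = df), df = df)
}

#' Algorithm A: search for a significantly and relevantly different cohort pair
#'
#' Repeatedly draws two disjoint simple-random cohorts of size
#' `cohort_size` from the avatar population and stops at the first
#' iteration whose two-sample t-test gives `p < alpha` **and**
#' `|Cohen's d| >= d_min` on the chosen anthropometric parameter.
#' Downstream, the correlation battery can be rerun per cohort via
#' `correlation_battery(..., subset_ids = )`.
#'
#' By default both cohorts are drawn from the whole population (the
#' trial-recruitment semantics). For validating the stopping rule against
#' a known effect, `strata` may supply a two-level grouping: cohort 1 is
#' then drawn from the first level and cohort 2 from the second, so a
#' planted between-group difference is seen by every draw.
#'
#' Non-termination is an explicit, reported outcome: if `max_iter` is
#' reached the result carries `converged = FALSE` (with a warning), never
#' an infinite loop or a silent error.
#'
#' @param avatars avatar data.frame from [generate_population()].
#' @param parameter one of `"bmi"` (default), `"weight"`, `"height"`,
#'   `"tibia_length"`.
#' @param cohort_size avatars per cohort (default 30).
#' @param d_min Cohen's d stopping threshold (default 0.9).
#' @param alpha t-test significance level (default 0.05).
#' @param max_iter iteration cap.
#' @param strata optional two-level factor/vector over avatars selecting
#'   the source stratum of each cohort.
#' @param seed optional seed (drawn through the `algorithm_a` stream).
#' @return A `cohort_pair_result` list: `iteration_found`, `parameter`,
#'   `cohort1_ids`, `cohort2_ids`, per-cohort means/SDs, `t`, `p`, `d`,
#'   `converged`.
#' @export
algorithm_a <- function(avatars,
                        parameter = c("bmi", "weight", "height",
                                      "tibia_length"),
                        cohort_size = 30L, d_min = 0.9, alpha = 0.05,
                        max_iter = 10000L, strata = NULL, seed = NULL) {
  parameter <- match.arg(parameter)
  values <- avatars[[parameter_columns[[parameter]]]]
  n <- as.integer(cohort_size)
  if (!is.null(seed)) set.seed(stream_seed(seed, "algorithm_a"))
  if (is.null(strata)) {
    if (length(values) < 2L * n) {
      stop("population smaller than two disjoint cohorts", call. = FALSE)
    }
    pool1 <- pool2 <- NULL
  } else {
    lev <- unique(strata)
    if (length(lev) != 2L) stop("strata must have two levels", call. = FALSE)
    pool1 <- which(strata == lev[1L])
    pool2 <- which(strata == lev[2L])
    if (length(pool1) < n || length(pool2) < n) {
      stop("each stratum must hold at least one cohort", call. = FALSE)
    }
  }
  for (it in seq_len(max_iter)) {
    if (is.null(strata)) {
      idx <- draw_idx(length(values), 2L * n)
      i1 <- idx[seq_len(n)]
      i2 <- idx[(n + 1L):(2L * n)]
    } else {
      i1 <- pool1[draw_idx(length(pool1), n)]
      i2 <- pool2[draw_idx(length(pool2), n)]
    }
    s <- pair_stats(values[i1], values[i2])
    if (s$sp == 0) next  # degenerate draw can never satisfy the rule
    d <- (s$m1 - s$m2) / s$sp
    t <- d * sqrt(n * n / (2 * n))
    p <- 2 * stats::pt(-abs(t), df = 2 * n - 2)
    if (p < alpha && abs(d) >= d_min) {
      return(structure(list(
        iteration_found = it, parameter = parameter,
        cohort1_ids = avatars$id[i1], cohort2_ids = avatars$id[i2],
        mean1 = s$m1, mean2 = s$m2, sd1 = s$s1, sd2 = s$s2,
        t = t, p = p, d = d, converged = TRUE,
        cohort_size = n, d_min = d_min, alpha = alpha
      ), class = "cohort_pair_result"))
    }
  }
  warning(sprintf(
    "no cohort pair with p < %g and |d| >= %g found in %d iterations",
    alpha, d_min, max_iter), call. = FALSE)
  structure(list(
    iteration_found = NA_integer_, parameter = parameter,
    cohort1_ids = NULL, cohort2_ids = NULL,
    mean1 = NA_real_, mean2 = NA_real_, sd1 = NA_real_, sd2 = NA_real_,
    t = NA_real_, p = NA_real_, d = NA_real_, converged = FALSE,
    cohort_size = n, d_min = d_min, alpha = alpha,
    max_iter = as.integer(max_iter)
  ), class = "cohort_pair_result")
}

#' @export
print.cohort_pair_result <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "Cohort pair on '%s' after %d iteration(s): d = %.3f, t = %.3f, p = %.3g\n",
      x$parameter, x$iteration_found, x$d, x$t, x$p))
    cat(sprintf("  cohort means %.3f vs %.3f (n = %d each)\n",
                x$mean1, x$mean2, x$cohort_size))
  } else {
    cat(sprintf(
      "No qualifying cohort pair on '%s' within %d iterations (|d| >= %g, p < %g)\n",
      x$parameter, x$max_iter, x$d_min, x$alpha))
  }
  invisible(x)
}

#' Algorithm B: mean draws until two trial cohorts differ
#'
#' For each trial size, repeatedly draws fresh disjoint cohort pairs from
#' a large metadata population and records, for every Cohen's d threshold
#' in `d_grid`, the first iteration at which the pair is significantly
#' (`p < alpha`) and relevantly (`|d| >=` threshold) different. Each of
#' the `repeats` runs consumes one stream of pair draws shared across the
#' whole d grid (common random numbers), so the recorded iteration counts
#' are pathwise non-decreasing in the threshold; the mean and SD over
#' repeats are reported per (trial size, threshold). Runs that hit
#' `max_iter` before satisfying a threshold are counted as censored for
#' that threshold and excluded from the mean.
#'
#' @param values numeric vector: one anthropometric parameter over the
#'   metadata population (e.g. BMI of 10^6 subjects).
#' @param trial_sizes subjects per cohort (default 10 to 60 in steps of 10).
#' @param d_grid Cohen's d thresholds (default 0.5 to 0.9 in steps of 0.1).
#' @param repeats independent runs per cell (default 100).
#' @param alpha significance level of the two-sample t-test.
#' @param max_iter per-run iteration cap.
#' @param parameter optional label copied into the output.
#' @param seed optional seed (drawn through the `algorithm_b` stream).
#' @return A data.frame with columns `parameter`, `trial_size`,
#'   `d_threshold`, `mean_iterations`, `sd_iterations`, `repeats`,
#'   `censored_runs`.
#' @export
algorithm_b <- function(values,
                        trial_sizes = seq(10L, 60L, by = 10L),
                        d_grid = seq(0.5, 0.9, by = 0.1),
                        repeats = 100L, alpha = 0.05, max_iter = 1e6,
                        parameter = NA_character_, seed = NULL) {
  n_pop <- length(values)
  if (n_pop < 2L * max(trial_sizes)) {
    stop("metadata population smaller than two cohorts of the largest size",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(stream_seed(seed, "algorithm_b"))
  d_grid <- sort(d_grid)
  nd <- length(d_grid)
  out <- vector("list", length(trial_sizes))
  for (si in seq_along(trial_sizes)) {
    n <- as.integer(trial_sizes[si])
    t_factor <- sqrt(n / 2)         # |t| = |d| * sqrt(n/2) for equal sizes
    df <- 2L * n - 2L
    t_crit <- stats::qt(1 - alpha / 2, df)
    stops <- matrix(NA_real_, nrow = repeats, ncol = nd)
    for (rep_i in seq_len(repeats)) {
      found <- rep(FALSE, nd)
      it <- 0
      while (!all(found) && it < max_iter) {
        it <- it + 1
        idx <- draw_idx(n_pop, 2L * n)
        s <- pair_stats(values[idx[seq_len(n)]],
                        values[idx[(n + 1L):(2L * n)]])
        if (s$sp == 0) next
        absd <- abs(s$m1 - s$m2) / s$sp
        if (absd * t_factor < t_crit) next  # not even significant
        newly <- !found & d_grid <= absd
        if (any(newly)) {
          stops[rep_i, newly] <- it
          found <- found | newly
        }
      }
    }
    out[[si]] <- data.frame(
      parameter = parameter,
      trial_size = n,
      d_threshold = d_grid,
      mean_iterations = colMeans(stops, na.rm = TRUE),
      sd_iterations = apply(stops, 2L, stats::sd, na.rm = TRUE),
      repeats = as.integer(repeats),
      censored_runs = as.integer(colSums(is.na(stops)))
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
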