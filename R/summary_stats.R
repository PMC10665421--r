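# Descriptive statistics of invariant fields and the anthropometry vs
# mechanics correlation/regression battery.

#' Six-statistic summary of an invariant field
#'
#' Mean, median, interquartile range, median absolute deviation and the
#' 90th/95th percentiles of a vector of cell values. Quantiles use linear
#' interpolation between order statistics (the common type-7 rule), the
#' MAD is unscaled (`median(|x - median|)`, no 1.4826 factor). Cell-area
#' weights are optional and off by default (fields are summarized per
#' mesh cell, unweighted); when given, mean and quantiles are
#' area-weighted.
#'
#' @param values numeric vector, non-empty and finite.
#' @param weights optional non-negative weights (e.g. cell areas).
#' @return Named numeric vector `mean, median, iqr, mad, p90, p95`.
#' @export
#' @examples
#' summarize_field(c(1, 2, 3, 4, 5))
summarize_field <- function(values, weights = NULL) {
  if (length(values) == 0L) stop("empty value vector", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (is.null(weights)) {
    qs <- stats::quantile(values, c(0.25, 0.5, 0.75, 0.9, 0.95),
                          names = FALSE, type = 7)
    med <- qs[2L]
    c(mean = mean(values), median = med, iqr = qs[3L] - qs[1L],
      mad = stats::median(abs(values - med)), p90 = qs[4L], p95 = qs[5L])
  } else {
    if (length(weights) != length(values) || any(weights < 0)) {
      stop("weights must be non-negative and match values", call. = FALSE)
    }
    qs <- weighted_quantile(values, weights, c(0.25, 0.5, 0.75, 0.9, 0.95))
    med <- qs[2L]
    c(mean = sum(values * weights) / sum(weights), median = med,
      iqr = qs[3L] - qs[1L],
      mad = weighted_quantile(abs(values - med), weights, 0.5),
      p90 = qs[4L], p95 = qs[5L])
  }
}

# weighted quantile by linear interpolation of the cumulative weight
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Two-sided Pearson correlation test
#'
#' Sample Pearson r with the two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, neither constant.
#' @return A list with elements `r`, `p`, `n`.
#' @export
#' @examples
#' pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
pearson_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (1 - r^2 < .Machine$double.eps) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Simple linear regression
#'
#' Ordinary least squares `y ~ x` via [stats::lm()]; the reported
#' r-squared equals the squared Pearson correlation.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, `x` not constant.
#' @return A list with `slope`, `intercept`, `r_squared`.
#' @export
linear_regression <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("x must not be constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       r_squared = if (tss == 0) NA_real_ else 1 - rss / tss)
}

# anthropometric parameter label -> avatar column
parameter_columns <- c(
  weight = "weight_kg",
  height = "height_m",
  bmi = "bmi",
  tibia_length = "tibia_length_mm"
)

#' Anthropometry vs mechanics correlation battery
#'
#' For every landmark x region x invariant x anthropometric parameter,
#' the Pearson correlation between the avatar-level summary statistic of
#' the invariant (the median by default, matching the reported analysis;
#' the other five statistics are available) and the parameter. With five
#' landmarks, two regions, four invariants and four parameters the table
#' has 160 rows. Correlations are flagged as significant at the 0.01
#' level (two-sided).
#'
#' @param summaries invariant summary table from [run_pipeline()] /
#'   [simulate_avatar_strains()] (one row per avatar x landmark x region
#'   x quantity).
#' @param avatars the avatar table the summaries were computed from.
#' @param statistic which summary statistic enters the correlation
#'   (`"median"` by default).
#' @param subset_ids optional avatar ids restricting the battery to a
#'   cohort (used for per-cohort reruns after a cohort search).
#' @return A data.frame with columns `parameter`, `landmark`, `region`,
#'   `quantity`, `r`, `p`, `n`, `significant_0p01`.
#' @export
correlation_battery <- function(summaries, avatars, statistic = "median",
                                subset_ids = NULL) {
  if (!statistic %in% c("mean", "median", "iqr", "mad", "p90", "p95")) {
    stop("unknown summary statistic: ", statistic, call. = FALSE)
  }
  if (!is.null(subset_ids)) {
    avatars <- avatars[avatars$id %in% subset_ids, , drop = FALSE]
    summaries <- summaries[summaries$avatar_id %in% subset_ids, , drop = FALSE]
  }
  if (nrow(avatars) < 3L) {
    stop("need at least 3 avatars with complete summaries", call. = FALSE)
  }
  landmarks <- unique(summaries$landmark)
  regions <- unique(summaries$region)
  quantities <- unique(summaries$quantity)
  rows <- vector("list",
                 length(parameter_columns) * length(landmarks) *
                   length(regions) * length(quantities))
  k <- 0L
  for (lm_id in landmarks) {
    sub_l <- summaries[summaries$landmark == lm_id, , drop = FALSE]
    for (reg in regions) {
      sub_r <- sub_l[sub_l$region == reg, , drop = FALSE]
      for (qt in quantities) {
        sub <- sub_r[sub_r$quantity == qt, , drop = FALSE]
        stat <- sub[[statistic]][match(avatars$id, sub$avatar_id)]
        if (any(is.na(stat))) {
          stop("incomplete summaries for landmark ", lm_id, call. = FALSE)
        }
        for (par in names(parameter_columns)) {
          ct <- pearson_correlation(avatars[[parameter_columns[[par]]]], stat)
          k <- k + 1L
          rows[[k]] <- data.frame(
            parameter = par, landmark = lm_id, region = reg, quantity = qt,
            r = ct$r, p = ct$p, n = ct$n,
            significant_0p01 = ct$p < 0.01
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
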