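# Avatar population synthesis: age-stratified truncated normal draws of
# height and BMI, with weight and tibia length derived per subject.

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampling from the normal(mean, sd) law restricted to
#' \[lo, hi\]. With `sd = 0` the distribution is degenerate at `mean`, which
#' must then lie inside the interval. Uses the current RNG state; seed with
#' `set.seed()` (the pipeline does this through named seed streams).
#'
#' @param n number of draws.
#' @param mean,sd normal parameters; recycled to length `n`. `sd >= 0`.
#' @param lo,hi truncation bounds, `lo < hi`.
#' @return Numeric vector of length `n`, all values in `[lo, hi]`.
#' @export
#' @examples
#' set.seed(1)
#' sample_truncated(5, mean = 26, sd = 3.5, lo = 18, hi = 35)
sample_truncated <- function(n, mean, sd, lo, hi) {
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  if (!(lo < hi)) stop("truncation bounds must satisfy lo < hi", call. = FALSE)
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  degen <- sd == 0
  if (any(degen)) {
    bad <- mean[degen] < lo | mean[degen] > hi
    if (any(bad)) {
      stop("degenerate (sd = 0) distribution lies outside [lo, hi]",
           call. = FALSE)
    }
    out[degen] <- mean[degen]
  }
  if (any(!degen)) {
    m <- mean[!degen]; s <- sd[!degen]
    a <- stats::pnorm(lo, m, s)
    b <- stats::pnorm(hi, m, s)
    if (any(b - a < 1e-12)) {
      stop("truncation interval carries numerically zero probability mass",
           call. = FALSE)
    }
    u <- stats::runif(sum(!degen))
    out[!degen] <- stats::qnorm(a + u * (b - a), m, s)
  }
  pmin(pmax(out, lo), hi)
}

#' Body weight from BMI and height
#'
#' @param bmi body mass index in kg/m^2.
#' @param height body height in m.
#' @return Weight in kg, `bmi * height^2`.
#' @export
#' @examples
#' derive_weight(24.81, 1.79) # ~79.5 kg
derive_weight <- function(bmi, height) {
  if (any(bmi <= 0) || any(height <= 0)) {
    stop("bmi and height must be positive", call. = FALSE)
  }
  bmi * height^2
}

#' Body mass index from weight and height
#'
#' Inverse of [derive_weight()].
#'
#' @param weight body weight in kg.
#' @param height body height in m.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' compute_bmi(79.5, 1.79) # ~24.81
compute_bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  weight / height^2
}

#' Tibia length from body height and age group
#'
#' Linear stature-to-tibia relation of the forensic type,
#' `length_cm = (height_cm - intercept) / slope`, plus a zero-mean normal
#' residual whose SD is age-group specific. With the default constants
#' (intercept 81.9 cm, slope 2.42) a 1.797 m subject maps to about 404 mm.
#'
#' @param height body height in m (vector).
#' @param age_group age group index (vector, recycled).
#' @param config pipeline configuration; only the `population` section used.
#' @return Tibia length in mm.
#' @export
derive_tibia_length <- function(height, age_group, config = default_config()) {
  p <- config$population
  if (any(height < p$height_bounds_m[1L] - 1e-9) ||
      any(height > p$height_bounds_m[2L] + 1e-9)) {
    stop("height outside configured bounds", call. = FALSE)
  }
  n <- length(height)
  age_group <- rep_len(as.integer(age_group), n)
  sd_cm <- p$tibia_resid_sd_cm[age_group]
  base_cm <- (height * 100 - p$tibia_intercept_cm) / p$tibia_slope
  noise_cm <- ifelse(sd_cm > 0, stats::rnorm(n, 0, sd_cm), 0)
  (base_cm + noise_cm) * 10
}

#' Generate the in silico avatar population
#'
#' Samples `n` avatars: age group from the configured group weights, then
#' height and BMI independently per group from truncated normal laws, with
#' body weight (`bmi * height^2`) and tibia length derived. Fully
#' reproducible: the population stream seed is derived from `seed` via
#' [stream_seed()].
#'
#' @param config pipeline configuration, see [default_config()].
#' @param n number of avatars (default from `config$pipeline$n_avatars`).
#' @param seed master seed; `NULL` uses the current RNG state.
#' @return A data.frame with columns `id`, `age_group`, `height_m`, `bmi`,
#'   `weight_kg`, `tibia_length_mm`.
#' @export
#' @examples
#' av <- generate_population(n = 10, seed = 1)
#' range(av$height_m)
generate_population <- function(config = default_config(),
                                n = config$pipeline$n_avatars,
                                seed = config$seed) {
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  config <- validate_config(config)
  p <- config$population
  if (!is.null(seed)) set.seed(stream_seed(seed, "population"))
  n_groups <- length(p$group_weights)
  grp <- sample.int(n_groups, n, replace = TRUE, prob = p$group_weights)
  height <- sample_truncated(n, p$height_mean_m[grp], p$height_sd_m[grp],
                             p$height_bounds_m[1L], p$height_bounds_m[2L])
  bmi <- sample_truncated(n, p$bmi_mean[grp], p$bmi_sd[grp],
                          p$bmi_bounds[1L], p$bmi_bounds[2L])
  weight <- derive_weight(bmi, height)
  if (!is.null(seed)) set.seed(stream_seed(seed, "tibia"))
  tibia <- derive_tibia_length(height, grp, config)
  data.frame(
    id = seq_len(n),
    age_group = grp,
    height_m = height,
    bmi = bmi,
    weight_kg = weight,
    tibia_length_mm = tibia
  )
}

#' Per-age-group summary of an avatar population
#'
#' Mean and SD of height, BMI and weight per age group, for checking the
#' generated moments against the configured (truncated) target moments.
#' SDs of single-avatar groups are reported as `NA`.
#'
#' @param avatars data.frame as returned by [generate_population()].
#' @return A data.frame with one row per age group present.
#' @export
summarize_population <- function(avatars) {
  if (nrow(avatars) == 0L) stop("empty population", call. = FALSE)
  groups <- sort(unique(avatars$age_group))
  rows <- lapply(groups, function(g) {
    a <- avatars[avatars$age_group == g, ]
    data.frame(
      age_group = g,
      n = nrow(a),
      height_mean_m = mean(a$height_m),
      height_sd_m = stats::sd(a$height_m),
      bmi_mean = mean(a$bmi),
      bmi_sd = stats::sd(a$bmi),
      weight_mean_kg = mean(a$weight_kg),
      weight_sd_kg = stats::sd(a$weight_kg)
    )
  })
  do.call(rbind, rows)
}
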