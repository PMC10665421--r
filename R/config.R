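# Pipeline configuration: defaults, YAML reading, validation.

#' Default pipeline configuration
#'
#' Returns the full nested configuration driving every stage of the
#' simulation pipeline. Every value can be overridden from a YAML file via
#' [read_config()]. The defaults encode the study conditions:
#'
#' * **population**: men aged 20--60 years in eight 5-year age groups,
#'   body height truncated to 1.60--1.95 m, BMI truncated to 18--35
#'   kg/m^2. National-survey moments per age group are not public at this
#'   granularity, so the defaults ship plausible stand-ins (height mean
#'   1.78 m, SD 0.07 m in every group; BMI mean rising linearly from 25.0
#'   to 27.5 across groups, SD 3.5) that are explicitly replaceable.
#' * **loads**: five stance-phase landmarks S1--S5 as six-component
#'   internal loads at the fracture level, stored as percent of the 755 N
#'   reference body weight (forces, %BW) and percent body-weight-metres
#'   (moments, %BW.m). The component values are configurable stand-ins
#'   chosen so that the axial force peak falls on S4 (about 2.6 x body
#'   weight) and the bending-moment peak on S5.
#' * **geometry / materials**: idealized nail-plus-tissue cross-section of
#'   the fractured tibia; see [surrogate_geometry()].
#' * **mechanoregulation**: an optional, disabled-by-default example
#'   threshold set for classifying cells in the (hydrostatic strain,
#'   octahedral shear strain) plane.
#'
#' @return A named nested list.
#' @export
default_config <- function() {
  n_groups <- 8L
  list(
    seed = 20231122L,
    pipeline = list(
      n_avatars = 300L
    ),
    population = list(
      age_min = 20,
      age_max = 60,
      age_group_width = 5,
      group_weights = rep(1 / n_groups, n_groups),
      height_mean_m = rep(1.78, n_groups),
      height_sd_m = rep(0.07, n_groups),
      bmi_mean = seq(25.0, 27.5, length.out = n_groups),
      bmi_sd = rep(3.5, n_groups),
      height_bounds_m = c(1.60, 1.95),
      bmi_bounds = c(18, 35),
      tibia_intercept_cm = 81.9,
      tibia_slope = 2.42,
      tibia_resid_sd_cm = rep(1.2, n_groups)
    ),
    loads = list(
      reference_bodyweight_n = 755,
      gravity_m_s2 = 9.81,
      table = list(
        landmark    = c("S1", "S2", "S3", "S4", "S5"),
        fx_pct      = c(15, 25, 12, 10, 8),
        fy_pct      = c(10, 8, 18, 8, 6),
        fz_pct      = c(-190, -160, -210, -260, -120),
        mx_pct_bwm  = c(0.60, 0.50, 0.80, 0.70, 1.60),
        my_pct_bwm  = c(0.40, 0.70, 0.60, 0.50, 1.30),
        mz_pct_bwm  = c(0.15, 0.20, 0.25, 0.20, 0.60)
      )
    ),
    geometry = list(
      radius_per_tibia_length = 0.028,
      cortical_thickness_frac = 0.35,
      nail_radius_mm = 5.5,
      gap_height_mm = 3.0,
      callus_radius_factor = 1.3,
      mesh_nr_gap = 10L,
      mesh_ntheta_gap = 48L,
      mesh_nr_callus = 6L,
      mesh_ntheta_callus = 48L
    ),
    materials = list(
      nail_e_mpa = 110000,
      nail_nu = 0.3,
      tissue_e_mpa = 3.0,
      tissue_nu = 0.3,
      shear_correction = 0.9,
      density_modulus_a = 6570,
      density_modulus_b = 1.37
    ),
    mechanoregulation = list(
      enabled = FALSE,
      # illustrative rectangular partition of the invariant plane; NOT a
      # published threshold set
      hydro_breaks = c(-0.0015, 0.0015),
      shear_breaks = 0.0025,
      labels = c(
        "cartilage", "bone", "fibrous_tissue",
        "fibrocartilage", "fibrocartilage", "fibrous_tissue"
      )
    )
  )
}

# recursive merge of user values over defaults; unknown keys rejected
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    abort_config(paste0(path, unknown[1L]), "is not a recognised key")
  }
  for (nm in names(user)) {
    defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                   path = paste0(path, nm, "$"))
  }
  defaults
}

#' Read and validate a pipeline configuration file
#'
#' Reads a YAML file, overlays it on [default_config()] and validates every
#' section. Unknown keys are rejected with the offending key named; an empty
#' file yields the full default configuration.
#'
#' @param path path to a YAML configuration file.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  config <- merge_config(default_config(), user)
  validate_config(config)
}

#' Validate a configuration list
#'
#' Checks ordering of bounds, non-negative standard deviations, probability
#' weights, per-group vector lengths, the five-landmark load table, and
#' geometry/material positivity. Called by [read_config()] and by
#' [run_pipeline()].
#'
#' @param config a configuration list shaped like [default_config()].
#' @return The validated configuration, invisibly usable.
#' @export
validate_config <- function(config) {
  p <- config$population
  n_groups <- (p$age_max - p$age_min) / p$age_group_width
  if (n_groups <= 0 || abs(n_groups - round(n_groups)) > 1e-9) {
    abort_config("population$age_group_width",
                 "must divide the age range into whole groups")
  }
  n_groups <- as.integer(round(n_groups))
  for (f in c("height_bounds_m", "bmi_bounds")) {
    b <- p[[f]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1L] >= b[2L]) {
      abort_config(paste0("population$", f), "must be an ordered pair")
    }
  }
  for (f in c("group_weights", "height_mean_m", "height_sd_m",
              "bmi_mean", "bmi_sd", "tibia_resid_sd_cm")) {
    if (length(p[[f]]) != n_groups) {
      abort_config(paste0("population$", f),
                   sprintf("must have one entry per age group (%d)", n_groups))
    }
  }
  if (any(p$group_weights < 0) || abs(sum(p$group_weights) - 1) > 1e-8) {
    abort_config("population$group_weights",
                 "must be non-negative and sum to 1")
  }
  for (f in c("height_sd_m", "bmi_sd", "tibia_resid_sd_cm")) {
    if (any(p[[f]] < 0)) {
      abort_config(paste0("population$", f), "must be non-negative")
    }
  }
  if (p$tibia_slope <= 0) {
    abort_config("population$tibia_slope", "must be positive")
  }

  l <- config$loads
  if (l$reference_bodyweight_n <= 0) {
    abort_config("loads$reference_bodyweight_n", "must be positive")
  }
  tb <- l$table
  cols <- c("landmark", "fx_pct", "fy_pct", "fz_pct",
            "mx_pct_bwm", "my_pct_bwm", "mz_pct_bwm")
  if (!all(cols %in% names(tb))) {
    abort_config("loads$table", "must provide all six load components")
  }
  if (length(tb$landmark) != 5L) {
    abort_config("loads$table", "must have exactly five landmark rows")
  }
  num <- unlist(tb[setdiff(cols, "landmark")])
  if (!all(is.finite(num))) {
    abort_config("loads$table", "contains non-finite load components")
  }

  g <- config$geometry
  for (f in c("radius_per_tibia_length", "cortical_thickness_frac",
              "nail_radius_mm", "gap_height_mm", "callus_radius_factor")) {
    if (!is.finite(g[[f]]) || g[[f]] <= 0) {
      abort_config(paste0("geometry$", f), "must be positive")
    }
  }
  if (g$cortical_thickness_frac >= 1) {
    abort_config("geometry$cortical_thickness_frac", "must be < 1")
  }
  if (g$callus_radius_factor <= 1) {
    abort_config("geometry$callus_radius_factor", "must exceed 1")
  }

  m <- config$materials
  for (f in c("nail_e_mpa", "tissue_e_mpa", "shear_correction",
              "density_modulus_a")) {
    if (!is.finite(m[[f]]) || m[[f]] <= 0) {
      abort_config(paste0("materials$", f), "must be positive")
    }
  }
  for (f in c("nail_nu", "tissue_nu")) {
    if (m[[f]] < 0 || m[[f]] >= 0.5) {
      abort_config(paste0("materials$", f), "must lie in [0, 0.5)")
    }
  }

  mr <- config$mechanoregulation
  if (isTRUE(mr$enabled)) {
    # constructor performs the structural checks
    mechanoreg_thresholds(mr$hydro_breaks, mr$shear_breaks, mr$labels)
  }
  config
}
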