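# Stance-phase load landmarks S1-S5 and body-weight rescaling.
#
# Coordinate convention (fixed, right-handed): x anterior, y medial,
# z superior. Compressive axial force at the fracture cross-section has
# Fz < 0, so the hydrostatic strain under stance loads is negative
# (compression) -- the sign-sensitive invariants depend on this.

#' Resolve the landmark load table at the reference body weight
#'
#' Turns the configured percent-body-weight table into absolute
#' six-component internal loads at the fracture level for the reference
#' body weight (default 755 N, the instrumented-nail reference subject).
#' Forces are stored in N, moments in N.m (percent body-weight-metres in
#' the config). The default table places the axial force peak (largest
#' |Fz|) at landmark S4 and the bending-moment peak at S5.
#'
#' @param config pipeline configuration.
#' @return A `landmark_loads` data.frame with columns `landmark`, `fx_n`,
#'   `fy_n`, `fz_n`, `mx_nm`, `my_nm`, `mz_nm`, carrying the
#'   `reference_bodyweight_n` attribute.
#' @export
#' @examples
#' load_landmark_table()
load_landmark_table <- function(config = default_config()) {
  config <- validate_config(config)
  tb <- config$loads$table
  ref <- config$loads$reference_bodyweight_n
  out <- data.frame(
    landmark = tb$landmark,
    fx_n = tb$fx_pct / 100 * ref,
    fy_n = tb$fy_pct / 100 * ref,
    fz_n = tb$fz_pct / 100 * ref,
    mx_nm = tb$mx_pct_bwm / 100 * ref,
    my_nm = tb$my_pct_bwm / 100 * ref,
    mz_nm = tb$mz_pct_bwm / 100 * ref
  )
  attr(out, "reference_bodyweight_n") <- ref
  class(out) <- c("landmark_loads", "data.frame")
  out
}

#' Rescale landmark loads to an avatar's body weight
#'
#' Multiplies every force and moment component by
#' `lambda = weight_kg * g / reference_bodyweight_n`. Scaling is
#' homogeneous and preserves load directions; lambda is strictly
#' increasing in body weight.
#'
#' @param loads a `landmark_loads` table from [load_landmark_table()].
#' @param avatar an avatar row (anything with a `weight_kg` element) or a
#'   plain numeric weight in kg.
#' @param gravity gravitational acceleration in m/s^2.
#' @return The rescaled `landmark_loads` table; the applied factor is
#'   stored in the `scale_factor` attribute.
#' @export
scale_loads <- function(loads, avatar, gravity = 9.81) {
  weight <- if (is.numeric(avatar)) avatar[[1L]] else avatar$weight_kg
  check_positive_scalar(weight, "avatar weight")
  ref <- attr(loads, "reference_bodyweight_n")
  if (is.null(ref)) stop("loads lack a reference body weight", call. = FALSE)
  lambda <- weight * gravity / ref
  comp <- c("fx_n", "fy_n", "fz_n", "mx_nm", "my_nm", "mz_nm")
  loads[comp] <- loads[comp] * lambda
  attr(loads, "scale_factor") <- lambda
  loads
}
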