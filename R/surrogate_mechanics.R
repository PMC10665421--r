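# Surrogate gap mechanics: an idealized tibia-plus-intramedullary-nail
# cross-section with a compliant fracture-gap layer. The nail and the
# soft-tissue annulus act as parallel springs for axial force, bending,
# transverse shear and torsion; the resulting interfragmentary motion is
# mapped to a per-cell strain tensor field over the discretized gap and
# callus annuli. This is an explicit surrogate for a patient-specific FE
# model: linear, anthropometry-dependent, with plausible spatial
# structure -- not a reproduction of any particular bone.

#' Density-to-modulus power law for bone
#'
#' Maps apparent density to an isotropic Young's modulus,
#' `E = a * rho_app^b` with the calibrated defaults a = 6570, b = 1.37
#' (E in MPa for rho_app in g/cm^3). In the surrogate's default
#' configuration the bone fragments are treated as rigid, so the mapping
#' only participates when elastic fragments are modelled explicitly; it is
#' exposed because it defines the material scale of the modelled bone.
#'
#' @param rho_app apparent density in g/cm^3, non-negative.
#' @param coef_a,exponent_b power-law constants.
#' @return Young's modulus in MPa.
#' @export
#' @examples
#' density_to_modulus(1.0) # 6570 MPa
density_to_modulus <- function(rho_app, coef_a = 6570, exponent_b = 1.37) {
  if (any(rho_app < 0)) stop("apparent density must be >= 0", call. = FALSE)
  coef_a * rho_app^exponent_b
}

#' Surrogate cross-section geometry for one avatar
#'
#' The tibial outer radius scales linearly with tibia length
#' (`radius_per_tibia_length`, default 0.028), which ties the gap
#' mechanics to the tibia-length covariate. The fracture gap occupies the
#' full cross-section between the nail surface and the outer cortex; the
#' callus annulus surrounds the cortex.
#'
#' @param tibia_length_mm avatar tibia length in mm.
#' @param config pipeline configuration (geometry section).
#' @return A `surrogate_geometry` list with radii (mm), gap height (mm)
#'   and polar mesh resolution.
#' @export
surrogate_geometry <- function(tibia_length_mm, config = default_config()) {
  check_positive_scalar(tibia_length_mm, "tibia length")
  g <- config$geometry
  outer <- g$radius_per_tibia_length * tibia_length_mm
  inner_cortical <- (1 - g$cortical_thickness_frac) * outer
  callus_outer <- g$callus_radius_factor * outer
  if (!(g$nail_radius_mm < inner_cortical &&
        inner_cortical < outer && outer < callus_outer)) {
    stop("degenerate geometry: need nail radius < inner cortical radius ",
         "< outer radius < callus radius", call. = FALSE)
  }
  structure(list(
    nail_radius_mm = g$nail_radius_mm,
    inner_cortical_radius_mm = inner_cortical,
    outer_radius_mm = outer,
    callus_outer_radius_mm = callus_outer,
    gap_height_mm = g$gap_height_mm,
    mesh_nr_gap = g$mesh_nr_gap,
    mesh_ntheta_gap = g$mesh_ntheta_gap,
    mesh_nr_callus = g$mesh_nr_callus,
    mesh_ntheta_callus = g$mesh_ntheta_callus
  ), class = "surrogate_geometry")
}

# polar annulus mesh; cell positions at sector area centroids so that
# first moments (neutral-axis checks) integrate accurately
annulus_mesh <- function(r0, r1, nr, nt, region, id0 = 0L) {
  r_edges <- seq(r0, r1, length.out = nr + 1L)
  dtheta <- 2 * pi / nt
  theta <- (seq_len(nt) - 0.5) * dtheta
  ri <- r_edges[-(nr + 1L)]
  ro <- r_edges[-1L]
  # sector area centroid radius; the sin(dt/2)/(dt/2) factor accounts for
  # the angular spread of the sector
  rc <- (2 / 3) * (ro^3 - ri^3) / (ro^2 - ri^2) * sin(dtheta / 2) / (dtheta / 2)
  area <- 0.5 * (ro^2 - ri^2) * dtheta
  grid <- expand.grid(ring = seq_len(nr), slice = seq_len(nt))
  data.frame(
    cell_id = id0 + seq_len(nrow(grid)),
    region = region,
    x = rc[grid$ring] * cos(theta[grid$slice]),
    y = rc[grid$ring] * sin(theta[grid$slice]),
    r = rc[grid$ring],
    area = area[grid$ring]
  )
}

#' Discretize the fracture gap and callus annuli
#'
#' Polar-grid mesh of the two evaluation regions: the gap annulus between
#' nail surface and outer cortex, and the callus annulus outside the
#' cortex. Cell areas are exact sector areas and sum to the annulus areas.
#'
#' @param geom a [surrogate_geometry()] object.
#' @return A data.frame with columns `cell_id`, `region` (`"gap"` or
#'   `"callus"`), `x`, `y`, `r` (mm) and `area` (mm^2).
#' @export
build_gap_mesh <- function(geom) {
  gap <- annulus_mesh(geom$nail_radius_mm, geom$outer_radius_mm,
                      geom$mesh_nr_gap, geom$mesh_ntheta_gap, "gap")
  cal <- annulus_mesh(geom$outer_radius_mm, geom$callus_outer_radius_mm,
                      geom$mesh_nr_callus, geom$mesh_ntheta_callus, "callus",
                      id0 = nrow(gap))
  rbind(gap, cal)
}

#' Cross-section stiffness bundle of the nail-tissue construct
#'
#' Areas, second moments and polar moments of the nail (solid circle) and
#' the tissue annulus (nail surface to callus boundary), combined into
#' parallel-spring stiffnesses across the gap of height `h`:
#' axial `k_ax = (En An + Et At)/h`, bending
#' `kappa = (En In + Et It)/h`, shear `k_sh = ks (Gn An + Gt At)/h` with
#' shear correction `ks`, torsion `k_tor = (Gn Jn + Gt Jt)/h`.
#'
#' @param geom a [surrogate_geometry()] object.
#' @param materials the `materials` section of the configuration.
#' @return A list of section properties (mm^2, mm^4) and stiffnesses
#'   (N/mm for translations, N.mm/rad for rotations).
#' @export
section_properties <- function(geom, materials = default_config()$materials) {
  m <- materials
  h <- geom$gap_height_mm
  rn <- geom$nail_radius_mm
  rc <- geom$callus_outer_radius_mm
  a_n <- pi * rn^2
  i_n <- pi * rn^4 / 4
  j_n <- 2 * i_n
  a_t <- pi * (rc^2 - rn^2)
  i_t <- pi * (rc^4 - rn^4) / 4
  j_t <- 2 * i_t
  g_n <- m$nail_e_mpa / (2 * (1 + m$nail_nu))
  g_t <- m$tissue_e_mpa / (2 * (1 + m$tissue_nu))
  list(
    area_nail_mm2 = a_n, i_nail_mm4 = i_n, j_nail_mm4 = j_n,
    area_tissue_mm2 = a_t, i_tissue_mm4 = i_t, j_tissue_mm4 = j_t,
    gap_height_mm = h,
    k_ax = (m$nail_e_mpa * a_n + m$tissue_e_mpa * a_t) / h,
    kappa_x = (m$nail_e_mpa * i_n + m$tissue_e_mpa * i_t) / h,
    kappa_y = (m$nail_e_mpa * i_n + m$tissue_e_mpa * i_t) / h,
    k_sh = m$shear_correction * (g_n * a_n + g_t * a_t) / h,
    k_tor = (g_n * j_n + g_t * j_t) / h
  )
}

#' Interfragmentary motion under one landmark load
#'
#' The parallel-spring response of the construct: translations
#' `dz = Fz/k_ax`, `dx = Fx/k_sh`, `dy = Fy/k_sh` (mm) and rotations
#' `phix = Mx/kappa_x`, `phiy = My/kappa_y`, `thetaz = Mz/k_tor` (rad).
#' Linear in the load, so strain fields inherit the body-weight scale
#' factor exactly.
#'
#' @param load one row of a `landmark_loads` table (forces in N, moments
#'   in N.m).
#' @param stiff stiffness bundle from [section_properties()].
#' @return Named numeric vector `dx, dy, dz, phix, phiy, thetaz`.
#' @export
gap_kinematics <- function(load, stiff) {
  ks <- unlist(stiff[c("k_ax", "kappa_x", "kappa_y", "k_sh", "k_tor")])
  if (any(!is.finite(ks)) || any(ks <= 0)) {
    stop("all construct stiffnesses must be positive", call. = FALSE)
  }
  c(
    dx = load$fx_n / stiff$k_sh,
    dy = load$fy_n / stiff$k_sh,
    dz = load$fz_n / stiff$k_ax,
    phix = load$mx_nm * 1000 / stiff$kappa_x,
    phiy = load$my_nm * 1000 / stiff$kappa_y,
    thetaz = load$mz_nm * 1000 / stiff$k_tor
  )
}

#' Per-cell strain tensor field from interfragmentary motion
#'
#' Kinematic strain reconstruction over the gap height `h`: the axial
#' strain combines the axial offset with the bending rotations,
#' `ezz = (dz + phix*y - phiy*x)/h`; the engineering transverse shears are
#' `gxz = (dx - thetaz*y)/h` and `gyz = (dy + thetaz*x)/h`; the in-plane
#' normal strains follow the unconfined tissue Poisson effect
#' `exx = eyy = -nu_t * ezz`. Tensor shear components are stored
#' (`exz = gxz/2`, engineering shears are twice the tensor entries).
#'
#' @param motion named vector from [gap_kinematics()].
#' @param mesh cell table from [build_gap_mesh()].
#' @param gap_height_mm gap height h in mm.
#' @param tissue_nu tissue Poisson ratio.
#' @return The mesh data.frame with strain component columns `exx`, `eyy`,
#'   `ezz`, `exy`, `exz`, `eyz` (dimensionless).
#' @export
cell_strain_field <- function(motion, mesh, gap_height_mm,
                              tissue_nu = default_config()$materials$tissue_nu) {
  h <- gap_height_mm
  check_positive_scalar(h, "gap height")
  ezz <- (motion[["dz"]] + motion[["phix"]] * mesh$y -
            motion[["phiy"]] * mesh$x) / h
  gxz <- (motion[["dx"]] - motion[["thetaz"]] * mesh$y) / h
  gyz <- (motion[["dy"]] + motion[["thetaz"]] * mesh$x) / h
  out <- mesh
  out$exx <- -tissue_nu * ezz
  out$eyy <- -tissue_nu * ezz
  out$ezz <- ezz
  out$exy <- 0
  out$exz <- gxz / 2
  out$eyz <- gyz / 2
  out
}
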