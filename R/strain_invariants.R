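# Strain tensor invariants: hydrostatic (mean normal) strain, octahedral
# shear strain, maximum principal strain and J2, the second invariant of
# the deviatoric strain tensor. Single-tensor functions operate on 3x3
# symmetric matrices; field_invariants() is the vectorized path over a
# whole cell table.
#
# Convention: tensors store tensor shear components (e_xy = gamma_xy / 2).
# "Hydrostatic strain" here is tr(eps)/3 (mean normal strain);
# volumetric_strain() exposes tr(eps), the trivially related alternative.
# The two differ only by the factor 3, which leaves every Pearson
# correlation downstream unchanged.

check_symmetric <- function(tensor) {
  if (!is.matrix(tensor) || any(dim(tensor) != c(3L, 3L)) ||
      !is.numeric(tensor)) {
    stop("strain tensor must be a numeric 3x3 matrix", call. = FALSE)
  }
  scale <- max(abs(tensor), .Machine$double.eps)
  if (max(abs(tensor - t(tensor))) > 1e-8 * scale) {
    stop("strain tensor must be symmetric", call. = FALSE)
  }
  invisible(tensor)
}

#' Principal strains of a symmetric strain tensor
#'
#' @param tensor numeric symmetric 3x3 matrix.
#' @return The three eigenvalues sorted decreasingly, `e1 >= e2 >= e3`.
#' @export
#' @examples
#' principal_strains(diag(c(3, 1, 2)) * 1e-3)
principal_strains <- function(tensor) {
  check_symmetric(tensor)
  sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Hydrostatic (mean normal) strain
#'
#' @param tensor numeric symmetric 3x3 matrix.
#' @return `tr(tensor) / 3`.
#' @export
hydrostatic_strain <- function(tensor) {
  check_symmetric(tensor)
  sum(diag(tensor)) / 3
}

#' Volumetric strain
#'
#' The trace of the strain tensor (first invariant); three times the
#' hydrostatic strain.
#'
#' @param tensor numeric symmetric 3x3 matrix.
#' @return `tr(tensor)`.
#' @export
volumetric_strain <- function(tensor) {
  check_symmetric(tensor)
  sum(diag(tensor))
}

#' Deviatoric part of a strain tensor
#'
#' @param tensor numeric symmetric 3x3 matrix.
#' @return `tensor - tr(tensor)/3 * I`; traceless and idempotent under
#'   repeated application.
#' @export
deviatoric <- function(tensor) {
  check_symmetric(tensor)
  tensor - diag(sum(diag(tensor)) / 3, 3L)
}

#' Second invariant of the deviatoric strain tensor (J2)
#'
#' `J2 = 1/2 * sum(dev_ij^2)`, equivalently
#' `((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2) / 6` in principal strains; always
#' non-negative and zero exactly for hydrostatic states.
#'
#' @param tensor numeric symmetric 3x3 matrix.
#' @return Scalar J2 (dimensionless, quadratic in strain).
#' @export
j2 <- function(tensor) {
  d <- deviatoric(tensor)
  sum(d * d) / 2
}

#' Octahedral shear strain
#'
#' `(2/3) * sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)` in principal strains,
#' identically equal to `2 * sqrt(2 * J2 / 3)`.
#'
#' @param tensor numeric symmetric 3x3 matrix.
#' @return Non-negative scalar.
#' @export
octahedral_shear <- function(tensor) {
  2 * sqrt(2 * j2(tensor) / 3)
}

#' Vectorized invariants over a strain field table
#'
#' Computes the four invariants for every cell of a strain field (columns
#' `exx, eyy, ezz, exy, exz, eyz`, tensor shear convention). Hydrostatic
#' strain and J2 come from closed-form component expressions; the maximum
#' principal strain uses the trigonometric (Cardano) eigenvalue solution
#' for symmetric 3x3 matrices, so no per-cell eigendecomposition is
#' needed.
#'
#' @param field data.frame with the six strain component columns, e.g.
#'   from [cell_strain_field()].
#' @return `field` with columns `hydrostatic`, `oct_shear`,
#'   `max_principal`, `j2` appended.
#' @export
field_invariants <- function(field) {
  need <- c("exx", "eyy", "ezz", "exy", "exz", "eyz")
  if (!all(need %in% names(field))) {
    stop("field must contain strain components ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  exx <- field$exx; eyy <- field$eyy; ezz <- field$ezz
  exy <- field$exy; exz <- field$exz; eyz <- field$eyz
  q <- (exx + eyy + ezz) / 3
  dxx <- exx - q; dyy <- eyy - q; dzz <- ezz - q
  j2v <- 0.5 * (dxx^2 + dyy^2 + dzz^2) + exy^2 + exz^2 + eyz^2
  oct <- 2 * sqrt(pmax(2 * j2v / 3, 0))

  # trigonometric eigenvalue formula for the largest eigenvalue
  p2 <- dxx^2 + dyy^2 + dzz^2 + 2 * (exy^2 + exz^2 + eyz^2)
  p <- sqrt(p2 / 6)
  maxp <- q
  nz <- p > 0
  if (any(nz)) {
    bxx <- dxx[nz] / p[nz]; byy <- dyy[nz] / p[nz]; bzz <- dzz[nz] / p[nz]
    bxy <- exy[nz] / p[nz]; bxz <- exz[nz] / p[nz]; byz <- eyz[nz] / p[nz]
    detb <- bxx * (byy * bzz - byz^2) -
      bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    maxp[nz] <- q[nz] + 2 * p[nz] * cos(phi)
  }
  field$hydrostatic <- q
  field$oct_shear <- oct
  field$max_principal <- maxp
  field$j2 <- j2v
  field
}

#' Mechanoregulation threshold set
#'
#' A rectangular partition of the (hydrostatic strain, octahedral shear
#' strain) plane, defined by strictly increasing break vectors on each
#' axis and a label for each rectangle. By construction the rectangles are
#' disjoint and cover the plane. Intervals are closed above: a point on a
#' boundary belongs to the lower region.
#'
#' @param hydro_breaks strictly increasing interior breaks on the
#'   hydrostatic axis.
#' @param shear_breaks strictly increasing interior breaks on the shear
#'   axis.
#' @param labels character labels, length
#'   `(length(hydro_breaks)+1) * (length(shear_breaks)+1)`, filled with
#'   the hydrostatic axis varying fastest.
#' @return A `mechanoreg_thresholds` object.
#' @export
mechanoreg_thresholds <- function(hydro_breaks, shear_breaks, labels) {
  for (b in list(hydro_breaks, shear_breaks)) {
    if (length(b) < 1L || any(!is.finite(b)) || is.unsorted(b, strictly = TRUE)) {
      stop("threshold breaks must be finite and strictly increasing",
           call. = FALSE)
    }
  }
  nh <- length(hydro_breaks) + 1L
  ns <- length(shear_breaks) + 1L
  if (length(labels) != nh * ns) {
    stop(sprintf("need %d labels for %d x %d rectangles", nh * ns, nh, ns),
         call. = FALSE)
  }
  structure(list(
    hydro_breaks = hydro_breaks,
    shear_breaks = shear_breaks,
    labels = matrix(as.character(labels), nrow = nh, ncol = ns)
  ), class = "mechanoreg_thresholds")
}

#' Classify cells in the mechanoregulation plane
#'
#' Assigns each (hydrostatic, octahedral shear) pair the label of its
#' rectangle in the threshold partition. Deterministic; boundary points go
#' to the lower region (intervals closed above).
#'
#' @param hydrostatic,oct_shear numeric vectors of equal length.
#' @param thresholds a [mechanoreg_thresholds()] object.
#' @return Character vector of labels.
#' @export
classify_mechanoregulation <- function(hydrostatic, oct_shear, thresholds) {
  if (!inherits(thresholds, "mechanoreg_thresholds")) {
    stop("thresholds must come from mechanoreg_thresholds()", call. = FALSE)
  }
  ih <- findInterval(hydrostatic, thresholds$hydro_breaks,
                     left.open = TRUE) + 1L
  is <- findInterval(oct_shear, thresholds$shear_breaks,
                     left.open = TRUE) + 1L
  thresholds$labels[cbind(ih, is)]
}
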