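# Independent oracles used across the suite. These deliberately take a
# different route than the implementation they check.

# closed-form mean/sd of normal(mean, sd) truncated to [lo, hi]
trunc_normal_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / z
}

trunc_normal_sd <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  v <- 1 + (a * dnorm(a) - b * dnorm(b)) / z - ((dnorm(a) - dnorm(b)) / z)^2
  sd * sqrt(v)
}

# random symmetric 3x3 strain tensor with entries O(scale)
random_symmetric_tensor <- function(scale = 1e-3) {
  m <- matrix(rnorm(9, sd = scale), 3, 3)
  (m + t(m)) / 2
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  q %*% diag(sign(diag(qr.R(qr_d))))
}

# eigenvalue-route invariants, independent of the component formulas
eigen_invariants <- function(tensor) {
  ev <- sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  sq <- (ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 + (ev[3] - ev[1])^2
  list(
    hydrostatic = sum(ev) / 3,
    oct_shear = (2 / 3) * sqrt(sq),
    max_principal = ev[1],
    j2 = sq / 6
  )
}

# build a tensor from the six stored components (tensor shear convention)
tensor_from_components <- function(exx, eyy, ezz, exy, exz, eyz) {
  matrix(c(exx, exy, exz,
           exy, eyy, eyz,
           exz, eyz, ezz), 3, 3)
}

# a small configuration with all sampling noise switched off
noiseless_config <- function() {
  cfg <- default_config()
  cfg$population$height_sd_m[] <- 0
  cfg$population$bmi_sd[] <- 0
  cfg$population$tibia_resid_sd_cm[] <- 0
  cfg
}
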