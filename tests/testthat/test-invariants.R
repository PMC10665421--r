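test_that("single-tensor invariants match hand-computed cases", {
  # principal strains
  expect_equal(principal_strains(diag(c(3, 1, 2)) * 1e-3),
               c(3, 2, 1) * 1e-3)
  shear <- tensor_from_components(0, 0, 0, 0.005, 0, 0)
  expect_equal(principal_strains(shear), c(0.005, 0, -0.005),
               tolerance = 1e-12)
  expect_equal(principal_strains(diag(3) * 4e-4), rep(4e-4, 3))
  expect_error(principal_strains(matrix(1:9, 3, 3)), "symmetric")

  # hydrostatic / volumetric
  expect_equal(hydrostatic_strain(diag(3) * 2e-3), 2e-3)
  expect_equal(hydrostatic_strain(diag(c(0.03, 0, 0))), 0.01)
  expect_equal(hydrostatic_strain(shear), 0)
  expect_equal(volumetric_strain(diag(c(0.03, 0, 0))), 0.03)

  # deviatoric part
  expect_equal(deviatoric(diag(3) * 5e-3), matrix(0, 3, 3))
  uni <- diag(c(0.03, 0, 0))
  expect_equal(deviatoric(uni), diag(c(0.02, -0.01, -0.01)))
  expect_equal(deviatoric(deviatoric(uni)), deviatoric(uni))

  # j2 and octahedral shear
  expect_equal(j2(uni), 3e-4)
  expect_equal(j2(diag(3) * 7e-3), 0)
  expect_equal(j2(shear), 2.5e-5)
  expect_equal(octahedral_shear(uni), 2 * sqrt(2) / 3 * 0.03,
               tolerance = 1e-12)
  expect_equal(octahedral_shear(uni), 0.02828, tolerance = 2e-4)
  expect_equal(octahedral_shear(shear), 0.008165, tolerance = 1e-4)
  expect_equal(octahedral_shear(diag(3) * 1e-3), 0)
})

test_that("octahedral shear equals 2 sqrt(2 J2 / 3) on random tensors", {
  set.seed(101)
  n <- 1e4
  comp <- data.frame(
    exx = rnorm(n, sd = 1e-3), eyy = rnorm(n, sd = 1e-3),
    ezz = rnorm(n, sd = 1e-3), exy = rnorm(n, sd = 1e-3),
    exz = rnorm(n, sd = 1e-3), eyz = rnorm(n, sd = 1e-3)
  )
  inv <- field_invariants(comp)
  expect_lt(max(abs(inv$oct_shear - 2 * sqrt(2 * inv$j2 / 3)) /
                  pmax(inv$oct_shear, 1e-300)), 1e-10)
  expect_true(all(inv$j2 >= 0))
  expect_true(all(inv$oct_shear >= 0))
})

test_that("vectorized field invariants agree with the eigenvalue route", {
  set.seed(33)
  n <- 500
  comp <- data.frame(
    exx = rnorm(n, sd = 1e-3), eyy = rnorm(n, sd = 1e-3),
    ezz = rnorm(n, sd = 1e-3), exy = rnorm(n, sd = 1e-3),
    exz = rnorm(n, sd = 1e-3), eyz = rnorm(n, sd = 1e-3)
  )
  inv <- field_invariants(comp)
  for (i in seq_len(n)) {
    o <- eigen_invariants(tensor_from_components(
      comp$exx[i], comp$eyy[i], comp$ezz[i],
      comp$exy[i], comp$exz[i], comp$eyz[i]))
    expect_equal(inv$hydrostatic[i], o$hydrostatic, tolerance = 1e-10)
    expect_equal(inv$oct_shear[i], o$oct_shear, tolerance = 1e-10)
    expect_equal(inv$max_principal[i], o$max_principal, tolerance = 1e-8)
    expect_equal(inv$j2[i], o$j2, tolerance = 1e-10)
  }
  # isotropic degenerate case: max principal equals the mean strain
  iso <- field_invariants(data.frame(exx = 2e-3, eyy = 2e-3, ezz = 2e-3,
                                     exy = 0, exz = 0, eyz = 0))
  expect_equal(iso$max_principal, 2e-3)
  expect_equal(iso$j2, 0)
})

test_that("all four invariants are rotation invariant", {
  set.seed(55)
  for (i in 1:200) {
    eps <- random_symmetric_tensor()
    q <- random_rotation()
    rot <- q %*% eps %*% t(q)
    rot <- (rot + t(rot)) / 2  # symmetrize away rounding
    tol <- 1e-10
    expect_equal(hydrostatic_strain(rot), hydrostatic_strain(eps),
                 tolerance = tol)
    expect_equal(octahedral_shear(rot), octahedral_shear(eps),
                 tolerance = tol)
    expect_equal(j2(rot), j2(eps), tolerance = tol)
    expect_equal(max(principal_strains(rot)), max(principal_strains(eps)),
                 tolerance = tol)
  }
})

test_that("invariants are homogeneous of the right degree", {
  set.seed(77)
  for (i in 1:50) {
    eps <- random_symmetric_tensor()
    lam <- runif(1, 0.1, 10)
    expect_equal(j2(lam * eps), lam^2 * j2(eps), tolerance = 1e-12)
    expect_equal(octahedral_shear(lam * eps), lam * octahedral_shear(eps),
                 tolerance = 1e-12)
    expect_equal(hydrostatic_strain(lam * eps),
                 lam * hydrostatic_strain(eps), tolerance = 1e-12)
    expect_equal(max(principal_strains(lam * eps)),
                 lam * max(principal_strains(eps)), tolerance = 1e-12)
    # deviatoric trace vanishes
    expect_lt(abs(sum(diag(deviatoric(eps)))), 1e-15)
  }
})

test_that("mechanoregulation classifier partitions the plane deterministically", {
  thr <- mechanoreg_thresholds(
    hydro_breaks = c(-0.0015, 0.0015), shear_breaks = 0.0025,
    labels = c("cartilage", "bone", "fibrous_tissue",
               "fibrocartilage", "fibrocartilage", "fibrous_tissue"))
  expect_identical(classify_mechanoregulation(0, 0, thr), "bone")
  # boundary points fall into the lower region (intervals closed above)
  expect_identical(classify_mechanoregulation(-0.0015, 0, thr), "cartilage")
  expect_identical(classify_mechanoregulation(0, 0.0025, thr), "bone")
  set.seed(9)
  h <- rnorm(1000, sd = 2e-3); s <- abs(rnorm(1000, sd = 3e-3))
  lab <- classify_mechanoregulation(h, s, thr)
  counts <- table(lab)
  expect_identical(sum(counts), 1000L)  # labels partition the field
  expect_identical(lab, classify_mechanoregulation(h, s, thr))

  expect_error(mechanoreg_thresholds(c(1, 1), 0, letters[1:6]),
               "strictly increasing")
  expect_error(mechanoreg_thresholds(0, 0, letters[1:3]), "labels")
})
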