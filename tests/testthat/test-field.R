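# Independent segment-quadrature oracle for the loop field (Biot-Savart sum
# over straight segments), used to cross-check the elliptic closed form.
bs_loop_quadrature <- function(R, I, z_loop, px, py, pz, nseg = 2880) {
  th <- (seq_len(nseg) - 0.5) / nseg * 2 * pi
  dth <- 2 * pi / nseg
  sx <- R * cos(th); sy <- R * sin(th)
  dlx <- -R * sin(th) * dth; dly <- R * cos(th) * dth
  rx <- px - sx; ry <- py - sy; rz <- pz - z_loop
  r3 <- (rx^2 + ry^2 + rz^2)^1.5
  k <- 1e-7 * I
  c(Bx = sum(k * dly * rz / r3), By = sum(k * (-dlx * rz) / r3),
    Bz = sum(k * (dlx * ry - dly * rx) / r3))
}

mu0 <- 4e-7 * pi

test_that("loop field matches the closed forms on axis", {
  f <- loop_field(0.05, 1, 0, 0, 0, 0)
  expect_equal(f$Bz, mu0 * 1 / (2 * 0.05), tolerance = 1e-4)
  expect_equal(c(f$Bx, f$By), c(0, 0))
  fz <- loop_field(0.05, 1, 0, 0, 0, 0.05)
  expect_equal(fz$Bz / f$Bz, 2^-1.5, tolerance = 1e-6)
  f0 <- loop_field(0.05, 0, 0, 0.01, 0.02, 0.01)
  expect_equal(c(f0$Bx, f0$By, f0$Bz), c(0, 0, 0))
  expect_error(loop_field(0.05, 1, 0, 0.05, 0, 0), "singular")
})

test_that("off-axis loop field agrees with segment quadrature", {
  for (p in list(c(0.012, 0.007, 0.02), c(-0.03, 0.01, -0.005),
                 c(0.049, 0, 0.002))) {
    q <- bs_loop_quadrature(0.025, 2, 0.01, p[1], p[2], p[3])
    e <- loop_field(0.025, 2, 0.01, p[1], p[2], p[3])
    expect_equal(c(e$Bx, e$By, e$Bz), unname(q), tolerance = 1e-5)
  }
})

test_that("finite solenoid matches closed forms on axis and the long-coil limit", {
  # long solenoid: center field ~ mu0 n I within 2%
  sp <- solenoid_spec(radius = 0.01, length = 0.2, turns = 400, z_inner = -0.1)
  b <- solenoid_field(sp, 1, 0, 0, 0)$Bz
  expect_equal(b, mu0 * (400 / 0.2), tolerance = 0.02)
  # finite solenoid closed form (mu0 n I / 2)(cos th1 + cos th2) within 0.1%
  sp2 <- solenoid_spec(radius = 0.03, length = 0.06, turns = 200, z_inner = -0.03)
  z0 <- 0.01
  b2 <- solenoid_field(sp2, 1.5, 0, 0, z0)$Bz
  c1 <- (0.03 + z0) / sqrt((0.03 + z0)^2 + 0.03^2)
  c2 <- (0.03 - z0) / sqrt((0.03 - z0)^2 + 0.03^2)
  expect_equal(b2, mu0 * (200 / 0.06) * 1.5 / 2 * (c1 + c2), tolerance = 1e-3)
  # winding sense flips the field exactly
  sp3 <- solenoid_spec(radius = 0.03, length = 0.06, turns = 200,
                       z_inner = -0.03, sense = -1)
  expect_equal(solenoid_field(sp3, 1.5, 0, 0, z0)$Bz, -b2)
  expect_error(solenoid_spec(turns = 0), "at least 1 turn")
})

test_that("the calibrated pair delivers ~3 mT, symmetric and flat at the midplane", {
  pair <- default_bioreactor()
  map <- pair_field_map(pair, I = 0.319)
  b0 <- map$Bz_mT[map$axis == "X" & map$coord_m == 0]
  expect_gt(b0, 2.7); expect_lt(b0, 3.0)
  # axial stationarity at the center (symmetric arrangement)
  bz <- function(z) solenoid_field(pair$top, 0.319, 0, 0, z)$Bz +
    solenoid_field(pair$bottom, 0.319, 0, 0, z)$Bz
  expect_lt(abs(bz(5e-4) - bz(-5e-4)) / bz(0), 1e-3)
  # X/Y symmetry of the axisymmetric pair and mirror symmetry in X
  xprof <- map[map$axis == "X", ]
  expect_equal(xprof$Bz_mT, rev(xprof$Bz_mT), tolerance = 1e-9)
  expect_equal(xprof$Bz_mT, map$Bz_mT[map$axis == "Y"], tolerance = 1e-9)
  # transverse components negligible in the central region
  central <- abs(xprof$coord_m) <= 0.012
  expect_lt(max(abs(xprof$Bx_mT[central]) / abs(xprof$Bz_mT[central])), 0.05)
  expect_lt(max(abs(xprof$By_mT)), 1e-12)
})

test_that("field maps are linear in current and superpose", {
  pair <- default_bioreactor()
  coords <- seq(-0.02, 0.02, length.out = 9)
  m1 <- pair_field_map(pair, I = 0.319, coords = coords)
  m2 <- pair_field_map(pair, I = 0.638, coords = coords)
  expect_equal(m2$Bz_mT, 2 * m1$Bz_mT, tolerance = 1e-12)
  top <- solenoid_field(pair$top, 0.319, coords, 0, 0)$Bz
  bottom <- solenoid_field(pair$bottom, 0.319, coords, 0, 0)$Bz
  expect_equal((top + bottom) * 1e3, m1$Bz_mT[m1$axis == "X"], tolerance = 1e-12)
})

test_that("homogeneity: zero for a uniform map, worse for a single loop than the pair", {
  u <- tibble::tibble(axis = "X", coord_m = seq(-0.04, 0.04, length.out = 41),
                      Bz_mT = 3)
  expect_equal(homogeneity(u), 0)
  off_center <- tibble::tibble(axis = "X",
                               coord_m = seq(-0.04, 0.04, length.out = 40),
                               Bz_mT = 3)
  expect_error(homogeneity(off_center, region_halfwidth = 1e-9), "empty")
  pair_h <- homogeneity(pair_field_map(default_bioreactor(), 0.319))
  # one loop of the same radius and ampere-turns at the near coil center
  loop_profile <- loop_field(0.05, 0.319 * 699, 0.04,
                             seq(-0.04, 0.04, length.out = 81), 0, 0)
  single <- tibble::tibble(axis = "X",
                           coord_m = seq(-0.04, 0.04, length.out = 81),
                           Bz_mT = loop_profile$Bz * 1e3)
  expect_gt(homogeneity(single), pair_h)
})

test_that("energy density and induced field follow their closed forms", {
  expect_equal(energy_density(0), 0)
  expect_equal(energy_density(3e-3), 3.58, tolerance = 1e-3)
  # u = 3.18 J/m^3 corresponds to ~2.83 mT ("circa 3 mT")
  expect_equal(sqrt(2 * mu0 * 3.18) * 1e3, 2.827, tolerance = 1e-3)
  expect_equal(induced_e_field(0.0175, 0), 0)
  expect_equal(induced_e_field(0.0175, 2.83e-3 / 1.36e-3), 0.0182,
               tolerance = 2e-3)
  r <- c(0.005, 0.01, 0.0175)
  expect_equal(induced_e_field(r, 2), r / r[1] * induced_e_field(r[1], 2))
})

test_that("the trapezoidal pulse is piecewise linear and fits its period", {
  wf <- current_waveform()
  expect_equal(wf$plateau, 1 / 150 - 1.36e-3)
  expect_equal(current_at(wf, 0), 0)
  expect_equal(current_at(wf, 1.36e-3 / 2), 0.319 / 2)
  expect_equal(current_at(wf, 1.36e-3 + 1e-4), 0.319)
  expect_equal(current_at(wf, 1 / 75 - 1e-6), 0)
  expect_equal(current_at(wf, 1 / 75 + 1.36e-3 / 2), 0.319 / 2) # periodic
  expect_equal(wf$dIdt_max, 0.319 / 1.36e-3)
  expect_error(current_waveform(rise = 8e-3, fall = 8e-3), "fit")
})

test_that("the dosimetry report reproduces the published exposure figures", {
  rep <- field_report()
  expect_gt(rep$B_center_mT, 2.7); expect_lt(rep$B_center_mT, 3.0)
  expect_gt(rep$u_J_m3, 2.9); expect_lt(rep$u_J_m3, 3.6)
  expect_equal(rep$E_edge_mV_m, 18.2, tolerance = 0.02)
})
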