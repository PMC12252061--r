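# Independent re-evaluation of every closed-form coefficient, written out
# directly from the model equations (kept deliberately separate from the
# package's internals so it can serve as an oracle).
oracle_insertion <- function(Dh, Ds, p, beta) {
  theta <- atan(p / (pi * Ds))
  rf <- (Dh + Ds) / 4
  rs <- (2 * Dh + 2 * Ds) / 6
  Kf0 <- 1 / 2 * (Ds - Dh) * (1 + tan(beta)^2) *
    sqrt(((Ds + Dh) / 4)^2 + (p / (2 * pi))^2)
  Ac <- tan(beta) * ((Ds - Dh) / 2)^2
  list(theta = theta, rf = rf, rs = rs, Kf0 = Kf0, Ac = Ac,
       G1 = rs * Ac / cos(theta), G2 = 2 * rf * Kf0 / cos(theta))
}

test_that("insertion coefficients match the independent oracle and frozen values", {
  geom <- screw_geometry()
  co <- insertion_coefficients(geom)
  orc <- oracle_insertion(3.2, 6.5, 2.75, 15 * pi / 180)
  for (f in names(orc)) {
    expect_equal(co[[f]], orc[[f]], tolerance = 1e-12, label = f)
  }
  # frozen hand-computed values for the HB 6.5 bench geometry
  expect_equal(co$theta, 0.13387, tolerance = 1e-4)
  expect_equal(co$rf, 2.425, tolerance = 1e-12)
  expect_equal(co$rs, 3.2333, tolerance = 1e-4)
  expect_equal(co$Ac, 0.7295, tolerance = 1e-4)
  expect_equal(co$Kf0, 4.3578, tolerance = 1e-4)
  expect_equal(co$G1, 2.3800, tolerance = 1e-4)
  expect_equal(co$G2, 21.326, tolerance = 1e-4)
  # all derived coefficients strictly positive
  expect_true(all(unlist(co[c("theta", "rf", "rs", "Kf0", "Ac", "G1",
                              "G2")]) > 0))
})

test_that("pitch angle vanishes in the zero-pitch limit", {
  co <- insertion_coefficients(screw_geometry(pitch = 1e-9))
  expect_lt(co$theta, 1e-9)
  expect_gt(co$theta, 0)
})

test_that("coefficient positivity holds across random valid geometries", {
  set.seed(101)
  for (i in 1:25) {
    Dh <- runif(1, 1, 5)
    geom <- screw_geometry(
      hole_diameter = Dh,
      major_diameter = Dh + runif(1, 0.5, 5),
      half_angle_deg = runif(1, 5, 60),
      pitch = runif(1, 0.5, 4),
      thread_length = runif(1, 5, 60),
      mu_thread = runif(1, 0, 1)
    )
    ico <- insertion_coefficients(geom)
    sco <- stripping_coefficients(geom)
    expect_true(all(c(ico$G1, ico$G2, ico$rf, ico$rs, ico$Ac, ico$Kf0,
                      sco$A_C) > 0))
    expect_lt(ico$theta, pi / 2)
  }
})

test_that("geometry invariant violations raise errors naming the field", {
  expect_error(screw_geometry(major_diameter = 3.0), "major_diameter")
  expect_error(screw_geometry(pitch = -1), "pitch")
  expect_error(screw_geometry(mu_thread = -0.1), "mu_thread")
  expect_error(screw_geometry(half_angle_deg = 95), "half_angle")
  expect_error(screw_geometry(head_diameter = 2.0), "head_diameter")
  expect_error(screw_geometry(thread_length = 0), "thread_length")
})

test_that("stripping coefficients match frozen values for the bench geometry", {
  sco <- stripping_coefficients(screw_geometry())
  expect_equal(sco$theta_tau, atan2(2.75, pi * 6.5) + atan2(1, -0.2),
               tolerance = 1e-12)
  expect_equal(sco$theta_tau, 1.90206, tolerance = 1e-5)
  expect_equal(sco$theta_tau * 180 / pi, 108.98, tolerance = 1e-4)
  expect_equal(sco$A_C, pi * 6.5 * 30, tolerance = 1e-12)
  expect_equal(sco$A_C, 612.61, tolerance = 1e-4)
  # bench shank is narrower than the thread root: gamma < 0, kt undefined
  expect_equal(sco$gamma, -0.0727, tolerance = 1e-3)
  expect_false(sco$kt_defined)
  expect_true(is.na(sco$kt))
})

test_that("kt is defined, >= 1 and increasing for gamma in (0, 3]", {
  # gamma = 1 closed form: 1 + (1 + 1.5 tanh(0.7))
  sco1 <- stripping_coefficients(
    screw_geometry(shank_diameter = 3.0 + 2.75, head_diameter = 12))
  expect_equal(sco1$gamma, 1, tolerance = 1e-12)
  expect_equal(sco1$kt, 1 + (1 + 1.5 * tanh(0.7)), tolerance = 1e-12)
  expect_equal(sco1$kt, 2.9066, tolerance = 1e-4)

  gammas <- seq(0.05, 3, by = 0.05)
  kts <- vapply(gammas, function(g) {
    stripping_coefficients(
      screw_geometry(shank_diameter = 3.0 + 2.75 * g,
                     head_diameter = 15))$kt
  }, numeric(1))
  expect_true(all(kts >= 1))
  expect_true(all(diff(kts) > 0))
})

test_that("theta_tau is strictly monotone in thread friction", {
  # atan2(1, -mu) opens from pi/2 towards pi as friction grows, so the
  # shear angle increases strictly with mu_T while staying in the second
  # quadrant (where both failure-torque bracket terms remain positive)
  mus <- seq(0, 2, by = 0.05)
  tt <- vapply(mus, function(m) {
    stripping_coefficients(screw_geometry(mu_thread = m))$theta_tau
  }, numeric(1))
  expect_true(all(diff(tt) > 0))
  expect_true(all(tt[-1] > pi / 2 & tt[-1] < pi))
})

test_that("engagement-offset policies behave as documented", {
  geom <- screw_geometry()
  co <- insertion_coefficients(geom)   # default: from taper geometry
  l_taper <- (6.5 - 3.2) / (2 * tan(60 * pi / 180))
  expect_equal(co$alpha, 2 * pi * l_taper / 2.75, tolerance = 1e-12)

  co2 <- insertion_coefficients(geom, alpha_policy = "explicit-value",
                                alpha = 0.5)
  expect_equal(co2$alpha, 0.5)
  expect_equal(co2$alpha_policy, "explicit-value")
  expect_error(insertion_coefficients(geom,
                                      alpha_policy = "explicit-value"),
               "alpha")
  # geometry-level alpha is picked up by the explicit policy
  geom_a <- screw_geometry(alpha = 1.25)
  expect_equal(insertion_coefficients(geom_a,
                                      alpha_policy = "explicit-value")$alpha,
               1.25)
})

test_that("geometry config files round-trip through YAML and JSON", {
  cfg <- list(hole_diameter_mm = 3.2, major_diameter_mm = 6.5,
              shank_diameter_mm = 2.8, head_diameter_mm = 7.0,
              minor_diameter_mm = 3.0, half_angle_deg = 15,
              pitch_mm = 2.75, thread_length_mm = 30, mu_thread = 0.2,
              mu_head = 0.45, end_taper_deg = 60)
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE, digits = NA)

  ref <- screw_geometry()
  for (path in c(yml, jsn)) {
    geom <- read_geometry(path)
    expect_equal(unclass(geom), unclass(ref), tolerance = 1e-12)
  }

  # missing key errors; unknown key warns
  bad <- cfg[-1]
  yaml::write_yaml(bad, yml)
  expect_error(read_geometry(yml), "hole_diameter_mm")
  extra <- c(cfg, list(bogus_key = 1))
  yaml::write_yaml(extra, yml)
  expect_warning(read_geometry(yml), "bogus_key")
})

test_that("the bundled geometry file loads to the default geometry", {
  path <- system.file("extdata", "hb65_geometry.yaml",
                      package = "screwstrip")
  expect_true(nzchar(path))
  expect_equal(unclass(read_geometry(path)),
               unclass(screw_geometry()), tolerance = 1e-12)
})
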