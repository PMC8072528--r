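test_that("profile generation places the exact ball budget", {
  sp <- surface_profile("S", dims = c(10, 10), chemistry = "Ps",
                        omega = 0.25, seed = 1)
  expect_equal(sum(sp$heights == 1), 25)
  expect_equal(sum(sp$heights > 1), 0)
  d <- surface_profile("D", dims = c(10, 10), chemistry = "Hs",
                       omega = 0.1, seed = 1)
  expect_equal(sum(d$heights == 2), 10)
  expect_equal(sum(d$heights == 1), 0)
  ds <- surface_profile("DS", dims = c(10, 10), chemistry = "Ps",
                        omega = 0.3, seed = 1)
  expect_equal(sum(ds$heights == 1), 15)
  expect_equal(sum(ds$heights == 2), 15)
  # odd DS budget: the extra column is single-ball
  ds2 <- surface_profile("DS", dims = c(5, 5), chemistry = "Ps",
                         omega = 0.2, seed = 1)   # n_b = 5
  expect_equal(sum(ds2$heights == 1), 3)
  expect_equal(sum(ds2$heights == 2), 2)
})

test_that("omega = 0 gives a smooth field with zero roughness", {
  sp <- surface_profile("S", dims = c(8, 8), chemistry = "Ps", omega = 0)
  rs <- roughness_stats(sp)
  expect_equal(rs$theta, 0)
  expect_equal(rs$h_bar, 0)
  expect_equal(rs$omega, 0)
})

test_that("generation is deterministic per seed", {
  a <- surface_profile("DS", dims = c(12, 12), chemistry = "Hs",
                       omega = 0.3, seed = 9)
  b <- surface_profile("DS", dims = c(12, 12), chemistry = "Hs",
                       omega = 0.3, seed = 9)
  expect_identical(a$heights, b$heights)
  c3 <- surface_profile("DS", dims = c(12, 12), chemistry = "Hs",
                        omega = 0.3, seed = 10)
  expect_false(identical(a$heights, c3$heights))
  # different seeds at the same coverage give identical statistics
  expect_equal(roughness_stats(a)$theta, roughness_stats(c3)$theta)
})

test_that("empirical roughness matches the closed forms exactly", {
  for (omega in seq(0, 0.5, by = 0.1)) {
    for (seed in 1:3) {
      for (style in c("S", "D", "DS")) {
        sp <- surface_profile(if (omega == 0) "smooth" else style,
                              dims = c(10, 10), chemistry = "Ps",
                              omega = omega, seed = seed)
        rs <- roughness_stats(sp)
        expect_equal(rs$theta, theta_closed_form(style, omega),
                     tolerance = 1e-12)
        expect_equal(rs$omega, omega)
      }
    }
  }
})

test_that("mean height follows the style arithmetic", {
  s <- surface_profile("S", dims = c(10, 10), chemistry = "Ps",
                       omega = 0.4, seed = 2)
  expect_equal(roughness_stats(s)$h_bar, 0.4)
  d <- surface_profile("D", dims = c(10, 10), chemistry = "Ps",
                       omega = 0.4, seed = 2)
  expect_equal(roughness_stats(d)$h_bar, 0.8)
  ds <- surface_profile("DS", dims = c(10, 10), chemistry = "Ps",
                        omega = 0.4, seed = 2)
  expect_equal(roughness_stats(ds)$h_bar, 1.5 * 0.4)   # equal split
})

test_that("coverage inversion reproduces the scanned roughness values", {
  expect_equal(coverage_for_roughness("S", 0), 0)
  expect_lt(abs(coverage_for_roughness("S", 0.458) - 0.30), 5e-3)
  expect_lt(abs(coverage_for_roughness("S", 0.432) - 0.25), 5e-3)
  expect_equal(coverage_for_roughness("D", 0.6), 0.10, tolerance = 1e-12)
  expect_error(coverage_for_roughness("S", 0.6), "unattainable")
  expect_error(coverage_for_roughness("D", 1.2), "unattainable")
  # round trip: generate at the solved coverage and recover theta within
  # the discretisation of round(omega * Ns)
  for (style in c("S", "D", "DS")) {
    for (theta in c(0.2, 0.4)) {
      om <- coverage_for_roughness(style, theta)
      sp <- surface_profile(style, dims = c(20, 20), chemistry = "Hs",
                            omega = om, seed = 4)
      # within the discretisation error of round(omega * Ns) on 400 columns
      expect_lt(abs(roughness_stats(sp)$theta - theta), 0.02)
    }
  }
})

test_that("surface sites enumerate plane plus balls", {
  sm <- surface_profile("smooth", dims = c(10, 10), chemistry = "Ps",
                        omega = 0)
  expect_equal(nrow(surface_sites(sm)), 100)
  s <- surface_profile("S", dims = c(10, 10), chemistry = "Ps",
                       omega = 0.25, seed = 1)
  expect_equal(nrow(surface_sites(s)), 125)
  d <- surface_profile("D", dims = c(10, 10), chemistry = "Ps",
                       omega = 0.1, seed = 1)
  expect_equal(nrow(surface_sites(d)), 120)
})

test_that("profiles survive a plain-text round trip", {
  sp <- surface_profile("DS", dims = c(9, 7), chemistry = "Hs",
                        omega = 0.33, seed = 77)
  path <- withr::local_tempfile(fileext = ".txt")
  write_surface_profile(sp, path)
  sp2 <- read_surface_profile(path)
  expect_identical(sp2$heights, sp$heights)
  expect_identical(sp2$style, sp$style)
  expect_identical(sp2$chemistry, sp$chemistry)
  expect_equal(sp2$omega, sp$omega)
})

test_that("unknown styles and smooth-with-balls are rejected", {
  expect_error(surface_profile("X", dims = c(8, 8), chemistry = "Ps",
                               omega = 0.2))
  expect_error(surface_profile("smooth", dims = c(8, 8), chemistry = "Ps",
                               omega = 0.2), "cannot carry balls")
})
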