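test_that("derived seeds are stable, distinct and in range", {
  a <- derive_seed(1, "profile", 2, 3)
  expect_identical(a, derive_seed(1, "profile", 2, 3))
  expect_false(a == derive_seed(1, "profile", 2, 4))
  expect_false(a == derive_seed(2, "profile", 2, 3))
  seeds <- vapply(1:500, function(i) derive_seed(7, "x", i), 1L)
  expect_true(all(seeds >= 1 & seeds < 2^31))
  expect_gt(length(unique(seeds)), 495)
})

test_that("a single-point bulk scan completes with one summary row", {
  ref <- find_reference_fibril(2, interaction_model(), restarts = 3,
                               anneal_mcs = 2e5, seed = 5)
  spec <- scan_spec(n_chains = 2, chemistry = "none", axis = "eps",
                    values = 0, box = simulation_box(10),
                    profiles_per_point = 1, runs_per_profile = 3,
                    max_mcs = 5e6, measure_interval = 1e4,
                    master_seed = 42, reference = ref)
  out <- run_scan(spec)
  expect_equal(nrow(out$summary), 1)
  expect_equal(nrow(out$runs), 3)
  expect_true(is.finite(out$summary$tau_agg) || out$summary$n == 0)
  expect_equal(out$metadata$mcs_mode, "single attempt per MCS")
})

test_that("scans are bit-reproducible and write their outputs", {
  ref <- find_reference_fibril(2, interaction_model(eps_ps = 1.0),
                               environment = "Ps", restarts = 3,
                               anneal_mcs = 2e5, seed = 5,
                               box = simulation_box(10, slab = TRUE))
  spec <- scan_spec(n_chains = 2, chemistry = "Ps", axis = "eps",
                    values = c(0.5, 1.0), box = simulation_box(10, slab = TRUE),
                    profiles_per_point = 1, runs_per_profile = 2,
                    max_mcs = 2e6, measure_interval = 1e4,
                    master_seed = 9, reference = ref)
  dir <- withr::local_tempdir()
  a <- run_scan(spec, out_dir = dir)
  b <- run_scan(spec)
  expect_identical(a$summary, b$summary)
  expect_identical(a$runs, b$runs)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "runs.csv")))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$master_seed, 9)
  expect_equal(nrow(a$runs), 2 * 1 * 2)
})

test_that("a theta scan at theta = 0 reduces to the smooth-surface point", {
  ref <- find_reference_fibril(2, interaction_model(eps_ps = 1.2),
                               environment = "Ps", restarts = 3,
                               anneal_mcs = 2e5, seed = 5,
                               box = simulation_box(10, slab = TRUE))
  base <- list(n_chains = 2, box = simulation_box(10, slab = TRUE),
               profiles_per_point = 1, runs_per_profile = 2,
               max_mcs = 2e6, measure_interval = 1e4, master_seed = 4,
               reference = ref)
  th <- do.call(scan_spec, c(base, list(chemistry = "Ps", axis = "theta",
                                        values = 0, style = "S", eps = 1.2)))
  ep <- do.call(scan_spec, c(base, list(chemistry = "Ps", axis = "eps",
                                        values = 1.2)))
  a <- run_scan(th)
  b <- run_scan(ep)
  expect_equal(a$runs$first_passage, b$runs$first_passage)
  expect_equal(a$summary$tau_agg, b$summary$tau_agg)
})

test_that("regime classification finds planted extrema", {
  # V-shaped curve with a planted minimum at 1.4 and maximum at 1.0
  v <- data.frame(value = c(0.6, 0.8, 1.0, 1.2, 1.4, 1.6),
                  ln_tau_agg = c(17.5, 17.9, 18.4, 16.5, 14.7, 15.5),
                  sem_ln = 0.1, n = 20)
  cl <- classify_regimes(v, axis = "eps")
  expect_equal(cl$shape, "nonmonotonic")
  expect_equal(cl$eps1, 1.0)
  expect_equal(cl$eps2, 1.4)
  # strictly increasing curve
  up <- data.frame(value = 1:5, ln_tau_agg = c(15, 15.5, 16, 17, 18),
                   sem_ln = 0.1, n = 20)
  cu <- classify_regimes(up, axis = "eps")
  expect_equal(cu$shape, "monotonic-increase")
  expect_equal(cu$eps1, 5)
  expect_true(is.na(cu$eps2))
  expect_error(classify_regimes(v[1:3, ]), "at least 4")
})

test_that("the U-shape flag needs a real dip below the smooth point", {
  u <- data.frame(value = c(0, 0.1, 0.2, 0.3, 0.4),
                  ln_tau_agg = c(16.0, 15.2, 15.5, 16.5, 17.5),
                  sem_ln = 0.1, n = 20)
  expect_true(classify_regimes(u, axis = "theta")$u_shape)
  mono <- data.frame(value = c(0, 0.1, 0.2, 0.3),
                     ln_tau_agg = c(16.0, 16.4, 17.0, 18.0),
                     sem_ln = 0.1, n = 20)
  expect_false(classify_regimes(mono, axis = "theta")$u_shape)
  # a dip within one pooled SEM is noise, not a U-shape
  noise <- data.frame(value = c(0, 0.1, 0.2, 0.3),
                      ln_tau_agg = c(16.0, 15.95, 16.4, 17.0),
                      sem_ln = 0.2, n = 20)
  expect_false(classify_regimes(noise, axis = "theta")$u_shape)
})

test_that("indeterminate classification is reported, not guessed", {
  bad <- data.frame(value = 1:4, ln_tau_agg = c(15, NA, 16, 17),
                    sem_ln = 0.1, n = 20)
  cl <- classify_regimes(bad, axis = "eps")
  expect_equal(cl$shape, "indeterminate")
  expect_true(is.na(cl$eps1))
})

test_that("scan spec validation catches inconsistent requests", {
  expect_error(scan_spec(axis = "theta", values = c(0, 0.2),
                         chemistry = "none"), "chemistry")
  expect_error(scan_spec(axis = "theta", values = c(0, 0.2),
                         chemistry = "Ps"), "eps")
  expect_error(scan_spec(axis = "eps", values = c(0.5, 1), chemistry = "none"),
               "chemistry")
})
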