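test_that("default interaction tables carry the published contact energies", {
  tab <- chain_interaction_table()
  expect_identical(tab, t(tab))
  expect_equal(tab["H", "H"], -1.0)
  expect_equal(tab["+", "-"], -0.7)
  expect_equal(tab["P", "P"], -0.2)
  m <- interaction_model(eps_ps = 1.3, eps_hs = 0.4)
  expect_equal(unname(m$ps_row), c(0.2, -1.3, -0.2, -0.2))
  expect_equal(unname(m$hs_row), c(-0.4, 0.2, 0.2, 0.2))
  expect_error(interaction_model(eps_ps = -0.1), ">= 0")
  expect_error(interaction_model(chain_table = matrix(1:16, 4)), "symmetric")
})

test_that("the in-register antiparallel extended dimer scores -5.8", {
  e <- total_energy(extended_dimer_state(), interaction_model())
  expect_equal(e$e_inter, -5.8)
  expect_equal(e$e_intra, 0)
  expect_equal(e$n_inter, 8)
})

test_that("a straight rod chain has zero energy in bulk", {
  st <- system_state(cbind(2:9, 5L, 5L), peptide_sequence(),
                     simulation_box(14))
  expect_equal(total_energy(st, interaction_model())$e_total, 0)
})

test_that("a flat chain over a smooth hydrophobic surface sums Table-2 rows", {
  st <- flat_chain_on_surface("Hs")
  # 4 H contacts at -eps_hs, 2 P and 2 charged contacts at +0.2
  e <- total_energy(st, interaction_model(eps_hs = 1.2))
  expect_equal(e$e_surf, 4 * (-1.2) + 4 * 0.2)
  expect_equal(e$e_surf, -4.0)
  e2 <- total_energy(st, interaction_model(eps_hs = 0.5))
  expect_equal(e2$e_surf, 4 * (-0.5) + 0.8)
})

test_that("energies are invariant under translation and chain relabeling", {
  st <- place_random_chains(4, box = simulation_box(12), seed = 21)
  model <- interaction_model(eps_ps = 0.7)
  e0 <- total_energy(st, model)
  shifted <- st
  shifted$coords <- (st$coords + rep(c(3L, 7L, 5L), each = nrow(st$coords))) %% 12L
  expect_equal(total_energy(shifted, model)$e_total, e0$e_total)
  # swap chains 1 and 3
  perm <- st
  idx <- function(c) ((c - 1) * 8 + 1):(c * 8)
  perm$coords[c(idx(1), idx(3)), ] <- st$coords[c(idx(3), idx(1)), ]
  expect_equal(total_energy(perm, model)$e_total, e0$e_total)
})

test_that("attainable energies sit on the 0.05 grid", {
  model <- interaction_model(eps_ps = 1.2, eps_hs = 0.8)
  sp <- surface_profile("S", dims = c(12, 12), chemistry = "Ps",
                        omega = 0.2, seed = 1)
  for (seed in 1:5) {
    st <- place_random_chains(3, box = simulation_box(12, slab = TRUE),
                              surface = sp, seed = seed)
    tr <- run_trajectory(st, model, mc_config(max_mcs = 2e4,
                                              measure_interval = 5e3,
                                              seed = seed))
    e <- tr$measurements$e_total
    expect_true(all(abs(e / 0.05 - round(e / 0.05)) < 1e-9))
  }
})

test_that("delta_energy of a null move is zero and of a detachment +eps_hs", {
  st <- flat_chain_on_surface("Hs")
  model <- interaction_model(eps_hs = 1.2)
  # null move: propose the current position of bead 1
  d0 <- delta_energy(st, model, chain = 1, beads = 1,
                     new_coords = st$coords[1, , drop = FALSE])
  expect_equal(d0$e_total, 0)
  # tail-rotating the "+" end bead off the surface loses its +0.2 contact
  up <- st$coords[2, ] + c(0L, 0L, 1L)
  d1 <- delta_energy(st, model, chain = 1, beads = 1,
                     new_coords = matrix(up, 1))
  expect_equal(d1$e_surf, -0.2)
  # detaching one H bead from an Hs contact costs exactly +eps_hs:
  # tail rotation of the end bead of a flat all-H chain
  sp <- surface_profile("smooth", dims = c(14, 14), chemistry = "Hs",
                        omega = 0)
  sth <- system_state(cbind(2:5, 5L, 1L), peptide_sequence("HHHH"),
                      simulation_box(14, slab = TRUE), sp)
  d3 <- delta_energy(sth, model, chain = 1, beads = 1,
                     new_coords = matrix(sth$coords[2, ] + c(0L, 0L, 1L), 1))
  expect_equal(d3$e_surf, 1.2)
  expect_equal(d3$e_total, 1.2)
})

test_that("incremental deltas equal full recomputation everywhere", {
  model <- interaction_model(eps_ps = 1.2, eps_hs = 0.8)
  envs <- list(
    bulk = NULL,
    S = surface_profile("S", dims = c(12, 12), chemistry = "Ps",
                        omega = 0.25, seed = 3),
    DS = surface_profile("DS", dims = c(12, 12), chemistry = "Hs",
                         omega = 0.2, seed = 5))
  for (nm in names(envs)) {
    st <- place_random_chains(3, box = simulation_box(12, slab = !is.null(envs[[nm]])),
                              surface = envs[[nm]], seed = 10)
    d <- check_delta_consistency(st, model, n_proposals = 500, seed = 20)
    expect_lt(max(abs(d$inc_total - d$full_total)), 1e-9)
  }
})

test_that("interaction models serialize bit-exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- interaction_model(eps_ps = 1.23456789, eps_hs = 0.333)
  write_interaction_model(m, path)
  m2 <- read_interaction_model(path)
  expect_identical(m2$eps_ps, m$eps_ps)
  expect_identical(m2$eps_hs, m$eps_hs)
  expect_identical(unname(m2$chain_table), unname(m$chain_table))
})
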