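test_that("Metropolis rule follows the Boltzmann closed forms", {
  expect_true(all(metropolis_accept(rep(-0.5, 50), 0.54)))
  expect_true(all(metropolis_accept(rep(0, 50), 0.54)))
  expect_equal(metropolis_probability(0.54 * log(2), 0.54), 0.5)
  expect_equal(metropolis_probability(1.0, 0.54), exp(-1 / 0.54))
  expect_equal(metropolis_probability(-3, 0.54), 1)
  expect_error(metropolis_accept(0, -1))
  # empirical acceptance at dE = T ln 2 is ~1/2
  set.seed(4)
  acc <- mean(metropolis_accept(rep(0.54 * log(2), 4000), 0.54))
  expect_gt(acc, 0.47)
  expect_lt(acc, 0.53)
})

test_that("max_mcs = 0 returns only the initial measurement", {
  st <- place_random_chains(2, box = simulation_box(10), seed = 1)
  tr <- run_trajectory(st, interaction_model(), mc_config(max_mcs = 0))
  expect_equal(nrow(tr$measurements), 1)
  expect_equal(tr$measurements$mcs, 0)
  expect_identical(tr$final_state$coords, st$coords)
})

test_that("trajectories are bit-reproducible per seed", {
  st <- place_random_chains(4, box = simulation_box(12), seed = 2)
  model <- interaction_model(eps_ps = 0.9)
  a <- run_trajectory(st, model, mc_config(max_mcs = 5e4, seed = 7))
  b <- run_trajectory(st, model, mc_config(max_mcs = 5e4, seed = 7))
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$final_state$coords, b$final_state$coords)
  d <- run_trajectory(st, model, mc_config(max_mcs = 5e4, seed = 8))
  expect_false(identical(a$final_state$coords, d$final_state$coords))
})

test_that("accepted moves never violate chain or box invariants", {
  sp <- surface_profile("DS", dims = c(12, 12), chemistry = "Hs",
                        omega = 0.25, seed = 3)
  st <- place_random_chains(4, box = simulation_box(12, slab = TRUE),
                            surface = sp, seed = 3)
  tr <- run_trajectory(st, interaction_model(eps_hs = 1.0),
                       mc_config(max_mcs = 2e5, seed = 5))
  expect_true(validate_state(tr$final_state))     # rebuilds occupancy
  expect_true(all(tr$final_state$coords[, 3] >= 1))
  expect_silent(build_occupancy(tr$final_state))
})

test_that("running energies agree with a fresh recomputation at the end", {
  st <- place_random_chains(5, box = simulation_box(12), seed = 6)
  model <- interaction_model()
  tr <- run_trajectory(st, model, mc_config(max_mcs = 1e5,
                                            measure_interval = 1e5, seed = 9))
  last <- tr$measurements[nrow(tr$measurements), ]
  fresh <- total_energy(tr$final_state, model)
  expect_equal(last$e_total, fresh$e_total, tolerance = 1e-9)
  expect_equal(last$n_inter, fresh$n_inter)
})

test_that("proposal geometry is correct and reversible for every kind", {
  st <- place_random_chains(4, box = simulation_box(10), seed = 4)
  props <- sample_proposals(st, interaction_model(), n = 4000,
                            temperature = 2.0, p_global = 0.3, seed = 14)
  kinds_seen <- character(0)
  L <- 10
  replay_proposals(st, props, function(kind, beads, old, new, coords, chain) {
    kinds_seen <<- c(kinds_seen, kind)
    m <- 8
    rows <- (chain - 1) * m + seq_len(m)
    ch <- coords[rows, ]
    if (kind == "corner_flip") {
      i <- beads[1]
      # target is the fourth corner of the plaquette through i-1, i, i+1
      b2 <- mi_wrap(ch[i + 1, ] - ch[i, ], L)
      expect_equal(as.integer((ch[i - 1, ] + b2) %% L), as.integer(new[1, ]))
      # involution: flipping again from the new state returns the old site
      b2r <- mi_wrap(ch[i + 1, ] - new[1, ], L)
      expect_equal(as.integer((ch[i - 1, ] + b2r) %% L), as.integer(old[1, ]))
    } else if (kind == "tail_rotation") {
      i <- beads[1]
      anchor <- if (i == 1) ch[2, ] else ch[m - 1, ]
      d <- abs(mi_wrap(new[1, ] - anchor, L))
      expect_equal(sum(d), 1)   # new site neighbours the anchor
      # the inverse move (back to the vacated old site) stays proposable
      dr <- abs(mi_wrap(old[1, ] - anchor, L))
      expect_equal(sum(dr), 1)
    } else if (kind == "crankshaft") {
      # bonds to the anchors are preserved
      i <- beads[1]
      expect_equal(sum(abs(mi_wrap(new[1, ] - ch[i - 1, ], L))), 1)
      expect_equal(sum(abs(mi_wrap(new[2, ] - ch[i + 2, ], L))), 1)
      expect_equal(sum(abs(mi_wrap(new[2, ] - new[1, ], L))), 1)
    } else if (kind == "rigid_rotation") {
      # some bead is the pivot: it maps to itself
      expect_true(any(rowSums(abs(new - old)) == 0) ||
                    !identical(dim(new), dim(old)))
      # rigid: all internal distances preserved (check bond lengths)
      expect_true(all(rowSums(abs(mi_wrap(diff(new), L))) == 1))
    } else if (kind == "rigid_translation") {
      sh <- mi_wrap(new - old, L)
      expect_equal(nrow(unique(sh)), 1)        # uniform shift
      expect_equal(sum(abs(sh[1, ])), 1)       # by one lattice unit
    }
  })
  expect_setequal(unique(kinds_seen),
                  c("tail_rotation", "corner_flip", "crankshaft",
                    "rigid_rotation", "rigid_translation"))
})

test_that("an isolated chain translation is always legal with zero dE", {
  st <- place_random_chains(1, box = simulation_box(10), seed = 1)
  props <- sample_proposals(st, interaction_model(), n = 2000,
                            temperature = 0.5, p_global = 1.0, seed = 2)
  trans <- Filter(function(p) identical(p$kind, "rigid_translation"), props)
  expect_gt(length(trans), 100)
  expect_true(all(vapply(trans, function(p) p$valid && p$accepted, TRUE)))
})

test_that("acceptance rate does not increase when temperature drops", {
  st <- place_random_chains(6, box = simulation_box(12), seed = 8)
  model <- interaction_model()
  rate <- function(temp) {
    tr <- run_trajectory(st, model, mc_config(temperature = temp,
                                              max_mcs = 2e5, seed = 3))
    sum(tr$move_counts[, "accepted"]) / sum(tr$move_counts[, "attempted"])
  }
  r <- vapply(c(0.3, 0.54, 1.0), rate, 0)
  expect_true(all(diff(r) >= 0))
})

test_that("sweep mode performs N*M attempts per MCS", {
  st <- place_random_chains(3, box = simulation_box(12), seed = 5)
  tr1 <- run_trajectory(st, interaction_model(),
                        mc_config(max_mcs = 1000, seed = 4))
  tr2 <- run_trajectory(st, interaction_model(),
                        mc_config(max_mcs = 1000, sweep_mode = TRUE, seed = 4))
  expect_equal(sum(tr1$move_counts[, "attempted"]), 1000)
  expect_equal(sum(tr2$move_counts[, "attempted"]), 1000 * 3 * 8)
})
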