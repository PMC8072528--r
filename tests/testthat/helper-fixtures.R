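# Shared fixtures and independent desk-scale oracles.

# antiparallel, in-register, fully extended two-chain configuration
# (8 inter-chain contacts pairing bead i with bead 9-i)
extended_dimer_state <- function(box = simulation_box(14)) {
  system_state(rbind(cbind(2:9, 5L, 5L), cbind(9:2, 6L, 5L)),
               peptide_sequence(), box)
}

# single extended chain lying flat at z = 1 over a smooth surface
flat_chain_on_surface <- function(chemistry = "Hs", model = interaction_model()) {
  sp <- surface_profile("smooth", dims = c(14, 14), chemistry = chemistry,
                        omega = 0)
  system_state(cbind(2:9, 5L, 1L), peptide_sequence(),
               simulation_box(14, slab = TRUE), sp)
}

# Independent enumeration oracle for a short chain in a small periodic box:
# enumerates all bond-direction sequences, keeps self-avoiding ones (site
# occupancy after wrapping), and tallies energy levels with minimum-image
# contact counting.  Pure R, no calls into the package's engine.
enum_energy_levels <- function(seq_chars, L = 4,
                               tab = chain_interaction_table()) {
  m <- length(seq_chars)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  energies <- numeric(0)
  combs <- as.matrix(expand.grid(rep(list(1:6), m - 1)))
  for (k in seq_len(nrow(combs))) {
    p <- matrix(0, m, 3)
    for (i in 2:m) p[i, ] <- p[i - 1, ] + dirs[combs[k, i - 1], ]
    pw <- p %% L
    if (anyDuplicated(apply(pw, 1, paste, collapse = ","))) next
    e <- 0
    for (i in seq_len(m - 2)) {
      for (j in seq(i + 2, m)) {
        d <- abs(pw[i, ] - pw[j, ])
        d <- pmin(d, L - d)
        if (sum(d) == 1) e <- e + tab[seq_chars[i], seq_chars[j]]
      }
    }
    energies <- c(energies, e)
  }
  lev <- sort(unique(round(energies, 10)))
  counts <- vapply(lev, function(l) sum(abs(energies - l) < 1e-9), 0L)
  list(levels = lev, counts = counts)
}

# minimum-image wrap of a displacement in a periodic box
mi_wrap <- function(d, L) {
  d <- d %% L
  ifelse(d > L / 2, d - L, d)
}

# Replay a list of sampled proposals against an R-side copy of the
# coordinates, calling `fn(kind, beads, old, new, coords_before)` for each
# accepted proposal.  Verifies that the record stream is consistent.
replay_proposals <- function(state, proposals, fn) {
  coords <- state$coords
  m <- length(state$sequence)
  for (p in proposals) {
    if (!isTRUE(p$accepted)) next
    rows <- (p$chain - 1) * m + p$beads
    stopifnot(all(coords[rows, ] == p$old_coords))
    fn(p$kind, p$beads, p$old_coords, p$new_coords, coords, p$chain)
    coords[rows, ] <- p$new_coords
  }
  coords
}
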