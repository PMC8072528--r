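# Contact energy model: bead-bead matrix, surface affinity rows and the
# three-term breakdown (intra-chain, inter-chain, chain-surface).
#
# Energies are in units of the hydrogen-bond energy; all default entries
# are multiples of 0.05, which the tests exploit as an exactness check.
# A contact is a pair of beads at minimum-image distance one; within a
# chain only pairs not successive in sequence (|i - j| >= 2) count.

#' Default bead-bead interaction matrix
#'
#' Symmetric 4x4 contact-energy matrix over the chain alphabet (H, P, +, -):
#' hydrophobic attraction -1.0 (the hydrogen-bond unit), weak polar and
#' polar-charge attraction -0.2, opposite-charge attraction -0.7,
#' like-charge repulsion 0.35, and a generic 0.2 penalty for
#' hydrophobic-polar and hydrophobic-charge contacts.
#'
#' @return a named 4x4 numeric matrix.
#' @export
chain_interaction_table <- function() {
  m <- matrix(c(
    -1.0,  0.2,  0.2,   0.2,
     0.2, -0.2, -0.2,  -0.2,
     0.2, -0.2,  0.35, -0.7,
     0.2, -0.2, -0.7,   0.35),
    nrow = 4, byrow = TRUE, dimnames = list(BEAD_TYPES, BEAD_TYPES))
  m
}

#' Interaction model: bead-bead matrix plus tunable surface affinities
#'
#' The surface affinity rows fix the non-tunable entries (hydrophilic Ps
#' beads: H = 0.2, + = -0.2, - = -0.2; hydrophobic Hs beads: P = 0.2,
#' + = 0.2, - = 0.2) and carry two tunable attractions: `eps_ps` is the
#' strength of the polar-bead/hydrophilic-surface contact (the Ps:P entry
#' is `-eps_ps`), `eps_hs` that of the hydrophobic-bead/hydrophobic-surface
#' contact (Hs:H entry `-eps_hs`).  Balls on rough surfaces carry the same
#' affinity row as the plane beads of their surface kind.
#'
#' @param eps_ps,eps_hs non-negative tunable surface attractions.
#' @param chain_table symmetric 4x4 matrix over (H, P, +, -); defaults to
#'   [chain_interaction_table()].
#' @return an object of class `interaction_model`.
#' @export
#' @examples
#' interaction_model(eps_ps = 1.2)
interaction_model <- function(eps_ps = 0, eps_hs = 0,
                              chain_table = chain_interaction_table()) {
  stopifnot(is.matrix(chain_table), all(dim(chain_table) == 4))
  if (!isTRUE(all.equal(chain_table, t(chain_table))))
    stop("chain interaction table must be symmetric")
  if (eps_ps < 0 || eps_hs < 0)
    stop("surface attractions eps_ps and eps_hs must be >= 0")
  dimnames(chain_table) <- list(BEAD_TYPES, BEAD_TYPES)
  structure(
    list(chain_table = chain_table,
         eps_ps = eps_ps, eps_hs = eps_hs,
         ps_row = c(H = 0.2, P = -eps_ps, `+` = -0.2, `-` = -0.2),
         hs_row = c(H = -eps_hs, P = 0.2, `+` = 0.2, `-` = 0.2)),
    class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  cat("<interaction_model> eps_ps =", x$eps_ps, " eps_hs =", x$eps_hs, "\n")
  print(x$chain_table)
  invisible(x)
}

# 6x6 matrix over (H, P, +, -, Ps, Hs) consumed by the engine
energy_matrix <- function(model) {
  m <- matrix(0, 6, 6,
              dimnames = list(c(BEAD_TYPES, SURFACE_TYPES),
                              c(BEAD_TYPES, SURFACE_TYPES)))
  m[1:4, 1:4] <- model$chain_table
  m[1:4, "Ps"] <- m["Ps", 1:4] <- model$ps_row
  m[1:4, "Hs"] <- m["Hs", 1:4] <- model$hs_row
  m
}

#' Total energy of a system state
#'
#' Sums three contact terms: `e_intra` over same-chain bead pairs not
#' successive in sequence at lattice distance one, `e_inter` over all
#' distance-one pairs from different chains, and `e_surf` over all
#' (chain bead, surface bead or ball) pairs at distance one.  A chain bead
#' next to several surface sites accrues one term per contact.
#'
#' @param state a [system_state()].
#' @param model an [interaction_model()].
#' @return an object of class `energy_breakdown`: list with `e_intra`,
#'   `e_inter`, `e_surf`, `e_total` and the inter-chain contact count
#'   `n_inter`.
#' @export
#' @examples
#' st <- place_random_chains(2, box = simulation_box(10), seed = 1)
#' total_energy(st, interaction_model())
total_energy <- function(state, model) {
  out <- cpp_total_energy(state$coords, bead_codes(state$sequence),
                          state$box$dims, state_heights(state),
                          state_chem(state), energy_matrix(model))
  structure(out, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "<energy_breakdown> intra %.3f + inter %.3f + surf %.3f = %.3f (%d inter contacts)\n",
    x$e_intra, x$e_inter, x$e_surf, x$e_total, as.integer(x$n_inter)))
  invisible(x)
}

#' Energy difference of an explicit move proposal
#'
#' Computes E(after) - E(before) from the contact shells of the affected
#' beads only, without touching the rest of the system.  The proposal must
#' be geometrically valid (bond lengths and self-avoidance are the
#' proposer's responsibility; coordinates are checked against the box and
#' surface layer).
#'
#' @param state a [system_state()].
#' @param model an [interaction_model()].
#' @param chain 1-based chain index.
#' @param beads 1-based bead indices being moved.
#' @param new_coords integer matrix (one row per moved bead, 0-based).
#' @return list with the per-term deltas `e_intra`, `e_inter`, `e_surf`,
#'   `e_total` and the inter-chain contact-count change `n_inter`.
#' @export
delta_energy <- function(state, model, chain, beads, new_coords) {
  new_coords <- matrix(as.integer(new_coords), ncol = 3)
  cpp_delta_energy(state$coords, bead_codes(state$sequence),
                   state$box$dims, state_heights(state), state_chem(state),
                   energy_matrix(model), as.integer(chain),
                   as.integer(beads), new_coords)
}

#' Stress-test incremental energy updates against full recomputation
#'
#' Runs Metropolis dynamics from `state` and, for each geometrically valid
#' proposal, records the incremental energy difference next to the
#' difference of two full energy recomputations.  The two must agree to
#' numerical precision for every move kind.
#'
#' @param state a [system_state()].
#' @param model an [interaction_model()].
#' @param n_proposals number of valid proposals to collect.
#' @param temperature,p_global dynamics parameters.
#' @param seed RNG seed.
#' @return a data frame with incremental and full deltas (total and by
#'   term).
#' @export
check_delta_consistency <- function(state, model, n_proposals = 1000,
                                    temperature = 0.54, p_global = 0.1,
                                    seed = 1) {
  m <- cpp_check_delta(state$coords, bead_codes(state$sequence),
                       state$box$dims, state_heights(state),
                       state_chem(state), energy_matrix(model),
                       temperature, p_global, as.integer(n_proposals),
                       as.double(seed))
  as.data.frame(m)
}

#' Serialize an interaction model to JSON
#'
#' Writes the 4x4 chain table and both tunable surface attractions so scan
#' configurations can override entries bit-exactly.
#'
#' @param model an [interaction_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_interaction_model <- function(model, path) {
  jsonlite::write_json(
    list(chain_table = model$chain_table,
         eps_ps = model$eps_ps, eps_hs = model$eps_hs),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_interaction_model
#' @export
read_interaction_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ct <- x$chain_table
  if (is.list(ct)) ct <- do.call(rbind, ct)
  interaction_model(eps_ps = x$eps_ps, eps_hs = x$eps_hs,
                    chain_table = matrix(as.numeric(ct), 4, 4))
}
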