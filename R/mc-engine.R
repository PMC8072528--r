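# Metropolis Monte Carlo dynamics.
#
# The move repertoire follows the standard lattice-polymer set: local moves
# (tail rotation, corner flip, crankshaft on two-bead U-segments) and
# global moves (rigid 90-degree rotation about a coordinate axis through a
# uniformly chosen pivot bead, rigid unit translation), mixed 1:9
# global:local.  Every proposal kind is its own inverse at equal a-priori
# selection probability, and geometrically impossible picks are consumed
# as null attempts, so detailed balance holds at the proposal level and
# Metropolis acceptance yields the Boltzmann distribution.
#
# One Monte Carlo step (MCS, the model's time unit) defaults to ONE
# attempted elementary move; a per-sweep mode (N*M attempts per MCS) is
# available behind the `sweep_mode` flag and recorded in all outputs.

#' Monte Carlo configuration
#'
#' @param temperature temperature in hydrogen-bond-energy units (k_B = 1);
#'   the aggregation studies use 0.49-0.58.
#' @param p_global probability that an attempt is a global (whole-chain)
#'   move; the remaining attempts are local.  Default 0.1 (1:9 mixing).
#' @param max_mcs maximum number of Monte Carlo steps.
#' @param measure_interval record a measurement every this many MCS.
#' @param sweep_mode if `TRUE` one MCS is N*M attempted moves instead of
#'   one.
#' @param seed integer RNG seed; trajectories are bit-reproducible.
#' @return an object of class `mc_config`.
#' @export
mc_config <- function(temperature = 0.54, p_global = 0.1, max_mcs = 1e6,
                      measure_interval = 1e4, sweep_mode = FALSE, seed = 1) {
  stopifnot(temperature > 0, p_global >= 0, p_global <= 1, max_mcs >= 0)
  structure(list(temperature = temperature, p_global = p_global,
                 max_mcs = max_mcs, measure_interval = measure_interval,
                 sweep_mode = isTRUE(sweep_mode), seed = seed),
            class = "mc_config")
}

#' Metropolis acceptance rule
#'
#' Accepts with probability `min(1, exp(-delta_e / temperature))`
#' (k_B = 1).  `metropolis_probability()` returns the probability itself.
#'
#' @param delta_e energy difference E(after) - E(before).
#' @param temperature temperature, > 0.
#' @return logical vector (`metropolis_accept`) or numeric probabilities.
#' @export
#' @examples
#' metropolis_accept(-1, 0.54)             # always TRUE
#' metropolis_probability(1, 0.54)         # exp(-1/0.54) ~ 0.157
metropolis_accept <- function(delta_e, temperature) {
  stopifnot(temperature > 0)
  runif(length(delta_e)) < metropolis_probability(delta_e, temperature)
}

#' @rdname metropolis_accept
#' @export
metropolis_probability <- function(delta_e, temperature) {
  stopifnot(temperature > 0)
  pmin(1, exp(-delta_e / temperature))
}

#' Run one Monte Carlo trajectory
#'
#' Iterates MCS from `state` under `model` at the configured temperature,
#' recording the energy breakdown and inter-chain contact count every
#' `measure_interval` MCS.  When a `reference` fibril is given the run
#' stops at the first MCS whose inter-chain contact count reaches
#' `threshold` of the reference's contact total (the aggregation
#' criterion), and measurements gain a `fibril_fraction` column.
#'
#' @param state a [system_state()].
#' @param model an [interaction_model()].
#' @param config an [mc_config()].
#' @param reference optional [find_reference_fibril()] result (or any list
#'   with a positive `q_fib`).
#' @param threshold fibril-contact fraction defining first passage
#'   (default 0.8).
#' @return an object of class `trajectory`: `measurements` data frame,
#'   `final_state`, `first_passage` (MCS, or `NA` if censored / no
#'   stopping criterion), `move_counts`, plus the configuration.
#' @export
#' @examples
#' st <- place_random_chains(2, box = simulation_box(10), seed = 2)
#' tr <- run_trajectory(st, interaction_model(), mc_config(max_mcs = 1000))
#' tail(tr$measurements)
run_trajectory <- function(state, model, config = mc_config(),
                           reference = NULL, threshold = 0.8) {
  stop_contacts <- -1
  q_fib <- NA_real_
  if (!is.null(reference)) {
    q_fib <- reference$q_fib
    if (is.null(q_fib) || q_fib <= 0)
      stop("reference must have a positive inter-chain contact count q_fib")
    stop_contacts <- ceiling(threshold * q_fib)
    if (threshold <= 0) stop_contacts <- -1   # degenerate: no stopping
  }
  res <- cpp_run_trajectory(
    state$coords, bead_codes(state$sequence), state$box$dims,
    state_heights(state), state_chem(state), energy_matrix(model),
    config$temperature, config$p_global, config$max_mcs,
    config$measure_interval, config$sweep_mode, stop_contacts,
    as.double(config$seed))
  meas <- as.data.frame(res$measurements)
  if (!is.null(reference)) meas$fibril_fraction <- meas$n_inter / q_fib
  final <- state
  final$coords <- res$final_coords
  fp <- res$first_passage
  if (!is.null(reference) && threshold <= 0) fp <- meas$mcs[1]
  structure(
    list(measurements = meas, final_state = final,
         first_passage = fp, move_counts = res$move_counts,
         config = config, q_fib = q_fib, threshold = threshold),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  last <- x$measurements[nrow(x$measurements), ]
  cat(sprintf(
    "<trajectory> %d measurement(s), final MCS %.0f, E = %.2f, %d inter contacts\n",
    nrow(x$measurements), last$mcs, last$e_total, as.integer(last$n_inter)))
  if (!is.na(x$first_passage))
    cat("  first passage at MCS", format(x$first_passage), "\n")
  invisible(x)
}

#' Sample raw move proposals (diagnostics)
#'
#' Runs the dynamics and returns each elementary proposal: kind, affected
#' beads, old and new coordinates, whether it was geometrically valid and
#' whether Metropolis accepted it.  Used to verify proposal reversibility
#' and geometric invariants.
#'
#' @inheritParams check_delta_consistency
#' @param n number of proposals to record.
#' @return a list of proposal records.
#' @export
sample_proposals <- function(state, model, n = 100, temperature = 0.54,
                             p_global = 0.1, seed = 1) {
  cpp_sample_proposals(state$coords, bead_codes(state$sequence),
                       state$box$dims, state_heights(state),
                       state_chem(state), energy_matrix(model),
                       temperature, p_global, as.integer(n),
                       as.double(seed))
}
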