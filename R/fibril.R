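# Reference fibrils, the 80%-contact aggregation criterion and
# first-passage / aggregation-time estimation.
#
# "Fibril contacts" are operationalised as the total inter-chain contact
# count relative to Q_fib, the inter-chain contact count of the
# environment-specific minimal-energy (reference) configuration.  A
# stricter mode restricted to bead-type pairs present in the reference
# contact map is available via `contact_mode = "typed"`.

#' Exhaustively enumerate single-chain ground states
#'
#' Enumerates every self-avoiding conformation of one chain in open space
#' (81,390 walks for M = 8) and returns the minimal intra-chain energy; in
#' the presence of a smooth surface also the minimal adsorbed energy, where
#' the conformation's lowest layer sits at z = 1 and each bead in it
#' contacts the plane bead below.  This is the exact oracle against which
#' annealed minima are checked.
#'
#' @param seq a [peptide_sequence()].
#' @param model an [interaction_model()].
#' @param surface_chemistry `NULL` (bulk), `"Ps"` or `"Hs"`.
#' @return list with `e_min`, `conformation` (0-based coords of a minimal
#'   state), `n_walks`, and for surfaces also `e_min_bulk` /
#'   `e_min_adsorbed`.
#' @export
#' @examples
#' enumerate_ground_state(peptide_sequence("+HPH"), interaction_model())
enumerate_ground_state <- function(seq, model, surface_chemistry = NULL) {
  seq <- peptide_sequence(seq)
  chem <- if (is.null(surface_chemistry)) -1L
          else match(match.arg(surface_chemistry, SURFACE_TYPES),
                     SURFACE_TYPES) + 3L
  res <- cpp_enumerate_ground(bead_codes(seq), energy_matrix(model), chem)
  if (is.null(surface_chemistry)) {
    list(e_min = res$e_min_bulk, conformation = res$coords_bulk,
         n_walks = res$n_walks)
  } else {
    adsorbed <- res$e_min_adsorbed <= res$e_min_bulk
    list(e_min = min(res$e_min_adsorbed, res$e_min_bulk),
         conformation = if (adsorbed) res$coords_adsorbed else res$coords_bulk,
         adsorbed = adsorbed,
         e_min_bulk = res$e_min_bulk, e_min_adsorbed = res$e_min_adsorbed,
         n_walks = res$n_walks)
  }
}

#' Find the reference fibril of an environment
#'
#' Searches for the minimal-energy configuration of `n_chains` chains in
#' the given environment (bulk, or a smooth hydrophilic/hydrophobic
#' surface at the model's current affinities) by simulated annealing from
#' several random restarts, keeping the best.  For a single chain the
#' exhaustive enumeration oracle can be used instead
#' (`method = "enumerate"`, exact).  The reference's inter-chain contact
#' count `q_fib` anchors the 80% aggregation criterion.
#'
#' @param n_chains number of chains (>= 1).
#' @param model an [interaction_model()].
#' @param seq a [peptide_sequence()].
#' @param environment `"bulk"`, `"Ps"` or `"Hs"` (smooth surface of that
#'   chemistry).
#' @param box a [simulation_box()]; default [default_box()].
#' @param restarts number of independent annealing runs.
#' @param anneal_mcs MCS per annealing stage.
#' @param t_hi,t_lo,n_stages geometric cooling schedule.
#' @param seed master seed; restart seeds are derived from it.
#' @param method `"anneal"`, `"enumerate"` (single chain only) or
#'   `"auto"` (enumerate when exact enumeration is feasible).
#' @return an object of class `reference_fibril`: `state`, `e_min`,
#'   `q_fib`, `environment`, `eps`, `method`, `seeds`.
#' @export
find_reference_fibril <- function(n_chains, model,
                                  seq = peptide_sequence(),
                                  environment = c("bulk", "Ps", "Hs"),
                                  box = NULL, restarts = 6,
                                  anneal_mcs = 4e5, t_hi = 1.0, t_lo = 0.15,
                                  n_stages = 16, seed = 1,
                                  method = c("auto", "anneal", "enumerate")) {
  environment <- match.arg(environment)
  method <- match.arg(method)
  seq <- peptide_sequence(seq)
  if (method == "auto")
    method <- if (n_chains == 1 && length(seq) <= 10) "enumerate" else "anneal"
  if (method == "enumerate" && n_chains != 1)
    stop("exhaustive enumeration is only available for a single chain")
  if (is.null(box)) box <- default_box(n_chains, m = length(seq),
                                       slab = environment != "bulk")
  surface <- NULL
  if (environment != "bulk") {
    box$slab <- TRUE
    surface <- surface_profile("smooth", dims = box$dims[1:2],
                               chemistry = environment, omega = 0)
  }
  eps <- c(eps_ps = model$eps_ps, eps_hs = model$eps_hs)

  if (method == "enumerate") {
    enum <- enumerate_ground_state(
      seq, model,
      surface_chemistry = if (environment == "bulk") NULL else environment)
    coords <- enum$conformation
    # centre the conformation in the box
    for (ax in 1:2)
      coords[, ax] <- coords[, ax] + (box$dims[ax] - max(coords[, ax])) %/% 2
    if (environment == "bulk")
      coords[, 3] <- coords[, 3] + (box$dims[3] - max(coords[, 3])) %/% 2
    st <- system_state(coords, seq, box, surface)
    return(structure(
      list(state = st, e_min = enum$e_min, q_fib = 0L,
           environment = environment, eps = eps, method = "enumerate",
           seeds = integer(0)),
      class = "reference_fibril"))
  }

  emat <- energy_matrix(model)
  heights <- if (is.null(surface)) NULL else surface$heights
  chem <- if (is.null(surface)) -1L
          else match(surface$chemistry, SURFACE_TYPES) + 3L
  best <- NULL
  seeds <- integer(0)
  for (r in seq_len(restarts)) {
    s_init <- derive_seed(seed, "ref-init", r)
    s_run <- derive_seed(seed, "ref-anneal", r)
    seeds <- c(seeds, s_init, s_run)
    st0 <- place_random_chains(n_chains, seq, box, surface, seed = s_init)
    res <- cpp_anneal(st0$coords, bead_codes(seq), box$dims, heights, chem,
                      emat, t_hi, t_lo, as.integer(n_stages),
                      anneal_mcs, 0.1, FALSE, as.double(s_run))
    if (is.null(best) || res$e_total < best$e_total - 1e-9) best <- res
  }
  st <- system_state(best$coords, seq, box, surface)
  q_fib <- as.integer(best$n_inter)
  if (n_chains >= 2 && q_fib <= 0)
    warning("annealing found no inter-chain contacts; increase the budget")
  structure(
    list(state = st, e_min = best$e_total, q_fib = q_fib,
         environment = environment, eps = eps, method = "anneal",
         seeds = seeds),
    class = "reference_fibril")
}

#' @export
print.reference_fibril <- function(x, ...) {
  cat(sprintf(
    "<reference_fibril> %s (%s), N = %d, E_min = %.2f, Q_fib = %d\n",
    x$environment, x$method, x$state$n_chains, x$e_min, x$q_fib))
  invisible(x)
}

#' Count inter-chain contacts of a state
#'
#' Number of distance-one bead pairs belonging to different chains.
#'
#' @param state a [system_state()].
#' @return an integer count.
#' @export
inter_chain_contacts <- function(state) {
  zero <- matrix(0, 6, 6)
  out <- cpp_total_energy(state$coords, bead_codes(state$sequence),
                          state$box$dims, state_heights(state),
                          state_chem(state), zero)
  as.integer(out$n_inter)
}

#' Fibril-contact fraction of a state
#'
#' The state's inter-chain contact count divided by the reference
#' fibril's `q_fib`; values above 1 are possible and returned uncapped.
#' With `contact_mode = "typed"` only contacts whose unordered bead-type
#' pair occurs among the reference's inter-chain contacts are counted.
#'
#' @param state a [system_state()].
#' @param reference a `reference_fibril` with `q_fib > 0`.
#' @param contact_mode `"count"` (default) or `"typed"`.
#' @return a fraction (>= 0, uncapped).
#' @export
fibril_fraction <- function(state, reference,
                            contact_mode = c("count", "typed")) {
  contact_mode <- match.arg(contact_mode)
  if (is.null(reference$q_fib) || reference$q_fib <= 0)
    stop("reference must have q_fib > 0")
  if (contact_mode == "count")
    return(inter_chain_contacts(state) / reference$q_fib)
  ref_pairs <- contact_type_pairs(reference$state)
  n <- sum(contact_type_pairs(state) %in% unique(ref_pairs))
  n / length(ref_pairs)
}

# unordered bead-type labels of each inter-chain contact of a state
contact_type_pairs <- function(state) {
  coords <- state$coords
  m <- length(state$sequence)
  n <- nrow(coords)
  if (n == 0) return(character(0))
  box <- state$box
  per <- if (box$slab) c(TRUE, TRUE, FALSE) else rep(TRUE, 3)
  types <- rep(unclass(state$sequence), state$n_chains)
  chain <- (seq_len(n) - 1L) %/% m
  out <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (chain[i] == chain[j]) next
      d <- abs(coords[i, ] - coords[j, ])
      d <- ifelse(per, pmin(d, box$dims - d), d)
      if (sum(d) == 1)
        out <- c(out, paste(sort(c(types[i], types[j])), collapse = ""))
    }
  }
  out
}

#' First-passage time of a trajectory
#'
#' Earliest measured MCS whose fibril-contact fraction reaches
#' `threshold`; `NA` (censored) if the trajectory never reaches it.  A
#' threshold of zero returns the first measurement's MCS.
#'
#' @param trajectory a [run_trajectory()] result whose measurements carry a
#'   `fibril_fraction` column, or any data frame with `mcs` and
#'   `fibril_fraction` columns.
#' @param threshold fraction in `[0, 1]` (default 0.8).
#' @return first-passage MCS, or `NA_real_` when censored.
#' @export
first_passage <- function(trajectory, threshold = 0.8) {
  meas <- if (inherits(trajectory, "trajectory")) trajectory$measurements
          else trajectory
  if (is.null(meas$fibril_fraction))
    stop("trajectory has no fibril_fraction measurements; ",
         "run it with a reference fibril")
  hit <- which(meas$fibril_fraction >= threshold)
  if (length(hit) == 0) return(NA_real_)
  meas$mcs[hit[1]]
}

#' Aggregation-time estimate from a first-passage ensemble
#'
#' The aggregation time `tau_agg` is the arithmetic mean of the uncensored
#' first-passage times pooled across surface profiles; `ln_tau_agg` is the
#' log of that mean (not the mean of logs).  The standard error is
#' bootstrapped over trajectories.  Censored runs are excluded from the
#' mean but reported; a censoring fraction above 20% flags the estimate as
#' a lower bound.
#'
#' @param first_passages numeric vector of first-passage MCS, `NA` for
#'   censored runs, or a data frame with a `first_passage` column.
#' @param n_boot bootstrap replicates for the SEM.
#' @param seed RNG seed for the bootstrap.
#' @return list with `tau_agg`, `ln_tau_agg`, `sem`, `sem_ln`, `n`,
#'   `n_censored`, `censored_fraction`, `lower_bound`.
#' @export
#' @examples
#' estimate_tau(c(exp(2), exp(4)))
estimate_tau <- function(first_passages, n_boot = 200, seed = 1) {
  if (is.data.frame(first_passages))
    first_passages <- first_passages$first_passage
  fp <- as.numeric(first_passages)
  n_total <- length(fp)
  cens <- is.na(fp)
  obs <- fp[!cens]
  if (length(obs) == 0)
    stop("all trajectories censored: increase max_mcs")
  tau <- mean(obs)
  if (length(obs) > 1) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b)
      mean(sample(obs, replace = TRUE)), 0))
    sem <- sd(boots)
    sem_ln <- sd(log(boots))
  } else {
    sem <- 0
    sem_ln <- 0
  }
  cf <- mean(cens)
  list(tau_agg = tau, ln_tau_agg = log(tau), sem = sem, sem_ln = sem_ln,
       n = length(obs), n_censored = sum(cens), censored_fraction = cf,
       lower_bound = cf > 0.2)
}
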