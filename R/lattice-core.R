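# Cubic-lattice geometry, chain representation and system state.
#
# Coordinates are 0-based integer triples; sites of an Lx x Ly x Lz box are
# {0..L-1} on each axis.  Bulk boxes are periodic on all axes.  When a
# surface is attached the box becomes a slab: x and y stay periodic, z is a
# wall axis with the surface plane occupying z = 0, balls z = 1 (and 2),
# and chain beads confined to 1 <= z <= Lz - 1.

#' Peptide sequence over the four-letter bead alphabet
#'
#' Chains are strings over \{+, -, H, P\}: positively and negatively charged,
#' hydrophobic and polar beads.  The default is the eight-bead sequence
#' +HHPPHH- used throughout the package.
#'
#' @param x a single string (e.g. `"+HHPPHH-"`) or a character vector of
#'   single bead letters.
#' @return an object of class `peptide_sequence` (character vector of beads).
#' @export
#' @examples
#' peptide_sequence()          # +HHPPHH-
#' peptide_sequence("+HPH")
peptide_sequence <- function(x = "+HHPPHH-") {
  if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
  x <- as.character(x)
  bad <- setdiff(unique(x), BEAD_TYPES)
  if (length(bad) > 0)
    stop("unknown bead type(s): ", paste(bad, collapse = ", "),
         " (alphabet is H, P, +, -)")
  if (length(x) < 3) stop("a peptide sequence needs at least 3 beads")
  structure(x, class = "peptide_sequence")
}

# internal 0-based codes used by the compiled engine
bead_codes <- function(seq) {
  match(unclass(seq), BEAD_TYPES) - 1L
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat("<peptide_sequence> ", paste(unclass(x), collapse = ""),
      " (M = ", length(x), ")\n", sep = "")
  invisible(x)
}

#' Simulation box
#'
#' @param dims integer vector of three box lengths (lattice units, all >= 4).
#' @param slab logical; `TRUE` for slab geometry (x, y periodic, z a wall
#'   axis carrying a surface at z = 0).  Bulk boxes (`FALSE`) are periodic
#'   on all three axes.
#' @return an object of class `simulation_box`.
#' @export
simulation_box <- function(dims, slab = FALSE) {
  dims <- as.integer(dims)
  if (length(dims) == 1) dims <- rep(dims, 3)
  if (length(dims) != 3 || any(is.na(dims)) || any(dims < 4))
    stop("box dimensions must be three integers >= 4")
  structure(list(dims = dims, slab = isTRUE(slab)), class = "simulation_box")
}

#' Default box for a given number of chains
#'
#' Box sizes are chosen so that the chain-bead number density matches the
#' working-concentration convention of the model: 6 chains of 8 beads in a
#' 14^3 box (density ~0.0175 beads per site), 12 chains in 18^3.  The
#' micromolar concentration quoted for the physical system is not
#' re-derivable from lattice units; the density is matched by convention and
#' recorded in scan metadata.
#'
#' @param n_chains number of chains.
#' @param m beads per chain.
#' @param slab logical, passed to [simulation_box()].
#' @return a `simulation_box`.
#' @export
default_box <- function(n_chains, m = 8, slab = FALSE) {
  if (n_chains <= 6 * 8 / m) l <- 14L
  else l <- max(14L, as.integer(round((n_chains * m / 0.0175)^(1 / 3))))
  simulation_box(rep(l, 3), slab = slab)
}

#' @export
print.simulation_box <- function(x, ...) {
  cat("<simulation_box> ", paste(x$dims, collapse = " x "),
      if (x$slab) " (slab: surface at z = 0)" else " (periodic)", "\n",
      sep = "")
  invisible(x)
}

#' Nearest-neighbour sites of a lattice site
#'
#' Returns the up-to-six unit-offset sites of `site`, wrapped on periodic
#' axes; sites beyond a wall axis (z in slab mode) are omitted.
#'
#' @param site integer triple (0-based).
#' @param box a [simulation_box()].
#' @return integer matrix with one neighbour per row.
#' @export
neighbors <- function(site, box) {
  site <- as.integer(site)
  dims <- box$dims
  if (length(site) != 3 || any(site < 0) || any(site >= dims))
    stop("site outside box")
  offs <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  storage.mode(offs) <- "integer"
  out <- matrix(0L, 0, 3)
  for (k in seq_len(6)) {
    p <- site + offs[k, ]
    if (box$slab) {
      if (p[3] < 0 || p[3] >= dims[3]) next
      p[1:2] <- p[1:2] %% dims[1:2]
    } else {
      p <- p %% dims
    }
    out <- rbind(out, p)
  }
  dimnames(out) <- NULL
  out
}

#' Are two lattice sites in contact?
#'
#' Contact means minimum-image distance exactly one lattice spacing; sites
#' on a diagonal are not in contact.
#'
#' @param r1,r2 integer triples (0-based, inside the box).
#' @param box a [simulation_box()].
#' @return logical.
#' @export
adjacent <- function(r1, r2, box) {
  r1 <- as.integer(r1); r2 <- as.integer(r2)
  dims <- box$dims
  if (any(r1 < 0) || any(r1 >= dims) || any(r2 < 0) || any(r2 >= dims))
    stop("site outside box")
  d <- abs(r1 - r2)
  per <- if (box$slab) c(TRUE, TRUE, FALSE) else rep(TRUE, 3)
  d <- ifelse(per, pmin(d, dims - d), d)
  sum(d) == 1L
}

#' Assemble a system state
#'
#' A `system_state` bundles N chain conformations, the box, the sequence and
#' (optionally) a surface profile.  Construction validates bond lengths,
#' self-avoidance, surface exclusion and box membership.
#'
#' @param coords integer matrix (N*M rows, 3 columns, 0-based) of bead
#'   positions, chains stored contiguously.
#' @param seq a [peptide_sequence()].
#' @param box a [simulation_box()]; slab mode is implied when `surface` is
#'   given.
#' @param surface a [surface_profile()] or `NULL` for bulk.
#' @return an object of class `system_state`.
#' @export
system_state <- function(coords, seq, box, surface = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  seq <- peptide_sequence(seq)
  if (!is.null(surface)) {
    stopifnot(inherits(surface, "surface_profile"))
    if (!all(surface$dims == box$dims[1:2]))
      stop("surface dims must match the box base")
    box$slab <- TRUE
  }
  st <- structure(
    list(coords = coords, sequence = seq, box = box, surface = surface,
         n_chains = nrow(coords) / length(seq)),
    class = "system_state")
  validate_state(st)
  st
}

# engine-facing pieces of a state
state_heights <- function(state) {
  if (is.null(state$surface)) NULL else state$surface$heights
}
state_chem <- function(state) {
  if (is.null(state$surface)) -1L
  else match(state$surface$chemistry, SURFACE_TYPES) + 3L
}

#' Validate a system state
#'
#' Rebuilds the occupancy index from scratch and checks every chain
#' invariant (bond length one, self-avoidance, no overlap with surface
#' sites, box membership).  Errors describe the first violation found.
#'
#' @param state a [system_state()].
#' @return `TRUE`, invisibly.
#' @export
validate_state <- function(state) {
  zero <- matrix(0, 6, 6)
  invisible(cpp_total_energy(state$coords, bead_codes(state$sequence),
                             state$box$dims, state_heights(state),
                             state_chem(state), zero))
  invisible(TRUE)
}

#' @export
print.system_state <- function(x, ...) {
  cat("<system_state> ", x$n_chains, " chain(s) of ",
      length(x$sequence), " beads in ",
      paste(x$box$dims, collapse = "x"),
      if (is.null(x$surface)) " bulk box"
      else paste0(" slab (", x$surface$style, " ", x$surface$chemistry,
                  " surface)"), "\n", sep = "")
  invisible(x)
}

#' Build the site-occupancy index of a state
#'
#' Enumerates every occupied site (chain beads, surface-plane beads and
#' balls) with its owner.  Raises an error naming both owners if any site
#' is claimed twice.
#'
#' @param state a [system_state()].
#' @return a data frame with columns `x`, `y`, `z`, `owner`.
#' @export
build_occupancy <- function(state) {
  coords <- state$coords
  m <- length(state$sequence)
  owner <- character(0)
  sites <- matrix(0L, 0, 3)
  if (nrow(coords) > 0) {
    sites <- coords
    owner <- sprintf("chain %d bead %d",
                     (seq_len(nrow(coords)) - 1L) %/% m + 1L,
                     (seq_len(nrow(coords)) - 1L) %% m + 1L)
  }
  if (!is.null(state$surface)) {
    ss <- surface_sites(state$surface)
    sites <- rbind(sites, ss)
    owner <- c(owner, rep("surface", nrow(ss)))
  }
  key <- paste(sites[, 1], sites[, 2], sites[, 3])
  dup <- duplicated(key)
  if (any(dup)) {
    k <- key[dup][1]
    both <- owner[key == k]
    stop("site (", k, ") occupied twice: ", both[1], " and ", both[2])
  }
  data.frame(x = sites[, 1], y = sites[, 2], z = sites[, 3], owner = owner,
             stringsAsFactors = FALSE)
}

#' Place chains at random in a box
#'
#' Each chain is grown as a self-avoiding walk from a uniformly chosen free
#' site, each next bead drawn uniformly among the free neighbour sites.
#' Dead ends abandon the chain and retry; exhausting the retry budget
#' raises an error suggesting a larger box.  Deterministic for a given
#' seed.
#'
#' @param n_chains number of chains (may be 0).
#' @param seq a [peptide_sequence()].
#' @param box a [simulation_box()]; defaults to [default_box()].
#' @param surface optional [surface_profile()]; implies slab geometry.
#' @param seed integer RNG seed.
#' @param max_retries retry budget per chain.
#' @return a [system_state()].
#' @export
#' @examples
#' st <- place_random_chains(2, peptide_sequence(), simulation_box(10), seed = 7)
#' st
place_random_chains <- function(n_chains, seq = peptide_sequence(),
                                box = NULL, surface = NULL, seed = 1,
                                max_retries = 10000) {
  seq <- peptide_sequence(seq)
  if (is.null(box)) box <- default_box(n_chains, m = length(seq),
                                       slab = !is.null(surface))
  heights <- NULL
  chem <- -1L
  if (!is.null(surface)) {
    stopifnot(inherits(surface, "surface_profile"))
    if (!all(surface$dims == box$dims[1:2]))
      stop("surface dims must match the box base")
    box$slab <- TRUE
    heights <- surface$heights
    chem <- match(surface$chemistry, SURFACE_TYPES) + 3L
  }
  coords <- cpp_place_chains(as.integer(n_chains), bead_codes(seq),
                             box$dims, heights, chem, as.double(seed),
                             as.integer(max_retries))
  system_state(coords, seq, box, surface)
}

# element labels for structure dumps
XYZ_ELEMENTS <- c("H" = "C", "P" = "N", "+" = "K", "-" = "O",
                  "Ps" = "S", "Hs" = "S")

#' Write a state snapshot in extended-XYZ format
#'
#' One frame per call; chain beads are labelled C (H), N (P), K (+), O (-)
#' and surface beads/balls S, with lattice coordinates written as floats.
#'
#' @param state a [system_state()].
#' @param path output file.
#' @param append append a frame instead of overwriting.
#' @param comment extra text for the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(state, path, append = FALSE, comment = "") {
  els <- XYZ_ELEMENTS[rep(unclass(state$sequence), state$n_chains)]
  xyz <- state$coords
  if (!is.null(state$surface)) {
    ss <- surface_sites(state$surface)
    xyz <- rbind(xyz, ss)
    els <- c(els, rep(XYZ_ELEMENTS[state$surface$chemistry], nrow(ss)))
  }
  d <- state$box$dims
  lat <- sprintf('Lattice="%d 0 0 0 %d 0 0 0 %d"', d[1], d[2], d[3])
  lines <- c(
    nrow(xyz),
    paste(lat, 'Properties=species:S:1:pos:R:3', comment),
    sprintf("%s %.1f %.1f %.1f", els, xyz[, 1], xyz[, 2], xyz[, 3]))
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
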