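# Smooth and rough surfaces.
#
# A surface is a plane of fixed beads at z = 0 plus, for rough styles,
# randomly placed balls: S-point columns carry one ball at z = 1, D-point
# columns two rigidly stacked balls at z = 1 and z = 2, and DS surfaces an
# equal mix of both.  The height field h over the Lx x Ly columns therefore
# takes values in {0, 1, 2}.  Roughness is the population standard
# deviation of h; coverage is the fraction of columns carrying balls.

SURFACE_STYLES <- c("smooth", "S", "D", "DS")

#' Generate a (possibly rough) surface profile
#'
#' Exactly `round(omega * Ns)` of the `Ns = Lx * Ly` columns receive balls,
#' chosen uniformly without replacement; for DS surfaces the ball columns
#' are split equally between single and double balls (an odd budget gives
#' the extra column to the single-ball type).  Either the coverage `omega`
#' or a target roughness `theta` (inverted through the style's closed form,
#' see [coverage_for_roughness()]) must be supplied.  Generation is
#' deterministic for a given seed.
#'
#' @param style one of `"smooth"`, `"S"`, `"D"`, `"DS"`.
#' @param dims integer pair: base dimensions Lx, Ly.
#' @param chemistry `"Ps"` (hydrophilic) or `"Hs"` (hydrophobic).
#' @param omega ball-column fraction in `[0, 1]`.
#' @param theta target roughness (alternative to `omega`).
#' @param seed integer RNG seed.
#' @return an object of class `surface_profile`.
#' @export
#' @examples
#' sp <- surface_profile("S", dims = c(10, 10), chemistry = "Hs",
#'                       omega = 0.25, seed = 1)
#' roughness_stats(sp)
surface_profile <- function(style = c("smooth", "S", "D", "DS"),
                            dims = c(14, 14),
                            chemistry = c("Ps", "Hs"),
                            omega = NULL, theta = NULL, seed = 1) {
  style <- match.arg(style)
  chemistry <- match.arg(chemistry)
  dims <- as.integer(dims)
  if (length(dims) == 1) dims <- rep(dims, 2)
  stopifnot(length(dims) == 2, all(dims >= 4))
  if (is.null(omega)) {
    if (is.null(theta)) {
      if (style == "smooth") omega <- 0
      else stop("supply either omega or theta for a rough surface")
    } else {
      omega <- coverage_for_roughness(style, theta)
    }
  }
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
  ns <- prod(dims)
  n_b <- round(omega * ns)
  if (style == "smooth" && n_b > 0)
    stop("a smooth surface cannot carry balls; use style S, D or DS")
  h <- matrix(0L, dims[1], dims[2])
  if (n_b > 0) {
    cols <- with_seed(seed, sample.int(ns, n_b))
    hv <- switch(style,
      S = rep(1L, n_b),
      D = rep(2L, n_b),
      DS = {
        n_d <- n_b %/% 2          # odd budgets: the extra column is S-type
        c(rep(1L, n_b - n_d), rep(2L, n_d))
      })
    h[cols] <- hv
  }
  structure(
    list(heights = h, dims = dims, style = style, chemistry = chemistry,
         omega = n_b / ns, n_b = n_b, seed = seed,
         theta_target = if (is.null(theta)) NA_real_ else theta),
    class = "surface_profile")
}

#' @export
print.surface_profile <- function(x, ...) {
  rs <- roughness_stats(x)
  cat(sprintf(
    "<surface_profile> %s %s, %d x %d, omega = %.4f (N_b = %d), theta = %.4f\n",
    x$style, x$chemistry, x$dims[1], x$dims[2], rs$omega, rs$n_b, rs$theta))
  invisible(x)
}

#' Roughness statistics of a surface profile
#'
#' The mean height `h_bar = sum(h_i) / Ns`, the roughness
#' `theta = sqrt(sum((h_i - h_bar)^2) / Ns)` (population standard
#' deviation), the ball-column fraction `omega = N_b / Ns` and the count
#' `n_b`.
#'
#' @param profile a [surface_profile()] (or a bare height matrix).
#' @return list with `h_bar`, `theta`, `omega`, `n_b`, `n_s`.
#' @export
roughness_stats <- function(profile) {
  h <- if (inherits(profile, "surface_profile")) profile$heights else profile
  ns <- length(h)
  h_bar <- sum(h) / ns
  theta <- sqrt(sum((h - h_bar)^2) / ns)
  n_b <- sum(h > 0)
  list(h_bar = h_bar, theta = theta, omega = n_b / ns, n_b = n_b, n_s = ns)
}

#' Closed-form roughness of an ideal profile
#'
#' For exact coverage `omega`: S surfaces have
#' `theta = sqrt(omega * (1 - omega))` (heights 0/1), D surfaces twice
#' that (heights 0/2), and DS surfaces (equal split)
#' `theta = sqrt(2.5 * omega - 2.25 * omega^2)`.
#'
#' @param style `"S"`, `"D"` or `"DS"` (or `"smooth"`, giving 0).
#' @param omega coverage fraction.
#' @return theta.
#' @export
theta_closed_form <- function(style, omega) {
  style <- match.arg(style, SURFACE_STYLES)
  switch(style,
    smooth = 0 * omega,
    S = sqrt(omega * (1 - omega)),
    D = 2 * sqrt(omega * (1 - omega)),
    DS = sqrt(2.5 * omega - 2.25 * omega^2))
}

#' Invert the roughness closed form for the coverage
#'
#' Returns the smaller root `omega` of the style's closed form, so
#' roughness scans can be parameterised by theta.  Attainable ranges:
#' S up to 0.5, D up to 1, DS up to 5/6 (at the smaller-root branch).
#'
#' @param style `"S"`, `"D"` or `"DS"`.
#' @param theta target roughness (>= 0).
#' @return the coverage fraction.
#' @export
#' @examples
#' coverage_for_roughness("S", 0.458)   # ~0.30
#' coverage_for_roughness("D", 0.6)     # 0.10
coverage_for_roughness <- function(style, theta) {
  style <- match.arg(style, SURFACE_STYLES)
  if (theta < 0) stop("theta must be >= 0")
  if (theta == 0) return(0)
  if (style == "smooth")
    stop("a smooth surface has theta = 0")
  t2 <- theta^2
  om <- switch(style,
    S = {
      if (theta > 0.5 + 1e-12) stop("theta > 0.5 unattainable for S surfaces")
      (1 - sqrt(max(0, 1 - 4 * t2))) / 2
    },
    D = {
      if (theta > 1 + 1e-12) stop("theta > 1 unattainable for D surfaces")
      (1 - sqrt(max(0, 1 - t2))) / 2
    },
    DS = {
      disc <- 6.25 - 9 * t2
      if (disc < -1e-12) stop("theta > 5/6 unattainable for DS surfaces")
      (2.5 - sqrt(max(0, disc))) / 4.5
    })
  min(max(om, 0), 1)
}

#' 3D sites occupied by a surface
#'
#' Plane sites at z = 0 for every column, ball sites at z = 1 for columns
#' with height >= 1 and z = 2 for double-ball columns.
#'
#' @param profile a [surface_profile()].
#' @return integer matrix of occupied sites (columns x, y, z; 0-based).
#' @export
surface_sites <- function(profile) {
  h <- profile$heights
  g <- expand.grid(x = seq_len(nrow(h)) - 1L, y = seq_len(ncol(h)) - 1L)
  out <- cbind(g$x, g$y, 0L)
  b1 <- which(h >= 1, arr.ind = TRUE) - 1L
  b2 <- which(h == 2, arr.ind = TRUE) - 1L
  if (nrow(b1)) out <- rbind(out, cbind(b1[, 1], b1[, 2], 1L))
  if (nrow(b2)) out <- rbind(out, cbind(b2[, 1], b2[, 2], 2L))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Write / read a surface profile as plain text
#'
#' A small header (dims, style, chemistry, omega, seed) followed by the
#' height grid, one row of the field per line, for exact replay.
#'
#' @param profile a [surface_profile()].
#' @param path file path.
#' @return `path` (writer) or the re-read `surface_profile` (reader).
#' @export
write_surface_profile <- function(profile, path) {
  hdr <- c(
    "# latfib surface profile",
    paste("dims", profile$dims[1], profile$dims[2]),
    paste("style", profile$style),
    paste("chemistry", profile$chemistry),
    paste("omega", format(profile$omega, digits = 17)),
    paste("seed", profile$seed))
  rows <- apply(profile$heights, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_surface_profile
#' @export
read_surface_profile <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln)]
  kv <- strsplit(ln[1:5], " ")
  fields <- vapply(kv, `[`, "", 1)
  stopifnot(identical(fields, c("dims", "style", "chemistry", "omega", "seed")))
  dims <- as.integer(kv[[1]][2:3])
  h <- do.call(rbind, lapply(ln[-(1:5)], function(s)
    as.integer(strsplit(trimws(s), " +")[[1]])))
  stopifnot(nrow(h) == dims[1], ncol(h) == dims[2])
  out <- structure(
    list(heights = h, dims = dims, style = kv[[2]][2],
         chemistry = kv[[3]][2], omega = as.numeric(kv[[4]][2]),
         n_b = sum(h > 0), seed = as.integer(kv[[5]][2]),
         theta_target = NA_real_),
    class = "surface_profile")
  out
}
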