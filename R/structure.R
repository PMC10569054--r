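#' Uniform RDF grid
#'
#' Bin `a` (1-based index) covers `[(a-1) dr, a dr)` with `dr = rmax/nbins`.
#'
#' @param rmax upper distance bound (Angstrom).
#' @param nbins number of bins.
#' @export
rdfGrid <- function(rmax, nbins) {
  if (rmax <= 0 || nbins < 1) stop("invalid grid")
  structure(list(rmax = rmax, nbins = as.integer(nbins), dr = rmax / nbins,
                 centers = (seq_len(nbins) - 0.5) * rmax / nbins),
            class = "rdf_grid")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$rmax, b$rmax)) && a$nbins == b$nbins
}

#' Bundle an RDF grid and g values into a curve
#'
#' @param grid an [rdfGrid()].
#' @param g per-bin values (`>= 0`).
#' @export
rdfCurve <- function(grid, g) {
  structure(list(grid = grid, g = as.numeric(g)), class = "rdf_curve")
}

#' Radial distribution function of a set of frames
#'
#' Minimum-image pair histogram per frame, normalized by the ideal-gas
#' expectation `N(N-1)/2 * 4 pi r_a^2 dr / V` (shell volume at the bin
#' center; `exact_shell` switches to the exact shell volume), averaged over
#' frames.
#'
#' @param frames a `cg_config` or list of them.
#' @param grid an [rdfGrid()].
#' @param allow_large_rmax permit `rmax > min(box)/2`.
#' @param exact_shell use exact shell volumes.
#' @return an `rdf_curve` with `grid` and `g`.
#' @export
computeRDF <- function(frames, grid, allow_large_rmax = FALSE,
                       exact_shell = FALSE) {
  if (inherits(frames, "cg_config")) frames <- list(frames)
  if (length(frames) == 0L) stop("empty frame list")
  g <- numeric(grid$nbins)
  for (fr in frames) {
    check_rc_box(grid$rmax, fr$box, allow_large_rmax)
    n <- nSites(fr)
    counts <- cpp_pair_hist(fr$positions, fr$box, grid$rmax, grid$nbins)
    V <- prod(fr$box)
    if (exact_shell) {
      edges <- seq(0, grid$rmax, length.out = grid$nbins + 1L)
      shell <- 4 * pi / 3 * diff(edges^3)
    } else {
      shell <- 4 * pi * grid$centers^2 * grid$dr
    }
    norm <- n * (n - 1) / 2 * shell / V
    g <- g + counts / norm
  }
  rdfCurve(grid, g / length(frames))
}

#' @export
print.rdf_curve <- function(x, ...) {
  cat(sprintf("<rdf_curve> %d bins on [0, %g) A, dr = %g\n",
              x$grid$nbins, x$grid$rmax, x$grid$dr))
  invisible(x)
}

#' Write / read two-column RDF files
#'
#' Whitespace text: bin center (Angstrom), g.
#' @param curve an `rdf_curve`.
#' @param path file path.
#' @export
writeRDF <- function(curve, path) {
  write.table(data.frame(r = curve$grid$centers, g = curve$g), path,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeRDF
#' @export
readRDF <- function(path) {
  tab <- read.table(path)
  r <- tab[[1]]
  nb <- length(r)
  dr <- r[2] - r[1]
  if (max(abs(diff(r) - dr)) > 1e-8) stop("non-uniform RDF grid in ", path)
  if (abs(r[1] - dr / 2) > 1e-8) stop("RDF grid must start at dr/2")
  rdfCurve(rdfGrid(nb * dr, nb), tab[[2]])
}

#' Potential of mean force from an RDF with core regularization
#'
#' `V(r_a) = -kB T ln g(r_a)` wherever `g > 0`. In the core region below the
#' shortest distance with nonzero RDF (bin index `a0`), the PMF is replaced
#' by a linear repulsive extrapolation `V(r_a) = V(r_a0) + (a0 - a) dV` with
#' `dV = V(r_a0) - V(r_a0 + 1)`, continuous at `a0`. Interior zero bins
#' (isolated gaps above `a0`) get the same treatment from the left edge of
#' their gap. Energy unit Kelvin.
#'
#' @param ref an `rdf_curve`.
#' @param thermo a [thermoState()].
#' @return a `pmf_table`: `grid`, `V`, `a0`, `dV`, plus a [pairTable()] view.
#' @export
pmfFromRDF <- function(ref, thermo) {
  g <- ref$g
  if (all(g <= 0)) stop("all-zero RDF: no PMF can be recovered")
  V <- ifelse(g > 0, -thermo$T * log(g), NA_real_)
  a0 <- which(g > 0)[1L]
  if (a0 < length(g) && !is.na(V[a0 + 1L])) {
    dV <- V[a0] - V[a0 + 1L]
  } else {
    dV <- 0
  }
  if (a0 > 1L)
    V[seq_len(a0 - 1L)] <- V[a0] + (a0 - seq_len(a0 - 1L)) * dV
  # interior gaps: bridge linearly from the previous finite value
  for (a in seq_along(V)) {
    if (is.na(V[a])) V[a] <- V[a - 1L]
  }
  structure(list(grid = ref$grid, V = V, a0 = a0, dV = dV,
                 table = pairTable(V, ref$grid$dr)),
            class = "pmf_table")
}

#' Total PMF energy of a configuration
#'
#' Sum over unordered minimum-image pairs of the tabulated value in the
#' pair's bin; pairs beyond the grid contribute zero.
#'
#' @param config a [periodicConfiguration()].
#' @param pmf a `pmf_table` or [pairTable()].
#' @param allow_large_rmax permit a grid beyond half the box.
#' @export
pmfTotalEnergy <- function(config, pmf, allow_large_rmax = TRUE) {
  tab <- if (inherits(pmf, "pmf_table")) pmf$table else pmf
  counts <- cpp_pair_hist(config$positions, config$box, tab$rmax,
                          length(tab$values))
  sum(counts * tab$values)
}

#' Triplet angle distribution in the first coordination shell
#'
#' For each central site, all unordered pairs of neighbours within `r_shell`
#' define an angle at the center. The histogram over `[0, 180]` degrees is
#' normalized to a per-bin probability and multiplied by the number of bins,
#' making the values independent of the binning.
#'
#' @param frames a `cg_config` or list of them.
#' @param r_shell shell radius (Angstrom), default 6.2.
#' @param n_bins number of angle bins.
#' @return list with `angle` (bin centers, degrees) and `density`.
#' @export
angularDistribution <- function(frames, r_shell = 6.2, n_bins = 90) {
  if (inherits(frames, "cg_config")) frames <- list(frames)
  counts <- numeric(n_bins)
  for (fr in frames) {
    if (r_shell > min(fr$box) / 2 + 1e-9)
      stop("r_shell exceeds half the box")
    counts <- counts + cpp_angular_hist(fr$positions, fr$box, r_shell, n_bins)
  }
  if (sum(counts) == 0) stop("no triplets found within r_shell")
  w <- 180 / n_bins
  list(angle = (seq_len(n_bins) - 0.5) * w,
       density = counts / sum(counts) * n_bins)
}

#' Three-body component of a network potential
#'
#' Two sites are fixed at separation `r12` in a large open box (no periodic
#' images within the cutoff); for each third-site position p on a planar
#' grid, `dE3(p) = E(1,2,p) - E(1,2) - E(2,p) - E(1,p)` where each `E` is
#' the model energy of the isolated pair/triplet. For any linear model this
#' vanishes identically, since site energies are then strict sums over pair
#' terms.
#'
#' @param model a [cgModel()].
#' @param r12 separation of the fixed pair (Angstrom); the standard presets
#'   are 3.4, 4.5 and 6.3.
#' @param x,y grid coordinates for the third site, in the plane of the pair
#'   (the pair lies on the x axis, centered at the origin).
#' @return matrix `length(x) x length(y)` of dE3 values (Kelvin).
#' @export
threeBodyMap <- function(model, r12, x = seq(-8, 8, by = 0.25),
                         y = seq(-8, 8, by = 0.25)) {
  L <- 4 * (model$spec$rc + r12 + max(abs(c(x, y))))
  box <- rep(L, 3L)
  ctr <- L / 2
  p1 <- c(ctr - r12 / 2, ctr, ctr)
  p2 <- c(ctr + r12 / 2, ctr, ctr)
  pairE <- function(a, b) {
    totalEnergy(periodicConfiguration(rbind(a, b), box, wrap = FALSE),
                model)$total
  }
  e12 <- pairE(p1, p2)
  out <- matrix(NA_real_, length(x), length(y))
  for (i in seq_along(x)) for (j in seq_along(y)) {
    p3 <- c(ctr + x[i], ctr + y[j], ctr)
    e123 <- totalEnergy(periodicConfiguration(rbind(p1, p2, p3), box,
                                              wrap = FALSE), model)$total
    out[i, j] <- e123 - e12 - pairE(p2, p3) - pairE(p1, p3)
  }
  out
}
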