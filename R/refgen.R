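#' Thermodynamic state point for reference generation
#'
#' Box and density are mutually consistent: give either `box` (Angstrom) or
#' `density` (kg/m^3, with the particle `mass` in amu).
#'
#' @param N number of particles.
#' @param T temperature (K).
#' @param density mass density in kg/m^3 (used with `mass` if `box` absent).
#' @param box cubic box edge in Angstrom (overrides `density`).
#' @param mass particle mass in amu (argon default 39.948).
#' @param eps,sigma,rcut Lennard-Jones parameters (K, Angstrom, Angstrom).
#'   Defaults are the standard liquid-argon values sigma = 3.405 A,
#'   eps/kB = 119.8 K (the source's LJ argon reference does not print them).
#' @return a `state_point`.
#' @export
statePoint <- function(N = 512, T = 95, density = 1374, box = NULL,
                       mass = 39.948, eps = 119.8, sigma = 3.405,
                       rcut = 10) {
  amu <- 1.66053906660e-27
  if (is.null(box)) {
    V <- N * mass * amu / density * 1e30           # Angstrom^3
    box <- V^(1 / 3)
  } else {
    V <- box^3
    density <- N * mass * amu / (V * 1e-30)
  }
  structure(list(N = N, T = T, density = density, box = rep(box, 3L),
                 mass = mass, eps = eps, sigma = sigma, rcut = rcut),
            class = "state_point")
}

#' @export
print.state_point <- function(x, ...) {
  cat(sprintf(
    "<state_point> N=%d, T=%g K, rho=%.1f kg/m^3, box %.3f A, LJ eps=%g K sigma=%g A\n",
    x$N, x$T, x$density, x$box[1], x$eps, x$sigma))
  invisible(x)
}

lattice_start <- function(N, box) {
  n <- ceiling(N^(1 / 3))
  a <- box[1] / n
  idx <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  pos <- as.matrix(idx[seq_len(N), ]) * a + a / 2
  periodicConfiguration(pos, box)
}

#' Generate Lennard-Jones reference data
#'
#' Equilibrated Metropolis MC under the exact (truncated, unshifted) LJ pair
#' potential; returns the reference RDF on the configured grid plus evenly
#' spaced equilibrium frames to serve as training starting points. This
#' replaces an external atomistic reference with a self-contained one.
#'
#' @param sp a [statePoint()].
#' @param run a [runConfig()]; defaults to a desk-scale budget of 2e7 steps
#'   with 1e6 equilibration, 200 saved frames.
#' @param seed RNG seed (two runs with the same seed are bit-identical).
#' @param exact_shell passed to the RDF normalization.
#' @return list: `reference` (`rdf_curve`), `frames`, `system`
#'   ([referenceSystem()]), `acceptance`, `state_point`.
#' @export
ljReference <- function(sp, run = NULL, seed = 1, exact_shell = FALSE) {
  if (is.null(run))
    run <- runConfig(steps = 2e7, equil_steps = 1e6, output_freq = 1000,
                     rdf_rmax = 10, rdf_nbins = 400, n_frames = 200)
  if (sp$rcut > min(sp$box) / 2 + 1e-9)
    stop("LJ cutoff exceeds half the box")
  if (run$n_frames < 1) stop("reference generation needs saved frames")
  thermo <- thermoState(sp$T)
  pot <- ljPotential(sp$eps, sp$sigma, sp$rcut)
  set.seed(seed)
  start <- lattice_start(sp$N, sp$box)
  acc <- runSampling(start, pot, run, thermo, exact_shell = exact_shell)
  reference <- rdfCurve(acc$grid, acc$g)
  list(reference = reference, frames = acc$frames,
       system = referenceSystem(reference, acc$frames, thermo,
                                label = sprintf("rho=%.0f", sp$density)),
       acceptance = acc$acceptance, state_point = sp, potential = pot)
}

#' Family of reference state points at several densities
#'
#' Emulates a concentration series: one reference bundle per density, all at
#' the base temperature, with an optional per-state scaling of the LJ well
#' depth (`eps_factors`) so that the underlying pair interaction is state
#' dependent, as effective coarse-grained potentials with implicit solvent
#' are. With state-dependent depths no single pair potential fits the whole
#' family, which is exactly the transferability problem shape used for
#' multi-state training.
#'
#' @param base a [statePoint()] template.
#' @param densities vector of densities (kg/m^3), `>= 2` entries unless a
#'   single state is requested explicitly.
#' @param labels unique labels (default from densities).
#' @param eps_factors optional per-state multipliers of `base$eps`.
#' @param run,seed,exact_shell passed to [ljReference()]; state `s` uses
#'   `seed + 100 * s`.
#' @return list of reference bundles (see [ljReference()]).
#' @export
stateSeries <- function(base, densities, labels = NULL, eps_factors = NULL,
                        run = NULL, seed = 1, exact_shell = FALSE) {
  if (is.null(labels)) labels <- sprintf("rho=%.0f", densities)
  if (anyDuplicated(labels)) stop("duplicate state labels")
  if (is.null(eps_factors)) eps_factors <- rep(1, length(densities))
  out <- vector("list", length(densities))
  names(out) <- labels
  for (s in seq_along(densities)) {
    sp <- statePoint(N = base$N, T = base$T, density = densities[s],
                     mass = base$mass, eps = base$eps * eps_factors[s],
                     sigma = base$sigma, rcut = base$rcut)
    out[[s]] <- ljReference(sp, run = run, seed = seed + 100L * s,
                            exact_shell = exact_shell)
    out[[s]]$system$label <- labels[s]
  }
  out
}
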