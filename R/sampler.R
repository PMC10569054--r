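#' Thermodynamic state
#'
#' Energies are handled in Kelvin (E/kB), so `beta = 1/T` in 1/K.
#'
#' @param T temperature in K (`> 0`).
#' @return a `thermo_state` with `T` and `beta`.
#' @export
thermoState <- function(T) {
  if (!is.finite(T) || T <= 0) stop("T must be positive")
  structure(list(T = T, beta = 1 / T), class = "thermo_state")
}

#' Lennard-Jones pair potential
#'
#' Truncated (not shifted) at `rcut`; energy unit Kelvin (epsilon = eps/kB).
#'
#' @param eps well depth in K.
#' @param sigma size parameter in Angstrom.
#' @param rcut truncation radius in Angstrom.
#' @export
ljPotential <- function(eps, sigma, rcut) {
  structure(list(eps = eps, sigma = sigma, rcut = rcut),
            class = c("lj_potential", "cg_energy"))
}

#' Tabulated pair potential
#'
#' Piecewise-constant on uniform bins `[a*dr, (a+1)*dr)`; zero beyond the
#' table. This is the representation used by the inverse-MC baseline and by
#' PMF-based sampling.
#'
#' @param values energy per bin (Kelvin).
#' @param dr bin width (Angstrom).
#' @export
pairTable <- function(values, dr) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("table values must be finite")
  if (dr <= 0) stop("dr must be positive")
  structure(list(values = values, dr = dr, rmax = dr * length(values)),
            class = c("pair_table", "cg_energy"))
}

energy_model_args <- function(energy) {
  if (inherits(energy, "lj_potential"))
    return(list(type = 0L, model = list(eps = energy$eps, sigma = energy$sigma,
                                        rcut = energy$rcut)))
  if (inherits(energy, "pair_table"))
    return(list(type = 1L, model = list(values = energy$values,
                                        dr = energy$dr)))
  if (inherits(energy, "cg_model"))
    return(list(type = 2L, model = as_model_list(energy)))
  stop("unsupported energy model")
}

#' One Metropolis displacement move
#'
#' A uniformly chosen site is displaced uniformly in a cube of half-width
#' `max_disp`, wrapped into the box, and accepted with probability
#' `min(1, exp(-beta dE))`. A non-finite `dE` rejects the move with a
#' warning. The energy change is computed incrementally and agrees with full
#' recomputation.
#'
#' @param config a [periodicConfiguration()].
#' @param energy an energy model ([ljPotential()], [pairTable()] or
#'   [cgModel()]).
#' @param max_disp maximum displacement per axis (Angstrom, `> 0`).
#' @param thermo a [thermoState()].
#' @return list with `config`, `dE`, `accepted`, `site`.
#' @export
metropolisStep <- function(config, energy, max_disp, thermo) {
  if (max_disp <= 0) stop("max_disp must be positive")
  em <- energy_model_args(energy)
  res <- cpp_metropolis_step(config$positions, config$box, thermo$beta,
                             em$type, em$model, max_disp)
  list(config = periodicConfiguration(res$pos, config$box, config$species,
                                      wrap = FALSE),
       dE = res$dE, accepted = res$accepted, site = res$site)
}

#' Metropolis Monte Carlo sampling with RDF and fluctuation accumulators
#'
#' Runs displacement MC from `start` under `energy`. During equilibration the
#' step size adapts multiplicatively toward the target acceptance ratio and
#' is then frozen for production (adapting during production would violate
#' detailed balance). Every `output_freq` production steps the instantaneous
#' RDF estimator is accumulated; for network models with `collect_grad =
#' TRUE` the fluctuation-formula terms `<dE/dw>` and `<g_a dE/dw>` are
#' accumulated as well, and with `collect_scov = TRUE` the pair-histogram
#' covariance needed by the inverse-MC baseline.
#'
#' @param start starting [periodicConfiguration()].
#' @param energy energy model.
#' @param run a [runConfig()].
#' @param thermo a [thermoState()].
#' @param collect_grad collect Eq-6-style weight-gradient averages (network
#'   models only).
#' @param collect_scov collect pair-histogram first/second moments.
#' @param keep_samples retain the per-sample RDF estimators (matrix
#'   `n_samples x n_bins`), used for noise-floor and standard-error
#'   estimation.
#' @param exact_shell use exact shell volumes in the RDF normalization
#'   instead of `4 pi r_center^2 dr`.
#' @return a `sampling_acc` list: `g`, `n_samples`, `acceptance`, `max_disp`,
#'   `final` (configuration), `frames`, and the requested accumulators
#'   (`dEdw`, `cross`, `S`, `SS`, `g_samples`).
#' @export
runSampling <- function(start, energy, run, thermo, collect_grad = FALSE,
                        collect_scov = FALSE, keep_samples = FALSE,
                        exact_shell = FALSE) {
  stopifnot(inherits(run, "run_config"))
  if (!run$allow_large_rmax && run$rdf_rmax > min(start$box) / 2 + 1e-9)
    stop("rdf_rmax exceeds half the box; set allow_large_rmax in runConfig")
  em <- energy_model_args(energy)
  if (collect_grad && em$type != 2L)
    stop("collect_grad requires a network energy model")
  res <- cpp_run_mc(start$positions, start$box, thermo$beta, em$type,
                    em$model, run$rdf_rmax, run$rdf_nbins, run$steps,
                    run$equil_steps, run$output_freq, run$max_disp,
                    run$target_acceptance, TRUE, run$adapt_interval,
                    collect_grad, collect_scov, keep_samples, run$n_frames,
                    exact_shell)
  out <- list(
    g = as.numeric(res$g), n_samples = res$n_samples,
    acceptance = res$acceptance, max_disp = res$max_disp,
    final = periodicConfiguration(res$pos, start$box, start$species,
                                  wrap = FALSE),
    frames = lapply(res$frames, function(p)
      periodicConfiguration(p, start$box, start$species, wrap = FALSE)),
    grid = rdfGrid(run$rdf_rmax, run$rdf_nbins),
    energy = res$energy)
  for (nm in c("dEdw", "cross", "S", "SS", "g_samples"))
    if (!is.null(res[[nm]])) out[[nm]] <- res[[nm]]
  class(out) <- "sampling_acc"
  out
}

#' @export
print.sampling_acc <- function(x, ...) {
  cat(sprintf("<sampling_acc> %d samples, acceptance %.3f, max_disp %.3f A\n",
              x$n_samples, x$acceptance, x$max_disp))
  invisible(x)
}

#' Sample several reference systems under one set of weights
#'
#' Each system gets an independent RNG stream derived from the master seed,
#' so results do not depend on execution order. Each run starts from a frame
#' drawn at random from the system's reference frame pool.
#'
#' @param systems list of reference systems (see [referenceSystem()]).
#' @param energy shared energy model (network).
#' @param run a [runConfig()]; the RDF grid is taken per system.
#' @param seed master seed; system `s` uses `seed + s`.
#' @param ... passed to [runSampling()].
#' @return list of `sampling_acc`, one per system.
#' @export
multiSystemSampling <- function(systems, energy, run, seed, ...) {
  out <- vector("list", length(systems))
  for (s in seq_along(systems)) {
    sys <- systems[[s]]
    set.seed(seed + s)
    start <- sys$frames[[sample.int(length(sys$frames), 1L)]]
    run_s <- run
    run_s$rdf_rmax <- sys$reference$grid$rmax
    run_s$rdf_nbins <- sys$reference$grid$nbins
    acc <- tryCatch(
      runSampling(start, energy, run_s, sys$thermo, ...),
      error = function(e) stop(sprintf("system %d: %s", s, conditionMessage(e)),
                               call. = FALSE))
    out[[s]] <- acc
  }
  out
}

#' Bundle a reference state point for training
#'
#' @param reference an `rdf_curve` (the reference RDF).
#' @param frames list of equilibrium [periodicConfiguration()] frames.
#' @param thermo a [thermoState()].
#' @param label optional name.
#' @return a `ref_system`.
#' @export
referenceSystem <- function(reference, frames, thermo, label = "system") {
  stopifnot(inherits(reference, "rdf_curve"), length(frames) >= 1L,
            inherits(thermo, "thermo_state"))
  structure(list(reference = reference, frames = frames, thermo = thermo,
                 label = label), class = "ref_system")
}
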