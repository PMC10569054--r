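#' Pair-distance histogram of a configuration
#'
#' Integer counts of unordered minimum-image pairs per grid bin; the total
#' equals the number of pairs within range.
#'
#' @param config a [periodicConfiguration()].
#' @param grid an [rdfGrid()].
#' @return integer-valued numeric vector `S` of length `nbins`.
#' @export
pairHistogram <- function(config, grid) {
  cpp_pair_hist(config$positions, config$box, grid$rmax, grid$nbins)
}

# Ideal-gas per-bin normalization shared by the RDF estimator and the
# reference-g <-> reference-S conversion (bin-center shell volume).
rdf_norm <- function(grid, N, V) {
  N * (N - 1) / 2 * 4 * pi * grid$centers^2 * grid$dr / V
}

pinv_svd <- function(A, rel_tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rel_tol * max(sv$d)
  if (!any(keep)) stop("all-zero covariance: nothing to invert")
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Initial inverse-MC table from the PMF
#'
#' The potential of mean force with the linear core extrapolation is the
#' standard starting guess for the iteration.
#'
#' @param reference reference `rdf_curve`.
#' @param thermo a [thermoState()].
#' @return a [pairTable()].
#' @export
imcInitialTable <- function(reference, thermo) {
  pmfFromRDF(reference, thermo)$table
}

#' One inverse Monte Carlo update of a tabulated pair potential
#'
#' Samples the system under the current table, accumulating the
#' pair-histogram moments, then solves the linearized relation
#' `d<S_a> = -beta Cov(S_a, S_c) dw_c` for the update that moves `<S>`
#' toward the reference, scaled by the regularization factor. The covariance
#' is inverted by SVD pseudo-inverse with a relative singular-value cutoff
#' (never-visited core bins drop out and keep their extrapolated values).
#'
#' @param system a [referenceSystem()] (reference RDF + starting frames).
#' @param table current [pairTable()] on the reference grid.
#' @param run a [runConfig()].
#' @param regularization factor in (0, 1].
#' @param seed RNG seed.
#' @param sv_tol relative singular-value cutoff of the pseudo-inverse.
#' @return list: updated `table`, `sampled` (`rdf_curve`), `loss`,
#'   `acceptance`, `delta` (the applied update).
#' @export
imcIterate <- function(system, table, run, regularization = 0.5, seed = 1,
                       sv_tol = 1e-10) {
  if (regularization <= 0 || regularization > 1)
    stop("regularization must be in (0, 1]")
  grid <- system$reference$grid
  if (abs(table$dr - grid$dr) > 1e-9 || length(table$values) != grid$nbins)
    stop("table and reference grids differ")
  set.seed(seed)
  start <- system$frames[[sample.int(length(system$frames), 1L)]]
  run$rdf_rmax <- grid$rmax
  run$rdf_nbins <- grid$nbins
  acc <- runSampling(start, table, run, system$thermo, collect_scov = TRUE)
  Cov <- acc$SS - outer(acc$S, acc$S)
  N <- nSites(start)
  V <- prod(start$box)
  S_ref <- system$reference$g * rdf_norm(grid, N, V)
  rhs <- S_ref - acc$S
  delta <- -(1 / system$thermo$beta) *
    drop(pinv_svd(Cov, sv_tol) %*% rhs) * regularization
  table$values <- table$values + delta
  sampled <- rdfCurve(grid, acc$g)
  list(table = table, sampled = sampled,
       loss = rdfLoss(sampled, system$reference),
       acceptance = acc$acceptance, delta = delta)
}

#' Run an inverse Monte Carlo optimization schedule
#'
#' Default schedule: five iterations with regularization 0.5, then five with
#' 1.0, starting from the PMF table.
#'
#' @param system a [referenceSystem()].
#' @param run a [runConfig()].
#' @param schedule vector of regularization factors, one per iteration.
#' @param table optional starting [pairTable()] (default: PMF).
#' @param seed master seed; iteration `it` uses `seed + it`.
#' @param verbose print per-iteration loss to stderr.
#' @return list: final `table`, `history` data frame, final `sampled` curve.
#' @export
imcRun <- function(system, run, schedule = c(rep(0.5, 5), rep(1, 5)),
                   table = NULL, seed = 1, verbose = FALSE) {
  if (is.null(table)) table <- imcInitialTable(system$reference, system$thermo)
  rows <- vector("list", length(schedule))
  sampled <- NULL
  for (it in seq_along(schedule)) {
    res <- imcIterate(system, table, run, regularization = schedule[it],
                      seed = seed + it)
    table <- res$table
    sampled <- res$sampled
    rows[[it]] <- data.frame(iteration = it, loss = res$loss,
                             regularization = schedule[it],
                             acceptance = res$acceptance)
    if (verbose)
      message(sprintf("imc iter %2d  loss %.5g  (reg %.2g)", it, res$loss,
                      schedule[it]))
  }
  list(table = table, history = do.call(rbind, rows), sampled = sampled)
}

#' Equivalence of a linear network and inverse Monte Carlo
#'
#' With a linear (no-hidden-layer) network whose descriptors are the
#' indicators of the pair-distance bins, the per-site descriptor sums equal
#' the double-counted pair histogram, the total energy equals the tabulated
#' pair energy, and the fluctuation-formula gradient rows equal the
#' inverse-MC covariance rows. With narrow Gaussians at the bin centers the
#' correspondence is approximate: a Gaussian basis carries per-pair mass
#' `sqrt(pi/eta)/dr` relative to the indicator basis (and the cosine cutoff
#' attenuates it by `fc(r)`), so the comparison rescales by
#' `kappa = dr * sqrt(eta/pi)` and compares against the `fc`-compensated
#' table.
#'
#' @param grid an [rdfGrid()] (bins double as descriptor centers).
#' @param configs list of [periodicConfiguration()]s for the energy
#'   comparison.
#' @param thermo a [thermoState()] for the gradient comparison.
#' @param weights table values / network weights per bin (default: a smooth
#'   LJ-like curve in Kelvin).
#' @param eta Gaussian width for the approximate mode (1/Angstrom^2).
#' @param run optional [runConfig()] for the sampling-based gradient check.
#' @param seed RNG seed.
#' @return list with `indicator` (max relative energy deviation,
#'   max absolute gradient-row deviation) and `gaussian` (RMS relative
#'   energy deviation).
#' @export
linearNNIMCEquivalence <- function(grid, configs, thermo, weights = NULL,
                                   eta = 400, run = NULL, seed = 1) {
  if (is.null(weights)) {
    # a smooth effective-potential-like curve: moderate repulsive shoulder
    # plus an attractive well, no extreme core values
    r <- grid$centers
    weights <- 150 * exp(-((r / (0.3 * grid$rmax))^2)) -
      100 * exp(-((r - 0.55 * grid$rmax) / (0.2 * grid$rmax))^2)
  }
  K <- grid$nbins
  ind_spec <- descriptorSpec(eta = rep(0, K), rs = grid$centers,
                             rc = grid$rmax, type = "indicator")
  ind_model <- cgModel(ind_spec, weights = weights)
  # (a) energies, indicator mode: E_NN vs sum_a w_a * 2 S_a
  dev_ind <- vapply(configs, function(cf) {
    eNN <- totalEnergy(cf, ind_model, allow_large_rmax = TRUE)$total
    S <- pairHistogram(cf, grid)
    eH <- sum(weights * 2 * S)
    abs(eNN - eH) / max(abs(eH), 1e-12)
  }, numeric(1))
  # (b) gradient rows vs covariance rows on one shared trajectory
  max_grad_dev <- NA_real_
  if (!is.null(run)) {
    set.seed(seed)
    run$rdf_rmax <- grid$rmax
    run$rdf_nbins <- grid$nbins
    run$allow_large_rmax <- TRUE
    acc <- runSampling(configs[[1L]], ind_model, run, thermo,
                       collect_grad = TRUE, collect_scov = TRUE)
    cov_nn <- acc$cross - outer(acc$g, acc$dEdw)
    cov_imc <- acc$SS - outer(acc$S, acc$S)
    N <- nSites(configs[[1L]])
    V <- prod(configs[[1L]]$box)
    norm <- rdf_norm(grid, N, V)
    # dE/dw_i = 2 S_i and g_a = S_a / norm_a, so cov_nn = 2 cov_imc / norm_a
    pred <- 2 * cov_imc / norm
    max_grad_dev <- max(abs(cov_nn - pred))
  }
  # (c) energies, narrow-Gaussian mode with mass and cutoff compensation
  kappa <- grid$dr * sqrt(eta / pi)
  gau_spec <- descriptorSpec(eta = rep(eta, K), rs = grid$centers,
                             rc = grid$rmax)
  gau_model <- cgModel(gau_spec, weights = weights)
  fc_c <- cutoffFc(grid$centers, grid$rmax)
  dev_gau <- vapply(configs, function(cf) {
    eNN <- totalEnergy(cf, gau_model, allow_large_rmax = TRUE)$total * kappa
    S <- pairHistogram(cf, grid)
    eH <- sum(weights * fc_c * 2 * S)
    (eNN - eH) / max(abs(eH), 1e-12)
  }, numeric(1))
  list(indicator = list(max_energy_dev = max(dev_ind),
                        max_grad_dev = max_grad_dev),
       gaussian = list(rms_energy_dev = sqrt(mean(dev_gau^2))))
}
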