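#' RDF-matching loss
#'
#' `L = sum_a (<g_a>^NN - <g_a>^ref)^2` over the shared grid.
#'
#' @param sampled,reference `rdf_curve`s on identical grids.
#' @export
rdfLoss <- function(sampled, reference) {
  if (!same_grid(sampled$grid, reference$grid)) stop("RDF grid mismatch")
  sum((sampled$g - reference$g)^2)
}

#' Loss gradient from the fluctuation (covariance) formula
#'
#' The sampled RDF is not a direct network output, so the chain rule through
#' the sampler is replaced by the statistical-mechanical identity
#' `d<g_a>/dw_i = -beta (<g_a dE/dw_i> - <g_a><dE/dw_i>)`, whose terms are
#' accumulated during sampling. Then
#' `dL/dw_i = sum_a 2 (<g_a> - g_a^ref) d<g_a>/dw_i`.
#'
#' @param acc a `sampling_acc` from [runSampling()] with `collect_grad =
#'   TRUE`.
#' @param reference reference `rdf_curve` on the same grid.
#' @param thermo a [thermoState()].
#' @return length-`nw` gradient vector.
#' @export
lossGradient <- function(acc, reference, thermo) {
  if (is.null(acc$cross) || is.null(acc$dEdw))
    stop("sampling accumulators lack gradient terms; rerun with collect_grad")
  if (!same_grid(acc$grid, reference$grid)) stop("RDF grid mismatch")
  if (acc$n_samples < 1) stop("no samples")
  cov <- acc$cross - outer(acc$g, acc$dEdw)        # <g dE/dw> - <g><dE/dw>
  dg_dw <- -thermo$beta * cov                       # n_bins x nw
  drop(crossprod(dg_dw, 2 * (acc$g - reference$g)))
}

#' AMSGrad optimizer state
#'
#' @param n number of parameters.
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps denominator offset.
#' @export
amsgradInit <- function(n, lr = 0.005, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  structure(list(m = numeric(n), v = numeric(n), vhat = numeric(n), t = 0,
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps),
            class = "amsgrad_state")
}

#' One AMSGrad update
#'
#' Bias-corrected first moment, element-wise running maximum of the
#' (bias-corrected) second moment: `w <- w - lr * mhat / (sqrt(vhat_c) +
#' eps)`. The max second moment never decreases.
#'
#' @param state an [amsgradInit()] state.
#' @param w parameter vector.
#' @param grad gradient vector.
#' @return list with updated `w` and `state`.
#' @export
amsgradStep <- function(state, w, grad) {
  if (any(!is.finite(grad))) stop("non-finite gradient")
  if (length(grad) != length(w)) stop("gradient/parameter length mismatch")
  res <- cpp_amsgrad_step(w, grad, state$m, state$v, state$vhat, state$t,
                          state$lr, state$beta1, state$beta2, state$eps)
  state$m <- res$m; state$v <- res$v; state$vhat <- res$vhat; state$t <- res$t
  list(w = res$w, state = state)
}

#' PMF-matching pretraining
#'
#' Each step: pick a random reference frame (per system), displace one
#' random site, and compute the energy change predicted by the network and
#' by the PMF pair sum. The per-step loss is `(dE_NN - dE_PMF)^2` with
#' gradient `2 (dE_NN - dE_PMF) (dE2_NN/dw - dE1_NN/dw)`; gradients are
#' averaged across systems, then one AMSGrad step is taken.
#'
#' @param systems list of [referenceSystem()]s.
#' @param model a [cgModel()]; its weights are the starting point.
#' @param n_steps number of pretraining steps (reference protocol: 50000).
#' @param max_disp displacement half-width (Angstrom).
#' @param lr,beta1,beta2,eps AMSGrad hyperparameters. The learning rate has
#'   energy units (weights are Kelvin-valued); the default is 0.01 kBT,
#'   i.e. `0.01 * mean(T)` across the systems.
#' @param allow_large_rmax permit `rc > min(box)/2`.
#' @return list: updated `model`, per-step `loss` history, optimizer state.
#' @export
pretrainModel <- function(systems, model, n_steps = 50000, max_disp = 0.5,
                          lr = NULL, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          allow_large_rmax = FALSE) {
  if (length(systems) < 1L) stop("need at least one system")
  if (is.null(lr))
    lr <- 0.01 * mean(vapply(systems, function(s) s$thermo$T, numeric(1)))
  sys_list <- lapply(systems, function(sys) {
    if (length(sys$frames) == 0L) stop("empty frame pool")
    check_rc_box(model$spec$rc, sys$frames[[1L]]$box, allow_large_rmax)
    pmf <- pmfFromRDF(sys$reference, sys$thermo)
    list(frames = lapply(sys$frames, function(fr) fr$positions),
         box = sys$frames[[1L]]$box, pmf = pmf$V, pmf_dr = pmf$grid$dr)
  })
  res <- cpp_pretrain(sys_list, model$spec$eta, model$spec$rs, model$spec$rc,
                      if (model$spec$type == "indicator") 1L else 0L,
                      model$sizes, model$w, max_disp, as.integer(n_steps),
                      lr, beta1, beta2, eps, list())
  model$w <- res$w
  list(model = model, loss = res$loss, opt = res$opt)
}

#' Measure the RDF sampling-noise floor of a reference system
#'
#' Re-samples the reference state with the given energy model and budget and
#' returns the loss of the re-sampled RDF against the reference curve. This
#' is the loss level below which differences are indistinguishable from
#' sampling noise at that budget.
#'
#' @param system a [referenceSystem()].
#' @param energy the generating energy model.
#' @param run a [runConfig()] matching the training sampling budget.
#' @param seed RNG seed.
#' @export
noiseFloor <- function(system, energy, run, seed = 1) {
  set.seed(seed)
  start <- system$frames[[sample.int(length(system$frames), 1L)]]
  run$rdf_rmax <- system$reference$grid$rmax
  run$rdf_nbins <- system$reference$grid$nbins
  acc <- runSampling(start, energy, run, system$thermo)
  rdfLoss(rdfCurve(acc$grid, acc$g), system$reference)
}

#' Train a network potential against reference RDFs
#'
#' Each iteration: Monte Carlo sampling of every system under the current
#' weights (independent RNG streams, starting from a random reference
#' frame), per-system losses and fluctuation-formula gradients, gradient
#' summed over systems (the total loss is the sum of per-system losses), one
#' AMSGrad step. Runs a fixed iteration budget with an optional early stop
#' on a loss plateau.
#'
#' @param systems list of [referenceSystem()]s sharing the descriptor spec.
#' @param model starting [cgModel()] (typically pretrained).
#' @param run a [runConfig()] giving the per-iteration MC budget.
#' @param n_iterations iteration budget (reference protocol: 50).
#' @param seed master seed; iteration `it`, system `s` uses
#'   `seed + 1000 * it + s`.
#' @param lr,beta1,beta2,eps AMSGrad hyperparameters. The learning rate has
#'   energy units; the default is 0.005 kBT (`0.005 * mean(T)` across
#'   systems).
#' @param plateau_tol,plateau_len early stop when the relative change of the
#'   smoothed loss over `plateau_len` iterations falls below `plateau_tol`
#'   (`NULL` disables).
#' @param opt_state optional optimizer state from a previous run (resume).
#' @param first_iteration iteration index to start from; per-iteration RNG
#'   streams are derived as `seed + 1000 * iteration + system`, so resuming
#'   a run at iteration k with the saved optimizer state and weights
#'   reproduces the remaining iterations exactly.
#' @param select `"final"` returns the weights after the last iteration;
#'   `"best"` returns the weights whose sampled total loss was lowest
#'   (fluctuation-gradient training is noisy, and taking the best-loss state
#'   for production is standard practice for these models).
#' @param verbose print per-iteration diagnostics to stderr.
#' @return a `training_state`: final `model`, `history` data frame
#'   (iteration, per-system losses, total, mean, acceptance), optimizer
#'   state, and `per_system` final sampled curves.
#' @export
trainModel <- function(systems, model, run, n_iterations = 50, seed = 1,
                       lr = NULL, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       plateau_tol = NULL, plateau_len = 5,
                       opt_state = NULL, first_iteration = 1L,
                       select = c("final", "best"), verbose = FALSE) {
  select <- match.arg(select)
  if (length(systems) < 1L) stop("need at least one system")
  if (is.null(lr))
    lr <- 0.005 * mean(vapply(systems, function(s) s$thermo$T, numeric(1)))
  opt <- if (is.null(opt_state))
    amsgradInit(model$nw, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
  else opt_state
  S <- length(systems)
  iters <- seq(first_iteration, length.out = n_iterations)
  hist_rows <- vector("list", n_iterations)
  last_acc <- NULL
  total_hist <- numeric(0)
  best_w <- model$w
  best_loss <- Inf
  for (it in iters) {
    grad <- numeric(model$nw)
    losses <- numeric(S)
    accs <- numeric(S)
    per_sys <- vector("list", S)
    for (s in seq_len(S)) {
      sys <- systems[[s]]
      set.seed(seed + 1000L * it + s)
      start <- sys$frames[[sample.int(length(sys$frames), 1L)]]
      run_s <- run
      run_s$rdf_rmax <- sys$reference$grid$rmax
      run_s$rdf_nbins <- sys$reference$grid$nbins
      acc <- tryCatch(
        runSampling(start, model, run_s, sys$thermo, collect_grad = TRUE),
        error = function(e)
          stop(sprintf("iteration %d, system %d: %s", it, s,
                       conditionMessage(e)), call. = FALSE))
      losses[s] <- rdfLoss(rdfCurve(acc$grid, acc$g), sys$reference)
      grad <- grad + lossGradient(acc, sys$reference, sys$thermo)
      accs[s] <- acc$acceptance
      per_sys[[s]] <- acc
    }
    if (all(grad == 0) && mean(accs) > 0.999)
      warning(sprintf(paste("iteration %d: zero gradient at acceptance ~1;",
                            "the bias-free ReLU network has likely collapsed",
                            "to zero output (reduce the learning rate)"), it))
    total <- sum(losses)
    if (total < best_loss) {
      # the sampled loss belongs to the weights *before* this update
      best_loss <- total
      best_w <- model$w
    }
    st <- amsgradStep(opt, model$w, grad)
    model$w <- st$w
    opt <- st$state
    total_hist <- c(total_hist, total)
    hist_rows[[it - first_iteration + 1L]] <- data.frame(
      iteration = it, total_loss = total, mean_loss = mean(losses),
      t(setNames(losses, paste0("loss_", seq_len(S)))),
      acceptance = mean(accs))
    last_acc <- per_sys
    if (verbose)
      message(sprintf("iter %3d  total loss %.5g  mean %.5g  acc %.3f",
                      it, total, mean(losses), mean(accs)))
    if (!is.null(plateau_tol) && length(total_hist) >= 2 * plateau_len) {
      recent <- mean(tail(total_hist, plateau_len))
      prev <- mean(tail(head(total_hist, -plateau_len), plateau_len))
      if (abs(prev - recent) < plateau_tol * abs(prev)) break
    }
  }
  if (select == "best") model$w <- best_w
  structure(list(model = model, opt = opt, best_loss = best_loss,
                 history = do.call(rbind, hist_rows[!vapply(hist_rows,
                                                            is.null, TRUE)]),
                 per_system = last_acc, seed = seed),
            class = "training_state")
}

#' @export
print.training_state <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<training_state> %d iterations, final total loss %.5g\n",
              n, x$history$total_loss[n]))
  invisible(x)
}
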