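#' Validate the fluctuation-formula gradient against finite differences
#'
#' The covariance (fluctuation) estimate of `d<g_a>/dw_i` from a single run
#' is compared with central finite differences of independently re-sampled
#' averages at `w +/- delta e_i`, for a small linear model. Everything is
#' replicated with independent seeds so each cell gets a standard error, and
#' the two estimators are compared cell-wise in units of their combined
#' standard error.
#'
#' @param model a linear [cgModel()] (few weights).
#' @param start starting [periodicConfiguration()].
#' @param thermo a [thermoState()].
#' @param run a [runConfig()] (per-run MC budget).
#' @param delta finite-difference step on each weight, in Kelvin. The
#'   default corresponds to 0.05 kBT, the scale at which the induced RDF
#'   change is resolvable without leaving the linear-response regime.
#' @param replicates independent replicate runs per estimator.
#' @param seed master seed.
#' @return list: `frac_within_3se` (fraction of (bin, weight) cells whose
#'   estimators agree within 3 combined standard errors), `z` (cell-wise
#'   standardized differences), `fluct`, `fd` (mean estimator matrices).
#' @export
fluctuationGradientCheck <- function(model, start, thermo, run,
                                     delta = 0.05 * thermo$T,
                                     replicates = 6, seed = 1) {
  if (length(model$sizes) != 2L)
    stop("the check is defined for linear models")
  K <- model$nw
  nb <- run$rdf_nbins
  fluct <- array(NA_real_, c(replicates, nb, K))
  fd <- array(NA_real_, c(replicates, nb, K))
  sample_g <- function(w, sd) {
    m <- model
    m$w <- w
    set.seed(sd)
    runSampling(start, m, run, thermo, collect_grad = TRUE)
  }
  for (r in seq_len(replicates)) {
    base_seed <- seed + 1000L * r
    acc <- sample_g(model$w, base_seed)
    fluct[r, , ] <- -thermo$beta * (acc$cross - outer(acc$g, acc$dEdw))
    for (i in seq_len(K)) {
      wp <- model$w; wp[i] <- wp[i] + delta
      wm <- model$w; wm[i] <- wm[i] - delta
      gp <- sample_g(wp, base_seed + 10L * i + 1L)$g
      gm <- sample_g(wm, base_seed + 10L * i + 2L)$g
      fd[r, , i] <- (gp - gm) / (2 * delta)
    }
  }
  mfl <- apply(fluct, c(2, 3), mean)
  mfd <- apply(fd, c(2, 3), mean)
  se <- sqrt(apply(fluct, c(2, 3), var) / replicates +
             apply(fd, c(2, 3), var) / replicates)
  diffm <- abs(mfl - mfd)
  z <- ifelse(se > 0, diffm / se, ifelse(diffm == 0, 0, Inf))
  list(frac_within_3se = mean(z <= 3), z = z, fluct = mfl, fd = mfd, se = se)
}
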