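#' Bias-free site-energy network
#'
#' A feed-forward network mapping each site's G2 vector to a scalar site
#' energy: ReLU on hidden layers, identity output, and no bias parameters
#' anywhere. The total energy of a configuration is the sum of site energies
#' (ascending site order, fixed for reproducibility). With no hidden layers
#' the model is linear, `E_n = sum_i w_i G2_{n,i}`, and the weights have the
#' meaning of an effective pair potential sampled at the Gaussian centers.
#'
#' @param spec a [descriptorSpec()]; its size fixes the input width.
#' @param hidden integer vector of hidden-layer widths (e.g. `c(20, 20, 20)`
#'   for Model 1, `c(40, 40, 40)` for Model 2, `integer(0)` for the linear
#'   model).
#' @param weights optional flat weight vector; if `NULL`, initialized
#'   uniformly in `[-1, 1]` from the current RNG state.
#' @return a `cg_model` with elements `spec`, `sizes`, `w`.
#' @export
cgModel <- function(spec, hidden = integer(0), weights = NULL) {
  stopifnot(inherits(spec, "desc_spec"))
  sizes <- as.integer(c(spec$K, hidden, 1L))
  if (any(sizes < 1L)) stop("layer widths must be positive")
  nw <- sum(sizes[-length(sizes)] * sizes[-1L])
  if (is.null(weights)) {
    weights <- runif(nw, -1, 1)
  } else {
    weights <- as.numeric(weights)
    if (length(weights) != nw)
      stop(sprintf("weight vector has length %d, expected %d",
                   length(weights), nw))
  }
  if (any(!is.finite(weights))) stop("weights must be finite")
  structure(list(spec = spec, sizes = sizes, w = weights, nw = nw),
            class = "cg_model")
}

#' @export
print.cg_model <- function(x, ...) {
  cat(sprintf("<cg_model> layers [%s], %d weights, %d %s descriptors\n",
              paste(x$sizes, collapse = " "), x$nw, x$spec$K, x$spec$type))
  invisible(x)
}

nWeights <- function(model) model$nw

as_model_list <- function(model) {
  list(eta = model$spec$eta, rs = model$spec$rs, rc = model$spec$rc,
       desc_type = if (model$spec$type == "indicator") 1L else 0L,
       sizes = model$sizes, w = model$w)
}

#' Site energies from a descriptor matrix
#'
#' @param G N x K descriptor matrix.
#' @param model a `cg_model`.
#' @return length-N vector of site energies (Kelvin).
#' @export
siteEnergies <- function(G, model) {
  if (any(!is.finite(model$w))) stop("weights must be finite")
  cpp_site_energies(as.matrix(G), model$sizes, model$w)
}

#' Energy of a single site from its G2 vector
#'
#' @param g2 length-K descriptor vector.
#' @param model a `cg_model`.
#' @export
siteEnergy <- function(g2, model) {
  siteEnergies(matrix(g2, nrow = 1L), model)[1L]
}

#' Total energy of a configuration
#'
#' @param config a [periodicConfiguration()], or `NULL` if `G` is given.
#' @param model a `cg_model`.
#' @param G optional precomputed descriptor matrix.
#' @param allow_large_rmax permit `rc > min(box)/2`.
#' @return list with `per_site` and `total` (Kelvin).
#' @export
totalEnergy <- function(config, model, G = NULL, allow_large_rmax = FALSE) {
  if (is.null(G)) G <- g2Matrix(config, model$spec, allow_large_rmax)
  e <- siteEnergies(G, model)
  list(per_site = e, total = sum(e))
}

#' Gradient of the total energy with respect to the weights
#'
#' Reverse-mode accumulation over all sites; ReLU subgradient at 0 is 0.
#'
#' @inheritParams totalEnergy
#' @return length-`nw` vector dE/dw.
#' @export
energyWeightGradient <- function(config, model, G = NULL,
                                 allow_large_rmax = FALSE) {
  if (is.null(G)) G <- g2Matrix(config, model$spec, allow_large_rmax)
  if (any(!is.finite(model$w))) stop("weights must be finite")
  cpp_energy_grad(as.matrix(G), model$sizes, model$w)
}
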