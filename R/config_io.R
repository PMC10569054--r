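#' Periodic configuration of coarse-grained sites
#'
#' A set of N site positions (Angstrom) in an orthorhombic periodic box.
#' Positions are wrapped into `[0, box)` on construction; the minimum-image
#' convention is applied by every distance-based operation.
#'
#' @param positions N x 3 numeric matrix of coordinates in Angstrom.
#' @param box numeric length-3 vector of box edge lengths in Angstrom.
#' @param species single character tag for the (single) CG site type.
#' @param wrap wrap positions into the box (default `TRUE`).
#' @return An object of class `cg_config`.
#' @export
periodicConfiguration <- function(positions, box, species = "CG", wrap = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  if (anyNA(positions) || any(!is.finite(positions)))
    stop("positions contain non-finite values")
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive lengths")
  if (wrap)
    positions <- sweep(positions, 2L, box, function(x, L) x - L * floor(x / L))
  structure(list(positions = positions, box = box, species = species),
            class = "cg_config")
}

#' @export
print.cg_config <- function(x, ...) {
  cat(sprintf("<cg_config> %d '%s' sites, box %.3f x %.3f x %.3f A\n",
              nrow(x$positions), x$species, x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

nSites <- function(config) nrow(config$positions)

parse_lattice <- function(comment, line_no) {
  m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (length(m) == 0L)
    stop(sprintf("line %d: missing Lattice=\"...\" box specification", line_no))
  vals <- suppressWarnings(as.numeric(strsplit(
    sub('Lattice="([^"]*)"', "\\1", m), "[[:space:]]+")[[1]]))
  vals <- vals[!is.na(vals)]
  if (length(vals) != 9L)
    stop(sprintf("line %d: Lattice must contain 9 numbers", line_no))
  latt <- matrix(vals, 3L, 3L, byrow = TRUE)
  off <- latt[row(latt) != col(latt)]
  if (any(abs(off) > 1e-8))
    stop(sprintf("line %d: only orthorhombic boxes are supported", line_no))
  diag(latt)
}

#' Read an extended-XYZ trajectory
#'
#' Frames must carry the box on the comment line as
#' `Lattice="Lx 0 0 0 Ly 0 0 0 Lz"` (orthorhombic only). All frames must
#' share the particle count.
#'
#' @param path file path.
#' @return list of [periodicConfiguration()] objects.
#' @export
readXYZ <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  nfirst <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("line %d: expected an atom count", i))
    if (is.na(nfirst)) nfirst <- n
    if (n != nfirst)
      stop(sprintf("line %d: frame has %d atoms, expected %d", i, n, nfirst))
    if (i + 1L + n > length(lines))
      stop(sprintf("line %d: truncated frame (%d atoms declared)", i, n))
    box <- parse_lattice(lines[i + 1L], i + 1L)
    pos <- matrix(NA_real_, n, 3L)
    spec <- character(n)
    for (k in seq_len(n)) {
      toks <- strsplit(trimws(lines[i + 1L + k]), "[[:space:]]+")[[1]]
      if (length(toks) < 4L)
        stop(sprintf("line %d: malformed atom record", i + 1L + k))
      xyz <- suppressWarnings(as.numeric(toks[2:4]))
      if (anyNA(xyz))
        stop(sprintf("line %d: non-numeric coordinates", i + 1L + k))
      spec[k] <- toks[1L]
      pos[k, ] <- xyz
    }
    frames[[length(frames) + 1L]] <-
      periodicConfiguration(pos, box, species = spec[1L], wrap = FALSE)
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no frames found in ", path)
  frames
}

#' Write configurations as extended XYZ
#'
#' @param frames a `cg_config` or list of them.
#' @param path output file.
#' @export
writeXYZ <- function(frames, path) {
  if (inherits(frames, "cg_config")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nSites(fr)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3',
      fr$box[1], fr$box[2], fr$box[3]), con)
    writeLines(sprintf("%s %.10f %.10f %.10f", fr$species,
                       fr$positions[, 1], fr$positions[, 2],
                       fr$positions[, 3]), con)
  }
  invisible(path)
}

#' Map atoms to center-of-mass CG sites
#'
#' Each group of atoms becomes one CG site at the mass-weighted mean
#' position. Groups straddling the periodic boundary are unwrapped using the
#' group's first atom as the anchor before averaging, and the site is wrapped
#' back into the box.
#'
#' @param atom_positions M x 3 matrix (Angstrom).
#' @param masses length-M weights.
#' @param groups list of integer index vectors (disjoint).
#' @param box length-3 box.
#' @param species CG species tag.
#' @return [periodicConfiguration()] with one site per group.
#' @export
mapCOM <- function(atom_positions, masses, groups, box, species = "CG") {
  atom_positions <- as.matrix(atom_positions)
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  idx <- unlist(groups)
  if (anyDuplicated(idx)) stop("groups must be disjoint")
  sites <- matrix(NA_real_, length(groups), 3L)
  for (g in seq_along(groups)) {
    ids <- groups[[g]]
    m <- masses[ids]
    if (sum(m) <= 0) stop("group ", g, " has zero total mass")
    anchor <- atom_positions[ids[1L], ]
    rel <- sweep(atom_positions[ids, , drop = FALSE], 2L, anchor)
    rel <- sweep(rel, 2L, box, function(d, L) d - L * round(d / L))
    sites[g, ] <- anchor + colSums(rel * m) / sum(m)
  }
  periodicConfiguration(sites, box, species = species, wrap = TRUE)
}

#' Save a trained model to a self-describing text file
#'
#' JSON with the descriptor spec, layer sizes and the flat weight vector.
#' Weights are stored as 17-significant-digit strings so the round trip is
#' binary-exact.
#'
#' @param model a `cg_model` (see [cgModel()]).
#' @param path output path.
#' @param meta optional named list of provenance metadata (seed, config hash).
#' @export
saveModel <- function(model, path, meta = list()) {
  stopifnot(inherits(model, "cg_model"))
  obj <- list(
    format = "cgnn-model-1",
    descriptors = list(eta = model$spec$eta, rs = model$spec$rs,
                       rc = model$spec$rc, type = model$spec$type),
    sizes = model$sizes,
    weights = sprintf("%.17g", model$w),
    meta = meta)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Load a model written by [saveModel()]
#'
#' @param path file path.
#' @return a `cg_model`.
#' @export
loadModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  spec <- descriptorSpec(eta = obj$descriptors$eta, rs = obj$descriptors$rs,
                         rc = obj$descriptors$rc,
                         type = if (is.null(obj$descriptors$type)) "gaussian"
                                else obj$descriptors$type)
  w <- as.numeric(obj$weights)
  m <- cgModel(spec, hidden = obj$sizes[-c(1L, length(obj$sizes))], weights = w)
  m$meta <- obj$meta
  m
}

#' Run configuration for Monte Carlo sampling
#'
#' @param steps total MC steps.
#' @param equil_steps equilibration steps (`< steps`); step-size adaptation
#'   happens only here.
#' @param output_freq collect observables every this many production steps.
#' @param target_acceptance target Metropolis acceptance ratio.
#' @param max_disp initial half-width of the displacement cube (Angstrom).
#' @param rdf_rmax,rdf_nbins RDF grid (uniform bins on `[0, rdf_rmax)`).
#' @param allow_large_rmax permit `rdf_rmax > min(box)/2` (explicit override).
#' @param adapt_interval steps between step-size updates during equilibration.
#' @param n_frames frames to save from production (0 = none).
#' @return a `run_config` list.
#' @export
runConfig <- function(steps = 8e6, equil_steps = 2e6, output_freq = 1000,
                      target_acceptance = 0.5, max_disp = 0.5,
                      rdf_rmax = 10, rdf_nbins = 400,
                      allow_large_rmax = FALSE, adapt_interval = 1000,
                      n_frames = 0) {
  if (equil_steps >= steps) stop("equil_steps must be < steps")
  if (output_freq < 1) stop("output_freq must be >= 1")
  if (target_acceptance <= 0 || target_acceptance >= 1)
    stop("target_acceptance must be in (0,1)")
  if (rdf_rmax <= 0 || rdf_nbins < 1) stop("invalid RDF grid")
  structure(list(steps = steps, equil_steps = equil_steps,
                 output_freq = output_freq,
                 target_acceptance = target_acceptance, max_disp = max_disp,
                 rdf_rmax = rdf_rmax, rdf_nbins = rdf_nbins,
                 allow_large_rmax = allow_large_rmax,
                 adapt_interval = adapt_interval, n_frames = n_frames),
            class = "run_config")
}
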