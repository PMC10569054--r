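test_that("RDF normalization matches the hand-evaluated single-pair case", {
  # two particles exactly at a bin center: one nonzero bin with value
  # 1 / (Npairs * 4 pi r^2 dr / V)
  box <- 20
  grid <- rdfGrid(10, 100)                 # dr = 0.1
  cfg <- periodicConfiguration(rbind(c(5, 5, 5), c(10.05, 5, 5)), box)
  curve <- computeRDF(cfg, grid)
  hit <- which(curve$g > 0)
  expect_equal(hit, 51L)                   # bin [5.0, 5.1)
  expect_equal(curve$g[hit], 1 / (4 * pi * 5.05^2 * 0.1 / box^3),
               tolerance = 1e-12)
  expect_error(computeRDF(list(), grid), "empty")
})

test_that("ideal-gas frames give g close to 1 on all resolvable bins", {
  set.seed(14)
  frames <- lapply(1:150, function(i) random_config(80, 16, seed = 1000 + i))
  grid <- rdfGrid(7.5, 50)
  curve <- computeRDF(frames, grid, exact_shell = TRUE)
  r <- grid$centers
  use <- r >= 2
  # per-bin Poisson-ish error of the mean
  npairs <- 80 * 79 / 2
  pbin <- 4 * pi * r^2 * grid$dr / 16^3
  sigma <- sqrt(pbin * npairs) / (pbin * npairs) / sqrt(150)
  expect_true(all(abs(curve$g[use] - 1) < 3.5 * sigma[use]))
})

test_that("PMF inverts the RDF and extrapolates the core linearly", {
  th <- thermoState(100)
  grid <- rdfGrid(5, 5)
  # g == 1 -> V == 0
  flat <- rdfCurve(grid, rep(1, 5))
  expect_equal(pmfFromRDF(flat, th)$V, rep(0, 5))
  # inverse identity on a known Boltzmann curve
  u <- c(250, 100, -40, -10, 2)
  curve <- rdfCurve(grid, exp(-th$beta * u))
  expect_equal(pmfFromRDF(curve, th)$V, u, tolerance = 1e-10)
  # core extrapolation on the 5-bin toy: g = (0, 0, 0.5, 1, 2)
  toy <- rdfCurve(grid, c(0, 0, 0.5, 1, 2))
  pmf <- pmfFromRDF(toy, th)
  V3 <- -100 * log(0.5)
  dV <- V3 - 0
  expect_equal(pmf$a0, 3L)
  expect_equal(pmf$dV, dV)
  expect_equal(pmf$V, c(V3 + 2 * dV, V3 + dV, V3, 0, -100 * log(2)),
               tolerance = 1e-12)
  expect_true(all(is.finite(pmf$V)))
  expect_error(pmfFromRDF(rdfCurve(grid, rep(0, 5)), th), "all-zero")
})

test_that("PMF total energy is the tabulated pair sum", {
  th <- thermoState(100)
  grid <- rdfGrid(6, 60)
  V <- 50 * cos(grid$centers)
  pmf <- list(table = pairTable(V, grid$dr))
  class(pmf) <- "pmf_table"
  # two particles in one bin
  cfg2 <- periodicConfiguration(rbind(c(1, 1, 1), c(4.05, 1, 1)), 15)
  expect_equal(pmfTotalEnergy(cfg2, pmf), V[31])
  # three equidistant particles (equilateral, side 2.05)
  a <- 2.05
  tri <- periodicConfiguration(rbind(c(1, 1, 1), c(1 + a, 1, 1),
                                     c(1 + a / 2, 1 + a * sqrt(3) / 2, 1)),
                               15)
  expect_equal(pmfTotalEnergy(tri, pmf), 3 * V[floor(a / 0.1) + 1])
  # brute-force double loop on a random configuration
  cfg <- random_config(20, 15, seed = 6)
  fun <- function(r) if (r < 6) V[floor(r / 0.1) + 1] else 0
  expect_equal(pmfTotalEnergy(cfg, pmf),
               oracle_pair_sum(cfg$positions, cfg$box, fun),
               tolerance = 1e-12)
})

test_that("angle distributions follow the probability-times-nbins convention", {
  # a single counted triplet: the apex angle is 100 degrees and the two base
  # sites are farther than r_shell apart, so only the apex contributes; all
  # mass in one bin with value = n_bins
  a <- 2.5
  tri <- periodicConfiguration(
    rbind(c(5, 5, 5), c(5 + a, 5, 5),
          c(5 + a * cos(100 * pi / 180), 5 + a * sin(100 * pi / 180), 5)),
    20)
  ang <- angularDistribution(tri, r_shell = 3, n_bins = 18)
  expect_equal(sum(ang$density > 0), 1L)
  expect_equal(max(ang$density), 18)
  expect_equal(ang$angle[which.max(ang$density)], 105)  # bin [100, 110)
  # normalization: per-bin probabilities sum to 1 before the x nbins factor
  set.seed(30)
  frames <- lapply(1:10, function(i) random_config(40, 14, seed = 300 + i))
  ad <- angularDistribution(frames, r_shell = 5, n_bins = 36)
  expect_equal(sum(ad$density / 36), 1, tolerance = 1e-12)
  # ideal-gas angles follow the sin(theta)/2 density (prob * nbins scale)
  th <- ad$angle * pi / 180
  binw <- pi / 36
  expected <- sin(th) / 2 * binw * 36
  err <- ad$density - expected
  expect_lt(mean(abs(err)), 0.15)
  expect_error(angularDistribution(tri, r_shell = 0.5), "no triplets")
})

test_that("three-body maps vanish for linear models and follow locality", {
  spec <- builtinDescriptorSet(1, rc = 8)
  set.seed(17)
  lin <- cgModel(spec)
  m <- threeBodyMap(lin, 3.4, x = seq(-6, 6, by = 2), y = seq(-6, 6, by = 2))
  expect_lt(max(abs(m)), 1e-10)
  # nonlinear model: far third particle contributes nothing
  net <- cgModel(spec, hidden = c(6, 6))
  m2 <- threeBodyMap(net, 4.5, x = c(0, 30), y = c(0, 30))
  expect_lt(abs(m2[2, 2]), 1e-10)   # third site beyond rc of both
  expect_lt(abs(m2[1, 2]), 1e-10)
  # one grid point of a genuinely nonlinear toy model, against the
  # independent forward-pass oracle on the three isolated configurations
  spec2 <- descriptorSpec(eta = c(0, 4), rs = c(0, 3), rc = 6)
  toy <- cgModel(spec2, hidden = 2,
                 weights = c(1, -2, 0.5, 1.5, 1, -1))
  r12 <- 3
  m3 <- threeBodyMap(toy, r12, x = 0, y = 4)
  big <- 60
  p1 <- c(big / 2 - r12 / 2, big / 2, big / 2)
  p2 <- c(big / 2 + r12 / 2, big / 2, big / 2)
  p3 <- c(big / 2, big / 2 + 4, big / 2)
  oe <- function(pos) oracle_total_energy(pos, rep(big, 3), spec2$eta,
                                          spec2$rs, spec2$rc, toy$sizes,
                                          toy$w)
  expected <- oe(rbind(p1, p2, p3)) - oe(rbind(p1, p2)) -
    oe(rbind(p2, p3)) - oe(rbind(p1, p3))
  expect_equal(m3[1, 1], expected, tolerance = 1e-10)
  expect_gt(abs(m3[1, 1]), 1e-6)   # the toy really has a three-body part
})

test_that("RDF files round-trip through the two-column text format", {
  grid <- rdfGrid(8, 40)
  curve <- rdfCurve(grid, runif(40))
  f <- withr::local_tempfile(fileext = ".rdf")
  writeRDF(curve, f)
  back <- readRDF(f)
  expect_equal(back$g, curve$g, tolerance = 1e-12)
  expect_equal(back$grid$rmax, 8)
  expect_equal(back$grid$nbins, 40L)
})
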