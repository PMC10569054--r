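test_that("RDF loss is the summed squared bin deviation", {
  grid <- rdfGrid(4, 4)
  a <- rdfCurve(grid, c(1, 2, 0.5, 1))
  expect_equal(rdfLoss(a, a), 0)
  b <- rdfCurve(grid, a$g + 0.3)
  expect_equal(rdfLoss(b, a), 4 * 0.3^2)
  # hand-summed value on two 4-bin curves
  c1 <- rdfCurve(grid, c(0.0, 0.8, 1.6, 1.1))
  c2 <- rdfCurve(grid, c(0.1, 1.2, 1.5, 0.7))
  expect_equal(rdfLoss(c1, c2), 0.1^2 + 0.4^2 + 0.1^2 + 0.4^2)
  expect_error(rdfLoss(a, rdfCurve(rdfGrid(4, 8), rep(1, 8))), "grid")
})

test_that("fluctuation-formula gradient vanishes in the degenerate cases", {
  grid <- rdfGrid(5, 10)
  nw <- 3
  acc <- structure(list(
    g = rep(1, 10), dEdw = c(1, 2, 3),
    cross = outer(rep(1, 10), c(1, 2, 3)),   # <g dE/dw> = <g><dE/dw>
    n_samples = 100, grid = grid), class = "sampling_acc")
  th <- thermoState(100)
  ref <- rdfCurve(grid, rep(0.5, 10))
  # zero covariance (constant dE/dw) -> zero gradient regardless of mismatch
  expect_equal(lossGradient(acc, ref, th), rep(0, nw))
  # sampled == reference -> zero gradient regardless of covariance
  acc$cross <- acc$cross + matrix(rnorm(30, sd = 0.1), 10, 3)
  expect_equal(lossGradient(acc, rdfCurve(grid, acc$g), th), rep(0, nw))
})

test_that("AMSGrad follows the hand computation and keeps its max property", {
  st <- amsgradInit(2, lr = 0.1)
  # zero gradient: parameters unchanged
  res <- amsgradStep(st, c(1, -1), c(0, 0))
  expect_equal(res$w, c(1, -1))
  # one step from zero state with constant gradient g: with bias-corrected
  # moments the step is -lr * g / (|g| + eps)
  st <- amsgradInit(2, lr = 0.1)
  res <- amsgradStep(st, c(0, 0), c(3, -0.2))
  expect_equal(res$w, -0.1 * c(3, -0.2) / (abs(c(3, -0.2)) + 1e-8),
               tolerance = 1e-12)
  expect_equal(res$state$m, 0.1 * c(3, -0.2))
  expect_equal(res$state$vhat, 0.001 * c(3, -0.2)^2)
  # second-moment max never decreases across random steps
  set.seed(19)
  st <- amsgradInit(4, lr = 0.01)
  w <- rnorm(4)
  prev <- st$vhat
  for (i in 1:100) {
    res <- amsgradStep(st, w, rnorm(4))
    w <- res$w
    st <- res$state
    expect_true(all(st$vhat >= prev - 1e-300))
    prev <- st$vhat
  }
  expect_error(amsgradStep(st, w, c(1, Inf, 0, 0)), "finite")
})

test_that("pretraining reduces the energy-change mismatch on a LJ reference", {
  ref <- tiny_lj_reference(n = 48, steps = 2e5, equil = 4e4, seed = 23,
                           nbins = 60, n_frames = 40)
  rc <- ref$reference$grid$rmax
  spec <- descriptorSpec(eta = c(0.125, rep(4, 5)), rs = c(0, seq(2, 4.8, by = 0.7)),
                         rc = rc)
  set.seed(2)
  model <- cgModel(spec)
  set.seed(3)
  res <- pretrainModel(list(ref$system), model, n_steps = 2000)
  early <- mean(res$loss[1:50])
  late <- mean(tail(res$loss, 200))
  expect_lt(late, early / 10)
  # a site displaced while isolated beyond rc: dE_PMF = 0, loss = dE_NN^2
  far <- periodicConfiguration(rbind(c(1, 1, 1), c(2.5, 1, 1),
                                     c(30, 30, 30)), 60)
  pmf <- pmfFromRDF(ref$reference, ref$system$thermo)
  sys_far <- referenceSystem(ref$reference, list(far), ref$system$thermo)
  # displacement of the isolated site cannot change the PMF energy
  e0 <- pmfTotalEnergy(far, pmf)
  far2 <- far
  far2$positions[3, ] <- c(40, 40, 40)
  expect_equal(pmfTotalEnergy(far2, pmf) - e0, 0)
})

test_that("pretraining is near its floor for a network that encodes the PMF", {
  # indicator descriptors + linear weights = PMF bin values reproduce the
  # PMF pair energy exactly, so per-step pretraining loss is ~0
  ref <- tiny_lj_reference(n = 48, steps = 1.5e5, equil = 4e4, seed = 29,
                           nbins = 60, n_frames = 30)
  th <- ref$system$thermo
  pmf <- pmfFromRDF(ref$reference, th)
  grid <- ref$reference$grid
  spec <- descriptorSpec(eta = rep(0, grid$nbins), rs = grid$centers,
                         rc = grid$rmax, type = "indicator")
  model <- cgModel(spec, weights = pmf$V / 2)   # per-site double counting
  res <- pretrainModel(list(ref$system), model, n_steps = 50, lr = 0)
  expect_lt(max(res$loss), 1e-16)
})

test_that("training a linear model against its own reference stays put", {
  # reference RDF generated by the model's current weights: the gradient has
  # no systematic component, so the loss stays at the sampling-noise floor
  ref <- tiny_lj_reference(n = 48, steps = 2e5, equil = 4e4, seed = 37,
                           nbins = 48, n_frames = 30)
  rc <- ref$reference$grid$rmax
  spec <- descriptorSpec(eta = c(0.125, rep(4, 4)),
                         rs = c(0, seq(2.2, 4.6, by = 0.8)), rc = rc)
  set.seed(41)
  model <- cgModel(spec, weights = c(80, 60, -40, -15, -5) / 2)
  run <- runConfig(steps = 6e4, equil_steps = 2e4, output_freq = 500,
                   rdf_rmax = rc, rdf_nbins = 48)
  th <- ref$system$thermo
  set.seed(43)
  own <- runSampling(ref$frames[[1]], model, run, th)
  own_ref <- rdfCurve(own$grid, own$g)
  system <- referenceSystem(own_ref, ref$frames, th)
  # noise floor: an independent re-sample of the same weights
  floor_loss <- noiseFloor(system, model, run, seed = 47)
  st <- trainModel(list(system), model, run, n_iterations = 4, seed = 53,
                   lr = 0.002)
  expect_lt(max(st$history$total_loss), 25 * floor_loss + 1e-6)
  expect_lt(max(abs(st$model$w - model$w)), 0.2 * max(abs(model$w)))
  # multi-system totals are exact sums of per-system losses
  expect_equal(st$history$total_loss, st$history$loss_1)
})

test_that("training resumes from a checkpoint bit-exactly", {
  ref <- tiny_lj_reference(n = 32, steps = 8e4, equil = 2e4, seed = 131,
                           nbins = 40, n_frames = 15)
  spec <- descriptorSpec(eta = c(0.125, rep(4, 3)), rs = c(0, 2.5, 3.5, 4.5),
                         rc = ref$reference$grid$rmax)
  set.seed(132)
  model <- cgModel(spec, weights = c(60, 30, -30, -10))
  run <- runConfig(steps = 2e4, equil_steps = 5e3, output_freq = 500,
                   rdf_rmax = ref$reference$grid$rmax, rdf_nbins = 40)
  full <- trainModel(list(ref$system), model, run, n_iterations = 4,
                     seed = 777, lr = 2)
  part <- trainModel(list(ref$system), model, run, n_iterations = 2,
                     seed = 777, lr = 2)
  rest <- trainModel(list(ref$system), part$model, run, n_iterations = 2,
                     seed = 777, lr = 2, opt_state = part$opt,
                     first_iteration = 3L)
  expect_identical(rest$model$w, full$model$w)
  expect_identical(rest$history$total_loss,
                   full$history$total_loss[3:4])
})
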