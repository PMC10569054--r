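test_that("moves with dE <= 0 are always accepted; zero potential accepts all", {
  flat <- pairTable(rep(0, 50), 0.1)
  cfg <- random_config(10, 12, seed = 1)
  th <- thermoState(100)
  set.seed(2)
  for (i in 1:50) {
    st <- metropolisStep(cfg, flat, 0.8, th)
    expect_true(st$accepted)
    expect_equal(st$dE, 0)
    cfg <- st$config
  }
  run <- runConfig(steps = 5000, equil_steps = 500, output_freq = 100,
                   rdf_rmax = 5, rdf_nbins = 25, max_disp = 0.7)
  set.seed(3)
  acc <- runSampling(random_config(10, 12, seed = 1), flat, run, th)
  expect_equal(acc$acceptance, 1)
})

test_that("uphill moves are accepted at the Boltzmann rate", {
  # two-level pair potential: V = 0 below 4 A, V = c on [4, 8); T chosen so
  # exp(-beta c) is well inside (0, 1)
  cc <- 120
  th <- thermoState(100)
  tab <- pairTable(c(rep(0, 40), rep(cc, 40)), 0.1)
  cfg <- periodicConfiguration(rbind(c(8, 8, 8), c(11, 8, 8)), 20)
  set.seed(42)
  up <- 0L; up_acc <- 0L
  for (i in 1:20000) {
    st <- metropolisStep(cfg, tab, 1.5, th)
    if (st$dE > 0) {
      up <- up + 1L
      if (st$accepted) up_acc <- up_acc + 1L
    } else {
      expect_true(st$accepted)
    }
    cfg <- st$config
  }
  p <- exp(-th$beta * cc)
  expect_gt(up, 1000)
  se <- sqrt(p * (1 - p) / up)
  expect_lt(abs(up_acc / up - p), 3 * se)
})

test_that("sampling is reproducible and its mean RDF equals the sample mean", {
  sp <- statePoint(N = 32, T = 95, density = 1374, rcut = 5)
  pot <- ljPotential(sp$eps, sp$sigma, sp$rcut)
  run <- runConfig(steps = 20000, equil_steps = 5000, output_freq = 250,
                   rdf_rmax = 5, rdf_nbins = 50, n_frames = 10)
  th <- thermoState(sp$T)
  start <- random_config(32, sp$box[1], seed = 4)
  set.seed(77)
  a <- runSampling(start, pot, run, th, keep_samples = TRUE)
  set.seed(77)
  b <- runSampling(start, pot, run, th, keep_samples = TRUE)
  expect_identical(a$g, b$g)                       # bit-identical under a seed
  expect_identical(a$final$positions, b$final$positions)
  expect_equal(a$g, colMeans(a$g_samples), tolerance = 1e-12)
  expect_length(a$frames, 10L)
})

test_that("step-size adaptation reaches the target acceptance and then freezes", {
  sp <- statePoint(N = 64, T = 95, density = 1374, rcut = 6)
  pot <- ljPotential(sp$eps, sp$sigma, sp$rcut)
  run <- runConfig(steps = 2.5e5, equil_steps = 1.5e5, output_freq = 1000,
                   rdf_rmax = 7, rdf_nbins = 70, target_acceptance = 0.5,
                   max_disp = 2.5)
  set.seed(11)
  acc <- runSampling(random_config(64, sp$box[1], seed = 12), pot, run,
                     thermoState(sp$T))
  expect_lt(abs(acc$acceptance - 0.5), 0.05)
})

test_that("empirical stationary distribution is Boltzmann (two-site audit)", {
  # 2 sites with a tabulated pair potential; the binned pair distance must be
  # distributed as shell_volume * exp(-beta V), conditioned on r < rmax
  th <- thermoState(100)
  nb <- 24
  rmax <- 6
  dr <- rmax / nb
  r <- (seq_len(nb) - 0.5) * dr
  V <- 150 * exp(-((r - 3) / 1.2)^2) - 80 * exp(-((r - 5) / 0.8)^2)
  tab <- pairTable(V, dr)
  run <- runConfig(steps = 1e6, equil_steps = 5e4, output_freq = 200,
                   rdf_rmax = rmax, rdf_nbins = nb, max_disp = 1.2)
  set.seed(123)
  acc <- runSampling(periodicConfiguration(rbind(c(1, 1, 1), c(3, 1, 1)), 16),
                     tab, run, th, keep_samples = TRUE)
  # per-sample instantaneous g has exactly one nonzero bin (or none)
  norm <- 1 * 4 * pi * r^2 * dr / 16^3
  counts <- colSums(acc$g_samples > 0)
  edges <- seq(0, rmax, by = dr)
  shell <- 4 * pi / 3 * diff(edges^3)
  p <- shell * exp(-th$beta * V)
  keep <- seq_len(nb)[-(1:4)]          # drop near-empty core bins
  p <- p[keep] / sum(p[keep])
  obs <- counts[keep]
  expect_gt(sum(obs), 500)
  chi <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(chi$p.value, 0.01)
})

test_that("multi-system sampling is order-independent with derived streams", {
  ref <- tiny_lj_reference(n = 32, steps = 6e4, equil = 2e4, seed = 31,
                           nbins = 40, n_frames = 10)
  sysA <- ref$system
  sysB <- ref$system
  sysB$label <- "copy"
  set.seed(1)
  spec <- descriptorSpec(eta = c(0.125, rep(4, 4)), rs = c(0, 2, 3, 4, 5),
                         rc = ref$reference$grid$rmax)
  model <- cgModel(spec)
  run <- runConfig(steps = 8000, equil_steps = 2000, output_freq = 200,
                   rdf_rmax = ref$reference$grid$rmax,
                   rdf_nbins = ref$reference$grid$nbins)
  two <- multiSystemSampling(list(sysA, sysB), model, run, seed = 50)
  # identical systems with identical derived seeds give identical results
  one <- multiSystemSampling(list(sysA), model, run, seed = 50)
  expect_identical(two[[1]]$g, one[[1]]$g)
  # a failing system reports its index
  bad <- sysA
  bad$reference$grid <- rdfGrid(1000, 10)
  expect_error(multiSystemSampling(list(sysA, bad), model, run, seed = 50),
               "system 2")
})
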