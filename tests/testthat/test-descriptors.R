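test_that("cosine cutoff has the right endpoints and monotone decay", {
  expect_equal(cutoffFc(3, 3), 0)
  expect_equal(cutoffFc(0, 3), 1)
  expect_equal(cutoffFc(1.5, 3), 0.5)
  expect_equal(cutoffFc(5, 3), 0)
  r <- seq(0, 3, by = 0.01)
  expect_true(all(diff(cutoffFc(r, 3)) <= 1e-12))
  expect_true(all(cutoffFc(r, 3) >= 0 & cutoffFc(r, 3) <= 1))
  expect_error(cutoffFc(1, -1), "rc")
})

test_that("single-pair descriptors reduce to closed forms", {
  box <- 30
  spec <- descriptorSpec(eta = 4, rs = 3, rc = 8)
  cfg <- periodicConfiguration(rbind(c(5, 5, 5), c(8, 5, 5)), box)
  # pair at r = rs: exp(0) * fc(rs)
  expect_equal(g2Site(cfg, 1, spec), cutoffFc(3, 8), tolerance = 1e-12)
  # eta = 0 degenerates to a smooth coordination count sum fc(r)
  spec0 <- descriptorSpec(eta = 0, rs = 0, rc = 8)
  cfg3 <- periodicConfiguration(rbind(c(5, 5, 5), c(8, 5, 5), c(5, 9, 5)),
                                box)
  expect_equal(g2Site(cfg3, 1, spec0), cutoffFc(3, 8) + cutoffFc(4, 8),
               tolerance = 1e-12)
})

test_that("descriptor matrix matches the brute-force double loop", {
  spec <- builtinDescriptorSet(1, rc = 9)
  for (seed in 1:3) {
    cfg <- random_config(5, 20, seed = seed)
    G <- g2Matrix(cfg, spec)
    Gref <- oracle_g2(cfg$positions, cfg$box, spec$eta, spec$rs, spec$rc)
    expect_lt(max(abs(G - Gref)), 1e-12)
    expect_true(all(G >= 0))
  }
})

test_that("incremental update equals full recomputation and is reversible", {
  spec <- builtinDescriptorSet(1, rc = 9)
  cfg <- random_config(30, 20, seed = 5)
  G <- g2Matrix(cfg, spec)
  set.seed(9)
  for (trial in 1:5) {
    moved <- sample.int(30, 1)
    new_pos <- cfg$positions[moved, ] + runif(3, -2, 2)
    upd <- g2Delta(cfg, moved, new_pos, spec, G)
    full <- g2Matrix(upd$config, spec)
    expect_lt(max(abs(upd$G - full)), 1e-10)
    # reverse restores the original matrix
    back <- g2Delta(upd$config, moved, cfg$positions[moved, ], spec, upd$G)
    expect_lt(max(abs(back$G - G)), 1e-10)
  }
})

test_that("a stale descriptor cache is detected when checking is enabled", {
  spec <- descriptorSpec(eta = 4, rs = 2, rc = 4)
  cfg <- random_config(8, 12, seed = 44)
  G <- g2Matrix(cfg, spec)
  stale <- G + 0.5
  expect_error(g2Delta(cfg, 1L, c(1, 1, 1), spec, stale, check = TRUE),
               "stale")
  expect_silent(g2Delta(cfg, 1L, c(1, 1, 1), spec, G, check = TRUE))
})

test_that("moving an isolated site changes only its own (zero) row", {
  spec <- descriptorSpec(eta = 4, rs = 2, rc = 3)
  pos <- rbind(c(5, 5, 5), c(6, 5, 5), c(20, 20, 20))
  cfg <- periodicConfiguration(pos, 50)
  G <- g2Matrix(cfg, spec)
  expect_equal(G[3, ], 0)
  upd <- g2Delta(cfg, 3L, c(25, 25, 25), spec, G)
  expect_equal(upd$changed, 3L)
  expect_equal(upd$G, G)
})

test_that("descriptors are invariant to rigid motions and equivariant to relabeling", {
  spec <- builtinDescriptorSet(1, rc = 9)
  cfg <- random_config(12, 20, seed = 21)
  G <- g2Matrix(cfg, spec)
  # translation (box-compatible)
  shifted <- periodicConfiguration(sweep(cfg$positions, 2, c(3.2, -1.1, 7.9),
                                         "+"), cfg$box)
  expect_lt(max(abs(g2Matrix(shifted, spec) - G)), 1e-10)
  # rotation: 90 degrees about z maps the cubic box onto itself
  rot <- cfg$positions[, c(2, 1, 3)]
  rot[, 1] <- cfg$box[1] - rot[, 1]
  rotated <- periodicConfiguration(rot, cfg$box)
  expect_lt(max(abs(g2Matrix(rotated, spec) - G)), 1e-10)
  # permutation equivariance
  perm <- sample(12)
  permuted <- periodicConfiguration(cfg$positions[perm, ], cfg$box)
  expect_lt(max(abs(g2Matrix(permuted, spec) - G[perm, ])), 1e-12)
})

test_that("built-in descriptor sets match their documented layout", {
  s1 <- builtinDescriptorSet(1)
  expect_equal(s1$K, 8L)
  expect_equal(s1$eta[1], 0.125)
  expect_equal(s1$rs, c(0, seq(3, 6, by = 0.5)))
  s2 <- builtinDescriptorSet(2, rc = 15)
  expect_equal(s2$K, 24L)
  expect_error(builtinDescriptorSet(3), "set")
  # cutoff beyond half the box is rejected without the override
  cfg <- random_config(5, 10, seed = 1)
  expect_error(g2Matrix(cfg, builtinDescriptorSet(1, rc = 8)), "half the box")
  expect_silent(g2Matrix(cfg, builtinDescriptorSet(1, rc = 8),
                         allow_large_rmax = TRUE))
})
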