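# Independent reference implementations (plain-R double loops) used as
# oracles against the compiled paths, plus small fixture builders.

oracle_min_image <- function(a, b, box) {
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

oracle_fc <- function(r, rc) ifelse(r < rc, 0.5 * (cos(pi * r / rc) + 1), 0)

# Brute-force N x K descriptor matrix.
oracle_g2 <- function(pos, box, eta, rs, rc) {
  n <- nrow(pos)
  K <- length(eta)
  G <- matrix(0, n, K)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- oracle_min_image(pos[i, ], pos[j, ], box)
    if (r < rc)
      G[i, ] <- G[i, ] + exp(-eta * (r - rs)^2) * oracle_fc(r, rc)
  }
  G
}

# Forward pass through a bias-free ReLU net, weights in the package's
# output-major flat layout.
oracle_forward <- function(x, sizes, w) {
  off <- 0L
  a <- x
  L <- length(sizes) - 1L
  for (l in seq_len(L)) {
    nin <- sizes[l]; nout <- sizes[l + 1L]
    W <- matrix(w[off + seq_len(nin * nout)], nrow = nout, byrow = TRUE)
    z <- drop(W %*% a)
    a <- if (l < L) pmax(z, 0) else z
    off <- off + nin * nout
  }
  a[1L]
}

oracle_total_energy <- function(pos, box, eta, rs, rc, sizes, w) {
  G <- oracle_g2(pos, box, eta, rs, rc)
  sum(apply(G, 1L, oracle_forward, sizes = sizes, w = w))
}

# Central finite differences of the total energy w.r.t. each weight.
oracle_fd_gradient <- function(G, sizes, w, h = 1e-6) {
  f <- function(wv) sum(apply(G, 1L, oracle_forward, sizes = sizes, w = wv))
  vapply(seq_along(w), function(i) {
    wp <- w; wp[i] <- wp[i] + h
    wm <- w; wm[i] <- wm[i] - h
    (f(wp) - f(wm)) / (2 * h)
  }, numeric(1))
}

oracle_pair_sum <- function(pos, box, fun) {
  n <- nrow(pos)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    e <- e + fun(oracle_min_image(pos[i, ], pos[j, ], box))
  e
}

random_config <- function(n, box, seed = 1) {
  set.seed(seed)
  periodicConfiguration(matrix(runif(3 * n) * box, n, 3), box)
}

# Small fast LJ reference bundle shared by several tests.
tiny_lj_reference <- function(n = 64, steps = 3e5, equil = 5e4, seed = 7,
                              nbins = 90, n_frames = 60) {
  sp <- statePoint(N = n, T = 95, density = 1374, rcut = 6.5)
  sp$rcut <- min(sp$rcut, 0.98 * min(sp$box) / 2)
  run <- runConfig(steps = steps, equil_steps = equil, output_freq = 500,
                   rdf_rmax = min(sp$box) / 2 * 0.98, rdf_nbins = nbins,
                   n_frames = n_frames)
  ljReference(sp, run, seed = seed)
}
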