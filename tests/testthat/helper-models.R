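# Shared fixtures: small candidate models and independent oracles.

# Gaussian candidate: y | x ~ N(f(x), sigma^2), loss = Gaussian NLL,
# sampler draws x ~ Unif(0, 1)
gaussian_candidate <- function(f = function(x) x, sigma = 1,
                               id = "gaussian") {
  force(f); force(sigma)
  candidate_model(
    id = id,
    loss = function(d) {
      0.5 * log(2 * pi * sigma^2) + (d$y - f(d$x))^2 / (2 * sigma^2)
    },
    sampler = function(n) {
      x <- stats::runif(n)
      data.frame(x = x, y = stats::rnorm(n, f(x), sigma))
    })
}

# candidate whose sampler replays a fixed dataset verbatim (a model that
# reproduces the observations exactly)
replay_candidate <- function(dataset, sigma = 1, id = "replay") {
  force(dataset); force(sigma)
  candidate_model(
    id = id,
    loss = function(d) {
      0.5 * log(2 * pi * sigma^2) + (d$y - d$x)^2 / (2 * sigma^2)
    },
    sampler = function(n) {
      stopifnot(n == nrow(dataset))
      dataset
    })
}

# literal double-sum estimate of P(R_A < R_B): the O(M^2) oracle that the
# sort-and-count implementation must reproduce exactly
b_emd_double_sum <- function(a, b) {
  va <- if (inherits(a, "risk_samples")) a$values else a
  vb <- if (inherits(b, "risk_samples")) b$values else b
  mean(outer(va, vb, `<`))
}

# small black-body HB spec used across process tests; sizes kept modest so
# each construction is fast
make_blackbody_spec <- function(c = 2^-2, n_points = 512L, l_synth = 1024L,
                                n_grid = 256L, n_refinements = 8L,
                                law = "planck", seed = 1L) {
  set.seed(seed)
  d <- generate_blackbody_data(n_points)
  cand <- fit_sigma_mle(d, blackbody_candidate(law))
  pp <- mixed_and_synthetic_ppfs(cand, d, l_synth = l_synth, n_grid = n_grid)
  hb_process_spec(pp$mixed, delta_emd(pp$mixed, pp$synthetic), c = c,
                  n_refinements = n_refinements)
}

# extract the normalised first-subincrement x1 at a given level/position
# from a sampled realisation
realisation_x1 <- function(realisation, spec, level, k) {
  N <- spec$n_refinements
  npts <- 2L^N + 1L
  step <- 2L^(N - level + 1L)
  li <- 1L + (k - 1L) * step
  mi <- li + step %/% 2L
  ri <- li + step
  q <- realisation$values
  (q[mi] - q[li]) / (q[ri] - q[li])
}
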