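test_that("beta centre and metric variance follow the digamma formulas", {
  # symmetry: any alpha = beta centres at (1/2, 1/2)
  for (a in c(0.2, 1, 5, 50)) {
    expect_equal(beta_centre_mvar(a, a)$centre, c(0.5, 0.5))
  }
  # alpha = beta = 1: mvar = psi_1(1) = pi^2 / 6
  expect_equal(beta_centre_mvar(1, 1)$mvar, pi^2 / 6)
  # mvar decreases monotonically to 0 for growing symmetric parameters
  mv <- vapply(c(1, 10, 100), function(a) beta_centre_mvar(a, a)$mvar,
               numeric(1))
  expect_true(all(diff(mv) < 0))
  expect_lt(mv[3], 0.03)
  # general centre against direct evaluation
  cm <- beta_centre_mvar(2, 5)
  expect_equal(cm$centre,
               exp(digamma(c(2, 5))) / sum(exp(digamma(c(2, 5)))))
  expect_equal(sum(cm$centre), 1)
  expect_error(beta_centre_mvar(-1, 2), "positive")
  expect_error(beta_centre_mvar(0, 1), "positive")
})

test_that("beta-parameter solver inverts the forward map", {
  # forward map (alpha, beta) -> (r, v) is the oracle; the solver must
  # recover the parameters to 6 significant digits on a 4 x 4 grid
  g <- expand.grid(alpha = c(0.5, 1, 2, 8), beta = c(0.5, 1, 2, 8))
  r <- exp(digamma(g$alpha) - digamma(g$beta))
  v <- trigamma(g$alpha) + trigamma(g$beta)
  sol <- solve_beta_params(r, v)
  expect_equal(sol$alpha, g$alpha, tolerance = 1e-6)
  expect_equal(sol$beta, g$beta, tolerance = 1e-6)

  # (r = 1, v = pi^2 / 3) -> (1, 1)
  sol11 <- solve_beta_params(1, pi^2 / 3)
  expect_equal(sol11$alpha, 1, tolerance = 1e-8)
  expect_equal(sol11$beta, 1, tolerance = 1e-8)

  # r = 1 forces alpha = beta for any v
  for (v1 in c(0.01, 1, 30)) {
    s <- solve_beta_params(1, v1)
    expect_equal(s$alpha, s$beta, tolerance = 1e-8)
  }
  # solved equations hold to tight absolute tolerance across 18 orders of
  # magnitude of the target metric variance
  rr <- c(1e-12, 1e12, 3, 0.02)
  vv <- c(1e-10, 5, 1e4, 1e8)
  s <- solve_beta_params(rr, vv)
  expect_lt(max(abs(digamma(s$alpha) - digamma(s$beta) - log(rr))), 1e-8)
  expect_lt(max(abs(log(trigamma(s$alpha) + trigamma(s$beta)) - log(vv))),
            1e-8)
  # at the variance cap (tiny alpha, beta) the transformed digamma
  # difference itself carries ~1e-8 of double-precision cancellation, so
  # only finiteness and a looser residual are meaningful there
  s_cap <- solve_beta_params(0.02, 2e15)
  expect_true(all(is.finite(unlist(s_cap))) && all(unlist(s_cap) > 0))
  expect_lt(abs(digamma(s_cap$alpha) - digamma(s_cap$beta) - log(0.02)),
            1e-6)
  expect_error(solve_beta_params(-1, 2), "positive")
})

test_that("increment statistics use the subincrement ratio of q*", {
  # linear q* -> equal subincrements -> r = 1
  lin <- emdselect:::new_ppf(seq(0, 1, length.out = 101),
                             seq(2, 4, length.out = 101))
  flat_delta <- structure(list(grid = lin$grid,
                               ordinates = rep(0.1, 101)),
                          class = "discrepancy_curve")
  spec <- hb_process_spec(lin, flat_delta, c = 0.25, n_refinements = 4)
  st <- increment_stats(spec, phi = c(0, 0.5), half_width = 0.25)
  expect_equal(st$r, c(1, 1), tolerance = 1e-9)
  expect_equal(st$v, rep(2 * 0.25 * 0.1^2, 2), tolerance = 1e-12)

  # c = 0 floors v (the process then collapses onto q* downstream)
  spec0 <- hb_process_spec(lin, flat_delta, c = 0, n_refinements = 4)
  st0 <- increment_stats(spec0, phi = 0, half_width = 0.25)
  expect_equal(st0$v, 1e-12)

  # convex q*: second subincrement larger -> r < 1
  conv <- emdselect:::new_ppf(seq(0, 1, length.out = 101),
                              seq(0, 1, length.out = 101)^2)
  spec_c <- hb_process_spec(conv, flat_delta, c = 0.25, n_refinements = 4)
  expect_lt(increment_stats(spec_c, 0.25, 0.125)$r, 1)
})

test_that("flat q* regions are clipped or deterministic, not errors", {
  ords <- c(rep(1, 50), seq(1, 2, length.out = 51))
  flat_left <- emdselect:::new_ppf(seq(0, 1, length.out = 101), ords)
  delta <- structure(list(grid = flat_left$grid,
                          ordinates = rep(0.05, 101)),
                     class = "discrepancy_curve")
  spec <- hb_process_spec(flat_left, delta, c = 1, n_refinements = 6)
  # completely flat parent increment -> deterministic midpoint split
  st <- increment_stats(spec, 0, 2^-3)
  expect_true(st$deterministic)
  # half-flat increment -> clipped ratio, still finite positive
  st2 <- increment_stats(spec, 0.375, 2^-3)
  expect_true(is.finite(st2$r) && st2$r > 0)
  # the whole table is solvable and sampling works
  r <- sample_realisation(spec)
  expect_false(is.unsorted(r$values))
})

test_that("endpoints are Gaussian around q* and always ordered", {
  spec <- make_blackbody_spec(c = 2^-2)
  q0m <- spec$mixed_ppf$ordinates[1]
  q1m <- spec$mixed_ppf$ordinates[length(spec$mixed_ppf$ordinates)]

  # c = 0: exactly the q* endpoints
  spec0 <- make_blackbody_spec(c = 0)
  expect_identical(sample_endpoints(spec0),
                   c(spec0$mixed_ppf$ordinates[1],
                     spec0$mixed_ppf$ordinates[length(spec0$mixed_ppf$ordinates)]))

  set.seed(21)
  draws <- t(replicate(1e4, sample_endpoints(spec)))
  expect_true(all(draws[, 1] < draws[, 2]))
  # rejection is negligible here, so sample means sit within 3 SE
  sd0 <- sqrt(spec$c) * spec$discrepancy$ordinates[1]
  sd1 <- sqrt(spec$c) *
    spec$discrepancy$ordinates[length(spec$discrepancy$ordinates)]
  expect_lt(abs(mean(draws[, 1]) - q0m), 3 * sd0 / sqrt(1e4) + 1e-12)
  expect_lt(abs(mean(draws[, 2]) - q1m), 3 * sd1 / sqrt(1e4) + 1e-12)
})

test_that("exhausting the endpoint rejection cap is a clear error", {
  # with ordered endpoint means each draw succeeds with probability >= 1/2,
  # so exhaustion only occurs for pathological caps; drive the error path
  # deterministically with a zero budget
  grid <- seq(0, 1, length.out = 11)
  qq <- emdselect:::new_ppf(grid, 1 + grid)
  dd <- structure(list(grid = grid, ordinates = rep(5, 11)),
                  class = "discrepancy_curve")
  spec <- hb_process_spec(qq, dd, c = 1, n_refinements = 2,
                          max_endpoint_rejections = 0)
  expect_error(sample_endpoints(spec), "rejections")
})

test_that("degenerate limits return q* exactly on the dyadic grid", {
  spec0 <- make_blackbody_spec(c = 0)
  r0 <- sample_realisation(spec0)
  expect_equal(r0$values, eval_ppf(spec0$mixed_ppf, r0$phis))
  expect_length(r0$values, 2^8 + 1)

  # delta == 0 collapses the process for any c
  spec <- make_blackbody_spec(c = 2^-2)
  dd0 <- structure(list(grid = spec$mixed_ppf$grid,
                        ordinates = rep(0, length(spec$mixed_ppf$grid))),
                   class = "discrepancy_curve")
  spec_d0 <- hb_process_spec(spec$mixed_ppf, dd0, c = 8)
  rd0 <- sample_realisation(spec_d0)
  expect_equal(rd0$values, eval_ppf(spec$mixed_ppf, rd0$phis))
})

test_that("every realisation is a nondecreasing quantile function", {
  set.seed(17)
  for (cc in c(2^-4, 2^-2, 1, 2^6)) {
    spec <- make_blackbody_spec(c = cc, seed = 2)
    ok <- vapply(1:300, function(i) {
      r <- sample_realisation(spec)
      !is.unsorted(r$values) && length(r$values) == 2^8 + 1
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("coarse dyadic points are invariant under deeper refinement", {
  set.seed(1)
  d <- generate_blackbody_data(512)
  cand <- fit_sigma_mle(d, blackbody_candidate("planck"))
  pp <- mixed_and_synthetic_ppfs(cand, d, l_synth = 1024, n_grid = 256)
  dd <- delta_emd(pp$mixed, pp$synthetic)
  s4 <- hb_process_spec(pp$mixed, dd, c = 2^-2, n_refinements = 4)
  s8 <- hb_process_spec(pp$mixed, dd, c = 2^-2, n_refinements = 8)
  for (seed in c(5, 6, 7)) {
    set.seed(seed); r4 <- sample_realisation(s4)
    set.seed(seed); r8 <- sample_realisation(s8)
    expect_identical(r4$values, r8$values[match(r4$phis, r8$phis)])
  }
})

test_that("increment pairs are centred on the q*-derived ratio", {
  # the Aitchison centre of the normalised subincrement pairs must match r
  # within Monte-Carlo error: E[log(x1/x2)] = psi(alpha) - psi(beta) = log r
  spec <- make_blackbody_spec(c = 2^-2)
  set.seed(8)
  M <- 5000
  reals <- replicate(M, sample_realisation(spec), simplify = FALSE)
  tab <- spec$beta_table
  level <- 4L
  for (k in c(2L, 5L, 7L)) {
    row <- tab[tab$level == level, ][k, ]
    if (row$deterministic) next
    x1 <- vapply(reals, realisation_x1, numeric(1), spec = spec,
                 level = level, k = k)
    lr <- log(x1) - log1p(-x1)
    lr <- lr[is.finite(lr)]
    se <- stats::sd(lr) / sqrt(length(lr))
    expect_lt(abs(mean(lr) - log(row$r)), 3 * se)
  }
})

test_that("increment metric variance tracks 2 c delta^2 approximately", {
  spec <- make_blackbody_spec(c = 2^-2)
  set.seed(9)
  M <- 5000
  reals <- replicate(M, sample_realisation(spec), simplify = FALSE)
  tab <- spec$beta_table
  level <- 4L
  rows <- tab[tab$level == level, ]
  for (k in c(2L, 5L, 7L)) {
    row <- rows[k, ]
    # only meaningful where the target variance is above the numerical floor
    if (row$deterministic || row$v <= 1e-10) next
    x1 <- vapply(reals, realisation_x1, numeric(1), spec = spec,
                 level = level, k = k)
    lr <- log(x1) - log1p(-x1)
    lr <- lr[is.finite(lr)]
    mvar_emp <- 0.5 * stats::var(lr)
    ratio <- mvar_emp / (row$v / 2)
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 2)
  }
})

test_that("realisations remain valid PPFs even at very large c", {
  spec <- make_blackbody_spec(c = 2^6)
  set.seed(12)
  rs <- replicate(500, sample_realisation(spec), simplify = FALSE)
  expect_true(all(vapply(rs, function(r) !is.unsorted(r$values),
                         logical(1))))
  # tracking degrades: the spread at large c exceeds the spread at small c
  spec_small <- make_blackbody_spec(c = 2^-4)
  set.seed(12)
  rs_small <- replicate(200, sample_realisation(spec_small),
                        simplify = FALSE)
  mid <- 2^7 + 1
  expect_gt(stats::var(vapply(rs, function(r) r$values[mid], numeric(1))),
            stats::var(vapply(rs_small, function(r) r$values[mid],
                              numeric(1))))
})

test_that("spec construction validates its inputs", {
  spec <- make_blackbody_spec()
  expect_error(hb_process_spec(spec$mixed_ppf, spec$discrepancy, c = -1),
               "nonnegative")
  expect_error(hb_process_spec(spec$mixed_ppf, spec$discrepancy, c = 1,
                               n_refinements = 0), "n_refinements")
  short <- structure(list(grid = c(0, 1), ordinates = c(0, 0)),
                     class = "discrepancy_curve")
  expect_error(hb_process_spec(spec$mixed_ppf, short, c = 1), "grid")
})
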