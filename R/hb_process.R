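#' Hierarchical beta process specification
#'
#' Parametrises the stochastic process over quantile functions from which
#' risk distributions are sampled. The process is centred (in the Aitchison
#' sense) on the mixed PPF `q*`, with metric variance proportional to
#' `c * delta^2`: the sensitivity factor `c` converts empirical model
#' discrepancy into epistemic uncertainty. Realisations are built by dyadic
#' refinement — each increment is split into two subincrements by a beta draw
#' — which makes every realisation a monotone, non-accumulating,
#' self-consistent quantile function.
#'
#' @param mixed_ppf The mixed PPF `q*` ([empirical_ppf()]).
#' @param discrepancy The discrepancy curve ([delta_emd()]); must share the
#'   mixed PPF's grid.
#' @param c Nonnegative sensitivity factor (dimensionless). `c = 0`
#'   collapses the process onto `q*`.
#' @param n_refinements Number of dyadic refinement levels `N`; realisations
#'   live on the grid `k * 2^-N`, `k = 0..2^N` (default 8, i.e. 257 points,
#'   past which risk integrals change negligibly).
#' @param max_endpoint_rejections Cap on redraws of the endpoint pair
#'   (endpoints are Gaussian and must satisfy `q(0) < q(1)`).
#' @return An `hb_spec` object with a precomputed table of beta parameters
#'   for every dyadic midpoint (the table depends only on `q*`, `delta` and
#'   `c`, so it is shared by all realisations).
#' @export
hb_process_spec <- function(mixed_ppf, discrepancy, c,
                            n_refinements = 8L,
                            max_endpoint_rejections = 1000L) {
  stopifnot(inherits(mixed_ppf, "empirical_ppf"),
            inherits(discrepancy, "discrepancy_curve"))
  if (length(mixed_ppf$grid) != length(discrepancy$grid) ||
      any(mixed_ppf$grid != discrepancy$grid)) {
    stop("mixed PPF and discrepancy curve must share a grid")
  }
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0) {
    stop("`c` must be a single nonnegative number")
  }
  n_refinements <- as.integer(n_refinements)
  if (is.na(n_refinements) || n_refinements < 1L) {
    stop("`n_refinements` must be >= 1")
  }
  spec <- structure(
    list(mixed_ppf = mixed_ppf, discrepancy = discrepancy, c = c,
         n_refinements = n_refinements,
         max_endpoint_rejections = as.integer(max_endpoint_rejections)),
    class = "hb_spec")
  spec$beta_table <- hb_beta_table(spec)
  spec$level_cache <- hb_level_cache(spec)
  spec
}

# per-level vectors (beta parameters and dyadic indices) for the sampling
# hot path; avoids repeated data-frame subsetting per realisation
hb_level_cache <- function(spec) {
  N <- spec$n_refinements
  npts <- 2L^N + 1L
  tab <- spec$beta_table
  lapply(seq_len(N), function(n) {
    rows <- tab[tab$level == n, , drop = FALSE]
    step <- 2L^(N - n + 1L)
    li <- seq.int(1L, npts - step, by = step)
    list(alpha = rows$alpha, beta = rows$beta,
         live = !rows$deterministic, n_live = sum(!rows$deterministic),
         li = li, mi = li + step %/% 2L, ri = li + step)
  })
}

#' @export
print.hb_spec <- function(x, ...) {
  cat(sprintf(
    "Hierarchical beta process: c = %g, N = %d refinements (%d dyadic points)\n",
    x$c, x$n_refinements, 2^x$n_refinements + 1))
  cat(sprintf("  q* range [%.6g, %.6g], sup delta %.6g\n",
              x$mixed_ppf$ordinates[1L],
              x$mixed_ppf$ordinates[length(x$mixed_ppf$ordinates)],
              max(x$discrepancy$ordinates)))
  invisible(x)
}

# numerical guards for degenerate increments (flat q* regions carry no
# information about the split; clipping keeps (alpha, beta) representable)
.hb_logr_clip <- log(1e12)
.hb_v_floor <- 1e-12
.hb_v_cap <- 2 * trigamma(1e-8)

#' Aitchison centre and metric variance of a beta increment pair
#'
#' For `x1 ~ Beta(alpha, beta)` and `x2 = 1 - x1`, the compositional centre
#' is `(e^psi(alpha), e^psi(beta))` normalised to sum to one, and the metric
#' variance is `(psigamma(alpha, 1) + psigamma(beta, 1)) / 2`, where `psi`
#' and `psi_1` are the digamma and trigamma functions. Unlike the ordinary
#' variance, the metric variance is unbounded, which is what makes the
#' parameter-selection equations solvable for any requested spread.
#'
#' @param alpha,beta Strictly positive beta parameters.
#' @return List with `centre` (length-2, sums to 1) and `mvar` (positive).
#' @export
#' @examples
#' beta_centre_mvar(1, 1)  # centre (0.5, 0.5), mvar pi^2 / 6
beta_centre_mvar <- function(alpha, beta) {
  if (!all(is.finite(alpha), is.finite(beta)) || alpha <= 0 || beta <= 0) {
    stop("`alpha` and `beta` must be finite and strictly positive")
  }
  # normalise in log space to avoid overflow of e^psi for large arguments
  pa <- digamma(alpha); pb <- digamma(beta)
  m <- max(pa, pb)
  w <- exp(c(pa, pb) - m)
  list(centre = w / sum(w),
       mvar = 0.5 * (trigamma(alpha) + trigamma(beta)))
}

#' Increment statistics (r, v) at a dyadic refinement point
#'
#' `r` is the ratio of the two subincrements of the mixed PPF over
#' `[phi, phi + 2 h]` split at the midpoint `phi + h`; `v` is twice the
#' requested metric variance, `2 c delta(phi + h)^2`. Degenerate flat
#' regions are clipped: `log r` to `+/- log(1e12)` when one subincrement is
#' zero, and the split is marked deterministic (midpoint exactly halves the
#' increment) when both are zero; `v` is floored/capped to the numerical
#' range of the trigamma function.
#'
#' @param spec An `hb_spec`.
#' @param phi Left edge(s) of the parent increment(s).
#' @param half_width Half the parent increment width (`2^(-n)` at refinement
#'   level `n`).
#' @return Data frame with columns `r`, `v`, `deterministic`.
#' @export
increment_stats <- function(spec, phi, half_width) {
  stopifnot(inherits(spec, "hb_spec"))
  if (any(phi < 0) || any(phi + 2 * half_width > 1 + 1e-12)) {
    stop("increment must lie inside [0, 1]")
  }
  q <- spec$mixed_ppf
  q0 <- eval_ppf(q, phi)
  qm <- eval_ppf(q, phi + half_width)
  q1 <- eval_ppf(q, pmin(phi + 2 * half_width, 1))
  num <- qm - q0
  den <- q1 - qm
  deterministic <- num <= 0 & den <= 0
  logr <- ifelse(deterministic, 0,
          ifelse(num <= 0, -.hb_logr_clip,
          ifelse(den <= 0, .hb_logr_clip,
                 pmin(pmax(log(num) - log(den), -.hb_logr_clip),
                      .hb_logr_clip))))
  dmid <- eval_ppf(spec$discrepancy, phi + half_width)
  v <- pmin(pmax(2 * spec$c * dmid^2, .hb_v_floor), .hb_v_cap)
  data.frame(r = exp(logr), v = v, deterministic = deterministic)
}

#' Solve for beta parameters matching a centre ratio and metric variance
#'
#' Finds `(alpha, beta)` with `psi(alpha) - psi(beta) = log r` and
#' `psigamma(alpha, 1) + psigamma(beta, 1) = v`. Solved by a damped Newton
#' iteration in `(log alpha, log beta)` (both equations are smooth and
#' monotone per coordinate), seeded from the large-argument asymptotics
#' `psi(z) ~ log z`, `psi_1(z) ~ 1/z`; entries that fail to converge fall
#' back to a nested bisection that exploits the monotonicity of the digamma
#' and trigamma functions.
#'
#' @param r Positive centre ratio(s).
#' @param v Positive metric-variance target(s) (`= 2 * Mvar`).
#' @param tol Absolute tolerance on the transformed equations.
#' @return Data frame with columns `alpha` and `beta`.
#' @export
#' @examples
#' solve_beta_params(1, pi^2 / 3)  # alpha = beta = 1
solve_beta_params <- function(r, v, tol = 1e-10) {
  if (length(v) == 1L && length(r) > 1L) v <- rep(v, length(r))
  if (length(r) == 1L && length(v) > 1L) r <- rep(r, length(v))
  stopifnot(length(r) == length(v))
  if (!all(is.finite(r) & r > 0) || !all(is.finite(v) & v > 0)) {
    stop("`r` and `v` must be finite and strictly positive")
  }
  logr <- pmin(pmax(log(r), -.hb_logr_clip), .hb_logr_clip)
  v <- pmin(pmax(v, .hb_v_floor), .hb_v_cap)

  # seed: z = psi1^{-1}(v / 2) from 1/z + 1/(2 z^2) = v/2, then split by r
  y <- v / 2
  z <- (1 + sqrt(1 + 2 * y)) / (2 * y)
  a <- log(z) + logr / 2
  b <- log(z) - logr / 2

  n <- length(r)
  active <- rep(TRUE, n)
  for (iter in 1:200) {
    al <- exp(a[active]); be <- exp(b[active])
    t1a <- trigamma(al); t1b <- trigamma(be)
    f1 <- digamma(al) - digamma(be) - logr[active]
    f2 <- log(t1a + t1b) - log(v[active])
    conv <- abs(f1) < tol & abs(f2) < tol
    if (all(conv)) { active[active] <- FALSE; break }
    # Jacobian wrt (log alpha, log beta)
    s <- t1a + t1b
    j11 <- al * t1a
    j12 <- -be * t1b
    j21 <- al * psigamma(al, 2) / s
    j22 <- be * psigamma(be, 2) / s
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-300] <- NA_real_
    da <- (f1 * j22 - f2 * j12) / det
    db <- (j11 * f2 - j21 * f1) / det
    # damp: cap the step to keep the iteration inside the basin
    da <- pmin(pmax(-da, -3), 3)
    db <- pmin(pmax(-db, -3), 3)
    da[is.na(da)] <- 0; db[is.na(db)] <- 0
    idx <- which(active)
    upd <- idx[!conv]
    a[upd] <- a[upd] + da[!conv]
    b[upd] <- b[upd] + db[!conv]
    active[idx[conv]] <- FALSE
    if (!any(active)) break
  }
  if (any(active)) {
    for (i in which(active)) {
      ab <- solve_beta_bisect(logr[i], v[i], tol)
      if (is.null(ab)) {
        stop(sprintf("beta-parameter solver failed for (r = %g, v = %g)",
                     r[i], v[i]))
      }
      a[i] <- log(ab[1L]); b[i] <- log(ab[2L])
    }
  }
  data.frame(alpha = exp(a), beta = exp(b))
}

# nested bisection fallback: for fixed alpha, beta is pinned by the (monotone)
# digamma equation; the remaining 1-d equation in alpha is monotone decreasing
solve_beta_bisect <- function(logr, v, tol = 1e-10) {
  inv_digamma <- function(y) {
    lo <- -45; hi <- 45
    f <- function(lz) digamma(exp(lz)) - y
    if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
    exp(stats::uniroot(f, c(lo, hi), tol = 1e-14)$root)
  }
  g <- function(la) {
    al <- exp(la)
    be <- inv_digamma(digamma(al) - logr)
    if (!is.finite(be)) return(NA_real_)
    trigamma(al) + trigamma(be) - v
  }
  lo <- -40; hi <- 40
  glo <- g(lo); ghi <- g(hi)
  if (!is.finite(glo) || !is.finite(ghi) || glo < 0 || ghi > 0) return(NULL)
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-14)$root
  al <- exp(root)
  be <- inv_digamma(digamma(al) - logr)
  if (abs(digamma(al) - digamma(be) - logr) > 1e-6 ||
      abs(log(trigamma(al) + trigamma(be)) - log(v)) > 1e-6) return(NULL)
  c(al, be)
}

# precompute (r, v, alpha, beta) for every dyadic midpoint, level-major;
# one row per new point introduced at level n (left edge phi, width 2^(1-n))
hb_beta_table <- function(spec) {
  N <- spec$n_refinements
  degenerate <- spec$c == 0 || max(spec$discrepancy$ordinates) == 0
  tabs <- vector("list", N)
  for (n in seq_len(N)) {
    h <- 2^(-n)
    left <- (0:(2^(n - 1) - 1)) * 2^(1 - n)
    st <- increment_stats(spec, left, h)
    if (degenerate) {
      ab <- data.frame(alpha = rep(NA_real_, nrow(st)),
                       beta = NA_real_)
      st$deterministic <- TRUE          # process collapses onto q*
    } else {
      ab <- data.frame(alpha = rep(NA_real_, nrow(st)),
                       beta = rep(NA_real_, nrow(st)))
      live <- !st$deterministic
      if (any(live)) {
        sol <- solve_beta_params(st$r[live], st$v[live])
        ab$alpha[live] <- sol$alpha
        ab$beta[live] <- sol$beta
      }
    }
    tabs[[n]] <- cbind(level = n, phi_left = left, st, ab)
  }
  do.call(rbind, tabs)
}

#' Sample the endpoints of a process realisation
#'
#' Draws `q(0) ~ N(q*(0), c delta(0)^2)` and `q(1) ~ N(q*(1), c delta(1)^2)`
#' independently, redrawing until `q(0) < q(1)` (a quantile function must be
#' increasing end to end). With `c = 0` the endpoints are exactly
#' `(q*(0), q*(1))`.
#'
#' @param spec An `hb_spec`.
#' @return Numeric vector `c(q0, q1)` with `q0 < q1`.
#' @export
sample_endpoints <- function(spec) {
  stopifnot(inherits(spec, "hb_spec"))
  q0m <- spec$mixed_ppf$ordinates[1L]
  q1m <- spec$mixed_ppf$ordinates[length(spec$mixed_ppf$ordinates)]
  if (spec$c == 0) {
    if (!(q0m < q1m)) stop("degenerate mixed PPF: q*(0) >= q*(1)")
    return(c(q0m, q1m))
  }
  sd0 <- sqrt(spec$c) * spec$discrepancy$ordinates[1L]
  sd1 <- sqrt(spec$c) *
    spec$discrepancy$ordinates[length(spec$discrepancy$ordinates)]
  for (i in seq_len(spec$max_endpoint_rejections)) {
    q0 <- stats::rnorm(1L, q0m, sd0)
    q1 <- stats::rnorm(1L, q1m, sd1)
    if (q0 < q1) return(c(q0, q1))
  }
  stop("endpoint sampling failed after ", spec$max_endpoint_rejections,
       " rejections: c * delta^2 is too large relative to q*(1) - q*(0)")
}

#' Draw one realisation of the hierarchical beta process
#'
#' After the Gaussian endpoints, refinement proceeds level-major and left to
#' right: at level `n` each increment over `[phi, phi + 2^(1-n)]` is split at
#' its midpoint by a draw `x1 ~ Beta(alpha, beta)` (parameters from the
#' precomputed table), setting
#' `q(phi + 2^-n) = q(phi) + x1 * (q(phi + 2^(1-n)) - q(phi))`. Increments
#' are nonnegative by construction so every realisation is a nondecreasing
#' quantile function, and points once sampled are never revisited, making
#' the process self-consistent under deeper refinement. The `c = 0` (or
#' `delta == 0`) limit returns `q*` on the dyadic grid without consuming
#' random numbers.
#'
#' @param spec An `hb_spec`.
#' @return An `hb_realisation`: list with `phis` (dyadic grid, length
#'   `2^N + 1`) and nondecreasing `values`.
#' @export
sample_realisation <- function(spec) {
  stopifnot(inherits(spec, "hb_spec"))
  N <- spec$n_refinements
  npts <- 2^N + 1L
  phis <- (0:(npts - 1L)) / 2^N
  if (spec$c == 0 || max(spec$discrepancy$ordinates) == 0) {
    return(structure(list(phis = phis,
                          values = eval_ppf(spec$mixed_ppf, phis)),
                     class = "hb_realisation"))
  }
  structure(list(phis = phis, values = hb_draw_values(spec, npts)),
            class = "hb_realisation")
}

# raw value vector of one realisation (hot path shared with risk sampling)
hb_draw_values <- function(spec, npts) {
  q <- numeric(npts)
  ends <- sample_endpoints(spec)
  q[1L] <- ends[1L]; q[npts] <- ends[2L]
  for (lev in spec$level_cache) {
    x1 <- rep.int(0.5, length(lev$li))
    if (lev$n_live > 0L) {
      x1[lev$live] <- stats::rbeta(lev$n_live, lev$alpha[lev$live],
                                   lev$beta[lev$live])
    }
    # clamp to the bracket: x1 near 0/1 can otherwise overshoot by an ulp
    q[lev$mi] <- pmin(pmax(q[lev$li] + x1 * (q[lev$ri] - q[lev$li]),
                           q[lev$li]), q[lev$ri])
  }
  q
}

#' @export
print.hb_realisation <- function(x, ...) {
  cat(sprintf("HB realisation: %d dyadic points, values [%.6g, %.6g], risk %.6g\n",
              length(x$phis), x$values[1L], x$values[length(x$values)],
              realisation_risk(x)))
  invisible(x)
}

#' Risk of a single process realisation
#'
#' Trapezoidal integral of the realised quantile function over its dyadic
#' grid.
#'
#' @param realisation An `hb_realisation`.
#' @return Scalar risk.
#' @export
realisation_risk <- function(realisation) {
  stopifnot(inherits(realisation, "hb_realisation"))
  trapz_unit(realisation$phis, realisation$values)
}
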