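#' Empirical PPF (quantile function) of a loss sample
#'
#' Sorts the per-sample losses and places the order statistics at abscissae
#' `Phi_i = i / (L + 1)`, so that the `L` sorted losses are uniformly spread
#' over (0, 1). The curve is then resampled by linear interpolation onto a
#' uniform interior grid of `n_grid` points, with explicit endpoints at
#' `Phi = 0` and `Phi = 1` carried by constant extrapolation of the first and
#' last ordinate (the end points are needed by the hierarchical beta process).
#' Ties in the losses give flat (nondecreasing, not strictly increasing)
#' segments.
#'
#' @param losses A [loss_sample()] or a numeric vector of finite losses.
#' @param n_grid Number of interior grid points; default `2^10 = 1024`.
#' @param kind One of `"mixed"`, `"synthetic"`, `"realisation"`.
#' @return An `empirical_ppf` object: list with `grid` (strictly increasing
#'   values in \[0, 1\], including both endpoints), `ordinates` (nondecreasing
#'   loss values) and `kind`.
#' @export
#' @examples
#' p <- empirical_ppf(c(3, 1, 2), n_grid = 8)
#' ppf_risk(p)  # close to mean(c(3, 1, 2))
empirical_ppf <- function(losses, n_grid = 1024L, kind = "mixed") {
  if (inherits(losses, "loss_sample")) losses <- losses$values
  losses <- as.numeric(losses)
  if (length(losses) < 2L) stop("need at least 2 losses to build a PPF")
  if (!all(is.finite(losses))) stop("losses must all be finite")
  n_grid <- as.integer(n_grid)
  if (is.na(n_grid) || n_grid < 2L) stop("`n_grid` must be an integer >= 2")

  L <- length(losses)
  q <- sort(losses, method = "radix")        # stable
  phi <- seq_len(L) / (L + 1)
  interior <- seq_len(n_grid) / (n_grid + 1)
  ord <- stats::approx(phi, q, xout = interior, rule = 2)$y
  new_ppf(grid = c(0, interior, 1),
          ordinates = c(ord[1L], ord, ord[n_grid]),
          kind = kind)
}

new_ppf <- function(grid, ordinates, kind = "mixed") {
  stopifnot(length(grid) == length(ordinates),
            all(diff(grid) > 0), grid[1L] >= 0,
            grid[length(grid)] <= 1)
  if (any(diff(ordinates) < 0)) stop("PPF ordinates must be nondecreasing")
  structure(list(grid = as.numeric(grid), ordinates = as.numeric(ordinates),
                 kind = match.arg(kind, c("mixed", "synthetic", "realisation"))),
            class = "empirical_ppf")
}

#' Evaluate a PPF (or discrepancy curve) at arbitrary probabilities
#'
#' Linear interpolation on the stored grid; beyond the stored range the first
#' or last ordinate is extended, so evaluation is defined on all of \[0, 1\]
#' and nondecreasing in `Phi` for a PPF.
#'
#' @param ppf An `empirical_ppf` or `discrepancy_curve`.
#' @param phi Numeric vector of probabilities in \[0, 1\].
#' @return Numeric vector of interpolated ordinates.
#' @export
eval_ppf <- function(ppf, phi) {
  stopifnot(inherits(ppf, c("empirical_ppf", "discrepancy_curve")))
  if (any(phi < 0 | phi > 1)) stop("`phi` must lie in [0, 1]")
  stats::approx(ppf$grid, ppf$ordinates, xout = phi, rule = 2)$y
}

#' @export
print.empirical_ppf <- function(x, ...) {
  cat(sprintf("Empirical PPF (%s): %d grid points on [%g, %g]\n",
              x$kind, length(x$grid), x$grid[1L], x$grid[length(x$grid)]))
  cat(sprintf("  ordinates in [%.6g, %.6g], risk %.6g\n",
              x$ordinates[1L], x$ordinates[length(x$ordinates)], ppf_risk(x)))
  invisible(x)
}

#' Mixed and synthetic PPFs of a candidate model
#'
#' The *mixed* PPF is the quantile function of the model's loss evaluated on
#' the observed data (loss under the model, distribution under the data).
#' The *synthetic* PPF evaluates the same loss on samples the model generates
#' itself. When the model reproduces the data-generating process exactly the
#' two coincide (up to sampling error); their pointwise gap is the empirical
#' model discrepancy.
#'
#' @param model A [candidate_model()] exposing both loss and sampler.
#' @param observed Data frame with columns `x` and `y`.
#' @param l_synth Number of model-generated samples for the synthetic PPF;
#'   default `2^12 = 4096`.
#' @param n_grid Interior grid size shared by both PPFs.
#' @return List with elements `mixed` and `synthetic`, both `empirical_ppf`s
#'   on the same grid.
#' @export
mixed_and_synthetic_ppfs <- function(model, observed, l_synth = 4096L,
                                     n_grid = 1024L) {
  stopifnot(inherits(model, "candidate_model"))
  if (!has_sampler(model)) {
    stop("model '", model$id, "' has no sampling capability; ",
         "the synthetic PPF cannot be built")
  }
  l_synth <- as.integer(l_synth)
  if (is.na(l_synth) || l_synth < 2L) stop("`l_synth` must be >= 2")
  obs_losses <- pointwise_losses(observed, model, dataset_id = "observed")
  synth <- as.data.frame(model$sampler(l_synth))
  synth_losses <- pointwise_losses(synth, model, dataset_id = "synthetic")
  list(mixed = empirical_ppf(obs_losses, n_grid = n_grid, kind = "mixed"),
       synthetic = empirical_ppf(synth_losses, n_grid = n_grid,
                                 kind = "synthetic"))
}

#' Empirical model discrepancy between synthetic and mixed PPFs
#'
#' The pointwise absolute difference `|q~(Phi) - q*(Phi)|` on the shared grid.
#' It vanishes identically when the model reproduces the observations exactly
#' and is treated as a nonparametric measure of misspecification: the larger
#' the discrepancy at `Phi`, the more epistemic variance the hierarchical
#' beta process assigns there.
#'
#' @param mixed,synthetic `empirical_ppf`s on identical grids (order of the
#'   two arguments is immaterial).
#' @return A `discrepancy_curve`: list with `grid` and nonnegative
#'   `ordinates` in loss units.
#' @export
delta_emd <- function(mixed, synthetic) {
  stopifnot(inherits(mixed, "empirical_ppf"),
            inherits(synthetic, "empirical_ppf"))
  if (length(mixed$grid) != length(synthetic$grid) ||
      any(mixed$grid != synthetic$grid)) {
    stop("mixed and synthetic PPFs must share the same grid")
  }
  structure(list(grid = mixed$grid,
                 ordinates = abs(synthetic$ordinates - mixed$ordinates)),
            class = "discrepancy_curve")
}

#' @export
print.discrepancy_curve <- function(x, ...) {
  cat(sprintf("Discrepancy curve: %d grid points, sup %.6g, mean %.6g\n",
              length(x$grid), max(x$ordinates), mean(x$ordinates)))
  invisible(x)
}

#' Risk functional of a quantile function
#'
#' The risk is the expectation of the pointwise loss, rewritten as the
#' one-dimensional integral of the loss PPF over `Phi` in \[0, 1\]; here it is
#' evaluated by the trapezoidal rule on the stored grid. Applied to the
#' empirical PPF of a loss sample it recovers the empirical risk (the sample
#' mean of the losses) up to interpolation error.
#'
#' @param ppf An `empirical_ppf`.
#' @return Scalar risk, in loss units.
#' @export
ppf_risk <- function(ppf) {
  stopifnot(inherits(ppf, "empirical_ppf"))
  trapz_unit(ppf$grid, ppf$ordinates)
}

# trapezoid integral on [0, 1]; grid assumed sorted and spanning [0, 1]
trapz_unit <- function(grid, y) {
  sum(diff(grid) * (y[-length(y)] + y[-1L])) / 2
}

# ---- delimited-text interfaces ---------------------------------------------

#' Read / write two-column datasets and (phi, value) curves
#'
#' Datasets are delimited text with a header row and two numeric columns
#' `x`, `y`. PPFs, discrepancy curves and process realisations share a
#' `phi,value` CSV dialect whose round trip is lossless to full double
#' precision (17 significant digits).
#'
#' @param path File path.
#' @param dataset Data frame with columns `x` and `y`.
#' @param sep Field separator (`,` or tab).
#' @name dataset_io
NULL

#' @rdname dataset_io
#' @export
read_dataset <- function(path, sep = ",") {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("x", "y") %in% names(d))) {
    stop("dataset must have header columns `x` and `y`: ", path)
  }
  d[, c("x", "y")]
}

#' @rdname dataset_io
#' @export
write_dataset <- function(dataset, path, sep = ",") {
  dataset <- as.data.frame(dataset)
  stopifnot(all(c("x", "y") %in% names(dataset)))
  writeLines(c(paste("x", "y", sep = sep),
               paste(sprintf("%.17g", dataset$x),
                     sprintf("%.17g", dataset$y), sep = sep)),
             path)
  invisible(path)
}

#' @param curve An `empirical_ppf`, `discrepancy_curve` or `hb_realisation`.
#' @param kind PPF kind to assign when reading.
#' @rdname dataset_io
#' @export
write_curve <- function(curve, path) {
  grid <- if (!is.null(curve$grid)) curve$grid else curve$phis
  value <- if (!is.null(curve$ordinates)) curve$ordinates else curve$values
  writeLines(c("phi,value",
               paste(sprintf("%.17g", grid), sprintf("%.17g", value),
                     sep = ",")),
             path)
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_ppf <- function(path, kind = "mixed") {
  d <- utils::read.csv(path)
  if (!all(c("phi", "value") %in% names(d))) {
    stop("curve file must have columns `phi` and `value`: ", path)
  }
  new_ppf(d$phi, d$value, kind = kind)
}

#' @rdname dataset_io
#' @export
read_discrepancy <- function(path) {
  d <- utils::read.csv(path)
  structure(list(grid = d$phi, ordinates = d$value),
            class = "discrepancy_curve")
}
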