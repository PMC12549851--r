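#' Epistemic distribution over data-generating processes
#'
#' Wraps a `draw()` function that samples a concrete data-generating process
#' — a list with a `sampler(n)` returning a data frame of `(x, y)` records,
#' plus an `omega` element recording the drawn hyperparameters. An epistemic
#' distribution represents the non-stationarity of experimental replication:
#' each simulated experiment is run under a freshly drawn process.
#'
#' @param draw Function of no arguments returning a process (uses the global
#'   RNG, so repeated draws under a set seed are reproducible).
#' @param description Label for reports.
#' @return An `epistemic_distribution` object.
#' @seealso [blackbody_epistemic_dist()] for the built-in example.
#' @export
epistemic_distribution <- function(draw, description = "epistemic") {
  stopifnot(is.function(draw))
  structure(list(draw = draw, description = description),
            class = "epistemic_distribution")
}

#' @export
print.epistemic_distribution <- function(x, ...) {
  cat("Epistemic distribution:", x$description, "\n")
  invisible(x)
}

#' True risk of a candidate under a known data-generating process
#'
#' The expectation of the candidate's pointwise loss under the process,
#' estimated as the empirical risk on a large synthetic sample. Below
#' `n = 1e4` the estimate is flagged as high-variance with a warning.
#'
#' @param process A data-generating process (list with `sampler(n)`), e.g.
#'   a draw from an [epistemic_distribution()].
#' @param candidate A [candidate_model()].
#' @param n Number of samples used for the estimate.
#' @return Scalar risk estimate.
#' @export
true_risk <- function(process, candidate, n = 2^14) {
  stopifnot(is.function(process$sampler), n >= 2)
  if (n < 1e4) {
    warning("true_risk with n = ", n,
            " is a high-variance estimate; n >= 1e4 recommended")
  }
  d <- as.data.frame(process$sampler(as.integer(n)))
  mean(pointwise_losses(d, candidate, dataset_id = "true-process")$values)
}

# deterministic child seed below 2^31 for experiment j of a master seed
child_seed <- function(master_seed, j) {
  (as.numeric(master_seed) * 69069 + 12345 * as.numeric(j)) %% 2147483647
}

#' Run simulated replication experiments to calibrate the sensitivity factor
#'
#' Per experiment: a data-generating process is drawn from the epistemic
#' distribution, a replicate dataset is generated, per-replicate nuisance
#' parameters of both candidates are fitted (via each candidate's `fit`
#' capability, when present), `B^EMD` between the two fitted candidates is
#' computed at each requested sensitivity `c`, and the ground-truth
#' indicator `[R_A < R_B]` is computed from the candidates' true risks under
#' the drawn process. One dataset is drawn per process draw (statistically
#' more efficient than reusing processes), and experiment `j` uses a child
#' seed derived from `(seed, j)` so runs are reproducible and
#' parallelisable in principle.
#'
#' @param omega An [epistemic_distribution()].
#' @param candidate_a,candidate_b [candidate_model()]s with loss and
#'   sampler (and optionally `fit`).
#' @param n_experiments Number of simulated experiments.
#' @param dataset_size Records per replicate dataset.
#' @param c Sensitivity factor; may be a vector, in which case each
#'   experiment's replicate data, fits and true risks are shared across the
#'   `c` values and one record is emitted per (experiment, c).
#' @param n_true_risk Sample size for the true-risk estimates.
#' @param seed Master seed.
#' @param n_grid,l_synth,n_refinements,rse_tol,m_min,m_max Passed through to
#'   PPF construction and risk sampling.
#' @return A `calibration_records` data frame with columns `omega_id`, `c`,
#'   `b_emd`, `a_beats_b` (indicator of true `R_A < R_B`), `risk_a_true`,
#'   `risk_b_true`, plus an attribute `skipped` counting replicates dropped
#'   because a candidate fit failed (with reasons).
#' @export
run_calibration <- function(omega, candidate_a, candidate_b,
                            n_experiments, dataset_size, c,
                            n_true_risk = 2^14, seed = 1L,
                            n_grid = 1024L, l_synth = 4096L,
                            n_refinements = 8L, rse_tol = 2^-5,
                            m_min = 32L, m_max = 4096L) {
  stopifnot(inherits(omega, "epistemic_distribution"),
            inherits(candidate_a, "candidate_model"),
            inherits(candidate_b, "candidate_model"),
            n_experiments >= 1L, dataset_size >= 2L,
            all(c >= 0))
  records <- vector("list", n_experiments)
  skipped <- character(0)
  for (j in seq_len(n_experiments)) {
    set.seed(child_seed(seed, j))
    proc <- omega$draw()
    replicate_data <- as.data.frame(proc$sampler(as.integer(dataset_size)))
    fit_a <- try(fit_candidate(candidate_a, replicate_data), silent = TRUE)
    fit_b <- try(fit_candidate(candidate_b, replicate_data), silent = TRUE)
    if (inherits(fit_a, "try-error") || inherits(fit_b, "try-error")) {
      reason <- if (inherits(fit_a, "try-error")) attr(fit_a, "condition")
                else attr(fit_b, "condition")
      skipped <- c(skipped,
                   sprintf("experiment %d: %s", j, conditionMessage(reason)))
      next
    }
    ra <- true_risk(proc, fit_a, n = n_true_risk)
    rb <- true_risk(proc, fit_b, n = n_true_risk)

    ppfs_a <- mixed_and_synthetic_ppfs(fit_a, replicate_data,
                                       l_synth = l_synth, n_grid = n_grid)
    ppfs_b <- mixed_and_synthetic_ppfs(fit_b, replicate_data,
                                       l_synth = l_synth, n_grid = n_grid)
    da <- delta_emd(ppfs_a$mixed, ppfs_a$synthetic)
    db <- delta_emd(ppfs_b$mixed, ppfs_b$synthetic)

    bvals <- vapply(c, function(ci) {
      spec_a <- hb_process_spec(ppfs_a$mixed, da, c = ci,
                                n_refinements = n_refinements)
      spec_b <- hb_process_spec(ppfs_b$mixed, db, c = ci,
                                n_refinements = n_refinements)
      rs_a <- sample_risk_distribution(spec_a, rse_tol = rse_tol,
                                       m_min = m_min, m_max = m_max,
                                       model_id = fit_a$id)
      rs_b <- sample_risk_distribution(spec_b, rse_tol = rse_tol,
                                       m_min = m_min, m_max = m_max,
                                       model_id = fit_b$id)
      b_emd(rs_a, rs_b)
    }, numeric(1))

    records[[j]] <- data.frame(omega_id = j, c = c, b_emd = bvals,
                               a_beats_b = as.integer(ra < rb),
                               risk_a_true = ra, risk_b_true = rb)
  }
  out <- do.call(rbind, records)
  if (is.null(out)) {
    out <- data.frame(omega_id = integer(0), c = numeric(0),
                      b_emd = numeric(0), a_beats_b = integer(0),
                      risk_a_true = numeric(0), risk_b_true = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("calibration_records", "data.frame")
  out
}

fit_candidate <- function(candidate, data) {
  if (is.null(candidate$fit)) return(candidate)
  candidate$fit(data)
}

#' Equal-count binning of calibration records
#'
#' Sorts the records by `b_emd` and splits them into `n_bins` contiguous
#' groups whose sizes differ by at most one, so every bin carries similar
#' statistical power; per-bin means of `b_emd` and of the ground-truth
#' indicator give one point of the calibration curve (the latter is the
#' conditional `B^epis`).
#'
#' @param records A `calibration_records` data frame (a single sensitivity
#'   `c`; mixed values are an error).
#' @param n_bins Number of bins, between 1 and the number of records.
#' @return A `calibration_curve` data frame with columns `bin_centre` (mean
#'   `b_emd`), `bin_bepis` (mean indicator) and `bin_count`.
#' @export
bin_calibration <- function(records, n_bins) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("`n_bins` must be >= 1")
  if (nrow(records) < n_bins) stop("more bins than records")
  if (length(unique(records$c)) > 1L) {
    stop("records mix several `c` values; bin each separately")
  }
  ord <- order(records$b_emd)
  b <- records$b_emd[ord]
  ind <- records$a_beats_b[ord]
  n <- length(b)
  base <- n %/% n_bins
  rem <- n %% n_bins
  counts <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  stopifnot(max(counts) - min(counts) <= 1L)
  idx <- rep(seq_len(n_bins), times = counts)
  out <- data.frame(
    bin_centre = as.numeric(tapply(b, idx, mean)),
    bin_bepis = as.numeric(tapply(ind, idx, mean)),
    bin_count = as.integer(counts))
  if (length(unique(records$c)) == 1L) attr(out, "c") <- records$c[1L]
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' Flag overconfident regions of a calibration curve
#'
#' A sensitivity factor is acceptable when the criterion is conservative:
#' the `B^EMD` deviation from 1/2 should not exceed the `B^epis` deviation,
#' `|B^EMD - 0.5| <~ |B^epis - 0.5|`. A bin is flagged overconfident when
#' its `B^EMD` deviation exceeds its `B^epis` deviation by more than the
#' slack (default: one binomial standard error of the bin's `B^epis`
#' estimate, allowing the small violations the soft inequality intends), or
#' when the two deviations point to opposite sides of 1/2 (the wrong-side
#' region) by more than the slack. With several curves from different
#' epistemic distributions sharing a bin layout, the per-bin minimum
#' `|B^epis - 0.5|` across curves is used, so conclusions hold under every
#' distribution tested.
#'
#' @param curve A `calibration_curve`, or a list of them (same number of
#'   bins) for the min-over-distributions aggregation.
#' @param slack `"se"` for one binomial SE per bin, or a fixed nonnegative
#'   number.
#' @return An `overconfidence_summary`: data frame of per-bin flags with
#'   attribute `flagged_fraction`.
#' @export
overconfidence_check <- function(curve, slack = "se") {
  curves <- if (inherits(curve, "calibration_curve")) list(curve) else curve
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "calibration_curve")))
  nb <- unique(vapply(curves, nrow, integer(1)))
  if (length(nb) != 1L) stop("curves must share the number of bins")

  dev_emd <- rowMeans(sapply(curves, function(cc) cc$bin_centre)) - 0.5
  # per-bin epistemic deviation: minimum magnitude across distributions,
  # with the sign of the minimising curve
  ep <- sapply(curves, function(cc) cc$bin_bepis - 0.5)
  ep <- matrix(ep, nrow = nb)
  pick <- apply(abs(ep), 1L, which.min)
  dev_epis <- ep[cbind(seq_len(nb), pick)]

  counts <- curves[[which.max(vapply(curves, function(cc)
    sum(cc$bin_count), numeric(1)))]]$bin_count
  if (identical(slack, "se")) {
    p <- dev_epis + 0.5
    slack_v <- sqrt(pmax(p * (1 - p), 0) / counts)
  } else {
    stopifnot(is.numeric(slack), all(slack >= 0))
    slack_v <- rep_len(slack, nb)
  }
  excess <- abs(dev_emd) > abs(dev_epis) + slack_v
  wrong_side <- sign(dev_emd) * sign(dev_epis) < 0 & abs(dev_emd) > slack_v
  flagged <- excess | wrong_side
  out <- data.frame(bin = seq_len(nb), dev_emd = dev_emd,
                    dev_epis = dev_epis, slack = slack_v,
                    excess = excess, wrong_side = wrong_side,
                    flagged = flagged)
  attr(out, "flagged_fraction") <- mean(flagged)
  class(out) <- c("overconfidence_summary", "data.frame")
  out
}

#' @export
print.overconfidence_summary <- function(x, ...) {
  cat(sprintf("Overconfidence check: %d / %d bins flagged (%.1f%%)\n",
              sum(x$flagged), nrow(x), 100 * attr(x, "flagged_fraction")))
  invisible(x)
}
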