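#' Sample a model's risk distribution from its hierarchical beta process
#'
#' Draws process realisations in batches, integrates each to a risk, and
#' stops once the relative standard error of the mean risk drops below
#' `rse_tol` (default `2^-5`, i.e. about 3 %) or `m_max` is reached. Typical
#' runs need on the order of a hundred realisations. When the mean risk is
#' (numerically) zero the relative criterion is undefined and an absolute
#' standard-error criterion is used instead, flagged in the output. With
#' `c = 0` the process is degenerate and the distribution is a Dirac at the
#' risk of `q*`.
#'
#' @param spec An [hb_process_spec()].
#' @param rse_tol Relative standard-error tolerance in (0, 1).
#' @param m_min Minimum number of realisations before the stopping rule is
#'   consulted (standard-error estimates are unstable below a few dozen).
#' @param m_max Hard cap on the number of realisations.
#' @param batch Realisations drawn between checks of the stopping rule.
#' @param model_id Label carried into the result.
#' @return A `risk_samples` object: list with `model_id`, `values` (risks),
#'   `rse` (achieved relative standard error) and `rse_fallback` (TRUE when
#'   the absolute criterion was used).
#' @export
sample_risk_distribution <- function(spec, rse_tol = 2^-5, m_min = 32L,
                                     m_max = 4096L, batch = 16L,
                                     model_id = "model") {
  stopifnot(inherits(spec, "hb_spec"))
  if (!is.numeric(rse_tol) || rse_tol <= 0 || rse_tol >= 1) {
    stop("`rse_tol` must lie in (0, 1)")
  }
  if (spec$c == 0 || max(spec$discrepancy$ordinates) == 0) {
    r0 <- realisation_risk(sample_realisation(spec))
    return(structure(list(model_id = model_id, values = r0, rse = 0,
                          rse_fallback = FALSE),
                     class = "risk_samples"))
  }
  npts <- 2L^spec$n_refinements + 1L
  h <- 1 / 2^spec$n_refinements
  values <- numeric(0)
  fallback <- FALSE
  repeat {
    k <- if (length(values) < m_min) m_min - length(values) else batch
    k <- min(k, m_max - length(values))
    values <- c(values, vapply(seq_len(k), function(i) {
      q <- hb_draw_values(spec, npts)
      h * (sum(q) - (q[1L] + q[npts]) / 2)   # uniform-grid trapezoid
    }, numeric(1)))
    m <- length(values)
    se <- stats::sd(values) / sqrt(m)
    mu <- mean(values)
    if (abs(mu) < .Machine$double.eps) {
      fallback <- TRUE
      rse <- se
    } else {
      rse <- se / abs(mu)
    }
    if ((m >= m_min && rse < rse_tol) || m >= m_max) break
  }
  structure(list(model_id = model_id, values = values, rse = rse,
                 rse_fallback = fallback),
            class = "risk_samples")
}

#' @export
print.risk_samples <- function(x, ...) {
  cat(sprintf("Risk samples '%s': M = %d, mean %.6g, sd %.3g, rse %.3g%s\n",
              x$model_id, length(x$values), mean(x$values),
              stats::sd(x$values), x$rse,
              if (isTRUE(x$rse_fallback)) " (absolute-SE fallback)" else ""))
  invisible(x)
}

#' Tail probability between two risk distributions
#'
#' `B^EMD = P(R_A < R_B)`, estimated as the fraction of ordered pairs
#' `(i, j)` with `R_A[i] < R_B[j]` over the two sample sets. Computed by
#' sorting one set and counting strict exceedances (identical in value to
#' the literal double sum, in `O((M_A + M_B) log)` time). Ties count for
#' neither direction, so with continuous risk samples
#' `b_emd(a, b) + b_emd(b, a) = 1` exactly; tied values reduce the sum by
#' the tie mass.
#'
#' @param a,b `risk_samples` objects (or bare numeric vectors of risks).
#' @return Scalar in \[0, 1\].
#' @export
b_emd <- function(a, b) {
  va <- if (inherits(a, "risk_samples")) a$values else as.numeric(a)
  vb <- if (inherits(b, "risk_samples")) b$values else as.numeric(b)
  if (length(va) == 0L || length(vb) == 0L) {
    stop("both risk sample sets must be nonempty")
  }
  sb <- sort(vb)
  # for each a_i, number of b_j strictly greater than a_i (ties excluded)
  gt <- length(sb) - findInterval(va, sb)
  sum(gt) / (length(va) * length(sb))
}

#' Pairwise comparison of candidate models on a shared test dataset
#'
#' End-to-end driver: for each model, evaluates losses on the observed data
#' and on its own synthetic samples, builds the mixed/synthetic PPF pair and
#' the discrepancy curve, parametrises the hierarchical beta process at the
#' given sensitivity `c`, samples a risk distribution, then fills the square
#' matrix of pairwise tail probabilities and applies the rejection rule.
#'
#' @param models List of [candidate_model()]s (each with loss and sampler).
#' @param observed Data frame with columns `x` and `y` (held-out test data).
#' @param c Sensitivity factor.
#' @param epsilon Rejection threshold in (0.5, 1\].
#' @param n_grid,l_synth PPF construction parameters.
#' @param n_refinements Process refinement depth.
#' @param rse_tol,m_min,m_max Risk-sampling parameters.
#' @return An `emd_comparison` object: list with `b_emd_matrix` (rows =
#'   model a, columns = model b), `empirical_risks`, `risk_samples`,
#'   `decision` and the parameters used.
#' @export
emd_compare <- function(models, observed, c = 2^-2, epsilon = 0.95,
                        n_grid = 1024L, l_synth = 4096L, n_refinements = 8L,
                        rse_tol = 2^-5, m_min = 32L, m_max = 4096L) {
  stopifnot(is.list(models), length(models) >= 2L,
            all(vapply(models, inherits, logical(1), "candidate_model")))
  ids <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("model ids must be unique")

  risks <- numeric(length(models))
  rsamples <- vector("list", length(models))
  names(rsamples) <- ids
  for (i in seq_along(models)) {
    ppfs <- mixed_and_synthetic_ppfs(models[[i]], observed,
                                     l_synth = l_synth, n_grid = n_grid)
    dd <- delta_emd(ppfs$mixed, ppfs$synthetic)
    spec <- hb_process_spec(ppfs$mixed, dd, c = c,
                            n_refinements = n_refinements)
    rsamples[[i]] <- sample_risk_distribution(
      spec, rse_tol = rse_tol, m_min = m_min, m_max = m_max,
      model_id = ids[i])
    risks[i] <- mean(pointwise_losses(observed, models[[i]])$values)
  }
  names(risks) <- ids

  B <- matrix(NA_real_, length(models), length(models),
              dimnames = list(ids, ids))
  for (i in seq_along(models)) {
    for (j in seq_along(models)) {
      B[i, j] <- if (i == j) 0.5 else b_emd(rsamples[[i]], rsamples[[j]])
    }
  }
  comparisons <- comparison_table(B, risks)
  structure(list(b_emd_matrix = B, empirical_risks = risks,
                 risk_samples = rsamples,
                 comparisons = comparisons,
                 decision = emd_reject(comparisons, epsilon = epsilon),
                 c = c, epsilon = epsilon),
            class = "emd_comparison")
}

# long-format ordered-pair table from a B matrix and empirical risks
comparison_table <- function(b_matrix, empirical_risks) {
  ids <- rownames(b_matrix)
  pairs <- expand.grid(model_a = ids, model_b = ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$model_a != pairs$model_b, , drop = FALSE]
  pairs$b_emd <- b_matrix[cbind(pairs$model_a, pairs$model_b)]
  pairs$empirical_risk_a <- empirical_risks[pairs$model_a]
  pairs$empirical_risk_b <- empirical_risks[pairs$model_b]
  rownames(pairs) <- NULL
  pairs
}

#' @export
print.emd_comparison <- function(x, ...) {
  cat(sprintf("EMD comparison of %d models (c = %g, epsilon = %g)\n",
              nrow(x$b_emd_matrix), x$c, x$epsilon))
  cat("B^EMD matrix (row model a vs column model b):\n")
  print(round(x$b_emd_matrix, 3))
  cat("Empirical risks:\n")
  print(signif(x$empirical_risks, 6))
  print(x$decision)
  invisible(x)
}

#' Ternary rejection rule over pairwise risk comparisons
#'
#' Rejects model `A` when some competitor `B` satisfies both
#' `P(R_B < R_A) > epsilon` (equivalently `b_emd(A, B) < 1 - epsilon`) and
#' `empirical_risk(A) > empirical_risk(B)`. The second condition keeps the
#' rule consistent when risk distributions are skewed. Each pair thus has a
#' genuinely ternary outcome: reject A, reject B, or no rejection; models no
#' competitor rejects are retained. Raising `epsilon` can only shrink the
#' rejected set.
#'
#' The box statement of the rule reads "reject A if `B^EMD_AB < epsilon`",
#' which taken literally rejects at any `B < epsilon`; that contradicts the
#' ternary structure above, so the threshold reading `B^EMD_AB < 1 - epsilon`
#' is the default. The literal reading is available via
#' `literal_threshold = TRUE` for comparison.
#'
#' @param comparisons Data frame of ordered pairs with columns `model_a`,
#'   `model_b`, `b_emd`, `empirical_risk_a`, `empirical_risk_b` (as built by
#'   [emd_compare()]), covering all ordered pairs of the candidate set.
#' @param epsilon Threshold in (0.5, 1\].
#' @param literal_threshold Use the literal `b_emd < epsilon` reading
#'   (not recommended; see above).
#' @return An `emd_decision`: list with `rejected` (character vector),
#'   `retained`, `epsilon` and the per-pair outcome table.
#' @export
emd_reject <- function(comparisons, epsilon, literal_threshold = FALSE) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0.5 || epsilon > 1) {
    stop("`epsilon` must lie in (0.5, 1]")
  }
  req <- c("model_a", "model_b", "b_emd",
           "empirical_risk_a", "empirical_risk_b")
  if (!all(req %in% names(comparisons))) {
    stop("`comparisons` must have columns ", paste(req, collapse = ", "))
  }
  thr <- if (literal_threshold) epsilon else 1 - epsilon
  hit <- comparisons$b_emd < thr &
    comparisons$empirical_risk_a > comparisons$empirical_risk_b
  models <- sort(unique(c(comparisons$model_a, comparisons$model_b)))
  rejected <- sort(unique(comparisons$model_a[hit]))
  outcome <- comparisons
  outcome$reject_a <- hit
  structure(list(rejected = rejected,
                 retained = setdiff(models, rejected),
                 epsilon = epsilon, outcomes = outcome),
            class = "emd_decision")
}

#' @export
print.emd_decision <- function(x, ...) {
  cat(sprintf("Rejection rule at epsilon = %g:\n", x$epsilon))
  cat("  rejected:", if (length(x$rejected)) paste(x$rejected, collapse = ", ")
      else "(none)", "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Dice-transitivity certificate for a chain of comparisons
#'
#' For thresholds above the inverse squared golden ratio
#' (`1/phi^2 ~ 0.382`), `B_AB > sqrt(epsilon)` and `B_BC > sqrt(epsilon)`
#' jointly certify `B_AC > epsilon` without computing it. Returns `TRUE`
#' when the certificate applies; `FALSE` makes no claim either way.
#'
#' @param b_ab,b_bc Tail probabilities in \[0, 1\].
#' @param epsilon Threshold; must exceed `1 / golden_ratio^2`.
#' @return Logical.
#' @export
transitivity_check <- function(b_ab, b_bc, epsilon) {
  phi_inv2 <- ((1 + sqrt(5)) / 2)^-2
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= phi_inv2) {
    stop(sprintf(
      "`epsilon` must exceed the inverse squared golden ratio (%.4f)",
      phi_inv2))
  }
  b_ab > sqrt(epsilon) & b_bc > sqrt(epsilon)
}
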