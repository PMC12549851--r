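#' Candidate model contract
#'
#' A candidate model is anything that can (a) evaluate a pointwise loss
#' `Q(x, y)` on records of a dataset and, optionally, (b) generate synthetic
#' `(x, y)` samples from its own distribution. These two capabilities are all
#' the risk-comparison machinery needs: models may be structurally different
#' or share equations and differ only in parameter values.
#'
#' @param id Character label identifying the model in tables and reports.
#' @param loss Function taking a data frame with columns `x` and `y` and
#'   returning one finite numeric loss per row (commonly the negative log
#'   likelihood, in nats). The loss must be defined (finite) for every record
#'   it will be evaluated on; a model assigning zero probability to an
#'   observation has no finite negative log likelihood there and cannot be
#'   scored.
#' @param sampler Optional function taking an integer `n` and returning a data
#'   frame with columns `x` and `y` holding `n` samples drawn from the model.
#'   Uses R's global random number generator. Required for the synthetic PPF.
#' @param fit Optional function taking a data frame with columns `x` and `y`
#'   and returning a new, fully specified `candidate_model`. Used by the
#'   calibration driver to fit per-replicate nuisance parameters (for the
#'   black-body candidates, the Gaussian noise scale).
#'
#' @return An object of class `candidate_model`.
#' @seealso [pointwise_losses()], [mixed_and_synthetic_ppfs()],
#'   [blackbody_candidate()]
#' @export
#' @examples
#' m <- candidate_model(
#'   id = "unit-gaussian",
#'   loss = function(d) 0.5 * log(2 * pi) + 0.5 * (d$y - d$x)^2,
#'   sampler = function(n) {
#'     x <- runif(n)
#'     data.frame(x = x, y = rnorm(n, mean = x))
#'   }
#' )
#' pointwise_losses(data.frame(x = 0:2, y = c(0, 2, 4)), m)
candidate_model <- function(id, loss, sampler = NULL, fit = NULL) {
  stopifnot(is.character(id), length(id) == 1L, is.function(loss))
  if (!is.null(sampler)) stopifnot(is.function(sampler))
  if (!is.null(fit)) stopifnot(is.function(fit))
  structure(list(id = id, loss = loss, sampler = sampler, fit = fit),
            class = "candidate_model")
}

#' @export
print.candidate_model <- function(x, ...) {
  cat("Candidate model:", x$id, "\n")
  cat("  capabilities:", paste(c(
    "loss",
    if (!is.null(x$sampler)) "sampler",
    if (!is.null(x$fit)) "fit"
  ), collapse = ", "), "\n")
  invisible(x)
}

has_sampler <- function(model) {
  inherits(model, "candidate_model") && !is.null(model$sampler)
}

#' Evaluate a model's pointwise loss on every record of a dataset
#'
#' Applies the candidate's loss capability to each `(x, y)` record, preserving
#' record order. The result is the raw material for empirical loss CDFs/PPFs
#' and for the empirical risk (their mean).
#'
#' @param dataset Data frame with numeric columns `x` and `y`, one record per
#'   row.
#' @param model A [candidate_model()].
#' @param dataset_id Optional label carried into the result.
#' @return A `loss_sample` object: a list with `values` (numeric losses, one
#'   per record), `model_id` and `dataset_id`.
#' @export
pointwise_losses <- function(dataset, model, dataset_id = "observed") {
  stopifnot(inherits(model, "candidate_model"))
  dataset <- as.data.frame(dataset)
  if (!all(c("x", "y") %in% names(dataset))) {
    stop("`dataset` must have columns `x` and `y`")
  }
  values <- as.numeric(model$loss(dataset))
  if (length(values) != nrow(dataset)) {
    stop("loss function returned ", length(values), " values for ",
         nrow(dataset), " records")
  }
  bad <- which(!is.finite(values))
  if (length(bad) > 0L) {
    stop("non-finite loss for record(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " of dataset '", dataset_id, "' under model '", model$id, "'; ",
         "the model must assign non-vanishing probability to every record")
  }
  loss_sample(values, model_id = model$id, dataset_id = dataset_id)
}

#' Construct a loss sample
#'
#' @param values Numeric vector of finite pointwise losses, length >= 2.
#' @param model_id,dataset_id Labels.
#' @return A `loss_sample` object.
#' @export
loss_sample <- function(values, model_id = "model", dataset_id = "data") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a loss sample needs at least 2 values")
  if (!all(is.finite(values))) stop("loss values must all be finite")
  structure(list(values = values, model_id = model_id,
                 dataset_id = dataset_id),
            class = "loss_sample")
}

#' @export
print.loss_sample <- function(x, ...) {
  cat(sprintf("Loss sample: %d losses of model '%s' on dataset '%s'\n",
              length(x$values), x$model_id, x$dataset_id))
  cat(sprintf("  mean (empirical risk) %.6g, range [%.6g, %.6g]\n",
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}
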