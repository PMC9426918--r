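#' Compare Cox model fits by AIC
#'
#' Tabulates AIC for a set of fits on the same panel and, relative to the
#' named baseline, the AIC improvement `delta_aic = AIC(baseline) -
#' AIC(model)` and the relative likelihood `exp(-delta_aic / 2)` -- the
#' probability that the baseline model is as good as the better-fitting
#' model (1 when the AICs tie, ~3.7e-6 when the model improves on the
#' baseline by 25 AIC units).
#'
#' @param fits Named list of `cox_fit` objects fit on the same panel.
#' @param baseline Name (in `fits`) of the reference model.
#' @return A data.frame of class `model_comparison` with one row per model:
#'   `model`, `n_parameters`, `log_partial_likelihood`, `aic`, `delta_aic`,
#'   `relative_likelihood`.
#' @export
compare_models <- function(fits, baseline = names(fits)[1L]) {
  if (length(fits) < 2L) stop("need at least two fits", call. = FALSE)
  if (is.null(names(fits)) || !baseline %in% names(fits))
    stop("fits must be named and include the baseline", call. = FALSE)
  fp <- vapply(fits, function(f) paste(f$n_rows, f$n_events), character(1))
  if (length(unique(fp)) != 1L)
    stop("fits were made on different panels: comparison invalid",
         call. = FALSE)
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  base_aic <- aic[[baseline]]
  out <- data.frame(
    model = names(fits),
    n_parameters = vapply(fits, function(f) f$n_parameters, integer(1)),
    log_partial_likelihood = vapply(fits,
                                    function(f) f$log_partial_likelihood,
                                    numeric(1)),
    aic = aic,
    delta_aic = base_aic - aic,
    relative_likelihood = exp(-(base_aic - aic) / 2),
    row.names = NULL
  )
  attr(out, "baseline") <- baseline
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' AIC gap and relative likelihood between two printed AIC values
#'
#' The same decision rule as [compare_models()], applicable to AIC values
#' taken from a published table rather than from in-session fits.
#'
#' @param aic_baseline,aic_model Two AIC values.
#' @return A list with `delta_aic = aic_baseline - aic_model` and
#'   `relative_likelihood = exp(-delta_aic / 2)`.
#' @export
#' @examples
#' aic_relative_likelihood(9269, 9244)  # gap 25, relative likelihood < 0.001
aic_relative_likelihood <- function(aic_baseline, aic_model) {
  delta <- aic_baseline - aic_model
  list(delta_aic = delta, relative_likelihood = exp(-delta / 2))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (baseline: %s)\n", attr(x, "baseline")))
  y <- x
  y$log_partial_likelihood <- round(y$log_partial_likelihood, 2)
  y$aic <- round(y$aic, 2)
  y$delta_aic <- round(y$delta_aic, 2)
  y$relative_likelihood <- signif(y$relative_likelihood, 3)
  print.data.frame(y)
  invisible(x)
}

#' Linear association between an outcome and a standardized score
#'
#' Ordinary least-squares slope of the binary event indicator on the
#' z-scored centrality: the change in predicted event probability per one
#' standard deviation of centrality.
#'
#' @param event Binary outcome vector.
#' @param z_centrality Numeric covariate (typically a z-score).
#' @return The OLS slope `b1`.
#' @export
linear_association <- function(event, z_centrality) {
  stopifnot(length(event) == length(z_centrality))
  if (stats::var(z_centrality) == 0)
    stop("constant centrality column: slope undefined", call. = FALSE)
  unname(stats::coef(stats::lm(event ~ z_centrality))[2L])
}

#' Correlation matrix of centrality measures and network covariates
#'
#' Pairwise correlations over the analytic sample, log-transforming each
#' column first by default (with the same positivity floor as the model
#' transform). Zero-variance columns yield `NA` rows/columns and a warning.
#'
#' @param columns A data.frame (or named list) of numeric columns.
#' @param log_transform Log-transform every column before correlating.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(columns, log_transform = TRUE,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- as.data.frame(columns)
  if (ncol(df) < 2L) stop("need at least two columns", call. = FALSE)
  if (log_transform)
    # log(x) up to a per-column additive constant, which no correlation sees
    df[] <- lapply(df, function(x) suppressMessages(
      log_component_normalize(x)))
  degenerate <- vapply(df, function(x) stats::sd(x) == 0, logical(1))
  if (any(degenerate))
    warning("zero-variance columns flagged NA: ",
            paste(names(df)[degenerate], collapse = ", "))
  m <- suppressWarnings(stats::cor(df, method = method))
  diag(m) <- 1
  m[degenerate, ] <- NA_real_
  m[, degenerate] <- NA_real_
  diag(m)[!degenerate] <- 1
  m
}
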