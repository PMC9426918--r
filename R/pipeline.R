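#' Configuration for an end-to-end ranking experiment
#'
#' @param sim A [sim_config()] block for the synthetic cohort.
#' @param window_quarters Rolling-window width in quarters (3 primary, 1
#'   robustness).
#' @param algorithms Subset of `"pagerank"`, `"hits"`, `"cohits"`, `"bgrm"`,
#'   `"birank"`.
#' @param variants Subset of `"unweighted"`, `"weighted"`. PageRank is
#'   computed on the projection of the unweighted network only; the
#'   MME-weighted variant applies to the bipartite indices.
#' @param transform Centrality transform for the panel.
#' @param quarters Analysis end quarters; `NULL` uses every quarter with a
#'   full window and an observable lagged outcome.
#' @param alpha,beta Damping factors passed to the ranking algorithms.
#' @param second_period Also run a replicate on a second simulated period
#'   (same configuration, shifted seed) as a robustness check.
#' @param mme_covariate Add each patient's in-window total MME as a direct
#'   covariate in companion sensitivity fits.
#' @param output_dir Directory for report files; `NULL` skips writing.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              window_quarters = 3L,
                              algorithms = c("pagerank", "hits", "cohits",
                                             "bgrm", "birank"),
                              variants = c("unweighted", "weighted"),
                              transform = "lognorm_z",
                              quarters = NULL,
                              alpha = 0.85, beta = 0.85,
                              second_period = TRUE,
                              mme_covariate = FALSE,
                              output_dir = NULL) {
  if (length(algorithms) == 0L || length(variants) == 0L)
    stop("select at least one algorithm and one variant", call. = FALSE)
  algorithms <- match.arg(tolower(algorithms),
                          c("pagerank", "hits", "cohits", "bgrm", "birank"),
                          several.ok = TRUE)
  variants <- match.arg(tolower(variants), c("unweighted", "weighted"),
                        several.ok = TRUE)
  if (!window_quarters %in% c(1L, 3L))
    stop("window_quarters must be 1 or 3", call. = FALSE)
  structure(list(sim = sim, window_quarters = as.integer(window_quarters),
                 algorithms = algorithms, variants = variants,
                 transform = transform, quarters = quarters,
                 alpha = alpha, beta = beta,
                 second_period = isTRUE(second_period),
                 mme_covariate = isTRUE(mme_covariate),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Patient centrality scores for one window network
#'
#' Computes every selected measure on a single window: the bipartite
#' indices on the bipartite matrix and PageRank on the patient projection.
#'
#' @param net Unweighted `bipartite_net` for the window.
#' @param net_weighted Optional MME-weighted `bipartite_net` on the same
#'   window (same sparsity pattern).
#' @param algorithms,variants,alpha,beta See [experiment_config()].
#' @return Named list of patient score vectors; weighted variants carry the
#'   suffix `_mme`.
#' @export
window_scores <- function(net, net_weighted = NULL,
                          algorithms = c("pagerank", "birank"),
                          variants = "unweighted",
                          alpha = 0.85, beta = 0.85) {
  out <- list()
  bip <- setdiff(algorithms, "pagerank")
  if ("unweighted" %in% variants) {
    if ("pagerank" %in% algorithms)
      out$pagerank <- as.numeric(pagerank_projection(project_patients(net),
                                                     alpha = alpha)) |>
        stats::setNames(net$patient_ids)
    for (alg in bip) {
      fit <- birank(net, alg,
                    alpha = if (alg == "hits") 1 else alpha,
                    beta = if (alg == "hits") 1 else beta)
      out[[alg]] <- fit$p
    }
  }
  if ("weighted" %in% variants) {
    if (is.null(net_weighted))
      stop("weighted variant requested but no weighted network supplied",
           call. = FALSE)
    for (alg in bip) {
      fit <- birank(net_weighted, alg,
                    alpha = if (alg == "hits") 1 else alpha,
                    beta = if (alg == "hits") 1 else beta)
      out[[paste0(alg, "_mme")]] <- fit$p
    }
  }
  out
}

#' Run the full simulate-rank-fit experiment
#'
#' Executes the whole analysis on one synthetic cohort: simulate claims,
#' build the rolling-window networks (unweighted and, if selected,
#' MME-weighted) for every analysis quarter, compute all selected
#' centralities, assemble the lagged patient-quarter panel, fit the
#' covariates-only baseline plus one Cox model per centrality measure
#' (never jointly -- the measures are highly collinear), and derive the AIC
#' comparison, the correlation matrix of measures, the per-measure linear
#' association slopes, and the weighted-versus-unweighted AIC table. With
#' `second_period = TRUE` the whole procedure repeats on a second simulated
#' period (shifted seed) as a robustness replicate.
#'
#' @param config An [experiment_config()].
#' @return An object of class `claims_experiment`: a list with the
#'   simulated cohort, the panel, the named `fits`, `comparison`,
#'   `correlations`, `slopes`, `weight_comparison`, the optional
#'   `replicate`, and the `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage [%s] failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  sim <- stage("simulate", simulate_claims(config$sim))
  w <- config$window_quarters
  nq <- config$sim$n_quarters
  quarters <- config$quarters
  if (is.null(quarters)) quarters <- seq(w - 1L, nq - 2L)
  if (length(quarters) == 0L)
    stop("stage [netbuild] failed: no analysis quarters available",
         call. = FALSE)

  networks <- list(); networks_w <- list(); scores <- list()
  for (q in quarters) {
    qc <- as.character(q)
    networks[[qc]] <- stage("netbuild",
      build_window_network(sim$prescriptions, q, w, weighted = FALSE))
    nw <- NULL
    if ("weighted" %in% config$variants)
      nw <- stage("netbuild",
        build_window_network(sim$prescriptions, q, w, weighted = TRUE))
    networks_w[[qc]] <- nw
    scores[[qc]] <- stage("rank",
      window_scores(networks[[qc]], nw, config$algorithms, config$variants,
                    config$alpha, config$beta))
  }

  panel <- stage("panel",
    build_panel(sim$patients, networks, scores, config$transform))
  if (isTRUE(config$mme_covariate))
    panel$window_mme_z <- pooled_z(log1p(window_mme_column(panel, networks_w)))

  measures <- attr(panel, "measures")
  fits <- list(baseline = stage("fit",
    fit_cox(panel, baseline_covariates(), label = "baseline")))
  for (ms in measures)
    fits[[ms]] <- stage("fit",
      fit_cox(panel, c(ms, baseline_covariates()), label = ms))
  if (isTRUE(config$mme_covariate))
    for (ms in measures)
      fits[[paste0(ms, "+mme")]] <- stage("fit",
        fit_cox(panel, c(ms, "window_mme_z", baseline_covariates()),
                label = paste0(ms, "+mme")))

  comparison <- stage("compare", compare_models(fits, "baseline"))

  corr_cols <- panel[, paste0(measures, "_raw"), drop = FALSE]
  names(corr_cols) <- measures
  corr_cols$degree <- panel$degree
  corr_cols$transitive_ties <- panel$transitive_ties + 1  # log-safe
  correlations <- stage("compare",
    correlation_matrix(corr_cols, log_transform = TRUE))

  slopes <- vapply(measures, function(ms)
    stage("compare", linear_association(panel$event, panel[[ms]])),
    numeric(1))

  weight_comparison <- NULL
  if (all(c("unweighted", "weighted") %in% config$variants)) {
    bip <- setdiff(config$algorithms, "pagerank")
    weight_comparison <- data.frame(
      algorithm = bip,
      aic_unweighted = vapply(bip, function(a) fits[[a]]$aic, numeric(1)),
      aic_weighted = vapply(bip, function(a) fits[[paste0(a, "_mme")]]$aic,
                            numeric(1)),
      row.names = NULL
    )
    weight_comparison$weighted_improvement <-
      weight_comparison$aic_unweighted - weight_comparison$aic_weighted
  }

  replicate <- NULL
  if (isTRUE(config$second_period)) {
    cfg2 <- config
    cfg2$second_period <- FALSE
    cfg2$output_dir <- NULL
    cfg2$sim$seed <- config$sim$seed + 1000L
    replicate <- stage("replicate", run_experiment(cfg2))
  }

  out <- structure(list(sim = sim, panel = panel, fits = fits,
                        comparison = comparison,
                        correlations = correlations, slopes = slopes,
                        weight_comparison = weight_comparison,
                        replicate = replicate, config = config),
                   class = "claims_experiment")
  if (!is.null(config$output_dir))
    stage("report", write_experiment(out, config$output_dir))
  out
}

# total in-window MME per patient-quarter row, from the weighted networks
window_mme_column <- function(panel, networks_w) {
  v <- numeric(nrow(panel))
  for (qc in names(networks_w)) {
    nw <- networks_w[[qc]]
    if (is.null(nw)) stop("MME covariate needs the weighted variant",
                          call. = FALSE)
    rows <- panel$quarter == as.integer(qc)
    v[rows] <- Matrix::colSums(nw$W)[match(panel$patient_id[rows],
                                           nw$patient_ids)]
  }
  v
}

#' Write the report bundle of an experiment
#'
#' Emits the comparison table, correlation matrix, slopes and weighted-AIC
#' table as TSV, the per-model fit report as JSON, and a run manifest
#' (seed, configuration hash, package version).
#'
#' @param experiment A `claims_experiment`.
#' @param dir Output directory (created if missing).
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "claims_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tsv(experiment$comparison, "model_comparison.tsv")
  corr <- as.data.frame(experiment$correlations)
  corr <- cbind(measure = rownames(experiment$correlations), corr)
  tsv(corr, "correlation_matrix.tsv")
  tsv(data.frame(measure = names(experiment$slopes),
                 slope = unname(experiment$slopes)), "slopes.tsv")
  if (!is.null(experiment$weight_comparison))
    tsv(experiment$weight_comparison, "weighted_aic.tsv")
  write_fit_report(experiment$fits, file.path(dir, "fits.json"))
  if (!is.null(experiment$replicate)) {
    tsv(experiment$replicate$comparison, "model_comparison_period2.tsv")
    if (!is.null(experiment$replicate$weight_comparison))
      tsv(experiment$replicate$weight_comparison, "weighted_aic_period2.tsv")
  }
  cfg_file <- file.path(dir, "config.txt")
  writeLines(utils::capture.output(utils::str(experiment$config)), cfg_file)
  manifest <- list(
    seed = experiment$config$sim$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("claimsrank")),
    n_patient_quarters = nrow(experiment$panel),
    n_events = sum(experiment$panel$event)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.claims_experiment <- function(x, ...) {
  cat("Claims ranking experiment\n")
  print(x$sim)
  cat(sprintf("  panel: %d patient-quarters, %d events\n",
              nrow(x$panel), sum(x$panel$event)))
  print(x$comparison)
  if (!is.null(x$weight_comparison)) {
    cat("MME-weighted vs unweighted AIC:\n")
    print(x$weight_comparison)
  }
  invisible(x)
}
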