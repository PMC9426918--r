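#' Assemble the patient-quarter analytic panel
#'
#' Builds the counting-process table the Cox models are fit on. Each row is
#' one patient-quarter: the covariates come from the rolling-window network
#' ending at quarter `q` and the outcome is the (one-quarter-lagged) event
#' indicator for quarter `q + 1`, giving the at-risk interval `(q, q + 1]`.
#' Rows exist only for patients present in the window network who are still
#' enrolled during the outcome quarter; censored patients contribute rows
#' only while present, and an event row terminates follow-up.
#'
#' Centrality covariates are normalized by their within-component mean and
#' log-transformed quarter by quarter, then z-scored over the pooled panel
#' (the `"lognorm_z"` transform); `"raw"` and `"dichotomize_99"` are the
#' robustness variants. Age, degree and transitive ties are standardized
#' (degree and transitive ties on the log1p scale, being right-skewed);
#' binary flags are left as 0/1.
#'
#' @param patients Patient table with demographics, comorbidity flags,
#'   enrollment span and `overdose_quarter` (see [simulate_outcomes()]).
#' @param networks Named list of `bipartite_net` objects keyed by their end
#'   quarter (as character).
#' @param scores Named list parallel to `networks`: for each quarter, a
#'   named list of centrality score vectors (names = patient ids), one per
#'   measure to include.
#' @param transform Centrality transform; see [transform_centrality()].
#' @return A data.frame of class `patient_quarter_table` with columns
#'   `patient_id`, `quarter` (network end quarter), `start`, `stop`,
#'   `event`, standardized covariates, and one transformed column per
#'   measure (raw scores kept as `<measure>_raw`).
#' @export
build_panel <- function(patients, networks, scores,
                        transform = c("lognorm_z", "raw", "dichotomize_99")) {
  transform <- match.arg(transform)
  if (!setequal(names(networks), names(scores)) ||
      is.null(names(networks)) || anyDuplicated(names(networks)) > 0)
    stop("quarter misalignment: networks and scores must be keyed by the same quarters",
         call. = FALSE)
  quarters <- sort(as.integer(names(networks)))
  measures <- unique(unlist(lapply(scores, names)))

  blocks <- lapply(quarters, function(q) {
    qc <- as.character(q)
    net <- networks[[qc]]
    sc <- scores[[qc]]
    if (!setequal(names(sc), measures))
      stop("quarter misalignment: measures differ across quarters",
           call. = FALSE)
    cov <- patient_covariates(net)
    idx <- match(cov$patient_id, patients$patient_id)
    if (anyNA(idx))
      stop("network contains patients absent from the patient table",
           call. = FALSE)
    od <- patients$overdose_quarter[idx]
    at_risk <- patients$entry_quarter[idx] <= q + 1L &
      patients$exit_quarter[idx] >= q + 1L &
      (is.na(od) | od >= q + 1L)
    keep <- which(at_risk)
    if (length(keep) == 0L) return(NULL)
    block <- data.frame(
      patient_id = cov$patient_id[keep],
      quarter = q,
      start = q,
      stop = q + 1L,
      event = as.integer(!is.na(od[keep]) & od[keep] == q + 1L),
      age = patients$age[idx[keep]],
      female = patients$female[idx[keep]],
      degree = cov$degree[keep],
      transitive_ties = cov$transitive_ties[keep],
      stringsAsFactors = FALSE
    )
    for (nm in comorbidity_names())
      block[[nm]] <- patients[[nm]][idx[keep]]
    if ("seeker" %in% names(patients))
      block$seeker <- patients$seeker[idx[keep]]
    for (ms in measures) {
      v <- sc[[ms]][block$patient_id]
      if (anyNA(v))
        stop(sprintf("missing %s scores for some in-network patients", ms),
             call. = FALSE)
      block[[paste0(ms, "_raw")]] <- unname(v)
      if (transform == "lognorm_z") {
        comp <- net$patient_component[match(block$patient_id,
                                            net$patient_ids)]
        block[[paste0(ms, "_lognorm")]] <-
          log_component_normalize(unname(v), comp)
      }
    }
    block
  })
  panel <- do.call(rbind, blocks)
  if (is.null(panel) || nrow(panel) == 0L)
    stop("empty panel: no at-risk patient-quarters", call. = FALSE)
  rownames(panel) <- NULL

  # pooled transforms over the whole analytic sample
  for (ms in measures) {
    panel[[ms]] <- switch(transform,
      lognorm_z = pooled_z(panel[[paste0(ms, "_lognorm")]]),
      raw = panel[[paste0(ms, "_raw")]],
      dichotomize_99 = {
        cut <- stats::quantile(panel[[paste0(ms, "_raw")]], 0.99,
                               names = FALSE)
        as.integer(panel[[paste0(ms, "_raw")]] > cut)
      })
    panel[[paste0(ms, "_lognorm")]] <- NULL
  }
  panel$age_z <- pooled_z(panel$age)
  panel$degree_z <- pooled_z(log1p(panel$degree))
  panel$transitive_ties_z <- pooled_z(log1p(panel$transitive_ties))
  attr(panel, "measures") <- measures
  attr(panel, "transform") <- transform
  class(panel) <- c("patient_quarter_table", "data.frame")
  panel
}

#' Baseline covariate set for the overdose models
#'
#' The control variables shared by every model specification: standardized
#' age, sex, standardized degree and transitive ties, and the six
#' comorbidity flags.
#'
#' @return Character vector of column names in the panel.
#' @export
baseline_covariates <- function() {
  c("age_z", "female", "degree_z", "transitive_ties_z", comorbidity_names())
}
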