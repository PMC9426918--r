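#' Build a rolling-window bipartite patient-provider network
#'
#' Constructs the provider-by-patient adjacency matrix `W` from prescription
#' records falling in the window of `window_quarters` consecutive quarters
#' ending at `end_quarter` (inclusive on both ends). A tie exists when a
#' patient received at least one prescription from a provider during the
#' window. In unweighted mode repeated ties collapse to 1; in weighted mode
#' the edge carries the total MME a provider prescribed to that patient over
#' the window. Patients and providers with no in-window ties are excluded,
#' so `W` has no all-zero rows or columns.
#'
#' Rows of `W` index providers and columns index patients; the generalized
#' degree of a provider is its row sum and of a patient its column sum.
#'
#' @param records Prescription records: a data frame with `patient_id`,
#'   `provider_id`, `quarter` and (for weighted networks) `mme`.
#' @param end_quarter Last quarter of the window (0-based index).
#' @param window_quarters Number of quarters in the window; 3 is the primary
#'   analysis window, 1 the single-quarter robustness variant.
#' @param weighted If `TRUE`, edges carry summed MME; otherwise binary ties.
#' @return An object of class `bipartite_net`: a list with the sparse matrix
#'   `W`, `provider_ids`, `patient_ids`, per-node component labels, the
#'   `window` as `c(start, end)`, and the `weighted` flag.
#' @export
#' @examples
#' rx <- data.frame(patient_id = c("P1", "P1", "P2"),
#'                  provider_id = c("D1", "D1", "D1"),
#'                  quarter = c(1L, 2L, 2L), mme = c(30, 45, 10))
#' net <- build_window_network(rx, end_quarter = 2, window_quarters = 3)
#' net$W
build_window_network <- function(records, end_quarter,
                                 window_quarters = 3L, weighted = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("patient_id", "provider_id", "quarter")
  if (weighted) need <- c(need, "mme")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0)
    stop("records lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (window_quarters < 1L)
    stop("window_quarters must be at least 1", call. = FALSE)
  start_quarter <- end_quarter - window_quarters + 1L
  inwin <- records$quarter >= start_quarter & records$quarter <= end_quarter
  rec <- records[inwin, , drop = FALSE]

  if (nrow(rec) == 0L) {
    message(sprintf("empty window [%d, %d]: returning empty network",
                    start_quarter, end_quarter))
    W <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(0L, 0L))
    return(new_bipartite_net(W, character(), character(),
                             c(start_quarter, end_quarter), weighted))
  }

  provider_ids <- sort(unique(rec$provider_id))
  patient_ids <- sort(unique(rec$patient_id))
  i <- match(rec$provider_id, provider_ids)
  j <- match(rec$patient_id, patient_ids)
  if (weighted) {
    if (any(is.na(rec$mme) | rec$mme <= 0))
      stop("weighted network requires strictly positive mme on every record",
           call. = FALSE)
    W <- Matrix::sparseMatrix(i = i, j = j, x = rec$mme,
                              dims = c(length(provider_ids),
                                       length(patient_ids)))
  } else {
    W <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(provider_ids),
                                       length(patient_ids)))
    W@x[] <- 1  # repeated ties are not valued in the unweighted network
  }
  new_bipartite_net(W, provider_ids, patient_ids,
                    c(start_quarter, end_quarter), weighted)
}

new_bipartite_net <- function(W, provider_ids, patient_ids, window, weighted) {
  dimnames(W) <- list(provider_ids, patient_ids)
  comp <- bipartite_component_labels(W)
  structure(list(W = W,
                 provider_ids = provider_ids,
                 patient_ids = patient_ids,
                 provider_component = comp$provider,
                 patient_component = comp$patient,
                 window = as.integer(window),
                 weighted = isTRUE(weighted)),
            class = "bipartite_net")
}

# component labels over the bipartite graph, via igraph
bipartite_component_labels <- function(W) {
  nd <- nrow(W); np <- ncol(W)
  if (nd == 0L || np == 0L)
    return(list(provider = integer(0), patient = integer(0)))
  idx <- Matrix::which(W != 0, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(
    cbind(idx[, 1L], nd + idx[, 2L]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nd + np - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  list(provider = as.integer(memb[seq_len(nd)]),
       patient = as.integer(memb[nd + seq_len(np)]))
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat(sprintf("Bipartite patient-provider network (%s), window quarters [%d, %d]\n",
              if (x$weighted) "MME-weighted" else "unweighted",
              x$window[1L], x$window[2L]))
  cat(sprintf("  %d providers x %d patients, %d edges, %d components\n",
              nrow(x$W), ncol(x$W), Matrix::nnzero(x$W),
              length(unique(c(x$provider_component, x$patient_component)))))
  invisible(x)
}

#' @export
summary.bipartite_net <- function(object, ...) {
  comps <- network_components(object)
  out <- list(
    n_providers = nrow(object$W), n_patients = ncol(object$W),
    n_edges = Matrix::nnzero(object$W),
    n_components = nrow(comps$sizes),
    largest_component_patient_coverage = comps$coverage,
    degree_assortativity = suppressWarnings(degree_assortativity(object))
  )
  class(out) <- "summary.bipartite_net"
  out
}

#' @export
print.summary.bipartite_net <- function(x, ...) {
  cat(sprintf("providers %d, patients %d, edges %d, components %d\n",
              x$n_providers, x$n_patients, x$n_edges, x$n_components))
  cat(sprintf("largest component holds %.1f%% of prescribed patients\n",
              100 * x$largest_component_patient_coverage))
  cat(sprintf("patient-provider degree assortativity r = %.4f\n",
              x$degree_assortativity))
  invisible(x)
}

#' One-mode patient projection of a bipartite network
#'
#' Projects the bipartite network onto the patient mode: two patients are
#' tied when they share at least one provider in-window, and the edge weight
#' counts the number of distinct shared providers (repeated transitive ties
#' are valued). The diagonal is zero. Projection always uses binary ties,
#' regardless of whether the bipartite network carries MME weights.
#'
#' @param net A `bipartite_net`.
#' @return An object of class `patient_projection` with the sparse symmetric
#'   matrix `A` and `patient_ids`.
#' @export
project_patients <- function(net) {
  stopifnot(inherits(net, "bipartite_net"))
  B <- binarize(net$W)
  A <- Matrix::t(B) %*% B
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  structure(list(A = A, patient_ids = net$patient_ids),
            class = "patient_projection")
}

binarize <- function(W) {
  B <- W
  B@x[] <- 1
  B
}

#' @export
print.patient_projection <- function(x, ...) {
  cat(sprintf("Patient one-mode projection: %d patients, %d ties (shared-provider weights)\n",
              nrow(x$A), Matrix::nnzero(x$A) / 2))
  invisible(x)
}

#' Patient-level network covariates
#'
#' Computes, for every patient in the network, the degree (number of unique
#' providers) and the transitive-tie count (number of distinct other patients
#' reachable through a shared provider). A multiplicity variant that counts
#' each shared provider separately is returned alongside; the distinct-alter
#' count is the default model covariate.
#'
#' @param net A `bipartite_net`.
#' @return A data frame with `patient_id`, `degree`, `transitive_ties`,
#'   `transitive_ties_multiplicity`.
#' @export
patient_covariates <- function(net) {
  stopifnot(inherits(net, "bipartite_net"))
  B <- binarize(net$W)
  proj <- project_patients(net)
  data.frame(
    patient_id = net$patient_ids,
    degree = Matrix::colSums(B),
    transitive_ties = Matrix::rowSums(proj$A != 0),
    transitive_ties_multiplicity = Matrix::rowSums(proj$A),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Bipartite degree assortativity
#'
#' Pearson correlation, over edges of the bipartite network, between the
#' (unweighted) degree of the patient endpoint and the degree of the provider
#' endpoint. Negative values mean high-degree patients tend to attach to
#' low-degree providers.
#'
#' @param net A `bipartite_net`.
#' @return Correlation in `[-1, 1]`, or `NA` with a warning when either
#'   endpoint degree is constant across edges.
#' @export
degree_assortativity <- function(net) {
  stopifnot(inherits(net, "bipartite_net"))
  B <- binarize(net$W)
  idx <- Matrix::which(B != 0, arr.ind = TRUE)
  if (nrow(idx) < 2L) {
    warning("fewer than two edges: assortativity undefined")
    return(NA_real_)
  }
  ddeg <- Matrix::rowSums(B)[idx[, 1L]]
  pdeg <- Matrix::colSums(B)[idx[, 2L]]
  if (stats::sd(ddeg) == 0 || stats::sd(pdeg) == 0) {
    warning("constant endpoint degrees: assortativity undefined")
    return(NA_real_)
  }
  stats::cor(pdeg, ddeg)
}

#' Connected components of the bipartite network
#'
#' @param net A `bipartite_net`.
#' @return A list with `sizes` (one row per component: counts of providers,
#'   patients and nodes), per-mode label vectors, and `coverage`, the
#'   fraction of in-network patients belonging to the largest component
#'   (largest by patient count).
#' @export
network_components <- function(net) {
  stopifnot(inherits(net, "bipartite_net"))
  pc <- net$provider_component
  qc <- net$patient_component
  ids <- sort(unique(c(pc, qc)))
  sizes <- data.frame(
    component = ids,
    n_providers = as.integer(table(factor(pc, levels = ids))),
    n_patients = as.integer(table(factor(qc, levels = ids)))
  )
  sizes$n_nodes <- sizes$n_providers + sizes$n_patients
  sizes <- sizes[order(-sizes$n_patients, -sizes$n_nodes), ]
  rownames(sizes) <- NULL
  coverage <- if (length(qc) > 0) max(table(qc)) / length(qc) else NA_real_
  list(sizes = sizes, provider_component = pc, patient_component = qc,
       coverage = as.numeric(coverage))
}
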