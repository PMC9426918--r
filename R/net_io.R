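#' Edge-list input and output for bipartite networks
#'
#' `write_edge_list()` writes a tab-delimited file with header
#' `provider_id`, `patient_id`, `weight`. `read_edge_list()` reads it back;
#' duplicate (provider, patient) rows are summed with a warning, matching
#' the build-time collapse rule. `write_component_report()` writes one row
#' per node (`node_id`, `mode`, `component_id`).
#'
#' @param net A `bipartite_net`.
#' @param path File path.
#' @param weighted Flag stored on the network read back from disk.
#' @return `read_edge_list()` returns a `bipartite_net`; writers return the
#'   path invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "bipartite_net"))
  idx <- Matrix::which(net$W != 0, arr.ind = TRUE)
  df <- data.frame(
    provider_id = net$provider_ids[idx[, 1L]],
    patient_id = net$patient_ids[idx[, 2L]],
    weight = net$W[idx],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$provider_id, df$patient_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, weighted = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("provider_id", "patient_id", "weight")
  if (!identical(names(df), need))
    stop("edge list must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) {
    W <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(0L, 0L))
    return(new_bipartite_net(W, character(), character(), c(0L, 0L),
                             weighted))
  }
  if (any(df$weight < 0))
    stop("edge weights must be nonnegative", call. = FALSE)
  if (anyDuplicated(df[, c("provider_id", "patient_id")]) > 0)
    warning("duplicate (provider, patient) rows summed")
  provider_ids <- sort(unique(df$provider_id))
  patient_ids <- sort(unique(df$patient_id))
  W <- Matrix::sparseMatrix(i = match(df$provider_id, provider_ids),
                            j = match(df$patient_id, patient_ids),
                            x = df$weight,
                            dims = c(length(provider_ids),
                                     length(patient_ids)))
  new_bipartite_net(W, provider_ids, patient_ids, c(0L, 0L), weighted)
}

#' @rdname write_edge_list
#' @export
write_component_report <- function(net, path) {
  stopifnot(inherits(net, "bipartite_net"))
  df <- data.frame(
    node_id = c(net$provider_ids, net$patient_ids),
    mode = rep(c("provider", "patient"),
               c(length(net$provider_ids), length(net$patient_ids))),
    component_id = c(net$provider_component, net$patient_component),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Matrix-exchange export of the adjacency matrix
#'
#' Writes `W` in MatrixMarket format plus a sidecar TSV mapping row and
#' column indices back to provider and patient identifiers.
#'
#' @param net A `bipartite_net`.
#' @param path Path of the `.mtx` file; the sidecar is `<path>.index.tsv`.
#' @export
write_network_mtx <- function(net, path) {
  stopifnot(inherits(net, "bipartite_net"))
  Matrix::writeMM(net$W, path)
  idx <- data.frame(
    index = c(seq_along(net$provider_ids), seq_along(net$patient_ids)),
    mode = rep(c("row_provider", "col_patient"),
               c(length(net$provider_ids), length(net$patient_ids))),
    node_id = c(net$provider_ids, net$patient_ids),
    stringsAsFactors = FALSE
  )
  utils::write.table(idx, paste0(path, ".index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
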