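#' Write and read synthetic claims tables
#'
#' The on-disk layout is two tab-delimited files with header rows:
#' `claims.tsv` (one prescription per row: `patient_id`, `provider_id`,
#' `quarter`, `mme`) and `patients.tsv` (one patient per row with binary
#' flags coded 0/1 and a possibly empty `overdose_quarter`). The round trip
#' is lossless for all fields.
#'
#' @param prescriptions Prescription records (see [simulate_prescriptions()]).
#' @param patients Patient panel table (see [simulate_outcomes()]).
#' @param path Directory to write into; created if missing.
#' @return `write_claims()` returns the directory invisibly; `read_claims()`
#'   returns a list with `prescriptions` and `patients`.
#' @export
write_claims <- function(prescriptions, patients, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  utils::write.table(prescriptions, file.path(path, "claims.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(patients, file.path(path, "patients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_claims
#' @export
read_claims <- function(path) {
  claims_file <- file.path(path, "claims.tsv")
  patients_file <- file.path(path, "patients.tsv")
  for (f in c(claims_file, patients_file))
    if (!file.exists(f)) stop("missing claims file: ", f, call. = FALSE)

  rx <- utils::read.table(claims_file, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "numeric"),
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "provider_id", "quarter", "mme")
  if (!identical(names(rx), need))
    stop("claims.tsv must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(rx$mme) | rx$mme <= 0)
  if (length(bad) > 0)
    stop(sprintf("claims.tsv line %d: mme must be a positive number",
                 bad[1L] + 1L), call. = FALSE)  # +1 for the header row
  bad <- which(is.na(rx$quarter) | rx$quarter < 0)
  if (length(bad) > 0)
    stop(sprintf("claims.tsv line %d: quarter must be a nonnegative integer",
                 bad[1L] + 1L), call. = FALSE)

  pats <- utils::read.table(patients_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(pats))
    stop("patients.tsv must carry a patient_id column", call. = FALSE)
  if (all(c("entry_quarter", "exit_quarter") %in% names(pats))) {
    bad <- which(pats$entry_quarter > pats$exit_quarter)
    if (length(bad) > 0)
      stop(sprintf("patients.tsv line %d: entry_quarter exceeds exit_quarter",
                   bad[1L] + 1L), call. = FALSE)
  }
  list(prescriptions = rx, patients = pats)
}
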