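#' PageRank on the one-mode patient projection
#'
#' The unipartite baseline: damped PageRank on the shared-provider patient
#' projection. The transition matrix divides each column of the symmetric
#' weight matrix `A` by the generalized out-degree of that patient, and the
#' iteration is `R <- alpha * S R + (1 - alpha) * R0` with a uniform prior
#' `R0 = 1/N`. Isolated patients (zero projection degree) pass no walk mass
#' and end up with exactly the teleportation share `(1 - alpha) / N`; on a
#' projection without isolated nodes the scores sum to 1.
#'
#' @param A A `patient_projection`, or a symmetric nonnegative matrix of
#'   projection weights.
#' @param alpha Damping factor (default 0.85).
#' @param tol L1 convergence threshold on successive iterates.
#' @param max_iter Iteration cap.
#' @return A named numeric vector of patient PageRank scores, with
#'   attributes `iterations` and `converged`.
#' @export
#' @examples
#' A <- rbind(c(0, 1), c(1, 0))
#' pagerank_projection(A)  # symmetric dyad: equal scores
pagerank_projection <- function(A, alpha = 0.85, tol = 1e-10,
                                max_iter = 1000L) {
  ids <- NULL
  if (inherits(A, "patient_projection")) {
    ids <- A$patient_ids
    A <- A$A
  }
  A <- methods::as(methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                           "dMatrix"),
                               "generalMatrix"), "CsparseMatrix")
  n <- ncol(A)
  if (n == 0L) {
    out <- numeric(0)
    attr(out, "iterations") <- 0L
    attr(out, "converged") <- TRUE
    return(out)
  }
  if (any(A@x < 0)) stop("projection weights must be nonnegative",
                         call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  kout <- Matrix::colSums(A)
  inv <- ifelse(kout > 0, 1 / kout, 0)
  S <- A %*% Matrix::Diagonal(x = inv)
  r0 <- rep(1 / n, n)
  r <- r0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r_new <- as.numeric(alpha * (S %*% r) + (1 - alpha) * r0)
    delta <- sum(abs(r_new - r))
    r <- r_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("PageRank did not converge in %d iterations", max_iter))
  if (!is.null(ids)) names(r) <- ids else names(r) <- colnames(A)
  attr(r, "iterations") <- iter
  attr(r, "converged") <- converged
  r
}
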