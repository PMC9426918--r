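#' Mode-transition matrices for the bipartite centrality family
#'
#' HITS, CoHITS, BGRM and BiRank share a single iterative scheme and differ
#' only in how the provider-by-patient adjacency matrix `W` is normalized
#' into the pair of transition matrices that carry scores between modes.
#' With `K_d = diag(rowSums(W))` (provider generalized degrees) and
#' `K_p = diag(colSums(W))` (patient generalized degrees):
#'
#' \describe{
#'   \item{HITS}{`S_p = W'`, `S_d = W` (no normalization).}
#'   \item{CoHITS}{`S_p = W' K_d^-1`, `S_d = W K_p^-1` (source out-degree;
#'     a random walk on the bipartite graph).}
#'   \item{BGRM}{`S_p = K_p^-1 W' K_d^-1`, `S_d = K_d^-1 W K_p^-1`
#'     (symmetric, both endpoints in full).}
#'   \item{BiRank}{`S_p = K_p^-1/2 W' K_d^-1/2`,
#'     `S_d = K_d^-1/2 W K_p^-1/2` (symmetric square-root).}
#' }
#'
#' A zero generalized degree inverts to 0, so degenerate nodes simply pass
#' no walk mass (they receive teleportation mass only).
#'
#' @param W Nonnegative provider-by-patient matrix (dense or `Matrix`
#'   sparse), or a `bipartite_net`.
#' @param algorithm One of `"hits"`, `"cohits"`, `"bgrm"`, `"birank"`
#'   (case-insensitive).
#' @return A list with `S_p` (patients-by-providers), `S_d`
#'   (providers-by-patients) and the generalized-degree vectors `k_d`, `k_p`.
#' @export
#' @examples
#' W <- rbind(c(1, 2), c(0, 1))  # 2 providers x 2 patients
#' build_transitions(W, "cohits")$S_d  # columns scaled by patient degree
build_transitions <- function(W, algorithm = c("hits", "cohits", "bgrm",
                                               "birank")) {
  algorithm <- match.arg(tolower(algorithm[1L]),
                         c("hits", "cohits", "bgrm", "birank"))
  W <- as_weight_matrix(W)
  if (any(W@x < 0)) stop("W must be nonnegative", call. = FALSE)
  k_d <- Matrix::rowSums(W)
  k_p <- Matrix::colSums(W)
  inv <- function(x) ifelse(x > 0, 1 / x, 0)
  Wt <- Matrix::t(W)
  switch(algorithm,
    hits = list(S_p = Wt, S_d = W, k_d = k_d, k_p = k_p),
    cohits = list(
      S_p = Wt %*% Matrix::Diagonal(x = inv(k_d)),
      S_d = W %*% Matrix::Diagonal(x = inv(k_p)),
      k_d = k_d, k_p = k_p),
    bgrm = list(
      S_p = Matrix::Diagonal(x = inv(k_p)) %*% Wt %*%
        Matrix::Diagonal(x = inv(k_d)),
      S_d = Matrix::Diagonal(x = inv(k_d)) %*% W %*%
        Matrix::Diagonal(x = inv(k_p)),
      k_d = k_d, k_p = k_p),
    birank = {
      Dd <- Matrix::Diagonal(x = sqrt(inv(k_d)))
      Dp <- Matrix::Diagonal(x = sqrt(inv(k_p)))
      list(S_p = Dp %*% Wt %*% Dd, S_d = Dd %*% W %*% Dp,
           k_d = k_d, k_p = k_p)
    })
}

as_weight_matrix <- function(W) {
  if (inherits(W, "bipartite_net")) W <- W$W
  W <- methods::as(methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                                           "dMatrix"),
                               "generalMatrix"), "CsparseMatrix")
  W
}

#' Fit bipartite centrality scores
#'
#' Estimates patient and provider centrality on a bipartite patient-provider
#' network by the damped two-mode fixed-point iteration
#' `p <- alpha * S_p d + (1 - alpha) * p0` and
#' `d <- beta * S_d p + (1 - beta) * d0`, where the transition pair `S_p`,
#' `S_d` is the algorithm-specific normalization of `W` (see
#' [build_transitions()]) and `p0`, `d0` are prior (teleportation) vectors,
#' uniform by default.
#'
#' HITS is the undamped member of the family: its default is
#' `alpha = beta = 1` and, to keep the iteration bounded, both score vectors
#' are renormalized to unit sum after every iteration. Damping remains
#' configurable for HITS but is non-default. The other three algorithms
#' default to the customary damping of 0.85 on both modes.
#'
#' Convergence is declared when the L1 change of the patient vector between
#' successive iterations falls below `tol`.
#'
#' @param W Nonnegative provider-by-patient matrix or `bipartite_net`.
#' @param algorithm `"hits"`, `"cohits"`, `"bgrm"` or `"birank"`.
#' @param alpha,beta Damping factors in `[0, 1]` for the patient and
#'   provider modes.
#' @param p0,d0 Nonnegative prior vectors (defaults: uniform, summing to 1).
#' @param tol Convergence threshold on the successive-iterate L1 change.
#' @param max_iter Iteration cap.
#' @return An object of class `birank`: patient scores `p`, provider scores
#'   `d` (both named), `iterations`, `converged`, final `residual`, and the
#'   call parameters.
#' @seealso [closed_form_rank()] for the direct linear-solve solution used
#'   as a numerical cross-check, [pagerank_projection()] for the one-mode
#'   baseline.
#' @export
#' @examples
#' W <- rbind(c(1, 1, 0), c(0, 1, 1))
#' fit <- birank(W, "birank")
#' coef(fit)
birank <- function(W, algorithm = c("birank", "cohits", "bgrm", "hits"),
                   alpha = NULL, beta = NULL, p0 = NULL, d0 = NULL,
                   tol = 1e-10, max_iter = 1000L) {
  algorithm <- match.arg(tolower(algorithm[1L]),
                         c("birank", "cohits", "bgrm", "hits"))
  if (is.null(alpha)) alpha <- if (algorithm == "hits") 1 else 0.85
  if (is.null(beta)) beta <- if (algorithm == "hits") 1 else 0.85
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("alpha and beta must lie in [0, 1]", call. = FALSE)
  Wm <- as_weight_matrix(W)
  tr <- build_transitions(Wm, algorithm)
  np <- ncol(Wm); nd <- nrow(Wm)
  if (np == 0L || nd == 0L)
    return(new_birank(numeric(0), numeric(0), 0L, TRUE, 0, algorithm,
                      alpha, beta, W))
  if (is.null(p0)) p0 <- rep(1 / np, np)
  if (is.null(d0)) d0 <- rep(1 / nd, nd)
  if (length(p0) != np || length(d0) != nd)
    stop("prior vectors must match the network dimensions", call. = FALSE)
  if (any(p0 < 0) || any(d0 < 0))
    stop("prior vectors must be nonnegative", call. = FALSE)

  hits_norm <- algorithm == "hits"
  p <- p0; d <- d0
  converged <- FALSE
  residual <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p_new <- as.numeric(alpha * (tr$S_p %*% d) + (1 - alpha) * p0)
    if (hits_norm && sum(p_new) > 0) p_new <- p_new / sum(p_new)
    d_new <- as.numeric(beta * (tr$S_d %*% p_new) + (1 - beta) * d0)
    if (hits_norm && sum(d_new) > 0) d_new <- d_new / sum(d_new)
    residual <- sum(abs(p_new - p))
    p <- p_new; d <- d_new
    if (!is.finite(residual)) {
      # BGRM's transition is substochastic only when every generalized
      # degree is >= 1; below that the undamped part can diverge
      warning(sprintf("%s iteration diverged (non-finite scores)",
                      toupper(algorithm)))
      break
    }
    if (residual < tol) { converged <- TRUE; break }
  }
  if (converged || is.finite(residual)) {
    if (!converged)
      warning(sprintf("%s did not converge in %d iterations (L1 change %.3e)",
                      toupper(algorithm), max_iter, residual))
  }
  new_birank(p, d, iter, converged, residual, algorithm, alpha, beta, W)
}

new_birank <- function(p, d, iterations, converged, residual, algorithm,
                       alpha, beta, W) {
  if (inherits(W, "bipartite_net")) {
    names(p) <- W$patient_ids
    names(d) <- W$provider_ids
  } else if (!is.null(dimnames(W))) {
    names(p) <- colnames(W)
    names(d) <- rownames(W)
  }
  structure(list(p = p, d = d, iterations = iterations,
                 converged = converged, residual = residual,
                 algorithm = algorithm, alpha = alpha, beta = beta),
            class = "birank")
}

#' @export
print.birank <- function(x, ...) {
  cat(sprintf("%s bipartite centrality (alpha = %.2f, beta = %.2f)\n",
              toupper(x$algorithm), x$alpha, x$beta))
  cat(sprintf("  %d patients, %d providers; %d iterations, %sconverged (L1 change %.2e)\n",
              length(x$p), length(x$d), x$iterations,
              if (x$converged) "" else "NOT ", x$residual))
  invisible(x)
}

#' @export
#' @describeIn birank Extract score vectors; `mode = "patient"` (default)
#'   returns `p`, `mode = "provider"` returns `d`.
coef.birank <- function(object, mode = c("patient", "provider"), ...) {
  mode <- match.arg(mode)
  if (mode == "patient") object$p else object$d
}

#' @export
summary.birank <- function(object, ...) {
  s <- function(v) if (length(v)) stats::quantile(v, c(0, .5, .99, 1)) else
    rep(NA_real_, 4)
  out <- list(algorithm = object$algorithm,
              iterations = object$iterations,
              converged = object$converged,
              residual = object$residual,
              patient_quantiles = s(object$p),
              provider_quantiles = s(object$d))
  class(out) <- "summary.birank"
  out
}

#' @export
print.summary.birank <- function(x, ...) {
  cat(sprintf("%s: %d iterations, converged = %s, final L1 change = %.2e\n",
              toupper(x$algorithm), x$iterations, x$converged, x$residual))
  cat("patient score quantiles (0/50/99/100%):\n")
  print(signif(x$patient_quantiles, 4))
  cat("provider score quantiles (0/50/99/100%):\n")
  print(signif(x$provider_quantiles, 4))
  invisible(x)
}

#' Closed-form solution of the damped bipartite fixed point
#'
#' Solves the stationary equations of the damped two-mode iteration directly:
#' substituting the provider update into the patient update gives
#' `(I - alpha * beta * S_p S_d) p = alpha * (1 - beta) * S_p d0 +
#' (1 - alpha) * p0`, a linear system solved exactly, after which
#' `d = beta * S_d p + (1 - beta) * d0`. Valid whenever damping is strictly
#' below 1 on at least one mode; the undamped case (classic HITS) has no
#' unique linear solution and must use the iterative path.
#'
#' Used as the independent numerical oracle for [birank()].
#'
#' @inheritParams birank
#' @return A list with patient scores `p` and provider scores `d`.
#' @export
closed_form_rank <- function(W, algorithm = c("birank", "cohits", "bgrm",
                                              "hits"),
                             alpha = 0.85, beta = 0.85,
                             p0 = NULL, d0 = NULL) {
  algorithm <- match.arg(tolower(algorithm[1L]),
                         c("birank", "cohits", "bgrm", "hits"))
  if (alpha >= 1 && beta >= 1)
    stop(paste("undamped system (alpha = beta = 1) has no unique linear",
               "solution; use the iterative birank() path"), call. = FALSE)
  Wm <- as_weight_matrix(W)
  tr <- build_transitions(Wm, algorithm)
  np <- ncol(Wm); nd <- nrow(Wm)
  if (is.null(p0)) p0 <- rep(1 / np, np)
  if (is.null(d0)) d0 <- rep(1 / nd, nd)
  M <- Matrix::Diagonal(np) - alpha * beta * (tr$S_p %*% tr$S_d)
  rhs <- alpha * (1 - beta) * as.numeric(tr$S_p %*% d0) + (1 - alpha) * p0
  p <- as.numeric(Matrix::solve(M, rhs))
  d <- as.numeric(beta * (tr$S_d %*% p) + (1 - beta) * d0)
  if (inherits(W, "bipartite_net")) {
    names(p) <- W$patient_ids; names(d) <- W$provider_ids
  }
  list(p = p, d = d)
}

#' Write centrality scores as a tidy TSV
#'
#' One row per node: `node_id`, `mode`, `algorithm`, `score`.
#'
#' @param fit A `birank` object.
#' @param path Output file.
#' @export
write_scores <- function(fit, path) {
  stopifnot(inherits(fit, "birank"))
  df <- data.frame(
    node_id = c(names(fit$p), names(fit$d)),
    mode = rep(c("patient", "provider"), c(length(fit$p), length(fit$d))),
    algorithm = fit$algorithm,
    score = c(unname(fit$p), unname(fit$d)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
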