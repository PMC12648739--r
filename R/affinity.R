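#' Affinity propagation clustering
#'
#' Message-passing exemplar clustering (responsibility / availability
#' updates with damping) on a similarity matrix, used to group genotypes
#' by event-time distributions without predefining the cluster number.
#' Similarity defaults to negative squared Euclidean distance; the shared
#' preference defaults to the median off-diagonal similarity.
#'
#' @param x numeric matrix (rows = items) or a precomputed similarity
#'   matrix when `is_similarity = TRUE`.
#' @param preference diagonal self-similarity; default median similarity.
#' @param damping damping factor in (0, 1).
#' @param maxit maximum iterations.
#' @param convits stop after this many iterations with unchanged exemplars.
#' @param is_similarity interpret `x` as a similarity matrix.
#' @return list with `cluster` (1-based labels), `exemplars` (row
#'   indices), `converged`.
#' @export
affinity_propagation <- function(x, preference = NULL, damping = 0.5,
                                 maxit = 1000, convits = 100,
                                 is_similarity = FALSE) {
  S <- if (is_similarity) x else -as.matrix(stats::dist(x))^2
  n <- nrow(S)
  if (n == 1) return(list(cluster = 1L, exemplars = 1L, converged = TRUE))
  off <- S[row(S) != col(S)]
  if (is.null(preference)) preference <- stats::median(off)
  diag(S) <- preference
  # tiny deterministic jitter removes degenerate ties (fixed pattern, no RNG)
  S <- S + S * 1e-12 * (outer(seq_len(n), seq_len(n)) %% 7)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  last_ex <- NULL; stable <- 0L; converged <- FALSE
  for (it in seq_len(maxit)) {
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dAnew <- colsum - diag(R)   # sum over i' != k of max(0, r(i', k))
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dAnew
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (length(ex) && identical(ex, last_ex)) stable <- stable + 1L
    else { stable <- 0L; last_ex <- ex }
    if (stable >= convits) { converged <- TRUE; break }
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (!length(ex)) ex <- which.max(diag(R) + diag(A))
  cl <- max.col(S[, ex, drop = FALSE], ties.method = "first")
  cl[ex] <- seq_along(ex)
  list(cluster = cl, exemplars = ex, converged = converged)
}

# deterministic k-medoid-style fallback for non-convergence: classical
# 1-D/feature-space partition via Ward clustering
kmedoid_fallback <- function(x, k = 3) {
  d <- stats::dist(x)
  cl <- stats::cutree(stats::hclust(d, method = "ward.D2"),
                      k = min(k, attr(d, "Size")))
  list(cluster = cl, exemplars = NULL, converged = FALSE)
}
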