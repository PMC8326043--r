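## Alpha and beta diversity on compositional abundance matrices.
## Matrices are oriented samples x taxa with sample IDs as rownames.

check_abundance_matrix <- function(X, relative = FALSE) {
  if (!is.matrix(X) || !is.numeric(X))
    stop_dietbiome("abundance table must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(X)))
    stop_dietbiome("abundance matrix needs sample IDs as rownames")
  if (any(!is.finite(X)))
    stop_dietbiome("abundance matrix contains non-finite values")
  if (any(X < 0))
    stop_dietbiome("abundance matrix contains negative entries")
  rs <- rowSums(X)
  if (any(rs == 0))
    stop_dietbiome("all-zero abundance row(s): ",
                   paste(rownames(X)[rs == 0], collapse = ", "))
  if (relative && any(abs(rs - 1) > 1e-9))
    stop_dietbiome("rows do not sum to 1; call to_relative_abundance() first")
  invisible(X)
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total so rows sum to one (compositional
#' form). All-zero samples are an error, named explicitly.
#'
#' @param counts Numeric samples-by-taxa matrix with sample-ID rownames.
#' @return Matrix of the same shape with unit row sums.
#' @export
#' @examples
#' m <- matrix(c(2, 2, 1, 3), 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' to_relative_abundance(m)
to_relative_abundance <- function(counts) {
  check_abundance_matrix(counts)
  counts / rowSums(counts)
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive abundance, in nats by
#' default (`0 * log(0)` is taken as 0). Accepts a single relative-abundance
#' vector or a samples-by-taxa matrix (one value per row).
#'
#' @param x Relative-abundance vector or matrix; each sample must sum to 1.
#' @param base Logarithm base; `exp(1)` (nats) by default.
#' @return Numeric vector of Shannon indices, `0 <= H <= log(S)`.
#' @export
#' @examples
#' shannon_index(rep(0.25, 4))           # log(4)
#' shannon_index(c(0.5, 0.25, 0.25))     # 1.0397
shannon_index <- function(x, base = exp(1)) {
  if (is.matrix(x)) return(apply(x, 1L, shannon_index, base = base))
  if (any(!is.finite(x)) || any(x < 0))
    stop_dietbiome("relative abundances must be finite and non-negative")
  if (abs(sum(x) - 1) > 1e-6)
    stop_dietbiome("relative abundances must sum to 1")
  p <- x[x > 0]
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum(|x - y|) / sum(x + y)` over taxa; on relative abundances
#' the values lie in \[0, 1\]. Bray-Curtis is a semimetric: symmetric with a
#' zero diagonal, but the triangle inequality need not hold.
#'
#' @param X Non-negative samples-by-taxa matrix, no all-zero rows.
#' @return A symmetric `n x n` matrix of class `dietbiome_dist` with sample
#'   IDs as dimnames.
#' @export
#' @examples
#' m <- rbind(a = c(0.5, 0.5), b = c(1, 0))
#' bray_curtis_matrix(m)  # off-diagonal 0.5
bray_curtis_matrix <- function(X) {
  check_abundance_matrix(X)
  rs <- rowSums(X)
  ## numerator sum|x_i - y_i| via Manhattan distance, denominator via row sums
  D <- as.matrix(stats::dist(X, method = "manhattan")) / outer(rs, rs, `+`)
  dimnames(D) <- list(rownames(X), rownames(X))
  class(D) <- c("dietbiome_dist", "matrix", "array")
  D
}

check_distance_matrix <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D))
    stop_dietbiome("distance input must be a square numeric matrix or 'dist'")
  if (any(!is.finite(D)) || any(D < 0))
    stop_dietbiome("distances must be finite and non-negative")
  if (max(abs(D - t(D))) > 1e-12)
    stop_dietbiome("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12))
    stop_dietbiome("distance matrix diagonal must be zero")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}
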