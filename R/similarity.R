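#' Integrate several similarity matrices into one
#'
#' Computes the weighted elementwise average
#' `sum_i w_i S_i / sum_i w_i`.  With all weights equal this is the
#' plain elementwise mean, i.e. every similarity source contributes
#' equally; the default weighting used for both the four SM similarity
#' sources and the two miRNA similarity sources.
#'
#' @param matrices list of square numeric matrices, all the same shape
#'   and identifier ordering, entries >= 0.
#' @param weights non-negative numeric vector, one weight per matrix;
#'   defaults to equal weights.
#' @return the integrated similarity matrix (same shape, dimnames of the
#'   first input).
#' @export
integrate_similarities <- function(matrices, weights = rep(1, length(matrices))) {
  if (!length(matrices)) stop("need at least one similarity matrix")
  if (length(weights) != length(matrices))
    stop("weights length must match number of matrices")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) == 0) stop("at least one weight must be positive")
  d <- dim(matrices[[1]])
  if (d[1] != d[2]) stop("similarity matrices must be square")
  for (M in matrices) {
    if (!identical(dim(M), d)) stop("similarity matrices differ in shape")
    if (any(M < 0)) stop("similarity entries must be non-negative")
  }
  out <- matrix(0, d[1], d[2], dimnames = dimnames(matrices[[1]]))
  for (i in seq_along(matrices)) out <- out + weights[i] * matrices[[i]]
  out / sum(weights)
}

#' Normalize a similarity matrix by row and column sums
#'
#' Entry `(i, j)` becomes `S(i,j) / sqrt(rowsum_i(S) * colsum_j(S))`
#' (style `"sqrt"`, default) or `S(i,j) / (rowsum_i * colsum_j)` (style
#' `"product"`).  Entries that are exactly zero stay zero, so all-zero
#' rows/columns pass through without division failures.  The sqrt form
#' is symmetric for symmetric input and invariant to a positive global
#' rescaling of `S`.
#'
#' @param S square numeric matrix with non-negative entries.
#' @param style `"sqrt"` or `"product"`.
#' @return the normalized matrix, same shape and dimnames.
#' @export
normalize_similarity <- function(S, style = c("sqrt", "product")) {
  style <- match.arg(style)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (any(S < 0)) stop("similarity entries must be non-negative")
  rs <- rowSums(S)
  cs <- colSums(S)
  nz <- S != 0
  # a nonzero entry forces its row and column sums positive
  stopifnot(all(rs[rowSums(nz) > 0] > 0), all(cs[colSums(nz) > 0] > 0))
  denom <- outer(rs, cs)
  if (style == "sqrt") denom <- sqrt(denom)
  out <- S
  out[nz] <- S[nz] / denom[nz]
  out
}
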