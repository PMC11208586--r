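# Contact-matrix balancing (ICE) and display capping.

#' Iterative correction (ICE) of a contact matrix
#'
#' Balances a symmetric non-negative contact matrix by iterative
#' correction: each round estimates a per-bin bias from the row sums,
#' renormalizes the biases to mean 1 over bins with signal, and divides
#' every entry by the product of its row and column biases. Bins whose
#' marginal is zero on input are excluded and stay exactly zero. After
#' the fixed number of rounds the matrix is rescaled so total mass
#' equals the input mass; symmetry is preserved throughout.
#'
#' @param mat square symmetric non-negative numeric matrix.
#' @param iterations number of correction rounds (default 30).
#' @param tol optional early-stop tolerance: stop once the coefficient
#'   of variation of the active row sums falls below `tol`. `NULL`
#'   (default) runs all `iterations` rounds.
#' @return The balanced matrix, same dimensions, total sum equal to
#'   `sum(mat)` to within numerical precision.
#' @examples
#' m <- matrix(c(0, 2, 2, 0), 2)
#' all.equal(ice_balance(m), m)  # already balanced up to scale
#' @export
ice_balance <- function(mat, iterations = 30L, tol = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (any(mat < 0)) stopf("contact matrix has negative entries")
  asym <- max(abs(mat - t(mat)))
  if (asym > 1e-8 * max(1, max(mat))) {
    stopf("contact matrix is not symmetric (max |M - t(M)| = %.3g)", asym)
  }
  total <- sum(mat)
  if (total == 0) return(mat)
  active <- rowSums(mat) > 0
  m <- mat
  for (i in seq_len(iterations)) {
    rs <- rowSums(m)
    bias <- rep(1, nrow(m))
    bias[active] <- rs[active] / mean(rs[active])
    m <- m / outer(bias, bias)
    if (!is.null(tol)) {
      rs2 <- rowSums(m)[active]
      if (stats::sd(rs2) / mean(rs2) < tol) break
    }
  }
  m * (total / sum(m))
}

#' Cap a matrix at its top quantile for display
#'
#' Sets every value above the `(1 - q)` quantile of the nonzero entries
#' to that quantile value, leaving the rest unchanged (with `q = 0.05`
#' the maximum displayed intensity corresponds to the top 5% score).
#' The quantile is taken as an attained data value (inverse ECDF), which
#' makes capping idempotent.
#'
#' @param mat numeric matrix.
#' @param q upper tail mass to cap, `0 < q < 1`.
#' @return The capped matrix.
#' @export
cap_top_quantile <- function(mat, q = 0.05) {
  assert_scalar_number(q, "q")
  if (q <= 0 || q >= 1) stopf("'q' must satisfy 0 < q < 1")
  nz <- mat[mat > 0]
  if (length(nz) == 0L) {
    warnf("all-zero matrix: nothing to cap")
    return(mat)
  }
  thr <- stats::quantile(nz, probs = 1 - q, type = 1L, names = FALSE)
  mat[mat > thr] <- thr
  mat
}

#' Read / write a dense contact matrix as TSV
#'
#' Plain text, tab-separated, no header: row `i` holds the contacts of
#' bin `i`.
#'
#' @param path file path.
#' @return `read_contact_matrix()`: a numeric matrix.
#' @export
read_contact_matrix <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  as.matrix(read.table(path, sep = "\t", header = FALSE))
}

#' @rdname read_contact_matrix
#' @param mat numeric matrix to write.
#' @export
write_contact_matrix <- function(mat, path) {
  write.table(mat, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
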