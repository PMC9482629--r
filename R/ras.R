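#' Biproportional (RAS) matrix balancing
#'
#' Scales a nonnegative matrix by alternating row and column multipliers until
#' its row and column sums meet the given targets. Zeros are structural and
#' preserved. This is the classical RAS algorithm used to balance social
#' accounting matrices.
#'
#' @param raw nonnegative numeric matrix.
#' @param row_targets,col_targets positive target sums; grand totals must
#'   agree to `tol` (relative).
#' @param tol relative convergence tolerance on the worst row/column residual.
#' @param max_iter maximum number of RAS sweeps.
#' @return balanced matrix with attributes `iterations` and `residual`.
#' @examples
#' m <- matrix(c(2, 1, 1, 2), 2)
#' b <- balance_matrix(m, c(4, 2), c(3, 3))
#' rowSums(b); colSums(b)
#' @export
balance_matrix <- function(raw, row_targets, col_targets,
                           tol = 1e-10, max_iter = 1000L) {
  abort_if(!is.matrix(raw) || any(!is.finite(raw)) || any(raw < 0),
           "balance_matrix() needs a finite nonnegative matrix")
  abort_if(length(row_targets) != nrow(raw) || length(col_targets) != ncol(raw),
           "target lengths must match matrix dimensions")
  abort_if(any(row_targets <= 0) || any(col_targets <= 0),
           "targets must be strictly positive")
  total <- sum(row_targets)
  abort_if(abs(total - sum(col_targets)) > 1e-8 * total,
           "row and column target grand totals differ")
  ## infeasible zero pattern: a row/col with a positive target but no support
  bad_r <- which(rowSums(raw) == 0)
  abort_if(length(bad_r) > 0,
           paste0("infeasible zero pattern: empty row(s) ",
                  paste(bad_r, collapse = ", "), " with positive target"))
  bad_c <- which(colSums(raw) == 0)
  abort_if(length(bad_c) > 0,
           paste0("infeasible zero pattern: empty column(s) ",
                  paste(bad_c, collapse = ", "), " with positive target"))

  m <- raw
  resid <- Inf
  for (it in seq_len(max_iter)) {
    m <- m * (row_targets / rowSums(m))
    m <- t(t(m) * (col_targets / colSums(m)))
    resid <- max(abs(rowSums(m) - row_targets) / total,
                 abs(colSums(m) - col_targets) / total)
    if (resid < tol) {
      attr(m, "iterations") <- it
      attr(m, "residual") <- resid
      return(m)
    }
  }
  stop(sprintf(
    "RAS balancing failed to converge after %d iterations (residual %.3e)",
    max_iter, resid))
}
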