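# Shared random-walk-with-restart solver.
#
# Iterates p <- (1 - r) * (W p + lost * p0) + r * p0 where W is a
# column-substochastic transition matrix and `lost` is the probability mass
# sitting in dangling (all-zero) columns, which is sent back to the restart
# distribution so the iterate stays exactly L1-normalized.

#' @importFrom Matrix sparseMatrix Diagonal colSums
rwr_iterate <- function(W, p0, restart, tol = 1e-10, max_iter = 10000L) {
  if (restart <= 0 || restart >= 1) stopf("restart must be in (0, 1)")
  p <- p0
  for (iter in seq_len(max_iter)) {
    w <- as.numeric(W %*% p)
    lost <- max(0, 1 - sum(w))
    p_new <- (1 - restart) * (w + lost * p0) + restart * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      return(stats::setNames(p, rownames(W)))
    }
  }
  stopf("random walk did not converge in %d iterations (residual %.3e)",
        max_iter, delta)
}

# Column-normalized (sub)stochastic adjacency of an igraph; dangling columns
# (isolated nodes) stay zero and are handled by the solver.
column_stochastic <- function(net) {
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  A <- (A > 0) * 1  # unweighted walk
  cs <- Matrix::colSums(A)
  inv <- ifelse(cs > 0, 1 / cs, 0)
  W <- A %*% Matrix::Diagonal(x = inv)
  dimnames(W) <- dimnames(A)
  W
}
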