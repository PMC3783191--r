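#' Lawson-Hanson nonnegative least squares
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0` by the classical
#' active-set method. Problem sizes here are tiny (at most 25 columns), so a
#' plain R implementation is ample.
#'
#' @param A numeric matrix (m x n)
#' @param b numeric vector (length m)
#' @param max_iter safety cap on outer iterations
#' @return list with `x`, `residual` (L2 norm) and `iterations`
#' @keywords internal
nnls_lawson_hanson <- function(A, b, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  if (length(b) != m) stop_input_error("nnls: dimension mismatch")
  if (is.null(max_iter)) max_iter <- 10L * n + 20L
  tol <- 10 * .Machine$double.eps * max(1, max(abs(A))) * max(m, n)

  x <- numeric(n)
  passive <- logical(n)
  w <- as.numeric(crossprod(A, b))
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop(errorCondition("nnls failed to converge",
                          class = c("decon_numeric_error", "decon_error")))
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0                       # rank-deficient: drop null dirs
      if (all(z[passive] > tol)) { x <- z; break }
      q <- passive & (z <= tol)
      alpha <- min(x[q] / (x[q] - z[q]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  list(x = x, residual = sqrt(sum((b - as.numeric(A %*% x))^2)),
       iterations = iter)
}
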