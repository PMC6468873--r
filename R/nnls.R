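#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0` with the classical
#' active-set algorithm: variables enter the passive set by largest
#' positive gradient of the dual `w = A'(b - A x)`, the unconstrained
#' least-squares subproblem is solved on the passive set by QR, and
#' variables that would go non-positive are moved back along the feasible
#' segment and dropped.  Deterministic; terminates at the KKT point
#' (`w <= tol` on the active set, `x > 0` with zero gradient on the
#' passive set).
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector (length m).
#' @param tol Dual-feasibility tolerance, scaled by `max(|A'b|)`
#'   (default 1e-10).
#' @return List with `x` (solution), `residual`
#'   (`||A x - b||_2`), and `fitted` (`A x`).
#' @export
nnls <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (nrow(A) != length(b)) gs_config_error("nrow(A) must equal length(b)")
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  scale <- max(abs(crossprod(A, b)), 1)
  w <- as.numeric(crossprod(A, b))
  max_outer <- 3L * n + 10L
  for (outer in seq_len(max_outer)) {
    cand <- which(!passive & w > tol * scale)
    if (length(cand) == 0) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      qr_p <- qr(A[, passive, drop = FALSE])
      s[passive] <- qr.coef(qr_p, b)
      s[passive][is.na(s[passive])] <- 0 # rank-deficient passive set
      if (all(s[passive] > 0)) {
        x <- s
        break
      }
      viol <- passive & s <= 0
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      passive <- passive & x > .Machine$double.eps * scale
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  fitted <- as.numeric(A %*% x)
  list(x = x, residual = sqrt(sum((b - fitted)^2)), fitted = fitted)
}
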