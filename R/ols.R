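#' Least-squares fit with maximum-likelihood standard errors
#'
#' Ordinary least squares via a pivoted QR decomposition, with coefficient
#' standard errors based on the maximum-likelihood residual variance
#' (residual sum of squares divided by n rather than n - p), matching the
#' convention of path-analysis software. The unbiased n - p divisor is
#' available via `var_type = "unbiased"`; it changes standard errors only,
#' never the coefficients.
#'
#' @param X Design matrix including an intercept column; must have full
#'   column rank and more rows than columns.
#' @param y Response vector.
#' @param var_type `"ml"` (default, divide by n) or `"unbiased"` (n - p).
#' @return List with `coefficients`, `se`, `sigma2` (the residual variance
#'   used for the SEs), `residuals`, `n`, `rank`.
#' @export
ols_ml <- function(X, y, var_type = c("ml", "unbiased")) {
  var_type <- match.arg(var_type)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more observations than regressors", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    cn <- colnames(X)
    if (is.null(cn)) cn <- paste0("V", seq_len(p))
    bad <- cn[qx$pivot[(qx$rank + 1L):p]]
    stop("collinear design: column(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cf <- qr.coef(qx, y)
  res <- as.numeric(y - X %*% cf)
  rss <- sum(res^2)
  sigma2 <- rss / if (var_type == "ml") n else (n - p)
  r_inv <- chol2inv(qr.R(qx))          # (R'R)^{-1} in pivoted order
  piv <- qx$pivot
  v <- numeric(p)
  v[piv] <- diag(r_inv)
  se <- sqrt(sigma2 * v)
  names(se) <- names(cf)
  list(coefficients = cf, se = se, sigma2 = sigma2, residuals = res,
       n = n, rank = qx$rank)
}
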