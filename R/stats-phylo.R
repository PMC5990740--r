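#' Brownian-motion phylogenetic covariance matrix
#'
#' Under Brownian trait evolution the covariance between two species is
#' proportional to the branch length they share from the root to their most
#' recent common ancestor, and a species' variance is its root-to-tip
#' length. This wraps the standard variance-covariance computation and adds
#' tip-order control and validation.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param tip_order Optional character vector: row/column order of the
#'   result. All names must be tips of the tree.
#' @return A symmetric species-by-species matrix C.
#' @export
phylo_covariance <- function(tree, tip_order = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths; Brownian covariance is undefined")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  C <- ape::vcv(tree)
  if (!is.null(tip_order)) {
    missing <- setdiff(tip_order, rownames(C))
    if (length(missing) > 0L) {
      stop("species missing from the tree: ", paste(missing, collapse = ", "))
    }
    C <- C[tip_order, tip_order, drop = FALSE]
  }
  C
}

#' Phylogenetic generalized least squares of log rate on log body mass
#'
#' Fits y = b0 + b1 * x by generalized least squares with the Brownian
#' covariance C: beta = (X' C^-1 X)^-1 X' C^-1 y. The raw residuals
#' y - X beta on the log scale are the body-mass-corrected growth rates used
#' downstream. With C = identity the fit reduces to ordinary least squares.
#'
#' @param y Response (log10 rate), named or in the order of `C`'s rows.
#' @param x Predictor (log10 body mass), same order.
#' @param C Species covariance matrix from [phylo_covariance()].
#' @return A `pgls_fit` list: `beta` (intercept, slope), `residuals`,
#'   `fitted`, `sigma2` (GLS error variance), `se` (coefficient standard
#'   errors), and `covariance_V` (the matrix used).
#' @export
pgls_fit <- function(y, x, C) {
  stopifnot(length(y) == length(x), nrow(C) == length(y), ncol(C) == length(y))
  X <- cbind(intercept = 1, slope = x)
  L <- tryCatch(chol(C), error = function(e) {
    stop("covariance matrix is singular or not positive definite; check branch lengths")
  })
  # whiten by the Cholesky factor: solve(t(L)) %*% X
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  beta <- stats::setNames(fit$coefficients, c("intercept", "slope"))
  fitted <- as.numeric(X %*% beta)
  res <- y - fitted
  n <- length(y)
  sigma2 <- sum(fit$residuals^2) / (n - 2L)
  XtVinvX_inv <- chol2inv(qr.R(qr(Xw)))
  se <- sqrt(diag(sigma2 * XtVinvX_inv))
  structure(
    list(beta = beta, residuals = res, fitted = fitted, sigma2 = sigma2,
         se = stats::setNames(se, c("intercept", "slope")), covariance_V = C),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls_fit> intercept %.4f (SE %.4f), slope %.4f (SE %.4f), n = %d\n",
              x$beta[1], x$se[1], x$beta[2], x$se[2], length(x$residuals)))
  invisible(x)
}
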