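#' Column standardization (z-scores with sample standard deviation)
#'
#' Centers each column on its mean and scales by its sample standard
#' deviation (divisor n - 1), so that every column of the result has mean 0
#' and sample standard deviation 1.
#'
#' @param x Numeric matrix or data frame, n >= 2 rows.
#' @param center,scale Optional centering/scaling vectors (e.g. from a
#'   previous fit); computed from `x` when `NULL`.
#' @return Matrix of the same shape with attributes `center` and `scale`.
#' @export
standardize_columns <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L && is.null(center)) stop("need at least two rows")
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2L, stats::sd)
  zero <- which(scale == 0)
  if (length(zero))
    stop("constant column(s): ",
         paste(colnames(x)[zero] %||% zero, collapse = ", "))
  z <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation matrix of a standardized data matrix
#'
#' \eqn{R = Z^T Z / (n - 1)} for a column-standardized matrix `Z`; equal to
#' the sample correlation matrix of the underlying data.
#'
#' @param z Standardized n x m matrix (see [standardize_columns()]).
#' @return m x m symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("need at least two rows")
  r <- crossprod(z) / (nrow(z) - 1L)
  (r + t(r)) / 2
}

#' Eigendecomposition of a correlation matrix with a fixed sign convention
#'
#' Eigenpairs are sorted by decreasing eigenvalue; tiny negative eigenvalues
#' (numerical noise of rank-deficient matrices) are clipped to zero.  Each
#' eigenvector is unit norm with its largest-magnitude entry made positive,
#' fixing the sign indeterminacy so that training and query projections share
#' one convention.
#'
#' @param r Symmetric m x m correlation matrix.
#' @return List with `values` (decreasing eigenvalues) and `vectors`
#'   (m x m matrix, one unit eigenvector per column).
#' @export
eigen_correlation <- function(r) {
  r <- as.matrix(r)
  if (max(abs(r - t(r))) > 1e-8) stop("correlation matrix is not symmetric")
  e <- eigen((r + t(r)) / 2, symmetric = TRUE)
  values <- pmax(e$values, 0)
  vectors <- e$vectors
  for (j in seq_len(ncol(vectors))) {
    lead <- which.max(abs(vectors[, j]))
    if (vectors[lead, j] < 0) vectors[, j] <- -vectors[, j]
  }
  dimnames(vectors) <- list(rownames(r), paste0("PC", seq_len(ncol(vectors))))
  list(values = values, vectors = vectors)
}

#' Choose the number of retained principal components
#'
#' Either a fixed count, or the smallest k whose cumulative variance
#' contribution \eqn{\sum_{i \le k} \lambda_i / m} reaches `value`.
#'
#' @param eigenvalues Eigenvalues sorted decreasing.
#' @param policy `"fixed"` or `"cumulative"`.
#' @param value Component count (fixed) or contribution threshold in (0, 1\]
#'   (cumulative).
#' @return Integer k.
#' @export
select_components <- function(eigenvalues, policy = c("fixed", "cumulative"),
                              value) {
  policy <- match.arg(policy)
  m <- length(eigenvalues)
  if (policy == "fixed") {
    k <- as.integer(value)
    if (k < 1L || k > m) stop("component count must be in 1..", m)
    return(k)
  }
  if (value > 1) stop("cumulative threshold cannot exceed 1")
  contrib <- cumsum(eigenvalues) / m
  which(contrib >= value - 1e-12)[1L]
}

#' Correlation-matrix principal component analysis
#'
#' Standardizes the descriptor columns (mean 0, sample sd 1), forms the
#' sample correlation matrix, and eigendecomposes it.  The variance
#' contribution of component i is \eqn{\lambda_i / m}.  Scores are the
#' projections of the standardized data onto the retained unit eigenvectors;
#' they are not whitened (not rescaled by \eqn{1/\sqrt{\lambda}}), matching
#' their downstream use as distance-bearing regression inputs.
#'
#' @param x Numeric matrix or data frame of raw descriptor values (molecules
#'   in rows).
#' @param ncomp Number of components to retain (fixed policy), or `NULL` to
#'   use `threshold`.
#' @param threshold Cumulative variance-contribution threshold used when
#'   `ncomp` is `NULL`; default 1 retains all components.
#' @return Object of class `"cor_pca"`: list with `center`, `scale`,
#'   `correlation`, `values` (eigenvalues, decreasing), `loadings`
#'   (unit eigenvectors in columns), `weights` (variance contributions
#'   \eqn{\lambda_i/m}), `ncomp`.
#' @examples
#' fit <- cor_pca(yno_bde()[, gra(yno_bde())$selected], ncomp = 6)
#' fit$values[1]                   # leading eigenvalue ~ 3.70
#' sum(fit$weights[1:6])           # ~ 0.9963 of total variance
#' @export
cor_pca <- function(x, ncomp = NULL, threshold = 1) {
  z <- standardize_columns(x)
  r <- correlation_matrix(z)
  e <- eigen_correlation(r)
  ncomp <- if (is.null(ncomp)) {
    select_components(e$values, "cumulative", threshold)
  } else {
    select_components(e$values, "fixed", ncomp)
  }
  structure(list(center = attr(z, "center"), scale = attr(z, "scale"),
                 correlation = r, values = e$values, loadings = e$vectors,
                 weights = e$values / length(e$values), ncomp = ncomp),
            class = "cor_pca")
}

#' Project data onto retained principal components
#'
#' Standardizes `newdata` with the means and standard deviations stored in
#' the fitted model, then projects onto the first `ncomp` unit eigenvectors.
#' When applied to the fitting data, score-column variances equal the
#' eigenvalues and score columns are pairwise uncorrelated.
#'
#' @param object Fitted `"cor_pca"` model.
#' @param newdata Matrix or data frame with the model's columns.
#' @param ncomp Number of components; defaults to the fitted `ncomp`.
#' @param ... Unused.
#' @return n x ncomp score matrix with columns `PC1..PCk`.
#' @export
predict.cor_pca <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$center))
  z <- standardize_columns(newdata, center = object$center,
                           scale = object$scale)
  z %*% object$loadings[, seq_len(ncomp), drop = FALSE]
}

#' @export
print.cor_pca <- function(x, digits = 4L, ...) {
  m <- length(x$values)
  cat("Correlation-matrix PCA of", m, "descriptors;", x$ncomp,
      "component(s) retained\n")
  tab <- data.frame(eigenvalue = round(x$values, digits),
                    contribution = round(x$weights, digits),
                    cumulative = round(cumsum(x$weights), digits))
  rownames(tab) <- paste0("PC", seq_len(m))
  print(tab, ...)
  invisible(x)
}

#' @export
summary.cor_pca <- function(object, ...) {
  structure(list(model = object), class = "summary.cor_pca")
}

#' @export
print.summary.cor_pca <- function(x, digits = 4L, ...) {
  print(x$model, digits = digits, ...)
  cat("\nLoadings (unit eigenvectors):\n")
  print(round(x$model$loadings[, seq_len(x$model$ncomp), drop = FALSE],
              digits))
  invisible(x)
}
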