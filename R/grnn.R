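#' Fit a generalized regression neural network
#'
#' A GRNN is a memory-based Gaussian-kernel regressor: it stores the training
#' patterns verbatim (no iterative training) and predicts a query as the
#' kernel-weighted average of the stored targets.  Its only parameter is the
#' smoothing factor `delta`, the common kernel bandwidth.
#'
#' With input scaling enabled, each input column is transformed using
#' statistics of the training patterns, and identically at prediction time:
#' `"zscore"` centers on the mean and divides by the sample standard
#' deviation (a constant column gets scale 1 rather than erroring),
#' `"minmax"` maps the training range onto \[0, 1\], `"none"` leaves inputs
#' untouched (appropriate for already-commensurate inputs such as principal
#' component scores).
#'
#' @param x Numeric matrix or data frame of training patterns (one row per
#'   sample).
#' @param y Numeric target vector, `length(y) == nrow(x)`.
#' @param delta Smoothing factor, > 0.
#' @param scale Input scaling: `"zscore"` (default), `"minmax"` or `"none"`.
#' @return Object of class `"grnn"`: list with `patterns` (scaled), `y`,
#'   `delta`, `scale`, `center`, `scaling` (per-column center/scale actually
#'   applied).
#' @examples
#' m <- grnn(matrix(c(0, 1, 2)), c(0, 1, 0), delta = 1, scale = "none")
#' predict(m, matrix(1))
#' @export
grnn <- function(x, y, delta, scale = c("zscore", "minmax", "none")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a positive scalar")
  if (nrow(x) != length(y)) stop("x and y have different lengths")
  if (nrow(x) < 1L) stop("need at least one training pattern")
  sc <- .grnn_scaling(x, scale)
  structure(list(patterns = .grnn_apply_scaling(x, sc), y = as.numeric(y),
                 delta = delta, scale = scale, scaling = sc),
            class = "grnn")
}

.grnn_scaling <- function(x, scale) {
  if (scale == "zscore") {
    s <- apply(x, 2L, stats::sd)
    if (anyNA(s)) s[is.na(s)] <- 0   # single pattern
    list(center = colMeans(x), scale = ifelse(s == 0, 1, s))
  } else if (scale == "minmax") {
    lo <- apply(x, 2L, min)
    hi <- apply(x, 2L, max)
    list(center = lo, scale = ifelse(hi == lo, 1, hi - lo))
  } else {
    list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
  }
}

.grnn_apply_scaling <- function(x, sc) {
  sweep(sweep(x, 2L, sc$center, "-"), 2L, sc$scale, "/")
}

#' Predict from a generalized regression neural network
#'
#' For each query \eqn{x}, pattern activations are
#' \eqn{p_i = \exp(-\|x - X_i\|^2 / (2\delta^2))}; the prediction is
#' \eqn{Y = S_N / S_D} with \eqn{S_N = \sum_i y_i p_i} and
#' \eqn{S_D = \sum_i p_i} -- a convex combination of the stored targets, so
#' every prediction lies in \[min(y), max(y)\].  If all activations
#' underflow to zero (query far from every pattern at small `delta`), the
#' target of the nearest pattern is returned (squared-distance argmin, ties
#' to the lowest pattern index).
#'
#' @param object Fitted `"grnn"` model.
#' @param newdata Query matrix/data frame with the same number of columns as
#'   the training patterns.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per query row.
#' @export
predict.grnn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$patterns))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         ncol(object$patterns))
  q <- .grnn_apply_scaling(newdata, object$scaling)
  .grnn_eval(object$patterns, object$y, q, object$delta)
}

# kernel-weighted average over stored patterns; vectorized over queries
.grnn_eval <- function(patterns, y, queries, delta) {
  # squared distances: |q|^2 + |p|^2 - 2 q.p  (n_query x n_pattern)
  p2 <- rowSums(patterns^2)
  q2 <- rowSums(queries^2)
  d2 <- outer(q2, p2, "+") - 2 * tcrossprod(queries, patterns)
  d2 <- pmax(d2, 0)
  w <- exp(-d2 / (2 * delta^2))
  sd_ <- rowSums(w)
  out <- as.numeric(w %*% y) / sd_
  dead <- which(sd_ == 0)
  if (length(dead)) {
    for (i in dead) out[i] <- y[which.min(d2[i, ])]
  }
  out
}

#' Smoothing-factor grid search for a GRNN
#'
#' Evaluates an error criterion at every grid value of the smoothing factor
#' and returns the minimizer (ties resolved toward the smallest value).
#' `criterion = "loo"` scores each candidate by leave-one-out RMS error on
#' the training set: each training pattern is removed from the pattern layer
#' before being predicted.  `criterion = "test"` scores by RMS error on a
#' supplied held-out set.
#'
#' @param x,y Training patterns and targets.
#' @param grid Candidate smoothing factors; default 0.02 to 1 in steps of
#'   0.02.
#' @param criterion `"loo"` or `"test"`.
#' @param newdata,newy Held-out set, required for `criterion = "test"`.
#' @param scale Input scaling, as in [grnn()].
#' @return Object of class `"grnn_sweep"`: list with `grid`, `values`
#'   (criterion per grid point), `best_delta`, `criterion`.
#' @export
grnn_sweep <- function(x, y, grid = seq(0.02, 1, by = 0.02),
                       criterion = c("loo", "test"),
                       newdata = NULL, newy = NULL,
                       scale = c("zscore", "minmax", "none")) {
  criterion <- match.arg(criterion)
  scale <- match.arg(scale)
  if (length(grid) < 1L || any(grid <= 0))
    stop("grid must be nonempty and positive")
  x <- as.matrix(x)
  if (criterion == "test" && (is.null(newdata) || is.null(newy)))
    stop("criterion 'test' requires newdata and newy")
  sc <- .grnn_scaling(x, scale)
  xs <- .grnn_apply_scaling(x, sc)
  values <- vapply(grid, function(delta) {
    if (criterion == "loo") {
      pred <- vapply(seq_len(nrow(xs)), function(i) {
        .grnn_eval(xs[-i, , drop = FALSE], y[-i],
                   xs[i, , drop = FALSE], delta)
      }, numeric(1L))
      rms(y - pred)
    } else {
      qs <- .grnn_apply_scaling(as.matrix(newdata), sc)
      rms(newy - .grnn_eval(xs, y, qs, delta))
    }
  }, numeric(1L))
  structure(list(grid = grid, values = values,
                 best_delta = grid[which.min(values)],
                 criterion = criterion),
            class = "grnn_sweep")
}

#' @export
print.grnn <- function(x, ...) {
  cat("Generalized regression neural network\n")
  cat("  patterns:", nrow(x$patterns), "x", ncol(x$patterns),
      " | smoothing factor delta =", x$delta,
      " | input scaling:", x$scale, "\n")
  invisible(x)
}

#' @export
print.grnn_sweep <- function(x, ...) {
  cat("GRNN smoothing-factor sweep (", x$criterion, " criterion)\n",
      sep = "")
  cat("  grid: ", min(x$grid), "..", max(x$grid), " (", length(x$grid),
      " points) | best delta = ", x$best_delta,
      " (criterion ", signif(min(x$values), 4), ")\n", sep = "")
  invisible(x)
}
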