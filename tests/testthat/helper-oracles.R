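# Independent brute-force oracles, deliberately written as plain double loops
# so they share no code path with the package implementations.

# Deng relational coefficients, elementwise
oracle_gra_coefficients <- function(x0, contrast, rho) {
  n <- length(x0)
  m <- ncol(contrast)
  delta <- matrix(NA_real_, n, m)
  for (i in seq_len(m)) {
    for (k in seq_len(n)) delta[k, i] <- abs(x0[k] - contrast[k, i])
  }
  dmin <- min(delta)
  dmax <- max(delta)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(m)) {
    for (k in seq_len(n)) {
      out[k, i] <- (dmin + rho * dmax) / (delta[k, i] + rho * dmax)
    }
  }
  out
}

# leading eigenpairs by power iteration with deflation
oracle_eigen <- function(r, tol = 1e-12, maxit = 10000L) {
  m <- nrow(r)
  values <- numeric(m)
  vectors <- matrix(0, m, m)
  a <- r
  for (j in seq_len(m)) {
    v <- rep(1 / sqrt(m), m)
    lam <- 0
    for (it in seq_len(maxit)) {
      w <- a %*% v
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break        # null space reached
      v_new <- as.numeric(w / nw)
      lam_new <- as.numeric(t(v_new) %*% r %*% v_new)
      if (max(abs(v_new - v)) < tol || max(abs(v_new + v)) < tol) {
        v <- v_new; lam <- lam_new; break
      }
      v <- v_new; lam <- lam_new
    }
    values[j] <- lam
    vectors[, j] <- v
    a <- a - lam * tcrossprod(v)
  }
  ord <- order(-values)
  list(values = values[ord], vectors = vectors[, ord, drop = FALSE])
}

# GRNN prediction for a single query, naive accumulation
oracle_grnn <- function(patterns, y, query, delta) {
  sn <- 0
  sd_ <- 0
  for (i in seq_len(nrow(patterns))) {
    d2 <- sum((query - patterns[i, ])^2)
    p <- exp(-d2 / (2 * delta^2))
    sn <- sn + y[i] * p
    sd_ <- sd_ + p
  }
  sn / sd_
}

# small valid descriptor table built in code
make_table <- function(n = 6L, seed = 42L) {
  set.seed(seed)
  data.frame(mol_id = seq_len(n), bond_class = "N-NO",
             split = rep(c("train", "test"), length.out = n),
             expt_bde = round(runif(n, 10, 45), 2),
             dH_homo = round(runif(n, 10, 45), 2),
             Q_Y = round(rnorm(n, -0.3, 0.1), 3),
             alpha_pol = round(runif(n, 50, 250), 2))
}
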