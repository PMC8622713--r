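# Independent brute-force oracles. These deliberately avoid the code
# paths they check.

# sliding-window polynomial least squares, evaluated (or differentiated)
# at the window center; interior points only (edges NA)
oracle_savgol <- function(y, h, window, polyorder, deriv = 0) {
  n <- length(y)
  k <- (window - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in (k + 1):(n - k)) {
    idx <- (i - k):(i + k)
    df <- data.frame(u = (idx - i) * h, y = y[idx])
    fit <- stats::lm(y ~ poly(u, polyorder, raw = TRUE), data = df)
    cf <- coef(fit)
    out[i] <- if (deriv == 0) cf[1] else factorial(deriv) * cf[deriv + 1]
  }
  out
}

# PCA via eigendecomposition of the covariance matrix
oracle_pca <- function(x, k) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  list(eigenvalues = ev$values[seq_len(k)],
       loadings = ev$vectors[, seq_len(k), drop = FALSE],
       scores = xc %*% ev$vectors[, seq_len(k), drop = FALSE])
}

# AUC as the pairwise concordance fraction (ties count 1/2)
oracle_auc <- function(scores, labels, positive = "C") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# textbook PLS1 NIPALS with X-only deflation (y left intact) -- an
# algebraically equivalent but independently coded recursion
oracle_pls1_coef <- function(X, y, a) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  p <- ncol(X)
  W <- P <- matrix(0, p, a); q <- numeric(a)
  Xd <- Xc
  for (j in seq_len(a)) {
    w <- drop(t(Xd) %*% yc)
    w <- w / sqrt(sum(w^2))
    t_j <- drop(Xd %*% w)
    p_j <- drop(t(Xd) %*% t_j) / sum(t_j^2)
    q[j] <- sum(yc * t_j) / sum(t_j^2)
    W[, j] <- w; P[, j] <- p_j
    Xd <- Xd - outer(t_j, p_j)
  }
  drop(W %*% solve(t(P) %*% W, q))
}

# band-window mean intensity around a center wavenumber
band_mean <- function(set, center, halfwidth = 6) {
  idx <- abs(set$wavenumbers - center) <= halfwidth
  mean(set$x[, idx])
}
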