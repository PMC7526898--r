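# independent oracles used across tests

# brute-force Mueller-Brown potential from the published 4-term table
mb_oracle <- function(x, y) {
  A <- c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7); b <- c(0, 0, 11, 0.6); cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1); y0 <- c(0, 0.5, 1.5, 1)
  sum(A * exp(a * (x - x0)^2 + b * (x - x0) * (y - y0) + cc * (y - y0)^2))
}

# central finite differences of a scalar function of an n x k matrix
fd_gradient <- function(f, X, h = 1e-6) {
  X <- as.matrix(X)
  G <- X * 0
  for (i in seq_len(nrow(X))) for (d in seq_len(ncol(X))) {
    Xp <- X; Xp[i, d] <- Xp[i, d] + h
    Xm <- X; Xm[i, d] <- Xm[i, d] - h
    G[i, d] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  G
}

# brute-force contact map: double loop, scalar contact function
contact_oracle <- function(X, pairs, r0 = 7.5, rc = 12) {
  vapply(seq_len(nrow(pairs)), function(p) {
    r <- sqrt(sum((X[pairs[p, 1], ] - X[pairs[p, 2], ])^2))
    if (r > rc) return(0)
    x <- r / r0
    if (abs(x - 1) < 1e-12) return(0.6)
    (1 - x^6) / (1 - x^10)
  }, numeric(1))
}

# Kabsch RMSD oracle via bio3d superposition
rmsd_oracle <- function(X, ref, align = seq_len(nrow(ref)),
                        calc = seq_len(nrow(ref))) {
  inds <- as.vector(t(cbind((align - 1) * 3 + 1, (align - 1) * 3 + 2,
                            (align - 1) * 3 + 3)))
  fit <- bio3d::fit.xyz(as.numeric(t(ref)), as.numeric(t(X)),
                        fixed.inds = inds, mobile.inds = inds)
  Xa <- matrix(fit, ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums((Xa[calc, , drop = FALSE] - ref[calc, , drop = FALSE])^2)))
}

# random bead cloud with controlled scale
random_config <- function(n, sd = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(3 * n, sd = sd), ncol = 3)
}
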