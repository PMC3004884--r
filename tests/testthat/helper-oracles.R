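# independent generalized-eigen oracle: symmetric whitening route.
# Sw^{-1/2} Sb Sw^{-1/2} is symmetric; its eigenvectors v map back to
# w = Sw^{-1/2} v. Uses only base linear algebra, no package code paths.
oracle_lda_directions <- function(x, labels, shrinkage = 1e-6) {
  x <- as.matrix(x)
  classes <- unique(labels)
  mu <- colMeans(x)
  d <- ncol(x)
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  for (cl in classes) {
    xc <- x[labels == cl, , drop = FALSE]
    mc <- colMeans(xc)
    Sw <- Sw + crossprod(sweep(xc, 2, mc))
    Sb <- Sb + nrow(xc) * tcrossprod(mc - mu)
  }
  Sw <- Sw + diag(shrinkage * sum(diag(Sw)) / d, d)
  es <- eigen(Sw, symmetric = TRUE)
  W_half_inv <- es$vectors %*% diag(1 / sqrt(es$values), d) %*% t(es$vectors)
  M <- W_half_inv %*% Sb %*% W_half_inv
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W_half_inv %*% em$vectors[, 1:2, drop = FALSE]
}
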