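# shared fixtures and independent oracles used across test files

# block-diagonal full-sib kinship: n/2 sib pairs with off-diagonal 0.5
sib_block_K <- function(n_pairs) {
  blk <- matrix(c(1, 0.5, 0.5, 1), 2)
  K <- matrix(0, 2 * n_pairs, 2 * n_pairs)
  for (i in seq_len(n_pairs)) {
    idx <- (2 * i - 1):(2 * i)
    K[idx, idx] <- blk
  }
  dimnames(K) <- list(paste0("i", seq_len(2 * n_pairs)),
                      paste0("i", seq_len(2 * n_pairs)))
  K
}

# literal step-up BH: adj_(i) = min over j >= i of min(1, p_(j) * m / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# restricted-likelihood grid search, written independently of reml_fit
reml_grid_oracle <- function(y, K, Q = matrix(1, length(y), 1),
                             step = 0.001) {
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- as.vector(crossprod(U, y))
  Qt <- crossprod(U, Q)
  n <- length(y)
  c <- ncol(Q)
  ll <- function(h) {
    v <- h * d + (1 - h)
    w <- 1 / v
    A <- crossprod(Qt, Qt * w)
    beta <- solve(A, crossprod(Qt * w, yt))
    r <- yt - Qt %*% beta
    s2 <- sum(w * r^2) / (n - c)
    as.numeric(-0.5 * ((n - c) * log(2 * pi * s2) + (n - c) + sum(log(v)) +
                         determinant(A)$modulus))
  }
  hs <- seq(0, 1 - step, by = step)
  lls <- vapply(hs, ll, 0)
  list(h = hs[which.max(lls)], ll = max(lls), grid_ll = lls, grid_h = hs)
}

# toy abundance table with known structure: 4 samples x 4 taxa, rows sum to 1
toy_abundance <- function() {
  A <- rbind(
    c(0.40, 0.30, 0.20, 0.10),
    c(0.10, 0.40, 0.30, 0.20),
    c(0.25, 0.25, 0.25, 0.25),
    c(0.05, 0.15, 0.35, 0.45)
  )
  dimnames(A) <- list(paste0("s", 1:4), paste0("t", 1:4))
  A
}

# draw y ~ N(0, h2 * K + (1 - h2) * I) given an eigendecomposable K
draw_polygenic_y <- function(K, h2) {
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  n <- nrow(K)
  as.vector(eg$vectors %*% (sqrt(d * h2) * stats::rnorm(n))) +
    stats::rnorm(n, 0, sqrt(1 - h2))
}
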