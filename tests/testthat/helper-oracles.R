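# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles with naive loops so they share no code
# with the implementation they check.

# discrete forward model: v[j] = dt * cbf * sum_{i<=j} aif_d[i] * Fr(t_j - t_i)
oracle_tissue_curve <- function(aif_values, dt, cbf, mtt, delay_frames = 0L) {
  n <- length(aif_values)
  a <- c(rep(0, delay_frames), aif_values)[seq_len(n)]
  v <- numeric(n)
  for (j in 0:(n - 1)) {
    acc <- 0
    for (i in 0:j) {
      acc <- acc + a[i + 1] * exp(-((j - i) * dt) / mtt)
    }
    v[j + 1] <- dt * cbf * acc
  }
  v
}

# Toeplitz convolution matrix, element by element
oracle_toeplitz <- function(aif_values, dt) {
  n <- length(aif_values)
  A <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (j <= i) A[i, j] <- dt * aif_values[i - j + 1]
    }
  }
  A
}

# circulant embedding: entry (i, j) = column[(i - j) mod 2N]
oracle_circulant <- function(aif_values, dt) {
  n <- length(aif_values)
  L <- 2L * n
  col1 <- c(dt * aif_values, rep(0, n))
  A <- matrix(0, L, L)
  for (i in 1:L) {
    for (j in 1:L) {
      A[i, j] <- col1[((i - j) %% L) + 1L]
    }
  }
  A
}

# concordance correlation, direct transcription of the defining formula
# with population moments
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx <- sqrt(sum((x - mx)^2) / n)
  sy <- sqrt(sum((y - my)^2) / n)
  sxy <- sum((x - mx) * (y - my)) / n
  pcc <- sxy / (sx * sy)
  2 * pcc * sx * sy / (sx^2 + sy^2 + (mx - my)^2)
}

# rectangle-rule quadrature of a curve on a dense grid (for AUC checks)
oracle_auc_dense <- function(fun, t_max, n_steps = 2e5) {
  tt <- seq(0, t_max, length.out = n_steps)
  sum(fun(tt)) * (tt[2] - tt[1])
}
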