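# shared fixtures, built in code

# epochs object from a channels x samples matrix (single epoch)
one_epoch <- function(m, fs = 250) {
  arr <- array(0, c(1, nrow(m), ncol(m)))
  arr[1, , ] <- m
  eeg_epochs(arr, fs)
}

# orthonormal zero-mean maps (rows), for constructing exact clustering cases
orthonormal_maps <- function(k, n_channels, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(stats::rnorm(n_channels * (k + 1)), n_channels)
    M <- cbind(1, M)                       # force the mean direction in
    Q <- qr.Q(qr(M))[, 2:(k + 1), drop = FALSE]  # orthogonal to constant
    t(Q)
  })
}

# exhaustive polarity-invariant 2-cluster search: the independent oracle for
# modified k-means GEV (optimal templates per side are the dominant
# eigenvectors of each side's channel covariance)
exhaustive_bipartition_gev <- function(X) {
  X <- X - rowMeans(X)
  n <- nrow(X)
  total <- sum(X^2)
  lambda1 <- function(M) {
    if (nrow(M) == 0) return(0)
    eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values[1]
  }
  best <- -Inf
  for (code in 1:(2^(n - 1) - 1)) {       # map 1 fixed in cluster 1
    side <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2)))))
    g <- (lambda1(X[side, , drop = FALSE]) +
            lambda1(X[!side, , drop = FALSE])) / total
    if (g > best) best <- g
  }
  best
}

# match each true template to the best recovered one, return matched |r|
matched_abs_r <- function(recovered, truth) {
  vapply(seq_len(nrow(truth$maps)), function(j)
    spatial_correlation(recovered$maps[j, ], truth$maps[j, ]),
    numeric(1))
}
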