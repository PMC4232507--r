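# Shared fixtures and independent oracles.

# Random proper rotation matrix (QR of a Gaussian matrix, det +1).
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(coords, R = rand_rotation(), shift = rnorm(3, sd = 5)) {
  sweep(coords %*% R, 2, shift, "+")
}

# Independent RMSD oracle: numeric minimization over unit quaternions with
# multi-start BFGS (no SVD), plus the optimal translation (centroids).
rmsd_quaternion_oracle <- function(P, Q, restarts = 25) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot_of <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) sqrt(mean(rowSums((Pc %*% t(rot_of(q)) - Qc)^2)))
  best <- Inf
  for (k in seq_len(restarts)) {
    q0 <- rnorm(4)
    fit <- optim(q0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Exhaustive GDT oracle for tiny chains: maximal residue count superposable
# within `cutoff`, over all subsets of size >= 3.
gdt_exhaustive_oracle <- function(P, Q, cutoff) {
  n <- nrow(P)
  best <- 0
  for (mask in seq_len(2^n - 1)) {
    subset <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(subset) < 3) next
    cp <- colMeans(P[subset, , drop = FALSE])
    cq <- colMeans(Q[subset, , drop = FALSE])
    s <- svd(crossprod(sweep(P[subset, , drop = FALSE], 2, cp),
                       sweep(Q[subset, , drop = FALSE], 2, cq)))
    R <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
    aligned <- sweep(sweep(P, 2, cp) %*% R, 2, cq, "+")
    d <- sqrt(rowSums((aligned - Q)^2))
    best <- max(best, sum(d <= cutoff))
  }
  best / n
}

# Friedman chi-square via the alternative rank-sum formula (independent of
# the package's centered-average form).
friedman_ranksum_oracle <- function(scores) {
  n <- nrow(scores); N <- ncol(scores)
  Rj <- rowSums(apply(scores, 2, rank))
  12 / (N * n * (n + 1)) * sum(Rj^2) - 3 * N * (n + 1)
}
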