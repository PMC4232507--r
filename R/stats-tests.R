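# Nonparametric comparison battery over an algorithms x functions table of
# mean best values: Friedman, aligned Friedman and Quade tests with their
# average ranks, plus the CPU-share metric.  Formulas follow the standard
# computational-intelligence methodology (chi-square references for
# Friedman and aligned Friedman, an F reference for Quade).

#' Assemble a results matrix for the rank tests
#'
#' @param means numeric matrix of mean best values, algorithms as rows and
#'   benchmark functions as columns.
#' @param algorithms,functions optional dimnames.
#' @param optima per-function known optimum values (defaults to 0), used by
#'   the error ranking orientation.
#' @return A `results_matrix`: the matrix with an `optima` attribute.
#' @export
results_matrix <- function(means, algorithms = rownames(means),
                           functions = colnames(means), optima = NULL) {
  means <- as.matrix(means)
  if (anyNA(means)) stop("results matrix must have no missing cells")
  rownames(means) <- algorithms %||% paste0("algo", seq_len(nrow(means)))
  colnames(means) <- functions %||% paste0("f", seq_len(ncol(means)))
  attr(means, "optima") <- rep_len(optima %||% 0, ncol(means))
  class(means) <- c("results_matrix", class(means))
  means
}

#' Read / write a results matrix as CSV
#'
#' The CSV stores algorithms as rows and functions as columns, with an
#' optional first data row named `optimum` carrying the per-function known
#' optima.
#'
#' @param path file path.
#' @return [read_results_matrix()] returns a `results_matrix`.
#' @export
read_results_matrix <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  optima <- NULL
  if ("optimum" %in% rownames(df)) {
    optima <- as.numeric(df["optimum", ])
    df <- df[rownames(df) != "optimum", , drop = FALSE]
  }
  results_matrix(as.matrix(df), optima = optima)
}

#' @rdname read_results_matrix
#' @param x a `results_matrix`.
#' @export
write_results_matrix <- function(x, path) {
  out <- rbind(optimum = attr(x, "optima"), unclass(x))
  write.csv(out, path)
  invisible(path)
}

# Orient scores so that smaller is better in every block: either the
# absolute error against the known optimum (default; for zero-optimum
# functions identical to the raw value ranking) or the raw mean.
oriented_scores <- function(means, orientation, optima) {
  if (orientation == "error") {
    optima <- rep_len(optima %||% attr(means, "optima") %||% 0, ncol(means))
    abs(sweep(unclass(means), 2, optima))
  } else {
    unclass(means)
  }
}

#' Within-block ranks of the algorithms
#'
#' Ranks the algorithms within each benchmark function (block), ascending
#' in `|mean - optimum|` (orientation `"error"`, the default) or in the raw
#' mean (`"raw"`).  Ties receive average ranks, so each block's ranks sum
#' to `n(n+1)/2`.
#'
#' @param means a [results_matrix()] or plain matrix (algorithms x
#'   functions).
#' @param orientation `"error"` or `"raw"`.
#' @param optima per-function optima; defaults to the matrix attribute.
#' @return A matrix of ranks with the shape of `means`.
#' @export
rank_blocks <- function(means, orientation = c("error", "raw"),
                        optima = NULL) {
  orientation <- match.arg(orientation)
  sc <- oriented_scores(means, orientation, optima)
  r <- apply(sc, 2, rank)
  dimnames(r) <- dimnames(means)
  r
}

rank_summary <- function(avg_rank, statistic, p_value, method, ranks) {
  structure(list(avg_rank = sort(avg_rank), statistic = statistic,
                 p_value = p_value, method = method, ranks = ranks),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat(sprintf("%s test: statistic %.6g, p = %.6g\naverage ranks:\n",
              x$method, x$statistic, x$p_value))
  print(round(x$avg_rank, 4))
  invisible(x)
}

#' Friedman test over a results matrix
#'
#' Average within-block ranks per algorithm and the Friedman chi-square
#' statistic `12N/(n(n+1)) * sum((Rbar_j - (n+1)/2)^2)` with `n - 1`
#' degrees of freedom (`n` algorithms, `N` function blocks).  The average
#' ranks always sum to `n(n+1)/2`.
#'
#' @inheritParams rank_blocks
#' @return A `rank_summary` with `avg_rank`, `statistic`, `p_value`.
#' @export
rank_friedman <- function(means, orientation = c("error", "raw"),
                          optima = NULL) {
  orientation <- match.arg(orientation)
  r <- rank_blocks(means, orientation, optima)
  n <- nrow(r); N <- ncol(r)
  avg <- rowMeans(r)
  stat <- 12 * N / (n * (n + 1)) * sum((avg - (n + 1) / 2)^2)
  rank_summary(avg, stat, pchisq(stat, n - 1, lower.tail = FALSE),
               "Friedman", r)
}

#' Aligned Friedman test over a results matrix
#'
#' Subtracts each block's mean score (aligning), ranks all `n * N` aligned
#' values jointly, and computes the aligned-ranks statistic referenced to a
#' chi-square distribution with `n - 1` degrees of freedom.  Reported
#' average ranks are per-algorithm means of the joint aligned ranks.
#'
#' @inheritParams rank_blocks
#' @return A `rank_summary`.
#' @export
rank_aligned_friedman <- function(means, orientation = c("error", "raw"),
                                  optima = NULL) {
  orientation <- match.arg(orientation)
  sc <- oriented_scores(means, orientation, optima)
  n <- nrow(sc); N <- ncol(sc)
  aligned <- sweep(sc, 2, colMeans(sc))
  AR <- matrix(rank(aligned), n, N, dimnames = dimnames(sc))
  Rj <- rowSums(AR)             # per algorithm
  Ri <- colSums(AR)             # per block
  M <- n * N
  stat <- (n - 1) * (sum(Rj^2) - (n * N^2 / 4) * (M + 1)^2) /
    (M * (M + 1) * (2 * M + 1) / 6 - sum(Ri^2) / n)
  rank_summary(Rj / N, stat, pchisq(stat, n - 1, lower.tail = FALSE),
               "Aligned Friedman", AR)
}

#' Quade test over a results matrix
#'
#' Weights each block by the rank of its within-block sample range, forms
#' the weighted centered rank statistics and the F-distributed test
#' statistic with `(n - 1, (N - 1)(n - 1))` degrees of freedom.  Average
#' ranks are the weighted ranks normalized by `N(N+1)/2`.
#'
#' @inheritParams rank_blocks
#' @return A `rank_summary`.
#' @export
rank_quade <- function(means, orientation = c("error", "raw"),
                       optima = NULL) {
  orientation <- match.arg(orientation)
  sc <- oriented_scores(means, orientation, optima)
  n <- nrow(sc); N <- ncol(sc)
  r <- apply(sc, 2, rank)
  Q <- rank(apply(sc, 2, function(z) diff(range(z))))
  S <- sweep(r, 1, (n + 1) / 2) * rep(Q, each = n)
  Sj <- rowSums(S)
  A2 <- sum(S^2); B <- sum(Sj^2) / N
  stat <- if (A2 > B) (N - 1) * B / (A2 - B) else 0
  avg <- as.numeric(r %*% Q) / (N * (N + 1) / 2)
  names(avg) <- rownames(sc)
  rank_summary(avg, stat,
               pf(stat, n - 1, (N - 1) * (n - 1), lower.tail = FALSE),
               "Quade", r)
}

#' CPU-share metric
#'
#' Each algorithm's computational time on a function divided by the total
#' over all algorithms on that function; the shares sum to 1.
#'
#' @param times positive per-algorithm times for one function.
#' @return Fractions summing to 1.
#' @export
cpu_share <- function(times) {
  if (any(!is.finite(times)) || any(times <= 0))
    stop("times must be positive and finite")
  times / sum(times)
}

#' Published mean results bundled with the package
#'
#' The 9 x 12 table of mean best values (nine optimizers by the twelve
#' benchmark functions at 30-D, 30 trials each) transcribed from the
#' published comparison this package's algorithms reproduce; used by the
#' rank-test examples and the acceptance checks.
#'
#' @return A `results_matrix` with the per-function optima attached.
#' @export
published_benchmark_means <- function() {
  read_results_matrix(system.file("extdata", "benchmark_means.csv",
                                  package = "adafa", mustWork = TRUE))
}
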