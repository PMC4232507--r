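# Model-quality scores for C-alpha traces: least-squares superposition
# RMSD (Kabsch), TM-score and GDT-TS / GDT-HA.

trace_coords <- function(x) {
  if (inherits(x, "ca_trace")) x$coords else as.matrix(x)
}

# Optimal proper rotation R (right-multiplication convention) minimizing
# ||P %*% R - Q|| for centered row-vector coordinate matrices.
kabsch_rotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

superpose_onto <- function(P, Q, subset = seq_len(nrow(P))) {
  cp <- colMeans(P[subset, , drop = FALSE])
  cq <- colMeans(Q[subset, , drop = FALSE])
  R <- kabsch_rotation(sweep(P[subset, , drop = FALSE], 2, cp),
                       sweep(Q[subset, , drop = FALSE], 2, cq))
  aligned <- sweep(sweep(P, 2, cp) %*% R, 2, cq, "+")
  list(aligned = aligned, rotation = R, translation = cq - cp %*% R)
}

#' Minimal RMSD under rigid superposition
#'
#' Least-squares rigid-body superposition (proper rotations only) of two
#' equal-length C-alpha traces, returning the minimal root-mean-square
#' deviation together with the optimal rotation and translation.
#'
#' @param a,b [ca_trace()] objects or n x 3 coordinate matrices of equal
#'   length (n >= 3).
#' @return An object of class `superposition`: `rmsd` (Angstrom),
#'   `rotation` (3 x 3), `translation` (length 3).
#' @export
superpose_rmsd <- function(a, b) {
  P <- trace_coords(a); Q <- trace_coords(b)
  if (nrow(P) != nrow(Q))
    stop("traces have different lengths (", nrow(P), " vs ", nrow(Q), ")")
  if (nrow(P) < 3) stop("superposition needs at least 3 atoms")
  fit <- superpose_onto(P, Q)
  structure(list(rmsd = sqrt(mean(rowSums((fit$aligned - Q)^2))),
                 rotation = fit$rotation,
                 translation = as.numeric(fit$translation)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD %.4f A\n", x$rmsd))
  invisible(x)
}

# Seed subsets for the iterative superposition searches: sliding windows
# of several lengths plus the full chain.
seed_subsets <- function(n, lengths) {
  subs <- list(seq_len(n))
  for (w in lengths) {
    if (w >= 3 && w <= n)
      for (s in seq_len(n - w + 1)) subs[[length(subs) + 1]] <- s:(s + w - 1)
  }
  subs
}

#' TM-score of a model against a reference
#'
#' Length-normalized model quality score in (0, 1]:
#' `max over superpositions of mean(1 / (1 + (d_i/d0)^2))` with
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8` clamped below at 0.5 Angstrom (the
#' small-protein convention, used for chains of 15 residues or fewer).
#' The maximization uses the standard iterative search: sliding-window
#' seeds, superposition on the current subset, then re-selection of the
#' residues within the inclusion cutoff until stable.
#'
#' @param model,ref [ca_trace()] objects or coordinate matrices of equal
#'   length.
#' @return The TM-score (1 for identical structures).
#' @export
tm_score <- function(model, ref) {
  P <- trace_coords(model); Q <- trace_coords(ref)
  if (nrow(P) != nrow(Q)) stop("model and reference lengths differ")
  n <- nrow(P)
  d0 <- if (n > 15) max(1.24 * (n - 15)^(1 / 3) - 1.8, 0.5) else 0.5
  score_of <- function(aligned) {
    d2 <- rowSums((aligned - Q)^2)
    mean(1 / (1 + d2 / d0^2))
  }
  best <- 0
  for (sub in seed_subsets(n, unique(c(n, floor(n / 2), floor(n / 4), 4)))) {
    subset <- sub
    for (iter in 1:20) {
      fit <- superpose_onto(P, Q, subset)
      best <- max(best, score_of(fit$aligned))
      d <- sqrt(rowSums((fit$aligned - Q)^2))
      cut <- d0
      new <- which(d < cut)
      while (length(new) < 3) {
        cut <- cut + 0.5
        new <- which(d < cut)
      }
      if (identical(new, subset)) break
      subset <- new
    }
  }
  best
}

# Largest residue count superposable within `cutoff`, by iterative
# extension from window seeds; monotone in the cutoff by construction of
# the caller (cummax over sorted cutoffs).
gdt_fraction <- function(P, Q, cutoff, lengths) {
  n <- nrow(P)
  best <- 0
  for (sub in seed_subsets(n, lengths)) {
    subset <- sub
    for (iter in 1:10) {
      fit <- superpose_onto(P, Q, subset)
      d <- sqrt(rowSums((fit$aligned - Q)^2))
      new <- which(d <= cutoff)
      best <- max(best, length(new))
      if (length(new) < 3 || identical(new, subset)) break
      subset <- new
    }
  }
  best / n
}

#' GDT-TS and GDT-HA scores
#'
#' Global distance test scores on the 0--100 scale: the mean over distance
#' cutoffs (1, 2, 4, 8 Angstrom for GDT-TS; 0.5, 1, 2, 4 for GDT-HA) of
#' the maximal percentage of residues superposable within the cutoff.
#' The per-cutoff maximization uses sliding-window seeds with iterative
#' extension; fractions are made monotone across cutoffs, so GDT-HA never
#' exceeds GDT-TS.
#'
#' @inheritParams tm_score
#' @return Named vector `c(gdt_ts =, gdt_ha =)`.
#' @export
gdt_scores <- function(model, ref) {
  P <- trace_coords(model); Q <- trace_coords(ref)
  if (nrow(P) != nrow(Q)) stop("model and reference lengths differ")
  n <- nrow(P)
  lengths <- unique(pmin(c(3, 5, 7, n), n))
  cuts <- c(0.5, 1, 2, 4, 8)
  fr <- vapply(cuts, function(cc) gdt_fraction(P, Q, cc, lengths),
               numeric(1))
  fr <- cummax(fr)
  c(gdt_ts = 100 * mean(fr[cuts %in% c(1, 2, 4, 8)]),
    gdt_ha = 100 * mean(fr[cuts %in% c(0.5, 1, 2, 4)]))
}

#' All model-quality scores at once
#'
#' @inheritParams tm_score
#' @return An object of class `score_set` with `rmsd`, `tm`, `gdt_ts`,
#'   `gdt_ha`.
#' @export
score_set <- function(model, ref) {
  g <- gdt_scores(model, ref)
  structure(list(rmsd = superpose_rmsd(model, ref)$rmsd,
                 tm = tm_score(model, ref),
                 gdt_ts = unname(g["gdt_ts"]), gdt_ha = unname(g["gdt_ha"])),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> RMSD %.3f A | TM %.3f | GDT-TS %.1f | GDT-HA %.1f\n",
              x$rmsd, x$tm, x$gdt_ts, x$gdt_ha))
  invisible(x)
}
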