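# C-alpha trace handling: virtual bond geometry extraction, conversion to
# distance constraints, and sequential chain rebuilding by per-atom
# constraint-energy minimization with the adaptive firefly optimizer.

#' Construct a C-alpha trace
#'
#' @param coords n x 3 matrix of C-alpha coordinates in Angstrom.
#' @param resid residue identifiers (default 1..n).
#' @param validate warn when consecutive C-alpha distances fall outside the
#'   (2.0, 4.5) Angstrom window expected of a physical trace.
#' @return An object of class `ca_trace`.
#' @export
ca_trace <- function(coords, resid = seq_len(nrow(coords)), validate = TRUE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  if (validate && nrow(coords) >= 2) {
    d <- sqrt(rowSums(diff(coords)^2))
    if (any(d <= 2.0 | d >= 4.5))
      warning(sum(d <= 2.0 | d >= 4.5),
              " consecutive C-alpha distance(s) outside (2.0, 4.5) A")
  }
  structure(list(resid = resid, coords = unname(coords)), class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %d residues\n", nrow(x$coords)))
  invisible(x)
}

#' Ideal helical C-alpha trace
#'
#' Parametric alpha-helical spiral used as a synthetic stand-in for
#' experimentally determined trans-membrane helices: residue k sits at
#' `(radius*cos(k*twist), radius*sin(k*twist), k*rise)`.  The defaults give
#' a consecutive C-alpha distance of about 3.8 Angstrom and constant
#' virtual bond angles and dihedrals along the chain.
#'
#' @param n number of residues (>= 5).
#' @param rise rise per residue along the helix axis, Angstrom.
#' @param radius helix radius, Angstrom.
#' @param twist rotation per residue, degrees.
#' @return A [ca_trace()].
#' @export
synthetic_helix <- function(n, rise = 1.5, radius = 2.3, twist = 100) {
  if (n < 5) stop("a helix fixture needs at least 5 residues")
  k <- seq_len(n) - 1
  ang <- k * twist * pi / 180
  ca_trace(cbind(radius * cos(ang), radius * sin(ang), k * rise))
}

#' Read the C-alpha trace of one chain from a PDB file
#'
#' Keeps `ATOM` records with atom name `CA` (alternate location blank or
#' `A`) of the requested chain, in residue order.
#'
#' @param path PDB file.
#' @param chain chain identifier; default takes the first chain present.
#' @return A [ca_trace()] with the original residue numbering.
#' @export
read_ca_trace <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$elety == "CA" &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) < 5) stop("chain ", chain, " has fewer than 5 C-alpha atoms")
  ca_trace(cbind(at$x, at$y, at$z), resid = at$resno)
}

#' Write a C-alpha trace as minimal PDB ATOM records
#'
#' @param trace a [ca_trace()].
#' @param path output file.
#' @param chain chain identifier to write.
#' @export
write_ca_pdb <- function(trace, path, chain = "A") {
  n <- nrow(trace$coords)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), chain, trace$resid,
    trace$coords[, 1], trace$coords[, 2], trace$coords[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vec_unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector has no direction")
  v / n
}

# Planar angle at B (degrees) and signed dihedral of A-B-C-D (degrees).
angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vec_cross(b1, b2); n2 <- vec_cross(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    return(NA_real_)
  m1 <- vec_cross(n1, vec_unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Extract virtual bond geometry from a C-alpha trace
#'
#' Computes the internal coordinates of the C-alpha chain: virtual bond
#' lengths `b[i]` (distance i-1 to i, for i >= 2), planar bond angles
#' `theta[i]` at atom i-1 (degrees, i >= 3) and signed dihedrals `tau[i]`
#' over atoms i-3..i (degrees in (-180, 180], i >= 4).  The geometry is
#' invariant under rigid motion and round-trips exactly through
#' [internal_to_cartesian()].
#'
#' @param trace a [ca_trace()] with at least 4 residues.
#' @return An object of class `internal_geometry` with fields
#'   `bond_lengths`, `bond_angles`, `dihedrals`, `n`.
#' @export
extract_geometry <- function(trace) {
  X <- trace$coords
  n <- nrow(X)
  if (n < 4) stop("geometry extraction needs at least 4 residues")
  b <- sqrt(rowSums(diff(X)^2))
  theta <- vapply(3:n, function(i) angle_deg(X[i - 2, ], X[i - 1, ], X[i, ]),
                  numeric(1))
  tau <- vapply(4:n, function(i)
    dihedral_deg(X[i - 3, ], X[i - 2, ], X[i - 1, ], X[i, ]), numeric(1))
  if (anyNA(tau))
    stop("dihedral undefined at residue ", (4:n)[which(is.na(tau))[1]],
         ": three consecutive atoms are collinear")
  structure(list(bond_lengths = b, bond_angles = theta, dihedrals = tau,
                 n = n),
            class = "internal_geometry")
}

#' @export
print.internal_geometry <- function(x, ...) {
  cat(sprintf(
    "<internal_geometry> %d residues: b ~ %.2f A, theta ~ %.1f deg, tau ~ %.1f deg\n",
    x$n, mean(x$bond_lengths), mean(x$bond_angles), mean(x$dihedrals)))
  invisible(x)
}

# Place atom D given atoms A, B, C and internal coordinates (b, theta, tau
# in degrees): the standard natural-extension reference frame step.
nerf_place <- function(a, b, c, length, theta, tau) {
  th <- theta * pi / 180; ta <- tau * pi / 180
  bc <- vec_unit(c - b)
  n <- vec_unit(vec_cross(b - a, bc))
  m <- vec_cross(n, bc)
  d2 <- c(-length * cos(th), length * sin(th) * cos(ta),
          -length * sin(th) * sin(ta))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Exact internal-to-Cartesian chain construction
#'
#' Builds C-alpha coordinates that realize the given internal geometry
#' exactly, in a canonical frame (atom 1 at the origin shifted by
#' `origin`, atom 2 along x, atom 3 in the xy plane).  This is the
#' zero-energy reference builder used to validate the optimizer-based
#' rebuild.
#'
#' @param geom an `internal_geometry` from [extract_geometry()].
#' @param origin position of the first atom (default the origin).
#' @return A [ca_trace()].
#' @export
internal_to_cartesian <- function(geom, origin = c(0, 0, 0)) {
  n <- geom$n
  b <- geom$bond_lengths; th <- geom$bond_angles; ta <- geom$dihedrals
  X <- matrix(0, n, 3)
  X[1, ] <- origin
  X[2, ] <- X[1, ] + c(b[1], 0, 0)
  t3 <- th[1] * pi / 180
  X[3, ] <- X[2, ] + b[2] * c(-cos(t3), sin(t3), 0)
  if (n >= 4) {
    for (i in 4:n) {
      X[i, ] <- nerf_place(X[i - 3, ], X[i - 2, ], X[i - 1, ],
                           b[i - 1], th[i - 2], ta[i - 3])
    }
  }
  ca_trace(X, validate = FALSE)
}

#' Distance constraints implied by the internal geometry
#'
#' For each atom `i >= 5`, the four target distances to atoms
#' `i-1, i-2, i-3, i-4` implied by the four bond lengths, three bond angles
#' and two dihedral angles of the local fragment.  `d(i, i-1)` equals the
#' bond length `b[i]` exactly; the others follow from an exact
#' internal-to-Cartesian construction of the five-atom fragment.
#'
#' @param geom an `internal_geometry`.
#' @return A matrix with rows named by atom index `5..n` and columns
#'   `d1..d4` (distance to atom `i-1` ... `i-4`), all positive.
#' @export
geometry_to_distances <- function(geom) {
  n <- geom$n
  if (n < 5) stop("distance constraints start at the fifth atom")
  out <- matrix(NA_real_, n - 4, 4,
                dimnames = list(5:n, paste0("d", 1:4)))
  for (i in 5:n) {
    frag <- structure(list(bond_lengths = geom$bond_lengths[(i - 4):(i - 1)],
                           bond_angles = geom$bond_angles[(i - 4):(i - 2)],
                           dihedrals = geom$dihedrals[(i - 4):(i - 3)],
                           n = 5L),
                      class = "internal_geometry")
    Xf <- internal_to_cartesian(frag)$coords
    out[i - 4, ] <- sqrt(colSums((Xf[5, ] - t(Xf[4:1, ]))^2))
  }
  out
}

#' Constraint energy of a candidate atom position
#'
#' Sum over the four previously placed atoms of the squared (default) or
#' absolute deviation between the candidate's distance to that atom and
#' the target distance.  Zero exactly when all four distances match.
#'
#' @param candidate length-3 coordinate.
#' @param prev 4 x 3 matrix of the previous four atoms, nearest first.
#' @param targets the four target distances (same order).
#' @param form `"squared"` or `"absolute"` deviation.
#' @return Non-negative energy.
#' @export
placement_energy <- function(candidate, prev, targets,
                             form = c("squared", "absolute")) {
  form <- match.arg(form)
  d <- sqrt(colSums((candidate - t(prev))^2))
  dev <- d - targets
  if (form == "squared") sum(dev^2) else sum(abs(dev))
}

#' Seed the first four atoms of a rebuild
#'
#' The first atom is placed uniformly at random in the unit box (its
#' location is irrelevant up to rigid motion); atoms 2--4 are placed
#' exactly from the first bond lengths, bond angles and dihedral via the
#' canonical construction, so the seeded fragment satisfies
#' `b2, b3, theta3, b4, theta4, tau4` exactly.
#'
#' @param geom an `internal_geometry`.
#' @return A 4 x 3 coordinate matrix.
#' @export
seed_first_four <- function(geom) {
  if (geom$n < 4) stop("need at least 4 residues of geometry")
  frag <- structure(list(bond_lengths = geom$bond_lengths[1:3],
                         bond_angles = geom$bond_angles[1:2],
                         dihedrals = geom$dihedrals[1],
                         n = 4L),
                    class = "internal_geometry")
  internal_to_cartesian(frag, origin = runif(3))$coords
}

#' Optimize the position of the next C-alpha atom
#'
#' Minimizes [placement_energy()] over a cubic search box centered on the
#' last placed atom (half-width `max(targets)`, so any feasible position is
#' inside) with the adaptive firefly optimizer in 3-D.
#'
#' @param prev 4 x 3 matrix of the previous four atoms, nearest first.
#' @param targets four target distances (to atom i-1 ... i-4).
#' @param cfg an [adafa_config()]; the rebuild default is a small swarm
#'   (`pop_size = 24`, `max_gen = 150`).
#' @param form energy form, `"squared"` or `"absolute"`.
#' @param restarts maximum number of independent swarm starts; the search
#'   stops as soon as the energy drops below `tol`.  Restarts guard
#'   against the reflected (wrong-chirality) local minimum of the
#'   four-sphere intersection.
#' @param tol energy below which a placement is accepted early.
#' @return A list with `position`, `energy`, `evaluations`.
#' @export
place_next_ca <- function(prev, targets,
                          cfg = adafa_config(pop_size = 24, max_gen = 150),
                          form = c("squared", "absolute"), restarts = 6,
                          tol = 1e-8) {
  form <- match.arg(form)
  stopifnot(nrow(prev) == 4, length(targets) == 4, all(targets > 0))
  center <- prev[1, ]
  h <- max(targets)
  space <- search_space(center - h, center + h)
  ctrl <- engine_ctrl(cfg, space, adaptive = TRUE, trace = FALSE)
  ctrl$prev_atoms <- prev
  ctrl$targets <- as.numeric(targets)
  ctrl$energy_abs <- (form == "absolute")
  best <- list(position = NULL, energy = Inf, evaluations = 0)
  for (k in seq_len(max(1, restarts))) {
    # seed the swarm on the sphere of radius d(i, i-1) around the anchor
    # atom: the nearest-neighbour constraint starts satisfied and both
    # chiral basins of the remaining constraints are sampled densely
    dirs <- matrix(rnorm(3 * cfg$pop_size), cfg$pop_size, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    X0 <- sweep(targets[1] * dirs, 2, center, "+")
    X0 <- pmin(pmax(X0, matrix(space$lower, cfg$pop_size, 3, byrow = TRUE)),
               matrix(space$upper, cfg$pop_size, 3, byrow = TRUE))
    res <- .run_swarm_cpp(X0, 100L, space$lower, space$upper, ctrl)
    best$evaluations <- best$evaluations + res$evaluations
    if (res$best_value < best$energy) {
      best$position <- as.numeric(res$best_position)
      best$energy <- res$best_value
    }
    if (best$energy < tol) break
  }
  best
}

#' Rebuild a C-alpha chain from its internal geometry
#'
#' Sequential construction: the first four atoms are seeded exactly
#' ([seed_first_four()]); from the fifth atom on, each position is found by
#' [place_next_ca()] under the four distance constraints of
#' [geometry_to_distances()].  Atoms whose final energy exceeds
#' `energy_tol` are flagged but the build continues.
#'
#' @param geom an `internal_geometry` with `n >= 5`.
#' @param cfg an [adafa_config()] for the per-atom optimizer.
#' @param seed integer seed making the whole rebuild reproducible.
#' @param form energy form passed to [place_next_ca()].
#' @param energy_tol per-atom energy above which the placement is flagged.
#' @return A list with `trace` (the rebuilt [ca_trace()]), `energies`
#'   (per optimized atom, named by index), and `flagged` (indices whose
#'   energy exceeded `energy_tol`).
#' @export
rebuild_chain <- function(geom,
                          cfg = adafa_config(pop_size = 24, max_gen = 150),
                          seed = NULL, form = c("squared", "absolute"),
                          energy_tol = 1e-6) {
  form <- match.arg(form)
  n <- geom$n
  if (n < 5) stop("rebuilding needs at least 5 residues")
  if (!is.null(seed)) set.seed(seed)
  targets <- geometry_to_distances(geom)
  X <- matrix(NA_real_, n, 3)
  X[1:4, ] <- seed_first_four(geom)
  energies <- setNames(numeric(n - 4), 5:n)
  for (i in 5:n) {
    prev <- X[(i - 1):(i - 4), , drop = FALSE]
    fit <- place_next_ca(prev, targets[i - 4, ], cfg = cfg, form = form)
    X[i, ] <- fit$position
    energies[i - 4] <- fit$energy
  }
  list(trace = ca_trace(X, validate = FALSE), energies = energies,
       flagged = as.integer(names(energies)[energies > energy_tol]))
}

#' Perturb internal geometry with proportional Gaussian noise
#'
#' Adds zero-mean Gaussian noise with standard deviation
#' `fraction * |value|` to every bond length, bond angle and dihedral
#' (emulating noisy native constraints).  Bond angles are clamped into
#' (0, 180) degrees and dihedrals re-wrapped into (-180, 180].
#'
#' @param geom an `internal_geometry`.
#' @param fraction relative noise level (e.g. `0.1` for 10% noise);
#'   `0` returns the geometry unchanged.
#' @return A perturbed `internal_geometry`.
#' @export
add_constraint_noise <- function(geom, fraction) {
  stopifnot(fraction >= 0)
  if (fraction == 0) return(geom)
  jitter <- function(v) v + rnorm(length(v), sd = fraction * abs(v))
  b <- abs(jitter(geom$bond_lengths))
  th <- pmin(pmax(jitter(geom$bond_angles), 1e-3), 180 - 1e-3)
  ta <- jitter(geom$dihedrals)
  ta <- ((ta + 180) %% 360) - 180
  ta[ta == -180] <- 180
  structure(list(bond_lengths = b, bond_angles = th, dihedrals = ta,
                 n = geom$n),
            class = "internal_geometry")
}
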