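# Z-matrix internal coordinates: definition, conversion, Jacobian, and
# transformation of a Cartesian Hessian into the internal curvature matrix.

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Distance, angle and dihedral of points
#'
#' Elementary internal-coordinate functions.  `calc_angle` returns the angle
#' at vertex `p2` of the triplet (p1, p2, p3) in radians.  `calc_dihedral`
#' returns the signed torsion of the chain p1-p2-p3-p4 in (-pi, pi], IUPAC
#' convention (right-handed, looking from p2 to p3; trans = pi).
#'
#' @param p1,p2,p3,p4 Numeric length-3 position vectors.
#' @return Scalar value (angstrom or radian).
#' @export
calc_distance <- function(p1, p2) {
  d <- vnorm(p2 - p1)
  if (d < 1e-10) stop("coincident atoms")
  d
}

#' @rdname calc_distance
#' @export
calc_angle <- function(p1, p2, p3) {
  u <- unitv(p1 - p2); v <- unitv(p3 - p2)
  acos(max(-1, min(1, sum(u * v))))
}

#' @rdname calc_distance
#' @export
calc_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  m1 <- cross3(b1, b2); m2 <- cross3(b2, b3)
  if (vnorm(m1) < 1e-10 || vnorm(m2) < 1e-10)
    stop("degenerate dihedral: collinear atoms")
  x <- sum(m1 * m2)
  y <- sum(cross3(m1, m2) * unitv(b2))
  phi <- atan2(y, x)
  if (phi <= -pi + 1e-15) phi <- pi   # branch cut: -pi and pi are identical
  phi
}

collinear <- function(p1, p2, p3, tol = 1e-8) {
  vnorm(cross3(p2 - p1, p3 - p1)) <
    tol * max(1, vnorm(p2 - p1) * vnorm(p3 - p1))
}

#' Build a Z-matrix definition from a bonded structure
#'
#' The first three atoms are the user-supplied reference atoms, which also
#' fix the molecular frame.  Every subsequent atom is appended in index
#' order among the atoms bonded to already-placed atoms; its distance
#' reference is a bonded placed atom, and the angle/dihedral references are
#' the most recently placed remaining atoms.  For N atoms this yields
#' exactly Ns = 3N - 6 internal coordinates (2 distances + 1 angle for the
#' reference triplet, then one distance, angle and dihedral per atom).
#'
#' @param structure A `cartesian_structure` with at least 3 atoms and a
#'   connected bond graph.
#' @param ref_atoms Three (or four, the fourth being carried as metadata
#'   only) atom indices; the first three must be non-collinear.
#' @return An object of class `zmatrix_definition` with fields
#'   `atom_order`, `refs` (per-atom distance/angle/dihedral reference
#'   indices), `labels` (data frame of coordinate kinds and atom tuples)
#'   and `n_internal`.
#' @export
build_zmatrix <- function(structure, ref_atoms) {
  n <- length(structure$elements)
  if (n < 3) stop("need at least 3 atoms to define a Z-matrix")
  ref_atoms <- as.integer(ref_atoms)
  extra_ref <- if (length(ref_atoms) >= 4) ref_atoms[4] else NA_integer_
  ref3 <- ref_atoms[1:3]
  if (anyNA(ref3) || length(unique(ref3)) != 3)
    stop("ref_atoms must contain three distinct atom indices")
  x <- structure$coords
  if (collinear(x[ref3[1], ], x[ref3[2], ], x[ref3[3], ]))
    stop("geometry error: reference atoms are collinear")
  nb <- bond_neighbours(structure)

  order <- ref3
  placed <- logical(n); placed[ref3] <- TRUE
  refs <- matrix(NA_integer_, n, 3,
                 dimnames = list(NULL, c("dist", "angle", "dihedral")))
  # reference triplet: atom2 relative to atom1; atom3 relative to a bonded
  # placed atom (prefer a bonded one) and the other reference atom
  refs[ref3[2], 1] <- ref3[1]
  a3_d <- intersect(nb[[ref3[3]]], ref3[1:2])
  refs[ref3[3], 1] <- if (length(a3_d)) a3_d[1] else ref3[1]
  refs[ref3[3], 2] <- setdiff(ref3[1:2], refs[ref3[3], 1])[1]

  while (length(order) < n) {
    cand <- which(!placed & vapply(nb, function(v) any(placed[v]), logical(1)))
    if (!length(cand))
      stop("topology error: bond graph is disconnected")
    i <- min(cand)
    dref <- intersect(rev(order), nb[[i]])[1]   # most recent bonded atom
    rest <- setdiff(rev(order), dref)
    refs[i, ] <- c(dref, rest[1], rest[2])
    order <- c(order, i); placed[i] <- TRUE
  }

  labels <- zmatrix_labels(order, refs)
  zdef <- list(atom_order = order, refs = refs, labels = labels,
               n_internal = 3L * n - 6L, n_atoms = n,
               ref_atoms = ref3, extra_ref = extra_ref)
  class(zdef) <- "zmatrix_definition"
  zdef
}

zmatrix_labels <- function(order, refs) {
  rows <- list()
  add <- function(kind, atoms)
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, a1 = atoms[1], a2 = atoms[2],
      a3 = ifelse(length(atoms) >= 3, atoms[3], NA),
      a4 = ifelse(length(atoms) >= 4, atoms[4], NA))
  for (pos in seq_along(order)) {
    i <- order[pos]
    if (pos == 1) next
    add("distance", c(i, refs[i, 1]))
    if (pos >= 3) add("angle", c(i, refs[i, 1], refs[i, 2]))
    if (pos >= 4) add("dihedral", c(i, refs[i, 1], refs[i, 2], refs[i, 3]))
  }
  do.call(rbind, rows)
}

#' @export
print.zmatrix_definition <- function(x, ...) {
  cat("<zmatrix_definition> ", x$n_atoms, " atoms, ", x$n_internal,
      " internal coordinates\n", sep = "")
  invisible(x)
}

#' Internal coordinates of a structure
#'
#' Measures the Z-matrix coordinates (distances in angstrom, angles and
#' dihedrals in radians) of a Cartesian structure.
#'
#' @param zdef A `zmatrix_definition`.
#' @param structure A `cartesian_structure` consistent with `zdef`.
#' @return Numeric vector of length `zdef$n_internal`, named by kind.
#' @export
cartesian_to_zmatrix <- function(zdef, structure) {
  x <- structure$coords
  lab <- zdef$labels
  q <- numeric(nrow(lab))
  for (r in seq_len(nrow(lab))) {
    a <- unlist(lab[r, c("a1", "a2", "a3", "a4")])
    q[r] <- switch(lab$kind[r],
                   distance = calc_distance(x[a[1], ], x[a[2], ]),
                   angle = calc_angle(x[a[1], ], x[a[2], ], x[a[3], ]),
                   dihedral = calc_dihedral(x[a[1], ], x[a[2], ],
                                            x[a[3], ], x[a[4], ]))
  }
  names(q) <- lab$kind
  q
}

check_internal_coords <- function(zdef, q) {
  kinds <- zdef$labels$kind
  if (length(q) != zdef$n_internal)
    stop("expected ", zdef$n_internal, " internal coordinates, got ", length(q))
  if (any(q[kinds == "distance"] <= 0)) stop("distances must be positive")
  ang <- q[kinds == "angle"]
  if (any(ang <= 0 | ang >= pi))
    stop("degenerate-dihedral error: bond angle at 0 or pi")
  invisible(TRUE)
}

#' Cartesian coordinates from internal coordinates
#'
#' Places the molecule with the deterministic convention: first reference
#' atom at the origin, second on +z, third in the xz-plane with positive x.
#' Later atoms are placed by the natural extension reference frame from
#' their distance/angle/dihedral references.
#'
#' @param zdef A `zmatrix_definition`.
#' @param q Internal coordinate vector in `zdef` order.
#' @return N x 3 coordinate matrix (angstrom) in the placement frame.
#' @export
zmatrix_to_cartesian <- function(zdef, q) {
  check_internal_coords(zdef, q)
  lab <- zdef$labels
  x <- matrix(NA_real_, zdef$n_atoms, 3)
  order <- zdef$atom_order
  x[order[1], ] <- c(0, 0, 0)
  ptr <- 1
  # second atom on +z
  x[order[2], ] <- c(0, 0, q[ptr]); ptr <- ptr + 1
  # third atom in the xz-plane, positive x
  i3 <- order[3]; d <- q[ptr]; th <- q[ptr + 1]; ptr <- ptr + 2
  dref <- zdef$refs[i3, 1]; aref <- zdef$refs[i3, 2]
  a <- unitv(x[aref, ] - x[dref, ])               # +z or -z
  x[i3, ] <- x[dref, ] + d * (cos(th) * a + sin(th) * c(1, 0, 0))
  for (pos in seq_along(order)[-(1:3)]) {
    i <- order[pos]
    d <- q[ptr]; th <- q[ptr + 1]; phi <- q[ptr + 2]; ptr <- ptr + 3
    A <- x[zdef$refs[i, 1], ]; B <- x[zdef$refs[i, 2], ]
    C <- x[zdef$refs[i, 3], ]
    x[i, ] <- place_atom(A, B, C, d, th, phi)
  }
  x
}

# Solve for r with |r-A| = d, angle(r,A,B) = th, dihedral(r,A,B,C) = phi.
place_atom <- function(A, B, C, d, th, phi) {
  axis <- unitv(B - A)
  pr <- (C - B) - sum((C - B) * axis) * axis
  if (vnorm(pr) < 1e-10)
    stop("degenerate-dihedral error: reference atoms collinear")
  p <- unitv(pr)
  nrm <- cross3(axis, p)
  v <- cos(th) * axis + sin(th) * (cos(phi) * p - sin(phi) * nrm)
  A + d * v
}

#' Jacobian of the placement map
#'
#' B[i, k] = d x_i / d q_k in the fixed placement frame of
#' [zmatrix_to_cartesian()], computed by Richardson-extrapolated central
#' differences (accurate to ~1e-10 relative for non-degenerate
#' geometries).  The raw columns are not orthogonal to the rigid-body
#' subspace; `rank(B) = Ns` holds because the placement frame pins six
#' degrees of freedom.
#'
#' @param zdef A `zmatrix_definition`.
#' @param q Internal coordinates.
#' @param h Base finite-difference step.
#' @return 3N x Ns matrix (rows in x1,y1,z1,x2,... order).
#' @export
coordinate_jacobian <- function(zdef, q, h = 1e-3) {
  f <- function(qq) as.vector(t(zmatrix_to_cartesian(zdef, qq)))
  ns <- zdef$n_internal
  B <- matrix(0, 3 * zdef$n_atoms, ns)
  for (k in seq_len(ns)) {
    B[, k] <- richardson_deriv(f, q, k, h)
  }
  B
}

#' Jacobian in the frame of a given structure
#'
#' Like [coordinate_jacobian()], but rotated into the Cartesian frame of
#' `structure` (via optimal rigid superposition of the placement-frame
#' geometry onto the input coordinates).  This is the Jacobian to pair
#' with a Hessian expressed in the input structure's own frame: the
#' resulting curvature matrix is then invariant under rigid motions of the
#' input.
#'
#' @param zdef A `zmatrix_definition`.
#' @param structure A `cartesian_structure`.
#' @return 3N x Ns matrix in the input frame.
#' @export
structure_jacobian <- function(zdef, structure) {
  q <- cartesian_to_zmatrix(zdef, structure)
  B <- coordinate_jacobian(zdef, q)
  xp <- zmatrix_to_cartesian(zdef, q)
  R <- kabsch_rotation(xp, structure$coords)
  kronecker(diag(nrow(xp)), R) %*% B
}

# rotation R minimizing || R P_centered - Q_centered ||_F
kabsch_rotation <- function(P, Q) {
  Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
  s <- svd(t(Qc) %*% Pc)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

richardson_deriv <- function(f, q, k, h) {
  cd <- function(hh) {
    qp <- q; qm <- q
    qp[k] <- qp[k] + hh; qm[k] <- qm[k] - hh
    (f(qp) - f(qm)) / (2 * hh)
  }
  (4 * cd(h / 2) - cd(h)) / 3
}

#' Internal curvature matrix from a Cartesian Hessian
#'
#' K = B^T H B, valid at a stationary point of the potential (the
#' gradient-dependent second-derivative term vanishes there; the model
#' assumes the structure is a representative energy minimum).  The result
#' is symmetrized.  Rigid-body modes are absent by construction because B
#' spans only internal deformations.  Eigenvalues below
#' `reg_tol * max(eigenvalue)` are floored to that threshold with a
#' warning, so the returned matrix is strictly positive definite;
#' eigenvalues below `-neg_tol * max(eigenvalue)` signal a non-minimum and
#' raise an error.
#'
#' @param H_cart Symmetric 3N x 3N Cartesian Hessian (energy per
#'   angstrom^2; any energy unit, carried through to K).
#' @param B Jacobian from [coordinate_jacobian()].
#' @param reg_tol Regularization floor, relative to the largest eigenvalue.
#' @param neg_tol Tolerance for negative eigenvalues.
#' @return Ns x Ns symmetric positive-definite curvature matrix, in the
#'   energy units of `H_cart` per (angstrom or radian)^2.
#' @export
hessian_to_curvature <- function(H_cart, B, reg_tol = 1e-8, neg_tol = 1e-6) {
  if (!isTRUE(all.equal(H_cart, t(H_cart), tolerance = 1e-8)))
    stop("input error: Cartesian Hessian is not symmetric")
  H_cart <- (H_cart + t(H_cart)) / 2
  K <- t(B) %*% H_cart %*% B
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  emax <- max(e$values)
  if (emax <= 0) stop("non-minimum error: curvature matrix has no positive mode")
  if (any(e$values < -neg_tol * emax))
    stop("non-minimum error: negative curvature eigenvalue ",
         format(min(e$values)))
  floorv <- reg_tol * emax
  if (any(e$values < floorv)) {
    warning("curvature eigenvalues below ", format(floorv),
            " floored (regularization)")
    vals <- pmax(e$values, floorv)
    K <- e$vectors %*% (vals * t(e$vectors))
    K <- (K + t(K)) / 2
  }
  K
}

#' Gradients of internal coordinates with respect to all Cartesians
#'
#' The Wilson B matrix (Ns x 3N): row k is the gradient of internal
#' coordinate k with respect to every Cartesian component.  Unlike
#' [coordinate_jacobian()], these rows are exactly orthogonal to rigid
#' translations and rotations, which makes this the natural tool for
#' constructing synthetic Hessians with known internal force constants.
#'
#' @param zdef A `zmatrix_definition`.
#' @param coords N x 3 Cartesian coordinates.
#' @param h Finite-difference step.
#' @return Ns x 3N matrix.
#' @export
wilson_b_matrix <- function(zdef, coords, h = 1e-4) {
  lab <- zdef$labels
  n <- zdef$n_atoms
  Bw <- matrix(0, nrow(lab), 3 * n)
  for (r in seq_len(nrow(lab))) {
    a <- unlist(lab[r, c("a1", "a2", "a3", "a4")])
    a <- a[!is.na(a)]
    fun <- switch(lab$kind[r], distance = calc_distance,
                  angle = calc_angle, dihedral = calc_dihedral)
    for (atom in a) {
      for (dim in 1:3) {
        cd <- function(hh) {
          pp <- coords; pm <- coords
          pp[atom, dim] <- pp[atom, dim] + hh
          pm[atom, dim] <- pm[atom, dim] - hh
          args_p <- unname(lapply(a, function(j) pp[j, ]))
          args_m <- unname(lapply(a, function(j) pm[j, ]))
          (do.call(fun, args_p) - do.call(fun, args_m)) / (2 * hh)
        }
        Bw[r, 3 * (atom - 1) + dim] <- (4 * cd(h / 2) - cd(h)) / 3
      }
    }
  }
  Bw
}
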