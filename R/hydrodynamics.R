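# Hydrodynamic bead model: Stokes-Einstein friction per bead,
# Rotne-Prager-Yamakawa coupling, and the generalized diffusion tensor over
# (translation +) rotation + internal Z-matrix coordinates.

#' Hydrodynamic parameters
#'
#' @param R_eff Hydrodynamic bead radius in angstrom (all beads equal).
#' @param C Boundary-condition coefficient: 6 = stick, 4 = slip.  The
#'   friction enters only through the product C*R*eta, so any positive
#'   value is accepted.
#' @param eta Solvent viscosity in Pa s.
#' @param temperature Temperature in K.
#' @return An object of class `hydro_params`.
#' @export
hydro_params <- function(R_eff = 2, C = 6, eta = 8.9e-4, temperature = 298.15) {
  stopifnot(R_eff > 0, C > 0, eta > 0, temperature > 0)
  out <- list(R_eff = R_eff, C = C, eta = eta, temperature = temperature)
  class(out) <- "hydro_params"
  out
}

#' Stokes-Einstein bead friction
#'
#' xi = C * pi * R * eta, the translational friction of a single bead.
#'
#' @param params A `hydro_params`.
#' @return Friction in kg/s.
#' @export
bead_friction <- function(params) {
  params$C * pi * (params$R_eff * 1e-10) * params$eta
}

#' Rotne-Prager-Yamakawa mobility matrix
#'
#' Cartesian 3N x 3N mobility for equal-radius beads.  Self blocks are
#' (1/xi) I with xi from [bead_friction()]; cross blocks use the RPY tensor
#' for non-overlapping spheres and the RPY overlapping-sphere branch for
#' separations below 2R (common at atomic bead radii), which keeps the
#' matrix positive definite.
#'
#' @param coords N x 3 bead coordinates in angstrom.
#' @param params A `hydro_params`.
#' @return 3N x 3N symmetric positive-definite mobility matrix (SI, s/kg).
#' @export
rotne_prager_mobility <- function(coords, params) {
  coords <- as.matrix(coords) * 1e-10   # to meters
  n <- nrow(coords)
  a <- params$R_eff * 1e-10
  eta <- params$eta
  xi <- bead_friction(params)
  M <- matrix(0, 3 * n, 3 * n)
  I3 <- diag(3)
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    M[ii, ii] <- I3 / xi
    if (i == n) next
    for (j in (i + 1):n) {
      jj <- (3 * j - 2):(3 * j)
      rij <- coords[j, ] - coords[i, ]
      r <- vnorm(rij)
      if (r < 1e-14) stop("coincident beads at indices ", i, ", ", j)
      rh <- rij / r
      P <- outer(rh, rh)
      if (r >= 2 * a) {
        blk <- (1 / (8 * pi * eta * r)) *
          ((1 + 2 * a^2 / (3 * r^2)) * I3 + (1 - 2 * a^2 / r^2) * P)
      } else {
        blk <- (1 / (6 * pi * eta * a)) *
          ((1 - 9 * r / (32 * a)) * I3 + (3 * r / (32 * a)) * P)
      }
      M[ii, jj] <- blk
      M[jj, ii] <- blk
    }
  }
  (M + t(M)) / 2
}

#' Geometry matrix mapping generalized to bead velocities
#'
#' Builds A (3N x (3 + 3 + Ns)) such that the stacked Cartesian bead
#' velocities (in m/s) are A %*% c(v_cm, omega, qdot) with v_cm in m/s,
#' omega in rad/s (about the weighted center), and qdot in angstrom/s or
#' rad/s for distance or angular coordinates.  Columns: an identity stack
#' (translation), cross-product operators -[r_i - r_c]x (rotation), and the
#' internal-coordinate Jacobian (scaled to meters).
#'
#' @param structure A `cartesian_structure`.
#' @param zdef Matching `zmatrix_definition`.
#' @param weights Per-bead weights for the rotation/translation reference
#'   point (default uniform: center of geometry).
#' @return 3N x (6 + Ns) matrix of full column rank for non-degenerate
#'   geometries.
#' @export
generalized_geometry_matrix <- function(structure, zdef = NULL,
                                        weights = NULL) {
  # work in the placement frame throughout, so that the rotation columns
  # and the internal Jacobian share one molecule-fixed frame and the
  # resulting tensor does not depend on the input's lab orientation;
  # zdef = NULL treats the assembly as rigid (translation + rotation only)
  if (is.null(zdef)) {
    ns <- 0L
    xpl <- structure$coords
  } else {
    ns <- zdef$n_internal
    q <- cartesian_to_zmatrix(zdef, structure)
    xpl <- zmatrix_to_cartesian(zdef, q)
  }
  x <- xpl * 1e-10
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- weights / sum(weights)
  cm <- colSums(x * weights)
  A <- matrix(0, 3 * n, 6 + ns)
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    A[ii, 1:3] <- diag(3)
    ri <- x[i, ] - cm
    A[ii, 4:6] <- -skew3(ri)
  }
  if (ns > 0) {
    B <- coordinate_jacobian(zdef, q)
    A[, 7:(6 + ns)] <- B * 1e-10
  }
  if (qr(A)$rank < 6 + ns)
    stop("degenerate-geometry error: geometry matrix is rank deficient")
  A
}

skew3 <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

#' Generalized hydrodynamic diffusion tensor
#'
#' Forms the generalized friction Xi = A^T M^-1 A over (translation,
#' rotation, internal) velocities, removes the translational rows/columns
#' by a Schur complement (equivalent to constraining zero total
#' hydrodynamic force), and returns D = kB*T * Xi_proj^-1 over the
#' remaining (3 + Ns) coordinates.
#'
#' @param structure A `cartesian_structure`.
#' @param zdef Matching `zmatrix_definition`.
#' @param params A `hydro_params`.
#' @param free_draining If TRUE, drop the Rotne-Prager cross blocks
#'   (diagonal mobility), mainly for validation.
#' @param weights Optional rotation reference weights, see
#'   [generalized_geometry_matrix()].
#' @return An object of class `generalized_diffusion_tensor`: list with
#'   `D` ((3+Ns) x (3+Ns), blocks D_RR in rad^2/s, D_SS in
#'   (angstrom or rad)^2/s, D_RS mixed), `D_trans` (the translational 3x3
#'   diffusion block before projection, m^2/s), and `n_internal`.
#' @export
hydro_diffusion_tensor <- function(structure, zdef = NULL, params,
                                   free_draining = FALSE, weights = NULL) {
  A <- generalized_geometry_matrix(structure, zdef, weights)
  ns <- if (is.null(zdef)) 0L else zdef$n_internal
  # mobility in the same (placement) frame as the geometry matrix
  xpl <- if (is.null(zdef)) structure$coords
         else zmatrix_to_cartesian(zdef, cartesian_to_zmatrix(zdef, structure))
  if (free_draining) {
    xi <- bead_friction(params)
    Xi <- xi * crossprod(A)
  } else {
    M <- rotne_prager_mobility(xpl, params)
    Minv <- solve(M)
    Xi <- t(A) %*% Minv %*% A
  }
  Xi <- (Xi + t(Xi)) / 2
  kT <- kBT(params$temperature)
  # Jacobi scaling: translational, rotational and internal columns differ
  # by ~1e-10 m/A factors, so invert the unit-diagonal scaled friction
  s <- 1 / sqrt(diag(Xi))
  Xis <- outer(s, s) * Xi
  Dfull <- tryCatch(kT * outer(s, s) * solve(Xis),
                    error = function(e)
                      stop("degenerate model error: singular generalized friction"))
  Dfull <- (Dfull + t(Dfull)) / 2
  # the rotational/internal sub-block of Xi^-1 equals the inverse of the
  # Schur complement of the translational block, i.e. the projection
  D <- Dfull[-(1:3), -(1:3), drop = FALSE]
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("degenerate model error: projected diffusion tensor not positive definite")
  out <- list(D = D, D_trans = Dfull[1:3, 1:3], n_internal = ns,
              params = params)
  class(out) <- "generalized_diffusion_tensor"
  out
}

#' @export
print.generalized_diffusion_tensor <- function(x, ...) {
  cat("<generalized_diffusion_tensor> 3 rotational + ", x$n_internal,
      " internal coordinates\n", sep = "")
  cat("  D_RR diagonal (s^-1): ",
      paste(format(diag(x$D)[1:3], digits = 4), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Extract blocks of a generalized diffusion tensor
#' @param Dg A `generalized_diffusion_tensor`.
#' @return List with `D_RR` (3x3), `D_SS` (Ns x Ns), `D_RS` (3 x Ns).
#' @export
diffusion_blocks <- function(Dg) {
  ns <- Dg$n_internal
  list(D_RR = Dg$D[1:3, 1:3, drop = FALSE],
       D_SS = Dg$D[3 + seq_len(ns), 3 + seq_len(ns), drop = FALSE],
       D_RS = Dg$D[1:3, 3 + seq_len(ns), drop = FALSE])
}

#' Write a generalized diffusion tensor to a labelled plain-text file
#' @param Dg A `generalized_diffusion_tensor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diffusion_tensor <- function(Dg, path) {
  con <- file(path, "w"); on.exit(close(con))
  cat("# generalized diffusion tensor: 3 rotational + ", Dg$n_internal,
      " internal rows/cols, s^-1 scale\n", sep = "", file = con)
  apply(Dg$D, 1, function(r)
    cat(paste(sprintf("%.17g", r), collapse = " "), "\n", file = con))
  invisible(path)
}
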