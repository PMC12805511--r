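# Assembly of the semiflexible-body (SFB) diffusion tensor in shifted
# coordinates, the z <-> q transformation, eigenvalue spectrum, coupling
# index, automatic BD scheduling, and the analytic 4x4 sandbox system.

sym_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix square root requires positive definiteness")
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

# eigen with ascending values and a reproducible sign convention
# (largest-magnitude component of each vector positive); an already
# diagonal matrix keeps its natural axes (sorting permutation) so that
# degenerate blocks do not pick up an arbitrary rotated basis
eigen_ascending <- function(M) {
  M <- (M + t(M)) / 2
  n <- nrow(M)
  offmax <- if (n > 1) max(abs(M - diag(diag(M), n))) else 0
  if (offmax <= 1e-13 * max(abs(diag(M)))) {
    idx <- order(diag(M))
    return(list(values = diag(M)[idx],
                vectors = diag(n)[, idx, drop = FALSE]))
  }
  e <- eigen(M, symmetric = TRUE)
  idx <- order(e$values)
  vals <- e$values[idx]
  vecs <- e$vectors[, idx, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(values = vals, vectors = vecs)
}

#' Assemble the SFB diffusion tensor in shifted coordinates
#'
#' Combines the hydrodynamic generalized diffusion tensor and the internal
#' curvature matrix into the (3 + Ns) x (3 + Ns) diffusion tensor governing
#' the dynamics in (orientation, z) coordinates.  The rotational block is
#' rotated into its principal (molecule-fixed) frame by `E`; the internal
#' block K^(1/2) D_SS K^(1/2) / kBT is diagonalized by the orthogonal
#' matrix `T`; the coupling block becomes E^T D_RS K^(1/2) T / sqrt(kBT).
#' The curvature scaling is applied symmetrically to the internal
#' rows/columns only, which keeps every block in s^-1 and reproduces the
#' sandbox tensor exactly.
#'
#' @param D_hydro A `generalized_diffusion_tensor`, or a plain
#'   (3+Ns) x (3+Ns) matrix.
#' @param K Ns x Ns positive-definite curvature matrix, in energy units
#'   consistent with `kT` per squared internal coordinate.
#' @param kT Thermal energy in the same energy units as `K`.
#' @param q0 Reference (minimum-energy) internal coordinates; defaults to
#'   zeros (as in dimensionless sandbox use).
#' @param zdef Optional `zmatrix_definition` carried for Cartesian
#'   reconstruction.
#' @return An object of class `sfb_model` with fields `D`, `E`, `Tmat`,
#'   `Ksqrt`, `q0`, `kT`, `n_internal`.
#' @export
assemble_diffusion <- function(D_hydro, K, kT, q0 = NULL, zdef = NULL) {
  if (inherits(D_hydro, "generalized_diffusion_tensor")) {
    Dh <- D_hydro$D
  } else {
    Dh <- as.matrix(D_hydro)
  }
  K <- as.matrix(K)
  ns <- nrow(K)
  stopifnot(nrow(Dh) == 3 + ns)
  if (is.null(q0)) q0 <- numeric(ns)
  if (ns == 0) {
    er <- eigen_ascending(Dh)
    E <- er$vectors
    if (det(E) < 0) E[, 1] <- -E[, 1]
    out <- list(D = diag(er$values, 3), E = E,
                Tmat = matrix(0, 0, 0), Ksqrt = matrix(0, 0, 0),
                q0 = q0, kT = kT, n_internal = 0L, zdef = zdef)
    class(out) <- "sfb_model"
    return(out)
  }
  D_RR <- Dh[1:3, 1:3]
  D_SS <- Dh[3 + seq_len(ns), 3 + seq_len(ns), drop = FALSE]
  D_RS <- Dh[1:3, 3 + seq_len(ns), drop = FALSE]

  Ksqrt <- sym_sqrt(K)
  S <- Ksqrt / sqrt(kT)

  er <- eigen_ascending(D_RR)
  E <- er$vectors
  if (det(E) < 0) E[, 1] <- -E[, 1]  # proper rotation
  Dzz <- S %*% D_SS %*% S
  ei <- eigen_ascending(Dzz)
  Tmat <- ei$vectors

  Drs <- t(E) %*% D_RS %*% S %*% Tmat
  D <- rbind(cbind(diag(er$values, 3), Drs),
             cbind(t(Drs), diag(ei$values, ns)))
  D <- (D + t(D)) / 2
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("model error: assembled diffusion tensor not positive definite ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  out <- list(D = D, E = E, Tmat = Tmat, Ksqrt = Ksqrt, q0 = q0, kT = kT,
              n_internal = ns, zdef = zdef)
  class(out) <- "sfb_model"
  out
}

#' @export
print.sfb_model <- function(x, ...) {
  sp <- mode_spectrum(x)
  cat("<sfb_model> 3 rotational + ", x$n_internal, " internal coordinates\n",
      "  eigenvalue range (s^-1): ", format(min(sp$omegas), digits = 5),
      " .. ", format(max(sp$omegas), digits = 5), "\n", sep = "")
  invisible(x)
}

#' Shifted-coordinate transformation
#'
#' `to_z` maps internal coordinates to the dimensionless shifted modes
#' z = (kBT)^(-1/2) T^T K^(1/2) (q - q0); `from_z` inverts the map
#' exactly.  At equilibrium each z component has zero mean and unit
#' variance.
#'
#' @param q Internal coordinate vector (or matrix, one column per frame).
#' @param model An `sfb_model`.
#' @return Vector/matrix of the same shape.
#' @export
to_z <- function(q, model) {
  qm <- as.matrix(q)
  z <- crossprod(model$Tmat, model$Ksqrt %*% (qm - model$q0)) / sqrt(model$kT)
  if (is.vector(q)) as.vector(z) else z
}

#' @rdname to_z
#' @param z Shifted-coordinate vector (or matrix, one column per frame).
#' @export
from_z <- function(z, model) {
  zm <- as.matrix(z)
  q <- model$q0 + sqrt(model$kT) *
    solve(model$Ksqrt, model$Tmat %*% zm)
  if (is.vector(z)) as.vector(q) else q
}

#' Eigenvalue spectrum of the SFB diffusion tensor
#'
#' The eigenvalues of D are the effective frequencies of the motions; the
#' slowest rank-2 relaxation time is estimated as tau = 1/(6 * min(omega))
#' (the bare 1/min(omega) convention is also reported), the fastest time
#' scale as 1/max(omega).
#'
#' @param model An `sfb_model`.
#' @return An object of class `mode_spectrum`: list with `omegas`
#'   (ascending, s^-1), `vectors`, `tau_slow`, `tau_slow_plain`,
#'   `t_fast`.
#' @export
mode_spectrum <- function(model) {
  e <- eigen_ascending(model$D)
  if (min(e$values) <= 0) stop("non-positive eigenvalue in diffusion tensor")
  out <- list(omegas = e$values, vectors = e$vectors,
              tau_slow = 1 / (6 * min(e$values)),
              tau_slow_plain = 1 / min(e$values),
              t_fast = 1 / max(e$values))
  class(out) <- "mode_spectrum"
  out
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat("<mode_spectrum> ", length(x$omegas), " modes\n", sep = "")
  cat("  omegas (s^-1):", format(x$omegas, digits = 5), "\n")
  cat("  tau_slow = 1/(6 min w) =", format(x$tau_slow, digits = 5), "s\n")
  invisible(x)
}

#' Coupling index of internal modes to rotation
#'
#' For each shifted coordinate z_j, CI_j sums the normalized magnitudes of
#' its coupling to the three rotational rows,
#' T_ij = |D[i, j+3]| / sqrt(D[i, i] * D[j+3, j+3]), normalized over all
#' internal coordinates so the indices sum to 1 whenever any coupling is
#' present.  CI_j = 0 iff column j of the rotational-internal block is
#' zero.
#'
#' @param model An `sfb_model`.
#' @return Numeric vector of length Ns, each entry in [0, 1].
#' @export
coupling_index <- function(model) {
  D <- model$D
  ns <- model$n_internal
  Tm <- matrix(0, 3, ns)
  for (i in 1:3)
    for (j in seq_len(ns))
      Tm[i, j] <- abs(D[i, j + 3]) / sqrt(D[i, i] * D[j + 3, j + 3])
  tot <- sum(Tm)
  if (tot == 0) return(numeric(ns))
  colSums(Tm) / tot
}

#' Automatic BD schedule from the mode spectrum
#'
#' Default scheduling: time step dt = 1/(2 max(omega)) for the
#' Runge-Kutta scheme or 1/(10 max(omega)) for Euler; per-trajectory
#' length 1000 * tau with tau = 1/(tau_factor * min(omega)); 20
#' trajectories; dump stride chosen so each trajectory yields about
#' `n_dump_target` snapshots.  All defaults can be overridden; a
#' user-supplied dt above the stability bound only triggers a warning.
#'
#' @param spectrum A `mode_spectrum`.
#' @param scheme `"runge_kutta"` or `"euler"`.
#' @param dt Optional time step override (s).
#' @param t_total Optional per-trajectory length override (s).
#' @param n_trajectories Number of trajectories (default 20).
#' @param n_dump_target Target snapshots per trajectory (default 1e4).
#' @param tau_factor 6 for the rank-2 correlation-time convention
#'   (default), 1 for the bare inverse-eigenvalue convention.
#' @return An object of class `bd_schedule`: list with `dt`, `n_steps`,
#'   `dump_stride`, `n_trajectories`, `scheme`, `tau`, `t_total`.
#' @export
make_schedule <- function(spectrum, scheme = c("runge_kutta", "euler"),
                          dt = NULL, t_total = NULL, n_trajectories = 20,
                          n_dump_target = 1e4, tau_factor = 6) {
  scheme <- match.arg(scheme)
  wmax <- max(spectrum$omegas); wmin <- min(spectrum$omegas)
  dt_bound <- if (scheme == "runge_kutta") 1 / (2 * wmax) else 1 / (10 * wmax)
  if (is.null(dt)) dt <- dt_bound
  else if (dt > dt_bound * (1 + 1e-12))
    warning("dt = ", format(dt), " exceeds the ", scheme,
            " stability bound ", format(dt_bound))
  tau <- 1 / (tau_factor * wmin)
  if (is.null(t_total)) t_total <- 1000 * tau
  n_steps <- max(1L, as.integer(ceiling(t_total / dt)))
  dump_stride <- max(1L, as.integer(round(n_steps / n_dump_target)))
  out <- list(dt = dt, n_steps = n_steps, dump_stride = dump_stride,
              n_trajectories = as.integer(n_trajectories), scheme = scheme,
              tau = tau, t_total = t_total)
  class(out) <- "bd_schedule"
  out
}

#' @export
print.bd_schedule <- function(x, ...) {
  cat("<bd_schedule> ", x$scheme, ": dt = ", format(x$dt, digits = 6),
      ", ", x$n_steps, " steps x ", x$n_trajectories,
      " trajectories, dump every ", x$dump_stride, " steps\n", sep = "")
  invisible(x)
}

#' Analytic sandbox system
#'
#' A minimal SFB system with three rotational coordinates and one internal
#' coordinate, in units scaled by the isotropic rotational diffusion rate:
#' the rotational block is the identity, the internal hydrodynamic
#' coefficient is 10, the only coupling (strength `c`) is to the D_ZZ
#' rotational entry, and the curvature is the scalar force constant `k` in
#' kBT units.  The resulting tensor is
#' `rbind(c(1,0,0,0), c(0,1,0,0), c(0,0,1,c*sqrt(k)), c(0,0,c*sqrt(k),10*k))`
#' with closed-form eigenvalues returned by [sandbox_eigenvalues()].
#'
#' @param c_coupling Dimensionless hydrodynamic coupling in [0, 1].
#' @param k Dimensionless force constant > 0.
#' @return An `sfb_model` (dimensionless; kT = 1).
#' @export
sandbox_model <- function(c_coupling, k) {
  stopifnot(k > 0, c_coupling >= 0)
  if (c_coupling^2 >= 10)
    stop("parameter error: sandbox tensor not positive definite (c^2 >= 10)")
  D_hydro <- rbind(c(1, 0, 0, 0),
                   c(0, 1, 0, 0),
                   c(0, 0, 1, c_coupling),
                   c(0, 0, c_coupling, 10))
  assemble_diffusion(D_hydro, K = matrix(k), kT = 1)
}

#' @rdname sandbox_model
#' @return For `sandbox_eigenvalues`: the four closed-form eigenvalues in
#'   ascending order.
#' @export
sandbox_eigenvalues <- function(c_coupling, k) {
  disc <- sqrt((1 - 10 * k)^2 + 4 * k * c_coupling^2)
  c((1 + 10 * k - disc) / 2, 1, 1, (1 + 10 * k + disc) / 2)
}

#' Human-readable spectrum and coupling report
#'
#' @param model An `sfb_model`.
#' @return Data frame with mode frequencies; internal modes carry their
#'   coupling index.
#' @export
spectrum_report <- function(model) {
  sp <- mode_spectrum(model)
  ci <- coupling_index(model)
  diag_w <- diag(model$D)
  data.frame(
    coordinate = c("rot_X", "rot_Y", "rot_Z",
                   paste0("z_", seq_len(model$n_internal))),
    diffusion_rate = diag_w,
    coupling_index = c(NA, NA, NA, ci)
  )
}

#' Serialize an SFB model to a labelled plain-text file
#' @param model An `sfb_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sfb_model <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  wmat <- function(name, M) {
    cat("[", name, "] ", nrow(M), " ", ncol(M), "\n", sep = "", file = con)
    apply(as.matrix(M), 1, function(r)
      cat(paste(sprintf("%.17g", r), collapse = " "), "\n", file = con))
  }
  cat("# sfb_model: kT = ", sprintf("%.17g", model$kT), " J, Ns = ",
      model$n_internal, "\n", sep = "", file = con)
  wmat("D", model$D); wmat("E", model$E); wmat("T", model$Tmat)
  wmat("Ksqrt", model$Ksqrt); wmat("q0", matrix(model$q0, nrow = 1))
  invisible(path)
}
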