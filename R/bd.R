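# Brownian dynamics propagation in (quaternion, z) coordinates: Euler and
# Runge-Kutta schemes with exact quaternion renormalization via a Lagrange
# multiplier.  Single steps are implemented in R (reference
# implementation); trajectories run through the compiled core, which
# consumes R's RNG stream so that both paths are bit-identical under the
# same seed.

#' Quaternion kinematic matrices
#'
#' `b_matrix` is the 4 x 3 matrix mapping a body-frame angular velocity to
#' the quaternion time derivative,
#' b(Q) = 1/2 * rbind(c(-Q1,-Q2,-Q3), c(Q0,-Q3,Q2), c(Q3,Q0,-Q1),
#' c(-Q2,Q1,Q0)).  `w_matrix` embeds it block-diagonally with an identity
#' on the internal rows, giving the (4+Ns) x (3+Ns) projection of
#' generalized increments onto the (quaternion, z) state.
#'
#' @param Q Length-4 quaternion (normalization not required for
#'   evaluation).
#' @return `b_matrix`: 4 x 3 matrix.
#' @export
b_matrix <- function(Q) {
  0.5 * matrix(c(-Q[2], -Q[3], -Q[4],
                 Q[1], -Q[4], Q[3],
                 Q[4], Q[1], -Q[2],
                 -Q[3], Q[2], Q[1]), 4, 3, byrow = TRUE)
}

#' @rdname b_matrix
#' @param ns Number of internal coordinates.
#' @return `w_matrix`: (4+ns) x (3+ns) matrix.
#' @export
w_matrix <- function(Q, ns) {
  W <- matrix(0, 4 + ns, 3 + ns)
  W[1:4, 1:3] <- b_matrix(Q)
  if (ns > 0) W[4 + seq_len(ns), 3 + seq_len(ns)] <- diag(ns)
  W
}

#' Quaternion renormalization by Lagrange multiplier
#'
#' Given the previous unit quaternion and the raw increment `Q_tilde`, the
#' multiplier lambda solves lambda^2 + 2*lambda*(Q_prev . Q_tilde) +
#' |Q_tilde|^2 = 1 and the updated quaternion Q_tilde + lambda * Q_prev
#' has unit norm exactly.  The root closer to +1 is selected (continuity
#' with the previous orientation).
#'
#' @param Q_prev Unit quaternion before the step.
#' @param Q_tilde Length-4 raw increment.
#' @return List with `lambda` and `Q_new`.
#' @export
lagrange_renormalize <- function(Q_prev, Q_tilde) {
  p <- sum(Q_prev * Q_tilde)
  disc <- p * p - sum(Q_tilde * Q_tilde) + 1
  if (disc < 0)
    stop("step-size error: quaternion renormalization has no real solution; ",
         "reduce dt")
  lambda <- -p + sqrt(disc)
  list(lambda = lambda, Q_new = Q_tilde + lambda * Q_prev)
}

# cache D^(1/2) (lower Cholesky factor) on the model; D is
# configuration-independent so this is computed once
model_dsqrt <- function(model) {
  if (is.null(model$Dsqrt)) t(chol(model$D)) else model$Dsqrt
}

#' Prepare a model for propagation
#'
#' Precomputes the Cholesky square root of D used for the random
#' displacement.
#' @param model An `sfb_model`.
#' @return The model with a `Dsqrt` field.
#' @export
bd_prepare <- function(model) {
  model$Dsqrt <- model_dsqrt(model)
  model
}

#' Single Brownian-dynamics steps
#'
#' Reference (R-level) implementations of the Euler and Runge-Kutta
#' updates.  The increment is
#' -dt * W(Q) D (0_3, z) + sqrt(2 dt) W(Q) D^(1/2) n, the previous state
#' is added on the internal rows, and the quaternion is renormalized
#' exactly.  The Runge-Kutta step evaluates a virtual Euler point with the
#' same noise vector and averages drift and noise-projection matrices
#' between the start and virtual points; the virtual quaternion is
#' renormalized before evaluating W there.
#'
#' @param state List with `Q` (unit quaternion), `z` (length-Ns vector),
#'   `t` (time, s).
#' @param model An `sfb_model` (ideally from [bd_prepare()]).
#' @param dt Time step, s.
#' @param noise Standard-Gaussian vector of length 3 + Ns.
#' @return Updated state list.
#' @export
euler_step <- function(state, model, dt, noise) {
  ns <- model$n_internal
  Dsq <- model_dsqrt(model)
  W <- w_matrix(state$Q, ns)
  drift <- model$D %*% c(0, 0, 0, state$z)
  incr <- -dt * (W %*% drift) + sqrt(2 * dt) * (W %*% (Dsq %*% noise))
  ren <- lagrange_renormalize(state$Q, incr[1:4])
  znew <- state$z + incr[4 + seq_len(ns)]
  list(Q = ren$Q_new, z = znew, t = state$t + dt)
}

#' @rdname euler_step
#' @export
rk_step <- function(state, model, dt, noise) {
  ns <- model$n_internal
  Dsq <- model_dsqrt(model)
  W1 <- w_matrix(state$Q, ns)
  u <- Dsq %*% noise
  drift1 <- model$D %*% c(0, 0, 0, state$z)
  # virtual Euler jump with the same noise
  incr1 <- -dt * (W1 %*% drift1) + sqrt(2 * dt) * (W1 %*% u)
  renv <- lagrange_renormalize(state$Q, incr1[1:4])
  z_e <- state$z + incr1[4 + seq_len(ns)]
  W2 <- w_matrix(renv$Q_new, ns)
  drift2 <- model$D %*% c(0, 0, 0, z_e)
  incr <- -dt / 2 * (W1 %*% drift1 + W2 %*% drift2) +
    sqrt(2 * dt) / 2 * ((W1 + W2) %*% u)
  ren <- lagrange_renormalize(state$Q, incr[1:4])
  list(Q = ren$Q_new, z = state$z + incr[4 + seq_len(ns)],
       t = state$t + dt)
}

#' Run a Brownian-dynamics trajectory
#'
#' Propagates the (quaternion, z) state over the schedule, dumping every
#' `dump_stride` steps (the initial state is the first snapshot).  The
#' initial z is drawn from the standard Gaussian and the initial
#' orientation uniformly on SO(3) (quaternion from a normalized 4D
#' Gaussian), i.e. from the equilibrium distribution.  Identical seed and
#' schedule give bit-identical trajectories.  Propagation aborts with a
#' step-size diagnosis if any |z_i| exceeds 10 standard deviations.
#'
#' @param model An `sfb_model`.
#' @param schedule A `bd_schedule`.
#' @param seed Integer RNG seed.
#' @return An object of class `bd_trajectory`: list with `times`, `Q`
#'   (n x 4), `z` (n x Ns), `seed`, `schedule`.
#' @export
run_trajectory <- function(model, schedule, seed) {
  model <- bd_prepare(model)
  ns <- model$n_internal
  set.seed(as.integer(seed))
  z0 <- rnorm(ns)
  q0 <- rnorm(4)
  q0 <- q0 / sqrt(sum(q0^2))
  res <- bd_core(model$D, model$Dsqrt, q0, z0, schedule$dt,
                 as.integer(schedule$n_steps),
                 as.integer(schedule$dump_stride),
                 schedule$scheme == "runge_kutta")
  out <- list(times = res$times, Q = res$Q, z = res$z,
              seed = as.integer(seed), schedule = schedule)
  class(out) <- "bd_trajectory"
  out
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat("<bd_trajectory> ", nrow(x$Q), " snapshots, dt = ",
      format(x$schedule$dt, digits = 5), " s, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Run an ensemble of independent trajectories
#'
#' Trajectory i uses seed `master_seed + i - 1` (documented, reproducible
#' derivation).
#'
#' @param model An `sfb_model`.
#' @param schedule A `bd_schedule`.
#' @param master_seed Integer master seed.
#' @param n Number of trajectories (default: `schedule$n_trajectories`).
#' @return List of `bd_trajectory`.
#' @export
run_ensemble <- function(model, schedule, master_seed, n = NULL) {
  if (is.null(n)) n <- schedule$n_trajectories
  lapply(seq_len(n), function(i)
    run_trajectory(model, schedule, as.integer(master_seed) + i - 1L))
}

#' Convert a trajectory to Cartesian frames
#'
#' Maps each dumped (Q, z) snapshot to laboratory-frame Cartesian
#' coordinates: z -> q (inverse shifted-coordinate map), q -> placement
#' frame, rotation into the principal rotational frame by E, then the
#' quaternion rotation into the LF.
#'
#' @param traj A `bd_trajectory`.
#' @param model The `sfb_model` used to generate it (must carry `zdef`).
#' @return List of N x 3 coordinate matrices, one per snapshot.
#' @export
trajectory_to_cartesian <- function(traj, model) {
  if (is.null(model$zdef))
    stop("model carries no zmatrix_definition; cannot rebuild Cartesians")
  qmat <- from_z(t(traj$z), model)   # Ns x nframes
  lapply(seq_len(nrow(traj$Q)), function(i) {
    xp <- zmatrix_to_cartesian(model$zdef, qmat[, i])
    R <- quat_to_rotmat(traj$Q[i, ])
    t(R %*% (t(model$E) %*% t(xp)))
  })
}

#' Write a trajectory to a plain-text table
#'
#' Columns: time, Q0..Q3, z_1..z_Ns; tab-separated with a header.
#'
#' @param traj A `bd_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  m <- cbind(traj$times, traj$Q, traj$z)
  colnames(m) <- c("time", paste0("Q", 0:3),
                   paste0("z", seq_len(ncol(traj$z))))
  utils::write.table(format(m, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
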