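# NMR observables: probe detection, dipolar-frame extraction, rank-2
# correlation functions, multiexponential fits, Lorentzian spectral
# densities, and dipolar(+CSA) relaxation (T1, T2, NOE).

#' Detect NMR probes from bonding topology
#'
#' Scans the bond list for C-H (nucleus "13C1H") or N-H (nucleus "15N1H")
#' pairs.  Each probe records the hydrogen, the heavy atom, and the
#' substituent X (the first non-hydrogen neighbour of the heavy atom),
#' which defines the dipolar-frame y axis.  A carbon bearing exactly two
#' hydrogens yields two probes flagged as a CH2 pair.  Heavy atoms with no
#' non-hydrogen substituent are skipped with a warning.
#'
#' @param structure A `cartesian_structure`.
#' @param nucleus `"13C1H"` or `"15N1H"`.
#' @param bond_length Effective bond length in angstrom (default 1.13,
#'   accounting for librational averaging).
#' @param delta_csa CSA anisotropy in ppm (default 0 = no CSA mechanism).
#' @param csa_tilt Euler angles of the CSA frame relative to the dipolar
#'   frame; carried as metadata (pass-through).
#' @return List of `nmr_probe` objects.
#' @export
detect_probes <- function(structure, nucleus = "13C1H", bond_length = 1.13,
                          delta_csa = 0, csa_tilt = c(0, 0, 0)) {
  heavy_el <- switch(nucleus, "13C1H" = "C", "15N1H" = "N",
                     stop("unsupported nucleus: ", nucleus))
  kind <- if (heavy_el == "C") "CH" else "NH"
  el <- toupper(substr(structure$elements, 1, 1))
  nb <- bond_neighbours(structure)
  probes <- list()
  for (heavy in which(el == heavy_el)) {
    hs <- nb[[heavy]][el[nb[[heavy]]] == "H"]
    if (!length(hs)) next
    xs <- nb[[heavy]][el[nb[[heavy]]] != "H"]
    if (!length(xs)) {
      warning("probe at atom ", heavy,
              " skipped: no non-hydrogen substituent to define X")
      next
    }
    ch2 <- (heavy_el == "C" && length(hs) == 2)
    for (h in hs) {
      p <- list(kind = kind, H = h, heavy = heavy, X = xs[1],
                is_ch2 = ch2, bond_length = bond_length,
                delta_csa = delta_csa, csa_tilt = csa_tilt,
                nucleus = nucleus)
      class(p) <- "nmr_probe"
      probes[[length(probes) + 1]] <- p
    }
  }
  probes
}

#' @export
print.nmr_probe <- function(x, ...) {
  cat("<nmr_probe> ", x$kind, if (x$is_ch2) " (CH2)", ": H", x$H,
      "-", x$heavy, " (X = ", x$X, ")\n", sep = "")
  invisible(x)
}

#' Dipolar frame of a bond probe
#'
#' Builds the magnetic (dipolar) frame: Z along the heavy-H bond, Y
#' perpendicular to the H-heavy-X plane, X by the right-hand rule.
#'
#' @param H_pos,C_pos,X_pos Length-3 positions (LF) of the hydrogen, the
#'   heavy atom, and the substituent.
#' @return List with `R` (3 x 3; columns are the dipolar axes in the LF,
#'   i.e. the rotation taking dipolar-frame to LF coordinates) and
#'   `euler` (ZYZ angles of the LF -> dipolar rotation).
#' @export
dipolar_frame <- function(H_pos, C_pos, X_pos) {
  zax <- unitv(H_pos - C_pos)
  yraw <- cross3(H_pos - C_pos, X_pos - C_pos)
  if (vnorm(yraw) < 1e-10)
    stop("degenerate-frame error: H, heavy atom and X are collinear")
  yax <- unitv(yraw)
  xax <- cross3(yax, zax)
  R <- unname(cbind(xax, yax, zax))
  list(R = R, euler = rotmat_to_euler_zyz(R))
}

#' Rank-2 Wigner functions with first index zero
#'
#' `wigner_d2_00` is the real function (3 cos^2(beta) - 1)/2;
#' `wigner_d2_0m` the complex D^2_{0m}(Omega) = d^2_{0m}(beta)
#' exp(-i m gamma) (the alpha dependence vanishes for first index 0).
#'
#' @param Omega Euler angles (alpha, beta, gamma), ZYZ; for
#'   `wigner_d2_00` a plain beta value is also accepted via `beta`.
#' @return Numeric (`wigner_d2_00`) or complex (`wigner_d2_0m`) value.
#' @export
wigner_d2_00 <- function(Omega = NULL, beta = NULL) {
  if (is.null(beta)) beta <- Omega[2]
  (3 * cos(beta)^2 - 1) / 2
}

#' @rdname wigner_d2_00
#' @param m Second index, in -2..2.
#' @export
wigner_d2_0m <- function(Omega, m) {
  stopifnot(m %in% -2:2)
  beta <- Omega[2]; gamma <- Omega[3]
  s <- sin(beta); c <- cos(beta)
  d <- switch(as.character(m),
              "0" = (3 * c^2 - 1) / 2,
              "1" = sqrt(3 / 2) * s * c,
              "-1" = -sqrt(3 / 2) * s * c,
              "2" = sqrt(3 / 8) * s^2,
              "-2" = sqrt(3 / 8) * s^2)
  d * exp(-1i * m * gamma)
}

#' Rank-2 autocorrelation function
#'
#' C(t) = 5 <D2_00(Omega(t+s)) D2_00(Omega(s))>, averaged over all time
#' origins s (unbiased per-lag normalization, FFT-based) and over
#' trajectories.  The factor 5 cancels the uniform-measure second moment
#' <|D2_00|^2> = 1/5 so that C(0) = 1 within Monte-Carlo error at
#' equilibrium.  Lags are capped at half the series length, where the
#' all-origins estimator is reliable.
#'
#' @param series_list Numeric vector or list of vectors (one per
#'   trajectory) of D2_00 values at the dump resolution.
#' @param dt Time between consecutive snapshots (s).
#' @param lag_frac Maximum lag as a fraction of the series length.
#' @return An object of class `acf_rank2`: list with `lags` (s), `values`,
#'   `n_traj`.
#' @export
rank2_acf <- function(series_list, dt, lag_frac = 0.5) {
  if (!is.list(series_list)) series_list <- list(series_list)
  n <- length(series_list[[1]])
  if (n < 2) stop("need at least 2 snapshots for an autocorrelation")
  stopifnot(all(vapply(series_list, length, 1L) == n))
  nlag <- max(2L, as.integer(floor(n * lag_frac)))
  acc <- numeric(nlag)
  for (x in series_list) {
    r <- acf_sums_fft(x)[seq_len(nlag)]
    acc <- acc + r / (n - seq_len(nlag) + 1)
  }
  vals <- 5 * acc / length(series_list)
  out <- list(lags = (seq_len(nlag) - 1) * dt, values = vals,
              n_traj = length(series_list))
  class(out) <- "acf_rank2"
  out
}

# lag sums r[k+1] = sum_i x_i x_{i+k} via FFT with zero padding
acf_sums_fft <- function(x) {
  n <- length(x)
  m <- 2^ceiling(log2(2 * n))
  xp <- c(x, rep(0, m - n))
  f <- fft(xp)
  Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / m
}

#' @export
print.acf_rank2 <- function(x, ...) {
  cat("<acf_rank2> ", length(x$lags), " lags, C(0) = ",
      format(x$values[1], digits = 5), ", ", x$n_traj, " trajectories\n",
      sep = "")
  invisible(x)
}

#' Multiexponential fit of a correlation function
#'
#' Fits C(t) ~ sum_k a_k exp(-t/tau_k) with nonnegative weights and
#' positive time constants.  The fit is separable least squares: a
#' Nelder-Mead search over log time constants with the weights solved at
#' each step by nonnegative least squares, followed by a
#' Levenberg-Marquardt polish of the active components.  The initial
#' guess places the time constants log-spaced between the dump resolution
#' and the longest lag; supplying `tau_init` overrides it (the escape
#' hatch when the automatic guess fails).
#'
#' @param acf An `acf_rank2` (or list with `lags`, `values`).
#' @param n_exp Number of exponentials, 1 to 5 (default 4).
#' @param tau_init Optional vector of initial time constants.
#' @param tau_max Upper bound on the time constants.  A decay slower than
#'   the observation window is not identifiable from the data, and a
#'   near-flat component fitted to correlated tail noise corrupts J(0)
#'   badly; when the generating mode spectrum is known, the slowest
#'   physical rank-2 time 1/(6 min(omega)) bounds every genuine component
#'   and a small multiple of it is the natural cap (the pipeline passes
#'   5x that time).  Default: 10x the longest lag.
#' @return An object of class `multi_exp_model`: `a` (weights, >= 0),
#'   `tau` (sorted ascending, s), `rss`, `fitted`.
#' @export
multiexp_fit <- function(acf, n_exp = 4, tau_init = NULL, tau_max = NULL) {
  stopifnot(n_exp >= 1, n_exp <= 5)
  t <- acf$lags; y <- acf$values
  if (y[1] <= 0) stop("C(0) must be positive for a multiexponential fit")
  pos_t <- t[t > 0]
  if (is.null(tau_max)) tau_max <- 10 * max(t)
  if (is.null(tau_init)) {
    tau_init <- exp(seq(log(min(pos_t)),
                        log(min(max(t), tau_max)), length.out = n_exp))
  }
  stopifnot(length(tau_init) == n_exp)

  design <- function(tau) outer(t, tau, function(tt, tk) exp(-tt / tk))
  clamp <- function(tau) pmin(tau, tau_max)
  obj <- function(ltau) {
    X <- design(clamp(exp(ltau)))
    w <- nnls_fit(X, y)
    sum((y - X %*% w)^2)
  }
  if (n_exp == 1) {
    opt <- stats::optimize(obj, interval = log(c(min(pos_t) / 10,
                                                 min(max(t) * 10, tau_max))),
                           tol = 1e-12)
    tau <- clamp(exp(opt$minimum))
  } else {
    opt <- optim(log(tau_init), obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    tau <- clamp(exp(opt$par))
  }
  a <- nnls_fit(design(tau), y)

  # prune inactive / duplicate components, then LM-polish
  keep <- a > 1e-9 * max(a)
  tau <- tau[keep]; a <- a[keep]
  o <- order(tau); tau <- tau[o]; a <- a[o]
  if (length(tau) > 1) {
    dup <- c(FALSE, diff(log(tau)) < 1e-3)
    if (any(dup)) {
      for (i in which(dup)) a[i - 1] <- a[i - 1] + a[i]
      tau <- tau[!dup]; a <- a[!dup]
    }
  }
  polished <- polish_lm(t, y, a, tau, tau_max)
  a <- polished$a; tau <- polished$tau
  o <- order(tau); tau <- tau[o]; a <- a[o]
  fitted <- as.vector(outer(t, tau, function(tt, tk) exp(-tt / tk)) %*% a)
  rss <- sum((y - fitted)^2)
  # convergence judged on the signal window (|C| above 10% of C(0)); the
  # tail carries correlated noise whose bulk depends only on how many
  # lags were recorded
  sig <- abs(y) > 0.1 * abs(y[1])
  rel <- sum((y[sig] - fitted[sig])^2) / sum(y[sig]^2)
  if (!any(sig) || rel > 0.2)
    stop("multiexponential fit did not converge (relative RSS ",
         format(rel, digits = 3),
         " on the signal window); supply a different tau_init initial guess")
  out <- list(a = a, tau = tau, n_exp = length(tau), rss = rss,
              fitted = fitted, lags = t)
  class(out) <- "multi_exp_model"
  out
}

# nonnegative least squares (unconstrained fast path, else Lawson-Hanson
# via pracma)
nnls_fit <- function(X, y) {
  fit <- tryCatch(stats::coef(stats::lm.fit(X, y)), error = function(e) NULL)
  if (!is.null(fit) && !anyNA(fit) && all(fit >= 0)) return(as.vector(fit))
  as.vector(pracma::lsqnonneg(X, y)$x)
}

polish_lm <- function(t, y, a, tau, tau_max = Inf) {
  k <- length(tau)
  if (k == 0) return(list(a = a, tau = tau))
  df <- data.frame(t = t, y = y)
  terms <- paste0("a", seq_len(k), " * exp(-t / tau", seq_len(k), ")")
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  start <- c(as.list(setNames(a, paste0("a", seq_len(k)))),
             as.list(setNames(tau, paste0("tau", seq_len(k)))))
  lower <- c(rep(0, k), rep(min(tau) * 1e-3, k))
  upper <- c(rep(Inf, k), rep(tau_max, k))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(a = a, tau = tau))
  cf <- stats::coef(fit)
  list(a = pmax(cf[seq_len(k)], 0), tau = pmin(cf[k + seq_len(k)], tau_max))
}

#' @export
print.multi_exp_model <- function(x, ...) {
  cat("<multi_exp_model> ", x$n_exp, " components, rss = ",
      format(x$rss, digits = 4), "\n", sep = "")
  for (i in seq_along(x$a))
    cat(sprintf("  tau = %-12.5g  weight = %.5g\n", x$tau[i], x$a[i]))
  invisible(x)
}

#' Lorentzian-sum spectral density
#'
#' J(omega) = sum_k a_k * 2 tau_k / (1 + omega^2 tau_k^2), the cosine
#' Fourier transform of the multiexponential correlation function.  Even
#' in omega, nonnegative for nonnegative weights; J(0) = 2 sum a_k tau_k.
#'
#' @param fit A `multi_exp_model`.
#' @param omega Angular frequencies (rad/s), any sign.
#' @return Numeric vector of J values (s/rad scale).
#' @export
spectral_density <- function(fit, omega) {
  vapply(omega, function(w)
    sum(fit$a * 2 * fit$tau / (1 + w^2 * fit$tau^2)), numeric(1))
}

#' NMR relaxation from a spectral density
#'
#' Standard dipolar (+ optional axially symmetric CSA) expressions for an
#' isolated X-H spin pair, with the interaction strength
#' d = (mu0/4pi) gamma_H gamma_X hbar / r^3 and the correlation function
#' normalized to 1 at t = 0:
#' 1/T1 = (d^2/4) (J(wH-wX) + 3 J(wX) + 6 J(wH+wX)) + c^2 J(wX),
#' 1/T2 = (d^2/8) (4 J(0) + J(wH-wX) + 3 J(wX) + 6 J(wH) + 6 J(wH+wX))
#'        + (c^2/6) (4 J(0) + 3 J(wX)),
#' NOE = 1 + (gamma_H/gamma_X) (d^2/4) (6 J(wH+wX) - J(wH-wX)) T1,
#' with c^2 = (2/15) wX^2 deltaCSA^2 (zero when deltaCSA = 0).
#'
#' @param fit A `multi_exp_model` (normalized correlation fit).
#' @param probe An `nmr_probe` (bond length, deltaCSA, nucleus).
#' @param fields 1H spectrometer frequencies in MHz.
#' @param calculate Subset of c("T1", "T2", "NOE").
#' @return Data frame with one row per field: `field_MHz`, `T1_ms`,
#'   `T2_ms`, `NOE` (requested columns only).
#' @export
relaxation <- function(fit, probe, fields, calculate = c("T1", "T2", "NOE")) {
  gH <- .const$gamma[["1H"]]
  gX <- switch(probe$nucleus, "13C1H" = .const$gamma[["13C"]],
               "15N1H" = .const$gamma[["15N"]],
               stop("unsupported nucleus: ", probe$nucleus))
  r <- probe$bond_length * 1e-10
  d <- .const$mu0_4pi * gH * gX * .const$hbar / r^3
  rows <- lapply(fields, function(f) {
    wH <- 2 * pi * f * 1e6
    wX <- wH * gX / gH
    J <- function(w) spectral_density(fit, abs(w))
    c2 <- (2 / 15) * wX^2 * (probe$delta_csa * 1e-6)^2
    R1 <- (d^2 / 4) * (J(wH - wX) + 3 * J(wX) + 6 * J(wH + wX)) + c2 * J(wX)
    R2 <- (d^2 / 8) * (4 * J(0) + J(wH - wX) + 3 * J(wX) + 6 * J(wH) +
                         6 * J(wH + wX)) + (c2 / 6) * (4 * J(0) + 3 * J(wX))
    noe <- 1 + (gH / gX) * (d^2 / 4) * (6 * J(wH + wX) - J(wH - wX)) / R1
    out <- list(field_MHz = f)
    if ("T1" %in% calculate) out$T1_ms <- 1000 / R1
    if ("T2" %in% calculate) out$T2_ms <- 1000 / R2
    if ("NOE" %in% calculate) out$NOE <- noe
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

#' D2_00 time series of a probe along a Cartesian trajectory
#'
#' @param frames List of N x 3 LF coordinate matrices.
#' @param probe An `nmr_probe`.
#' @return Numeric vector of D2_00(Omega_dip(t)).
#' @export
probe_d200_series <- function(frames, probe) {
  vapply(frames, function(x) {
    fr <- dipolar_frame(x[probe$H, ], x[probe$heavy, ], x[probe$X, ])
    (3 * fr$R[3, 3]^2 - 1) / 2
  }, numeric(1))
}

#' Export an ACF (and optional fit) as a two-column TSV table
#' @param acf An `acf_rank2`.
#' @param path Output path.
#' @param fit Optional `multi_exp_model` adding a fitted column.
#' @return `path`, invisibly.
#' @export
write_acf <- function(acf, path, fit = NULL) {
  df <- data.frame(lag_s = acf$lags, C = acf$values)
  if (!is.null(fit)) df$fitted <- fit$fitted
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
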