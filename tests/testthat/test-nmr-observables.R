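# Probe detection, dipolar frames, Wigner functions, correlation
# functions, multiexponential fits, spectral densities and relaxation.

test_that("probe detection finds C-H pairs, flags CH2 groups, and skips
           substituent-less carbons", {
  # C1(-H2)(-C3), C3(-H4)(-H5): one CH + one CH2 pair
  s <- cartesian_structure(
    c("C", "H", "C", "H", "H"),
    rbind(c(0, 0, 0), c(0, 0, 1.1), c(1.5, 0, 0),
          c(1.9, 1.0, 0), c(1.9, -1.0, 0)),
    rbind(c(1, 2), c(1, 3), c(3, 4), c(3, 5)))
  probes <- detect_probes(s, "13C1H")
  expect_length(probes, 3)
  expect_equal(vapply(probes, function(p) p$H, 1L), c(2L, 4L, 5L))
  expect_equal(vapply(probes, function(p) p$is_ch2, TRUE),
               c(FALSE, TRUE, TRUE))
  expect_equal(probes[[2]]$X, 1L)   # substituent of the CH2 carbon
  # lone methane-like carbon: no non-H substituent -> warn and skip
  s2 <- cartesian_structure(c("C", "H", "H", "H", "H"),
                            rbind(c(0, 0, 0), c(1.1, 0, 0), c(-1.1, 0, 0),
                                  c(0, 1.1, 0), c(0, -1.1, 0)),
                            rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  expect_warning(p2 <- detect_probes(s2, "13C1H"), "substituent")
  expect_length(p2, 0)
  # N-H detection
  s3 <- cartesian_structure(c("N", "H", "C"),
                            rbind(c(0, 0, 0), c(0, 0, 1.02), c(1.4, 0, 0)),
                            rbind(c(1, 2), c(1, 3)))
  p3 <- detect_probes(s3, "15N1H")
  expect_length(p3, 1)
  expect_equal(p3[[1]]$kind, "NH")
  expect_error(detect_probes(s3, "31P1H"), "unsupported")
})

test_that("dipolar frame is orthonormal, aligned with the bond, and
           composes with rigid rotations", {
  # H on +z, X in the xz-plane -> beta = 0
  fr <- dipolar_frame(c(0, 0, 1.1), c(0, 0, 0), c(1.4, 0, -0.4))
  expect_equal(unname(fr$euler["beta"]), 0, tolerance = 1e-12)
  set.seed(10)
  for (rep in 1:10) {
    H <- rnorm(3); C <- rnorm(3); X <- rnorm(3)
    if (sqrt(sum((H - C)^2)) < 0.1) next
    fr <- tryCatch(dipolar_frame(H, C, X), error = function(e) NULL)
    if (is.null(fr)) next
    expect_lt(max(abs(t(fr$R) %*% fr$R - diag(3))), 1e-12)
    expect_equal(det(fr$R), 1, tolerance = 1e-12)
    # Z axis along the bond
    expect_equal(fr$R[, 3], (H - C) / sqrt(sum((H - C)^2)),
                 tolerance = 1e-12)
    # compounding with a known rotation
    R <- euler_to_rotmat(0.4, 1.1, -0.8)
    fr2 <- dipolar_frame(R %*% H, R %*% C, R %*% X)
    expect_equal(fr2$R, R %*% fr$R, tolerance = 1e-12)
  }
  expect_error(dipolar_frame(c(0, 0, 1), c(0, 0, 0), c(0, 0, -2)),
               "degenerate-frame")
})

test_that("rank-2 Wigner functions: special values and unitarity", {
  expect_equal(wigner_d2_00(c(0, 0, 0)), 1)
  expect_equal(wigner_d2_00(beta = acos(1 / sqrt(3))), 0, tolerance = 1e-14)
  set.seed(77)
  for (rep in 1:20) {
    Om <- c(runif(1, -pi, pi), runif(1, 0, pi), runif(1, -pi, pi))
    tot <- sum(vapply(-2:2, function(m) Mod(wigner_d2_0m(Om, m))^2,
                      numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
    expect_equal(Re(wigner_d2_0m(Om, 0)), wigner_d2_00(Om))
  }
})

test_that("acf of i.i.d. uniform orientations is 1 at lag 0 and near zero
           later; frozen orientation gives the flat unnormalized value 5", {
  set.seed(20)
  n <- 20000
  Q <- matrix(rnorm(4 * n), ncol = 4)
  Q <- Q / sqrt(rowSums(Q^2))
  d200 <- quat_d200_series(Q)
  ac <- rank2_acf(d200, dt = 1, lag_frac = 0.01)
  expect_equal(ac$values[1], 1, tolerance = 0.05)
  expect_lt(max(abs(ac$values[-1])), 0.05)
  frozen <- rank2_acf(rep(1, 200), dt = 1)   # beta = 0 throughout
  expect_equal(unique(round(frozen$values, 12)), 5)
  expect_error(rank2_acf(1.0, dt = 1), "at least 2")
})

test_that("acf estimator recovers the isotropic-rotor exponential", {
  m <- assemble_diffusion(diag(3), matrix(nrow = 0, ncol = 0), kT = 1)
  sch <- make_schedule(mode_spectrum(m), "runge_kutta", dt = 0.01,
                       t_total = 500, n_dump_target = 1e4)
  trs <- run_ensemble(m, sch, 55, n = 8)
  ac <- rank2_acf(lapply(trs, function(tr) quat_d200_series(tr$Q)),
                  sch$dt * sch$dump_stride, lag_frac = 0.005)
  theo <- exp(-6 * ac$lags)
  expect_lt(max(abs(ac$values - theo)), 0.08)
})

test_that("multiexponential fit: exact single-exponential recovery with
           spare components pruned", {
  tt <- seq(0, 10, by = 0.01)
  ac <- list(lags = tt, values = exp(-tt))
  f <- multiexp_fit(ac, n_exp = 4)
  active <- f$a > 1e-6
  expect_lt(max(abs(f$tau[active] - 1)), 1e-6)
  expect_lt(sum(f$a[!active]), 1e-6)
  expect_equal(sum(f$a), 1, tolerance = 1e-8)   # weights sum to C(0)
})

test_that("two time scales are recovered within 5% from 1%-noise data", {
  tt <- seq(0, 10, by = 0.001)
  set.seed(2)
  y <- 0.8 * exp(-tt / 1) + 0.2 * exp(-tt / 0.01) +
    rnorm(length(tt), sd = 0.01)
  f <- multiexp_fit(list(lags = tt, values = y), n_exp = 2)
  expect_equal(f$n_exp, 2)
  expect_lt(abs(f$tau[1] / 0.01 - 1), 0.05)
  expect_lt(abs(f$tau[2] / 1 - 1), 0.05)
  expect_equal(sum(f$a), 1, tolerance = 0.02)
})

test_that("non-convergent fits raise an error requesting a new initial
           guess", {
  tt <- seq(0, 10, by = 0.1)
  bad <- list(lags = tt, values = cos(5 * tt))   # not a decay at all
  expect_error(multiexp_fit(bad, n_exp = 2), "initial guess")
  expect_error(multiexp_fit(list(lags = tt, values = -exp(-tt))), "positive")
})

test_that("spectral density: closed-form values and agreement with a
           numeric cosine transform", {
  f1 <- list(a = 1, tau = 2, n_exp = 1)
  class(f1) <- "multi_exp_model"
  expect_equal(spectral_density(f1, 0), 4)            # J(0) = 2 tau
  expect_equal(spectral_density(f1, 1 / 2), 2)        # omega tau = 1 -> tau
  expect_true(all(diff(spectral_density(f1, c(0, 1, 2, 5))) < 0))
  f2 <- list(a = c(0.7, 0.3), tau = c(1, 0.05), n_exp = 2)
  class(f2) <- "multi_exp_model"
  # numeric transform J(w) = 2 int C(t) cos(wt) dt
  tt <- seq(0, 60, by = 0.002)
  Ct <- 0.7 * exp(-tt) + 0.3 * exp(-tt / 0.05)
  for (w in c(0, 0.5, 2)) {
    g <- Ct * cos(w * tt)
    Jnum <- 2 * 0.002 * (sum(g) - (g[1] + g[length(g)]) / 2)  # trapezoid
    expect_equal(spectral_density(f2, w), Jnum, tolerance = 1e-4)
  }
  expect_equal(spectral_density(f2, -3), spectral_density(f2, 3))
})

test_that("relaxation matches an independent evaluation of the standard
           dipolar expressions", {
  # independent constants and formulas, written out from scratch
  gH <- 2.6752218744e8; gC <- 6.728284e7
  hbar <- 1.054571817e-34
  tau <- 50e-12
  fit <- list(a = 1, tau = tau, n_exp = 1)
  class(fit) <- "multi_exp_model"
  probe <- list(kind = "CH", nucleus = "13C1H", bond_length = 1.13,
                delta_csa = 0, csa_tilt = c(0, 0, 0))
  class(probe) <- "nmr_probe"
  res <- relaxation(fit, probe, 600.132)
  r <- 1.13e-10
  d <- 1e-7 * gH * gC * hbar / r^3
  wH <- 2 * pi * 600.132e6
  wC <- wH * gC / gH
  Jf <- function(w) 2 * tau / (1 + (w * tau)^2)
  R1 <- d^2 / 4 * (Jf(wH - wC) + 3 * Jf(wC) + 6 * Jf(wH + wC))
  R2 <- d^2 / 8 * (4 * Jf(0) + Jf(wH - wC) + 3 * Jf(wC) + 6 * Jf(wH) +
                     6 * Jf(wH + wC))
  noe <- 1 + (gH / gC) * d^2 / 4 * (6 * Jf(wH + wC) - Jf(wH - wC)) / R1
  expect_equal(res$T1_ms, 1000 / R1, tolerance = 1e-10)
  expect_equal(res$T2_ms, 1000 / R2, tolerance = 1e-10)
  expect_equal(res$NOE, noe, tolerance = 1e-10)
  expect_lt(res$T2_ms, res$T1_ms + 1e-9)
})

test_that("extreme narrowing: T1 = T2 and the 13C NOE reaches
           1 + gamma_H / (2 gamma_C)", {
  fit <- list(a = 1, tau = 1e-12, n_exp = 1)
  class(fit) <- "multi_exp_model"
  probe <- list(kind = "CH", nucleus = "13C1H", bond_length = 1.13,
                delta_csa = 0)
  class(probe) <- "nmr_probe"
  res <- relaxation(fit, probe, 600.132)
  expect_equal(res$T1_ms, res$T2_ms, tolerance = 1e-4)
  expect_equal(res$NOE, 1 + 2.6752218744e8 / (2 * 6.728284e7),
               tolerance = 1e-4)
})

test_that("CSA contributes only when deltaCSA is nonzero, shortening T1", {
  fit <- list(a = 1, tau = 30e-12, n_exp = 1)
  class(fit) <- "multi_exp_model"
  p0 <- list(kind = "CH", nucleus = "13C1H", bond_length = 1.13,
             delta_csa = 0)
  p1 <- modifyList(p0, list(delta_csa = 150))
  class(p0) <- class(p1) <- "nmr_probe"
  r0 <- relaxation(fit, p0, 600.132)
  r1 <- relaxation(fit, p1, 600.132)
  expect_lt(r1$T1_ms, r0$T1_ms)
  expect_lt(r1$T2_ms, r0$T2_ms)
  # repeating with deltaCSA = 0 reproduces the dipolar-only numbers
  expect_identical(relaxation(fit, p0, 600.132), r0)
})
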