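# Diffusion-tensor assembly in shifted coordinates, z <-> q maps, mode
# spectrum, coupling index, scheduling, and the analytic sandbox system.

sandbox_reference_tensor <- function(cc, k) {
  rbind(c(1, 0, 0, 0),
        c(0, 1, 0, 0),
        c(0, 0, 1, cc * sqrt(k)),
        c(0, 0, cc * sqrt(k), 10 * k))
}

test_that("assembly reproduces the sandbox tensor exactly", {
  for (cc in c(0, 0.3, 1)) {
    for (k in c(0.5, 10)) {
      m <- sandbox_model(cc, k)
      expect_equal(m$D, sandbox_reference_tensor(cc, k), tolerance = 1e-14)
    }
  }
  expect_error(sandbox_model(4, 0.001), "positive definite")
})

test_that("zero coupling gives a block-diagonal tensor whose spectrum is
           the union of the block spectra", {
  set.seed(21)
  ns <- 3
  Dh <- matrix(0, 3 + ns, 3 + ns)
  Dh[1:3, 1:3] <- random_spd(3)
  Dh[4:6, 4:6] <- random_spd(ns)
  K <- random_spd(ns)
  m <- assemble_diffusion(Dh, K, kT = 1)
  expect_equal(m$D[1:3, 4:6], matrix(0, 3, ns), tolerance = 1e-14)
  Ks <- sfbdyn:::sym_sqrt(K)
  expected <- sort(c(eigen(Dh[1:3, 1:3], symmetric = TRUE)$values,
                     eigen(Ks %*% Dh[4:6, 4:6] %*% Ks,
                           symmetric = TRUE)$values))
  expect_equal(sort(eigen(m$D, symmetric = TRUE)$values), expected,
               tolerance = 1e-10)
})

test_that("assembled tensor equals a dense brute-force congruence
           transform", {
  set.seed(31)
  for (rep in 1:5) {
    ns <- sample(2:5, 1)
    Dh <- random_spd(3 + ns, scale = 2)
    K <- random_spd(ns)
    kT <- 0.7
    m <- assemble_diffusion(Dh, K, kT)
    # dense reference: blkdiag(E,T)^T blkdiag(1, K^(1/2)/sqrt(kT)) Dh (...)
    S <- sfbdyn:::sym_sqrt(K) / sqrt(kT)
    U <- rbind(cbind(m$E, matrix(0, 3, ns)),
               cbind(matrix(0, ns, 3), m$Tmat))
    G <- rbind(cbind(diag(3), matrix(0, 3, ns)),
               cbind(matrix(0, ns, 3), S))
    Dref <- t(U) %*% G %*% Dh %*% G %*% U
    expect_lt(max(abs(m$D - Dref)), 1e-12 * max(abs(Dref)))
    # and the spectrum is that of the scaled tensor independently of E, T
    expect_equal(mode_spectrum(m)$omegas,
                 sort(eigen(G %*% Dh %*% G, symmetric = TRUE)$values),
                 tolerance = 1e-10)
    # diagonal blocks came out diagonal
    offr <- m$D[1:3, 1:3]; diag(offr) <- 0
    offi <- m$D[3 + 1:ns, 3 + 1:ns]; diag(offi) <- 0
    expect_lt(max(abs(offr)), 1e-10 * max(m$D))
    expect_lt(max(abs(offi)), 1e-10 * max(m$D))
  }
})

test_that("to_z / from_z invert exactly and obey the 1D closed form", {
  set.seed(8)
  ns <- 4
  Dh <- random_spd(3 + ns)
  K <- random_spd(ns)
  q0 <- rnorm(ns)
  m <- assemble_diffusion(Dh, K, kT = 2.5, q0 = q0)
  expect_equal(to_z(q0, m), rep(0, ns), tolerance = 1e-12)
  q <- q0 + rnorm(ns)
  expect_equal(from_z(to_z(q, m), m), q, tolerance = 1e-12)
  # 1D: z = sqrt(k / kBT) (q - q0)
  m1 <- assemble_diffusion(diag(4), matrix(9), kT = 4, q0 = 2)
  expect_equal(to_z(3, m1), sqrt(9 / 4) * (3 - 2), tolerance = 1e-14)
})

test_that("sandbox closed-form eigenvalues match the numeric
           eigendecomposition over the parameter grid", {
  for (cc in c(0, 0.1, 1)) {
    for (k in c(0.1, 1, 10, 100, 1000)) {
      closed <- sandbox_eigenvalues(cc, k)
      numeric_ev <- sort(eigen(sandbox_reference_tensor(cc, k),
                               symmetric = TRUE)$values)
      expect_lt(max(abs(closed - numeric_ev) / pmax(1, numeric_ev)), 1e-12)
      if (cc == 0)
        expect_equal(closed, sort(c(1, 1, 1, 10 * k)))
    }
  }
  # explicit closed forms at c = 1, k = 10
  m <- sandbox_model(1, 10)
  sp <- mode_spectrum(m)
  disc <- sqrt((1 - 100)^2 + 40)
  expect_equal(sp$omegas,
               c((101 - disc) / 2, 1, 1, (101 + disc) / 2),
               tolerance = 1e-12)
})

test_that("sandbox eigenvalue trends: w1 falls and w4 rises with coupling;
           w1 plateaus at large k", {
  k <- 10
  w1 <- sapply(c(0, 0.5, 1), function(cc) sandbox_eigenvalues(cc, k)[1])
  w4 <- sapply(c(0, 0.5, 1), function(cc) sandbox_eigenvalues(cc, k)[4])
  expect_true(all(diff(w1) < 0))
  expect_true(all(diff(w4) > 0))
  # k -> infinity at fixed c: w1 approaches the plateau 1 - c^2/10
  cc <- 0.8
  w1k <- sapply(c(1e2, 1e4, 1e6), function(k) sandbox_eigenvalues(cc, k)[1])
  expect_true(all(diff(w1k) > 0))
  expect_equal(w1k[3], 1 - cc^2 / 10, tolerance = 1e-4)
})

test_that("mode spectrum agrees with a dense eigensolver for a molecular
           model", {
  fx <- branched_fixture()
  p <- hydro_params(2, 6, 8.9e-4, 298.15)
  Dg <- hydro_diffusion_tensor(fx$structure, fx$zdef, p)
  K <- hessian_to_curvature(hessian_to_si(fx$H),
                            structure_jacobian(fx$zdef, fx$structure))
  m <- assemble_diffusion(Dg, K, kBT(298.15), fx$q0, fx$zdef)
  sp <- mode_spectrum(m)
  ref <- sort(eigen(m$D, symmetric = TRUE)$values)
  expect_lt(max(abs(sp$omegas - ref) / ref), 1e-10)
  expect_true(all(diff(sp$omegas) >= 0))
  expect_equal(sp$tau_slow, 1 / (6 * min(ref)))
})

test_that("spectrum is invariant under rotation of the input structure", {
  fx <- branched_fixture()
  p <- hydro_params(2, 6, 8.9e-4, 298.15)
  build <- function(s, H) {
    Dg <- hydro_diffusion_tensor(s, fx$zdef, p)
    K <- hessian_to_curvature(hessian_to_si(H),
                              structure_jacobian(fx$zdef, s))
    mode_spectrum(assemble_diffusion(Dg, K, kBT(298.15)))$omegas
  }
  w0 <- build(fx$structure, fx$H)
  R <- euler_to_rotmat(1.2, 0.7, -0.4)
  sr <- cartesian_structure(fx$structure$elements,
                            fx$structure$coords %*% t(R),
                            fx$structure$bonds)
  Hr <- kronecker(diag(4), R) %*% fx$H %*% t(kronecker(diag(4), R))
  expect_equal(build(sr, Hr), w0, tolerance = 1e-8)
})

test_that("coupling index: zero for decoupled, concentrated for the
           sandbox, equivariant under permutation", {
  set.seed(13)
  ns <- 3
  Dh <- matrix(0, 3 + ns, 3 + ns)
  Dh[1:3, 1:3] <- random_spd(3)
  Dh[4:6, 4:6] <- random_spd(ns)
  m0 <- assemble_diffusion(Dh, diag(ns), kT = 1)
  expect_equal(coupling_index(m0), rep(0, ns))
  m1 <- sandbox_model(0.6, 10)
  expect_equal(coupling_index(m1), 1)
  # permutation: build a 2-coordinate diagonal model directly and swap
  D2 <- rbind(c(1, 0, 0, 0.2, 0.05),
              c(0, 1.5, 0, 0, 0.1),
              c(0, 0, 2, 0.1, 0),
              c(0.2, 0, 0.1, 5, 0),
              c(0.05, 0.1, 0, 0, 9))
  mk <- function(D) {
    m <- list(D = D, n_internal = 2L); class(m) <- "sfb_model"; m
  }
  ci <- coupling_index(mk(D2))
  perm <- c(1, 2, 3, 5, 4)
  ci_p <- coupling_index(mk(D2[perm, perm]))
  expect_equal(ci_p, ci[c(2, 1)], tolerance = 1e-14)
  expect_true(all(ci >= 0 & ci <= 1))
})

test_that("schedule derives dt, length and dump stride from the spectrum
           and respects overrides", {
  m <- sandbox_model(0.5, 10)
  sp <- mode_spectrum(m)
  sch_rk <- make_schedule(sp, "runge_kutta")
  expect_equal(sch_rk$dt, 1 / (2 * max(sp$omegas)))
  sch_eu <- make_schedule(sp, "euler")
  expect_equal(sch_eu$dt, 1 / (10 * max(sp$omegas)))
  expect_equal(sch_rk$tau, 1 / (6 * min(sp$omegas)))
  expect_equal(sch_rk$t_total, 1000 * sch_rk$tau)
  expect_equal(sch_rk$n_trajectories, 20L)
  expect_equal(sch_rk$n_steps, as.integer(ceiling(sch_rk$t_total / sch_rk$dt)))
  expect_equal(sch_rk$dump_stride,
               max(1L, as.integer(round(sch_rk$n_steps / 1e4))))
  # the bare tau convention is exposed
  expect_equal(make_schedule(sp, "runge_kutta", tau_factor = 1)$tau,
               1 / min(sp$omegas))
  expect_warning(make_schedule(sp, "euler", dt = 1 / max(sp$omegas)),
                 "stability bound")
})

test_that("model serialization writes a recoverable plain-text record", {
  m <- sandbox_model(0.4, 3)
  f <- tempfile()
  write_sfb_model(m, f)
  txt <- readLines(f)
  expect_true(any(grepl("^\\[D\\] 4 4", txt)))
  d_row <- as.numeric(strsplit(txt[grep("^\\[D\\]", txt) + 4], " ")[[1]])
  expect_equal(d_row, m$D[4, ], tolerance = 1e-15)
})

test_that("spectrum report tabulates frequencies and coupling indices", {
  m <- sandbox_model(1, 10)
  rep <- spectrum_report(m)
  expect_equal(nrow(rep), 4)
  expect_equal(rep$coupling_index[4], 1)
  expect_true(all(is.na(rep$coupling_index[1:3])))
})
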