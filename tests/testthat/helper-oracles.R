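# Independent brute-force oracles and small geometry builders used across
# the tests.  These deliberately avoid the package's own code paths.

# --- independent internal-coordinate oracles (plain vector algebra) ----
bf_dist <- function(p1, p2) sqrt(sum((p1 - p2)^2))

bf_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v))   # atan2 form, not acos
}

bf_dihedral <- function(p1, p2, p3, p4) {
  # projection formula in an explicit orthonormal frame of the p2->p3 axis
  b2 <- p3 - p2
  e <- b2 / sqrt(sum(b2^2))
  u <- (p1 - p2) - sum((p1 - p2) * e) * e
  v <- (p4 - p3) - sum((p4 - p3) * e) * e
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  # right-handed angle from the p1-side projection to the p4-side
  # projection, looking along the 2 -> 3 axis
  atan2(sum(cr * e), sum(u * v))
}

# random non-degenerate chain geometry with n atoms (chain topology)
random_chain_structure <- function(n, seed) {
  set.seed(seed)
  repeat {
    x <- matrix(0, n, 3)
    for (i in 2:n) {
      d <- runif(1, 1.0, 2.0)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      x[i, ] <- x[i - 1, ] + d * dir
    }
    s <- cartesian_structure(rep("C", n), x, cbind(seq_len(n - 1), 2:n))
    ok <- tryCatch({
      zd <- build_zmatrix(s, 1:3)
      q <- cartesian_to_zmatrix(zd, s)
      ang <- q[zd$labels$kind == "angle"]
      all(ang > 0.2) && all(ang < pi - 0.2)
    }, error = function(e) FALSE)
    if (ok) return(s)
  }
}

random_unit_quaternion <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

# random symmetric positive-definite matrix
random_spd <- function(n, scale = 1) {
  A <- matrix(rnorm(n * n), n)
  A %*% t(A) * scale / n + diag(n) * 0.1 * scale
}

# Fibonacci shell of beads on a sphere surface
sphere_shell <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

branched_fixture <- function(...) make_fixture(list(type = "branched4", ...))
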