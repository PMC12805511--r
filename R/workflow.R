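# Workflow: keyword configuration parsing, pipeline orchestration
# (model build -> BD -> analysis), synthetic fixtures, and trajectory
# convergence diagnostics.

.required_keywords <- c("project", "refAtoms", "Reff", "C", "viscosity",
                        "temperature", "seed", "nucleus", "bondLength",
                        "deltaCSA", "frequency", "calculate")
.optional_keywords <- c("ff", "grad", "hessian_file", "scheme",
                        "n_trajectories", "n_dump", "t_total", "dt")

#' Parse a keyword configuration file
#'
#' Whitespace-separated `keyword value(s)` lines, order-free; `#` starts a
#' comment.  Required keywords: project, refAtoms (3-4 atom indices; the
#' fourth is metadata identifying a dihedral of interest), Reff (angstrom),
#' C, viscosity (Pa s), temperature (K), seed, nucleus, bondLength
#' (angstrom), deltaCSA (ppm), frequency (MHz list), calculate (subset of
#' T1 T2 NOE).  `ff` and `grad` are accepted for compatibility but act as
#' metadata (the Hessian arrives through `hessian_file`).  Artifact
#' extensions: hessian_file, scheme (euler/runge_kutta), n_trajectories,
#' n_dump, t_total, dt.
#'
#' @param text Character vector of lines, or a length-1 path to a file.
#' @return A typed `run_config` list.
#' @export
parse_config <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  else if (length(text) == 1) text <- strsplit(text, "\n")[[1]]
  text <- sub("#.*$", "", text)
  text <- trimws(text)
  text <- text[nzchar(text)]
  kv <- list()
  for (ln in seq_along(text)) {
    f <- strsplit(text[ln], "\\s+")[[1]]
    key <- f[1]
    if (!key %in% c(.required_keywords, .optional_keywords))
      stop("parse error: unknown keyword '", key, "' (line ", ln, ")")
    if (length(f) < 2)
      stop("parse error: keyword '", key, "' has no value (line ", ln, ")")
    kv[[key]] <- f[-1]
  }
  missing <- setdiff(.required_keywords, names(kv))
  if (length(missing))
    stop("parse error: missing required keyword(s): ",
         paste(missing, collapse = ", "))
  num <- function(key, n = 1) {
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (anyNA(v)) stop("parse error: malformed number for keyword '", key, "'")
    if (!is.na(n) && length(v) != n)
      stop("parse error: keyword '", key, "' expects ", n, " value(s)")
    v
  }
  refs <- suppressWarnings(as.integer(kv$refAtoms))
  if (anyNA(refs) || length(refs) < 3)
    stop("parse error: refAtoms needs at least 3 integer atom indices")
  calc <- kv$calculate
  if (!all(calc %in% c("T1", "T2", "NOE")))
    stop("parse error: calculate accepts only T1, T2, NOE")
  cfg <- list(
    project = kv$project[1],
    refAtoms = refs,
    ff = if (!is.null(kv$ff)) kv$ff[1] else NA_character_,
    grad = if (!is.null(kv$grad)) num("grad") else NA_real_,
    Reff = num("Reff"),
    C = num("C"),
    viscosity = num("viscosity"),
    temperature = num("temperature"),
    seed = as.integer(num("seed")),
    nucleus = kv$nucleus[1],
    bondLength = num("bondLength"),
    deltaCSA = num("deltaCSA"),
    frequency = num("frequency", NA),
    calculate = calc,
    hessian_file = if (!is.null(kv$hessian_file)) kv$hessian_file[1] else NULL,
    scheme = if (!is.null(kv$scheme)) kv$scheme[1] else "runge_kutta",
    n_trajectories = if (!is.null(kv$n_trajectories))
      as.integer(num("n_trajectories")) else 20L,
    n_dump = if (!is.null(kv$n_dump)) num("n_dump") else 1e4,
    t_total = if (!is.null(kv$t_total)) num("t_total") else NULL,
    dt = if (!is.null(kv$dt)) num("dt") else NULL
  )
  class(cfg) <- "run_config"
  cfg
}

#' Synthetic molecule + Hessian fixture
#'
#' Builds a toy molecule with a chain (optionally branched) topology and a
#' Cartesian Hessian assembled from chosen internal force constants,
#' H = Bw^T diag(k) Bw with Bw the Wilson gradient matrix, so the true
#' internal curvature matrix is diag(k) exactly and rigid-body modes are
#' exactly zero.  Default force constants are typical molecular-mechanics
#' scales: 350 kcal/mol/A^2 stretches, 60 kcal/mol/rad^2 bends,
#' 8 kcal/mol/rad^2 torsions.
#'
#' @param spec List: `type` ("chain" or "branched4" for the branched
#'   4-atom demonstration topology), `n_atoms`, `elements`, `bond_length`
#'   (angstrom), `angle`, `dihedral` (radians), `k_stretch`, `k_bend`,
#'   `k_torsion` or full vector `k` (kcal/mol units), `seed` for
#'   reproducible jitter (`jitter` relative amplitude, default 0).
#' @return List: `structure`, `zdef`, `H` (Cartesian Hessian,
#'   kcal/mol/A^2), `K_true` (kcal/mol units), `q0`, `config` (a template
#'   `run_config`-compatible keyword list).
#' @export
make_fixture <- function(spec = list()) {
  type <- spec$type %||% "chain"
  seed <- spec$seed %||% 1L
  jit <- spec$jitter %||% 0
  set.seed(seed)
  if (type == "branched4") {
    # 4 atoms, bonds 1-2, 1-3, 3-4
    elements <- spec$elements %||% c("C", "H", "C", "H")
    bonds <- rbind(c(1, 2), c(1, 3), c(3, 4))
    n <- 4
    ref <- c(1, 2, 3)
  } else {
    n <- spec$n_atoms %||% 4
    if (n < 3) stop("degenerate fixture spec: need >= 3 atoms")
    elements <- spec$elements %||% rep(c("C", "C", "C", "H"), length.out = n)
    bonds <- cbind(seq_len(n - 1), 2:n)
    ref <- c(1, 2, 3)
  }
  bl <- spec$bond_length %||% 1.5
  ang <- spec$angle %||% (109.5 * pi / 180)
  dih <- spec$dihedral %||% (pi / 3)
  # geometry via a provisional placement, then the definitive zdef
  zdef0 <- build_zmatrix(
    cartesian_structure(elements, provisional_coords(n, bonds, bl, ang, dih),
                        bonds), ref)
  q <- fixture_internal_values(zdef0, bl, ang, dih)
  if (jit > 0) q <- q * (1 + jit * stats::runif(length(q), -1, 1))
  coords <- zmatrix_to_cartesian(zdef0, q)
  struct <- cartesian_structure(elements, coords, bonds)
  zdef <- build_zmatrix(struct, ref)
  kinds <- zdef$labels$kind
  k <- spec$k %||% {
    ks <- spec$k_stretch %||% 350
    kb <- spec$k_bend %||% 60
    kt <- spec$k_torsion %||% 8
    unname(c(distance = ks, angle = kb, dihedral = kt)[kinds])
  }
  if (jit > 0) k <- k * (1 + jit * stats::runif(length(k), -1, 1))
  Bw <- wilson_b_matrix(zdef, coords)
  H <- t(Bw) %*% (k * Bw)
  H <- (H + t(H)) / 2
  list(structure = struct, zdef = zdef, H = H, K_true = diag(k, length(k)),
       q0 = cartesian_to_zmatrix(zdef, struct), k = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rough starting geometry used only to define the Z-matrix topology
provisional_coords <- function(n, bonds, bl, ang, dih) {
  x <- matrix(0, n, 3)
  for (i in 2:n) x[i, ] <- x[i - 1, ] + c(bl * 0.9^(i %% 2), bl * 0.45, 0.3)
  x
}

fixture_internal_values <- function(zdef, bl, ang, dih) {
  kinds <- zdef$labels$kind
  q <- numeric(length(kinds))
  q[kinds == "distance"] <- bl
  q[kinds == "angle"] <- ang
  q[kinds == "dihedral"] <- dih
  q
}

#' Write fixture files (XYZ + Hessian + config) to a directory
#'
#' @param fx A fixture from [make_fixture()].
#' @param dir Output directory (created if needed).
#' @param project Base name for the files.
#' @return Named list of the written paths.
#' @export
write_fixture <- function(fx, dir, project = "toy") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xyz <- file.path(dir, paste0(project, ".xyz"))
  hes <- file.path(dir, paste0(project, ".hess"))
  cfgp <- file.path(dir, paste0(project, ".key"))
  write_tinker_xyz(fx$structure, xyz, title = project)
  write_hessian_file(fx$H, hes)
  writeLines(c(
    paste("project", project),
    paste("refAtoms", paste(c(fx$zdef$ref_atoms,
                              fx$zdef$atom_order[4]), collapse = " ")),
    "ff synthetic",
    "grad 0.01",
    "Reff 2.0",
    "C 6.0",
    "viscosity 8.9e-4",
    "temperature 298.15",
    "seed 123456789",
    "nucleus 13C1H",
    "bondLength 1.13",
    "deltaCSA 0",
    "frequency 600.132 699.973",
    "calculate T1 T2 NOE",
    paste("hessian_file", hes)), cfgp)
  list(xyz = xyz, hessian = hes, config = cfgp)
}

#' Run the full pipeline
#'
#' Stages, in order: (ii) diffusion-tensor construction (hydrodynamic bead
#' model + curvature matrix -> SFB tensor in shifted coordinates),
#' (iii) BD trajectory ensemble and Cartesian reconstruction,
#' (iv) probe detection, rank-2 correlation functions, multiexponential
#' fits, spectral densities, and relaxation data.  Fully reproducible from
#' the config seed.
#'
#' @param config A `run_config` from [parse_config()].
#' @param structure A `cartesian_structure` (else read from
#'   `<project>.xyz`).
#' @param hessian Cartesian Hessian matrix in kcal/mol/A^2 (else read from
#'   `config$hessian_file`).
#' @param output_dir Optional directory for TSV/report outputs.
#' @param verbose Log stage progress to stderr.
#' @return List with `model`, `spectrum`, `schedule`, `trajectories`,
#'   `probes`, `acf`, `fits`, `relaxation` (data frame), `convergence`.
#' @export
run_pipeline <- function(config, structure = NULL, hessian = NULL,
                         output_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[sfbdyn] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(structure))
    structure <- stage("input", read_tinker_xyz(paste0(config$project, ".xyz")))
  if (is.null(hessian)) {
    if (is.null(config$hessian_file))
      stop("pipeline stage 'input' failed: no Hessian supplied ",
           "(hessian argument or hessian_file keyword)")
    hf <- stage("input", read_hessian_file(config$hessian_file))
    hessian <- hf$H
    h_units <- hf$units
  } else h_units <- "kcal_mol_A2"

  say("stage ii: diffusion tensors")
  model <- stage("diffusion-tensor", {
    zdef <- build_zmatrix(structure, config$refAtoms)
    q0 <- cartesian_to_zmatrix(zdef, structure)
    B <- structure_jacobian(zdef, structure)
    K <- hessian_to_curvature(hessian_to_si(hessian, h_units), B)
    params <- hydro_params(config$Reff, config$C, config$viscosity,
                           config$temperature)
    Dg <- hydro_diffusion_tensor(structure, zdef, params)
    assemble_diffusion(Dg, K, kBT(config$temperature), q0, zdef)
  })
  spectrum <- mode_spectrum(model)
  schedule <- make_schedule(spectrum, config$scheme, dt = config$dt,
                            t_total = config$t_total,
                            n_trajectories = config$n_trajectories,
                            n_dump_target = config$n_dump)
  say("stage iii: BD trajectories (", schedule$n_trajectories, " x ",
      schedule$n_steps, " steps)")
  trajs <- stage("bd-trajectory",
                 run_ensemble(model, schedule, config$seed))
  frames <- stage("bd-trajectory",
                  lapply(trajs, trajectory_to_cartesian, model = model))

  say("stage iv: correlation functions and relaxation")
  probes <- stage("nmr-analysis",
                  detect_probes(structure, config$nucleus,
                                bond_length = config$bondLength,
                                delta_csa = config$deltaCSA))
  if (!length(probes))
    stop("pipeline stage 'nmr-analysis' failed: no probes detected for ",
         config$nucleus)
  dt_dump <- schedule$dt * schedule$dump_stride
  acfs <- list(); fits <- list(); relax <- list()
  for (pi in seq_along(probes)) {
    p <- probes[[pi]]
    series <- lapply(frames, probe_d200_series, probe = p)
    ac <- stage("nmr-analysis", rank2_acf(series, dt_dump))
    ft <- stage("nmr-analysis",
                multiexp_fit(ac, tau_max = 5 * spectrum$tau_slow))
    rx <- stage("nmr-analysis",
                relaxation(ft, p, config$frequency, config$calculate))
    rx <- cbind(probe = paste0(p$kind, "_H", p$H), rx)
    acfs[[pi]] <- ac; fits[[pi]] <- ft; relax[[pi]] <- rx
  }
  relax <- do.call(rbind, relax)
  conv <- convergence_report(trajs, model)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_sfb_model(model, file.path(output_dir, "model.txt"))
    utils::write.table(format(relax, digits = 4),
                       file.path(output_dir, "relaxation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (pi in seq_along(probes))
      write_acf(acfs[[pi]], file.path(output_dir, paste0("acf_", pi, ".tsv")),
                fits[[pi]])
    utils::write.table(format(conv, digits = 4),
                       file.path(output_dir, "convergence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(model = model, spectrum = spectrum, schedule = schedule,
       trajectories = trajs, probes = probes, acf = acfs, fits = fits,
       relaxation = relax, convergence = conv)
}

#' Trajectory convergence diagnostics
#'
#' Histogram-style convergence check for the free-tumbling + harmonic
#' system: at
#' equilibrium alpha and gamma are uniform on (-pi, pi], cos(beta) uniform
#' on [-1, 1], and every z_i standard normal.  For each coordinate the
#' Kolmogorov-Smirnov statistic of the pooled dumped series is compared,
#' at the 1% level, with the critical value for an effective sample size
#' n_eff = T_total / (2 t_corr), where t_corr = 1/(2 D_iso) for the
#' orientational coordinates (rank-1 rotational decorrelation) and
#' 1/omega_i for z_i (Ornstein-Uhlenbeck decorrelation).  This corrects
#' for serial correlation in the dumped series; a raw snapshot count would
#' grossly overstate the information content.  A coordinate with
#' n_eff < 50 carries too little information to assess and is reported as
#' not converged.
#'
#' @param trajectories A `bd_trajectory` or list of them.
#' @param model The generating `sfb_model`.
#' @return Data frame: coordinate, ks_stat, n_eff, ks_crit (1% level),
#'   assessable, pass.
#' @export
convergence_report <- function(trajectories, model) {
  if (inherits(trajectories, "bd_trajectory"))
    trajectories <- list(trajectories)
  ns <- model$n_internal
  D <- model$D
  t_total <- sum(vapply(trajectories,
                        function(tr) max(tr$times), numeric(1)))
  eul <- do.call(rbind, lapply(trajectories,
                               function(tr) quat_series_to_euler(tr$Q)))
  zs <- do.call(rbind, lapply(trajectories, function(tr) tr$z))
  d_iso <- mean(diag(D)[1:3])
  t_rot <- 1 / (2 * d_iso)
  rows <- list()
  addrow <- function(name, x, cdf, t_corr) {
    ks <- suppressWarnings(do.call(ks.test, c(list(x), cdf)))
    # effective sample size: decorrelation-limited, and never more than
    # the number of snapshots actually dumped
    n_eff <- min(length(x), floor(t_total / (2 * t_corr)))
    crit <- 1.628 / sqrt(max(n_eff, 1))   # 1% asymptotic KS critical value
    assessable <- n_eff >= 50
    rows[[length(rows) + 1]] <<- data.frame(
      coordinate = name, ks_stat = unname(ks$statistic), n_eff = n_eff,
      ks_crit = crit, assessable = assessable,
      pass = assessable && unname(ks$statistic) < crit)
  }
  addrow("alpha", eul[, "alpha"], list("punif", -pi, pi), t_rot)
  addrow("cos_beta", cos(eul[, "beta"]), list("punif", -1, 1), t_rot)
  addrow("gamma", eul[, "gamma"], list("punif", -pi, pi), t_rot)
  for (i in seq_len(ns))
    addrow(paste0("z_", i), zs[, i], list("pnorm"), 1 / D[3 + i, 3 + i])
  do.call(rbind, rows)
}
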