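#' Molecular structure container
#'
#' A minimal Cartesian structure: element symbols, coordinates in angstrom,
#' bond list, and optional integer atom types (as used by the Tinker XYZ
#' dialect).
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric N x 3 matrix of coordinates (angstrom).
#' @param bonds Two-column integer matrix of bonded atom index pairs
#'   (1-based; each pair stored once, i < j).
#' @param atom_types Optional integer vector of force-field atom types.
#' @return An object of class `cartesian_structure`.
#' @export
cartesian_structure <- function(elements, coords, bonds,
                                atom_types = rep(0L, length(elements))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  bonds <- normalize_bonds(bonds, n)
  structure(list(elements = as.character(elements), coords = coords,
                 bonds = bonds, atom_types = as.integer(atom_types)),
            class = "cartesian_structure")
}

normalize_bonds <- function(bonds, n) {
  if (is.null(bonds) || length(bonds) == 0)
    return(matrix(integer(0), ncol = 2))
  bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 2)
  if (any(bonds < 1L) || any(bonds > n))
    stop("bond indices out of range")
  if (any(bonds[, 1] == bonds[, 2]))
    stop("self-bond in bond list")
  bonds <- t(apply(bonds, 1, sort))
  bonds <- unique(bonds)
  bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
}

#' @export
print.cartesian_structure <- function(x, ...) {
  cat("<cartesian_structure> ", length(x$elements), " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Neighbour list from a bond table
#' @param structure A `cartesian_structure`.
#' @return List: element i holds the sorted indices bonded to atom i.
#' @export
bond_neighbours <- function(structure) {
  n <- length(structure$elements)
  nb <- vector("list", n)
  b <- structure$bonds
  for (r in seq_len(nrow(b))) {
    nb[[b[r, 1]]] <- c(nb[[b[r, 1]]], b[r, 2])
    nb[[b[r, 2]]] <- c(nb[[b[r, 2]]], b[r, 1])
  }
  lapply(nb, function(v) sort(unique(v)))
}

#' Read a Tinker-dialect XYZ file
#'
#' Line 1: atom count plus optional title.  Each atom line: index, element
#' symbol, x, y, z (angstrom), atom-type integer, then the indices of the
#' bonded atoms.
#'
#' @param path File path.
#' @return A `cartesian_structure`.
#' @export
read_tinker_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(header[1])
  if (is.na(n) || n < 1) stop("malformed Tinker XYZ header: ", lines[1])
  if (length(lines) < 1 + n) stop("Tinker XYZ truncated: expected ", n, " atoms")
  elements <- character(n); coords <- matrix(NA_real_, n, 3)
  types <- integer(n); bonds <- list()
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    if (length(f) < 6) stop("malformed atom line ", i + 1)
    elements[i] <- f[2]
    coords[i, ] <- as.numeric(f[3:5])
    types[i] <- as.integer(f[6])
    if (length(f) > 6) {
      for (j in as.integer(f[-(1:6)])) bonds[[length(bonds) + 1]] <- c(i, j)
    }
  }
  if (anyNA(coords)) stop("non-numeric coordinates in Tinker XYZ")
  b <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), ncol = 2)
  cartesian_structure(elements, coords, b, types)
}

#' Write a Tinker-dialect XYZ file (single- or multi-frame)
#'
#' @param structure A `cartesian_structure` (its bonds/elements are reused
#'   for all frames).
#' @param path Output path.
#' @param frames Optional list of N x 3 coordinate matrices; defaults to the
#'   single frame stored in `structure`.
#' @param title Title appended to the count line.
#' @return `path`, invisibly.
#' @export
write_tinker_xyz <- function(structure, path, frames = NULL, title = "sfbdyn") {
  if (is.null(frames)) frames <- list(structure$coords)
  n <- length(structure$elements)
  nb <- bond_neighbours(structure)
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    cat(sprintf("%6d  %s\n", n, title), file = con)
    for (i in seq_len(n)) {
      cat(sprintf("%6d  %-3s %14.8f %14.8f %14.8f %6d %s\n",
                  i, structure$elements[i], fr[i, 1], fr[i, 2], fr[i, 3],
                  structure$atom_types[i],
                  paste(sprintf("%d", nb[[i]]), collapse = " ")),
          file = con)
    }
  }
  invisible(path)
}

#' Read a plain-text Cartesian Hessian file
#'
#' Format: optional comment/header lines starting with `#` (a
#' `# units: kcal_mol_A2` line declares the units, which is also the
#' default), followed by the dense 3N x 3N matrix in row order.
#'
#' @param path File path.
#' @return List with `H` (3N x 3N matrix, in the units of the file) and
#'   `units` (string).
#' @export
read_hessian_file <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  units <- "kcal_mol_A2"
  um <- regmatches(hdr, regexpr("units:\\s*\\S+", hdr))
  if (length(um)) units <- sub("units:\\s*", "", um[[1]])
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  if (anyNA(vals)) stop("non-numeric entry in Hessian file")
  d <- sqrt(length(vals))
  if (d != round(d)) stop("Hessian file does not contain a square matrix")
  H <- matrix(vals, nrow = d, byrow = TRUE)
  list(H = H, units = units)
}

#' Write a plain-text Cartesian Hessian file
#' @param H 3N x 3N matrix.
#' @param path Output path.
#' @param units Units string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_hessian_file <- function(H, path, units = "kcal_mol_A2") {
  con <- file(path, "w"); on.exit(close(con))
  cat("# units: ", units, "\n", sep = "", file = con)
  apply(H, 1, function(r)
    cat(paste(sprintf("%.17g", r), collapse = " "), "\n", file = con))
  invisible(path)
}

#' Convert a Hessian to SI-compatible internal units
#'
#' Converts kcal mol^-1 A^-2 (Tinker convention) to J A^-2 per molecule,
#' the unit system used by [hessian_to_curvature()] consumers (coordinates
#' in angstrom and radian, energies in joule).
#'
#' @param H Matrix in `units`.
#' @param units Currently `"kcal_mol_A2"` or `"J_A2"`.
#' @return Matrix in J A^-2.
#' @export
hessian_to_si <- function(H, units = "kcal_mol_A2") {
  switch(units,
         kcal_mol_A2 = H * .const$kcal / .const$NA_avog,
         J_A2 = H,
         stop("unknown Hessian units: ", units))
}
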