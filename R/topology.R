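#' Molecular topology and conformer containers
#'
#' `mm_topology()` holds the minimal connectivity a molecular-mechanics
#' energy needs: atom names, force-field atom-type labels, partial charges
#' and a bond list. `conformer_set()` holds one or more Cartesian frames
#' (Angstrom) for that topology, optionally tagged with quantum single-point
#' energies (kcal/mol). Atom indices are 1-based throughout the R API and in
#' the plain-text interchange formats.
#'
#' @param atoms tibble (or data frame) with columns `name`, `type`,
#'   `charge` (e).
#' @param bonds tibble with integer columns `i`, `j`.
#' @return `mm_topology()` an object of class `mm_topology`.
#' @seealso [read_topology()], [read_xyz()], [enumerate_terms()]
#' @export
mm_topology <- function(atoms, bonds) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("name", "type", "charge") %in% names(atoms)))
  check_type_labels(atoms$type)
  bonds <- tibble::as_tibble(bonds)
  stopifnot(all(c("i", "j") %in% names(bonds)))
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  n <- nrow(atoms)
  if (nrow(bonds) > 0) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)) {
      abort("bond index out of range", class = "boronfit_invalid_topology")
    }
    if (any(bonds$i == bonds$j)) {
      abort("self-bond in bond list", class = "boronfit_invalid_topology")
    }
    sig <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(sig)) {
      abort("duplicate bond in bond list", class = "boronfit_invalid_topology")
    }
  }
  structure(list(atoms = atoms, bonds = bonds), class = "mm_topology")
}

#' @export
print.mm_topology <- function(x, ...) {
  cat("<mm_topology> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds; types: ",
      paste(sort(unique(x$atoms$type)), collapse = " "), "\n", sep = "")
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

adjacency_list <- function(top) {
  n <- n_atoms(top)
  adj <- vector("list", n)
  for (r in seq_len(nrow(top$bonds))) {
    i <- top$bonds$i[r]; j <- top$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Bonded graph distances up to `max_d` (BFS per atom); used for nonbonded
# exclusion classes 1-2, 1-3, 1-4.
bond_distance_matrix <- function(top, max_d = 3L) {
  n <- n_atoms(top)
  adj <- adjacency_list(top)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    for (k in seq_len(max_d)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[d[s, nxt] == Inf]
      if (length(nxt) == 0) break
      d[s, nxt] <- k
      frontier <- nxt
    }
  }
  d
}

#' @param coords a single N x 3 numeric matrix or a list of them (Angstrom).
#' @param qm_energy optional numeric vector, one energy (kcal/mol) per
#'   frame.
#' @return `conformer_set()` an object of class `conformer_set`: a list of
#'   frames with optional `qm_energy`.
#' @rdname mm_topology
#' @export
conformer_set <- function(coords, qm_energy = NULL) {
  if (is.matrix(coords)) coords <- list(coords)
  stopifnot(is.list(coords), length(coords) >= 1)
  nat <- unique(map_int(coords, nrow))
  if (length(nat) != 1L) {
    abort("all frames must share the atom count", class = "boronfit_alignment_error")
  }
  coords <- map(coords, function(m) {
    m <- unname(as.matrix(m))
    stopifnot(ncol(m) == 3)
    if (!all(is.finite(m))) abort("non-finite coordinates", class = "boronfit_invalid_topology")
    m
  })
  if (!is.null(qm_energy) && length(qm_energy) != length(coords)) {
    abort("qm_energy length must equal the number of frames",
          class = "boronfit_alignment_error")
  }
  structure(list(coords = coords, qm_energy = qm_energy), class = "conformer_set")
}

#' @export
length.conformer_set <- function(x) length(x$coords)

#' @export
print.conformer_set <- function(x, ...) {
  cat("<conformer_set> ", length(x$coords), " frame(s) of ", nrow(x$coords[[1]]),
      " atoms", if (!is.null(x$qm_energy)) " (with QM energies)", "\n", sep = "")
  invisible(x)
}

#' @param conformers a [conformer_set()].
#' @param energies numeric vector of QM energies, kcal/mol, one per frame.
#' @rdname mm_topology
#' @export
set_qm_energies <- function(conformers, energies) {
  conformer_set(conformers$coords, qm_energy = energies)
}

#' Plain-text molecular file formats
#'
#' Readers and writers for the toolkit's interchange formats:
#' \describe{
#'   \item{multi-frame XYZ}{`read_xyz()` / `write_xyz()`: repeated blocks of
#'     atom count, comment line, then `element x y z` lines.}
#'   \item{minimal topology}{`read_topology()` / `write_topology()`: lines
#'     `atom <index> <name> <type> <charge>` and `bond <i> <j>`, 1-based,
#'     `#` comments allowed.}
#'   \item{PDB}{`read_pdb_conformers()`: ATOM/HETATM coordinates, frames
#'     split on MODEL records (via bio3d).}
#'   \item{mol2}{`read_mol2_system()`: ATOM and BOND blocks giving a
#'     topology plus one conformer (via bio3d); `write_mol2_system()` emits
#'     a minimal mol2.}
#'   \item{QM energies}{`read_qm_energies()`: one energy per non-comment
#'     line, order-matched to the coordinate file; hartree values are
#'     converted at 627.509474 kcal/mol.}
#' }
#'
#' @param path file path.
#' @param conformers a [conformer_set()].
#' @param elements character vector of element symbols (defaults to the
#'   atom names of `top` when supplied).
#' @param top an [mm_topology()].
#' @param comment comment string for XYZ frames.
#' @name molecular-io
NULL

#' @rdname molecular-io
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); elements <- NULL
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat)) {
      abort(sprintf("XYZ parse failure at line %d: expected atom count", pos),
            class = "boronfit_format_error")
    }
    block <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    el <- map_chr2(toks, 1L)
    xyz <- matrix(NA_real_, nat, 3)
    for (k in 1:3) xyz[, k] <- as.numeric(map_chr2(toks, k + 1L))
    if (!all(is.finite(xyz))) {
      abort(sprintf("XYZ parse failure in frame starting at line %d", pos),
            class = "boronfit_format_error")
    }
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + nat
  }
  if (length(frames) == 0) abort("empty XYZ file", class = "boronfit_format_error")
  out <- conformer_set(frames)
  attr(out, "elements") <- elements
  out
}

map_chr2 <- function(toks, k) vapply(toks, function(t) t[[k]], character(1))

#' @rdname molecular-io
#' @export
write_xyz <- function(conformers, path, elements = NULL, top = NULL,
                      comment = "boronfit frame") {
  nat <- nrow(conformers$coords[[1]])
  if (is.null(elements)) {
    elements <- if (!is.null(top)) gsub("[0-9]", "", top$atoms$name) else rep("C", nat)
  }
  out <- unlist(imap(conformers$coords, function(m, f) {
    c(as.character(nat), sprintf("%s %d", comment, f),
      sprintf("%-3s %14.8f %14.8f %14.8f", elements, m[, 1], m[, 2], m[, 3]))
  }))
  writeLines(out, path)
  invisible(path)
}

#' @rdname molecular-io
#' @export
read_topology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  kind <- map_chr2(toks, 1L)
  at <- toks[kind == "atom"]
  bd <- toks[kind == "bond"]
  if (!all(kind %in% c("atom", "bond"))) {
    abort("minimal-topology lines must start with 'atom' or 'bond'",
          class = "boronfit_format_error")
  }
  atoms <- tibble::tibble(
    index = as.integer(map_chr2(at, 2L)),
    name = map_chr2(at, 3L),
    type = map_chr2(at, 4L),
    charge = as.numeric(map_chr2(at, 5L))
  ) %>% arrange(.data$index)
  if (!identical(atoms$index, seq_len(nrow(atoms)))) {
    abort("atom indices must be 1..N", class = "boronfit_format_error")
  }
  bonds <- tibble::tibble(
    i = as.integer(vapply(bd, function(t) t[[2]], character(1))),
    j = as.integer(vapply(bd, function(t) t[[3]], character(1)))
  )
  mm_topology(atoms[, c("name", "type", "charge")], bonds)
}

#' @rdname molecular-io
#' @export
write_topology <- function(top, path) {
  out <- c(
    "# boronfit minimal topology: atom <index> <name> <type> <charge>; bond <i> <j> (1-based)",
    sprintf("atom %d %s %s %.6f", seq_len(n_atoms(top)), top$atoms$name,
            top$atoms$type, top$atoms$charge),
    sprintf("bond %d %d", top$bonds$i, top$bonds$j)
  )
  writeLines(out, path)
  invisible(path)
}

#' @rdname molecular-io
#' @export
read_pdb_conformers <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB files requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  frames <- lapply(seq_len(nrow(xyz)), function(f) {
    matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  })
  conformer_set(frames)
}

#' @rdname molecular-io
#' @export
read_mol2_system <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading mol2 files requires the bio3d package")
  }
  mol <- bio3d::read.mol2(path)
  atoms <- tibble::tibble(
    name = mol$atom$elena,
    type = tolower(sub("\\..*", "", mol$atom$elety)),
    charge = as.numeric(mol$atom$charge)
  )
  bonds <- tibble::tibble(i = as.integer(mol$bond$origin), j = as.integer(mol$bond$target))
  top <- mm_topology(atoms, bonds)
  coords <- cbind(as.numeric(mol$atom$x), as.numeric(mol$atom$y), as.numeric(mol$atom$z))
  list(topology = top, conformers = conformer_set(coords))
}

#' @rdname molecular-io
#' @export
write_mol2_system <- function(top, conformers, path, name = "boronfit") {
  m <- conformers$coords[[1]]
  out <- c(
    "@<TRIPOS>MOLECULE", name,
    sprintf("%d %d 1 0 0", n_atoms(top), nrow(top$bonds)),
    "SMALL", "USER_CHARGES", "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %10.4f %10.4f %10.4f %-6s 1 LIG %10.6f",
            seq_len(n_atoms(top)), top$atoms$name, m[, 1], m[, 2], m[, 3],
            top$atoms$type, top$atoms$charge),
    "@<TRIPOS>BOND",
    sprintf("%6d %5d %5d 1", seq_len(nrow(top$bonds)), top$bonds$i, top$bonds$j)
  )
  writeLines(out, path)
  invisible(path)
}

#' @param units `"kcal"` (pass-through) or `"hartree"`.
#' @rdname molecular-io
#' @export
read_qm_energies <- function(path, units = c("kcal", "hartree")) {
  units <- match.arg(units)
  lines <- readLines(path, warn = FALSE)
  keepers <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  vals <- suppressWarnings(as.numeric(trimws(lines[keepers])))
  if (anyNA(vals)) {
    bad <- keepers[which(is.na(vals))[1]]
    abort(sprintf("non-numeric energy at line %d: %s", bad, lines[bad]),
          class = "boronfit_format_error")
  }
  if (units == "hartree") vals <- vals * .HARTREE_KCAL
  vals
}

#' @param energies numeric energies, kcal/mol.
#' @rdname molecular-io
#' @export
write_qm_energies <- function(energies, path) {
  writeLines(c("# one energy per line, kcal/mol", sprintf("%.10f", energies)), path)
  invisible(path)
}
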