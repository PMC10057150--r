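#' Internal-coordinate measurements
#'
#' Bond lengths (Angstrom), interior angles (degrees, \[0, 180\]) and
#' torsion angles (degrees, (-180, 180], IUPAC sign convention: the cis
#' arrangement is 0 and the angle is positive for a clockwise rotation of
#' the far bond when sighting along j to k). Torsions satisfy the reversal
#' symmetry `measure_torsion(c, i, j, k, l) == measure_torsion(c, l, k, j, i)`.
#'
#' @param coords N x 3 coordinate matrix, Angstrom.
#' @param i,j,k,l 1-based atom indices.
#' @return A numeric scalar.
#' @examples
#' sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' measure_torsion(sq, 1, 2, 3, 4)  # 0 (planar cis)
#' @name internal-coordinates
NULL

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

#' @rdname internal-coordinates
#' @export
measure_bond <- function(coords, i, j) {
  stopifnot(i != j)
  vnorm(coords[j, ] - coords[i, ])
}

#' @rdname internal-coordinates
#' @export
measure_angle <- function(coords, i, j, k) {
  stopifnot(length(unique(c(i, j, k))) == 3L)
  u <- coords[i, ] - coords[j, ]
  v <- coords[k, ] - coords[j, ]
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu == 0 || nv == 0) {
    abort("zero-length bond vector in angle measurement", class = "boronfit_degenerate_geometry")
  }
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) / .DEG
}

#' @rdname internal-coordinates
#' @export
measure_torsion <- function(coords, i, j, k, l) {
  stopifnot(length(unique(c(i, j, k, l))) == 4L)
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- vnorm(b2)
  if (nb2 == 0 || vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    abort("degenerate (zero-length or collinear) geometry in torsion measurement",
          class = "boronfit_degenerate_geometry")
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  wrap_angle(atan2(y, x) / .DEG)
}

#' Enumerate bonded interaction terms of a topology
#'
#' Walks the bond graph: angle terms are all simple paths of length two,
#' proper torsions all simple paths of length three (one orientation per
#' central bond), and improper torsions are instantiated only where an
#' explicit improper key of `pset` matches an atom with exactly three
#' neighbors (the central atom sits third in the key, per AMBER
#' convention).
#'
#' @param top an [mm_topology()].
#' @param pset optional [param_set()] whose improper keys seed improper
#'   detection; with no `pset`, no impropers are enumerated.
#' @return A list of tibbles `bonds` (i, j), `angles` (i, j, k), `propers`
#'   (i, j, k, l) and `impropers` (i, j, k, l; k central).
#' @export
enumerate_terms <- function(top, pset = NULL) {
  adj <- adjacency_list(top)
  bonds <- top$bonds[, c("i", "j")]

  angles <- list()
  for (jc in seq_len(n_atoms(top))) {
    nb <- sort(adj[[jc]])
    if (length(nb) >= 2) {
      prs <- utils::combn(nb, 2)
      angles[[length(angles) + 1L]] <- tibble::tibble(i = prs[1, ], j = jc, k = prs[2, ])
    }
  }
  angles <- if (length(angles)) bind_rows(angles) else tibble::tibble(i = integer(), j = integer(), k = integer())

  propers <- list()
  for (r in seq_len(nrow(bonds))) {
    jc <- bonds$i[r]; kc <- bonds$j[r]
    # one orientation per central bond: low index second
    if (jc > kc) { tmp <- jc; jc <- kc; kc <- tmp }
    for (ic in setdiff(adj[[jc]], kc)) {
      for (lc in setdiff(adj[[kc]], jc)) {
        if (ic != lc) {
          propers[[length(propers) + 1L]] <- tibble::tibble(i = ic, j = jc, k = kc, l = lc)
        }
      }
    }
  }
  propers <- if (length(propers)) bind_rows(propers) else tibble::tibble(i = integer(), j = integer(), k = integer(), l = integer())

  impropers <- tibble::tibble(i = integer(), j = integer(), k = integer(), l = integer())
  if (!is.null(pset)) {
    ikeys <- pset$dihedrals[pset$dihedrals$improper, , drop = FALSE]
    types <- top$atoms$type
    rows <- list()
    for (ctr in seq_len(n_atoms(top))) {
      nb <- adj[[ctr]]
      if (length(nb) != 3) next
      for (r in seq_len(nrow(ikeys))) {
        key <- c(ikeys$a1[r], ikeys$a2[r], ikeys$a3[r], ikeys$a4[r])
        if (key[3] != types[ctr]) next
        perm <- match_improper_neighbors(types[nb], key[c(1, 2, 4)])
        if (!is.null(perm)) {
          ord <- nb[perm]
          rows[[length(rows) + 1L]] <- tibble::tibble(i = ord[1], j = ord[2], k = ctr, l = ord[3])
          break  # one improper per matching center
        }
      }
    }
    if (length(rows)) impropers <- distinct(bind_rows(rows))
  }

  list(bonds = bonds, angles = angles, propers = propers, impropers = impropers)
}

# Match the three neighbor types against improper key positions 1, 2, 4
# (wildcard X allowed); returns a permutation of 1:3 or NULL.
match_improper_neighbors <- function(nb_types, key3) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    ok <- all(key3 == "X" | nb_types[p] == key3)
    if (ok) return(p)
  }
  NULL
}
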