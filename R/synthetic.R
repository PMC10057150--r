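#' Torsion definitions
#'
#' A labelled quadruple of 1-based atom indices defining a torsion to
#' monitor, scan or fit.
#'
#' @param label short label, e.g. `"tau1"`.
#' @param indices integer vector of four distinct atom indices.
#' @param atom_names optional human-readable atom-name string.
#' @return An object of class `torsion_definition`.
#' @export
torsion_definition <- function(label, indices, atom_names = NULL) {
  indices <- as.integer(indices)
  stopifnot(length(indices) == 4L, !anyDuplicated(indices))
  structure(list(label = label, indices = indices,
                 atom_names = atom_names %||% paste(indices, collapse = "-")),
            class = "torsion_definition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.torsion_definition <- function(x, ...) {
  cat("<torsion> ", x$label, ": atoms ", paste(x$indices, collapse = "-"),
      " (", x$atom_names, ")\n", sep = "")
  invisible(x)
}

# --- internal-coordinate (NeRF) placement -------------------------------

normalize <- function(v) v / vnorm(v)

# Position X bonded to P with |X-P| = r, angle X-P-A = theta and torsion
# X-P-A-D = phi (degrees, measure_torsion convention).
place_atom <- function(xP, xA, xD, r, theta, phi) {
  e1 <- normalize(xA - xP)
  t <- xD - xA
  e3 <- normalize(cross3(e1, t))
  e2 <- cross3(e3, e1)
  th <- theta * .DEG; ph <- phi * .DEG
  xP + r * (cos(th) * e1 + sin(th) * (cos(ph) * e2 - sin(ph) * e3))
}

place_third <- function(xP, xA, r, theta) {
  e1 <- normalize(xA - xP)
  ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- normalize(cross3(cross3(e1, ref), e1))
  th <- theta * .DEG
  xP + r * (cos(th) * e1 + sin(th) * e2)
}

# Dihedral separation (about the P-parent axis) of two children placed at
# parent angles theta1, theta2 that realizes sibling angle `sib` exactly.
sibling_delta <- function(theta1, theta2, sib) {
  c1 <- cos(theta1 * .DEG); c2 <- cos(theta2 * .DEG)
  s1 <- sin(theta1 * .DEG); s2 <- sin(theta2 * .DEG)
  cd <- (cos(sib * .DEG) - c1 * c2) / (s1 * s2)
  acos(max(-1, min(1, cd))) / .DEG
}

# Build coordinates from a z-matrix tibble with columns
# name, type, p (parent), a (angle ref), d (dihedral ref), phi; bond
# lengths and angles come from the parameter set (equilibrium values), so
# every tree bond and every parent-referenced angle is strain-free.
build_zmat <- function(zmat, pset) {
  n <- nrow(zmat)
  coords <- matrix(NA_real_, n, 3)
  get_r <- function(t1, t2) {
    p <- lookup_bond(pset, c(t1, t2))
    if (nrow(p) == 0) abort(paste("fixture bond parameter missing:", t1, t2),
                            class = "boronfit_parameter_gap")
    p$r_eq
  }
  get_th <- function(t1, t2, t3) {
    p <- lookup_angle(pset, c(t1, t2, t3))
    if (nrow(p) == 0) abort(paste("fixture angle parameter missing:", t1, t2, t3),
                            class = "boronfit_parameter_gap")
    p$theta_eq
  }
  types <- zmat$type
  for (q in seq_len(n)) {
    if (q == 1L) { coords[1, ] <- c(0, 0, 0); next }
    p <- zmat$p[q]
    r <- get_r(types[q], types[p])
    if (q == 2L) { coords[2, ] <- coords[p, ] + c(r, 0, 0); next }
    a <- zmat$a[q]
    th <- get_th(types[q], types[p], types[a])
    if (is.na(zmat$d[q])) {
      coords[q, ] <- place_third(coords[p, ], coords[a, ], r, th)
    } else {
      coords[q, ] <- place_atom(coords[p, ], coords[a, ], coords[zmat$d[q], ],
                                r, th, zmat$phi[q])
    }
  }
  coords
}

# Default per-type partial charges for fixtures; boron absorbs the residual
# so every fixture is exactly neutral.
fixture_charges <- function(types) {
  base <- c(b = 0, o = -0.65, oh = -0.65, ho = 0.42, hn = 0.38, h1 = 0.06,
            hc = 0.03, ha = 0.13, c2 = 0.10, c3 = 0.05, ca = -0.10,
            cx = 0.05, "2c" = 0.12, n3 = -0.85)
  q <- unname(base[types])
  q[types == "b"] <- -sum(q[types != "b"]) / sum(types == "b")
  round(q, 6)
}

zrow <- function(name, type, p = NA, a = NA, d = NA, phi = NA) {
  tibble::tibble(name = name, type = type, p = as.integer(p), a = as.integer(a),
                 d = as.integer(d), phi = as.numeric(phi))
}

# Planar aromatic ring rows: the ipso atom `first` must already be in the
# z-matrix; appends C2..C6 (chained, phi 180 then 0) and the five ring
# hydrogens. `first_ref` is the exocyclic atom bonded to the ipso carbon.
aryl_ring_rows <- function(first, first_ref) {
  i <- first
  bind_rows(
    zrow("C2", "ca", i, first_ref, NA, NA),          # placed as in-plane third atom
    zrow("C3", "ca", i + 1, i, first_ref, 180),
    zrow("C4", "ca", i + 2, i + 1, i, 0),
    zrow("C5", "ca", i + 3, i + 2, i + 1, 0),
    zrow("C6", "ca", i + 4, i + 3, i + 2, 0),
    zrow("H2", "ha", i + 1, i, first_ref, 0),
    zrow("H3", "ha", i + 2, i + 1, i, 180),
    zrow("H4", "ha", i + 3, i + 2, i + 1, 180),
    zrow("H5", "ha", i + 4, i + 3, i + 2, 180),
    zrow("H6", "ha", i + 5, i + 4, i + 3, 180)
  )
}

#' Toy boronate fixtures
#'
#' Small, deterministic serine-adduct analogs of the boronate warheads the
#' built-in library parameterizes. They are reduced analogs, not full
#' compounds: each exists so that every dihedral key of the built-in
#' library is enumerable in at least one fixture (see
#' [audit_fixture_coverage()]), with idealized geometry built at the
#' equilibrium bond lengths and angles of the parameter library. The
#' `"ester"` kind is a boronate diol-ester analog carrying the
#' ester-oxygen and terminal-methylene keys (including the improper) that
#' the four named warhead analogs cannot realize in a small fragment.
#'
#' Atom types follow the serine-adduct interpretation of the library:
#' `2c` is the serine beta-carbon bearing the linking `oh` oxygen, `cx`
#' the alpha-carbon stand-in; caps are aliphatic hydrogens so fragments
#' stay at or below 24 atoms.
#'
#' @param kind one of `"phenyl"`, `"benzyl"`, `"benzylamino"`,
#'   `"methylamino"`, `"ester"`.
#' @return A list with `topology` ([mm_topology()]), `conformers` (a
#'   single-frame [conformer_set()]) and `torsions` (four
#'   [torsion_definition()]s around the boron center, mirroring the
#'   monitored warhead torsions).
#' @examples
#' fx <- toy_boronate_fixture("phenyl")
#' fx$topology
#' @export
toy_boronate_fixture <- function(kind = c("phenyl", "benzyl", "benzylamino",
                                          "methylamino", "ester")) {
  kind <- match.arg(kind)
  pset <- merge_params(builtin_boronate_params(), generic_fallback_params())
  build <- switch(kind,
    phenyl = fixture_phenyl(),
    benzyl = fixture_benzyl(),
    benzylamino = fixture_benzylamino(),
    methylamino = fixture_methylamino(),
    ester = fixture_ester()
  )
  zmat <- build$zmat
  coords <- build_zmat(zmat, pset)
  bonds <- bind_rows(
    tibble::tibble(i = zmat$p[-1], j = 2:nrow(zmat)),
    build$extra_bonds
  )
  atoms <- tibble::tibble(name = zmat$name, type = zmat$type,
                          charge = fixture_charges(zmat$type))
  top <- mm_topology(atoms, bonds)
  list(topology = top, conformers = conformer_set(coords),
       torsions = build$torsions)
}

# B(aryl)(oh-ho)(oh-ho)(oh-2c<H1,H1>-cx<H3>): tetrahedral phenylboronate
# serine adduct analog, 24 atoms.
fixture_phenyl <- function() {
  zmat <- bind_rows(
    zrow("B",   "b"),                      # 1
    zrow("C1",  "ca", 1),                  # 2
    aryl_ring_rows(2, 1),                  # 3..12 (C2..C6, H2..H6)
    zrow("O1",  "oh", 1, 2, 3, 30),        # 13
    zrow("O2",  "oh", 1, 2, 3, 150),       # 14
    zrow("OG",  "oh", 1, 2, 3, -90),       # 15
    zrow("HO1", "ho", 13, 1, 2, 180),      # 16
    zrow("HO2", "ho", 14, 1, 2, 180),      # 17
    zrow("CB",  "2c", 15, 1, 2, 160),      # 18
    zrow("HB1", "h1", 18, 15, 1, 40),      # 19
    zrow("HB2", "h1", 18, 15, 1, -80),     # 20
    zrow("CA",  "cx", 18, 15, 1, 160),     # 21
    zrow("HA1", "hc", 21, 18, 15, 60),     # 22
    zrow("HA2", "hc", 21, 18, 15, 180),    # 23
    zrow("HA3", "hc", 21, 18, 15, -60)     # 24
  )
  list(
    zmat = zmat,
    extra_bonds = tibble::tibble(i = 7L, j = 2L),   # ring closure C6-C1
    torsions = list(
      torsion_definition("tau1", c(18, 15, 1, 2), "CB-OG-B-C1"),
      torsion_definition("tau2", c(15, 1, 2, 3), "OG-B-C1-C2"),
      torsion_definition("tau3", c(16, 13, 1, 2), "HO1-O1-B-C1"),
      torsion_definition("tau4", c(17, 14, 1, 2), "HO2-O2-B-C1")
    )
  )
}

# B(c2<ha><aryl>)(oh-ho)(oh-2c<H3>)(o-ho): tetrahedral benzylidene-type
# adduct analog carrying the aryl-c2 and mixed hydroxyl/ester-oxygen keys,
# 23 atoms.
fixture_benzyl <- function() {
  d_ca <- sibling_delta(109.50, 120.97, 123.30)   # realizes ca-c2-ha exactly
  zmat <- bind_rows(
    zrow("B",   "b"),                      # 1
    zrow("C7",  "c2", 1),                  # 2
    zrow("H7",  "ha", 2, 1),               # 3
    zrow("C1",  "ca", 2, 1, 3, d_ca),      # 4
    aryl_ring_rows(4, 2),                  # 5..14
    zrow("O1",  "oh", 1, 2, 3, 57),        # 15
    zrow("OG",  "oh", 1, 2, 3, 177),       # 16
    zrow("O3",  "o",  1, 2, 3, -63),       # 17
    zrow("HO1", "ho", 15, 1, 2, 180),      # 18
    zrow("CB",  "2c", 16, 1, 2, 160),      # 19
    zrow("HB1", "h1", 19, 16, 1, 60),      # 20
    zrow("HB2", "h1", 19, 16, 1, 180),     # 21
    zrow("HB3", "h1", 19, 16, 1, -60),     # 22
    zrow("HO3", "ho", 17, 1, 2, 180)       # 23
  )
  list(
    zmat = zmat,
    extra_bonds = tibble::tibble(i = 9L, j = 4L),
    torsions = list(
      torsion_definition("tau1", c(19, 16, 1, 2), "CB-OG-B-C7"),
      torsion_definition("tau2", c(1, 2, 4, 5), "B-C7-C1-C2"),
      torsion_definition("tau3", c(18, 15, 1, 2), "HO1-O1-B-C7"),
      torsion_definition("tau4", c(23, 17, 1, 2), "HO3-O3-B-C7")
    )
  )
}

# B(c3<h1><n3H2><aryl>)(oh-ho)(oh-2c<H3>): trigonal benzylamino adduct
# analog, 24 atoms.
fixture_benzylamino <- function() {
  zmat <- bind_rows(
    zrow("B",   "b"),                      # 1
    zrow("C7",  "c3", 1),                  # 2
    zrow("H7",  "h1", 2, 1),               # 3
    zrow("N",   "n3", 2, 1, 3, -120),      # 4
    zrow("C1",  "ca", 2, 1, 3, 120),       # 5
    aryl_ring_rows(5, 2),                  # 6..15
    zrow("HN1", "hn", 4, 2, 1, 60),        # 16
    zrow("HN2", "hn", 4, 2, 1, 180),       # 17
    zrow("O1",  "oh", 1, 2, 3, 45),        # 18
    zrow("OG",  "oh", 1, 2, 3, 165),       # 19
    zrow("HO1", "ho", 18, 1, 2, 160),      # 20
    zrow("CB",  "2c", 19, 1, 2, 180),      # 21
    zrow("HB1", "h1", 21, 19, 1, 60),      # 22
    zrow("HB2", "h1", 21, 19, 1, 180),     # 23
    zrow("HB3", "h1", 21, 19, 1, -60)      # 24
  )
  list(
    zmat = zmat,
    extra_bonds = tibble::tibble(i = 10L, j = 5L),
    torsions = list(
      torsion_definition("tau1", c(21, 19, 1, 2), "CB-OG-B-C7"),
      torsion_definition("tau2", c(1, 2, 5, 6), "B-C7-C1-C2"),
      torsion_definition("tau3", c(20, 18, 1, 2), "HO1-O1-B-C7"),
      torsion_definition("tau4", c(16, 4, 2, 1), "HN1-N-C7-B")
    )
  )
}

# B(c3<h1,h1><n3H2>)(oh-ho)(oh-2c<H1,H1>-cx<H3>): trigonal methylamino
# serine adduct analog, 17 atoms.
fixture_methylamino <- function() {
  zmat <- bind_rows(
    zrow("B",   "b"),                      # 1
    zrow("C7",  "c3", 1),                  # 2
    zrow("H71", "h1", 2, 1),               # 3
    zrow("H72", "h1", 2, 1, 3, 120),       # 4
    zrow("N",   "n3", 2, 1, 3, -120),      # 5
    zrow("HN1", "hn", 5, 2, 1, 60),        # 6
    zrow("HN2", "hn", 5, 2, 1, 180),       # 7
    zrow("O1",  "oh", 1, 2, 3, 45),        # 8
    zrow("OG",  "oh", 1, 2, 3, 165),       # 9
    zrow("HO1", "ho", 8, 1, 2, 160),       # 10
    zrow("CB",  "2c", 9, 1, 2, 180),       # 11
    zrow("HB1", "h1", 11, 9, 1, 40),       # 12
    zrow("HB2", "h1", 11, 9, 1, -80),      # 13
    zrow("CA",  "cx", 11, 9, 1, 160),      # 14
    zrow("HA1", "hc", 14, 11, 9, 60),      # 15
    zrow("HA2", "hc", 14, 11, 9, 180),     # 16
    zrow("HA3", "hc", 14, 11, 9, -60)      # 17
  )
  list(
    zmat = zmat,
    extra_bonds = tibble::tibble(i = integer(), j = integer()),
    torsions = list(
      torsion_definition("tau1", c(11, 9, 1, 2), "CB-OG-B-C7"),
      torsion_definition("tau2", c(1, 2, 5, 6), "B-C7-N-HN1"),
      torsion_definition("tau3", c(10, 8, 1, 2), "HO1-O1-B-C7"),
      torsion_definition("tau4", c(14, 11, 9, 1), "CA-CB-OG-B")
    )
  )
}

# B(c2H2)(o-ho)(o-c3H2-c3H3): trigonal methylene boronate diol-ester
# analog; realizes the ester-oxygen torsions and the b-ha-c2-ha improper,
# 14 atoms.
fixture_ester <- function() {
  d_ha <- sibling_delta(109.50, 109.50, 120.00)
  zmat <- bind_rows(
    zrow("B",   "b"),                      # 1
    zrow("C7",  "c2", 1),                  # 2
    zrow("H71", "ha", 2, 1),               # 3
    zrow("H72", "ha", 2, 1, 3, d_ha),      # 4
    zrow("O1",  "o",  1, 2, 3, 30),        # 5
    zrow("O2",  "o",  1, 2, 3, 150),       # 6
    zrow("HO1", "ho", 5, 1, 2, 180),       # 7
    zrow("C8",  "c3", 6, 1, 2, 160),       # 8
    zrow("H81", "h1", 8, 6, 1, 40),        # 9
    zrow("H82", "h1", 8, 6, 1, -80),       # 10
    zrow("C9",  "c3", 8, 6, 1, 160),       # 11
    zrow("H91", "hc", 11, 8, 6, 60),       # 12
    zrow("H92", "hc", 11, 8, 6, 180),      # 13
    zrow("H93", "hc", 11, 8, 6, -60)       # 14
  )
  list(
    zmat = zmat,
    extra_bonds = tibble::tibble(i = integer(), j = integer()),
    torsions = list(
      torsion_definition("tau1", c(2, 1, 6, 8), "C7-B-O2-C8"),
      torsion_definition("tau2", c(7, 5, 1, 2), "HO1-O1-B-C7"),
      torsion_definition("tau3", c(5, 1, 6, 8), "O1-B-O2-C8"),
      torsion_definition("tau4", c(1, 6, 8, 11), "B-O2-C8-C9")
    )
  )
}

#' Generic fallback parameters
#'
#' Loads the synthetic GAFF-style generic sp2/sp3 parameter file shipped
#' with the package (`extdata/generic_fallback.frcmod`): idealized aromatic
#' ring, aliphatic, amine and serine-cap bond/angle parameters plus
#' wildcard ring and single-bond torsions. These complete the bonded terms
#' of the toy fixtures that the boron-centered built-in library does not
#' cover.
#'
#' @return A [param_set()].
#' @export
generic_fallback_params <- function() {
  read_frcmod(system.file("extdata", "generic_fallback.frcmod",
                          package = "boronfit", mustWork = TRUE))
}

#' Systematic rigid torsion scan
#'
#' Generates `360 / step` frames by rigidly rotating the component of the
#' molecule containing atom l about the j-k bond axis, in increments of
#' `step` degrees; frame m has measured torsion equal to the input torsion
#' plus `m * step` (wrapped to (-180, 180]). All internal coordinates
#' within each of the two components are preserved exactly; only the
#' relative rotation about the bond changes. The j-k bond must be acyclic
#' (removing it must split the bond graph), and a right-handed rotation
#' about the j to k direction increases the torsion.
#'
#' @param top an [mm_topology()].
#' @param conformer starting geometry (N x 3 matrix or [conformer_set()]).
#' @param torsion a [torsion_definition()].
#' @param step scan step in degrees; must divide 360.
#' @return A [conformer_set()] of `360 / step` frames, the first identical
#'   to the input.
#' @export
scan_torsion <- function(top, conformer, torsion, step = 10) {
  stopifnot(inherits(torsion, "torsion_definition"))
  if (360 %% step != 0) abort("step must divide 360", class = "boronfit_invalid_spec")
  coords <- as_frame(conformer)
  idx <- torsion$indices
  j <- idx[2]; k <- idx[3]
  bonded <- any((top$bonds$i == j & top$bonds$j == k) | (top$bonds$i == k & top$bonds$j == j))
  if (!bonded) abort("torsion axis j-k is not a bond", class = "boronfit_invalid_spec")
  # BFS from k with the j-k edge removed; reaching j means the bond is in
  # a ring and the torsion is not rotatable
  adj <- adjacency_list(top)
  adj[[j]] <- setdiff(adj[[j]], k)
  adj[[k]] <- setdiff(adj[[k]], j)
  seen <- rep(FALSE, n_atoms(top)); seen[k] <- TRUE
  frontier <- k
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  if (seen[j]) {
    abort("the j-k bond lies in a ring; the torsion is not rotatable",
          class = "boronfit_non_rotatable")
  }
  axis <- coords[k, ] - coords[j, ]
  if (vnorm(axis) == 0) abort("degenerate torsion axis", class = "boronfit_degenerate_geometry")
  u <- normalize(axis)
  moving <- which(seen)
  nframes <- 360 %/% step
  frames <- map(seq_len(nframes) - 1L, function(m) {
    delta <- m * step * .DEG
    out <- coords
    if (delta != 0) {
      rel <- sweep(coords[moving, , drop = FALSE], 2, coords[j, ])
      cosd <- cos(delta); sind <- sin(delta)
      rot <- t(apply(rel, 1, function(v) {
        v * cosd + cross3(u, v) * sind + u * sum(u * v) * (1 - cosd)
      }))
      out[moving, ] <- sweep(rot, 2, coords[j, ], `+`)
    }
    out
  })
  conformer_set(frames)
}

#' Torsion-space coverage of a structure set
#'
#' Bins each monitored torsion over 12 bins of 30 degrees on (-180, 180]
#' and reports the fraction of populated bins: the quality check that a
#' fitting structure set adequately samples the space of the torsions
#' being fit. A warning flag is raised when any torsion covers less than
#' half the circle.
#'
#' @param conformers a [conformer_set()].
#' @param torsions a list of [torsion_definition()]s.
#' @param n_bins number of circular bins (default 12).
#' @param warn_below coverage fraction below which the set is flagged.
#' @return A tibble (`torsion`, `coverage`) with attributes `overall_min`
#'   and `flagged`.
#' @export
coverage_check <- function(conformers, torsions, n_bins = 12L, warn_below = 0.5) {
  stopifnot(length(conformers) >= 1)
  rows <- map(torsions, function(td) {
    ang <- map_dbl(conformers$coords, function(m) {
      measure_torsion(m, td$indices[1], td$indices[2], td$indices[3], td$indices[4])
    })
    bins <- angle_bin(ang, n_bins)
    tibble::tibble(torsion = td$label, coverage = length(unique(bins)) / n_bins)
  })
  out <- bind_rows(rows)
  attr(out, "overall_min") <- min(out$coverage)
  attr(out, "flagged") <- any(out$coverage < warn_below)
  if (attr(out, "flagged")) {
    warn(sprintf("structure set covers as little as %.0f%% of torsion space (threshold %.0f%%)",
                 100 * attr(out, "overall_min"), 100 * warn_below),
         class = "boronfit_low_coverage")
  }
  out
}

# bin index on (-180, 180]: bin 1 covers (-180, -180 + w], etc.
angle_bin <- function(angle, n_bins) {
  w <- 360 / n_bins
  b <- ceiling((wrap_angle(angle) + 180) / w)
  b[b < 1] <- 1L
  as.integer(b)
}

#' Synthetic QM-like energies from known parameters
#'
#' Emits per-frame energies equal to the molecular-mechanics energy under a
#' chosen "true" parameter set plus a constant offset (emulating the
#' absolute-scale difference between quantum and MM energies) plus
#' independent Gaussian noise. Fitting against these energies with the true
#' parameters as the generator is the package's self-consistency oracle:
#' at zero noise a correctly implemented fitter recovers the generator
#' parameters exactly and an offset K equal to minus the applied offset.
#'
#' @param top an [mm_topology()].
#' @param pset_true the generating [param_set()].
#' @param conformers a [conformer_set()].
#' @param noise_sd Gaussian noise standard deviation, kcal/mol.
#' @param offset constant added to every energy, kcal/mol.
#' @param seed integer seed (noise is reproducible per seed).
#' @param nb optional [nonbonded_params()] included in the generator.
#' @return Numeric vector of energies, kcal/mol, one per frame.
#' @export
synthetic_qm_energies <- function(top, pset_true, conformers, noise_sd = 0,
                                  offset = 0, seed = 1L, nb = NULL) {
  model <- compile_energy_model(top, pset_true, nb = nb)
  e <- map_dbl(conformers$coords, function(m) eval_energy_model(model, m))
  noise <- withr::with_seed(as.integer(seed), rnorm(length(e), 0, noise_sd))
  e + offset + noise
}

#' Audit fixture coverage of the built-in dihedral library
#'
#' Enumerates the torsions of every toy fixture and checks that each
#' dihedral key of the built-in boronate library is realized (resolvable by
#' lookup from an actual torsion path) in at least one fixture.
#'
#' @return A tibble (`key`, `improper`, `fixtures`, `realized`) with one
#'   row per distinct built-in dihedral key.
#' @export
audit_fixture_coverage <- function() {
  pset <- merge_params(builtin_boronate_params(), generic_fallback_params())
  lib <- builtin_boronate_params()$dihedrals
  lib$key <- paste(lib$a1, lib$a2, lib$a3, lib$a4, sep = "-")
  lib <- distinct(lib, .data$key, .data$improper)

  kinds <- c("phenyl", "benzyl", "benzylamino", "methylamino", "ester")
  realized <- map(kinds, function(kd) {
    fx <- toy_boronate_fixture(kd)
    terms <- enumerate_terms(fx$topology, pset)
    types <- fx$topology$atoms$type
    keys <- character()
    for (kind in c("propers", "impropers")) {
      tt <- terms[[kind]]
      for (r in seq_len(nrow(tt))) {
        ty <- types[c(tt$i[r], tt$j[r], tt$k[r], tt$l[r])]
        hit <- lookup_dihedral(pset, ty, improper = kind == "impropers")
        keys <- c(keys, paste(hit$a1, hit$a2, hit$a3, hit$a4, sep = "-"))
      }
    }
    unique(keys)
  })
  names(realized) <- kinds

  lib$fixtures <- map_chr(lib$key, function(k) {
    paste(kinds[map_lgl(realized, function(x) k %in% x)], collapse = ",")
  })
  lib$realized <- nzchar(lib$fixtures)
  tibble::as_tibble(lib[, c("key", "improper", "fixtures", "realized")])
}
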