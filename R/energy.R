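#' AMBER-functional-form molecular-mechanics energies
#'
#' The bonded energy of a conformer is
#' \deqn{E = \sum_{bonds} K_r (r - r_{eq})^2 + \sum_{angles} K_\theta
#'   (\theta - \theta_{eq})^2 + \sum_{torsions} \frac{V_n}{divider}
#'   (1 + \cos(n \phi - \gamma))}
#' with \eqn{K_\theta} per radian squared (angles are converted from degrees
#' at evaluation) and improper torsions using the same Fourier form. The
#' periodicity n is applied literally as a real number, so fitted
#' non-integer and negative periodicities are honoured:
#' \eqn{\cos(-a\phi - \gamma) \ne \cos(a\phi - \gamma)} unless
#' \eqn{\gamma = 0}, and the sign is physically meaningful.
#'
#' `nonbonded_energy()` adds point-charge Coulomb (332.0522173
#' kcal A mol^-1 e^-2) and 12-6 Lennard-Jones terms with Lorentz-Berthelot
#' combination; 1-2 and 1-3 pairs are excluded, 1-4 pairs scaled by 1/1.2
#' (electrostatic) and 1/2.0 (van der Waals). No cutoff is applied: the
#' intended systems are single gas-phase covalent-adduct molecules.
#'
#' @param top an [mm_topology()].
#' @param pset a [param_set()] resolving every enumerated term.
#' @param conformer an N x 3 coordinate matrix (Angstrom), or a
#'   [conformer_set()] whose first frame is used.
#' @param terms optionally a precomputed [enumerate_terms()] list.
#' @return `bonded_energy()` and `nonbonded_energy()` return the energy in
#'   kcal/mol with a `breakdown` attribute (tibble of per-term
#'   contributions); `total_mm_energy()` returns the sum with a `components`
#'   attribute.
#' @examples
#' fx <- toy_boronate_fixture("methylamino")
#' p <- merge_params(builtin_boronate_params(), generic_fallback_params())
#' bonded_energy(fx$topology, p, fx$conformers)
#' @export
bonded_energy <- function(top, pset, conformer, terms = NULL) {
  coords <- as_frame(conformer)
  if (is.null(terms)) terms <- enumerate_terms(top, pset)
  types <- top$atoms$type
  rows <- list()
  missing <- character()

  for (r in seq_len(nrow(terms$bonds))) {
    i <- terms$bonds$i[r]; j <- terms$bonds$j[r]
    p <- lookup_bond(pset, types[c(i, j)])
    if (nrow(p) == 0) { missing <- c(missing, paste(types[c(i, j)], collapse = "-")); next }
    rr <- measure_bond(coords, i, j)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      term = "bond", atoms = paste(i, j), key = paste(types[c(i, j)], collapse = "-"),
      value = rr, energy = p$k_r * (rr - p$r_eq)^2)
  }
  for (r in seq_len(nrow(terms$angles))) {
    ijk <- c(terms$angles$i[r], terms$angles$j[r], terms$angles$k[r])
    p <- lookup_angle(pset, types[ijk])
    if (nrow(p) == 0) { missing <- c(missing, paste(types[ijk], collapse = "-")); next }
    th <- measure_angle(coords, ijk[1], ijk[2], ijk[3])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      term = "angle", atoms = paste(ijk, collapse = " "),
      key = paste(types[ijk], collapse = "-"),
      value = th, energy = p$k_theta * ((th - p$theta_eq) * .DEG)^2)
  }
  for (kind in c("propers", "impropers")) {
    tt <- terms[[kind]]
    for (r in seq_len(nrow(tt))) {
      ijkl <- c(tt$i[r], tt$j[r], tt$k[r], tt$l[r])
      p <- lookup_dihedral(pset, types[ijkl], improper = kind == "impropers")
      if (nrow(p) == 0) { missing <- c(missing, paste(types[ijkl], collapse = "-")); next }
      phi <- measure_torsion(coords, ijkl[1], ijkl[2], ijkl[3], ijkl[4])
      e <- sum((p$v_n / p$divider) * (1 + cos((p$n * phi - p$gamma) * .DEG)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = if (kind == "propers") "dihedral" else "improper",
        atoms = paste(ijkl, collapse = " "),
        key = paste(types[ijkl], collapse = "-"), value = phi, energy = e)
    }
  }
  if (length(missing) > 0) {
    abort(paste("missing force-field parameters for key(s):",
                paste(unique(missing), collapse = ", ")),
          class = "boronfit_parameter_gap")
  }
  breakdown <- if (length(rows)) bind_rows(rows) else
    tibble::tibble(term = character(), atoms = character(), key = character(),
                   value = numeric(), energy = numeric())
  structure(sum(breakdown$energy), breakdown = breakdown)
}

as_frame <- function(conformer) {
  if (inherits(conformer, "conformer_set")) conformer$coords[[1]] else unname(as.matrix(conformer))
}

#' Nonbonded parameter table
#'
#' Per-atom-type Lennard-Jones parameters (`rstar` in Angstrom, `epsilon`
#' in kcal/mol) plus the global 1-4 scale factors. These are user-supplied
#' constants of the surrounding force field, not fitted quantities.
#'
#' @param lj tibble with columns `type`, `rstar`, `epsilon`.
#' @param scee,scnb 1-4 divisors for electrostatics and Lennard-Jones
#'   (AMBER defaults 1.2 and 2.0).
#' @return An object of class `nonbonded_params`.
#' @export
nonbonded_params <- function(lj, scee = 1.2, scnb = 2.0) {
  lj <- tibble::as_tibble(lj)
  stopifnot(all(c("type", "rstar", "epsilon") %in% names(lj)),
            all(lj$epsilon >= 0), all(lj$rstar > 0))
  structure(list(lj = lj, scee = scee, scnb = scnb), class = "nonbonded_params")
}

#' Generic Lennard-Jones parameters for the boronate fixtures
#'
#' A small synthetic table of GAFF-style van der Waals radii and well
#' depths covering the atom types used by [toy_boronate_fixture()]; the
#' boron entry is a generic placeholder since standard small-molecule
#' force fields carry no boron LJ type.
#'
#' @return A [nonbonded_params()] object.
#' @export
default_nonbonded <- function() {
  nonbonded_params(tibble::tribble(
    ~type, ~rstar, ~epsilon,
    "b",  2.0000, 0.0340,
    "o",  1.6612, 0.2100,
    "oh", 1.7210, 0.2104,
    "ho", 0.3019, 0.0047,
    "hn", 0.6000, 0.0157,
    "ha", 1.4590, 0.0150,
    "h1", 1.3870, 0.0157,
    "hc", 1.4870, 0.0157,
    "c2", 1.9080, 0.0860,
    "c3", 1.9080, 0.1094,
    "ca", 1.9080, 0.0860,
    "cx", 1.9080, 0.1094,
    "2c", 1.9080, 0.1094,
    "n3", 1.8240, 0.1700
  ))
}

#' @param nb a [nonbonded_params()].
#' @rdname bonded_energy
#' @export
nonbonded_energy <- function(top, nb, conformer) {
  stopifnot(inherits(nb, "nonbonded_params"))
  coords <- as_frame(conformer)
  n <- n_atoms(top)
  types <- top$atoms$type
  qs <- top$atoms$charge
  idx <- match(types, nb$lj$type)
  if (anyNA(idx)) {
    abort(paste("missing Lennard-Jones parameters for type(s):",
                paste(unique(types[is.na(idx)]), collapse = ", ")),
          class = "boronfit_parameter_gap")
  }
  rstar <- nb$lj$rstar[idx]; eps <- nb$lj$epsilon[idx]
  d <- bond_distance_matrix(top, max_d = 3L)
  elec <- 0; vdw <- 0
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (d[i, j] <= 2) next
      r <- vnorm(coords[i, ] - coords[j, ])
      se <- if (d[i, j] == 3) 1 / nb$scee else 1
      sv <- if (d[i, j] == 3) 1 / nb$scnb else 1
      ee <- se * .COULOMB_KCAL * qs[i] * qs[j] / r
      rmin <- rstar[i] + rstar[j]
      eij <- sqrt(eps[i] * eps[j])
      vv <- sv * eij * ((rmin / r)^12 - 2 * (rmin / r)^6)
      elec <- elec + ee; vdw <- vdw + vv
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = if (d[i, j] == 3) "nonbonded14" else "nonbonded",
        atoms = paste(i, j), key = paste(types[c(i, j)], collapse = "-"),
        value = r, energy = ee + vv)
    }
  }
  breakdown <- if (length(rows)) bind_rows(rows) else
    tibble::tibble(term = character(), atoms = character(), key = character(),
                   value = numeric(), energy = numeric())
  structure(elec + vdw, elec = elec, vdw = vdw, breakdown = breakdown)
}

#' @rdname bonded_energy
#' @export
total_mm_energy <- function(top, pset, conformer, nb = NULL, terms = NULL) {
  eb <- bonded_energy(top, pset, conformer, terms = terms)
  en <- if (is.null(nb)) 0 else nonbonded_energy(top, nb, conformer)
  components <- c(bonded = as.numeric(eb), nonbonded = as.numeric(en))
  structure(as.numeric(eb) + as.numeric(en), components = components,
            breakdown = bind_rows(attr(eb, "breakdown"), attr(en, "breakdown")))
}

#' Per-frame energy table for a conformer set
#'
#' @param conformers a [conformer_set()].
#' @inheritParams bonded_energy
#' @param nb optional [nonbonded_params()]; omitted means bonded-only.
#' @return A tibble with one row per frame: `frame`, `bond`, `angle`,
#'   `dihedral`, `improper`, `nonbonded`, `total` (kcal/mol).
#' @export
mm_energy_table <- function(top, pset, conformers, nb = NULL) {
  terms <- enumerate_terms(top, pset)
  rows <- vector("list", length(conformers$coords))
  for (f in seq_along(conformers$coords)) {
    e <- total_mm_energy(top, pset, conformers$coords[[f]], nb = nb, terms = terms)
    br <- attr(e, "breakdown")
    by <- vapply(c("bond", "angle", "dihedral", "improper"),
                 function(k) sum(br$energy[br$term == k]), numeric(1))
    rows[[f]] <- tibble::tibble(frame = f, bond = by[["bond"]], angle = by[["angle"]],
                                dihedral = by[["dihedral"]], improper = by[["improper"]],
                                nonbonded = sum(br$energy[startsWith(br$term, "nonbonded")]),
                                total = as.numeric(e))
  }
  bind_rows(rows)
}

# --- compiled (vectorized, breakdown-free) energy evaluation ------------
# Internal fast path used by the fitter and the synthetic-energy
# generator, where the same topology is evaluated over many frames.

compile_energy_model <- function(top, pset, nb = NULL, terms = NULL) {
  if (is.null(terms)) terms <- enumerate_terms(top, pset)
  types <- top$atoms$type
  missing <- character()

  bl <- terms$bonds
  bp <- map(seq_len(nrow(bl)), function(r) lookup_bond(pset, types[c(bl$i[r], bl$j[r])]))
  bad <- map_int(bp, nrow) == 0
  if (any(bad)) missing <- c(missing, vapply(which(bad), function(r)
    paste(types[c(bl$i[r], bl$j[r])], collapse = "-"), character(1)))

  al <- terms$angles
  ap <- map(seq_len(nrow(al)), function(r) lookup_angle(pset, types[c(al$i[r], al$j[r], al$k[r])]))
  bad <- map_int(ap, nrow) == 0
  if (any(bad)) missing <- c(missing, vapply(which(bad), function(r)
    paste(types[c(al$i[r], al$j[r], al$k[r])], collapse = "-"), character(1)))

  tl <- bind_rows(mutate(terms$propers, improper = FALSE),
                  mutate(terms$impropers, improper = TRUE))
  texp <- list()
  for (r in seq_len(nrow(tl))) {
    key <- types[c(tl$i[r], tl$j[r], tl$k[r], tl$l[r])]
    hit <- lookup_dihedral(pset, key, improper = tl$improper[r])
    if (nrow(hit) == 0) { missing <- c(missing, paste(key, collapse = "-")); next }
    texp[[length(texp) + 1L]] <- tibble::tibble(
      i = tl$i[r], j = tl$j[r], k = tl$k[r], l = tl$l[r],
      vd = hit$v_n / hit$divider, gamma = hit$gamma, n = hit$n)
  }
  if (length(missing) > 0) {
    abort(paste("missing force-field parameters for key(s):",
                paste(unique(missing), collapse = ", ")),
          class = "boronfit_parameter_gap")
  }
  tors <- if (length(texp)) bind_rows(texp) else
    tibble::tibble(i = integer(), j = integer(), k = integer(), l = integer(),
                   vd = numeric(), gamma = numeric(), n = numeric())

  model <- list(
    bi = bl$i, bj = bl$j,
    bk = map_dbl(bp, "k_r"), br = map_dbl(bp, "r_eq"),
    ai = al$i, aj = al$j, ak = al$k,
    akt = map_dbl(ap, "k_theta"), ath = map_dbl(ap, "theta_eq"),
    tors = tors
  )
  if (!is.null(nb)) {
    n <- n_atoms(top)
    d <- bond_distance_matrix(top, max_d = 3L)
    idx <- match(types, nb$lj$type)
    if (anyNA(idx)) {
      abort(paste("missing Lennard-Jones parameters for type(s):",
                  paste(unique(types[is.na(idx)]), collapse = ", ")),
            class = "boronfit_parameter_gap")
    }
    prs <- which(upper.tri(d) & d > 2, arr.ind = TRUE)
    s14 <- d[prs] == 3
    qi <- top$atoms$charge[prs[, 1]]; qj <- top$atoms$charge[prs[, 2]]
    model$nb <- list(
      i = prs[, 1], j = prs[, 2],
      qq = .COULOMB_KCAL * qi * qj * ifelse(s14, 1 / nb$scee, 1),
      eps = sqrt(nb$lj$epsilon[idx[prs[, 1]]] * nb$lj$epsilon[idx[prs[, 2]]]) *
        ifelse(s14, 1 / nb$scnb, 1),
      rmin = nb$lj$rstar[idx[prs[, 1]]] + nb$lj$rstar[idx[prs[, 2]]]
    )
  }
  model
}

torsions_vectorized <- function(coords, i, j, k, l) {
  b1 <- coords[j, , drop = FALSE] - coords[i, , drop = FALSE]
  b2 <- coords[k, , drop = FALSE] - coords[j, , drop = FALSE]
  b3 <- coords[l, , drop = FALSE] - coords[k, , drop = FALSE]
  crossm <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- crossm(b1, b2); n2 <- crossm(b2, b3)
  x <- rowSums(n1 * n2)
  y <- rowSums(crossm(n1, n2) * b2) / sqrt(rowSums(b2 * b2))
  wrap_angle(atan2(y, x) / .DEG)
}

eval_energy_model <- function(model, coords) {
  e <- 0
  if (length(model$bi) > 0) {
    dv <- coords[model$bj, , drop = FALSE] - coords[model$bi, , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    e <- e + sum(model$bk * (r - model$br)^2)
  }
  if (length(model$ai) > 0) {
    u <- coords[model$ai, , drop = FALSE] - coords[model$aj, , drop = FALSE]
    v <- coords[model$ak, , drop = FALSE] - coords[model$aj, , drop = FALSE]
    cth <- pmin(1, pmax(-1, rowSums(u * v) / sqrt(rowSums(u * u) * rowSums(v * v))))
    th <- acos(cth) / .DEG
    e <- e + sum(model$akt * ((th - model$ath) * .DEG)^2)
  }
  tt <- model$tors
  if (nrow(tt) > 0) {
    phi <- torsions_vectorized(coords, tt$i, tt$j, tt$k, tt$l)
    e <- e + sum(tt$vd * (1 + cos((tt$n * phi - tt$gamma) * .DEG)))
  }
  if (!is.null(model$nb)) {
    dv <- coords[model$nb$j, , drop = FALSE] - coords[model$nb$i, , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    sr <- (model$nb$rmin / r)^6
    e <- e + sum(model$nb$qq / r) + sum(model$nb$eps * (sr^2 - 2 * sr))
  }
  e
}
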