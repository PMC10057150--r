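#' Force-field parameter sets
#'
#' A `param_set` is a typed store of AMBER bonded parameters keyed by
#' atom-type tuples: harmonic bonds (2 types), harmonic angles (3 types) and
#' Fourier dihedrals (4 types, proper or improper). A dihedral key may carry
#' several rows; they are additive Fourier terms, the AMBER norm for
#' multi-term torsion series. Lookups are symmetric under key reversal.
#'
#' Units are the AMBER conventions: force constants in kcal/mol/A^2 (bonds)
#' and kcal/mol/rad^2 (angles), equilibrium lengths in Angstrom, equilibrium
#' and phase angles in degrees, barrier heights in kcal/mol. Periodicities
#' are stored as real numbers and evaluated literally: a fitted torsion
#' library may legitimately print non-integer or negative periodicities, and
#' reinterpreting them (for example as frcmod continuation flags) would
#' change the energy model. See [write_frcmod()] for the export dialects.
#'
#' @param bonds tibble with columns `a1, a2, k_r, r_eq` (optionally `note`).
#' @param angles tibble with columns `a1, a2, a3, k_theta, theta_eq`
#'   (optionally `note`).
#' @param dihedrals tibble with columns `a1, a2, a3, a4, divider, v_n,
#'   gamma, n, improper` (optionally `note`). `improper` is logical; the
#'   central atom of an improper is the third type, per AMBER convention.
#' @return A `param_set` object (list of three tibbles). Duplicate rows with
#'   identical key (up to reversal) and identical numeric values are
#'   collapsed to one; rows sharing a key but differing numerically are kept
#'   as additive terms.
#' @seealso [builtin_boronate_params()], [lookup_dihedral()], [read_frcmod()]
#' @export
param_set <- function(bonds = NULL, angles = NULL, dihedrals = NULL) {
  bonds <- validate_param_tbl(bonds, c("a1", "a2"), c("k_r", "r_eq"))
  angles <- validate_param_tbl(angles, c("a1", "a2", "a3"), c("k_theta", "theta_eq"))
  dihedrals <- validate_param_tbl(
    dihedrals, c("a1", "a2", "a3", "a4"),
    c("divider", "v_n", "gamma", "n")
  )
  if (!"improper" %in% names(dihedrals)) dihedrals$improper <- FALSE
  stopifnot(all(bonds$k_r > 0), all(bonds$r_eq > 0))
  stopifnot(all(angles$k_theta > 0), all(angles$theta_eq > 0), all(angles$theta_eq < 180))
  stopifnot(all(dihedrals$divider >= 1), all(is.finite(dihedrals$gamma)), all(is.finite(dihedrals$n)))

  bonds <- collapse_duplicates(bonds, 2L)
  angles <- collapse_duplicates(angles, 3L)
  dihedrals <- collapse_duplicates(dihedrals, 4L)
  structure(list(bonds = bonds, angles = angles, dihedrals = dihedrals),
            class = "param_set")
}

validate_param_tbl <- function(tbl, key_cols, val_cols) {
  if (is.null(tbl)) {
    tbl <- tibble::as_tibble(setNames(
      c(rep(list(character()), length(key_cols)), rep(list(numeric()), length(val_cols)),
        list(character())),
      c(key_cols, val_cols, "note")
    ))
  }
  tbl <- tibble::as_tibble(tbl)
  missing <- setdiff(c(key_cols, val_cols), names(tbl))
  if (length(missing) > 0) {
    abort(paste("parameter table lacks columns:", paste(missing, collapse = ", ")),
          class = "boronfit_invalid_key")
  }
  if (!"note" %in% names(tbl)) tbl$note <- rep("", nrow(tbl))
  for (kc in key_cols) check_type_labels(tbl[[kc]])
  tbl
}

check_type_labels <- function(x) {
  ok <- grepl("^([a-z0-9]{1,2}|X)$", x)
  if (!all(ok)) {
    abort(paste("malformed atom-type label(s):", paste(unique(x[!ok]), collapse = ", "),
                "(expect lowercase alphanumeric of <=2 chars, or the wildcard 'X')"),
          class = "boronfit_invalid_key")
  }
  invisible(x)
}

# Canonical orientation of a key: the lexicographically smaller of the key
# and its reversal, so reversed duplicates collapse together.
canonical_key <- function(tbl, arity) {
  cols <- paste0("a", seq_len(arity))
  fwd <- do.call(paste, c(tbl[cols], sep = "-"))
  rev <- do.call(paste, c(tbl[rev(cols)], sep = "-"))
  ifelse(fwd <= rev, fwd, rev)
}

collapse_duplicates <- function(tbl, arity) {
  if (nrow(tbl) == 0) return(tbl)
  val_cols <- setdiff(names(tbl), c(paste0("a", seq_len(arity)), "note"))
  sig <- paste(canonical_key(tbl, arity),
               do.call(paste, c(tbl[val_cols], sep = "|")))
  tbl[!duplicated(sig), , drop = FALSE]
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set> ", nrow(x$bonds), " bonds, ", nrow(x$angles), " angles, ",
      sum(!x$dihedrals$improper), " proper dihedral terms, ",
      sum(x$dihedrals$improper), " improper terms\n", sep = "")
  invisible(x)
}

#' Combine parameter sets
#'
#' Later sets act as fallbacks: their rows are appended after the rows of
#' earlier sets, and identical duplicates collapse. Because lookup scans
#' exact keys before wildcards and returns all rows for the winning key,
#' an explicit entry in the primary set shadows nothing and wildcard
#' fallbacks only fire when no explicit entry exists.
#'
#' @param ... `param_set` objects.
#' @return A merged `param_set`.
#' @export
merge_params <- function(...) {
  sets <- list(...)
  stopifnot(all(map_lgl(sets, inherits, "param_set")))
  param_set(
    bonds = bind_rows(map(sets, "bonds")),
    angles = bind_rows(map(sets, "angles")),
    dihedrals = bind_rows(map(sets, "dihedrals"))
  )
}

#' Built-in boronate parameter library
#'
#' The package's boronate covalent-warhead library: 31 proper dihedral rows
#' and one improper fitted for phenyl-, benzyl-, benzylamino- and
#' methylamino-boronates covalently bound to a serine side chain, plus the 5
#' bond and 20 angle harmonic parameters for the boron center taken from the
#' aryl/alkyl-boronic-acid and boronate-ester force-field literature. Atom
#' types follow GAFF/ff14SB naming (`b`, `oh`, `ca`, `2c`, `cx`, ...).
#'
#' Two printed rows of the dihedral library share the key `oh-b-c3-h1` with
#' different coefficients; they are stored as two additive Fourier terms on
#' that key. Identical duplicate rows are stored once.
#'
#' @return A [param_set()] with the complete library.
#' @examples
#' p <- builtin_boronate_params()
#' lookup_dihedral(p, c("oh", "b", "ca", "ca"))
#' lookup_bond(p, c("b", "o"))
#' @export
builtin_boronate_params <- function() {
  dihedrals <- tibble::tribble(
    ~a1,  ~a2,  ~a3,  ~a4,  ~divider, ~v_n,     ~gamma,   ~n,
    "oh", "b",  "ca", "ca", 1,        15.7206,  170.366,  -1.001,
    "b",  "c2", "ca", "ca", 1,        0.7000,   180.000,  2.000,
    "b",  "o",  "c3", "c3", 1,        3.4800,   106.880,  1.500,
    "b",  "o",  "c3", "h1", 1,        4.1053,   256.511,  2.000,
    "o",  "b",  "o",  "ho", 1,        0.8361,   0.000,    3.000,
    "o",  "b",  "c2", "ha", 1,        2.5070,   172.978,  0.129,
    "o",  "b",  "c2", "ca", 1,        15.7206,  170.366,  -1.000,
    "o",  "b",  "o",  "c3", 1,        0.8347,   0.000,    3.000,
    "ho", "o",  "b",  "c2", 1,        2.0509,   112.044,  5.000,
    "c2", "b",  "o",  "c3", 1,        2.3740,   114.599,  -0.197,
    "cx", "2c", "oh", "b",  1,        3.4800,   106.881,  1.500,
    "ho", "oh", "b",  "o",  1,        0.8361,   0.000,    3.000,
    "ho", "oh", "b",  "c2", 1,        2.0509,   112.044,  5.000,
    "ho", "oh", "b",  "ca", 1,        2.0509,   112.044,  5.000,
    "oh", "b",  "o",  "ho", 1,        0.8361,   0.000,    3.000,
    "oh", "b",  "oh", "ho", 1,        0.8361,   0.000,    3.000,
    "oh", "b",  "c2", "ha", 1,        2.5070,   172.978,  0.129,
    "oh", "b",  "c3", "h1", 1,        2.5070,   172.978,  0.129,
    "oh", "b",  "c2", "ca", 1,        15.7206,  170.366,  -1.000,
    "oh", "b",  "c3", "ca", 1,        15.7205,  170.366,  0.000,
    "h1", "2c", "oh", "b",  1,        4.1053,   256.511,  2.000,
    "2c", "oh", "b",  "o",  1,        2.3743,   114.599,  -0.197,
    "2c", "oh", "b",  "c2", 1,        2.3743,   114.599,  -0.197,
    "h1", "2c", "oh", "b",  1,        4.1053,   256.511,  2.000,
    "oh", "b",  "c3", "n3", 1,        -2.2276,  0.000,    2.156,
    "2c", "oh", "b",  "oh", 1,        -44.4201, 0.000,    1.251,
    "2c", "oh", "b",  "c3", 1,        -12.2011, 0.000,    2.000,
    "ho", "oh", "b",  "c3", 1,        8.0608,   0.000,    -0.101,
    "oh", "b",  "c3", "h1", 1,        0.5691,   0.000,    2.385,
    "oh", "b",  "ca", "ca", 1,        15.7206,  170.366,  -1.001,
    "2c", "oh", "b",  "ca", 1,        2.3743,   114.599,  -0.197
  )
  dihedrals$improper <- FALSE
  dihedrals$note <- "fitted boronate library"
  improper <- tibble::tibble(
    a1 = "b", a2 = "ha", a3 = "c2", a4 = "ha",
    divider = 1, v_n = 1.1000, gamma = 180.000, n = 2.000,
    improper = TRUE, note = "fitted boronate library"
  )

  lit_a <- "literature boronic-acid set (cited as refs 8/12)"
  lit_b <- "literature boronate-ester set (cited as refs 15/19)"
  bonds <- tibble::tribble(
    ~a1,  ~a2, ~k_r,   ~r_eq, ~note,
    "b",  "o",  450.00, 1.510, lit_a,
    "oh", "b",  450.00, 1.510, lit_a,
    "b",  "c2", 340.00, 1.630, lit_a,
    "b",  "ca", 340.00, 1.630, lit_a,
    "b",  "c3", 326.80, 1.510, lit_a
  )
  angles <- tibble::tribble(
    ~a1,  ~a2,  ~a3,  ~k_theta, ~theta_eq, ~note,
    "ca", "c2", "ha", 47.90,    123.30,    lit_a,
    "b",  "o",  "ho", 35.00,    109.50,    lit_a,
    "ho", "oh", "b",  35.00,    109.50,    lit_a,
    "b",  "c2", "ha", 50.00,    109.50,    lit_b,
    "b",  "c3", "h1", 50.00,    109.50,    lit_b,
    "b",  "c3", "hc", 50.00,    109.50,    lit_b,
    "b",  "c3", "c3", 50.00,    109.50,    lit_b,
    "b",  "c3", "n3", 50.00,    109.31,    lit_b,
    "b",  "c2", "ca", 127.38,   120.97,    lit_b,
    "b",  "ca", "ca", 127.38,   120.97,    lit_b,
    "b",  "o",  "c3", 90.00,    109.50,    lit_a,
    "o",  "b",  "o",  90.00,    109.50,    lit_a,
    "oh", "b",  "o",  90.00,    109.50,    lit_a,
    "oh", "b",  "oh", 90.00,    109.50,    lit_a,
    "oh", "b",  "c2", 60.00,    109.50,    lit_a,
    "oh", "b",  "ca", 60.00,    109.50,    lit_a,
    "oh", "b",  "c3", 60.00,    109.50,    lit_a,
    "o",  "b",  "c2", 60.00,    109.50,    lit_a,
    "2c", "oh", "b",  60.00,    109.50,    lit_a,
    "b",  "c3", "ca", 127.38,   111.90,    lit_b
  )
  param_set(bonds = bonds, angles = angles,
            dihedrals = bind_rows(dihedrals, improper))
}

match_key_rows <- function(tbl, key, arity) {
  cols <- paste0("a", seq_len(arity))
  hit <- rep(TRUE, nrow(tbl))
  for (i in seq_len(arity)) hit <- hit & tbl[[cols[i]]] == key[i]
  hit
}

#' Look up bonded parameters by atom-type key
#'
#' Lookup is symmetric under key reversal. For dihedrals the resolution
#' order is: exact key, reversed key, then wildcard patterns with `X` in the
#' first and fourth positions (both orientations); all rows of the first
#' matching pattern are returned (a key may hold a multi-term Fourier
#' series). An unmatched key returns a zero-row tibble and leaves the error
#' policy to the caller.
#'
#' @param pset a [param_set()].
#' @param key character vector of atom-type labels: length 2 (bond), 3
#'   (angle) or 4 (dihedral).
#' @param improper for `lookup_dihedral()`, match improper instead of proper
#'   terms.
#' @return A tibble of matching parameter rows (zero rows if unmatched).
#' @examples
#' p <- builtin_boronate_params()
#' lookup_dihedral(p, c("ca", "ca", "b", "oh"))  # reversed match
#' @export
lookup_dihedral <- function(pset, key, improper = FALSE) {
  stopifnot(inherits(pset, "param_set"))
  key <- as.character(key)
  if (length(key) != 4L) {
    abort("dihedral key must have exactly 4 atom-type labels", class = "boronfit_invalid_key")
  }
  check_type_labels(key)
  tbl <- pset$dihedrals[pset$dihedrals$improper == improper, , drop = FALSE]
  candidates <- list(
    key,
    rev(key),
    c("X", key[2], key[3], "X"),
    c("X", key[3], key[2], "X")
  )
  for (cand in candidates) {
    hit <- match_key_rows(tbl, cand, 4L)
    if (any(hit)) return(tbl[hit, , drop = FALSE])
  }
  tbl[0, , drop = FALSE]
}

#' @rdname lookup_dihedral
#' @export
lookup_bond <- function(pset, key) {
  stopifnot(inherits(pset, "param_set"))
  key <- as.character(key)
  if (length(key) != 2L) abort("bond key must have 2 labels", class = "boronfit_invalid_key")
  check_type_labels(key)
  hit <- match_key_rows(pset$bonds, key, 2L) | match_key_rows(pset$bonds, rev(key), 2L)
  pset$bonds[hit, , drop = FALSE][seq_len(min(1, sum(hit))), , drop = FALSE]
}

#' @rdname lookup_dihedral
#' @export
lookup_angle <- function(pset, key) {
  stopifnot(inherits(pset, "param_set"))
  key <- as.character(key)
  if (length(key) != 3L) abort("angle key must have 3 labels", class = "boronfit_invalid_key")
  check_type_labels(key)
  hit <- match_key_rows(pset$angles, key, 3L) | match_key_rows(pset$angles, rev(key), 3L)
  pset$angles[hit, , drop = FALSE][seq_len(min(1, sum(hit))), , drop = FALSE]
}
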