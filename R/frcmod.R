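#' Read and write AMBER frcmod files
#'
#' `read_frcmod()` parses the sections BOND, ANGLE, DIHE and IMPROPER of an
#' AMBER force-field modification file into a [param_set()] (MASS and NONBON
#' sections are tolerated and skipped). `write_frcmod()` emits one.
#'
#' Two dialects are supported on write. In the default `"literal"` dialect
#' the periodicity PN is written exactly as stored, to 3 decimals; fitted
#' libraries legitimately carry non-integer and negative periodicities, and
#' lines holding one receive a trailing `; nonstandard periodicity` comment.
#' In the `"strict"` dialect PN is rounded to the nearest nonzero integer
#' (with a lossy-export warning when the rounding error exceeds 0.5) and
#' multi-term series on one key are encoded with the standard negative-PN
#' continuation convention. Reading always interprets PN literally, so a
#' file written in the literal dialect round-trips bit-exactly at the
#' written precision (4 decimals for barrier and phase, 3 for periodicity).
#'
#' @param path file path.
#' @param pset a [param_set()].
#' @param dialect `"literal"` (default) or `"strict"`; see Details.
#' @param title first line written to the file.
#' @return `read_frcmod()` a [param_set()]; `write_frcmod()` the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".frcmod")
#' write_frcmod(builtin_boronate_params(), f)
#' p <- read_frcmod(f)
#' @export
read_frcmod <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- NA_character_
  bonds <- list(); angles <- list(); dihes <- list(); imps <- list()
  key_re <- "^\\s*((?:[A-Za-z0-9*]{1,2}\\s?-\\s?){1,3}[A-Za-z0-9*]{1,2})\\s*(\\s-?[0-9].*)$"
  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    txt <- sub("\\s+$", "", raw)
    if (ln == 1L && !grepl("^(MASS|BOND|ANGLE|DIHE|IMPROPER|NONBON|NONB)\\b", txt)) next  # title line
    if (!nzchar(trimws(txt))) next
    up <- toupper(trimws(txt))
    if (up %in% c("MASS", "BOND", "ANGLE", "DIHE", "DIHEDRAL", "IMPROPER", "NONBON", "NONB")) {
      section <- up
      next
    }
    if (is.na(section) || section %in% c("MASS", "NONBON", "NONB")) next
    m <- regmatches(txt, regexec(key_re, txt, perl = TRUE))[[1]]
    if (length(m) == 0) {
      abort(sprintf("frcmod parse failure at line %d: %s", ln, raw),
            class = "boronfit_format_error")
    }
    key <- strsplit(gsub("\\s", "", m[2]), "-", fixed = TRUE)[[1]]
    key <- ifelse(key == "*", "X", key)
    rest <- strsplit(trimws(m[3]), "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(rest))
    take <- function(k) {
      if (length(nums) < k || anyNA(nums[seq_len(k)])) {
        abort(sprintf("frcmod parse failure at line %d: expected %d numeric fields: %s",
                      ln, k, raw), class = "boronfit_format_error")
      }
      nums[seq_len(k)]
    }
    if (section == "BOND") {
      if (length(key) != 2) abort(sprintf("line %d: BOND key needs 2 types", ln), class = "boronfit_format_error")
      v <- take(2)
      bonds[[length(bonds) + 1L]] <- tibble::tibble(a1 = key[1], a2 = key[2], k_r = v[1], r_eq = v[2])
    } else if (section == "ANGLE") {
      if (length(key) != 3) abort(sprintf("line %d: ANGLE key needs 3 types", ln), class = "boronfit_format_error")
      v <- take(2)
      angles[[length(angles) + 1L]] <- tibble::tibble(
        a1 = key[1], a2 = key[2], a3 = key[3], k_theta = v[1], theta_eq = v[2])
    } else {
      if (length(key) != 4) abort(sprintf("line %d: %s key needs 4 types", ln, section), class = "boronfit_format_error")
      if (section %in% c("DIHE", "DIHEDRAL")) {
        v <- take(4)
        dihes[[length(dihes) + 1L]] <- tibble::tibble(
          a1 = key[1], a2 = key[2], a3 = key[3], a4 = key[4],
          divider = v[1], v_n = v[2], gamma = v[3], n = v[4], improper = FALSE)
      } else {
        # IMPROPER lines have no IDIVF field
        v <- take(3)
        imps[[length(imps) + 1L]] <- tibble::tibble(
          a1 = key[1], a2 = key[2], a3 = key[3], a4 = key[4],
          divider = 1, v_n = v[1], gamma = v[2], n = v[3], improper = TRUE)
      }
    }
  }
  param_set(
    bonds = if (length(bonds)) bind_rows(bonds) else NULL,
    angles = if (length(angles)) bind_rows(angles) else NULL,
    dihedrals = if (length(dihes) + length(imps)) bind_rows(c(dihes, imps)) else NULL
  )
}

pad_type <- function(x) formatC(x, width = -2)

fmt_key <- function(...) paste(pad_type(c(...)), collapse = "-")

#' @rdname read_frcmod
#' @export
write_frcmod <- function(pset, path, dialect = c("literal", "strict"),
                         title = "boronfit parameter export") {
  stopifnot(inherits(pset, "param_set"))
  dialect <- match.arg(dialect)
  out <- c(title, "BOND")
  if (nrow(pset$bonds) > 0) {
    out <- c(out, sprintf("%s  %8.2f  %7.3f", mapply(fmt_key, pset$bonds$a1, pset$bonds$a2),
                          pset$bonds$k_r, pset$bonds$r_eq))
  }
  out <- c(out, "", "ANGLE")
  if (nrow(pset$angles) > 0) {
    out <- c(out, sprintf("%s  %8.2f  %8.2f",
                          mapply(fmt_key, pset$angles$a1, pset$angles$a2, pset$angles$a3),
                          pset$angles$k_theta, pset$angles$theta_eq))
  }
  pro <- pset$dihedrals[!pset$dihedrals$improper, , drop = FALSE]
  imp <- pset$dihedrals[pset$dihedrals$improper, , drop = FALSE]
  out <- c(out, "", "DIHE")
  if (nrow(pro) > 0) {
    keys <- mapply(fmt_key, pro$a1, pro$a2, pro$a3, pro$a4)
    if (dialect == "literal") {
      comment <- ifelse(abs(pro$n - round(pro$n)) > 1e-9 | pro$n <= 0,
                        "   ; nonstandard periodicity", "")
      out <- c(out, sprintf("%s %4d %10.4f %10.4f %8.3f%s", keys,
                            as.integer(pro$divider), pro$v_n, pro$gamma, pro$n, comment))
    } else {
      ckey <- canonical_key(pro, 4L)
      for (k in unique(ckey)) {
        rows <- pro[ckey == k, , drop = FALSE]
        n_int <- pmax(1, round(abs(rows$n)))
        err <- abs(abs(rows$n) - n_int)
        if (any(err > 0.5)) {
          warn(sprintf("strict frcmod export of key %s loses periodicity (|error| = %.3f > 0.5)",
                       k, max(err)), class = "boronfit_lossy_export")
        }
        # continuation convention: negative PN on all terms but the last
        pn <- n_int * c(rep(-1, nrow(rows) - 1L), 1)
        out <- c(out, sprintf("%s %4d %10.4f %10.4f %8.3f",
                              mapply(fmt_key, rows$a1, rows$a2, rows$a3, rows$a4),
                              as.integer(rows$divider), rows$v_n, rows$gamma, pn))
      }
    }
  }
  out <- c(out, "", "IMPROPER")
  if (nrow(imp) > 0) {
    out <- c(out, sprintf("%s %10.4f %10.4f %8.3f",
                          mapply(fmt_key, imp$a1, imp$a2, imp$a3, imp$a4),
                          imp$v_n, imp$gamma, imp$n))
  }
  out <- c(out, "")
  writeLines(out, path)
  invisible(path)
}
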