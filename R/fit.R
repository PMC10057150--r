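#' Least-squares alignment of MM and QM energies
#'
#' The fitting objective is \deqn{f(N, E_{QM}, K) = \sum_{i=1}^{N}
#' (E_{MM,i} - E_{QM,i} + K)^2} over the N structures of the fitting set.
#' The offset constant K depends on the molecule and structure set only and
#' aligns the absolute MM and QM energy scales; for fixed MM energies its
#' unique minimizer is the closed form `K = mean(e_qm - e_mm)`, so K is
#' profiled out analytically rather than exposed to the optimizer. The
#' coefficient of determination is computed between the offset-corrected
#' MM energies and the QM energies.
#'
#' @param e_mm,e_qm numeric vectors of equal length, kcal/mol.
#' @param K offset constant, kcal/mol.
#' @return `optimal_offset()` the scalar K; `objective_value()` the scalar
#'   f (kcal^2/mol^2); `r_squared()` the scalar R^2.
#' @examples
#' optimal_offset(c(10, 11, 12), c(1, 2, 3))  # -9, and f at that K is 0
#' @name qm-mm-objective
NULL

#' @rdname qm-mm-objective
#' @export
optimal_offset <- function(e_mm, e_qm) {
  if (length(e_mm) == 0 || length(e_qm) == 0) {
    abort("empty energy vectors", class = "boronfit_empty_input")
  }
  check_aligned(e_mm, e_qm)
  mean(e_qm - e_mm)
}

#' @rdname qm-mm-objective
#' @export
objective_value <- function(e_mm, e_qm, K) {
  check_aligned(e_mm, e_qm)
  sum((e_mm - e_qm + K)^2)
}

#' @rdname qm-mm-objective
#' @export
r_squared <- function(e_mm, e_qm, K) {
  check_aligned(e_mm, e_qm)
  if (length(e_qm) < 2 || sd(e_qm) == 0) {
    abort("R^2 needs at least two structures with nonzero QM energy variance",
          class = "boronfit_degenerate_target")
  }
  1 - sum((e_mm + K - e_qm)^2) / sum((e_qm - mean(e_qm))^2)
}

check_aligned <- function(e_mm, e_qm) {
  if (length(e_mm) != length(e_qm)) {
    abort(sprintf("energy vectors are misaligned (%d MM vs %d QM values)",
                  length(e_mm), length(e_qm)),
          class = "boronfit_alignment_error")
  }
  invisible(TRUE)
}

#' Specify which dihedral parameters float in a fit
#'
#' @param keys character vector of dihedral keys, as `"a1-a2-a3-a4"`
#'   strings or a list of length-4 character vectors. Every Fourier term
#'   stored on a named key floats.
#' @param float which of the per-term quantities `v_n`, `gamma`, `n` float.
#' @param fit_n_continuous when `FALSE`, the periodicity `n` is held fixed
#'   even if listed in `float`. Defaults to `TRUE`: a fitted library may
#'   need non-integer periodicities to reproduce a quantum torsion profile.
#' @param bounds named list of length-2 numeric bounds for `v_n`, `gamma`
#'   and `n`. The default periodicity bound is |n| <= 6.
#' @param multistart number of optimizer starts (the stored parameter
#'   values seed the first start; the rest are drawn inside the bounds).
#' @param seed integer seed controlling the random starts.
#' @param ftol relative f-change convergence tolerance.
#' @return An object of class `fit_spec`.
#' @seealso [fit_dihedrals()]
#' @export
fit_spec <- function(keys, float = c("v_n", "gamma", "n"),
                     fit_n_continuous = TRUE,
                     bounds = list(v_n = c(-100, 100), gamma = c(-360, 720), n = c(-6, 6)),
                     multistart = 8L, seed = 1L, ftol = 1e-10) {
  if (is.character(keys)) keys <- strsplit(keys, "-", fixed = TRUE)
  keys <- map(keys, as.character)
  stopifnot(length(keys) >= 1, all(map_int(keys, length) == 4L))
  for (k in keys) check_type_labels(k)
  if (length(float) == 0) {
    abort("at least one parameter must float", class = "boronfit_invalid_spec")
  }
  float <- match.arg(float, c("v_n", "gamma", "n"), several.ok = TRUE)
  if (!fit_n_continuous) float <- setdiff(float, "n")
  if (length(float) == 0) {
    abort("at least one parameter must float", class = "boronfit_invalid_spec")
  }
  for (b in names(bounds)) {
    if (bounds[[b]][1] >= bounds[[b]][2]) {
      abort(sprintf("bounds for %s are not ordered", b), class = "boronfit_invalid_spec")
    }
  }
  structure(list(keys = keys, float = float, bounds = bounds,
                 multistart = as.integer(multistart), seed = as.integer(seed),
                 ftol = ftol),
            class = "fit_spec")
}

#' Fit dihedral Fourier parameters to quantum single-point energies
#'
#' Nonlinear least squares of the molecular-mechanics energy against QM
#' energies over a conformer set, floating the barrier height, phase and
#' (optionally) real-valued periodicity of the selected dihedral keys. The
#' offset constant K is profiled analytically at every objective
#' evaluation, which removes one flat direction and improves conditioning.
#' A Levenberg-Marquardt local optimizer is run from `multistart` starting
#' points; the lowest objective wins, with ties broken toward the smallest
#' total |v_n| (parsimony). Phases are reported wrapped to \[0, 360).
#'
#' @param top an [mm_topology()].
#' @param pset a [param_set()] resolving every term; rows whose key matches
#'   `spec$keys` float.
#' @param conformers a [conformer_set()] carrying `qm_energy` for every
#'   frame (kcal/mol).
#' @param spec a [fit_spec()].
#' @param nb optional [nonbonded_params()]; when supplied the nonbonded
#'   energy is included in the MM energy during fitting (the choice is
#'   recorded in the result).
#' @return A `fit_result`: list with the updated `param_set`, the fitted
#'   parameter tibble, `K`, objective `f`, `r2`, per-structure residuals
#'   and convergence diagnostics (including the monotone objective trace of
#'   the winning start). Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' \donttest{
#' fx <- toy_boronate_fixture("methylamino")
#' p <- merge_params(builtin_boronate_params(), generic_fallback_params())
#' scan <- scan_torsion(fx$topology, fx$conformers, fx$torsions[[3]], step = 30)
#' qm <- synthetic_qm_energies(fx$topology, p, scan, noise_sd = 0, offset = -1000, seed = 1)
#' fit <- fit_dihedrals(fx$topology, p, set_qm_energies(scan, qm),
#'                      fit_spec("ho-oh-b-c3", multistart = 2))
#' glance(fit)
#' }
#' @export
fit_dihedrals <- function(top, pset, conformers, spec, nb = NULL) {
  stopifnot(inherits(spec, "fit_spec"), inherits(conformers, "conformer_set"))
  e_qm <- conformers$qm_energy
  if (is.null(e_qm)) {
    abort("conformers carry no QM energies", class = "boronfit_alignment_error")
  }
  nframe <- length(conformers)

  # Rows of the dihedral table that float: any row whose key matches a
  # requested key (in either orientation).
  dtbl <- pset$dihedrals
  target_rows <- which(map_lgl(seq_len(nrow(dtbl)), function(r) {
    key <- c(dtbl$a1[r], dtbl$a2[r], dtbl$a3[r], dtbl$a4[r])
    any(map_lgl(spec$keys, function(k) {
      identical(key, k) || identical(key, rev(k))
    }))
  }))
  if (length(target_rows) == 0) {
    abort("no parameter rows match the requested keys", class = "boronfit_invalid_spec")
  }

  # Torsion instances resolved by each floating row: instance phi values
  # are geometry only, so precompute the per-frame phi matrix once.
  terms <- enumerate_terms(top, pset)
  types <- top$atoms$type
  inst <- bind_rows(
    mutate(terms$propers, improper = FALSE),
    mutate(terms$impropers, improper = TRUE)
  )
  inst_rows <- map(seq_len(nrow(inst)), function(q) {
    key <- types[c(inst$i[q], inst$j[q], inst$k[q], inst$l[q])]
    hit <- lookup_dihedral(pset, key, improper = inst$improper[q])
    # identify pset row indices of the resolved terms
    which(map_lgl(seq_len(nrow(dtbl)), function(r) {
      any(dtbl$a1[r] == hit$a1 & dtbl$a2[r] == hit$a2 & dtbl$a3[r] == hit$a3 &
            dtbl$a4[r] == hit$a4 & dtbl$v_n[r] == hit$v_n & dtbl$gamma[r] == hit$gamma &
            dtbl$n[r] == hit$n & dtbl$improper[r] == hit$improper)
    }))
  })
  target_inst <- which(map_lgl(inst_rows, function(rr) any(rr %in% target_rows)))
  if (length(target_inst) == 0) {
    abort("the topology contains no torsion resolving to the requested keys",
          class = "boronfit_invalid_spec")
  }
  phi <- vapply(seq_len(nframe), function(f) {
    vapply(target_inst, function(q) {
      measure_torsion(conformers$coords[[f]], inst$i[q], inst$j[q], inst$k[q], inst$l[q])
    }, numeric(1))
  }, numeric(length(target_inst)))
  phi <- matrix(phi, nrow = length(target_inst))  # instances x frames

  # instance -> floating rows incidence
  inst_row_map <- map(inst_rows[target_inst], function(rr) intersect(rr, target_rows))

  # Base MM energy: everything except the floating rows' contribution.
  pset_zero <- pset
  pset_zero$dihedrals$v_n[target_rows] <- 0
  base_model <- compile_energy_model(top, pset_zero, nb = nb, terms = terms)
  e_base <- vapply(seq_len(nframe), function(f) {
    eval_energy_model(base_model, conformers$coords[[f]])
  }, numeric(1))

  # Parameter vector layout: per floating row, the floating fields in
  # spec$float order.
  fields <- spec$float
  npar_row <- length(fields)
  theta0 <- unlist(map(target_rows, function(r) {
    setNames(as.numeric(dtbl[r, fields]), fields)
  }))
  npar <- length(theta0)
  if (nframe < npar) {
    warn(sprintf("underdetermined fit: %d floating parameters but %d structures",
                 npar, nframe), class = "boronfit_rank_deficiency")
  }
  lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
  for (b in intersect(names(spec$bounds), fields)) {
    pos <- which(rep(fields, length(target_rows)) == b)
    lower[pos] <- spec$bounds[[b]][1]; upper[pos] <- spec$bounds[[b]][2]
  }

  target_energy <- function(theta) {
    tm <- matrix(theta, nrow = npar_row)
    v <- dtbl$v_n[target_rows]; g <- dtbl$gamma[target_rows]; nn <- dtbl$n[target_rows]
    div <- dtbl$divider[target_rows]
    for (fi in seq_along(fields)) {
      val <- tm[fi, ]
      if (fields[fi] == "v_n") v <- val else if (fields[fi] == "gamma") g <- val else nn <- val
    }
    e <- numeric(nframe)
    for (q in seq_along(target_inst)) {
      rr <- match(inst_row_map[[q]], target_rows)
      for (t in rr) {
        e <- e + (v[t] / div[t]) * (1 + cos((nn[t] * phi[q, ] - g[t]) * .DEG))
      }
    }
    e
  }

  residual_fn <- function(theta) {
    e_mm <- e_base + target_energy(theta)
    d <- e_mm - e_qm
    d - mean(d)  # profile out K analytically
  }

  starts <- list(theta0)
  if (spec$multistart > 1L) {
    starts <- c(starts, withr::with_seed(spec$seed, {
      map(seq_len(spec$multistart - 1L), function(s) {
        vapply(seq_len(npar), function(p) {
          fld <- rep(fields, length(target_rows))[p]
          rng <- switch(fld, v_n = c(-20, 20), gamma = c(0, 360), n = c(-6, 6))
          runif(1, max(rng[1], lower[p]), min(rng[2], upper[p]))
        }, numeric(1))
      })
    }))
  }

  runs <- map(starts, function(st) {
    fit <- try(minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper, fn = residual_fn,
      control = minpack.lm::nls.lm.control(ftol = spec$ftol, maxiter = 500)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    list(par = fit$par, f = fit$deviance, trace = fit$rsstrace,
         converged = fit$info %in% 1:4, niter = fit$niter, message = fit$message)
  })
  runs <- runs[!map_lgl(runs, is.null)]
  if (length(runs) == 0) abort("all optimizer starts failed", class = "boronfit_fit_failure")
  fs <- map_dbl(runs, "f")
  vsum <- map_dbl(runs, function(r) {
    tm <- matrix(r$par, nrow = npar_row)
    if ("v_n" %in% fields) sum(abs(tm[which(fields == "v_n"), ])) else 0
  })
  best <- order(fs, vsum)[1]
  win <- runs[[best]]

  e_mm <- e_base + target_energy(win$par)
  K <- optimal_offset(e_mm, e_qm)
  f <- objective_value(e_mm, e_qm, K)
  r2 <- tryCatch(r_squared(e_mm, e_qm, K), error = function(e) NA_real_)

  # write the winning parameters back into the parameter set
  fitted_pset <- pset
  tm <- matrix(win$par, nrow = npar_row)
  for (fi in seq_along(fields)) {
    val <- tm[fi, ]
    if (fields[fi] == "gamma") val <- val %% 360
    fitted_pset$dihedrals[[fields[fi]]][target_rows] <- val
  }
  fitted_pset$dihedrals$note[target_rows] <- "fitted by fit_dihedrals"

  params <- fitted_pset$dihedrals[target_rows, , drop = FALSE] %>%
    mutate(key = paste(.data$a1, .data$a2, .data$a3, .data$a4, sep = "-")) %>%
    select("key", "divider", "v_n", "gamma", "n", "improper")

  structure(list(
    pset = fitted_pset,
    params = params,
    K = K, f = f, r2 = r2,
    residuals = tibble::tibble(structure = seq_len(nframe), e_mm = e_mm, e_qm = e_qm,
                               residual = e_mm - e_qm + K),
    diagnostics = list(converged = win$converged, niter = win$niter,
                       message = win$message, trace = win$trace,
                       starts = length(starts), start_f = fs,
                       nonbonded_included = !is.null(nb)),
    seed = spec$seed, spec = spec
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", nrow(x$params), " dihedral term(s) fitted over ",
      nrow(x$residuals), " structures\n", sep = "")
  cat(sprintf("  K = %.6f kcal/mol, f = %.6g kcal^2/mol^2, R^2 = %.6f\n",
              x$K, x$f, x$r2))
  if (!x$diagnostics$converged) cat("  WARNING: optimizer did not report convergence\n")
  print(x$params)
  invisible(x)
}

#' @param x a `fit_result`.
#' @param ... unused.
#' @rdname fit_dihedrals
#' @method tidy fit_result
#' @export
tidy.fit_result <- function(x, ...) x$params

#' @rdname fit_dihedrals
#' @method glance fit_result
#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(
    K = x$K, f = x$f, r2 = x$r2,
    n_structures = nrow(x$residuals),
    n_terms = nrow(x$params),
    converged = x$diagnostics$converged,
    seed = x$seed
  )
}

#' Canonical form of a dihedral Fourier term
#'
#' A single term \eqn{v (1 + \cos(n\phi - \gamma))} has equivalent
#' parameterizations: \eqn{(v, \gamma, n)} and \eqn{(v, -\gamma, -n)}
#' describe the identical energy, and \eqn{(-v, \gamma + 180, n)} differs
#' only by a constant (which the offset K absorbs in fitting). For
#' comparing fitted terms against generator truth, this helper maps a term
#' to the representative with \eqn{n \ge 0}, \eqn{v \ge 0} and
#' \eqn{\gamma \in [0, 360)}.
#'
#' @param v_n,gamma,n term parameters (vectors accepted).
#' @return A tibble with columns `v_n`, `gamma`, `n` in canonical form.
#' @export
canonical_dihedral_term <- function(v_n, gamma, n) {
  flip_n <- n < 0
  gamma <- ifelse(flip_n, -gamma, gamma)
  n <- abs(n)
  flip_v <- v_n < 0
  gamma <- ifelse(flip_v, gamma + 180, gamma)
  v_n <- abs(v_n)
  tibble::tibble(v_n = v_n, gamma = gamma %% 360, n = n)
}
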