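#' Boltzmann equilibrium conformer populations
#'
#' Converts relative conformer energies into equilibrium percentages at
#' temperature T via the Boltzmann distribution
#' \deqn{p_i = \frac{e^{-\Delta E_i / RT}}{\sum_j e^{-\Delta E_j / RT}}
#'   \times 100}
#' with R = 1.987204e-3 kcal/mol/K. Energies are re-referenced to their
#' minimum internally, so absolute or relative energies may be supplied.
#'
#' @param delta_e numeric vector of conformer energies, kcal/mol; or a
#'   data frame whose first two columns are conformer label and energy.
#' @param temperature temperature in kelvin (default 298 K, the standard
#'   conformational-analysis convention).
#' @param labels optional conformer labels.
#' @return A tibble of class `boltzmann_table` with columns `label`,
#'   `delta_e` (re-referenced, kcal/mol) and `percent`, ordered as given;
#'   the temperature is stored as an attribute.
#' @examples
#' boltzmann_populations(c(0, 2.16, 2.97, 3.54, 4.10))
#' @export
boltzmann_populations <- function(delta_e, temperature = 298, labels = NULL) {
  if (is.data.frame(delta_e)) {
    if (is.null(labels)) labels <- as.character(delta_e[[1]])
    delta_e <- as.numeric(delta_e[[2]])
  }
  if (length(delta_e) == 0) {
    abort("no conformer energies supplied", class = "boronfit_empty_input")
  }
  if (!all(is.finite(delta_e))) {
    abort("conformer energies must be finite", class = "boronfit_invalid_spec")
  }
  stopifnot(temperature > 0)
  de <- delta_e - min(delta_e)
  w <- exp(-de / (.GAS_CONSTANT_KCAL * temperature))
  out <- tibble::tibble(
    label = labels %||% paste0("conf", seq_along(de)),
    delta_e = de,
    percent = 100 * w / sum(w)
  )
  structure(out, temperature = temperature,
            class = c("boltzmann_table", class(out)))
}

#' @export
print.boltzmann_table <- function(x, ...) {
  cat("Boltzmann equilibrium populations at", attr(x, "temperature"), "K\n")
  NextMethod()
}

#' Torsion time series over a conformer set
#'
#' Measures each monitored torsion in every frame.
#'
#' @param conformers a [conformer_set()] (e.g. trajectory frames read with
#'   [read_xyz()] or generated with [scan_torsion()]).
#' @param torsions a list of [torsion_definition()]s (a single definition
#'   is accepted).
#' @return A tibble of class `torsion_series`: columns `torsion`, `frame`,
#'   `angle` (degrees in (-180, 180]), frame order preserved.
#' @export
torsion_timeseries <- function(conformers, torsions) {
  if (inherits(torsions, "torsion_definition")) torsions <- list(torsions)
  rows <- map(torsions, function(td) {
    ang <- map_dbl(seq_along(conformers$coords), function(f) {
      tryCatch(
        measure_torsion(conformers$coords[[f]], td$indices[1], td$indices[2],
                        td$indices[3], td$indices[4]),
        boronfit_degenerate_geometry = function(e) {
          abort(sprintf("degenerate geometry for torsion %s in frame %d", td$label, f),
                class = "boronfit_degenerate_geometry")
        })
    })
    tibble::tibble(torsion = td$label, frame = seq_along(ang), angle = ang)
  })
  out <- bind_rows(rows)
  structure(out, class = c("torsion_series", class(out)))
}

#' Detect populated torsional basins
#'
#' Builds a circular histogram of a torsion series and segments it into
#' basins: maximal runs of contiguous non-empty bins, treated circularly
#' (runs touching across +/-180 are merged). Basins populated below
#' `min_occupancy` are discarded — only geometries visited by more than
#' that fraction of frames are reported. The basin center is the circular
#' mean of the member angles (atan2 of the mean sine and cosine), which
#' averages correctly across the +/-180 wrap.
#'
#' @param series a `torsion_series` tibble (possibly holding several
#'   torsions) or a numeric vector of angles in degrees.
#' @param bin_width histogram bin width in degrees (default 10).
#' @param min_occupancy minimum occupancy fraction for a basin to be
#'   reported (default 0.10).
#' @return A tibble of class `basin_summary`: columns `torsion`, `basin`,
#'   `center` (degrees), `occupancy` (fraction of frames), `support_lo`,
#'   `support_hi` (bin-edge support interval, possibly wrapping) and `n`.
#' @examples
#' detect_basins(c(rnorm(50, 60, 5), rnorm(50, -170, 5)))
#' @export
detect_basins <- function(series, bin_width = 10, min_occupancy = 0.10) {
  if (is.numeric(series)) {
    series <- tibble::tibble(torsion = "tau", frame = seq_along(series),
                             angle = as.numeric(series))
  }
  stopifnot(360 %% bin_width == 0, nrow(series) > 0)
  n_bins <- as.integer(360 / bin_width)
  out <- series %>%
    group_by(.data$torsion) %>%
    group_modify2(function(df) basins_one(df$angle, n_bins, bin_width, min_occupancy)) %>%
    ungroup()
  structure(out, class = c("basin_summary", class(out)))
}

# dplyr::group_modify with a simpler contract
group_modify2 <- function(.data, f) {
  dplyr::group_modify(.data, function(df, key) f(df))
}

basins_one <- function(angles, n_bins, bin_width, min_occupancy) {
  bins <- angle_bin(angles, n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  occupied <- counts > 0
  if (!any(occupied)) return(empty_basins())
  # label runs over the linear bin sequence, then merge across the wrap
  run_id <- integer(n_bins); rid <- 0L
  for (b in seq_len(n_bins)) {
    if (occupied[b]) {
      if (b == 1L || !occupied[b - 1L]) rid <- rid + 1L
      run_id[b] <- rid
    }
  }
  if (occupied[1L] && occupied[n_bins] && run_id[1L] != run_id[n_bins]) {
    run_id[run_id == run_id[n_bins]] <- run_id[1L]
  }
  ids <- unique(run_id[run_id > 0])
  total <- length(angles)
  rows <- map(ids, function(id) {
    member_bins <- which(run_id == id)
    in_basin <- bins %in% member_bins
    occ <- sum(in_basin) / total
    # support interval: contiguous bin-edge span, possibly wrapping
    if (length(member_bins) == n_bins) {
      lo <- -180; hi <- 180
    } else {
      # start of the circular run: the member whose predecessor bin is empty
      start <- member_bins[!(((member_bins - 2L) %% n_bins) + 1L) %in% member_bins][1]
      lo <- -180 + (start - 1L) * bin_width
      len <- length(member_bins)
      hi <- wrap_angle(lo + len * bin_width)
      if (len * bin_width == 360) hi <- lo
    }
    tibble::tibble(center = circular_mean(angles[in_basin]),
                   occupancy = occ, support_lo = lo, support_hi = hi,
                   n = sum(in_basin))
  })
  res <- bind_rows(rows) %>% filter(.data$occupancy >= min_occupancy)
  if (nrow(res) == 0) return(empty_basins())
  res <- res %>% arrange(.data$center) %>% mutate(basin = row_number()) %>%
    select("basin", "center", "occupancy", "support_lo", "support_hi", "n")
  res
}

empty_basins <- function() {
  tibble::tibble(basin = integer(), center = numeric(), occupancy = numeric(),
                 support_lo = numeric(), support_hi = numeric(), n = integer())
}

#' Compare detected basins to reference conformer minima
#'
#' For each reference conformer and torsion, finds the nearest detected
#' basin center by minimal circular distance and flags whether it falls
#' within a matching threshold. This is the correspondence check between
#' torsion preferences sampled by molecular dynamics and the minima located
#' by a quantum conformational analysis.
#'
#' @param basins a `basin_summary` (from [detect_basins()]) with a
#'   `torsion` column.
#' @param reference a data frame of reference minima: either long format
#'   (columns `conformer`, `torsion`, `angle`) or wide format (column
#'   `conformer` plus one column per torsion label).
#' @param threshold circular distance (degrees) below which a reference
#'   angle counts as matched (default 30).
#' @return A tibble: `conformer`, `torsion`, `ref_angle`, `basin_center`,
#'   `delta` (minimal circular distance, degrees; NA when no basin was
#'   detected for that torsion) and `matched`.
#' @examples
#' b <- detect_basins(rnorm(100, -65, 4))
#' b$torsion <- "tau3"
#' compare_to_reference(b, data.frame(conformer = "1A", torsion = "tau3", angle = -68))
#' @export
compare_to_reference <- function(basins, reference, threshold = 30) {
  reference <- tibble::as_tibble(reference)
  if (!"torsion" %in% names(reference)) {
    if (!"conformer" %in% names(reference)) {
      abort("reference needs a 'conformer' column", class = "boronfit_schema_mismatch")
    }
    reference <- tidyr::pivot_longer(reference, -"conformer",
                                     names_to = "torsion", values_to = "angle")
  }
  need <- c("conformer", "torsion", "angle")
  if (!all(need %in% names(reference))) {
    abort("reference needs columns conformer, torsion, angle",
          class = "boronfit_schema_mismatch")
  }
  if (!"torsion" %in% names(basins)) {
    abort("basin summary lacks a torsion column", class = "boronfit_schema_mismatch")
  }
  if (nrow(basins) > 0) {
    missing_t <- setdiff(unique(reference$torsion), unique(basins$torsion))
    if (length(missing_t) > 0) {
      abort(paste("reference torsion label(s) absent from the basin summary:",
                  paste(missing_t, collapse = ", ")),
            class = "boronfit_schema_mismatch")
    }
  }
  rows <- pmap(reference[, need], function(conformer, torsion, angle) {
    cand <- basins[basins$torsion == torsion, , drop = FALSE]
    if (nrow(cand) == 0) {
      return(tibble::tibble(conformer = conformer, torsion = torsion,
                            ref_angle = angle, basin_center = NA_real_,
                            delta = NA_real_, matched = FALSE))
    }
    d <- circular_distance(cand$center, angle)
    b <- which.min(d)
    tibble::tibble(conformer = conformer, torsion = torsion, ref_angle = angle,
                   basin_center = cand$center[b], delta = d[b],
                   matched = d[b] <= threshold)
  })
  bind_rows(rows)
}
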