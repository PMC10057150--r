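# Shared fixtures and independent oracles for the test suite.

full_params <- function() {
  merge_params(builtin_boronate_params(), generic_fallback_params())
}

# Independent torsion oracle: project the outer bond vectors onto the
# plane perpendicular to the central bond and take the signed angle
# between the projections (a different construction from the
# normal-vector atan2 route used by measure_torsion).
oracle_torsion <- function(coords, i, j, k, l) {
  u <- coords[k, ] - coords[j, ]
  u <- u / sqrt(sum(u^2))
  v1 <- coords[i, ] - coords[j, ]
  v2 <- coords[l, ] - coords[k, ]
  p1 <- v1 - u * sum(u * v1)
  p2 <- v2 - u * sum(u * v2)
  cr <- c(p1[2] * p2[3] - p1[3] * p2[2],
          p1[3] * p2[1] - p1[1] * p2[3],
          p1[1] * p2[2] - p1[2] * p2[1])
  ang <- atan2(sum(cr * u), sum(p1 * p2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

oracle_angle <- function(coords, i, j, k) {
  u <- coords[i, ] - coords[j, ]
  v <- coords[k, ] - coords[j, ]
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# random non-degenerate quadruple of points
random_quadruple <- function() {
  repeat {
    m <- matrix(rnorm(12), 4, 3)
    b1 <- m[2, ] - m[1, ]; b2 <- m[3, ] - m[2, ]; b3 <- m[4, ] - m[3, ]
    n1 <- sqrt(sum((c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
                      b1[1] * b2[2] - b1[2] * b2[1]))^2))
    n2 <- sqrt(sum((c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
                      b2[1] * b3[2] - b2[2] * b3[1]))^2))
    if (n1 > 1e-3 && n2 > 1e-3) return(m)
  }
}

# brute-force circular mean: the resultant-direction mean is the exact
# minimizer of the summed (1 - cos) circular dispersion; search it on a
# fine grid as an independent route
oracle_circular_mean <- function(angles, grid_step = 0.05) {
  grid <- seq(-180 + grid_step, 180, by = grid_step)
  cost <- vapply(grid, function(g) sum(1 - cos((angles - g) * pi / 180)), numeric(1))
  grid[which.min(cost)]
}

# rigid-body transform: random rotation (QR-based) plus translation
random_rigid_transform <- function(coords) {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(coords %*% q, 2, rnorm(3, sd = 5), `+`)
}

# relative energies of the printed conformer table (kcal/mol) and the
# printed equilibrium percentages used for desk-level reproduction
reference_conformer_table <- function() {
  tibble::tribble(
    ~compound, ~label, ~delta_e, ~percent,
    1, "1A", 0.00, 37.9,
    1, "1B", 0.18, 28.0,
    1, "1C", 0.54, 15.1,
    1, "1D", 0.91, 8.1,
    1, "1E", 1.25, 4.6,
    1, "1F", 1.34, 4.0,
    1, "1G", 2.28, 0.8,
    1, "1H", 2.32, 0.8,
    1, "1I", 2.39, 0.7,
    2, "2A", 0.00, 96.5,
    2, "2B", 2.16, 2.5,
    2, "2C", 2.97, 0.6,
    2, "2D", 3.54, 0.2,
    2, "2E", 4.10, 0.1,
    3, "3A", 0.00, 53.7,
    3, "3B", 0.73, 15.6,
    3, "3C", 0.90, 11.7,
    3, "3D", 0.91, 11.6,
    3, "3E", 1.33, 5.7,
    3, "3F", 2.18, 1.4,
    3, "3G", 2.93, 0.4,
    4, "4A", 0.00, 69.9,
    4, "4B", 1.12, 10.6,
    4, "4C", 1.12, 10.5,
    4, "4D", 1.21, 9.0
  )
}

# a small noiseless synthetic fitting problem reused by several tests:
# methylamino fixture, 36-frame 10-degree scan of the hydroxyl torsion,
# generator truth (v = 2.5, gamma = 180, n = 2) on key ho-oh-b-c3
recovery_problem <- function(noise_sd = 0, seed = 1L, step = 10) {
  pset <- full_params()
  fx <- toy_boronate_fixture("methylamino")
  scan <- scan_torsion(fx$topology, fx$conformers, fx$torsions[[3]], step = step)
  truth <- pset
  i <- which(truth$dihedrals$a1 == "ho" & truth$dihedrals$a2 == "oh" &
               truth$dihedrals$a3 == "b" & truth$dihedrals$a4 == "c3")
  truth$dihedrals$v_n[i] <- 2.5
  truth$dihedrals$gamma[i] <- 180
  truth$dihedrals$n[i] <- 2.0
  qm <- synthetic_qm_energies(fx$topology, truth, scan, noise_sd = noise_sd,
                              offset = -1500, seed = seed)
  list(top = fx$topology, pset = pset, truth = truth,
       conformers = set_qm_energies(scan, qm), fixture = fx)
}
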