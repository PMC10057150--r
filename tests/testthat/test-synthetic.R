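test_that("torsion scans are rigid and hit the requested angles", {
  fx <- toy_boronate_fixture("methylamino")
  td <- fx$torsions[[1]]
  co <- fx$conformers$coords[[1]]
  start <- measure_torsion(co, td$indices[1], td$indices[2], td$indices[3], td$indices[4])
  sc <- scan_torsion(fx$topology, fx$conformers, td, step = 10)
  expect_length(sc$coords, 36)
  expect_equal(sc$coords[[1]], co)  # first frame is the input
  for (m in c(0, 7, 19, 35)) {
    got <- measure_torsion(sc$coords[[m + 1]], td$indices[1], td$indices[2],
                           td$indices[3], td$indices[4])
    expect_lt(circular_distance(got, start + m * 10), 1e-9)
  }
  # rigid-body property: bond lengths and an uninvolved internal
  # coordinate are preserved to machine precision
  bl0 <- apply(fx$topology$bonds, 1, function(b) measure_bond(co, b[1], b[2]))
  for (f in c(10, 25)) {
    blf <- apply(fx$topology$bonds, 1, function(b) measure_bond(sc$coords[[f]], b[1], b[2]))
    expect_lt(max(abs(blf - bl0)), 1e-12)
  }
  ang0 <- measure_angle(co, 3, 2, 5)
  expect_lt(abs(measure_angle(sc$coords[[18]], 3, 2, 5) - ang0), 1e-9)
})

test_that("scans refuse ring bonds and non-bonded axes", {
  fx <- toy_boronate_fixture("phenyl")
  ring_td <- torsion_definition("ring", c(1, 2, 3, 4))  # B-C1-C2-C3, ring bond C1-C2
  expect_error(scan_torsion(fx$topology, fx$conformers, ring_td, step = 10),
               class = "boronfit_non_rotatable")
  bad <- torsion_definition("bad", c(1, 2, 4, 5))  # 2-4 not bonded
  expect_error(scan_torsion(fx$topology, fx$conformers, bad, step = 10),
               class = "boronfit_invalid_spec")
  td <- fx$torsions[[1]]
  expect_error(scan_torsion(fx$topology, fx$conformers, td, step = 7),
               class = "boronfit_invalid_spec")
})

test_that("coverage check bins torsions and flags sparse sets", {
  fx <- toy_boronate_fixture("methylamino")
  sc <- scan_torsion(fx$topology, fx$conformers, fx$torsions[[3]], step = 10)
  cov <- coverage_check(sc, fx$torsions[3])
  expect_equal(cov$coverage, 1)        # 36-frame scan fills all 12 bins
  expect_false(attr(cov, "flagged"))

  one <- conformer_set(rep(fx$conformers$coords, 5))
  expect_warning(cov1 <- coverage_check(one, fx$torsions[3]),
                 class = "boronfit_low_coverage")
  expect_equal(cov1$coverage, 1 / 12)  # identical frames occupy one bin

  # brute-force bin-count oracle on random angle sets
  withr::local_seed(21)
  for (rep in 1:10) {
    ang <- runif(40, -180, 180)
    bins <- boronfit:::angle_bin(ang, 12L)
    oracle <- length(unique(floor((ang + 180 - 1e-12) / 30))) / 12
    expect_equal(length(unique(bins)) / 12, oracle)
  }
})

test_that("fixtures are deterministic and strain-free at the build geometry", {
  p <- full_params()
  for (kind in c("phenyl", "benzyl", "benzylamino", "methylamino", "ester")) {
    f1 <- toy_boronate_fixture(kind)
    f2 <- toy_boronate_fixture(kind)
    expect_identical(f1$topology, f2$topology)
    expect_identical(f1$conformers$coords, f2$conformers$coords)
    expect_lte(nrow(f1$topology$atoms), 24)
    expect_equal(sum(f1$topology$atoms$charge), 0, tolerance = 1e-9)

    e <- bonded_energy(f1$topology, p, f1$conformers)
    br <- attr(e, "breakdown")
    expect_lt(sum(br$energy[br$term == "bond"]), 1e-16)   # bonds exactly at r_eq
    expect_lt(sum(br$energy[br$term == "angle"]), 0.5)    # near-equilibrium angles
    # byte-identical topology export
    t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
    write_topology(f1$topology, t1); write_topology(f2$topology, t2)
    expect_identical(readLines(t1), readLines(t2))
  }
})

test_that("every built-in dihedral key is realized by some fixture", {
  audit <- audit_fixture_coverage()
  expect_equal(nrow(audit), 29)  # 28 distinct proper keys + 1 improper
  expect_true(all(audit$realized))
  expect_true(audit$improper[audit$key == "b-ha-c2-ha"])
})

test_that("fixture torsion definitions sit on real bonds around boron", {
  for (kind in c("phenyl", "benzyl", "benzylamino", "methylamino", "ester")) {
    fx <- toy_boronate_fixture(kind)
    expect_length(fx$torsions, 4)
    sig <- paste(pmin(fx$topology$bonds$i, fx$topology$bonds$j),
                 pmax(fx$topology$bonds$i, fx$topology$bonds$j))
    for (td in fx$torsions) {
      for (q in 1:3) {
        expect_true(paste(min(td$indices[q:(q + 1)]), max(td$indices[q:(q + 1)])) %in% sig)
      }
    }
  }
})

test_that("synthetic QM energies are reproducible and correctly calibrated", {
  prob <- recovery_problem()
  e1 <- synthetic_qm_energies(prob$top, prob$truth, prob$conformers,
                              noise_sd = 0.2, offset = -10, seed = 99)
  e2 <- synthetic_qm_energies(prob$top, prob$truth, prob$conformers,
                              noise_sd = 0.2, offset = -10, seed = 99)
  expect_identical(e1, e2)

  # Monte-Carlo check of the noise scale at n = 1000
  big <- conformer_set(rep(prob$conformers$coords, length.out = 1000))
  e_noisy <- synthetic_qm_energies(prob$top, prob$truth, big,
                                   noise_sd = 0.3, offset = 2, seed = 7)
  e_clean <- synthetic_qm_energies(prob$top, prob$truth, big,
                                   noise_sd = 0, offset = 2, seed = 7)
  resid <- e_noisy - e_clean
  expect_lt(abs(mean(resid)), 3 * 0.3 / sqrt(1000))
  expect_lt(abs(sd(resid) - 0.3), 3 * 0.3 / sqrt(2 * 999))
})

test_that("interchange formats round-trip fixtures", {
  fx <- toy_boronate_fixture("ester")
  d <- withr::local_tempdir()

  tpath <- file.path(d, "ester.top")
  write_topology(fx$topology, tpath)
  top2 <- read_topology(tpath)
  expect_equal(top2$atoms$type, fx$topology$atoms$type)
  expect_equal(top2$bonds, fx$topology$bonds)

  xpath <- file.path(d, "scan.xyz")
  sc <- scan_torsion(fx$topology, fx$conformers, fx$torsions[[4]], step = 90)
  write_xyz(sc, xpath, top = fx$topology)
  back <- read_xyz(xpath)
  expect_length(back$coords, 4)
  expect_lt(max(abs(back$coords[[3]] - sc$coords[[3]])), 1e-7)

  mpath <- file.path(d, "ester.mol2")
  write_mol2_system(fx$topology, fx$conformers, mpath)
  skip_if_not_installed("bio3d")
  sys <- read_mol2_system(mpath)
  expect_equal(sys$topology$atoms$type, fx$topology$atoms$type)
  expect_equal(nrow(sys$topology$bonds), nrow(fx$topology$bonds))
  expect_lt(max(abs(sys$conformers$coords[[1]] - fx$conformers$coords[[1]])), 1e-3)
})

test_that("PDB frames split on MODEL records", {
  skip_if_not_installed("bio3d")
  d <- withr::local_tempfile(fileext = ".pdb")
  pdb_atom <- function(i, x, y, z) {
    sprintf("ATOM  %5d  C   LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           C", i, x, y, z)
  }
  writeLines(c(
    "MODEL     1", pdb_atom(1, 0, 0, 0), pdb_atom(2, 1.5, 0, 0), "ENDMDL",
    "MODEL     2", pdb_atom(1, 0, 0, 0), pdb_atom(2, 0, 2.5, 0), "ENDMDL",
    "END"), d)
  conf <- read_pdb_conformers(d)
  expect_length(conf$coords, 2)
  expect_equal(measure_bond(conf$coords[[1]], 1, 2), 1.5)
  expect_equal(measure_bond(conf$coords[[2]], 1, 2), 2.5)
})
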