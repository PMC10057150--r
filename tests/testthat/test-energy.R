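# two-atom / few-atom micro-systems with hand-evaluable energies

test_that("bond term matches the harmonic closed form", {
  top <- mm_topology(tibble::tibble(name = c("B", "O"), type = c("b", "o"), charge = 0),
                     tibble::tibble(i = 1, j = 2))
  co <- rbind(c(0, 0, 0), c(1.610, 0, 0))
  e <- bonded_energy(top, builtin_boronate_params(), co)
  # 450 * (1.610 - 1.510)^2 = 4.500
  expect_equal(as.numeric(e), 4.5, tolerance = 1e-12)
})

test_that("proper and improper torsion terms match the Fourier closed form", {
  p <- builtin_boronate_params()
  # o-b-o-ho: v = 0.8361, gamma = 0, n = 3
  top <- mm_topology(
    tibble::tibble(name = c("O1", "B", "O2", "HO"), type = c("o", "b", "o", "ho"),
                   charge = 0),
    tibble::tibble(i = 1:3, j = 2:4))
  co0 <- rbind(c(-0.5, 1.2, 0), c(0, 0, 0), c(1.51, 0, 0), c(2.0, 1.2, 0))  # phi = 0
  e0 <- bonded_energy(top, p, co0, terms = list(
    bonds = tibble::tibble(i = integer(), j = integer()),
    angles = tibble::tibble(i = integer(), j = integer(), k = integer()),
    propers = tibble::tibble(i = 1L, j = 2L, k = 3L, l = 4L),
    impropers = tibble::tibble(i = integer(), j = integer(), k = integer(), l = integer())))
  expect_equal(measure_torsion(co0, 1, 2, 3, 4), 0)
  expect_equal(as.numeric(e0), 1.6722, tolerance = 1e-10)

  td <- torsion_definition("t", c(1, 2, 3, 4))
  sc <- scan_torsion(top, co0, td, step = 60)
  co60 <- sc$coords[[2]]
  e60 <- bonded_energy(top, p, co60, terms = list(
    bonds = tibble::tibble(i = integer(), j = integer()),
    angles = tibble::tibble(i = integer(), j = integer(), k = integer()),
    propers = tibble::tibble(i = 1L, j = 2L, k = 3L, l = 4L),
    impropers = tibble::tibble(i = integer(), j = integer(), k = integer(), l = integer())))
  expect_equal(as.numeric(e60), 0, tolerance = 1e-10)

  # improper b-ha-c2-ha: v = 1.1, gamma = 180, n = 2
  imp_terms <- list(
    bonds = tibble::tibble(i = integer(), j = integer()),
    angles = tibble::tibble(i = integer(), j = integer(), k = integer()),
    propers = tibble::tibble(i = integer(), j = integer(), k = integer(), l = integer()),
    impropers = tibble::tibble(i = 1L, j = 2L, k = 3L, l = 4L))
  itop <- mm_topology(
    tibble::tibble(name = c("B", "H1", "C", "H2"), type = c("b", "ha", "c2", "ha"),
                   charge = 0),
    tibble::tibble(i = c(3, 3, 3), j = c(1, 2, 4)))
  planar <- rbind(c(-1, 1, 0), c(-1, -1, 0), c(0, 0, 0), c(1.4, 0, 0))
  expect_equal(as.numeric(bonded_energy(itop, p, planar, terms = imp_terms)), 0,
               tolerance = 1e-10)
  bent <- rbind(c(-1, 1, 0), c(-1, -1, 0), c(0, 0, 0), c(0, 0, 1.4))  # phi = 90
  expect_equal(abs(measure_torsion(bent, 1, 2, 3, 4)), 90)
  expect_equal(as.numeric(bonded_energy(itop, p, bent, terms = imp_terms)), 2.2,
               tolerance = 1e-10)
})

test_that("nonbonded energy reproduces Coulomb and Lennard-Jones closed forms", {
  nb <- default_nonbonded()
  # opposite unit charges, LJ off: -332.0522173 / r
  top <- mm_topology(
    tibble::tibble(name = c("A", "B"), type = c("c3", "c3"), charge = c(1, -1)),
    tibble::tibble(i = integer(), j = integer()))
  nb0 <- nonbonded_params(tibble::tibble(type = "c3", rstar = 1.9, epsilon = 0))
  co <- rbind(c(0, 0, 0), c(3.320522173, 0, 0))
  expect_equal(as.numeric(nonbonded_energy(top, nb0, co)), -100, tolerance = 1e-9)

  # neutral pair at the LJ minimum: energy -sqrt(eps_i eps_j)
  top2 <- mm_topology(
    tibble::tibble(name = c("A", "B"), type = c("c3", "oh"), charge = 0),
    tibble::tibble(i = integer(), j = integer()))
  rmin <- 1.9080 + 1.7210
  co2 <- rbind(c(0, 0, 0), c(rmin, 0, 0))
  expect_equal(as.numeric(nonbonded_energy(top2, nb, co2)),
               -sqrt(0.1094 * 0.2104), tolerance = 1e-12)

  # 4-atom chain: only the 1-4 pair contributes, scaled by 1/1.2 and 1/2
  chain <- mm_topology(
    tibble::tibble(name = c("a", "b", "c", "d"), type = "c3",
                   charge = c(0.3, 0, 0, -0.3)),
    tibble::tibble(i = 1:3, j = 2:4))
  co4 <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.5, 0), c(3, 1.5, 0))
  e <- nonbonded_energy(chain, nb, co4)
  br <- attr(e, "breakdown")
  expect_equal(nrow(br), 1)
  expect_equal(br$term, "nonbonded14")
  r14 <- measure_bond(co4, 1, 4)
  lj <- (1 / 2) * 0.1094 * ((2 * 1.908 / r14)^12 - 2 * (2 * 1.908 / r14)^6)
  expect_equal(as.numeric(e),
               (1 / 1.2) * 332.0522173 * 0.3 * (-0.3) / r14 + lj, tolerance = 1e-12)
})

test_that("total energy is additive and invariant under rigid-body motion", {
  p <- full_params()
  nb <- default_nonbonded()
  fx <- toy_boronate_fixture("benzyl")
  co <- fx$conformers$coords[[1]]
  eb <- bonded_energy(fx$topology, p, co)
  en <- nonbonded_energy(fx$topology, nb, co)
  et <- total_mm_energy(fx$topology, p, co, nb = nb)
  expect_equal(as.numeric(et), as.numeric(eb) + as.numeric(en))
  expect_equal(as.numeric(et), sum(attr(et, "breakdown")$energy))

  withr::local_seed(5)
  for (rep in 1:3) {
    co2 <- random_rigid_transform(co)
    expect_lt(abs(as.numeric(total_mm_energy(fx$topology, p, co2, nb = nb)) -
                    as.numeric(et)), 1e-9)
  }
})

test_that("missing parameters raise a parameter-gap error listing the keys", {
  top <- mm_topology(tibble::tibble(name = c("A", "B"), type = c("b", "n3"), charge = 0),
                     tibble::tibble(i = 1, j = 2))
  co <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  expect_error(bonded_energy(top, builtin_boronate_params(), co),
               "b-n3", class = "boronfit_parameter_gap")
  nb0 <- nonbonded_params(tibble::tibble(type = "b", rstar = 2, epsilon = 0.03))
  expect_error(nonbonded_energy(top, nb0, co), "n3", class = "boronfit_parameter_gap")
})

test_that("compiled energy model agrees with the per-term reference path", {
  p <- full_params()
  nb <- default_nonbonded()
  for (kind in c("methylamino", "ester")) {
    fx <- toy_boronate_fixture(kind)
    co <- fx$conformers$coords[[1]]
    m <- boronfit:::compile_energy_model(fx$topology, p, nb = nb)
    expect_equal(boronfit:::eval_energy_model(m, co),
                 as.numeric(total_mm_energy(fx$topology, p, co, nb = nb)),
                 tolerance = 1e-12)
  }
})

test_that("per-frame energy tables cover every component", {
  p <- full_params()
  fx <- toy_boronate_fixture("ester")
  sc <- scan_torsion(fx$topology, fx$conformers, fx$torsions[[4]], step = 120)
  tab <- mm_energy_table(fx$topology, p, sc, nb = default_nonbonded())
  expect_equal(nrow(tab), 3)
  expect_equal(tab$total, tab$bond + tab$angle + tab$dihedral + tab$improper + tab$nonbonded)
})
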