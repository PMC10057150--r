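test_that("QM energy files parse with unit conversion and comment handling", {
  f <- withr::local_tempfile()
  writeLines(c("# header", "-100.000000", "", "-99.999000"), f)
  e <- read_qm_energies(f, units = "hartree")
  expect_equal(diff(e), 0.001 * 627.509474)
  expect_equal(diff(e), 0.627509, tolerance = 1e-6)

  writeLines(c("1.5", "2.5"), f)
  expect_equal(read_qm_energies(f), c(1.5, 2.5))  # kcal pass-through

  writeLines(c("1.5", "oops"), f)
  expect_error(read_qm_energies(f), "line 2", class = "boronfit_format_error")
})

test_that("the analytic offset minimizes the objective", {
  expect_equal(optimal_offset(c(10, 11, 12), c(1, 2, 3)), -9)
  expect_equal(objective_value(c(10, 11, 12), c(1, 2, 3), -9), 0)
  expect_equal(optimal_offset(c(1, 2), c(1, 2)), 0)
  expect_error(optimal_offset(numeric(), numeric()), class = "boronfit_empty_input")

  # K from the closed form beats every K on a dense grid
  withr::local_seed(3)
  for (rep in 1:20) {
    e_mm <- rnorm(15, sd = 5); e_qm <- rnorm(15, sd = 5)
    K <- optimal_offset(e_mm, e_qm)
    f0 <- objective_value(e_mm, e_qm, K)
    grid <- seq(K - 50, K + 50, length.out = 1e4)
    expect_true(all(f0 <= vapply(grid, function(g) objective_value(e_mm, e_qm, g),
                                 numeric(1)) + 1e-12))
  }
})

test_that("objective and R^2 match their definitions", {
  expect_equal(objective_value(c(1, 3), c(2, 2), 0), 2)  # residuals 1, -1
  withr::local_seed(8)
  e_mm <- rnorm(30); e_qm <- rnorm(30)
  K <- optimal_offset(e_mm, e_qm)
  expect_equal(objective_value(e_mm, e_qm, K), sum((e_mm - e_qm + K)^2))
  # independent regression-summary oracle: R^2 of lm with fixed slope 1
  r2 <- r_squared(e_mm, e_qm, K)
  oracle <- 1 - sum(((e_mm + K) - e_qm)^2) / sum((e_qm - mean(e_qm))^2)
  expect_equal(r2, oracle, tolerance = 1e-12)
  expect_equal(r_squared(e_qm, e_qm, 0), 1)
  # constant prediction at the target mean scores zero
  expect_equal(r_squared(rep(mean(e_qm), 30), e_qm, 0), 0)
  expect_error(r_squared(e_mm, rep(1, 30), 0), class = "boronfit_degenerate_target")
  expect_error(objective_value(1:3, 1:4, 0), class = "boronfit_alignment_error")
})

test_that("a noiseless synthetic scan is recovered exactly", {
  prob <- recovery_problem(noise_sd = 0)
  fit <- fit_dihedrals(prob$top, prob$pset, prob$conformers,
                       fit_spec("ho-oh-b-c3", multistart = 8, seed = 2))
  got <- canonical_dihedral_term(fit$params$v_n, fit$params$gamma, fit$params$n)
  expect_equal(got$v_n, 2.5, tolerance = 1e-4)
  expect_lt(circular_distance(got$gamma, 180), 0.1)
  expect_equal(got$n, 2, tolerance = 1e-3)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$K, -1500, tolerance = 1e-6)
  expect_true(fit$diagnostics$converged)

  # profile property: the returned K is the analytic optimum and no grid
  # K improves f
  e_mm <- fit$residuals$e_mm; e_qm <- fit$residuals$e_qm
  expect_equal(fit$K, optimal_offset(e_mm, e_qm))
  grid <- seq(fit$K - 10, fit$K + 10, length.out = 2000)
  expect_true(all(fit$f <= vapply(grid, function(g) objective_value(e_mm, e_qm, g),
                                  numeric(1)) + 1e-12))

  # objective trace of the winning start is monotone non-increasing
  expect_true(all(diff(fit$diagnostics$trace) <= 1e-12))
})

test_that("shifting all QM energies only moves K", {
  prob <- recovery_problem(noise_sd = 0.05, seed = 9)
  sp <- fit_spec("ho-oh-b-c3", multistart = 4, seed = 5)
  f1 <- fit_dihedrals(prob$top, prob$pset, prob$conformers, sp)
  shifted <- set_qm_energies(prob$conformers, prob$conformers$qm_energy + 123.4)
  f2 <- fit_dihedrals(prob$top, prob$pset, shifted, sp)
  expect_equal(f2$K - f1$K, 123.4, tolerance = 1e-6)
  expect_equal(f2$params$v_n, f1$params$v_n, tolerance = 1e-6)
  expect_equal(f2$params$n, f1$params$n, tolerance = 1e-6)
  expect_equal(f2$f, f1$f, tolerance = 1e-6)
})

test_that("degenerate fit specifications are rejected", {
  expect_error(fit_spec("ho-oh-b-c3", float = character()), "at least one")
  expect_error(fit_spec("ho-oh-b-c3", float = "gamma", fit_n_continuous = FALSE,
                        bounds = list(v_n = c(2, 1))),
               class = "boronfit_invalid_spec")
  expect_error(fit_spec("ho-oh-b"))   # three labels are not a dihedral key
  prob <- recovery_problem()
  expect_error(fit_dihedrals(prob$top, prob$pset, prob$conformers,
                             fit_spec("hn-n3-hn-hn")),
               class = "boronfit_invalid_spec")
  no_qm <- conformer_set(prob$conformers$coords)
  expect_error(fit_dihedrals(prob$top, prob$pset, no_qm, fit_spec("ho-oh-b-c3")),
               class = "boronfit_alignment_error")
})

test_that("fit results are reproducible per seed and expose tidy methods", {
  prob <- recovery_problem(noise_sd = 0.1, seed = 4)
  sp <- fit_spec("ho-oh-b-c3", multistart = 4, seed = 11)
  f1 <- fit_dihedrals(prob$top, prob$pset, prob$conformers, sp)
  f2 <- fit_dihedrals(prob$top, prob$pset, prob$conformers, sp)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$K, f2$K)

  td <- tidy(f1)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("key", "divider", "v_n", "gamma", "n", "improper"))
  expect_true(td$gamma >= 0 && td$gamma < 360)
  gl <- glance(f1)
  expect_equal(gl$n_structures, 36)
  expect_equal(gl$seed, 11L)

  # fitted parameters survive an frcmod round trip
  f <- withr::local_tempfile(fileext = ".frcmod")
  write_frcmod(f1$pset, f)
  back <- read_frcmod(f)
  key <- back$dihedrals$a1 == "ho" & back$dihedrals$a2 == "oh" &
    back$dihedrals$a3 == "b" & back$dihedrals$a4 == "c3"
  expect_equal(back$dihedrals$v_n[key], round(f1$params$v_n, 4))
})

test_that("canonical dihedral form preserves the energy profile", {
  withr::local_seed(13)
  phi <- seq(-180, 170, by = 10)
  for (rep in 1:25) {
    v <- runif(1, -20, 20); g <- runif(1, -360, 360); n <- runif(1, -6, 6)
    canon <- canonical_dihedral_term(v, g, n)
    e1 <- v * (1 + cos((n * phi - g) * pi / 180))
    e2 <- canon$v_n * (1 + cos((canon$n * phi - canon$gamma) * pi / 180))
    # equal up to an additive constant
    expect_lt(max(abs((e1 - mean(e1)) - (e2 - mean(e2)))), 1e-9)
    expect_gte(canon$v_n, 0)
    expect_gte(canon$n, 0)
  }
})
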