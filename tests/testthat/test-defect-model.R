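test_that("shipped presets carry the published parametrization and round-trip", {
  td0 <- td_preset("TD0")
  expect_equal(td0$roll_angle_deg, 27.1)
  expect_equal(td0$stacking_multiplier, 10)
  expect_equal(td0$n_modified_steps, 1L)
  expect_equal(td0$hbond_weakening_fraction, 0.60)
  td1 <- td_preset("TD1")
  expect_equal(td1$roll_angle_deg, 37.0)
  expect_equal(td1$n_modified_steps, 2L)
  expect_equal(td1$hbond_weakening_fraction, 0.10)
  td2 <- td_preset("TD2")
  expect_equal(td2$roll_angle_deg, 18.3)
  expect_equal(td2$hbond_weakening_fraction, 0.55)

  # lossless serialization round trip for every preset
  for (nm in c("TD0", "TD1", "TD2")) {
    spec <- td_preset(nm)
    path <- withr::local_tempfile(fileext = ".model")
    write_model_spec(spec, path)
    expect_equal(read_model_spec(path), spec)
  }
})

test_that("defect model validation rejects out-of-range parameters", {
  expect_error(defect_model_spec("X", roll_angle_deg = 50), "\\[0, 45\\]")
  expect_error(defect_model_spec("X", 20, n_modified_steps = 3), "1 or 2")
  expect_error(defect_model_spec("X", 20, hbond_weakening_fraction = 1.2),
               "\\[0, 1\\]")
  expect_error(defect_model_spec("X", 20, stacking_multiplier = 0.5), ">= 1")
})

test_that("apply_roll is a rigid rotation", {
  tri <- diag(3)
  # identity case
  expect_equal(apply_roll(tri, 0, c(1, 0, 0)), tri)
  # orthonormality preserved for arbitrary angles
  set.seed(4)
  for (phi in runif(5, -180, 180)) {
    ax <- rnorm(3)
    out <- apply_roll(tri, phi, ax)
    expect_lt(max(abs(crossprod(out) - diag(3))), 1e-9)
  }
  # rotation by 27.1 degrees about the frame's first (base) vector matches
  # the explicit axis-angle oracle, and moves the normal by exactly 27.1 deg
  phi <- 27.1
  out <- apply_roll(tri, phi, tri[, 1])
  expect_equal(out, rotation_oracle(phi, c(1, 0, 0)) %*% tri, tolerance = 1e-12)
  ang <- acos(sum(out[, 2] * tri[, 2])) * 180 / pi
  expect_equal(ang, phi, tolerance = 1e-9)
  # composition with the inverse rotation is the identity
  back <- apply_roll(out, -phi, tri[, 1])
  expect_lt(max(abs(back - tri)), 1e-9)
  # error paths
  expect_error(apply_roll(tri, 10, c(0, 0, 0)), "nonzero")
  expect_error(apply_roll(matrix(1, 3, 3), 10, c(1, 0, 0)), "orthonormal")
})

test_that("relaxed linking number and superhelical density follow their definitions", {
  expect_equal(linking_number_relaxed(600, 10.55), 56.87, tolerance = 0.005 / 56.87)
  expect_equal(linking_number_relaxed(0, 10.55), 0)
  expect_equal(linking_number_relaxed(1055, 10.55), 100)
  expect_error(linking_number_relaxed(100, 0), "> 0")

  expect_equal(superhelical_density(56.87, 56.87), 0)
  expect_equal(superhelical_density(52.87, 56.87), -0.070335, tolerance = 1e-4)
  expect_error(superhelical_density(1, 0), "nonzero")

  # exact inverse round trip
  for (sig in c(-0.073, -0.01, 0.05)) {
    lk0 <- 56.87
    expect_equal(superhelical_density(lk0 + turns_for_sigma(sig, lk0), lk0),
                 sig, tolerance = 1e-15)
  }

  book <- topology_bookkeeping(600)
  expect_equal(book$Lk0, 600 / 10.55)
  book <- add_turns(book, -4)
  expect_equal(book$Lk, book$Lk0 - 4)
  expect_equal(book$sigma, -4 / book$Lk0)
})

test_that("loop-formation energy reduction follows theta0 * sqrt(2 kBT p F zbar)", {
  # zero bend, zero reduction
  expect_equal(loop_energy_reduction(loop_energy_params(0)), 0)
  base <- loop_energy_params(theta0_deg = 11.3, persistence_length_nm = 45,
                             force_pN = 1.5, zbar = 0.88, temperature_K = 300)
  e1 <- loop_energy_reduction(base)
  # linear in theta0
  e2 <- loop_energy_reduction(loop_energy_params(22.6, 45, 1.5, 0.88, 300))
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  # scales as sqrt(F)
  e4 <- loop_energy_reduction(loop_energy_params(11.3, 45, 3.0, 0.88, 300))
  expect_equal(e4, sqrt(2) * e1, tolerance = 1e-12)
  # thermal (MD-row) reference angles of the presets drive the preset route
  expect_equal(loop_energy_reduction(td_preset("TD0")),
               loop_energy_reduction(loop_energy_params(11.3)))
  expect_equal(loop_energy_reduction(td_preset("TD0"), angle = "min"),
               loop_energy_reduction(loop_energy_params(13.6)))
})

test_that("kBT conversion is physical", {
  expect_equal(kbt_pn_nm(300), 4.1419, tolerance = 1e-4)
  expect_error(kbt_pn_nm(-1))
})

test_that("predicted bend angle increases with roll and is linear over the validated range", {
  spec <- function(phi, nsteps = 1L)
    defect_model_spec("test", roll_angle_deg = phi, n_modified_steps = nsteps)
  # no roll, straight minimum
  expect_lt(predict_bend_angle(spec(0), 40L), 0.1)
  phis <- c(10, 25, 40)
  th <- vapply(phis, function(p) predict_bend_angle(spec(p), 40L), 0)
  expect_true(all(diff(th) > 0))
  # two modified steps bend more than one at equal roll
  expect_gt(predict_bend_angle(spec(25, 2L), 40L),
            predict_bend_angle(spec(25, 1L), 40L))
  expect_error(predict_bend_angle(spec(20), 10L), ">= 20")
})
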