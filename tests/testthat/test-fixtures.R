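test_that("random sequences are reproducible with the requested composition", {
  expect_identical(random_sequence(600, 0.5, 7), random_sequence(600, 0.5, 7))
  expect_true(all(random_sequence(100, 1, 1) %in% c("G", "C")))
  expect_true(all(random_sequence(100, 0, 1) %in% c("A", "T")))
  # binomial bound at n = 6000
  gc <- sum(random_sequence(6000, 0.5, 3) %in% c("G", "C"))
  expect_lt(abs(gc - 3000), 3 * sqrt(6000 * 0.25))
})

test_that("ideal helices satisfy the conformation invariants", {
  conf <- ideal_helix(600, 10.55)
  expect_equal(twist(conf), 56.87, tolerance = 0.01 / 56.87)
  validate_conformation(conf, energy_params())
  # collinearity
  ax <- axis(conf)
  expect_lt(max(abs(ax$points[, 1:2])), 1e-9)
  # minimal case runs through the analyzers without error
  tiny <- ideal_helix(3, 10.55)
  expect_equal(twist(tiny), 3 / 10.55, tolerance = 1e-9)
  expect_silent(writhe(tiny))
})

test_that("planted plectonemes carry consistent ground truth", {
  fx <- planted_plectoneme(600, tip_bp = 300, size_bp = 150, seed = 9)
  # the fixture's documented hard-core envelope is 1.9 nm (apical loop)
  validate_conformation(fx$conformation,
                        energy_params(excluded_diameter_nm = 1.9))
  # generator is a pure function of (parameters, seed)
  fx2 <- planted_plectoneme(600, tip_bp = 300, size_bp = 150, seed = 9)
  expect_identical(fx$conformation, fx2$conformation)
  # detector closes the loop on the fixture
  calls <- detect_plectonemes(fx$conformation)
  expect_equal(nrow(calls), 1L)
  expect_lt(abs(calls$tip_bp - fx$truth$tip_bp), 10)
  # degenerate case: size 0 plants nothing
  fx0 <- planted_plectoneme(600, tip_bp = 300, size_bp = 0, seed = 9)
  expect_equal(fx0$truth$size_bp, 0L)
  expect_equal(nrow(detect_plectonemes(fx0$conformation)), 0L)
  # writhe sign matches the planted chirality
  wrm <- writhe(fx$conformation) # default chirality -1
  wrp <- writhe(planted_plectoneme(600, 300, 150, chirality = +1,
                                   seed = 9)$conformation)
  expect_equal(sign(wrm), -1)
  expect_equal(sign(wrp), +1)
  expect_gt(abs(wrm), 0.5)
  # impossible geometry errors
  expect_error(planted_plectoneme(600, tip_bp = 20, size_bp = 200), "outside")
  expect_error(planted_plectoneme(600, 300, 150, superhelix_pitch_nm = 1.5),
               "self-intersection")
})

test_that("planted bubbles mark the requested run and nothing else", {
  helix <- ideal_helix(300)
  # single-site run: a negative control the bubble detector must not call
  fx1 <- plant_bubble(helix, 150, 1)
  expect_equal(nrow(detect_bubbles(denatured_mask(fx1$conformation))), 0L)
  # three-site run: exactly one bubble with matching extent
  fx3 <- plant_bubble(helix, 150, 3)
  b <- detect_bubbles(denatured_mask(fx3$conformation))
  expect_equal(nrow(b), 1L)
  expect_equal(b$start_bp, 150)
  expect_equal(b$length_bp, 3L)
  # two disjoint runs: two calls
  fx2 <- plant_bubble(fx3$conformation, 200, 4)
  b2 <- detect_bubbles(denatured_mask(fx2$conformation))
  expect_equal(nrow(b2), 2L)
  # overlap with handles is an error
  expect_error(plant_bubble(helix, 298, 5), "outside|handle")
})

test_that("the committed plectoneme corpus manifest is reproducible input", {
  man <- plectoneme_corpus_manifest()
  expect_equal(nrow(man), 200L)
  expect_true(all(man$size_bp >= 60 & man$size_bp <= 300))
  expect_true(all(c("seed", "n", "size_bp", "tip_bp", "chirality") %in%
                    names(man)))
  # a sampled row regenerates deterministically
  row <- man[17, ]
  fx <- planted_plectoneme(row$n, row$tip_bp, row$size_bp,
                           chirality = row$chirality, seed = row$seed)
  fxb <- planted_plectoneme(row$n, row$tip_bp, row$size_bp,
                            chirality = row$chirality, seed = row$seed)
  expect_identical(fx, fxb)
})
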