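test_that("axis extracts core midpoints in order, excluding handles", {
  conf <- ideal_helix(100, handle_bp = 3L)
  ax <- axis(conf)
  expect_equal(nrow(ax$points), 100)
  expect_equal(ax$bp, 0:99)
  # collinear: residual from the best-fit line is numerically zero
  ctr <- sweep(ax$points, 2, colMeans(ax$points))
  s <- svd(ctr)
  expect_lt(s$d[2], 1e-9)
  # equivariance: axis of a rigidly rotated conformation = rotated axis
  R <- rotation_oracle(33, c(1, 2, 3))
  conf2 <- conf
  conf2$positions <- conf$positions %*% t(R)
  conf2$normals <- conf$normals %*% t(R)
  expect_equal(axis(conf2)$points, ax$points %*% t(R), tolerance = 1e-12)
})

test_that("twist of an ideal helix equals its relaxed linking number", {
  conf <- ideal_helix(600, bp_per_turn = 10.55)
  expect_equal(twist(conf), 56.87, tolerance = 0.01 / 56.87)
  # untwisted ribbon: all material normals parallel
  rib <- conf
  rib$normals <- matrix(rep(c(1, 0, 0), each = nrow(rib$normals)),
                        ncol = 3)
  expect_equal(twist(rib), 0)
  # additivity: one extra full turn distributed uniformly adds exactly 1
  n_steps <- nrow(conf$normals)
  extra <- 2 * pi / n_steps
  tw_plus <- conf
  for (k in seq_len(n_steps)) {
    t_k <- c(0, 0, 1)
    Rk <- rotation_oracle(extra * (k - 1) * 180 / pi, t_k)
    tw_plus$normals[k, ] <- c(Rk %*% conf$normals[k, ])
  }
  # the core sum spans n of the n_steps steps; adding extra twist on every
  # step adds n/n_steps of the added turn plus the uniform increment
  got <- twist(tw_plus) - twist(conf)
  expect_equal(got, (602 - 2) / n_steps, tolerance = 1e-6)
})

test_that("writhe: planar curves vanish, mirror images flip sign, oracle agrees", {
  # planar zig-zag in the xz-plane (contains the closure axis)
  set.seed(7)
  m <- 40
  pts <- cbind(sin(seq(0, 3 * pi, length.out = m)), 0, seq(0, 20, length.out = m))
  expect_lt(abs(writhe(pts, closure = "axial")), 1e-6)
  expect_lt(abs(writhe(pts, closure = "none")), 1e-12)

  # smooth random curve: closed form vs dense quadrature
  for (seed in 1:3) {
    set.seed(seed)
    tt <- seq(0, 2 * pi, length.out = 30)
    crv <- cbind(3 * sin(2 * tt) + rnorm(1), 3 * cos(3 * tt), 8 * tt / pi)
    wr_cf <- writhe(crv, closure = "none")
    wr_or <- writhe_quadrature(crv, closed = FALSE, nsub = 10L)
    expect_equal(wr_cf, wr_or, tolerance = 2e-3 / max(abs(wr_cf), 1))
    # chirality antisymmetry under reflection
    mir <- crv
    mir[, 1] <- -mir[, 1]
    expect_equal(writhe(mir, closure = "none"), -wr_cf, tolerance = 1e-12)
    # invariance under rigid motion and uniform rescaling
    R <- rotation_oracle(71, c(1, -1, 2))
    expect_equal(writhe(2.5 * crv %*% t(R) + 3, closure = "none"), wr_cf,
                 tolerance = 1e-9)
  }
})

test_that("closed-polygon writhe matches quadrature on an interwound curve", {
  tt <- seq(0, 6 * pi, length.out = 120)
  helix <- cbind(2 * cos(tt), 2 * sin(tt), tt / 2)
  # close it coarsely far away to make a closed polygon
  poly <- rbind(helix, c(30, 0, max(helix[, 3])), c(30, 0, -5), c(2, 0, -5))
  expect_equal(plectodimer:::cpp_writhe_closed(poly),
               writhe_quadrature(poly, closed = TRUE, nsub = 6L),
               tolerance = 2e-3)
})

test_that("twist-writhe report closes the bookkeeping on a fresh chain", {
  conf <- build_initial_conformation(random_sequence(100, 0.5, 3),
                                     handle_bp = 4L)
  rep <- twist_writhe_report(conf)
  expect_equal(rep$Tw, conf$bookkeeping$Lk0, tolerance = 1e-9)
  expect_lt(abs(rep$Wr), 1e-9)
  expect_lt(abs(rep$residual), 1e-9)
  # invariance under rigid rotation about the pulling axis
  R <- rotation_oracle(40, c(0, 0, 1))
  conf2 <- conf
  conf2$positions <- conf$positions %*% t(R)
  conf2$normals <- conf$normals %*% t(R)
  rep2 <- twist_writhe_report(conf2)
  expect_equal(rep2$Tw, rep$Tw, tolerance = 1e-6)
  expect_equal(rep2$Wr, rep$Wr, tolerance = 1e-6)
  # against an explicit bookkeeping object the core twist is used
  book <- topology_bookkeeping(100)
  rep3 <- twist_writhe_report(conf, book)
  expect_lt(abs(rep3$residual), 1e-9)
})

test_that("plectoneme detection finds planted structures and nothing else", {
  # straight chain: no calls
  expect_equal(nrow(detect_plectonemes(ideal_helix(400))), 0L)

  fx <- planted_plectoneme(600, tip_bp = 300, size_bp = 150, seed = 11)
  calls <- detect_plectonemes(fx$conformation)
  expect_equal(nrow(calls), 1L)
  expect_lt(abs(calls$tip_bp - fx$truth$tip_bp), 10)
  # extent overlaps truth by >= 90% (Jaccard)
  inter <- min(calls$end_bp, fx$truth$end_bp) - max(calls$start_bp, fx$truth$start_bp) + 1
  union <- max(calls$end_bp, fx$truth$end_bp) - min(calls$start_bp, fx$truth$start_bp) + 1
  expect_gte(inter / union, 0.90)
  expect_true(all(calls$start_bp <= calls$tip_bp & calls$tip_bp <= calls$end_bp))

  # doubling the contact distance never shrinks a call
  wide <- detect_plectonemes(fx$conformation,
                             plectoneme_params(contact_distance_nm = 14))
  expect_gte(wide$end_bp[1] - wide$start_bp[1],
             calls$end_bp[1] - calls$start_bp[1])
})

test_that("two well-separated planted plectonemes give two calls", {
  fx1 <- planted_plectoneme(700, tip_bp = 180, size_bp = 120, seed = 5)
  # graft a second plectoneme by concatenating two fixtures along z
  fx2 <- planted_plectoneme(700, tip_bp = 500, size_bp = 120, seed = 5)
  conf <- fx1$conformation
  # splice: use fx2 geometry above bp 340
  hi <- plectodimer:::core_row(conf, 340):nrow(conf$positions)
  shift <- conf$positions[plectodimer:::core_row(conf, 340), ] -
    fx2$conformation$positions[plectodimer:::core_row(conf, 340), ]
  conf$positions[hi, ] <- sweep(fx2$conformation$positions[hi, , drop = FALSE],
                                2, -shift)
  calls <- detect_plectonemes(conf)
  expect_equal(nrow(calls), 2L)
  expect_lt(abs(calls$tip_bp[1] - fx1$truth$tip_bp), 10)
  expect_lt(abs(calls$tip_bp[2] - fx2$truth$tip_bp), 10)
})

test_that("position series and pinning metrics distinguish pinned from diffusing", {
  pinned <- planted_walk_trajectory(120, seed = 2, pinned = TRUE)
  ser_p <- plectoneme_position_series(pinned$trajectory)
  expect_equal(ser_p$n_with_call, 120)
  # delta-like histogram at the planted tip
  expect_equal(ser_p$histogram$bp[which.max(ser_p$histogram$prob)],
               pinned$truth$tips[1] + 0.5, tolerance = 3)
  met_p <- pinning_metrics(ser_p)
  expect_equal(met_p$width_fwhm_bp, ser_p$bin_bp)
  expect_lt(abs(met_p$msd_slope_bp2), 1e-9)

  walk <- planted_walk_trajectory(300, walk_step = 5, seed = 3, pinned = FALSE)
  ser_w <- plectoneme_position_series(walk$trajectory)
  # histogram mean tracks the walk mean
  hist_mean <- with(ser_w$histogram, sum(bp * prob))
  walk_mean <- mean(walk$truth$tips)
  walk_se <- stats::sd(walk$truth$tips) / sqrt(30) # generous effective n
  expect_lt(abs(hist_mean - walk_mean), 2 * walk_se + 5)
  # short lags, where boundary reflections are still negligible, follow the
  # random-walk law MSD = step^2 * lag
  met_w <- pinning_metrics(ser_w, max_lag = 4L)
  expect_lt(abs(met_w$msd_slope_bp2 - 25) / 25, 0.10)
  # pinned distribution is the sharper one
  expect_gt(met_p$peak_height, met_w$peak_height)
})

test_that("pinning metrics return a typed insufficient-data result", {
  short <- planted_walk_trajectory(100, seed = 4, pinned = TRUE)
  ser <- plectoneme_position_series(short$trajectory)
  out <- pinning_metrics(ser, min_calls = 500L)
  expect_s3_class(out, "insufficient_data")
})

test_that("curvature profile localizes a planted kink", {
  kink <- planted_kink(n = 120, kink_bp = 60, angle_deg = 30)
  prof <- curvature_profile(kink$conformation, window = 5L)
  expect_equal(prof$bp[which.max(prof$mean_angle_deg)], 60, tolerance = 5)
  expect_equal(max(prof$mean_angle_deg), 30, tolerance = 1)
  # straight frames: flat near zero
  prof0 <- curvature_profile(ideal_helix(120), window = 5L)
  expect_lt(max(prof0$mean_angle_deg), 1e-6)
  # invariance under rigid rotation
  conf <- kink$conformation
  R <- rotation_oracle(25, c(3, 1, 2))
  conf$positions <- conf$positions %*% t(R)
  conf$normals <- conf$normals %*% t(R)
  prof_rot <- curvature_profile(conf, window = 5L)
  expect_lt(max(abs(prof_rot$mean_angle_deg - prof$mean_angle_deg)), 1e-4)
})
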