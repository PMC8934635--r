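test_that("denaturation mask follows the strict 10% binding-energy criterion", {
  ref <- rep(10, 5)
  e <- c(-0.5, -1.0, -9.9, -10, 0) # |E| relative to |E_max| = 10
  mask <- denatured_mask(energies = e, reference = ref)
  # 5% of max -> denatured; exactly 10% -> not (strict <); absent/zero -> denatured
  expect_equal(mask, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # all pairs at full strength -> all intact
  expect_false(any(denatured_mask(energies = rep(-10, 5), reference = ref)))
  expect_error(denatured_mask(energies = e), "reference")
  # state route copies the core pairing states
  fx <- plant_bubble(ideal_helix(60), start = 10, length = 3)
  m <- denatured_mask(fx$conformation)
  expect_equal(which(m) - 1L, 10:12)
})

test_that("bubble detection requires at least two consecutive denatured bp", {
  mask <- rep(FALSE, 200)
  mask[51] <- TRUE # isolated broken bp: not a bubble
  expect_equal(nrow(detect_bubbles(mask)), 0L)
  mask[151:153] <- TRUE
  b <- detect_bubbles(mask)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start_bp, 150)
  expect_equal(b$end_bp, 152)
  expect_equal(b$centre_bp, 151)
  expect_equal(nrow(detect_bubbles(rep(FALSE, 50))), 0L)
  mask[61:62] <- TRUE
  expect_equal(nrow(detect_bubbles(mask)), 2L)
})

test_that("frame classification applies the 20 bp co-localization rule and precedence", {
  plec <- data.frame(start_bp = 250, end_bp = 350, tip_bp = 300, size_bp = 101)
  bub_near <- data.frame(start_bp = 314, end_bp = 316, centre_bp = 315,
                         length_bp = 3)
  bub_far <- data.frame(start_bp = 324, end_bp = 326, centre_bp = 325,
                        length_bp = 3)
  none <- data.frame()
  expect_equal(classify_frame(bub_near, plec), "tip-bubble plectoneme")
  expect_equal(classify_frame(bub_far, plec), "plectoneme")
  expect_equal(classify_frame(bub_far, none), "bubble")
  expect_equal(classify_frame(none, none), "B-DNA")
  # strict inequality at exactly 20 bp
  bub_edge <- data.frame(centre_bp = 320)
  expect_equal(classify_frame(bub_edge, plec), "plectoneme")
  # totality over random call sets: always exactly one of four labels
  set.seed(1)
  for (k in 1:20) {
    p <- if (runif(1) < 0.5) plec[0, ] else plec
    b <- data.frame(centre_bp = runif(sample(0:3, 1), 0, 600))
    expect_true(classify_frame(b, p) %in%
                  c("B-DNA", "plectoneme", "tip-bubble plectoneme", "bubble"))
  }
})

test_that("state occupancy applies the dominance thresholds", {
  # build a fake trajectory of fixture frames with known labels
  helix <- ideal_helix(300)
  bubbly <- plant_bubble(helix, 100, 5)$conformation
  frames <- c(replicate(11, bubbly, simplify = FALSE),
              replicate(9, helix, simplify = FALSE))
  traj <- structure(list(
    frames = frames,
    channels = data.frame(sweep = 1:20, extension_nm = rnorm(20)),
    meta = list(sigma = -0.05, force_pN = 2, production_from = 1L,
                equilibration = list(tau_eq = 0, n_discarded = 0L,
                                     n_retained = 20L, converged = TRUE))),
    class = "td_trajectory")
  occ <- state_occupancy(traj)
  expect_equal(sum(occ$occupancy), 1, tolerance = 1e-12)
  expect_equal(unname(occ$occupancy["bubble"]), 0.55)
  expect_equal(occ$dominant, "bubble") # 0.55 >= 0.5
  # mixed and none labels
  expect_equal(plectodimer:::occupancy_label(c(a = 0.45, b = 0.3, c = 0.25, d = 0)),
               "mixed")
  expect_equal(plectodimer:::occupancy_label(c(a = 0.39, b = 0.31, c = 0.3, d = 0)),
               "none")
  # unequilibrated trajectories are refused without an override
  traj$meta$equilibration <- NULL
  expect_error(state_occupancy(traj), "override")
})

test_that("state diagram table is sorted, labelled and rejects duplicates", {
  mk <- function(sig, f, occ) {
    structure(list(occupancy = stats::setNames(occ, plectodimer:::STATE_LABELS),
                   dominant = plectodimer:::occupancy_label(
                     stats::setNames(occ, plectodimer:::STATE_LABELS)),
                   per_replica = NULL, n_frames = 100L, sigma = sig,
                   force_pN = f),
              class = "state_occupancy")
  }
  cells <- list(mk(-0.073, 2, c(0, 0.2, 0.25, 0.55)),
                mk(-0.038, 2, c(0.9, 0.1, 0, 0)),
                mk(-0.073, 0.5, c(0.1, 0.8, 0.1, 0)))
  dg <- state_diagram(cells)
  expect_equal(nrow(dg), 3L)
  expect_equal(dg$force_pN, c(0.5, 2, 2))
  expect_equal(dg$sigma, c(-0.073, -0.073, -0.038))
  expect_equal(dg$dominant, c("plectoneme", "bubble", "B-DNA"))
  # permuting the input order leaves the output sorted identically
  expect_equal(state_diagram(cells[c(3, 1, 2)]), dg)
  expect_error(state_diagram(c(cells, cells[1])), "duplicate")
  # single-cell grid
  expect_equal(nrow(state_diagram(cells[1])), 1L)
})

test_that("bend angle recovers planted kinks by two-group line fitting", {
  # straight chain: zero
  expect_lt(bend_angle(ideal_helix(80), boundary_bp = 40)$theta_deg, 0.1)
  for (ang in c(10, 20, 30)) {
    fx <- planted_kink(n = 80, kink_bp = 40, angle_deg = ang)
    got <- bend_angle(fx$conformation, boundary_bp = 40)
    expect_equal(got$theta_deg, ang, tolerance = 1 / ang)
  }
  # symmetric in group order: measuring from the mirrored chain is identical
  fx <- planted_kink(n = 80, kink_bp = 40, angle_deg = 30)
  rev_conf <- fx$conformation
  nr <- nrow(rev_conf$positions)
  rev_conf$positions <- rev_conf$positions[nr:1, ]
  rev_conf$normals <- -rev_conf$normals[(nr - 1):1, ]
  expect_equal(bend_angle(rev_conf, boundary_bp = 39)$theta_deg,
               bend_angle(fx$conformation, boundary_bp = 40)$theta_deg,
               tolerance = 0.15)
  expect_error(bend_angle(fx$conformation, boundary_bp = 5), "at least 10")
})

test_that("equilibration policy recovers known autocorrelation times", {
  set.seed(42)
  # white noise: tau_eq ~ 1 sample interval
  wn <- equilibration_policy(rnorm(5000))
  expect_lt(abs(wn$tau_eq - 1), 0.5)
  expect_true(wn$converged)
  # AR(1) with rho = 0.9: integrated time 2 * (0.5 + rho/(1-rho)) = 19
  rho <- 0.9
  x <- as.numeric(stats::arima.sim(list(ar = rho), 60000))
  ar <- equilibration_policy(x)
  expect_lt(abs(ar$tau_eq - (1 + rho) / (1 - rho)) / 19, 0.20)
  expect_gte(ar$n_discarded, 2 * ar$tau_eq)
  expect_gte(ar$n_retained, 6 * ar$tau_eq)
  # constant series: typed unconverged result
  cst <- equilibration_policy(rep(1, 100))
  expect_true(is.na(cst$tau_eq))
  expect_false(cst$converged)
  # short series: policy restated
  y <- rnorm(60)
  short <- equilibration_policy(y)
  expect_true(short$converged)
  expect_gte(short$n_discarded, 2 * short$tau_eq)
  expect_error(equilibration_policy(rnorm(10)), "50")
})

test_that("denaturation probability routes agree with construction", {
  helix <- ideal_helix(100, sequence = rep(c("A", "T", "G", "C"),
                                           length.out = 100))
  open2 <- plant_bubble(helix, 40, 2)$conformation # an A,T adjacent pair
  all_open <- helix
  all_open$intact[] <- FALSE
  mk_traj <- function(frames) structure(list(
    frames = frames,
    channels = data.frame(sweep = seq_along(frames),
                          extension_nm = rnorm(length(frames))),
    meta = list(production_from = 1L, sigma = 0, force_pN = 1,
                equilibration = list(tau_eq = 0, n_discarded = 0L,
                                     n_retained = length(frames),
                                     converged = TRUE))),
    class = "td_trajectory")

  # all-open trajectory: probability 1 on every route
  tr1 <- mk_traj(replicate(10, all_open, simplify = FALSE))
  for (target in c("at_any", "at_mean"))
    expect_equal(denaturation_probability(tr1, target)$probability, 1)
  expect_equal(denaturation_probability(tr1, "site_pair", bp = 40)$probability, 1)

  # exactly half the frames have the target pair open
  tr2 <- mk_traj(c(replicate(5, open2, simplify = FALSE),
                   replicate(5, helix, simplify = FALSE)))
  dp <- denaturation_probability(tr2, "site_pair", bp = 40)
  expect_equal(dp$probability, 0.5)
  expect_true(dp$ci95[1] < 0.5 && dp$ci95[2] > 0.5)

  # ANY-route >= MEAN-route on every input
  for (tr in list(tr1, tr2)) {
    expect_gte(denaturation_probability(tr, "at_any")$probability,
               denaturation_probability(tr, "at_mean")$probability)
  }

  # no eligible pairs: typed empty result
  gc_only <- ideal_helix(60, sequence = rep(c("G", "C"), 30))
  tr3 <- mk_traj(replicate(5, gc_only, simplify = FALSE))
  expect_s3_class(denaturation_probability(tr3, "at_any"), "insufficient_data")
})

test_that("twist profile is flat for relaxed helices and dips at untwisted windows", {
  helix <- ideal_helix(120)
  mk_traj <- function(frames) structure(list(
    frames = frames,
    channels = data.frame(sweep = seq_along(frames),
                          extension_nm = rnorm(length(frames))),
    meta = list(production_from = 1L, sigma = 0, force_pN = 1,
                equilibration = list(tau_eq = 0, n_discarded = 0L,
                                     n_retained = length(frames),
                                     converged = TRUE))),
    class = "td_trajectory")
  tr <- mk_traj(replicate(4, helix, simplify = FALSE))
  prof <- twist_profile(tr)
  expect_equal(max(abs(prof$mean_twist_deg - 360 / 10.55)), 0, tolerance = 0.1)

  # plant an untwisted 10-step window
  dip <- helix
  rows <- plectodimer:::core_row(helix, 50:59)
  for (k in rows) {
    tng <- c(0, 0, 1)
    back <- rotation_oracle(-(360 / 10.55), tng)
    dip$normals[k, ] <- c(back %*% matrix(dip$normals[k, ], 3)) # cancel one step
  }
  # rebuild cumulative consistency: simply rotate normals from row 50 on
  dip <- helix
  ang <- -2 * pi / 10.55
  for (k in seq(rows[1], nrow(dip$normals))) {
    shift <- min(10, k - rows[1] + 1) # first 10 steps each lose one unit
    R <- rotation_oracle(shift * ang * 180 / pi, c(0, 0, 1))
    dip$normals[k, ] <- c(R %*% matrix(helix$normals[k, ], 3))
  }
  tr2 <- mk_traj(list(dip))
  prof2 <- twist_profile(tr2)
  window <- prof2$bp >= 49 & prof2$bp <= 59
  expect_lt(mean(prof2$mean_twist_deg[window]),
            mean(prof2$mean_twist_deg[!window]) - 20)
  # invariance under rigid rotation of all frames
  rot <- dip
  R <- rotation_oracle(17, c(1, 1, 1))
  rot$positions <- rot$positions %*% t(R)
  rot$normals <- rot$normals %*% t(R)
  prof3 <- twist_profile(mk_traj(list(rot)))
  expect_equal(prof3$mean_twist_deg, prof2$mean_twist_deg, tolerance = 1e-9)
})
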