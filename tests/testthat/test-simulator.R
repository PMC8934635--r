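test_that("initial conformations are ideal, intact and deterministic", {
  par <- energy_params()
  seqs <- random_sequence(120, 0.5, 2)
  conf <- build_initial_conformation(seqs, par, handle_bp = 12L)
  expect_equal(twist(conf), 120 / 10.55, tolerance = 1e-6)
  expect_true(all(conf$intact))
  expect_identical(conf, build_initial_conformation(seqs, par, handle_bp = 12L))
  validate_conformation(conf, par)
  expect_error(build_initial_conformation(c(seqs, "X"), par), "A/C/G/T")
})

test_that("total energy matches closed forms", {
  par <- energy_params()
  prot0 <- free_protocol(0)
  conf <- ideal_helix(80)
  e <- total_energy(conf, par, prot0)
  expect_equal(unname(e[c("bend", "twist", "stretch", "pairing")]),
               rep(0, 4), tolerance = 1e-18)
  expect_equal(unname(e["overlap"]), 0)

  # single joint deflected by theta: bend = (p/h) theta^2 / 2
  for (th in c(10, 25)) {
    kink <- planted_kink(n = 80, kink_bp = 40, angle_deg = th)
    ek <- total_energy(kink$conformation, par, prot0)
    expect_equal(unname(ek["bend"]),
                 (45 / 0.34) * (th * pi / 180)^2 / 2, tolerance = 1e-9)
    expect_lt(unname(ek["twist"]), 1e-9)
  }

  # an intact dimer step deflected by exactly phi about its roll axis
  # contributes zero bending energy (the roll is its preferred geometry)
  phi <- 27.1
  spec <- defect_model_spec("TD0x", roll_angle_deg = phi,
                            stacking_multiplier = 10,
                            n_modified_steps = 1L, defect_index = 30L)
  pard <- energy_params(defect = spec)
  conf <- ideal_helix(80)
  v <- 30L + conf$handle_bp + 1L # 0-based modified joint (vertex index)
  axis_u <- conf$normals[v, ]    # material normal of the incoming segment
  R <- rotation_oracle(phi, axis_u)
  rows <- (v + 2L):nrow(conf$positions)
  pivot <- conf$positions[v + 1L, ]
  conf$positions[rows, ] <- t(R %*% (t(conf$positions[rows, , drop = FALSE]) -
                                       pivot) + pivot)
  srows <- (v + 1L):nrow(conf$normals)
  conf$normals[srows, ] <- conf$normals[srows, , drop = FALSE] %*% t(R)
  ed <- total_energy(conf, pard, prot0)
  expect_lt(unname(ed["bend"]), 1e-9)
  # the same geometry without the defect pays the full bending price
  e0 <- total_energy(conf, energy_params(), prot0)
  expect_gt(unname(e0["bend"]), 10)

  # hard-core overlap reports the +Inf sentinel, not an exception
  clash <- ideal_helix(80)
  clash$positions[40, ] <- clash$positions[60, ] + c(0.5, 0, 0)
  # keep bond lengths legal by bringing neighbours along
  clash$positions[39:41, ] <- clash$positions[59:61, ] + c(0.5, 0.17, 0)
  eo <- suppressWarnings(cpp_energy <- plectodimer:::cpp_total_energy(
    clash$positions, clash$normals, as.integer(!clash$intact),
    plectodimer:::site_opening_costs(clash, par),
    plectodimer:::params_cpp(par), list(n_mod = 0L),
    plectodimer:::protocol_cpp(clash, prot0, 300)))
  expect_equal(unname(eo["overlap"]), 1)
  expect_equal(unname(eo["total"]), Inf)
})

test_that("Metropolis dynamics is deterministic per seed and downhill when quenched", {
  par <- energy_params()
  prot <- tweezer_protocol(force_pN = 1.5)
  conf <- build_initial_conformation(random_sequence(60, 0.5, 4), par)
  s1 <- mc_sweep(conf, par, prot, quick_schedule(seed = 11), n_sweeps = 30)
  s2 <- mc_sweep(conf, par, prot, quick_schedule(seed = 11), n_sweeps = 30)
  expect_identical(s1$conformation, s2$conformation)
  s3 <- mc_sweep(conf, par, prot, quick_schedule(seed = 12), n_sweeps = 30)
  expect_false(identical(s3$conformation$positions, s1$conformation$positions))

  # beta x100 quench: energy of a relaxed conformation does not increase
  mini <- minimize_conformation(ideal_helix(50), par, seed = 1)
  e0 <- sum(total_energy(mini, par, free_protocol(0))[1:4])
  q <- mc_sweep(mini, par, free_protocol(0),
                quick_schedule(seed = 5, beta_factor = 100), n_sweeps = 100)
  e1 <- sum(total_energy(q$conformation, par, free_protocol(0))[1:4])
  expect_lt(e1, e0 + 0.5)
})

test_that("move energetics are reversible (detailed-balance energy antisymmetry)", {
  # a frozen short chain: apply an explicit crankshaft and its exact inverse
  par <- energy_params()
  prot <- free_protocol(0)
  base <- planted_kink(n = 12, kink_bp = 6, angle_deg = 20,
                       handle_bp = 1L)$conformation
  e_base <- sum(total_energy(base, par, prot)[1:4])
  for (ang in c(15, -25, 40)) {
    fwd <- crank_conf(base, a = 3L, b = 9L, angle_deg = ang)
    e_fwd <- sum(total_energy(fwd, par, prot)[1:4])
    back <- crank_conf(fwd, a = 3L, b = 9L, angle_deg = -ang)
    e_back <- sum(total_energy(back, par, prot)[1:4])
    dE_fwd <- e_fwd - e_base
    dE_rev <- e_back - e_fwd
    # reverse move restores the energy exactly: Metropolis ratios satisfy
    # acc(fwd)/acc(rev) = exp(-dE_fwd)
    expect_equal(dE_fwd, -dE_rev, tolerance = 1e-9)
    expect_equal(e_back, e_base, tolerance = 1e-9)
  }
})

test_that("winding conserves Tw + Wr and updates the bookkeeping", {
  par <- energy_params()
  prot <- tweezer_protocol(force_pN = 1.5, winding_rate_sweeps_per_turn = 300L)
  conf <- build_initial_conformation(random_sequence(100, 0.5, 8), par)
  sched <- simulation_schedule(seed = 3, sample_interval_sweeps = 10L,
                               store_frames = TRUE)
  traj <- wind(conf, par, prot, sched, turns = -1.5, extra_sweeps = 200L)
  ch <- traj$channels
  expect_equal(ch$applied_turns[nrow(ch)], -1.5, tolerance = 1e-9)
  resid <- ch$tw_all + ch$writhe - ch$lk_book
  expect_lt(max(abs(resid)), 0.05)
  # measured Tw + Wr changed by the applied turns
  expect_equal((ch$tw_all + ch$writhe)[nrow(ch)] -
                 (conf$bookkeeping$lk_book0), -1.5, tolerance = 0.05)
  # extraction at an intermediate superhelical density
  mid <- extract_state(traj, sigma = -0.08)
  expect_s3_class(mid, "chain_conformation")
  expect_equal(mid$bookkeeping$applied_turns,
               turns_for_sigma(-0.08, conf$bookkeeping$Lk0), tolerance = 0.2)
  expect_error(extract_state(traj, sigma = -0.5), "outside")
  # winding in a torsionally unconstrained protocol is refused
  expect_error(wind(conf, par, free_protocol(1), sched, turns = -1),
               "tweezer")
})

test_that("state-point replicas are independent but reproducible", {
  par <- energy_params()
  sched <- simulation_schedule(seed = 40, n_sweeps = 300L,
                               sample_interval_sweeps = 10L,
                               writhe_channel = FALSE)
  trs <- run_state_point(random_sequence(60, 0.5, 12), NULL, sigma = 0,
                         force_pN = 1.5, schedule = sched, n_replicas = 2L,
                         params = par)
  expect_length(trs, 2L)
  # distinct seeds give distinct trajectories
  expect_false(identical(trs[[1]]$channels$extension_nm,
                         trs[[2]]$channels$extension_nm))
  expect_equal(trs[[1]]$meta$seed + 1L, trs[[2]]$meta$seed)
  # bit-identical rerun with the same seed
  trs2 <- run_state_point(random_sequence(60, 0.5, 12), NULL, sigma = 0,
                          force_pN = 1.5, schedule = sched, n_replicas = 1L,
                          params = par)
  expect_identical(trs[[1]]$channels, trs2[[1]]$channels)
  # relaxed chain at sigma = 0: B-DNA in >= 95% of frames
  labs <- unlist(lapply(trs, function(tr)
    plectodimer:::classify_frames(tr$frames)))
  expect_gte(mean(labs == "B-DNA"), 0.95)
})

test_that("energy minimization relaxes to fixed points", {
  par <- energy_params()
  straight <- ideal_helix(40)
  m1 <- minimize_conformation(straight, par, seed = 2)
  expect_equal(m1$positions, straight$positions, tolerance = 1e-9)
  # idempotence
  spec <- td_preset("TD0")
  spec$defect_index <- 19L
  pard <- energy_params(defect = spec)
  conf <- build_initial_conformation(rep(c("A", "T"), 20), pard, handle_bp = 1L)
  r1 <- minimize_conformation(conf, pard, seed = 2)
  r2 <- minimize_conformation(r1, pard, seed = 3)
  expect_lt(abs(attr(r2, "energy") - attr(r1, "energy")), 1e-6)
  # the defect bends the minimized duplex
  th <- bend_angle(r1, boundary_bp = 20L)$theta_deg
  expect_gt(th, 5)
})
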