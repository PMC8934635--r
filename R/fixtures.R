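# run code with a local, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random DNA sequence
#'
#' Reproducible random sequence with a given expected GC content.
#'
#' @param n length in bp.
#' @param gc expected GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return character vector of bases.
#' @export
random_sequence <- function(n = 600L, gc = 0.5, seed = 1L) {
  stopifnot(gc >= 0, gc <= 1, n >= 1)
  with_seed(seed, sample(c("G", "C", "A", "T"), n, replace = TRUE,
                         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)))
}

#' Ideal straight helix
#'
#' A straight conformation along +z with uniform rise and uniform twist
#' `360/bp_per_turn` per step; its core twist equals the relaxed linking
#' number `n / bp_per_turn`.
#'
#' @param n core length in bp.
#' @param bp_per_turn helical repeat.
#' @param rise_nm rise per bp.
#' @param handle_bp cap sites per end.
#' @param sequence optional core sequence (defaults to alternating A/T).
#' @return a [chain_conformation()].
#' @export
ideal_helix <- function(n, bp_per_turn = 10.55, rise_nm = 0.34,
                        handle_bp = 1L, sequence = NULL) {
  stopifnot(n >= 3)
  if (is.null(sequence)) sequence <- rep(c("A", "T"), length.out = n)
  stopifnot(length(sequence) == n)
  hseq <- rep(c("G", "C"), length.out = handle_bp)
  full <- c(hseq, sequence, rev(hseq))
  ntot <- length(full)
  tw <- 2 * pi / bp_per_turn
  positions <- cbind(0, 0, rise_nm * (seq_len(ntot) - 1L))
  ang <- tw * (seq_len(ntot - 1L) - 1L)
  normals <- cbind(cos(ang), sin(ang), 0)
  conf <- chain_conformation(full, positions, normals, rep(TRUE, ntot),
                             handle_bp = handle_bp, rise_nm = rise_nm)
  conf$bookkeeping <- list(Lk0 = n / bp_per_turn,
                           pitch_bp_per_turn = bp_per_turn,
                           applied_turns = 0,
                           lk_book0 = sum(cpp_joint_twists(conf$positions,
                                                           conf$normals)) / (2 * pi))
  conf
}

# transport a material frame along a polyline and add uniform intrinsic
# twist; returns the (n-1) x 3 normals matrix
transported_normals <- function(points, twist_per_step_rad) {
  d <- diff(points)
  t <- d / sqrt(rowSums(d^2))
  m <- nrow(t)
  u <- matrix(NA_real_, m, 3)
  # initial normal: any unit vector orthogonal to t[1, ]
  ref <- if (abs(t[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u0 <- ref - sum(ref * t[1, ]) * t[1, ]
  u0 <- u0 / sqrt(sum(u0^2))
  u[1, ] <- u0
  for (k in 2:m) {
    ax <- c(t[k - 1, 2] * t[k, 3] - t[k - 1, 3] * t[k, 2],
            t[k - 1, 3] * t[k, 1] - t[k - 1, 1] * t[k, 3],
            t[k - 1, 1] * t[k, 2] - t[k - 1, 2] * t[k, 1])
    s <- sqrt(sum(ax^2))
    cc <- sum(t[k - 1, ] * t[k, ])
    if (s < 1e-14) {
      u[k, ] <- u[k - 1, ]
    } else {
      u[k, ] <- c(rotation_matrix(atan2(s, cc), ax / s) %*% u[k - 1, ])
    }
    # orthogonalize against accumulated rounding
    u[k, ] <- u[k, ] - sum(u[k, ] * t[k, ]) * t[k, ]
    u[k, ] <- u[k, ] / sqrt(sum(u[k, ]^2))
  }
  # add intrinsic twist about each tangent
  for (k in seq_len(m)) {
    if (twist_per_step_rad != 0) {
      u[k, ] <- c(rotation_matrix(twist_per_step_rad * (k - 1L), t[k, ]) %*% u[k, ])
    }
  }
  u
}

#' Planted plectoneme fixture
#'
#' A deterministic conformation containing one plectoneme with known
#' ground truth: two interwound superhelical arms around a horizontal axis,
#' an end-loop arc whose apex is the tip, and straight flanking stems that
#' leave the branch tangent-continuously. Triads are parallel-transported
#' along the axis with uniform intrinsic twist; all base pairs are intact.
#'
#' The geometry respects a 1.9 nm hard core everywhere; around the apical
#' loop the two duplexes approach closer than the mid-chain duplex-duplex
#' distance, as real sharply bent plectoneme tips do.
#'
#' Positive `chirality` winds the arms counterclockwise about the outward
#' superhelix axis (seen from the stem), which yields positive writhe;
#' negative chirality (the default, matching underwound DNA) yields
#' negative writhe.
#'
#' @param n core length in bp.
#' @param tip_bp requested 0-based core index of the tip.
#' @param size_bp requested plectoneme extent in bp; 0 plants nothing.
#' @param superhelix_radius_nm radius of the interwound arms.
#' @param superhelix_pitch_nm axial period of the interwinding.
#' @param chirality +1 or -1.
#' @param seed seed for the random core sequence.
#' @param handle_bp cap sites per end.
#' @param rise_nm rise per bp.
#' @param bp_per_turn helical repeat for the intrinsic twist.
#' @return list with `conformation` and `truth` (list: `start_bp`, `end_bp`,
#'   `tip_bp`, `size_bp`, `chirality`, `seed`; all actual values realized
#'   after resampling, `NULL`s when `size_bp = 0`).
#' @export
planted_plectoneme <- function(n = 600L, tip_bp = 300, size_bp = 150,
                               superhelix_radius_nm = 2.2,
                               superhelix_pitch_nm = 6.0,
                               chirality = -1L, seed = 1L,
                               handle_bp = 1L, rise_nm = 0.34,
                               bp_per_turn = 10.55) {
  h <- rise_nm
  sequence <- random_sequence(n, 0.5, seed)
  if (size_bp == 0) {
    conf <- ideal_helix(n, bp_per_turn, h, handle_bp, sequence)
    return(list(conformation = conf,
                truth = list(start_bp = NULL, end_bp = NULL, tip_bp = NULL,
                             size_bp = 0L, chirality = chirality, seed = seed)))
  }
  rho <- superhelix_radius_nm
  b <- superhelix_pitch_nm / (2 * pi)
  if (rho <= 0 || superhelix_pitch_nm <= 0) stop("radius and pitch must be > 0")
  if (pi * b < 1.0)
    stop("requested pitch brings the interwound arms closer than 1 nm: self-intersection")
  # end loop: circular arc joining the antipodal arm ends, wider than a
  # semicircle and sampled no finer than the rise so it clears the hard core
  r_loop <- 1.3 * rho
  arc_ang <- 2 * asin(min(1, rho / r_loop))
  loop_bp <- max(3L, as.integer(floor(r_loop * arc_ang / h)) - 1L)
  arm_bp <- round((size_bp - loop_bp) / 2)
  if (arm_bp < 5L)
    stop("size_bp too small for the requested loop radius")
  ntot <- n + 2L * handle_bp
  a_tip <- tip_bp + handle_bp # 0-based absolute index of the tip
  n_pre <- a_tip - arm_bp - loop_bp %/% 2L
  n_post <- ntot - n_pre - 2L * arm_bp - loop_bp
  if (n_pre < 2L || n_post < 2L)
    stop("tip_bp +/- size_bp/2 falls outside the chain")

  chi <- sign(chirality)
  th_step <- h / sqrt(b^2 + rho^2)
  theta_max <- arm_bp * th_step
  z0 <- (n_pre - 1L) * h # height of the branch
  # entry stem: leaves the branch within ~30 degrees of the arm's entry
  # tangent (a gentle, hard-core-safe corner) while receding from the
  # interwound body
  d1 <- c(0.35, -0.7, 0.62); d1 <- d1 / sqrt(sum(d1^2))
  p_pre <- t(sapply(seq_len(n_pre), function(k)
    c(0, rho, z0) - (n_pre - k) * h * d1))
  # outgoing arm: rises from the branch while advancing in +x
  th1 <- seq_len(arm_bp) * th_step
  p_arm1 <- cbind(b * th1, rho * cos(th1), z0 + rho * sin(th1))
  # end loop: arc bulging outward in +x between the antipodal arm ends
  cen <- c(b * theta_max, 0, z0)
  e1 <- (p_arm1[arm_bp, ] - cen) / rho
  cen_l <- cen - sqrt(r_loop^2 - rho^2) * c(1, 0, 0)
  phi0 <- atan2(rho, sqrt(r_loop^2 - rho^2))
  psi <- phi0 - seq_len(loop_bp) * (2 * phi0 / (loop_bp + 1L))
  p_loop <- t(sapply(psi, function(ps)
    cen_l + r_loop * sin(ps) * e1 + r_loop * cos(ps) * c(1, 0, 0)))
  # returning arm (same spatial handedness, phase-shifted by pi)
  th2 <- rev(seq_len(arm_bp) - 1L) * th_step
  p_arm2 <- cbind(b * th2, -rho * cos(th2), z0 - rho * sin(th2))
  # exit stem likewise, receding on the other side
  d2 <- c(-0.35, -0.7, 0.62); d2 <- d2 / sqrt(sum(d2^2))
  p_post <- t(sapply(seq_len(n_post), function(k) c(0, -rho, z0) + k * h * d2))

  pts <- rbind(p_pre, p_arm1, p_loop, p_arm2, p_post)
  stopifnot(nrow(pts) == ntot)
  # chirality: the construction above is left-handed (negative writhe, as
  # for underwound DNA); mirror y for the right-handed variant (frames are
  # transported afterwards, so B-form twist is preserved)
  if (chi > 0) pts[, 2] <- -pts[, 2]
  tw0 <- 2 * pi / bp_per_turn
  normals <- transported_normals(pts, tw0)
  conf <- chain_conformation(sequence = c(rep(c("G", "C"), length.out = handle_bp),
                                          sequence,
                                          rev(rep(c("G", "C"), length.out = handle_bp))),
                             positions = pts, normals = normals,
                             intact = rep(TRUE, ntot), handle_bp = handle_bp,
                             rise_nm = h)
  conf$bookkeeping <- list(Lk0 = n / bp_per_turn, pitch_bp_per_turn = bp_per_turn,
                           applied_turns = 0,
                           lk_book0 = sum(cpp_joint_twists(pts, normals)) / (2 * pi))
  start_abs <- n_pre            # 0-based absolute index of first arm point
  end_abs <- n_pre + 2L * arm_bp + loop_bp - 1L
  tip_abs <- n_pre + arm_bp + (loop_bp - 1L) / 2
  list(conformation = conf,
       truth = list(start_bp = start_abs - handle_bp,
                    end_bp = end_abs - handle_bp,
                    tip_bp = tip_abs - handle_bp,
                    size_bp = end_abs - start_abs + 1L,
                    chirality = chi, seed = seed))
}

#' Plant a denaturation bubble
#'
#' Marks core base pairs `[start, start + length)` as denatured, optionally
#' flaring their midpoints sideways (to exercise geometric pairing
#' detection on exported coordinates).
#'
#' @param conf a [chain_conformation()].
#' @param start 0-based core index of the first denatured bp.
#' @param length run length (>= 1).
#' @param flare_nm lateral midpoint displacement of the run.
#' @return list with `conformation` and `truth` (`start_bp`, `length_bp`).
#' @export
plant_bubble <- function(conf, start, length, flare_nm = 0) {
  stopifnot(inherits(conf, "chain_conformation"), length >= 1)
  n_core <- n_core_bp(conf)
  if (start < 0 || start + length > n_core)
    stop("bubble overlaps the handles or falls outside the core")
  rows <- core_row(conf, start:(start + length - 1L))
  conf$intact[rows] <- FALSE
  if (flare_nm != 0)
    conf$positions[rows, 1] <- conf$positions[rows, 1] + flare_nm
  list(conformation = conf,
       truth = list(start_bp = start, length_bp = as.integer(length)))
}

#' Planted plectoneme-walk trajectory
#'
#' A sequence of planted-plectoneme frames whose tip either stays fixed
#' (`pinned = TRUE`) or performs a reflected random walk with the given
#' step, for testing position-series and pinning statistics against known
#' ground truth.
#'
#' @param n_frames number of frames (>= 100).
#' @param walk_step tip step per frame in bp.
#' @param seed seed (walk and sequences).
#' @param pinned keep the tip fixed.
#' @param n core length in bp.
#' @param size_bp plectoneme size.
#' @param tip0 starting tip position (0-based core bp).
#' @return list with `trajectory` (a `td_trajectory`) and `truth`
#'   (`tips`: planted tip per frame).
#' @export
planted_walk_trajectory <- function(n_frames = 200L, walk_step = 5,
                                    seed = 1L, pinned = FALSE,
                                    n = 400L, size_bp = 120L, tip0 = 200) {
  stopifnot(n_frames >= 100L)
  lo <- size_bp / 2 + 30
  hi <- n - size_bp / 2 - 30
  tips <- numeric(n_frames)
  tips[1] <- tip0
  if (!pinned) {
    steps <- with_seed(seed, sample(c(-walk_step, walk_step), n_frames - 1L,
                                    replace = TRUE))
    for (k in 2:n_frames) {
      x <- tips[k - 1] + steps[k - 1]
      if (x < lo) x <- 2 * lo - x
      if (x > hi) x <- 2 * hi - x
      tips[k] <- x
    }
  } else {
    tips[] <- tip0
  }
  frames <- vector("list", n_frames)
  planted <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    fx <- planted_plectoneme(n = n, tip_bp = round(tips[k]), size_bp = size_bp,
                             seed = seed)
    frames[[k]] <- fx$conformation
    planted[k] <- fx$truth$tip_bp
  }
  channels <- data.frame(
    sweep = seq_len(n_frames),
    applied_turns = 0,
    extension_nm = vapply(frames, function(f)
      f$positions[nrow(f$positions), 3] - f$positions[1, 3], 0))
  traj <- structure(
    list(frames = frames, channels = channels,
         meta = list(force_pN = NA_real_, applied_turns = 0, sigma = 0,
                     model = "fixture", seed = seed, temperature_K = NA_real_,
                     handle_bp = frames[[1]]$handle_bp,
                     n_core = n, sample_interval = 1L,
                     production_from = 1L,
                     equilibration = structure(
                       list(tau_eq = 0, n_discarded = 0L,
                            n_retained = n_frames, converged = TRUE,
                            n_samples = n_frames),
                       class = "equilibration_report"))),
    class = "td_trajectory")
  list(trajectory = traj, truth = list(tips = planted, pinned = pinned,
                                       walk_step = walk_step, seed = seed))
}

#' Planted kink fixture
#'
#' A straight helix with a single kink of the given angle at a core base
#' pair, for bend-angle and curvature-profile validation.
#'
#' @param n core length in bp.
#' @param kink_bp 0-based core index of the kink.
#' @param angle_deg kink angle.
#' @param handle_bp cap sites per end.
#' @param rise_nm rise per bp.
#' @param bp_per_turn helical repeat.
#' @return list with `conformation` and `truth`.
#' @export
planted_kink <- function(n = 80L, kink_bp = 40L, angle_deg = 30,
                         handle_bp = 1L, rise_nm = 0.34,
                         bp_per_turn = 10.55) {
  ntot <- n + 2L * handle_bp
  a <- kink_bp + handle_bp # 0-based absolute vertex of the kink
  ang <- angle_deg * pi / 180
  d1 <- c(0, 0, 1)
  d2 <- c(sin(ang), 0, cos(ang))
  pts <- matrix(NA_real_, ntot, 3)
  pts[1, ] <- c(0, 0, 0)
  for (k in 2:ntot) {
    dir <- if (k - 2L < a) d1 else d2
    pts[k, ] <- pts[k - 1, ] + rise_nm * dir
  }
  normals <- transported_normals(pts, 2 * pi / bp_per_turn)
  conf <- chain_conformation(rep(c("A", "T"), length.out = ntot), pts, normals,
                             rep(TRUE, ntot), handle_bp = handle_bp,
                             rise_nm = rise_nm)
  conf$bookkeeping <- list(Lk0 = n / bp_per_turn, pitch_bp_per_turn = bp_per_turn,
                           applied_turns = 0,
                           lk_book0 = sum(cpp_joint_twists(pts, normals)) / (2 * pi))
  list(conformation = conf,
       truth = list(kink_bp = kink_bp, angle_deg = angle_deg))
}

#' The committed randomized plectoneme corpus manifest
#'
#' Returns the manifest (seed, chain length, plectoneme size, tip position,
#' chirality) of the randomized planted-plectoneme corpus used for detector
#' validation. The manifest ships with the package so the corpus is fully
#' reproducible.
#'
#' @return data.frame, one row per fixture.
#' @export
plectoneme_corpus_manifest <- function() {
  path <- system.file("extdata", "plectoneme_corpus.tsv",
                      package = "plectodimer", mustWork = TRUE)
  utils::read.delim(path)
}
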