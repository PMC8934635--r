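#' Total energy of a conformation
#'
#' Energy breakdown in units of kBT: bending, twisting, bond stretching,
#' base pairing (opening free energies plus domain-wall costs), pulling
#' force, repulsion planes and transverse trap. Hard-core overlaps make the
#' total `+Inf` (the move-rejection sentinel), with the `overlap` element
#' set to 1.
#'
#' @param conf a [chain_conformation()].
#' @param params an [energy_params()].
#' @param protocol a [tweezer_protocol()].
#' @param temperature_K temperature (sets the force and trap energy scales).
#' @return named numeric vector with elements `bend`, `twist`, `stretch`,
#'   `pairing`, `force`, `plane`, `trap`, `overlap`, `total`.
#' @export
total_energy <- function(conf, params = energy_params(),
                         protocol = tweezer_protocol(),
                         temperature_K = 300) {
  validate_conformation(conf)
  cpp_total_energy(conf$positions, conf$normals,
                   as.integer(!conf$intact),
                   site_opening_costs(conf, params),
                   params_cpp(params), defect_cpp(conf, params),
                   protocol_cpp(conf, protocol, temperature_K))
}

# schedule list handed to the C++ engine
schedule_cpp <- function(conf, protocol, schedule, wind_sweeps, prod_sweeps,
                         turns_target, seed = NULL) {
  mix <- schedule$move_mix
  if (is.null(mix)) mix <- default_move_mix(protocol)
  list(seed = as.numeric(if (is.null(seed)) schedule$seed else seed),
       beta = schedule$beta_factor,
       amplitudes = schedule$move_amplitudes,
       move_mix = mix,
       wind_sweeps = as.integer(wind_sweeps),
       prod_sweeps = as.integer(prod_sweeps),
       sample_interval = schedule$sample_interval_sweeps,
       store_frames = schedule$store_frames,
       writhe_channel = schedule$writhe_channel,
       turns_target = turns_target,
       lk_book0 = if (is.null(conf$bookkeeping)) 0 else conf$bookkeeping$lk_book0)
}

run_engine <- function(conf, params, protocol, schedule, wind_sweeps,
                       prod_sweeps, turns_target, seed = NULL) {
  res <- cpp_run_mc(conf$positions, conf$normals, as.integer(!conf$intact),
                    site_opening_costs(conf, params),
                    params_cpp(params), defect_cpp(conf, params),
                    protocol_cpp(conf, protocol, schedule$temperature_K),
                    schedule_cpp(conf, protocol, schedule, wind_sweeps,
                                 prod_sweeps, turns_target, seed))
  final <- conf_from_state(res$state, conf)
  frames <- lapply(res$frames, conf_from_state, template = conf)
  channels <- as.data.frame(res$channels)
  traj <- structure(
    list(frames = frames, channels = channels,
         meta = list(
           force_pN = protocol$force_pN,
           applied_turns = res$state$applied_turns,
           sigma = if (!is.null(conf$bookkeeping))
             res$state$applied_turns / conf$bookkeeping$Lk0 else NA_real_,
           model = if (is.null(params$defect)) "undamaged" else params$defect$name,
           seed = if (is.null(seed)) schedule$seed else seed,
           temperature_K = schedule$temperature_K,
           handle_bp = conf$handle_bp,
           n_core = n_core_bp(conf),
           sample_interval = schedule$sample_interval_sweeps,
           protocol = protocol, schedule = schedule,
           equilibration = NULL)),
    class = "td_trajectory")
  list(trajectory = traj, conformation = final, acceptance = res$acceptance)
}

#' Monte Carlo sweeps over a conformation
#'
#' Runs `n_sweeps` Metropolis sweeps (one attempted move per site per
#' sweep) and returns the updated conformation together with per-move-type
#' acceptance statistics. The move set comprises internal crankshaft
#' rotations, single and block triad twirls, transverse wave displacements,
#' ramped axial shifts, per-site pairing flips (with twist re-partitioning)
#' and, for unconstrained chains, tail pivots.
#'
#' @inheritParams total_energy
#' @param schedule a [simulation_schedule()]; its `seed` makes the sweep
#'   deterministic.
#' @param n_sweeps number of sweeps.
#' @return list with elements `conformation`, `acceptance` (matrix of
#'   attempts/accepts per move type) and `channels` (samples recorded at the
#'   schedule's sampling interval).
#' @export
mc_sweep <- function(conf, params = energy_params(),
                     protocol = tweezer_protocol(),
                     schedule = simulation_schedule(), n_sweeps = 1L) {
  out <- run_engine(conf, params, protocol, schedule,
                    wind_sweeps = 0L, prod_sweeps = n_sweeps,
                    turns_target = if (is.null(conf$bookkeeping)) 0
                                   else conf$bookkeeping$applied_turns)
  list(conformation = out$conformation, acceptance = out$acceptance,
       channels = out$trajectory$channels)
}

#' Quasi-static winding to a target number of turns
#'
#' Rotates the pulled-end handle about the helical axis at
#' `winding_rate_sweeps_per_turn`, updating the linking-number bookkeeping
#' continuously, and samples conformations along the way, so that a
#' configuration at any intermediate superhelical density can be extracted
#' with [extract_state()].
#'
#' @inheritParams mc_sweep
#' @param turns target applied turns (absolute, not incremental); defaults
#'   to `protocol$applied_turns`.
#' @param extra_sweeps production sweeps appended after the ramp.
#' @return a `td_trajectory`; the final conformation is attached as
#'   attribute `"final"` and also retrievable via [last_frame()].
#' @export
wind <- function(conf, params = energy_params(),
                 protocol = tweezer_protocol(),
                 schedule = simulation_schedule(),
                 turns = NULL, extra_sweeps = 0L) {
  if (!protocol$constrain_turns)
    stop("winding requires a turn-constrained (tweezer) protocol")
  if (is.null(turns)) turns <- protocol$applied_turns
  d_turns <- turns - conf$bookkeeping$applied_turns
  wind_sweeps <- ceiling(abs(d_turns) * protocol$winding_rate_sweeps_per_turn)
  out <- run_engine(conf, params, protocol, schedule,
                    wind_sweeps = wind_sweeps,
                    prod_sweeps = as.integer(extra_sweeps),
                    turns_target = turns)
  traj <- out$trajectory
  attr(traj, "final") <- out$conformation
  attr(traj, "acceptance") <- out$acceptance
  traj
}

#' Extract the sampled conformation nearest a superhelical density
#'
#' @param traj a `td_trajectory` with stored frames.
#' @param sigma requested superhelical density.
#' @param tol how far (in turns) the nearest sample may be from the request.
#' @return a [chain_conformation()].
#' @export
extract_state <- function(traj, sigma, tol = 0.5) {
  stopifnot(inherits(traj, "td_trajectory"))
  if (length(traj$frames) == 0L) stop("trajectory has no stored frames")
  lk0 <- traj$frames[[1]]$bookkeeping$Lk0
  want <- turns_for_sigma(sigma, lk0)
  turns <- traj$channels$applied_turns
  i <- which.min(abs(turns - want))
  if (abs(turns[i] - want) > tol)
    stop(sprintf("requested sigma %.4f (%.2f turns) outside the wound range [%.2f, %.2f]",
                 sigma, want, min(turns), max(turns)))
  traj$frames[[i]]
}

#' @rdname extract_state
#' @export
last_frame <- function(traj) {
  fin <- attr(traj, "final")
  if (!is.null(fin)) return(fin)
  if (length(traj$frames) == 0L) stop("trajectory has no stored frames")
  traj$frames[[length(traj$frames)]]
}

#' @export
print.td_trajectory <- function(x, ...) {
  cat(sprintf("<td_trajectory> %d stored frames, %d samples\n",
              length(x$frames), nrow(x$channels)))
  cat(sprintf("  model %s, F = %.2f pN, sigma = %.4f, seed %d\n",
              x$meta$model, x$meta$force_pN, x$meta$sigma, x$meta$seed))
  if (!is.null(x$meta$equilibration))
    cat(sprintf("  equilibration: tau_eq = %.1f samples, converged = %s\n",
                x$meta$equilibration$tau_eq, x$meta$equilibration$converged))
  invisible(x)
}

#' Potential-energy minimization of a conformation
#'
#' Zero-temperature (downhill-only) relaxation with amplitude annealing,
#' used for measuring the intrinsic bend angle of a defect. With
#' `protocol_off = TRUE` (default) traps, force and planes are disabled and
#' the chain relaxes freely.
#'
#' @inheritParams total_energy
#' @param protocol_off disable traps/force/planes.
#' @param seed seed of the (deterministic) move stream.
#' @param max_rounds annealing rounds cap (20 sweeps each).
#' @param tol energy-improvement tolerance per round (kBT).
#' @return the relaxed [chain_conformation()], with attributes
#'   `"energy"` (kBT) and `"rounds"`.
#' @export
minimize_conformation <- function(conf, params = energy_params(),
                                  protocol = NULL, protocol_off = TRUE,
                                  seed = 1L, max_rounds = 4000L, tol = 1e-8) {
  if (protocol_off || is.null(protocol))
    protocol <- free_protocol(force_pN = if (protocol_off || is.null(protocol)) 0
                              else protocol$force_pN,
                              handle_length_bp = conf$handle_bp)
  sched <- simulation_schedule(
    seed = seed, n_sweeps = 0L, store_frames = FALSE, writhe_channel = FALSE,
    move_mix = list(crankshaft = 0.2, twirl = 0.2, block_twirl = 0.1,
                    zshift = 0, pairing = 0, pivot = 0.3, local = 0.1,
                    wave = 0.1))
  res <- cpp_minimize(conf$positions, conf$normals, as.integer(!conf$intact),
                      site_opening_costs(conf, params),
                      params_cpp(params), defect_cpp(conf, params),
                      protocol_cpp(conf, protocol, sched$temperature_K),
                      schedule_cpp(conf, protocol, sched, 0L, 0L,
                                   conf$bookkeeping$applied_turns %||% 0),
                      as.integer(max_rounds), tol)
  if (!res$converged)
    stop(sprintf("minimization did not converge within %d rounds (energy %.6g, last round %d)",
                 max_rounds, res$energy, res$rounds))
  out <- conf_from_state(res$state, conf)
  attr(out, "energy") <- res$energy
  attr(out, "rounds") <- res$rounds
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate replicas at one (sigma, force) state point
#'
#' Builds an ideal starting conformation, winds quasi-statically to the
#' requested superhelical density, then collects production sweeps.
#' Replicas use seeds `seed + 0, 1, 2, ...` and are therefore independent
#' but reproducible. The equilibration policy (autocorrelation of the
#' end-to-end distance, burn-in of `2 tau_eq`, at least `6 tau_eq`
#' retained) is applied to each trajectory and recorded in its metadata;
#' failure to equilibrate is flagged, not fatal.
#'
#' @param sequence core sequence (vector of bases or one string).
#' @param model a [defect_model_spec()] or `NULL` for undamaged DNA.
#' @param sigma target superhelical density.
#' @param force_pN pulling force.
#' @param schedule a [simulation_schedule()]; `n_sweeps` is the production
#'   length per replica.
#' @param n_replicas number of independent replicas (>= 1; the study
#'   protocol uses at least 3).
#' @param params an [energy_params()]; its `defect` field is overridden by
#'   `model`.
#' @param protocol a [tweezer_protocol()]; `force_pN` and target turns are
#'   overridden.
#' @return list of `td_trajectory`, one per replica.
#' @export
run_state_point <- function(sequence, model = NULL, sigma = 0,
                            force_pN = 1.5,
                            schedule = simulation_schedule(),
                            n_replicas = 3L,
                            params = energy_params(),
                            protocol = tweezer_protocol()) {
  stopifnot(n_replicas >= 1)
  params$defect <- model
  protocol$force_pN <- force_pN
  out <- vector("list", n_replicas)
  for (k in seq_len(n_replicas)) {
    conf <- build_initial_conformation(sequence, params,
                                       handle_bp = protocol$handle_length_bp)
    turns <- turns_for_sigma(sigma, conf$bookkeeping$Lk0)
    wind_sweeps <- ceiling(abs(turns) * protocol$winding_rate_sweeps_per_turn)
    res <- run_engine(conf, params, protocol, schedule,
                      wind_sweeps = wind_sweeps,
                      prod_sweeps = schedule$n_sweeps,
                      turns_target = turns,
                      seed = schedule$seed + (k - 1L))
    traj <- res$trajectory
    attr(traj, "final") <- res$conformation
    # production part starts after the winding ramp
    prod <- traj$channels$sweep > ceiling(wind_sweeps)
    traj$meta$production_from <- which(prod)[1]
    eq <- try(equilibration_policy(traj), silent = TRUE)
    if (!inherits(eq, "try-error")) traj$meta$equilibration <- eq
    out[[k]] <- traj
  }
  out
}
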