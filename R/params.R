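#' Elastic and pairing parameters of the mesoscale chain
#'
#' One rigid site per base pair; intact and denatured (single-stranded)
#' steps differ in bending and torsional persistence length, preferred
#' twist, and excluded-volume diameter. Denatured steps have near-zero
#' preferred twist and a tiny twist modulus, which is what lets bubbles
#' absorb torsional stress.
#'
#' Opening free energies and the bubble domain-wall cost are calibration
#' knobs. `dG_open_AT` / `dG_open_GC` are *effective* opening free energies:
#' the engine adds the joint-softening entropy released when a step switches
#' from duplex to single-stranded stiffness
#' (`ln(p_ds/p_ss) + ln(C_ds/C_ss)/2`, about 4.4 kBT at the defaults) to
#' obtain the bare flip energy, so the stated value is the net cost of
#' opening a base pair in a relaxed chain. The defaults were calibrated on
#' the undamaged chain so that denaturation competes with plectoneme
#' formation in the piconewton force range, with the bubble state taking
#' over from the plectonemic states at `F = 2 pN` as sigma approaches -0.09
#' (see the package vignette for the calibration runs).
#'
#' @param rise_nm helical rise per base pair (nm).
#' @param p_ds_nm,p_ss_nm bending persistence length of intact / denatured
#'   steps (nm).
#' @param C_ds_nm,C_ss_nm torsional persistence length of intact / denatured
#'   steps (nm).
#' @param intrinsic_twist_deg preferred twist per intact step (degrees);
#'   360/10.55 by default.
#' @param dG_open_AT,dG_open_GC opening free energy per A:T / G:C base pair
#'   (kBT).
#' @param boundary_cost free-energy cost per intact<->denatured domain wall
#'   (kBT).
#' @param excluded_diameter_nm hard-core diameter between intact sites (nm);
#'   about the effective duplex diameter at 100 mM monovalent salt.
#' @param excluded_diameter_ss_nm hard-core diameter when either site of a
#'   pair is denatured (nm).
#' @param ev_min_separation smallest sequence separation (in sites) checked
#'   for hard-core overlap; closer pairs cannot cross without divergent
#'   bending energy.
#' @param stretch_stiffness_kbt_nm2 harmonic stiffness of the bond length
#'   about `rise_nm` (kBT/nm^2).
#' @param defect a [defect_model_spec()] or `NULL` for undamaged DNA.
#' @return an object of class `energy_params`.
#' @export
energy_params <- function(rise_nm = 0.34,
                          p_ds_nm = 45,
                          p_ss_nm = 3,
                          C_ds_nm = 95,
                          C_ss_nm = 3,
                          intrinsic_twist_deg = 360 / 10.55,
                          dG_open_AT = 5.5,
                          dG_open_GC = 7.0,
                          boundary_cost = 2.5,
                          excluded_diameter_nm = 2.5,
                          excluded_diameter_ss_nm = 1.0,
                          ev_min_separation = 8L,
                          stretch_stiffness_kbt_nm2 = 800,
                          defect = NULL) {
  stopifnot(rise_nm > 0, p_ds_nm > 0, p_ss_nm > 0, C_ds_nm > 0, C_ss_nm > 0,
            dG_open_AT > 0, dG_open_GC >= dG_open_AT, boundary_cost >= 0,
            stretch_stiffness_kbt_nm2 > 0, ev_min_separation >= 2)
  if (!is.null(defect) && !inherits(defect, "defect_model_spec"))
    stop("defect must be NULL or a defect_model_spec")
  structure(
    list(rise_nm = rise_nm, p_ds_nm = p_ds_nm, p_ss_nm = p_ss_nm,
         C_ds_nm = C_ds_nm, C_ss_nm = C_ss_nm,
         intrinsic_twist_deg = intrinsic_twist_deg,
         dG_open_AT = dG_open_AT, dG_open_GC = dG_open_GC,
         boundary_cost = boundary_cost,
         excluded_diameter_nm = excluded_diameter_nm,
         excluded_diameter_ss_nm = excluded_diameter_ss_nm,
         ev_min_separation = as.integer(ev_min_separation),
         stretch_stiffness_kbt_nm2 = stretch_stiffness_kbt_nm2,
         defect = defect),
    class = "energy_params"
  )
}

#' Magnetic-tweezer boundary conditions
#'
#' One chain end ("surface" handle) is held rigidly; the other ("bead"
#' handle) is confined to the pulling axis but free to move along it, is
#' pulled with a constant force `F`, and can be rotated about the axis to
#' impose turns. Repulsion planes at both handles prevent the chain from
#' wrapping around the ends, which would change the linking number.
#'
#' @param handle_length_bp handle sites at each end (default 12).
#' @param trap_stiffness_kbt_nm2 transverse stiffness of the bead trap; the
#'   default is stiff enough that the handle is effectively rigid.
#' @param force_pN pulling force in pN.
#' @param applied_turns turns imposed on the bead handle (negative =
#'   underwinding).
#' @param winding_rate_sweeps_per_turn quasi-static winding rate.
#' @param plane_repulsion logical; keep repulsion planes on.
#' @param plane_stiffness_kbt_nm2 stiffness of the repulsion planes.
#' @param constrain_turns logical; `FALSE` gives a torsionally unconstrained
#'   chain (free end swivel, no transverse trap), used for force-extension
#'   sampling and energy minimization.
#' @param pulled_end_axial_free logical, documentation of the trap geometry:
#'   the trap component along the pulling axis is zero.
#' @return an object of class `tweezer_protocol`.
#' @export
tweezer_protocol <- function(handle_length_bp = 12L,
                             trap_stiffness_kbt_nm2 = 1000,
                             force_pN = 1.5,
                             applied_turns = 0,
                             winding_rate_sweeps_per_turn = 2000L,
                             plane_repulsion = TRUE,
                             plane_stiffness_kbt_nm2 = 1000,
                             constrain_turns = TRUE,
                             pulled_end_axial_free = TRUE) {
  stopifnot(handle_length_bp >= 1, winding_rate_sweeps_per_turn >= 1,
            force_pN >= 0, trap_stiffness_kbt_nm2 >= 0,
            plane_stiffness_kbt_nm2 >= 0)
  if (constrain_turns && handle_length_bp < 2)
    stop("imposing turns requires handle_length_bp >= 2")
  structure(
    list(handle_length_bp = as.integer(handle_length_bp),
         trap_stiffness_kbt_nm2 = trap_stiffness_kbt_nm2,
         force_pN = force_pN,
         applied_turns = applied_turns,
         winding_rate_sweeps_per_turn = as.integer(winding_rate_sweeps_per_turn),
         plane_repulsion = isTRUE(plane_repulsion),
         plane_stiffness_kbt_nm2 = plane_stiffness_kbt_nm2,
         constrain_turns = isTRUE(constrain_turns),
         pulled_end_axial_free = isTRUE(pulled_end_axial_free)),
    class = "tweezer_protocol"
  )
}

#' Free-chain protocol
#'
#' Convenience wrapper for a torsionally unconstrained chain under force:
#' no transverse trap, no imposed turns, no repulsion planes. Used for
#' force-extension sampling and free energy minimization.
#'
#' @param force_pN pulling force in pN.
#' @param handle_length_bp cap sites per end (>= 1).
#' @export
free_protocol <- function(force_pN = 0, handle_length_bp = 1L) {
  tweezer_protocol(handle_length_bp = handle_length_bp,
                   force_pN = force_pN, applied_turns = 0,
                   plane_repulsion = FALSE, constrain_turns = FALSE)
}

#' Monte Carlo schedule
#'
#' @param temperature_K temperature in kelvin; enters through the force and
#'   trap energy scales (elastic constants are specified athermally via
#'   persistence lengths).
#' @param seed integer seed of the engine's random stream; recorded in every
#'   trajectory.
#' @param n_sweeps production sweeps (one sweep = one attempted move per
#'   site).
#' @param sample_interval_sweeps sweeps between stored samples.
#' @param move_amplitudes named list of maximum move sizes; see Details.
#' @param move_mix named non-negative weights for the move types
#'   `crankshaft`, `twirl`, `block_twirl`, `zshift`, `pairing`, `pivot`,
#'   `local`, `wave`. `NULL` selects defaults appropriate to the protocol.
#' @param store_frames keep full conformations at each sample (needed for
#'   per-frame structural analysis).
#' @param writhe_channel compute the writhe channel at each sample
#'   (O(n^2) per sample).
#' @param beta_factor multiplies the inverse temperature; > 1 quenches the
#'   chain (used in tests of the Metropolis property).
#'
#' @details Default amplitudes: crankshaft 40 degrees over spans up to 50
#' segments, single twirl 10 degrees, block twirl 4 degrees, pulled-handle
#' z-shifts 0.4 nm (ramped over up to 30 bonds), pivot 20 degrees, local vertex displacement 0.05 nm.
#' @return an object of class `simulation_schedule`.
#' @export
simulation_schedule <- function(temperature_K = 300,
                                seed = 1L,
                                n_sweeps = 2000L,
                                sample_interval_sweeps = 10L,
                                move_amplitudes = list(),
                                move_mix = NULL,
                                store_frames = TRUE,
                                writhe_channel = TRUE,
                                beta_factor = 1) {
  amp <- list(crankshaft_max_deg = 40, twirl_max_deg = 10,
              block_twirl_max_deg = 4, max_segment_span = 50L,
              zshift_max_nm = 0.4, pivot_max_deg = 20, local_max_nm = 0.05,
              wave_max_nm = 1.2, wave_max_span = 300L)
  stopifnot(all(names(move_amplitudes) %in% names(amp)))
  amp[names(move_amplitudes)] <- move_amplitudes
  stopifnot(temperature_K > 0, n_sweeps >= 0, sample_interval_sweeps >= 1,
            beta_factor > 0)
  structure(
    list(temperature_K = temperature_K, seed = as.integer(seed),
         n_sweeps = as.integer(n_sweeps),
         sample_interval_sweeps = as.integer(sample_interval_sweeps),
         move_amplitudes = amp, move_mix = move_mix,
         store_frames = isTRUE(store_frames),
         writhe_channel = isTRUE(writhe_channel),
         beta_factor = beta_factor),
    class = "simulation_schedule"
  )
}

default_move_mix <- function(protocol) {
  if (isTRUE(protocol$constrain_turns)) {
    list(crankshaft = 0.25, twirl = 0.15, block_twirl = 0.20,
         zshift = 0.10, pairing = 0.15, pivot = 0, local = 0.05,
         wave = 0.10)
  } else {
    list(crankshaft = 0.25, twirl = 0.15, block_twirl = 0.15,
         zshift = 0, pairing = 0.10, pivot = 0.20, local = 0.05,
         wave = 0.10)
  }
}

#' Read / write a run configuration file
#'
#' A single INI-style file with `[energy]`, `[protocol]` and `[schedule]`
#' sections whose keys mirror the arguments of [energy_params()],
#' [tweezer_protocol()] and [simulation_schedule()] (scalar fields only;
#' the defect is referenced by a `model_file` key in `[energy]`). Every run
#' started from a config logs the resolved values.
#'
#' @param path file path.
#' @return `read_config()` returns `list(energy, protocol, schedule)`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  out <- list(energy = list(), protocol = list(), schedule = list())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% names(out)) stop("unknown config section: ", section)
    } else {
      m <- regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.*)$", ln)[[1]]
      if (length(m) == 1L || !nzchar(section))
        stop("malformed config line: ", ln)
      kv <- regmatches(ln, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.*)$", ln))[[1]]
      val <- kv[3]
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
      else if (val %in% c("TRUE", "FALSE", "true", "false"))
        val <- toupper(val) == "TRUE"
      out[[section]][[kv[2]]] <- val
    }
  }
  energy_args <- out$energy
  if (!is.null(energy_args$model_file)) {
    energy_args$defect <- read_model_spec(energy_args$model_file)
    energy_args$model_file <- NULL
  }
  list(
    energy = do.call(energy_params, energy_args),
    protocol = do.call(tweezer_protocol, out$protocol),
    schedule = do.call(simulation_schedule,
                       out$schedule[names(out$schedule) != "move_amplitudes"])
  )
}

#' @rdname read_config
#' @param energy an [energy_params()].
#' @param protocol a [tweezer_protocol()].
#' @param schedule a [simulation_schedule()].
#' @param model_file optional path written for the defect preset.
#' @export
write_config <- function(path, energy, protocol, schedule, model_file = NULL) {
  fmt <- function(x) {
    if (is.logical(x)) return(ifelse(x, "TRUE", "FALSE"))
    format(x, digits = 15, scientific = FALSE)
  }
  scal <- function(lst, drop = character()) {
    keep <- vapply(lst, function(v) is.atomic(v) && length(v) == 1L, TRUE)
    lst <- lst[keep & !names(lst) %in% drop]
    vapply(names(lst), function(k) sprintf("%s = %s", k, fmt(lst[[k]])), "")
  }
  lines <- c("[energy]", scal(unclass(energy), drop = "defect"))
  if (!is.null(model_file)) lines <- c(lines, sprintf("model_file = %s", model_file))
  lines <- c(lines, "", "[protocol]", scal(unclass(protocol)),
             "", "[schedule]",
             scal(unclass(schedule), drop = c("move_amplitudes", "move_mix")))
  writeLines(lines, path)
  invisible(path)
}
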