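#' Thymine-dimer defect model specification
#'
#' A `defect_model_spec` parametrizes a cyclobutane pyrimidine dimer (CPD,
#' "thymine dimer") as a local modification of the duplex: an extra roll
#' angle `phi` imposed at the dimer-containing base-pair step(s), a
#' weakening of the hydrogen bonding (base-pairing free energy) at the two
#' dimer base pairs, and a stacking enhancement that keeps the two thymines
#' stacked even when the dimer flips out of the helix.
#'
#' Three shipped presets (`TD0`, `TD1`, `TD2`, see [td_preset()]) span the
#' experimentally plausible range: a single strongly stacked step with a
#' 27.1 degree roll and 60% hydrogen-bond weakening (TD0), two rolled steps
#' with mild (10%) weakening producing a larger duplex bend (TD1), and two
#' rolled steps with 55% weakening and a TD0-like bend (TD2).
#'
#' @param name identifier, e.g. `"TD0"`.
#' @param roll_angle_deg roll angle `phi` in degrees, in `[0, 45]` (the
#'   validated linear regime of bend angle versus roll).
#' @param stacking_multiplier dimensionless stacking enhancement factor,
#'   `>= 1`. Mimics the covalent cyclobutane link between the thymines.
#' @param n_modified_steps number of base-pair steps carrying the modified
#'   roll; 1 or 2.
#' @param hbond_weakening_fraction fraction in `[0, 1]` by which the opening
#'   free energy of the two dimer base pairs is reduced.
#' @param defect_index 0-based base-pair index of the 5'-most dimer base
#'   pair (the dimer occupies `defect_index` and `defect_index + 1`).
#' @param reference_bend_min_deg,reference_bend_md_deg documentation values
#'   of the duplex bend angle `theta0` (degrees) measured for this
#'   parametrization at the potential-energy minimum and in thermal
#'   simulation, respectively. Used by [loop_energy_reduction()] presets.
#' @return an object of class `defect_model_spec`.
#' @seealso [td_preset()], [read_model_spec()], [loop_energy_reduction()]
#' @export
defect_model_spec <- function(name,
                              roll_angle_deg,
                              stacking_multiplier = 1,
                              n_modified_steps = 1,
                              hbond_weakening_fraction = 0,
                              defect_index = 409L,
                              reference_bend_min_deg = NA_real_,
                              reference_bend_md_deg = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  roll_angle_deg <- as.numeric(roll_angle_deg)
  if (!is.finite(roll_angle_deg) || roll_angle_deg < 0 || roll_angle_deg > 45)
    stop("roll_angle_deg must lie in [0, 45] (validated linear regime)")
  stacking_multiplier <- as.numeric(stacking_multiplier)
  if (!is.finite(stacking_multiplier) || stacking_multiplier < 1)
    stop("stacking_multiplier must be >= 1")
  n_modified_steps <- as.integer(n_modified_steps)
  if (!n_modified_steps %in% c(1L, 2L))
    stop("n_modified_steps must be 1 or 2")
  hbond_weakening_fraction <- as.numeric(hbond_weakening_fraction)
  if (!is.finite(hbond_weakening_fraction) ||
      hbond_weakening_fraction < 0 || hbond_weakening_fraction > 1)
    stop("hbond_weakening_fraction must lie in [0, 1]")
  defect_index <- as.integer(defect_index)
  if (is.na(defect_index) || defect_index < 0)
    stop("defect_index must be a non-negative 0-based base-pair index")
  structure(
    list(
      name = name,
      roll_angle_deg = roll_angle_deg,
      stacking_multiplier = stacking_multiplier,
      n_modified_steps = n_modified_steps,
      hbond_weakening_fraction = hbond_weakening_fraction,
      defect_index = defect_index,
      reference_bend_min_deg = as.numeric(reference_bend_min_deg),
      reference_bend_md_deg = as.numeric(reference_bend_md_deg)
    ),
    class = "defect_model_spec"
  )
}

#' @export
print.defect_model_spec <- function(x, ...) {
  cat(sprintf("<defect_model_spec %s>\n", x$name))
  cat(sprintf("  roll angle phi          : %.1f deg over %d step(s)\n",
              x$roll_angle_deg, x$n_modified_steps))
  cat(sprintf("  stacking multiplier     : %g\n", x$stacking_multiplier))
  cat(sprintf("  H-bond weakening        : %.0f%%\n",
              100 * x$hbond_weakening_fraction))
  cat(sprintf("  defect index (0-based)  : %d\n", x$defect_index))
  cat(sprintf("  reference theta0        : %.1f deg (minimum), %.1f deg (thermal)\n",
              x$reference_bend_min_deg, x$reference_bend_md_deg))
  invisible(x)
}

#' Load a shipped thymine-dimer preset
#'
#' Reads one of the packaged model files `td0.model`, `td1.model`,
#' `td2.model` (flat key = value text, see [read_model_spec()]).
#'
#' @param name `"TD0"`, `"TD1"` or `"TD2"` (case-insensitive).
#' @return a [defect_model_spec()].
#' @export
#' @examples
#' td_preset("TD0")
td_preset <- function(name = c("TD0", "TD1", "TD2")) {
  name <- toupper(match.arg(toupper(name), c("TD0", "TD1", "TD2")))
  path <- system.file("extdata", paste0(tolower(name), ".model"),
                      package = "plectodimer", mustWork = TRUE)
  read_model_spec(path)
}

#' Read / write a defect model specification file
#'
#' Model files are flat `key = value` text, one preset per file, so model
#' variants are diffable. Unknown keys are an error; missing keys fall back
#' to [defect_model_spec()] defaults.
#'
#' @param path file path.
#' @return [read_model_spec()] returns a [defect_model_spec()];
#'   `write_model_spec()` returns `path` invisibly.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed model-file line: ", lines[bad][1])
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  allowed <- c("name", "roll_angle_deg", "stacking_multiplier",
               "n_modified_steps", "hbond_weakening_fraction",
               "defect_index", "reference_bend_min_deg",
               "reference_bend_md_deg")
  if (any(!keys %in% allowed))
    stop("unknown model-file key: ", keys[!keys %in% allowed][1])
  if (anyDuplicated(keys)) stop("duplicate model-file key")
  args <- as.list(vals)
  names(args) <- keys
  num <- setdiff(keys, "name")
  args[num] <- lapply(args[num], as.numeric)
  do.call(defect_model_spec, args)
}

#' @rdname read_model_spec
#' @param spec a [defect_model_spec()].
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "defect_model_spec"))
  fmt <- function(x) {
    if (is.character(x)) x else format(x, digits = 15, scientific = FALSE)
  }
  writeLines(
    vapply(names(spec), function(k) sprintf("%s = %s", k, fmt(spec[[k]])), ""),
    path
  )
  invisible(path)
}

#' Boltzmann energy scale
#'
#' `kbt_pn_nm(T)` returns the thermal energy `k_B * T` in piconewton
#' nanometres (1 pN nm = 1e-21 J), the natural unit for single-molecule
#' force spectroscopy. At 300 K this is about 4.142 pN nm.
#'
#' @param temperature_K absolute temperature in kelvin.
#' @export
kbt_pn_nm <- function(temperature_K = 300) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  1.380649e-2 * temperature_K
}

#' Rotate an orthonormal triad about an axis
#'
#' Rigid (Rodrigues) rotation of a 3x3 orthonormal frame by `phi_deg`
#' degrees about the unit vector `axis`. Used to impose the dimer roll: the
#' frame downstream of the lesion is rotated about the base vector before
#' elastic energies are evaluated.
#'
#' @param triad 3x3 matrix whose columns are the frame vectors.
#' @param phi_deg rotation angle in degrees.
#' @param axis length-3 unit vector.
#' @return the rotated 3x3 frame.
#' @export
apply_roll <- function(triad, phi_deg, axis) {
  triad <- as.matrix(triad)
  if (!all(dim(triad) == c(3L, 3L)))
    stop("triad must be a 3x3 matrix")
  if (max(abs(crossprod(triad) - diag(3))) > 1e-9)
    stop("triad is not orthonormal (tolerance 1e-9)")
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("axis must be a nonzero 3-vector")
  axis <- axis / nrm
  rotation_matrix(phi_deg * pi / 180, axis) %*% triad
}

# Rodrigues rotation matrix, angle in radians about unit axis.
rotation_matrix <- function(angle, axis) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Relaxed linking number of a duplex
#'
#' `Lk0 = n_bp / pitch`: the number of helical turns in torsionally relaxed
#' B-DNA. For the 600-bp construct at 10.55 bp/turn this is about 56.87.
#'
#' @param n_bp number of base pairs (>= 0).
#' @param pitch_bp_per_turn helical repeat in base pairs per turn.
#' @return linking number in turns.
#' @export
#' @examples
#' linking_number_relaxed(600, 10.55)
linking_number_relaxed <- function(n_bp, pitch_bp_per_turn = 10.55) {
  if (!is.numeric(n_bp) || length(n_bp) != 1L || n_bp < 0)
    stop("n_bp must be a single non-negative count")
  if (!is.numeric(pitch_bp_per_turn) || pitch_bp_per_turn <= 0)
    stop("pitch must be > 0 bp/turn")
  n_bp / pitch_bp_per_turn
}

#' Superhelical density and its inverse
#'
#' `sigma = (Lk - Lk0) / Lk0` measures over-/under-winding relative to the
#' relaxed linking number; `turns_for_sigma()` returns the excess turns
#' `Lk - Lk0 = sigma * Lk0` needed to reach a target `sigma`.
#'
#' @param Lk linking number in turns.
#' @param Lk0 relaxed linking number in turns (nonzero).
#' @export
#' @examples
#' superhelical_density(52.87, 56.87)
superhelical_density <- function(Lk, Lk0) {
  if (!is.numeric(Lk0) || any(Lk0 == 0)) stop("Lk0 must be nonzero")
  (Lk - Lk0) / Lk0
}

#' @rdname superhelical_density
#' @param sigma superhelical density (dimensionless).
#' @export
turns_for_sigma <- function(sigma, Lk0) {
  if (!is.numeric(Lk0) || any(Lk0 == 0)) stop("Lk0 must be nonzero")
  sigma * Lk0
}

#' Topology bookkeeping for a torsionally constrained duplex
#'
#' Tracks `Lk0 = n_bp / pitch`, the current linking number `Lk`, and
#' `sigma = (Lk - Lk0)/Lk0`. `add_turns()` updates `Lk` and keeps `sigma`
#' consistent.
#'
#' @param n_bp duplex length in base pairs.
#' @param pitch_bp_per_turn helical repeat (default 10.55 bp/turn).
#' @param Lk current linking number; defaults to `Lk0` (relaxed).
#' @return an object of class `topology_bookkeeping` with fields `n_bp`,
#'   `pitch_bp_per_turn`, `Lk0`, `Lk`, `sigma`.
#' @export
topology_bookkeeping <- function(n_bp, pitch_bp_per_turn = 10.55, Lk = NULL) {
  Lk0 <- linking_number_relaxed(n_bp, pitch_bp_per_turn)
  if (is.null(Lk)) Lk <- Lk0
  structure(
    list(n_bp = as.integer(n_bp), pitch_bp_per_turn = pitch_bp_per_turn,
         Lk0 = Lk0, Lk = Lk, sigma = superhelical_density(Lk, Lk0)),
    class = "topology_bookkeeping"
  )
}

#' @rdname topology_bookkeeping
#' @param book a `topology_bookkeeping` object.
#' @param turns turns to add to `Lk` (negative = underwinding).
#' @export
add_turns <- function(book, turns) {
  stopifnot(inherits(book, "topology_bookkeeping"))
  book$Lk <- book$Lk + turns
  book$sigma <- superhelical_density(book$Lk, book$Lk0)
  book
}

#' @export
print.topology_bookkeeping <- function(x, ...) {
  cat(sprintf("<topology_bookkeeping> %d bp, pitch %.2f bp/turn\n",
              x$n_bp, x$pitch_bp_per_turn))
  cat(sprintf("  Lk0 = %.4f, Lk = %.4f, sigma = %.5f\n", x$Lk0, x$Lk, x$sigma))
  invisible(x)
}

#' Parameters of the plectoneme loop-formation energy estimate
#'
#' The free-energy reduction for nucleating a plectonemic end loop at a
#' bent defect, relative to undamaged DNA, is estimated as
#' `theta0 * sqrt(2 kBT p F zbar)` where `theta0` is the defect bend angle,
#' `p` the bending persistence length, `F` the applied force and `zbar` a
#' dimensionless correction for writhe fluctuations in B-DNA.
#'
#' @param theta0_deg defect bend angle in degrees (>= 0).
#' @param persistence_length_nm bending persistence length `p` in nm.
#' @param force_pN applied force `F` in pN.
#' @param zbar writhe-fluctuation correction in (0, 1].
#' @param temperature_K temperature in kelvin (sets `kBT`).
#' @return an object of class `loop_energy_params`.
#' @export
loop_energy_params <- function(theta0_deg,
                               persistence_length_nm = 45,
                               force_pN = 1.5,
                               zbar = 0.88,
                               temperature_K = 300) {
  stopifnot(is.numeric(theta0_deg), theta0_deg >= 0,
            persistence_length_nm > 0, force_pN > 0,
            zbar > 0, zbar <= 1, temperature_K > 0)
  structure(
    list(theta0_deg = theta0_deg,
         persistence_length_nm = persistence_length_nm,
         force_pN = force_pN, zbar = zbar, temperature_K = temperature_K),
    class = "loop_energy_params"
  )
}

#' Loop-formation free-energy reduction at a bent defect
#'
#' Evaluates `theta0 * sqrt(2 kBT p F zbar) / kBT` (units of `kBT`), the
#' estimated reduction in the plectoneme end-loop formation free energy
#' attributable to the intrinsic bend `theta0` of the defect.
#'
#' @param params a [loop_energy_params()], or a [defect_model_spec()] (in
#'   which case the thermal ("MD") reference bend angle of the preset is
#'   used together with the `...` defaults of [loop_energy_params()]).
#' @param ... passed to [loop_energy_params()] when `params` is a
#'   [defect_model_spec()].
#' @param angle which reference angle of a preset to use: the thermal
#'   (`"md"`, default) or energy-minimum (`"min"`) bend angle.
#' @return energy reduction in units of `kBT` at the given temperature.
#' @export
#' @examples
#' loop_energy_reduction(loop_energy_params(theta0_deg = 11.3))
loop_energy_reduction <- function(params, ..., angle = c("md", "min")) {
  if (inherits(params, "defect_model_spec")) {
    angle <- match.arg(angle)
    theta0 <- switch(angle,
                     md = params$reference_bend_md_deg,
                     min = params$reference_bend_min_deg)
    if (!is.finite(theta0))
      stop("preset carries no reference bend angle '", angle, "'")
    params <- loop_energy_params(theta0_deg = theta0, ...)
  }
  stopifnot(inherits(params, "loop_energy_params"))
  kbt <- kbt_pn_nm(params$temperature_K)
  theta0 <- params$theta0_deg * pi / 180
  theta0 * sqrt(2 * kbt * params$persistence_length_nm *
                  params$force_pN * params$zbar) / kbt
}

#' Predicted duplex bend angle for a defect parametrization
#'
#' Builds a short duplex carrying the defect, relaxes it by potential-energy
#' minimization ([minimize_conformation()]) with traps and force disabled,
#' and measures the bend angle by two-group line fitting ([bend_angle()]).
#' The resulting `theta0` is linear in the roll angle `phi` over the
#' validated regime (`phi` up to 45 degrees).
#'
#' @param spec a [defect_model_spec()]; its `defect_index` is ignored and
#'   the defect is centred on the test duplex.
#' @param chain_length duplex length in bp (>= 20).
#' @param seed integer seed for the (deterministic, zero-temperature)
#'   minimizer.
#' @return bend angle in degrees.
#' @export
predict_bend_angle <- function(spec, chain_length = 40L, seed = 1L) {
  stopifnot(inherits(spec, "defect_model_spec"))
  chain_length <- as.integer(chain_length)
  if (chain_length < 20L) stop("chain_length must be >= 20 bp")
  centre <- chain_length %/% 2L - 1L
  if (centre < 5L || centre > chain_length - 6L)
    stop("defect too close to a chain end (need >= 5 bp margin)")
  spec$defect_index <- centre
  seq <- rep(c("A", "T"), length.out = chain_length)
  params <- energy_params(defect = spec)
  conf <- build_initial_conformation(seq, params, handle_bp = 1L)
  mini <- minimize_conformation(conf, params, protocol_off = TRUE, seed = seed)
  # boundary between the two fitted groups: after the modified step(s)
  boundary <- centre + (spec$n_modified_steps + 1L) %/% 2L
  bend_angle(mini, boundary_bp = boundary)$theta_deg
}
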