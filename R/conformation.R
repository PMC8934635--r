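#' Chain conformations
#'
#' A `chain_conformation` is the common currency of the simulator and the
#' analysis layer: one site per base pair, carrying the base-pair midpoint
#' position (nm), a material frame per base-pair step, and a binary pairing
#' state (intact or denatured).
#'
#' Each end carries `handle_bp >= 1` handle/cap sites. Handle sites are
#' excluded from all per-base-pair statistics; "core" base-pair indices are
#' 0-based and run from 0 to `n_core - 1`. Embedding the core between
#' handles means an n-bp core spans exactly n twist steps, so the twist of
#' an ideal relaxed helix equals its relaxed linking number `n/pitch`.
#'
#' Internally the frame of step i is stored as its material normal
#' (`normals[i, ]`), the tangent being the normalized bond vector; the full
#' per-site triad array (tangent, major-groove normal, binormal) is exposed
#' by [triads()].
#'
#' @param sequence character vector of bases (A/C/G/T), one per site
#'   (handles included).
#' @param positions numeric n x 3 matrix of midpoints in nm.
#' @param normals numeric (n-1) x 3 matrix of per-step material normals
#'   (each orthogonal to its bond vector).
#' @param intact logical vector, `TRUE` = base pair intact.
#' @param handle_bp handle sites per end.
#' @param rise_nm nominal rise (nm), used by validity checks.
#' @param bookkeeping optional list with `Lk0`, `applied_turns`, `lk_book0`.
#' @return an object of class `chain_conformation`.
#' @export
chain_conformation <- function(sequence, positions, normals, intact,
                               handle_bp = 1L, rise_nm = 0.34,
                               bookkeeping = NULL) {
  n <- length(sequence)
  positions <- as.matrix(positions)
  normals <- as.matrix(normals)
  stopifnot(nrow(positions) == n, ncol(positions) == 3,
            nrow(normals) == n - 1, ncol(normals) == 3,
            length(intact) == n)
  if (!all(sequence %in% c("A", "C", "G", "T")))
    stop("sequence letters must be A/C/G/T")
  handle_bp <- as.integer(handle_bp)
  if (handle_bp < 1L) stop("handle_bp must be >= 1")
  if (n < 2L * handle_bp + 1L) stop("chain too short for its handles")
  structure(
    list(sequence = sequence, positions = unname(positions),
         normals = unname(normals), intact = as.logical(intact),
         handle_bp = handle_bp, rise_nm = rise_nm,
         bookkeeping = bookkeeping),
    class = "chain_conformation"
  )
}

#' @export
print.chain_conformation <- function(x, ...) {
  n <- length(x$sequence)
  cat(sprintf("<chain_conformation> %d sites (%d core bp + 2 x %d handle)\n",
              n, n - 2L * x$handle_bp, x$handle_bp))
  cat(sprintf("  denatured sites: %d\n", sum(!x$intact)))
  if (!is.null(x$bookkeeping))
    cat(sprintf("  Lk0 = %.3f, applied turns = %.3f\n",
                x$bookkeeping$Lk0, x$bookkeeping$applied_turns))
  invisible(x)
}

#' Number of core base pairs
#' @param conf a [chain_conformation()].
#' @export
n_core_bp <- function(conf) length(conf$sequence) - 2L * conf$handle_bp

# absolute (1-based R) row index of 0-based core bp index k
core_row <- function(conf, k) conf$handle_bp + k + 1L

#' Per-site triads of a conformation
#'
#' Returns a 3 x 3 x n array; columns of `triads(conf)[, , i]` are the
#' tangent, the material (major-groove) normal and the binormal of step i.
#' The last site repeats the frame of the final step.
#'
#' @param conf a [chain_conformation()].
#' @export
triads <- function(conf) {
  n <- nrow(conf$positions)
  d <- diff(conf$positions)
  t <- d / sqrt(rowSums(d^2))
  u <- conf$normals
  # re-orthogonalize u against t
  u <- u - t * rowSums(u * t)
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(t[, 2] * u[, 3] - t[, 3] * u[, 2],
             t[, 3] * u[, 1] - t[, 1] * u[, 3],
             t[, 1] * u[, 2] - t[, 2] * u[, 1])
  out <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n - 1)) out[, , i] <- cbind(t[i, ], u[i, ], v[i, ])
  out[, , n] <- out[, , n - 1]
  out
}

#' Validate conformation invariants
#'
#' Checks frame orthonormality, bond-length sanity (each bond within
#' `[0.5, 2]` times the rise) and, when `params` is given, the hard-core
#' excluded-volume condition.
#'
#' @param conf a [chain_conformation()].
#' @param params optional [energy_params()] for the excluded-volume check.
#' @param tol orthonormality tolerance.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_conformation <- function(conf, params = NULL, tol = 1e-8) {
  stopifnot(inherits(conf, "chain_conformation"))
  d <- diff(conf$positions)
  len <- sqrt(rowSums(d^2))
  if (any(len < 0.5 * conf$rise_nm) || any(len > 2 * conf$rise_nm))
    stop("bond length outside [0.5, 2] x rise")
  t <- d / len
  u <- conf$normals
  if (any(abs(rowSums(u^2) - 1) > 1e-6))
    stop("material normals are not unit vectors")
  if (any(abs(rowSums(u * t)) > 1e-4))
    stop("material normals are not orthogonal to the tangents")
  tri <- triads(conf)
  for (i in seq_len(dim(tri)[3])) {
    g <- crossprod(tri[, , i])
    if (max(abs(g - diag(3))) > tol)
      stop("triad ", i, " not orthonormal within ", tol)
  }
  if (!is.null(params)) {
    cp <- cpp_contact_pairs(conf$positions, params$ev_min_separation,
                            params$excluded_diameter_nm)
    if (nrow(cp) > 0) {
      open <- !conf$intact
      bad <- vapply(seq_len(nrow(cp)), function(k) {
        i <- cp[k, 1]; j <- cp[k, 2]
        dia <- if (open[i] || open[j]) params$excluded_diameter_ss_nm
               else params$excluded_diameter_nm
        cp[k, 3] < dia
      }, TRUE)
      if (any(bad)) stop("excluded-volume violation between sites ",
                         cp[which(bad)[1], 1], " and ", cp[which(bad)[1], 2])
    }
  }
  invisible(TRUE)
}

#' Build an ideal B-form starting conformation
#'
#' A straight helix along +z with uniform rise and intrinsic twist, all base
#' pairs intact. Handle sites (sequence `G`/`C` alternating) are added at
#' both ends; the core sequence is the input.
#'
#' @param sequence core sequence: character vector of bases or a single
#'   string.
#' @param params an [energy_params()].
#' @param handle_bp handle sites per end (default 12, the tweezer handle).
#' @return a [chain_conformation()] with topology bookkeeping attached:
#'   `Lk0 = n/pitch` for the core, zero applied turns, and the build-time
#'   invariant `lk_book0 = Tw + Wr` used by conservation checks.
#' @export
build_initial_conformation <- function(sequence, params = energy_params(),
                                       handle_bp = 12L) {
  if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  if (!all(sequence %in% c("A", "C", "G", "T")))
    stop("sequence letters must be A/C/G/T")
  n_core <- length(sequence)
  if (n_core < 30L) stop("core sequence must be >= 30 bp")
  handle_bp <- as.integer(handle_bp)
  hseq <- rep(c("G", "C"), length.out = handle_bp)
  full <- c(hseq, sequence, rev(hseq))
  n <- length(full)
  h <- params$rise_nm
  tw <- params$intrinsic_twist_deg * pi / 180
  positions <- cbind(0, 0, h * (seq_len(n) - 1L))
  ang <- tw * (seq_len(n - 1L) - 1L)
  normals <- cbind(cos(ang), sin(ang), 0)
  pitch <- 360 / params$intrinsic_twist_deg
  conf <- chain_conformation(full, positions, normals,
                             intact = rep(TRUE, n), handle_bp = handle_bp,
                             rise_nm = h)
  lk0 <- linking_number_relaxed(n_core, pitch)
  tw_all <- sum(cpp_joint_twists(conf$positions, conf$normals)) / (2 * pi)
  conf$bookkeeping <- list(Lk0 = lk0, pitch_bp_per_turn = pitch,
                           applied_turns = 0,
                           lk_book0 = tw_all + writhe(axis_points_full(conf)))
  conf
}

# all vertex midpoints (handles included), used for conservation writhe
axis_points_full <- function(conf) conf$positions

# Bare per-site opening energies (kBT) handed to the engine. The
# user-facing dG_open_* are effective opening free energies; opening a site
# also softens its joint (duplex -> single-stranded stiffness), which
# releases entropy ln(kb_ds/kb_open) + ln(kt_ds/kt_open)/2 per joint, so
# the bare flip energy is the effective cost plus that softening term. At
# the dimer the stacking restraint keeps part of the stiffness when open,
# which reduces the released entropy accordingly.
site_opening_costs <- function(conf, params) {
  h <- params$rise_nm
  kb_ds <- params$p_ds_nm / h
  kb_ss <- params$p_ss_nm / h
  kt_ds <- params$C_ds_nm / h
  kt_ss <- params$C_ss_nm / h
  soften <- log(kb_ds / kb_ss) + 0.5 * log(kt_ds / kt_ss)
  dG <- ifelse(conf$sequence %in% c("A", "T"), params$dG_open_AT,
               params$dG_open_GC) + soften
  def <- params$defect
  if (!is.null(def)) {
    a <- core_row(conf, def$defect_index) # 5'-most dimer site, 1-based
    if (a + 1L > length(dG) - conf$handle_bp)
      stop("defect_index outside the core region")
    eff <- ifelse(conf$sequence[c(a, a + 1L)] %in% c("A", "T"),
                  params$dG_open_AT, params$dG_open_GC) *
      (1 - def$hbond_weakening_fraction)
    align <- max(0, def$stacking_multiplier - 1)
    # which of the two dimer sites sit on stacking-modified joints
    jmod <- def$defect_index + seq_len(def$n_modified_steps) # 0-based joints
    sites <- c(a, a + 1L) # 1-based rows = 0-based site index + 1
    soft_d <- vapply(sites, function(row) {
      modified <- (row - 1L - conf$handle_bp) %in% jmod
      if (modified && align > 0) {
        log(kb_ds / (kb_ss + align)) + 0.5 * log(kt_ds / (kt_ss + align))
      } else soften
    }, 0)
    dG[sites] <- eff + soft_d
  }
  dG
}

# C++ defect descriptor: 0-based indices
defect_cpp <- function(conf, params) {
  def <- params$defect
  if (is.null(def)) return(list(n_mod = 0L))
  a <- conf$handle_bp + def$defect_index # absolute 0-based site
  list(mod_j0 = a + 1L, n_mod = def$n_modified_steps,
       phi_deg = def$roll_angle_deg,
       align_k = max(0, def$stacking_multiplier - 1),
       def_site = a)
}

# C++ protocol descriptor
protocol_cpp <- function(conf, protocol, temperature_K) {
  kbt <- kbt_pn_nm(temperature_K)
  list(handle_bp = conf$handle_bp,
       tweezer = protocol$constrain_turns,
       force_red = protocol$force_pN / kbt,
       kplane = if (protocol$plane_repulsion) protocol$plane_stiffness_kbt_nm2 else 0,
       ktrap = protocol$trap_stiffness_kbt_nm2,
       applied_turns = if (is.null(conf$bookkeeping)) 0 else conf$bookkeeping$applied_turns)
}

params_cpp <- function(params) {
  list(rise_nm = params$rise_nm, p_ds_nm = params$p_ds_nm,
       p_ss_nm = params$p_ss_nm, C_ds_nm = params$C_ds_nm,
       C_ss_nm = params$C_ss_nm,
       intrinsic_twist_deg = params$intrinsic_twist_deg,
       stretch_stiffness_kbt_nm2 = params$stretch_stiffness_kbt_nm2,
       boundary_cost = params$boundary_cost,
       excluded_diameter_nm = params$excluded_diameter_nm,
       excluded_diameter_ss_nm = params$excluded_diameter_ss_nm,
       ev_min_separation = params$ev_min_separation)
}

# rebuild a conformation from an engine state
conf_from_state <- function(state, template) {
  out <- template
  out$positions <- state$positions
  out$normals <- state$normals
  out$intact <- state$open == 0L
  if (!is.null(out$bookkeeping))
    out$bookkeeping$applied_turns <- state$applied_turns
  out
}
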