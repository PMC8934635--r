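STATE_LABELS <- c("B-DNA", "plectoneme", "tip-bubble plectoneme", "bubble")

#' Denaturation mask of a frame
#'
#' Either copies the binary pairing state of a conformation's core region,
#' or applies the binding-energy criterion: a base pair is denatured iff its
#' hydrogen-bond binding energy is (strictly) less than `threshold` times
#' its maximum possible value.
#'
#' @param conf a [chain_conformation()] (state route), or `NULL`.
#' @param energies numeric vector of per-base-pair hydrogen-bond energies
#'   (<= 0; 0 or `NA` = unbound) for the energy route.
#' @param reference per-base-pair maximum possible binding-energy magnitude
#'   (> 0); required on the energy route.
#' @param threshold binding-energy fraction below which a pair counts as
#'   denatured (strict inequality).
#' @return logical vector (`TRUE` = denatured), one element per core bp.
#' @export
denatured_mask <- function(conf = NULL, energies = NULL, reference = NULL,
                           threshold = 0.10) {
  if (!is.null(conf)) {
    stopifnot(inherits(conf, "chain_conformation"))
    n <- length(conf$intact)
    h <- conf$handle_bp
    return(!conf$intact[(h + 1L):(n - h)])
  }
  if (is.null(energies)) stop("provide a conformation or an energy vector")
  if (is.null(reference))
    stop("the energy route requires per-pair reference maxima")
  if (length(reference) == 1L) reference <- rep(reference, length(energies))
  stopifnot(length(reference) == length(energies), all(reference > 0))
  e <- abs(energies)
  e[is.na(e)] <- 0
  e < threshold * reference
}

#' Detect denaturation bubbles
#'
#' Maximal runs of denatured base pairs of length at least `min_len`
#' (default 2: a single broken base pair is not a bubble).
#'
#' @param mask logical denaturation mask (element 1 = core bp 0).
#' @param min_len minimum run length.
#' @return data.frame with 0-based `start_bp`, `end_bp`, `centre_bp`,
#'   `length_bp` (possibly empty).
#' @export
detect_bubbles <- function(mask, min_len = 2L) {
  stopifnot(is.logical(mask))
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start_bp = starts[keep] - 1L, end_bp = ends[keep] - 1L)
  out$centre_bp <- (out$start_bp + out$end_bp) / 2
  out$length_bp <- out$end_bp - out$start_bp + 1L
  out
}

#' Classify a frame into one of the four structural states
#'
#' A frame is a tip-bubble plectoneme iff some plectoneme and some bubble
#' co-localize (distance between the bubble centre and the plectoneme tip
#' strictly less than `tip_dist_bp`); otherwise a plectoneme if any
#' plectoneme call exists (writhe being the dominant structural response
#' when a far bubble coexists); otherwise a bubble if any bubble exists;
#' otherwise B-DNA.
#'
#' @param bubbles data.frame from [detect_bubbles()].
#' @param plectonemes data.frame from [detect_plectonemes()].
#' @param tip_dist_bp co-localization distance (bp, strict `<`).
#' @return one of `"B-DNA"`, `"plectoneme"`, `"tip-bubble plectoneme"`,
#'   `"bubble"`.
#' @export
classify_frame <- function(bubbles, plectonemes, tip_dist_bp = 20) {
  has_p <- !is.null(plectonemes) && nrow(plectonemes) > 0L
  has_b <- !is.null(bubbles) && nrow(bubbles) > 0L
  if (has_p && has_b) {
    d <- outer(bubbles$centre_bp, plectonemes$tip_bp,
               function(a, b) abs(a - b))
    if (any(d < tip_dist_bp)) return("tip-bubble plectoneme")
  }
  if (has_p) return("plectoneme")
  if (has_b) return("bubble")
  "B-DNA"
}

# classify all retained frames of a trajectory
classify_frames <- function(frames, plec_params = plectoneme_params(),
                            min_bubble_len = 2L, tip_dist_bp = 20) {
  vapply(frames, function(f) {
    classify_frame(detect_bubbles(denatured_mask(f), min_bubble_len),
                   detect_plectonemes(f, plec_params), tip_dist_bp)
  }, "")
}

# indices of retained (equilibrated production) frames
retained_indices <- function(traj, equilibrated = TRUE, override = FALSE) {
  n <- length(traj$frames)
  if (n == 0L) stop("trajectory has no stored frames")
  from <- traj$meta$production_from
  if (is.null(from) || is.na(from)) from <- 1L
  idx <- seq.int(from, n)
  if (!equilibrated) return(idx)
  eq <- traj$meta$equilibration
  if (is.null(eq)) {
    if (!override)
      stop("trajectory has no equilibration report; pass override = TRUE to use all production frames")
    return(idx)
  }
  if (!isTRUE(eq$converged) && !override)
    stop("trajectory is not equilibrated (tau_eq = ", round(eq$tau_eq, 1),
         " samples); pass override = TRUE to proceed")
  idx[idx > (from - 1L) + eq$n_discarded]
}

#' State occupancy of a trajectory (or replicas)
#'
#' Fraction of retained frames in each of the four structural states,
#' pooled over replicas, with per-replica fractions retained for error
#' estimates. The dominant state requires occupancy >= 0.5; a maximum in
#' [0.4, 0.5) is labelled `"mixed"`, below 0.4 `"none"`.
#'
#' @param traj a `td_trajectory` or a list of replica trajectories.
#' @param plec_params a [plectoneme_params()].
#' @param min_bubble_len bubble criterion (>= 2 consecutive denatured bp).
#' @param tip_dist_bp tip-bubble co-localization distance.
#' @param override use unequilibrated trajectories anyway.
#' @return object of class `state_occupancy`: `occupancy` (named fractions
#'   summing to 1), `dominant`, `per_replica`, `n_frames`, `sigma`,
#'   `force_pN`.
#' @export
state_occupancy <- function(traj, plec_params = plectoneme_params(),
                            min_bubble_len = 2L, tip_dist_bp = 20,
                            override = FALSE) {
  trajs <- if (inherits(traj, "td_trajectory")) list(traj) else traj
  per <- lapply(seq_along(trajs), function(k) {
    tr <- trajs[[k]]
    idx <- retained_indices(tr, override = override)
    lab <- classify_frames(tr$frames[idx], plec_params, min_bubble_len,
                           tip_dist_bp)
    tab <- table(factor(lab, levels = STATE_LABELS))
    data.frame(replica = k, n_frames = length(lab),
               t(as.numeric(tab) / length(lab)))
  })
  per <- do.call(rbind, per)
  names(per)[3:6] <- STATE_LABELS
  counts <- colSums(as.matrix(per[, 3:6, drop = FALSE]) * per$n_frames)
  occ <- counts / sum(per$n_frames)
  dominant <- occupancy_label(occ)
  structure(list(occupancy = occ, dominant = dominant, per_replica = per,
                 n_frames = sum(per$n_frames),
                 sigma = trajs[[1]]$meta$sigma,
                 force_pN = trajs[[1]]$meta$force_pN),
            class = "state_occupancy")
}

occupancy_label <- function(occ) {
  m <- max(occ)
  if (m >= 0.5) names(occ)[which.max(occ)]
  else if (m >= 0.4) "mixed"
  else "none"
}

#' @export
print.state_occupancy <- function(x, ...) {
  cat(sprintf("<state_occupancy> sigma %.4f, F %.2f pN, %d frames\n",
              x$sigma, x$force_pN, x$n_frames))
  for (k in names(x$occupancy))
    cat(sprintf("  %-22s %.3f\n", k, x$occupancy[k]))
  cat("  dominant:", x$dominant, "\n")
  invisible(x)
}

#' Assemble a force-torsion state diagram
#'
#' @param cells list of [state_occupancy()] results (one per (sigma, force)
#'   grid point), or a data.frame with columns `sigma`, `force_pN` and one
#'   occupancy column per state label.
#' @return data.frame sorted by (`force_pN`, `sigma`) with occupancy columns
#'   and the `dominant` label (`"mixed"` / `"none"` per the occupancy
#'   rules).
#' @export
state_diagram <- function(cells) {
  if (is.data.frame(cells)) {
    df <- cells
    stopifnot(all(c("sigma", "force_pN") %in% names(df)),
              all(STATE_LABELS %in% names(df)))
    occm <- as.matrix(df[, STATE_LABELS, drop = FALSE])
    df$dominant <- apply(occm, 1L, function(r) {
      names(r) <- STATE_LABELS
      occupancy_label(r)
    })
  } else {
    df <- do.call(rbind, lapply(cells, function(cell) {
      stopifnot(inherits(cell, "state_occupancy"))
      out <- data.frame(sigma = cell$sigma, force_pN = cell$force_pN)
      out[STATE_LABELS] <- as.list(cell$occupancy)
      out$dominant <- cell$dominant
      out
    }))
  }
  if (anyDuplicated(df[, c("sigma", "force_pN")]))
    stop("duplicate (sigma, force) grid points")
  df <- df[order(df$force_pN, df$sigma), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Plot a state diagram
#'
#' Tile plot of dominant states over the (sigma, force) grid. Requires
#' ggplot2.
#'
#' @param diagram output of [state_diagram()].
#' @export
plot_state_diagram <- function(diagram) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_state_diagram requires ggplot2")
  ggplot2::ggplot(diagram,
                  ggplot2::aes(x = sigma, y = factor(force_pN),
                               fill = dominant)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::labs(x = expression(sigma), y = "force (pN)", fill = "dominant state")
}

#' Duplex bend angle by two-group line fitting
#'
#' Splits the core midpoints at `boundary_bp` (excluding
#' `exclusion_halfwidth` bp on each side of it), fits a total-least-squares
#' line (principal direction) through each group, and reports the angle
#' between the two directions, oriented into [0, 180] degrees.
#'
#' @param conf a [chain_conformation()].
#' @param boundary_bp 0-based core bp index of the split.
#' @param exclusion_halfwidth bp excluded around the boundary so the kink
#'   itself does not contaminate either line.
#' @return object of class `bend_angle_measurement`: `theta_deg`,
#'   `boundary_bp`, `rms_residuals_nm` (per group).
#' @export
bend_angle <- function(conf, boundary_bp, exclusion_halfwidth = 2L) {
  ax <- axis(conf)
  g1 <- ax$bp < boundary_bp - exclusion_halfwidth
  g2 <- ax$bp > boundary_bp + exclusion_halfwidth
  if (sum(g1) < 10L || sum(g2) < 10L)
    stop("need at least 10 bp on each side of the boundary")
  fit <- function(pts) {
    ctr <- colMeans(pts)
    x <- sweep(pts, 2L, ctr)
    s <- svd(x, nu = 0L, nv = 3L)
    if (s$d[1] < 1e-9) stop("degenerate group: points coincide")
    dirv <- s$v[, 1]
    # orient along increasing bp
    if (sum((pts[nrow(pts), ] - pts[1, ]) * dirv) < 0) dirv <- -dirv
    resid <- sqrt(mean(rowSums((x - (x %*% dirv) %*% t(dirv))^2)))
    list(dir = dirv, rms = resid)
  }
  f1 <- fit(ax$points[g1, , drop = FALSE])
  f2 <- fit(ax$points[g2, , drop = FALSE])
  cosang <- max(-1, min(1, sum(f1$dir * f2$dir)))
  structure(list(theta_deg = acos(cosang) * 180 / pi,
                 boundary_bp = boundary_bp,
                 rms_residuals_nm = c(group1 = f1$rms, group2 = f2$rms)),
            class = "bend_angle_measurement")
}

#' @export
print.bend_angle_measurement <- function(x, ...) {
  cat(sprintf("bend angle %.2f deg at boundary bp %d (rms residuals %.3g / %.3g nm)\n",
              x$theta_deg, x$boundary_bp,
              x$rms_residuals_nm[1], x$rms_residuals_nm[2]))
  invisible(x)
}

#' Equilibration policy from the end-to-end distance autocorrelation
#'
#' The equilibration time `tau_eq` is estimated as twice the integrated
#' autocorrelation time of the end-to-end distance, using an automatic
#' (Sokal-style) window: the smallest W with `W >= c * tau_int(W)`. The
#' first `2 tau_eq` samples are discarded and the trajectory counts as
#' converged iff at least `6 tau_eq` samples remain.
#'
#' @param traj a `td_trajectory`, or a numeric series of samples.
#' @param c_sokal window constant.
#' @return object of class `equilibration_report`: `tau_eq` (in sample
#'   intervals), `n_discarded`, `n_retained`, `converged`, `n_samples`.
#'   A constant series gives `tau_eq = NA` and `converged = FALSE`.
#' @export
equilibration_policy <- function(traj, c_sokal = 5) {
  if (inherits(traj, "td_trajectory")) {
    from <- traj$meta$production_from
    if (is.null(from) || is.na(from)) from <- 1L
    x <- traj$channels$extension_nm[seq.int(from, nrow(traj$channels))]
  } else {
    x <- as.numeric(traj)
  }
  n <- length(x)
  if (n < 50L) stop("need at least 50 samples")
  if (stats::sd(x) < 1e-12)
    return(structure(list(tau_eq = NA_real_, n_discarded = n, n_retained = 0L,
                          converged = FALSE, n_samples = n),
                     class = "equilibration_report"))
  rho <- stats::acf(x, lag.max = min(n - 1L, max(100L, n %/% 4L)),
                    plot = FALSE)$acf[-1]
  tau_int <- 0.5
  W <- 0L
  for (k in seq_along(rho)) {
    tau_int <- tau_int + rho[k]
    W <- k
    if (W >= c_sokal * tau_int) break
  }
  tau_eq <- max(2 * tau_int, 1e-8)
  n_disc <- ceiling(2 * tau_eq)
  n_ret <- max(0L, n - n_disc)
  structure(list(tau_eq = tau_eq, n_discarded = as.integer(n_disc),
                 n_retained = as.integer(n_ret),
                 converged = n_ret >= 6 * tau_eq, n_samples = n),
            class = "equilibration_report")
}

#' @export
print.equilibration_report <- function(x, ...) {
  cat(sprintf("tau_eq = %.2f samples; discard %d, retain %d of %d; converged = %s\n",
              x$tau_eq, x$n_discarded, x$n_retained, x$n_samples, x$converged))
  invisible(x)
}

wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Denaturation probability of target base pairs
#'
#' Three routes over the retained frames of one or more replica
#' trajectories:
#' * `"site_pair"`: fraction of frames in which both base pairs of the
#'   given (or the defect's) site pair are denatured;
#' * `"at_any"`: fraction of frames in which at least one pair of adjacent
#'   A/T base pairs is fully open;
#' * `"at_mean"`: the per-pair open fraction averaged over all adjacent A/T
#'   pairs (the average probability that a single given AT pair is open).
#'
#' Confidence intervals are 95% Wilson intervals on the pooled counts;
#' replicas are pooled by concatenation with per-replica fractions reported.
#'
#' @param traj a `td_trajectory` or list of replicas.
#' @param target `"site_pair"`, `"at_any"` or `"at_mean"`.
#' @param bp 0-based core index of the 5'-most base pair of the target
#'   site pair; defaults to the trajectory's defect site when present.
#' @param override use unequilibrated trajectories anyway.
#' @return object of class `denaturation_probability`: `probability`,
#'   `ci95`, `n`, `per_replica`; or `insufficient_data` when no eligible
#'   pair exists.
#' @export
denaturation_probability <- function(traj,
                                     target = c("site_pair", "at_any", "at_mean"),
                                     bp = NULL, override = FALSE) {
  target <- match.arg(target)
  trajs <- if (inherits(traj, "td_trajectory")) list(traj) else traj
  conf1 <- trajs[[1]]$frames[[1]]
  h <- conf1$handle_bp
  n <- length(conf1$sequence)
  core_seq <- conf1$sequence[(h + 1L):(n - h)]
  n_core <- length(core_seq)

  if (target == "site_pair" && is.null(bp)) {
    stop("site_pair route requires `bp` (0-based index of the 5'-most target base pair)")
  }
  if (target %in% c("at_any", "at_mean")) {
    at <- core_seq %in% c("A", "T")
    elig <- which(at[-n_core] & at[-1]) # 1-based start of eligible pairs
    if (length(elig) == 0L)
      return(structure(list(reason = "no adjacent A/T base pairs in sequence"),
                       class = "insufficient_data"))
  }

  per <- lapply(seq_along(trajs), function(r) {
    tr <- trajs[[r]]
    idx <- retained_indices(tr, override = override)
    masks <- vapply(tr$frames[idx], denatured_mask, logical(n_core))
    # masks: n_core x n_frames
    if (target == "site_pair") {
      i <- bp + 1L
      stopifnot(i >= 1L, i + 1L <= n_core)
      succ <- sum(masks[i, ] & masks[i + 1L, ])
      tot <- ncol(masks)
    } else if (target == "at_any") {
      both <- masks[elig, , drop = FALSE] & masks[elig + 1L, , drop = FALSE]
      succ <- sum(apply(both, 2L, any))
      tot <- ncol(masks)
    } else {
      both <- masks[elig, , drop = FALSE] & masks[elig + 1L, , drop = FALSE]
      succ <- sum(both)
      tot <- length(both)
    }
    c(succ = succ, tot = tot)
  })
  succ <- sum(vapply(per, `[[`, 0, "succ"))
  tot <- sum(vapply(per, `[[`, 0, "tot"))
  per_rep <- data.frame(
    replica = seq_along(per),
    fraction = vapply(per, function(p) p[["succ"]] / max(1, p[["tot"]]), 0))
  structure(list(probability = succ / tot, ci95 = wilson_ci(succ, tot),
                 n = tot, target = target, per_replica = per_rep),
            class = "denaturation_probability")
}

#' @export
print.denaturation_probability <- function(x, ...) {
  cat(sprintf("denaturation probability (%s): %.4f [%.4f, %.4f], n = %d\n",
              x$target, x$probability, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Mean local twist profile along the duplex
#'
#' Per-step mean twist angle (degrees) over the retained frames, with a 95%
#' normal-approximation confidence band. When `reference` (a profile from
#' an undamaged run) is supplied, the difference profile is added, which
#' quantifies twist absorption at a defect.
#'
#' @param traj a `td_trajectory` or list of replicas.
#' @param reference optional data.frame from a previous `twist_profile()`
#'   call.
#' @param override use unequilibrated trajectories anyway.
#' @return data.frame `bp` (0-based core step index), `mean_twist_deg`,
#'   `sd_deg`, `ci95_deg`, `n`, and `delta_deg` when a reference is given.
#' @export
twist_profile <- function(traj, reference = NULL, override = FALSE) {
  trajs <- if (inherits(traj, "td_trajectory")) list(traj) else traj
  conf1 <- trajs[[1]]$frames[[1]]
  h <- conf1$handle_bp
  n <- nrow(conf1$positions)
  core_k <- h:(n - h - 1L) # indices into the joint-twist vector
  acc <- NULL
  for (tr in trajs) {
    idx <- retained_indices(tr, override = override)
    tw <- vapply(tr$frames[idx], function(f)
      cpp_joint_twists(f$positions, f$normals)[core_k] * 180 / pi,
      numeric(length(core_k)))
    acc <- if (is.null(acc)) tw else cbind(acc, tw)
  }
  m <- rowMeans(acc)
  s <- apply(acc, 1L, stats::sd)
  out <- data.frame(bp = seq_along(core_k) - 1L, mean_twist_deg = m,
                    sd_deg = s, ci95_deg = 1.96 * s / sqrt(ncol(acc)),
                    n = ncol(acc))
  if (!is.null(reference)) {
    stopifnot(nrow(reference) == nrow(out))
    out$delta_deg <- out$mean_twist_deg - reference$mean_twist_deg
  }
  out
}
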