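#' Duplex axis of a conformation
#'
#' The ordered base-pair midpoints of the core region (handles excluded),
#' with their 0-based core base-pair indices.
#'
#' @param conf a [chain_conformation()].
#' @return an object of class `axis_curve`: list with `points` (m x 3 nm)
#'   and `bp` (0-based indices).
#' @export
axis <- function(conf) {
  stopifnot(inherits(conf, "chain_conformation"))
  n <- nrow(conf$positions)
  h <- conf$handle_bp
  idx <- (h + 1L):(n - h)
  structure(list(points = conf$positions[idx, , drop = FALSE],
                 bp = idx - h - 1L),
            class = "axis_curve")
}

#' @export
print.axis_curve <- function(x, ...) {
  cat(sprintf("<axis_curve> %d points, bp %d..%d\n",
              nrow(x$points), min(x$bp), max(x$bp)))
  invisible(x)
}

#' Twist of a conformation
#'
#' Sum over base-pair steps of the local twist angle between successive
#' material frames about the local tangent, after parallel-transport removal
#' (so that twist is the true decomposition partner of writhe), divided by
#' 360 degrees.
#'
#' With `region = "core"` (default) the sum runs over the core steps only
#' (an n-bp core between handles spans exactly n steps, so an ideal relaxed
#' helix gives `n/pitch`). `region = "all"` includes the handle joints and
#' is the quantity whose sum with writhe is conserved along a trajectory.
#'
#' @param conf a [chain_conformation()].
#' @param region `"core"` or `"all"`.
#' @return twist in turns.
#' @export
twist <- function(conf, region = c("core", "all")) {
  region <- match.arg(region)
  tw <- cpp_joint_twists(conf$positions, conf$normals)
  n <- nrow(conf$positions)
  h <- conf$handle_bp
  if (region == "core") {
    if (h >= 1L) tw <- tw[h:(n - h - 1L)]
  }
  sum(tw) / (2 * pi)
}

#' Per-joint twist angles
#'
#' @param conf a [chain_conformation()].
#' @param degrees return degrees (default) or radians.
#' @return vector of length `n - 2`; element k is the twist of the step
#'   between frames k and k+1.
#' @export
joint_twists <- function(conf, degrees = TRUE) {
  tw <- cpp_joint_twists(conf$positions, conf$normals)
  if (degrees) tw * 180 / pi else tw
}

#' Writhe of a curve
#'
#' Writhe by the exact per-segment-pair solid-angle (Gauss integral) closed
#' form. Open curves are closed virtually: both ends are extended along
#' the pulling axis (-z below, +z above) to distant points joined far from
#' the chain, the standard convention for the tweezer geometry where the
#' ends are axially constrained (`closure = "axial"`). `closure = "none"`
#' evaluates the double sum over the open curve only, and
#' `closure = "polygon"` treats the input as an already closed polygon.
#'
#' @param x an `axis_curve`, a [chain_conformation()] (its full midpoint
#'   polyline is used), or an m x 3 matrix of points.
#' @param closure `"axial"`, `"none"` or `"polygon"`.
#' @return dimensionless writhe.
#' @export
writhe <- function(x, closure = c("axial", "none", "polygon")) {
  closure <- match.arg(closure)
  pts <- if (inherits(x, "axis_curve")) x$points
         else if (inherits(x, "chain_conformation")) x$positions
         else as.matrix(x)
  if (nrow(pts) < 4L) stop("need at least 4 points")
  switch(closure,
         axial = cpp_writhe_axial_closure(pts),
         polygon = cpp_writhe_closed(pts),
         none = writhe_open_sum(pts))
}

# double sum of the Gauss integral over an open polyline (exact closed form
# per segment pair, no closure)
writhe_open_sum <- function(pts) {
  m <- nrow(pts) - 1L
  tot <- 0
  for (i in seq_len(m - 2L)) {
    jj <- (i + 2L):m
    for (j in jj) {
      tot <- tot + writhe_pair_r(pts[i, ], pts[i + 1L, ], pts[j, ], pts[j + 1L, ])
    }
  }
  tot / (2 * pi)
}

writhe_pair_r <- function(p1, p2, q1, q2) {
  r13 <- q1 - p1; r14 <- q2 - p1; r23 <- q1 - p2; r24 <- q2 - p2
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(r13, r14); n2 <- cr(r14, r24); n3 <- cr(r24, r23); n4 <- cr(r23, r13)
  ln <- function(v) sqrt(sum(v^2))
  l <- c(ln(n1), ln(n2), ln(n3), ln(n4))
  s <- c(ln(r13), ln(r14), ln(r23), ln(r24))
  # relative degeneracy guard (coplanar/collinear pairs contribute zero)
  if (any(l < 1e-9 * c(s[1] * s[2], s[2] * s[4], s[4] * s[3], s[3] * s[1])))
    return(0)
  n1 <- n1 / l[1]; n2 <- n2 / l[2]; n3 <- n3 / l[3]; n4 <- n4 / l[4]
  cl <- function(x) asin(max(-1, min(1, x)))
  om <- cl(sum(n1 * n2)) + cl(sum(n2 * n3)) + cl(sum(n3 * n4)) + cl(sum(n4 * n1))
  s <- if (sum(cr(q2 - q1, p2 - p1) * r13) >= 0) 1 else -1
  om * s
}

#' Twist-writhe-linking-number report
#'
#' Decomposes the conformation's topology: twist of the core region, writhe
#' of the axially closed midpoint curve, measured linking number and the
#' residual against bookkeeping. With the conformation's own bookkeeping
#' (default), the residual uses the full-chain twist sum, for which
#' `Tw + Wr - applied_turns` is an exact invariant of the simulation;
#' against an external [topology_bookkeeping()] the core twist is used.
#'
#' @param conf a [chain_conformation()].
#' @param bookkeeping optional [topology_bookkeeping()].
#' @return list of class `twist_writhe_report` with fields `Tw`, `Tw_all`,
#'   `Wr`, `Lk_measured`, `Lk_bookkeeping`, `residual`.
#' @export
twist_writhe_report <- function(conf, bookkeeping = NULL) {
  tw_core <- twist(conf, "core")
  tw_all <- twist(conf, "all")
  wr <- writhe(conf, closure = "axial")
  if (is.null(bookkeeping)) {
    if (is.null(conf$bookkeeping))
      stop("conformation carries no bookkeeping; pass one explicitly")
    lk_book <- conf$bookkeeping$lk_book0 + conf$bookkeeping$applied_turns
    lk_meas <- tw_all + wr
  } else {
    stopifnot(inherits(bookkeeping, "topology_bookkeeping"))
    lk_book <- bookkeeping$Lk
    lk_meas <- tw_core + wr
  }
  structure(list(Tw = tw_core, Tw_all = tw_all, Wr = wr,
                 Lk_measured = lk_meas, Lk_bookkeeping = lk_book,
                 residual = lk_meas - lk_book),
            class = "twist_writhe_report")
}

#' @export
print.twist_writhe_report <- function(x, ...) {
  cat(sprintf("Tw(core) %.4f  Tw(all) %.4f  Wr %.4f  Lk %.4f  book %.4f  residual %+.4f\n",
              x$Tw, x$Tw_all, x$Wr, x$Lk_measured, x$Lk_bookkeeping, x$residual))
  invisible(x)
}

#' Plectoneme detection parameters
#'
#' @param min_seq_separation_bp smallest sequence separation between two
#'   sites counted as a (non-local) contact.
#' @param contact_distance_nm midpoint distance defining a contact.
#' @param cluster_gap_bp single-linkage gap (Chebyshev metric on the
#'   contact-pair plane) merging contacts into one plectoneme.
#' @param min_plectoneme_size_bp smallest reported call.
#' @export
plectoneme_params <- function(min_seq_separation_bp = 40L,
                              contact_distance_nm = 7.0,
                              cluster_gap_bp = 20L,
                              min_plectoneme_size_bp = 40L) {
  stopifnot(min_seq_separation_bp > 0, contact_distance_nm > 0,
            cluster_gap_bp > 0, min_plectoneme_size_bp > 0)
  structure(list(min_seq_separation_bp = as.integer(min_seq_separation_bp),
                 contact_distance_nm = contact_distance_nm,
                 cluster_gap_bp = as.integer(cluster_gap_bp),
                 min_plectoneme_size_bp = as.integer(min_plectoneme_size_bp)),
            class = "plectoneme_params")
}

#' Detect plectonemes from the duplex axis
#'
#' Contact pairs (i, j) with sequence separation at least
#' `min_seq_separation_bp` and midpoint distance at most
#' `contact_distance_nm` are clustered by single linkage (gap
#' `cluster_gap_bp` in sequence space). Each cluster becomes a call with
#' `start = min(i)`, `end = max(j)`, and the tip (apical end-loop centre)
#' at the midpoint of the cluster's minimum-separation contact pair. Calls
#' smaller than `min_plectoneme_size_bp` are discarded.
#'
#' @param x an `axis_curve` or a [chain_conformation()].
#' @param params a [plectoneme_params()].
#' @return data.frame with 0-based columns `start_bp`, `end_bp`, `tip_bp`,
#'   `size_bp`, `n_contacts`, sorted by `start_bp` (possibly empty).
#' @export
detect_plectonemes <- function(x, params = plectoneme_params()) {
  ax <- if (inherits(x, "axis_curve")) x else axis(x)
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      tip_bp = numeric(), size_bp = integer(),
                      n_contacts = integer())
  cp <- cpp_contact_pairs(ax$points, params$min_seq_separation_bp,
                          params$contact_distance_nm)
  if (nrow(cp) == 0L) return(empty)
  bi <- ax$bp[cp[, 1]]
  bj <- ax$bp[cp[, 2]]
  cl <- cpp_cluster_pairs(as.integer(bi), as.integer(bj),
                          params$cluster_gap_bp)
  dist <- cp[, 3]
  calls <- lapply(split(seq_along(cl), cl), function(k) {
    # A plectoneme's interwound arms wind around each other at close to the
    # hard-core distance; grazes near the cutoff distance (e.g. the flanking
    # duplex passing the branch) belong to the cluster but say little about
    # the superhelical body. Extent and tip therefore come from the "tight"
    # contacts within 1 nm of the cluster's closest approach: the extent is
    # their span, and the tip (apical end-loop centre) is the mean contact
    # midpoint of their shortest-separation half, which is symmetric about
    # the end loop.
    tight <- k[dist[k] <= min(dist[k]) + 1.0]
    sep <- bj[tight] - bi[tight]
    apical <- tight[sep <= stats::quantile(sep, 0.5)]
    data.frame(start_bp = min(bi[tight]), end_bp = max(bj[tight]),
               tip_bp = mean((bi[apical] + bj[apical]) / 2),
               size_bp = max(bj[tight]) - min(bi[tight]) + 1L,
               n_contacts = length(k))
  })
  out <- do.call(rbind, calls)
  out <- out[out$size_bp >= params$min_plectoneme_size_bp, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out <- out[order(out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plectoneme position series and distribution over a trajectory
#'
#' Detects plectonemes in every stored frame; when several coexist the
#' largest is tracked. Frames without a call are recorded as absent and
#' excluded from the histogram mass.
#'
#' @param traj a `td_trajectory` with stored frames, or a list of
#'   conformations.
#' @param params a [plectoneme_params()].
#' @param position track the apical end-loop centre (`"tip"`, default) or
#'   the extent midpoint (`"midpoint"`).
#' @param bin_bp histogram bin width in bp.
#' @return list of class `plectoneme_series`: `series` (data.frame `frame`,
#'   `position_bp`, `size_bp`), `histogram` (data.frame `bp`, `prob`,
#'   normalized over frames with calls), `bin_bp`, `n_frames`, `n_with_call`.
#' @export
plectoneme_position_series <- function(traj, params = plectoneme_params(),
                                       position = c("tip", "midpoint"),
                                       bin_bp = 1L) {
  position <- match.arg(position)
  frames <- if (inherits(traj, "td_trajectory")) traj$frames else traj
  if (length(frames) == 0L) stop("no stored frames")
  pos <- rep(NA_real_, length(frames))
  siz <- rep(NA_real_, length(frames))
  for (f in seq_along(frames)) {
    calls <- detect_plectonemes(frames[[f]], params)
    if (nrow(calls) > 0L) {
      k <- which.max(calls$size_bp)
      pos[f] <- if (position == "tip") calls$tip_bp[k]
                else (calls$start_bp[k] + calls$end_bp[k]) / 2
      siz[f] <- calls$size_bp[k]
    }
  }
  n_core <- n_core_bp(frames[[1]])
  breaks <- seq(0, ceiling(n_core / bin_bp) * bin_bp, by = bin_bp)
  with_call <- !is.na(pos)
  hist_counts <- if (any(with_call))
    table(cut(pos[with_call], breaks, right = FALSE)) else NULL
  hg <- data.frame(bp = breaks[-length(breaks)] + bin_bp / 2,
                   prob = if (is.null(hist_counts)) 0
                          else as.numeric(hist_counts) / sum(with_call))
  structure(list(series = data.frame(frame = seq_along(frames),
                                     position_bp = pos, size_bp = siz),
                 histogram = hg, bin_bp = bin_bp,
                 n_frames = length(frames), n_with_call = sum(with_call)),
            class = "plectoneme_series")
}

#' Pinning metrics of a plectoneme position series
#'
#' Peak height and width at half maximum of the position distribution, and
#' the slope of the mean-squared displacement of the tracked position
#' versus lag (a mobility measure: zero for a pinned plectoneme). Absent
#' frames are bridged by last observation carried forward, but only across
#' gaps of at most `max_gap` frames.
#'
#' @param series a `plectoneme_series`.
#' @param max_lag largest lag (in frames) entering the MSD fit.
#' @param max_gap largest bridged run of absent frames.
#' @param min_calls required number of frames with calls; below this a
#'   result of class `insufficient_data` is returned.
#' @return list of class `pinning_metrics`: `peak_height`, `width_fwhm_bp`,
#'   `msd_slope_bp2`, `n_calls`; or an `insufficient_data` object.
#' @export
pinning_metrics <- function(series, max_lag = 10L, max_gap = 5L,
                            min_calls = 100L) {
  stopifnot(inherits(series, "plectoneme_series"))
  pos <- series$series$position_bp
  ok <- !is.na(pos)
  if (sum(ok) < min_calls)
    return(structure(list(reason = sprintf(
      "only %d frames with plectoneme calls (need %d)", sum(ok), min_calls),
      n_calls = sum(ok)), class = "insufficient_data"))
  # bridge short gaps by last observation carried forward
  filled <- pos
  last <- NA_real_
  gap <- 0L
  for (i in seq_along(filled)) {
    if (!is.na(filled[i])) { last <- filled[i]; gap <- 0L }
    else { gap <- gap + 1L; if (gap <= max_gap) filled[i] <- last }
  }
  lags <- seq_len(min(max_lag, floor(sum(!is.na(filled)) / 4)))
  msd <- vapply(lags, function(L) {
    d <- filled[seq_len(length(filled) - L) + L] - filled[seq_len(length(filled) - L)]
    mean(d^2, na.rm = TRUE)
  }, 0)
  slope <- stats::coef(stats::lm(msd ~ lags))[["lags"]]
  hg <- series$histogram
  peak <- max(hg$prob)
  width <- sum(hg$prob >= peak / 2) * series$bin_bp
  structure(list(peak_height = peak, width_fwhm_bp = width,
                 msd_slope_bp2 = slope, n_calls = sum(ok),
                 msd = data.frame(lag = lags, msd = msd)),
            class = "pinning_metrics")
}

#' Mean local bend-angle profile along the duplex
#'
#' For each core base pair i, the angle between the chords spanning the
#' `w` base pairs before and after i, averaged over frames. A planted or
#' thermally preferred kink shows up as a local maximum.
#'
#' @param traj a `td_trajectory` with stored frames, a list of
#'   conformations, or a single conformation.
#' @param window half window `w` in bp.
#' @return data.frame `bp` (0-based), `mean_angle_deg`, `n_frames`.
#' @export
curvature_profile <- function(traj, window = 5L) {
  frames <- if (inherits(traj, "td_trajectory")) traj$frames
            else if (inherits(traj, "chain_conformation")) list(traj)
            else traj
  stopifnot(length(frames) >= 1L)
  w <- as.integer(window)
  ax0 <- axis(frames[[1]])
  m <- nrow(ax0$points)
  idx <- (w + 1L):(m - w)
  acc <- numeric(length(idx))
  for (f in frames) {
    p <- axis(f)$points
    a <- p[idx, , drop = FALSE] - p[idx - w, , drop = FALSE]
    b <- p[idx + w, , drop = FALSE] - p[idx, , drop = FALSE]
    ca <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
    acc <- acc + acos(pmax(-1, pmin(1, ca))) * 180 / pi
  }
  data.frame(bp = ax0$bp[idx], mean_angle_deg = acc / length(frames),
             n_frames = length(frames))
}
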