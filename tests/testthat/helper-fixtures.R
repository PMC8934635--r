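# shared helpers for the test suite

quick_params <- function(...) energy_params(...)

# tiny deterministic schedule for fast engine tests
quick_schedule <- function(seed = 1L, n_sweeps = 50L, ...) {
  simulation_schedule(seed = seed, n_sweeps = n_sweeps,
                      sample_interval_sweeps = 10L,
                      writhe_channel = FALSE, store_frames = FALSE, ...)
}

# dense-quadrature oracle for the Gauss writhe integral over a polyline,
# independent of the closed-form implementation: subdivide every segment and
# sum the discretized double integral.
writhe_quadrature <- function(pts, closed = FALSE, nsub = 8L) {
  m <- nrow(pts)
  segs <- if (closed) m else m - 1L
  fine <- list()
  for (s in seq_len(segs)) {
    p1 <- pts[s, ]
    p2 <- pts[if (s == m) 1L else s + 1L, ]
    lam0 <- (seq_len(nsub) - 1L) / nsub
    lam1 <- seq_len(nsub) / nsub
    for (k in seq_len(nsub)) {
      fine[[length(fine) + 1L]] <- list(
        a = p1 + lam0[k] * (p2 - p1),
        b = p1 + lam1[k] * (p2 - p1),
        parent = s)
    }
  }
  tot <- 0
  nf <- length(fine)
  for (i in seq_len(nf - 1L)) {
    fi <- fine[[i]]
    ti <- fi$b - fi$a
    ci <- (fi$a + fi$b) / 2
    for (j in (i + 1L):nf) {
      fj <- fine[[j]]
      if (fj$parent == fi$parent) next
      if (closed && abs(fj$parent - fi$parent) %in% c(0, 1, segs - 1)) {
        # adjacent straight segments contribute zero; skipping avoids the
        # near-singular integrand
      }
      tj <- fj$b - fj$a
      cj <- (fj$a + fj$b) / 2
      rr <- ci - cj # Gauss integrand: (dr1 x dr2) . (r1 - r2) / |r1 - r2|^3
      d <- sqrt(sum(rr^2))
      if (d < 1e-9) next
      cr <- c(ti[2] * tj[3] - ti[3] * tj[2],
              ti[3] * tj[1] - ti[1] * tj[3],
              ti[1] * tj[2] - ti[2] * tj[1])
      tot <- tot + sum(cr * rr) / d^3
    }
  }
  2 * tot / (4 * pi)
}

# explicit axis-angle rotation matrix oracle (independent of the package's
# internal Rodrigues helper)
rotation_oracle <- function(angle_deg, axis) {
  th <- angle_deg * pi / 180
  axis <- axis / sqrt(sum(axis^2))
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c <- cos(th); s <- sin(th); C <- 1 - c
  matrix(c(x*x*C + c,   x*y*C - z*s, x*z*C + y*s,
           y*x*C + z*s, y*y*C + c,   y*z*C - x*s,
           z*x*C - y*s, z*y*C + x*s, z*z*C + c),
         3, 3, byrow = TRUE)
}

# apply a crankshaft rotation to a conformation at the R level (independent
# re-implementation used for reversibility checks)
crank_conf <- function(conf, a, b, angle_deg) {
  ax <- conf$positions[b, ] - conf$positions[a, ]
  ax <- ax / sqrt(sum(ax^2))
  R <- rotation_oracle(angle_deg, ax)
  out <- conf
  idx <- (a + 1L):(b - 1L)
  out$positions[idx, ] <- t(R %*% (t(conf$positions[idx, , drop = FALSE]) -
                                     conf$positions[a, ]) + conf$positions[a, ])
  sidx <- a:(b - 1L)
  out$normals[sidx, ] <- t(R %*% t(conf$normals[sidx, , drop = FALSE]))
  out
}

make_ox_duplex_fixture <- function(dir, n_bp = 8L) {
  conf <- ideal_helix(n_bp - 2L, handle_bp = 1L)
  top <- file.path(dir, "duplex.top")
  cfg <- file.path(dir, "duplex.dat")
  export_to_oxdna(conf, top, cfg)
  list(top = top, conf = cfg, conformation = conf)
}
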