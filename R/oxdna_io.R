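# oxDNA length unit in nanometres (the ecosystem's standard conversion)
OXDNA_UNIT_NM <- 0.8518

#' Read / write an oxDNA topology file
#'
#' Classic oxDNA topology dialect: a header `"N_nucleotides N_strands"`,
#' then one line per nucleotide: `strand base neighbour3 neighbour5`
#' (neighbour indices 0-based, -1 = strand end).
#'
#' @param path file path.
#' @return `read_topology()` returns an object of class `oxdna_topology`:
#'   list with `n_nucleotides`, `n_strands`, `strand`, `base`, `neighbor3`,
#'   `neighbor5`.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty topology file: ", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr))
    stop("line 1: malformed topology header (expected 'N_nucleotides N_strands')")
  n <- hdr[1]; ns <- hdr[2]
  if (length(lines) - 1L != n)
    stop(sprintf("topology declares %d nucleotides but has %d records",
                 n, length(lines) - 1L))
  strand <- integer(n); base <- character(n)
  n3 <- integer(n); n5 <- integer(n)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(lines[k + 1L]), "\\s+")[[1]]
    if (length(f) != 4L)
      stop(sprintf("line %d: expected 4 fields, found %d", k + 1L, length(f)))
    strand[k] <- suppressWarnings(as.integer(f[1]))
    base[k] <- toupper(f[2])
    n3[k] <- suppressWarnings(as.integer(f[3]))
    n5[k] <- suppressWarnings(as.integer(f[4]))
    if (is.na(strand[k]) || is.na(n3[k]) || is.na(n5[k]))
      stop(sprintf("line %d: non-integer field", k + 1L))
    if (!base[k] %in% c("A", "C", "G", "T"))
      stop(sprintf("line %d: unknown base '%s'", k + 1L, f[2]))
    if (n3[k] < -1L || n3[k] >= n || n5[k] < -1L || n5[k] >= n)
      stop(sprintf("line %d: dangling neighbour index", k + 1L))
  }
  if (length(unique(strand)) != ns)
    stop(sprintf("topology declares %d strands but records use %d",
                 ns, length(unique(strand))))
  if (any(diff(match(strand, unique(strand))) < 0))
    stop("strand records are not contiguous")
  structure(list(n_nucleotides = n, n_strands = ns, strand = strand,
                 base = base, neighbor3 = n3, neighbor5 = n5),
            class = "oxdna_topology")
}

#' @rdname read_topology
#' @param topology an `oxdna_topology`.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "oxdna_topology"))
  lines <- c(sprintf("%d %d", topology$n_nucleotides, topology$n_strands),
             sprintf("%d %s %d %d", topology$strand, topology$base,
                     topology$neighbor3, topology$neighbor5))
  writeLines(lines, path)
  invisible(path)
}

parse_ox_frame <- function(lines, pos, n, frame_index) {
  if (pos + 2L > length(lines)) return(NULL)
  h1 <- lines[pos]; h2 <- lines[pos + 1L]; h3 <- lines[pos + 2L]
  if (!grepl("^t\\s*=", h1)) {
    if (all(!nzchar(trimws(c(h1, h2, h3))))) return(NULL)
    stop(sprintf("frame %d: expected 't = ...' header, got '%s'",
                 frame_index, h1))
  }
  if (!grepl("^b\\s*=", h2) || !grepl("^E\\s*=", h3))
    stop(sprintf("frame %d: malformed 'b =' / 'E =' headers", frame_index))
  num <- function(s, tag) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(sub("^.*=", "", s)), "\\s+")[[1]]))
    if (anyNA(v)) stop(sprintf("frame %d: malformed %s header", frame_index, tag))
    v
  }
  tval <- num(h1, "t")[1]
  box <- num(h2, "b")
  en <- num(h3, "E")
  if (pos + 2L + n > length(lines))
    stop(sprintf("frame %d: truncated (expected %d nucleotide records)",
                 frame_index, n))
  rec <- lines[pos + 3L:(2L + n)]
  m <- t(vapply(rec, function(s) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
    if (length(v) < 9L || anyNA(v[1:9]))
      stop(sprintf("frame %d: malformed nucleotide record '%s'", frame_index, s))
    c(v, rep(0, 15L - length(v)))[1:15]
  }, numeric(15), USE.NAMES = FALSE))
  a1 <- m[, 4:6, drop = FALSE]; a3 <- m[, 7:9, drop = FALSE]
  n1 <- sqrt(rowSums(a1^2)); n3n <- sqrt(rowSums(a3^2))
  if (any(abs(n1 - 1) > 1e-5) || any(abs(n3n - 1) > 1e-5))
    stop(sprintf("frame %d: versor norm outside tolerance 1e-5 (nucleotide %d)",
                 frame_index, which(abs(n1 - 1) > 1e-5 | abs(n3n - 1) > 1e-5)[1]))
  if (any(abs(rowSums(a1 * a3)) > 1e-3))
    stop(sprintf("frame %d: versors not orthogonal within 1e-3", frame_index))
  frame <- structure(list(time = tval, box = box, energies = en,
                          positions = m[, 1:3, drop = FALSE],
                          a1 = a1, a3 = a3,
                          velocities = m[, 10:12, drop = FALSE],
                          angular_velocities = m[, 13:15, drop = FALSE]),
                     class = "oxdna_conf_frame")
  list(frame = frame, next_pos = pos + 3L + n)
}

#' Read oxDNA configuration/trajectory files
#'
#' The classic configuration dialect: per frame, headers `t = ...`,
#' `b = x y z`, `E = etot eU eK`, then one line per nucleotide with
#' position, backbone-base versor, normal versor, velocity and angular
#' velocity. `ox_configuration_reader()` returns a lazy reader whose
#' `$read_frame()` yields one `oxdna_conf_frame` at a time (`NULL` at end
#' of file); `read_oxdna_trajectory()` reads all frames at once.
#'
#' @param path configuration file.
#' @param topology the matching `oxdna_topology`.
#' @export
ox_configuration_reader <- function(path, topology) {
  stopifnot(inherits(topology, "oxdna_topology"))
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  pos <- 1L
  k <- 0L
  list(read_frame = function() {
    res <- parse_ox_frame(lines, pos, topology$n_nucleotides, k + 1L)
    if (is.null(res)) return(NULL)
    pos <<- res$next_pos
    k <<- k + 1L
    res$frame
  })
}

#' @rdname ox_configuration_reader
#' @export
read_oxdna_trajectory <- function(path, topology) {
  rd <- ox_configuration_reader(path, topology)
  frames <- list()
  repeat {
    f <- rd$read_frame()
    if (is.null(f)) break
    frames[[length(frames) + 1L]] <- f
  }
  frames
}

#' Write an oxDNA configuration frame
#'
#' @param frame an `oxdna_conf_frame`.
#' @param path output path.
#' @param append append to an existing trajectory file.
#' @export
write_configuration <- function(frame, path, append = FALSE) {
  stopifnot(inherits(frame, "oxdna_conf_frame"))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  fmt <- function(m) apply(m, 1L, function(r) paste(sprintf("%.8f", r), collapse = " "))
  writeLines(c(sprintf("t = %g", frame$time),
               sprintf("b = %s", paste(sprintf("%.8f", frame$box), collapse = " ")),
               sprintf("E = %s", paste(sprintf("%.8f", frame$energies), collapse = " ")),
               paste(fmt(frame$positions), fmt(frame$a1), fmt(frame$a3),
                     fmt(frame$velocities), fmt(frame$angular_velocities))),
             con)
  invisible(path)
}

#' Read / write a per-base-pair hydrogen-bond energy table
#'
#' Whitespace-delimited columns `frame i j E_HB` (0-based nucleotide
#' indices, energies in model units, `#` comments). Positive energies are
#' clamped to zero with a warning; duplicate pairs within a frame are an
#' error.
#'
#' @param path file path.
#' @return object of class `pair_energy_table`: data.frame with columns
#'   `frame`, `i`, `j`, `E_HB`.
#' @export
read_pair_energies <- function(path) {
  if (!file.exists(path)) stop("pair-energy file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(structure(data.frame(frame = integer(), i = integer(),
                                j = integer(), E_HB = numeric()),
                     class = c("pair_energy_table", "data.frame")))
  }
  m <- t(vapply(seq_along(lines), function(k) {
    v <- suppressWarnings(as.numeric(strsplit(lines[k], "\\s+")[[1]]))
    if (length(v) != 4L || anyNA(v))
      stop(sprintf("pair-energy line %d is malformed: '%s'", k, lines[k]))
    v
  }, numeric(4)))
  df <- data.frame(frame = as.integer(m[, 1]), i = as.integer(m[, 2]),
                   j = as.integer(m[, 3]), E_HB = m[, 4])
  if (any(df$i >= df$j)) {
    swap <- df$i > df$j
    tmp <- df$i[swap]; df$i[swap] <- df$j[swap]; df$j[swap] <- tmp
    if (any(df$i == df$j)) stop("pair with i == j in pair-energy table")
  }
  if (any(df$E_HB > 0)) {
    warning("positive hydrogen-bond energies clamped to 0")
    df$E_HB[df$E_HB > 0] <- 0
  }
  key <- paste(df$frame, df$i, df$j)
  if (anyDuplicated(key))
    stop("duplicate (i, j) pair within a frame in pair-energy table")
  structure(df, class = c("pair_energy_table", "data.frame"))
}

#' @rdname read_pair_energies
#' @param table a `pair_energy_table`.
#' @export
write_pair_energies <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("frame", "i", "j", "E_HB")],
                   path, row.names = FALSE)
  invisible(path)
}

# per-pair-type reference maxima |E| from a table + topology: named vector
# c(AT = ..., GC = ...)
pair_reference_maxima <- function(table, topology) {
  at <- topology$base[table$i + 1L] %in% c("A", "T")
  ref <- c(AT = suppressWarnings(max(abs(table$E_HB[at]))),
           GC = suppressWarnings(max(abs(table$E_HB[!at]))))
  ref[!is.finite(ref)] <- NA_real_
  ref
}

#' Map an oxDNA frame to a duplex conformation
#'
#' Builds a [chain_conformation()] from an oxDNA configuration frame of a
#' two-strand duplex: base-pair midpoints are the averages of the paired
#' nucleotide positions (strand-1 nucleotide i with strand-2 nucleotide
#' N-1-i), converted to nm; material normals come from the base-base
#' vector. Pairing states use the hydrogen-bond energy table and the
#' binding-energy criterion when provided (a pair is denatured iff its
#' |energy| is strictly below `threshold` times the reference maximum for
#' its pair type); with `geometric_fallback = TRUE` and no table, pairing
#' is inferred from base-site proximity and versor anti-alignment (an
#' approximation of the energy criterion); otherwise all pairs are intact.
#'
#' The terminal base pair at each end is treated as a cap (handle) site.
#'
#' @param frame an `oxdna_conf_frame`.
#' @param topology the matching two-strand `oxdna_topology`.
#' @param pairing optional `pair_energy_table` (rows for this frame's
#'   `frame` index, or a single-frame table).
#' @param frame_index which frame's rows to use from `pairing` (default:
#'   the table's first frame).
#' @param threshold binding-energy fraction (strict `<`).
#' @param reference optional named vector `c(AT=, GC=)` of reference
#'   binding-energy magnitudes; defaults to the per-pair-type maxima
#'   observed in `pairing`.
#' @param geometric_fallback infer pairing geometrically when no table is
#'   given.
#' @param fallback_distance_nm base-base midpoint distance below which a
#'   pair counts as intact on the geometric route.
#' @return a [chain_conformation()] (`handle_bp = 1`).
#' @export
duplex_from_oxdna <- function(frame, topology, pairing = NULL,
                              frame_index = NULL, threshold = 0.10,
                              reference = NULL, geometric_fallback = FALSE,
                              fallback_distance_nm = 1.6) {
  stopifnot(inherits(frame, "oxdna_conf_frame"),
            inherits(topology, "oxdna_topology"))
  if (topology$n_strands != 2L)
    stop("duplex mapping requires exactly 2 strands")
  sids <- unique(topology$strand)
  i1 <- which(topology$strand == sids[1])
  i2 <- which(topology$strand == sids[2])
  if (length(i1) != length(i2)) stop("strand lengths are unequal")
  m <- length(i1)
  N <- topology$n_nucleotides
  # bp k (1-based): strand-1 nucleotide k pairs strand-2 nucleotide N-1-(k-1)
  p1 <- frame$positions[i1, , drop = FALSE] * OXDNA_UNIT_NM
  partner <- (N - 1L) - (seq_len(m) - 1L) + 1L # 1-based row of partner
  p2 <- frame$positions[partner, , drop = FALSE] * OXDNA_UNIT_NM
  mid <- (p1 + p2) / 2
  bb <- p1 - p2 # base-base vector
  d <- diff(mid)
  t <- d / pmax(sqrt(rowSums(d^2)), 1e-12)
  u <- bb[seq_len(m - 1L), , drop = FALSE]
  u <- u - t * rowSums(u * t)
  nu <- sqrt(rowSums(u^2))
  if (any(nu < 1e-9)) stop("degenerate base-base vector")
  u <- u / nu

  intact <- rep(TRUE, m)
  if (!is.null(pairing)) {
    tb <- as.data.frame(pairing)
    if (is.null(frame_index)) frame_index <- tb$frame[1]
    tb <- tb[tb$frame == frame_index, , drop = FALSE]
    if (is.null(reference)) reference <- pair_reference_maxima(pairing, topology)
    for (k in seq_len(m)) {
      iA <- i1[k] - 1L; iB <- partner[k] - 1L # 0-based
      lo <- min(iA, iB); hi <- max(iA, iB)
      row <- tb[tb$i == lo & tb$j == hi, , drop = FALSE]
      e <- if (nrow(row) == 0L) 0 else abs(row$E_HB[1])
      typ <- if (topology$base[i1[k]] %in% c("A", "T")) "AT" else "GC"
      ref <- reference[[typ]]
      if (!is.finite(ref) || ref <= 0)
        stop("no reference binding-energy maximum available for pair type ", typ)
      intact[k] <- !(e < threshold * ref)
    }
  } else if (geometric_fallback) {
    dist <- sqrt(rowSums(bb^2))
    anti <- rowSums(frame$a1[i1, , drop = FALSE] *
                      frame$a1[partner, , drop = FALSE]) < -0.5
    intact <- dist < fallback_distance_nm & anti
  }
  chain_conformation(sequence = topology$base[i1], positions = mid,
                     normals = u, intact = intact, handle_bp = 1L,
                     rise_nm = 0.34)
}

#' Export a conformation to the oxDNA dialect
#'
#' Writes a two-strand topology and a single configuration frame whose
#' base-pair midpoints reproduce the conformation's midpoints exactly
#' (strand-1 nucleotide i and strand-2 nucleotide N-1-i are placed
#' symmetrically about the midpoint along the material normal).
#'
#' @param conf a [chain_conformation()].
#' @param top_path,conf_path output paths.
#' @param base_sep_nm distance between the two paired nucleotides.
#' @return invisible list with the two paths.
#' @export
export_to_oxdna <- function(conf, top_path, conf_path, base_sep_nm = 1.2) {
  n <- nrow(conf$positions)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  # per-site normals (last step's normal reused for the last site)
  tri <- triads(conf)
  u <- t(tri[, 2, ])
  t1 <- t(tri[, 1, ])
  seq1 <- conf$sequence
  top <- structure(list(
    n_nucleotides = 2L * n, n_strands = 2L,
    strand = rep(1:2, each = n),
    base = c(seq1, rev(unname(comp[seq1]))),
    neighbor3 = c(-1L, seq_len(n - 1L) - 1L, -1L, n + seq_len(n - 1L) - 1L),
    neighbor5 = c(seq_len(n - 1L), -1L, n + seq_len(n - 1L), -1L)),
    class = "oxdna_topology")
  write_topology(top, top_path)
  p1 <- (conf$positions + (base_sep_nm / 2) * u) / OXDNA_UNIT_NM
  p2r <- (conf$positions - (base_sep_nm / 2) * u) / OXDNA_UNIT_NM
  # strand 2 nucleotide N-1-i pairs bp i: reverse the order
  p2 <- p2r[n:1, , drop = FALSE]
  a1 <- rbind(-u, u[n:1, , drop = FALSE])
  a3 <- rbind(t1, -t1[n:1, , drop = FALSE])
  # re-orthogonalize a1 against a3 to the format's tolerance
  a1 <- a1 - a3 * rowSums(a1 * a3)
  a1 <- a1 / sqrt(rowSums(a1^2))
  frame <- structure(list(time = 0, box = rep(1000, 3), energies = c(0, 0, 0),
                          positions = rbind(p1, p2), a1 = a1, a3 = a3,
                          velocities = matrix(0, 2L * n, 3),
                          angular_velocities = matrix(0, 2L * n, 3)),
                     class = "oxdna_conf_frame")
  write_configuration(frame, conf_path)
  invisible(list(topology = top_path, configuration = conf_path))
}
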