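# Population geometry: the two analysed point clouds and the spatial
# configuration of one-dimensional attractors.

#' Population matrix from a rate-map stack
#'
#' Crops the central `crop_px` x `crop_px` window of each map (the central
#' 60 cm of a 1 m arena for the default geometry, avoiding boundary
#' irregularities) and stacks the cropped maps as rows: `M[i, j]` is the
#' mean rate of cell i in crop pixel j.
#'
#' @param maps array `[n_cells, n_px, n_px]` (a simulation's `maps` field
#'   or an [ideal_grid_population()]).
#' @param crop_px crop width in pixels (default 25).
#' @return matrix `n_cells x crop_px^2` with attributes `crop_px` and
#'   `pixel_xy` (crop-pixel coordinates, metres, pixel index runs x-fastest).
#' @export
population_matrix <- function(maps, crop_px = 25) {
  np <- dim(maps)[2]
  if (crop_px > np) stop("crop exceeds the map")
  i0 <- (np - crop_px) %/% 2
  idx <- i0 + seq_len(crop_px)
  n_cells <- dim(maps)[1]
  M <- matrix(0, n_cells, crop_px^2)
  for (i in seq_len(n_cells)) M[i, ] <- as.vector(maps[i, idx, idx])
  px <- attr(maps, "pixel_size")
  if (is.null(px)) px <- 0.024
  arena <- attr(maps, "arena_side")
  if (is.null(arena)) arena <- 1
  off <- (arena - np * px) / 2
  cs <- off + (idx - 0.5) * px
  structure(M, crop_px = crop_px,
            pixel_xy = cbind(x = rep(cs, times = crop_px),
                             y = rep(cs, each = crop_px)))
}

#' Population-activity point cloud (pixels as points)
#'
#' The columns of the population matrix — one population-rate vector per
#' crop pixel — form a cloud of `crop_px^2` points in R^(n_cells), endowed
#' with the kNN-geodesic metric.  For aligned grid populations this cloud
#' is a sample of a torus.
#'
#' @param maps rate-map stack (see [population_matrix()]).
#' @param k geodesic neighbourhood size (default 10).
#' @param crop_px crop width in pixels.
#' @return a [point_cloud()] with provenance `"population"`.
#' @export
build_population_cloud <- function(maps, k = 10, crop_px = 25) {
  M <- population_matrix(maps, crop_px)
  if (all(M == 0)) stop("degenerate population matrix (all rates zero)")
  cl <- point_cloud(t(M), metric = "knn_geodesic", k = k,
                    provenance = "population")
  attr(cl, "pixel_xy") <- attr(M, "pixel_xy")
  cl
}

#' Neuron point cloud (cells as points)
#'
#' The rows of the population matrix — one cropped map per neuron — form a
#' cloud of `n_cells` points in R^(crop_px^2), endowed with the Pearson
#' correlation distance.  Its homology reflects the architecture of the
#' recurrent network (ring, stripe, torus).
#'
#' @inheritParams build_population_cloud
#' @return a [point_cloud()] with provenance `"neurons"`.
#' @export
build_neuron_cloud <- function(maps, crop_px = 25) {
  M <- population_matrix(maps, crop_px)
  if (all(M == 0)) stop("degenerate population matrix (all rates zero)")
  point_cloud(M, metric = "correlation", provenance = "neurons")
}

#' Attractor-coordinate phase map
#'
#' Assigns to each crop pixel the coordinate of the attractor region best
#' describing the population activity there: the activity-weighted
#' circular mean of the neuron ring angles (`ring1d`), or the
#' activity-weighted linear mean of positions along the stripe
#' (`stripe1dl`).  Pixels whose circular mean is degenerate (two balanced
#' antipodal activity bumps) are flagged.
#'
#' @param maps rate-map stack.
#' @param architecture `"ring1d"` or `"stripe1dl"`.
#' @param crop_px crop width in pixels.
#' @return object of class `phase_map`: `phase` (crop matrix; radians in
#'   `[0, 2 pi)` for ring, position in `[0, 1]` for stripe), `flagged`
#'   logical matrix, `architecture`.
#' @export
attractor_phase_map <- function(maps, architecture = c("ring1d", "stripe1dl"),
                                crop_px = 25) {
  architecture <- match.arg(architecture)
  M <- population_matrix(maps, crop_px)
  n <- nrow(M)
  tot <- colSums(M)
  if (architecture == "ring1d") {
    th <- 2 * pi * (seq_len(n) - 1) / n
    z <- colSums(M * exp(1i * th))
    phase <- Arg(z) %% (2 * pi)
    flagged <- Mod(z) < 1e-6 * pmax(tot, 1e-300) | tot == 0
  } else {
    pos <- (seq_len(n) - 1) / (n - 1)
    phase <- ifelse(tot > 0, colSums(M * pos) / tot, NA_real_)
    flagged <- tot == 0
  }
  structure(list(phase = matrix(phase, crop_px, crop_px),
                 flagged = matrix(flagged, crop_px, crop_px),
                 architecture = architecture,
                 pixel_xy = attr(M, "pixel_xy")),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("phase_map (%s): %d x %d pixels, %d flagged\n",
              x$architecture, nrow(x$phase), ncol(x$phase),
              sum(x$flagged)))
  invisible(x)
}

#' @export
plot.phase_map <- function(x, ...) {
  graphics::image(x$phase, col = grDevices::hcl.colors(64, "Spectral"),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}

# field centres (local maxima above frac*max) of one full map
field_centers <- function(map, pixel_size, arena_off, frac = 0.5) {
  n <- nrow(map)
  mx <- max(map)
  out <- NULL
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    v <- map[i, j]
    if (v < frac * mx) next
    nb <- map[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v == max(nb) && sum(nb == v) == 1)
      out <- rbind(out, c(arena_off + (i - 0.5) * pixel_size,
                          arena_off + (j - 0.5) * pixel_size))
  }
  out
}

# shell order of a lattice displacement: 0 for the origin, 1 for nearest
# neighbours (distance = spacing), 2 for sqrt(3)*spacing, 3 for 2*spacing...
lattice_shell_order <- function(m1, m2, a1, a2) {
  if (m1 == 0 && m2 == 0) return(0L)
  g <- expand.grid(p = -5:5, q = -5:5)
  len <- sqrt((g$p * a1[1] + g$q * a2[1])^2 + (g$p * a1[2] + g$q * a2[2])^2)
  shells <- sort(unique(round(len[len > 1e-9], 9)))
  d <- sqrt((m1 * a1[1] + m2 * a2[1])^2 + (m1 * a1[2] + m2 * a2[2])^2)
  as.integer(which.min(abs(shells - d)))
}

#' Configuration order of a ring-attractor solution
#'
#' Classifies how a one-dimensional ring attractor is laid out in physical
#' space: one full cycle along the attractor is traced through the firing
#' fields of successive ring neurons, and the net spatial displacement of
#' the cycle is expressed in the hexagonal lattice basis.  The order is
#' the neighbour-shell of that lattice displacement: a cycle that closes
#' on itself is order 0, a cycle ending one field over is order 1, and so
#' on.  A frontier mask (pixels of abrupt phase change) is reported
#' alongside.
#'
#' @param maps rate-map stack of a ring-architecture population.
#' @param spacing,orientation lattice geometry; estimated from the
#'   population autocorrelogram when missing.
#' @param phase_map optional [attractor_phase_map()] result (computed when
#'   missing) used for the frontier mask.
#' @param max_step largest credible spatial jump between consecutive
#'   neurons' fields, as a fraction of the spacing; larger jumps mark the
#'   solution "unresolvable".
#' @return object of class `config_report`: `order` (integer or NA),
#'   `winding` (lattice coordinates of the cycle displacement),
#'   `displacement` (metres), `resolved`, `frontier_mask`, `path`.
#' @export
configuration_order <- function(maps, spacing = NULL, orientation = NULL,
                                phase_map = NULL, max_step = 0.5) {
  geom <- estimate_lattice_geometry(maps, spacing, orientation)
  a1 <- geom$a1; a2 <- geom$a2
  n_cells <- dim(maps)[1]
  np <- dim(maps)[2]
  px <- attr(maps, "pixel_size"); if (is.null(px)) px <- 0.024
  arena <- attr(maps, "arena_side"); if (is.null(arena)) arena <- 1
  off <- (arena - np * px) / 2
  tr <- trace_attractor_path(maps, c(seq_len(n_cells), 1L), geom,
                             max_step = max_step, px = px, off = off,
                             arena = arena)
  if (!tr$ok)
    return(config_report(NA, c(NA, NA), c(NA, NA), FALSE, maps, phase_map))
  path <- tr$path
  D <- tr$displacement
  m <- solve(cbind(a1, a2), D)
  mi <- round(m)
  if (max(abs(m - mi)) > 0.25)
    return(config_report(NA, c(NA, NA), D, FALSE, maps, phase_map))
  order <- lattice_shell_order(mi[1], mi[2], a1, a2)
  rep <- config_report(order, as.integer(mi), D, TRUE, maps, phase_map)
  rep$path <- path
  rep
}

config_report <- function(order, winding, displacement, resolved, maps,
                          phase_map) {
  if (is.null(phase_map))
    phase_map <- tryCatch(attractor_phase_map(maps, "ring1d"),
                          error = function(e) NULL)
  fm <- if (!is.null(phase_map)) frontier_mask(phase_map) else NULL
  structure(list(order = order, winding = winding,
                 displacement = displacement, resolved = resolved,
                 frontier_mask = fm, path = NULL),
            class = "config_report")
}

#' @export
print.config_report <- function(x, ...) {
  if (x$resolved)
    cat(sprintf("config_report: order O_%d (winding %d,%d)\n", x$order,
                x$winding[1], x$winding[2]))
  else cat("config_report: unresolvable\n")
  invisible(x)
}

# 3x3 box smoothing; sampling noise of trained rate maps otherwise
# litters the field detection with spurious local maxima
smooth3 <- function(m) {
  n <- nrow(m)
  p <- matrix(0, n + 2, n + 2)
  p[2:(n + 1), 2:(n + 1)] <- m
  cnt <- matrix(1, n + 2, n + 2)
  cnt[c(1, n + 2), ] <- 0
  cnt[, c(1, n + 2)] <- 0
  acc <- den <- matrix(0, n, n)
  for (dx in 0:2) for (dy in 0:2) {
    acc <- acc + p[(1:n) + dx, (1:n) + dy]
    den <- den + cnt[(1:n) + dx, (1:n) + dy]
  }
  acc / den
}

# Follow the attractor through physical space: starting from the first
# listed cell's field nearest the arena centre, step to the next cell's
# nearest field, allowing lattice translates so the trace may run beyond
# the mapped area.  Returns the accumulated displacement of the path.
trace_attractor_path <- function(maps, cell_seq, geom, max_step, px, off,
                                 arena) {
  centers <- lapply(seq_len(dim(maps)[1]), function(i)
    field_centers(smooth3(maps[i, , ]), px, off))
  if (any(vapply(centers[cell_seq], is.null, logical(1))))
    return(list(ok = FALSE))
  lat <- as.matrix(expand.grid(-3:3, -3:3)) %*% rbind(geom$a1, geom$a2)
  first <- centers[[cell_seq[1]]]
  start <- first[which.min(rowSums(sweep(
    first, 2, c(arena / 2, arena / 2))^2)), ]
  p <- start
  path <- matrix(start, 1)
  for (c in cell_seq[-1]) {
    cc <- centers[[c]]
    cand <- cc[rep(seq_len(nrow(cc)), each = nrow(lat)), , drop = FALSE] +
      lat[rep(seq_len(nrow(lat)), times = nrow(cc)), ]
    d2 <- rowSums(sweep(cand, 2, p)^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) > max_step * geom$spacing) return(list(ok = FALSE))
    p <- cand[j, ]
    path <- rbind(path, p)
  }
  list(ok = TRUE, path = path, displacement = p - start)
}

# pixels where the circular phase gradient exceeds pi/4 per pixel
frontier_mask <- function(pm) {
  ph <- pm$phase
  n <- nrow(ph)
  circ <- function(d) {
    d <- d %% (2 * pi)
    pmin(d, 2 * pi - d)
  }
  gx <- gy <- matrix(0, n, n)
  gx[2:n, ] <- circ(ph[2:n, ] - ph[1:(n - 1), ])
  gy[, 2:n] <- circ(ph[, 2:n] - ph[, 1:(n - 1)])
  pmax(gx, gy) > pi / 4
}

#' Configuration order of a stripe-attractor solution
#'
#' Reports how far apart the two extremes of a stripe attractor come to
#' lie in physical space, in hexagonal-lattice neighbour order.  The open
#' attractor path is traced from the first neuron's field through the
#' fields of successive neurons to the last; the accumulated displacement
#' (which, unlike the nearest lattice image of the endpoint, distinguishes
#' a stretched stripe from one folding back onto its start) is classified
#' by neighbour shell: 0 when the extremes share a field, 1 when one
#' lattice vector apart, and so on.
#'
#' @param maps rate-map stack of a stripe-architecture population.
#' @param spacing,orientation lattice geometry (estimated when missing).
#' @param max_step largest credible jump between consecutive neurons'
#'   fields, as a fraction of the spacing.
#' @return a `config_report` (the `winding` field holds the lattice
#'   coordinates of the extreme-to-extreme displacement).
#' @export
stripe_order <- function(maps, spacing = NULL, orientation = NULL,
                         max_step = 0.5) {
  geom <- estimate_lattice_geometry(maps, spacing, orientation)
  n_cells <- dim(maps)[1]
  np <- dim(maps)[2]
  px <- attr(maps, "pixel_size"); if (is.null(px)) px <- 0.024
  arena <- attr(maps, "arena_side"); if (is.null(arena)) arena <- 1
  off <- (arena - np * px) / 2
  tr <- trace_attractor_path(maps, seq_len(n_cells), geom,
                             max_step = max_step, px = px, off = off,
                             arena = arena)
  if (!tr$ok)
    return(structure(list(order = NA, winding = c(NA, NA),
                          displacement = c(NA, NA), resolved = FALSE,
                          frontier_mask = NULL, path = NULL),
                     class = "config_report"))
  m <- solve(cbind(geom$a1, geom$a2), tr$displacement)
  mi <- round(m)
  if (max(abs(m - mi)) > 0.25)
    return(structure(list(order = NA, winding = c(NA, NA),
                          displacement = tr$displacement, resolved = FALSE,
                          frontier_mask = NULL, path = tr$path),
                     class = "config_report"))
  order <- lattice_shell_order(mi[1], mi[2], geom$a1, geom$a2)
  structure(list(order = order, winding = as.integer(mi),
                 displacement = tr$displacement, resolved = TRUE,
                 frontier_mask = NULL, path = tr$path),
            class = "config_report")
}

# lattice basis from the population autocorrelogram (or explicit values)
estimate_lattice_geometry <- function(maps, spacing = NULL,
                                      orientation = NULL) {
  if (is.null(spacing) || is.null(orientation)) {
    px <- attr(maps, "pixel_size"); if (is.null(px)) px <- 0.024
    ac <- population_autocorrelogram(maps, px)
    sp <- estimate_spacing(ac)
    if (is.na(sp)) stop("cannot estimate lattice geometry from the maps")
    if (is.null(spacing)) spacing <- as.numeric(sp)
    if (is.null(orientation)) {
      mx <- autocorr_maxima(ac, spacing)
      if (nrow(mx) < 3) stop("cannot estimate lattice orientation")
      orientation <- min(mx$angle %% 60) * pi / 180
    }
  }
  list(spacing = spacing, orientation = orientation,
       a1 = spacing * c(cos(orientation), sin(orientation)),
       a2 = spacing * c(cos(orientation + pi / 3), sin(orientation + pi / 3)))
}
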