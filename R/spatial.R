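#' Fit a kernel utilization distribution
#'
#' Gaussian product-kernel density of planar relocations on a regular grid,
#' normalized so that `sum(density) * cell_size^2 = 1`, together with the
#' percent-volume (isopleth) surface: each cell is labelled with the smallest
#' percent-volume contour that contains it, obtained by sorting cells by
#' density and accumulating probability mass. The 95% isopleth is the
#' conventional home range, the 50% isopleth the core area.
#'
#' @param relocations data.frame with columns `x_km`, `y_km` (rows for one
#'   group).
#' @param bandwidth_rule `"href"` for the per-coordinate normal reference
#'   rule `h_i = sd_i * n^(-1/6)`, or a numeric length-2 vector of bandwidths
#'   in km.
#' @param cell_size grid cell edge, km.
#' @param group_id optional label stored with the fit.
#' @param lims optional `c(xmin, xmax, ymin, ymax)` grid limits; used to put
#'   several groups on a common grid. Defaults to the data extent padded by
#'   3 bandwidths.
#' @return object of class `utilization_distribution`: grid centre vectors
#'   `x`, `y`, matrices `density` and `isopleth` (percent volume, 0-100),
#'   `cell_size`, `bandwidth`, `n`, `group_id`.
#' @export
fit_kde <- function(relocations, bandwidth_rule = "href", cell_size = 0.1,
                    group_id = NULL, lims = NULL) {
  x <- relocations$x_km
  y <- relocations$y_km
  n <- length(x)
  if (n < 30) stop("insufficient relocations: need >= 30, got ", n)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in a coordinate; cannot fit a kernel density")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (is.numeric(bandwidth_rule)) {
    h <- rep_len(bandwidth_rule, 2)
  } else if (identical(bandwidth_rule, "href")) {
    h <- c(sd(x), sd(y)) * n^(-1 / 6)
  } else stop("unknown bandwidth rule: ", bandwidth_rule)
  if (is.null(lims)) {
    lims <- c(min(x) - 3 * h[1], max(x) + 3 * h[1],
              min(y) - 3 * h[2], max(y) + 3 * h[2])
  }
  gx <- seq(lims[1], lims[2], by = cell_size)
  gy <- seq(lims[3], lims[4], by = cell_size)
  # MASS::kde2d uses h/4 as the Gaussian sd
  kd <- MASS::kde2d(x, y, h = 4 * h, n = c(length(gx), length(gy)),
                    lims = c(range(gx), range(gy)))
  dens <- kd$z / (sum(kd$z) * cell_size^2)
  ud <- list(x = kd$x, y = kd$y, density = dens,
             isopleth = isopleth_surface(dens, cell_size),
             cell_size = cell_size, bandwidth = h, n = n, group_id = group_id)
  class(ud) <- "utilization_distribution"
  ud
}

# percent-volume relabeling: cells sorted by density, cumulative mass * 100.
# Zero-density cells get 100 (contained only by the full support).
isopleth_surface <- function(density, cell_size) {
  mass <- density * cell_size^2
  ord <- order(mass, decreasing = TRUE)
  iso <- numeric(length(mass))
  iso[ord] <- pmin(cumsum(mass[ord]) / sum(mass), 1) * 100
  iso[density <= 0] <- 100
  matrix(iso, nrow = nrow(density))
}

#' Fit utilization distributions for several groups on one common grid
#'
#' @param relocations data.frame with `group_id`, `x_km`, `y_km`.
#' @inheritParams fit_kde
#' @return named list of `utilization_distribution` objects sharing a grid.
#' @export
fit_kde_groups <- function(relocations, bandwidth_rule = "href",
                           cell_size = 0.1) {
  ids <- sort(unique(relocations$group_id))
  hs <- lapply(ids, function(g) {
    d <- relocations[relocations$group_id == g, ]
    if (is.numeric(bandwidth_rule)) rep_len(bandwidth_rule, 2)
    else c(sd(d$x_km), sd(d$y_km)) * nrow(d)^(-1 / 6)
  })
  hmax <- apply(do.call(rbind, hs), 2, max)
  lims <- c(min(relocations$x_km) - 3 * hmax[1],
            max(relocations$x_km) + 3 * hmax[1],
            min(relocations$y_km) - 3 * hmax[2],
            max(relocations$y_km) + 3 * hmax[2])
  uds <- lapply(ids, function(g)
    fit_kde(relocations[relocations$group_id == g, ], bandwidth_rule,
            cell_size, group_id = g, lims = lims))
  names(uds) <- ids
  uds
}

#' Percent-volume region of a utilization distribution
#'
#' All grid cells whose isopleth label is at most `p` (and with nonzero
#' density), their total area, and the polygonal outline of the region.
#'
#' @param ud a `utilization_distribution`.
#' @param p percent volume in (0, 100\].
#' @return list with `cells` (logical matrix), `area_km2`, and `polygons`
#'   (list of closed rings, each a 2-column matrix of km coordinates; cells
#'   are treated as squares of side `cell_size` centred on grid points).
#' @export
percent_volume_region <- function(ud, p) {
  stopifnot(p > 0, p <= 100)
  cells <- ud$isopleth <= p & ud$density > 0
  list(cells = cells,
       area_km2 = sum(cells) * ud$cell_size^2,
       polygons = region_outline(cells, ud$x, ud$y, ud$cell_size))
}

# Trace the boundary of a union of grid squares. Each TRUE cell contributes
# its 4 edges on the half-open vertex lattice; edges shared by two cells
# cancel; remaining edges are stitched into closed rings.
region_outline <- function(cells, gx, gy, cell) {
  idx <- which(cells, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  i <- idx[, 1]; j <- idx[, 2]
  nvx <- length(gx) + 1L
  vid <- function(a, b) (b - 1L) * (nvx + 1L) + a  # vertex (a,b), a in 0..nvx
  # corners of cell (i,j): (i-1,j-1) (i,j-1) (i,j) (i-1,j) in vertex units
  e <- rbind(cbind(vid(i - 1L, j - 1L), vid(i, j - 1L)),
             cbind(vid(i, j - 1L), vid(i, j)),
             cbind(vid(i, j), vid(i - 1L, j)),
             cbind(vid(i - 1L, j), vid(i - 1L, j - 1L)))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[key %in% names(which(table(key) == 1)), , drop = FALSE]
  # stitch directed edges (interior on the left) into rings
  nxt <- split(seq_len(nrow(e)), e[, 1])
  used <- rep(FALSE, nrow(e))
  rings <- list()
  vx <- function(v) gx[1] - cell / 2 + (v %% (nvx + 1L)) * cell
  vy <- function(v) gy[1] - cell / 2 + (v %/% (nvx + 1L)) * cell
  for (start in seq_len(nrow(e))) {
    if (used[start]) next
    path <- integer(0)
    cur <- start
    repeat {
      used[cur] <- TRUE
      path <- c(path, e[cur, 1])
      nxt_cands <- nxt[[as.character(e[cur, 2])]]
      nxt_cands <- nxt_cands[!used[nxt_cands]]
      if (length(nxt_cands) == 0) break
      cur <- nxt_cands[1]
    }
    path <- c(path, path[1])
    rings[[length(rings) + 1]] <- cbind(x = vx(path), y = vy(path))
  }
  rings
}

#' Overlap between two groups' percent-volume regions
#'
#' @param ud_a,ud_b `utilization_distribution` objects. If their grids
#'   differ, the second is resampled onto the first's grid by nearest cell;
#'   grids without a common extent are an error.
#' @param p isopleth level, default 95 (the home range).
#' @return list `fraction_a_in_b`, `fraction_b_in_a`, `shared_area_km2`.
#' @export
overlap_fraction <- function(ud_a, ud_b, p = 95) {
  if (!isTRUE(all.equal(ud_a$x, ud_b$x)) ||
      !isTRUE(all.equal(ud_a$y, ud_b$y))) {
    ud_b <- resample_ud(ud_b, ud_a)
  }
  a <- percent_volume_region(ud_a, p)$cells
  b <- percent_volume_region(ud_b, p)$cells
  shared <- sum(a & b)
  list(fraction_a_in_b = if (sum(a) > 0) shared / sum(a) else 0,
       fraction_b_in_a = if (sum(b) > 0) shared / sum(b) else 0,
       shared_area_km2 = shared * ud_a$cell_size^2)
}

# nearest-cell resampling of ud onto the grid of `template`
resample_ud <- function(ud, template) {
  if (max(ud$x) < min(template$x) - ud$cell_size ||
      min(ud$x) > max(template$x) + ud$cell_size ||
      max(ud$y) < min(template$y) - ud$cell_size ||
      min(ud$y) > max(template$y) + ud$cell_size)
    stop("utilization distributions are on disjoint grids")
  ix <- findInterval(template$x, ud$x - ud$cell_size / 2)
  iy <- findInterval(template$y, ud$y - ud$cell_size / 2)
  ok_x <- ix >= 1 & ix <= length(ud$x)
  ok_y <- iy >= 1 & iy <= length(ud$y)
  dens <- matrix(0, length(template$x), length(template$y))
  iso <- matrix(100, length(template$x), length(template$y))
  dens[ok_x, ok_y] <- ud$density[ix[ok_x], iy[ok_y]]
  iso[ok_x, ok_y] <- ud$isopleth[ix[ok_x], iy[ok_y]]
  out <- template
  out$density <- dens / (sum(dens) * template$cell_size^2)
  out$isopleth <- iso
  out$group_id <- ud$group_id
  out
}

#' Kernel usage value at points
#'
#' Usage is 100 minus the smallest percent-volume isopleth containing the
#' point's grid cell: near 100 in the core of the range, 0 outside it (and 0
#' for points off the grid).
#'
#' @param ud a `utilization_distribution`.
#' @param x,y point coordinates in km (vectors).
#' @return numeric vector of usage values in \[0, 100\].
#' @export
usage_at <- function(ud, x, y) {
  ix <- findInterval(x, c(ud$x - ud$cell_size / 2, max(ud$x) + ud$cell_size / 2),
                     rightmost.closed = TRUE)
  iy <- findInterval(y, c(ud$y - ud$cell_size / 2, max(ud$y) + ud$cell_size / 2),
                     rightmost.closed = TRUE)
  on <- ix >= 1 & ix <= length(ud$x) & iy >= 1 & iy <= length(ud$y)
  out <- numeric(length(x))
  out[on] <- 100 - ud$isopleth[cbind(ix[on], iy[on])]
  out
}

#' Per-hunt usage-difference scores
#'
#' Each hunt gets two kernel usage values, one under the hunting group's UD
#' and one under the other group's, and the score
#' `usage_difference = usage_other_group - usage_hunt_group`. Positive scores
#' mean the hunt fell in an area used relatively more by the group that did
#' not hunt. (Field descriptions of this score sometimes gloss the sign the
#' other way round; this function implements the printed formula.)
#'
#' @param hunts data.frame with `hunt_id`, `x_km`, `y_km`, `catcher_group`.
#' @param uds named list of `utilization_distribution` objects, one per
#'   group; names are group ids.
#' @return data.frame `hunt_id`, `usage_hunt_group`, `usage_other_group`,
#'   `usage_difference`.
#' @export
usage_difference <- function(hunts, uds) {
  ids <- names(uds)
  if (length(ids) != 2) stop("exactly two groups' UDs are required")
  missing_ud <- setdiff(unique(hunts$catcher_group), ids)
  if (length(missing_ud) > 0)
    stop("no utilization distribution for group(s): ",
         paste(missing_ud, collapse = ", "))
  other <- setNames(rev(ids), ids)
  u <- vapply(ids, function(g) usage_at(uds[[g]], hunts$x_km, hunts$y_km),
              numeric(nrow(hunts)))
  u <- matrix(u, nrow = nrow(hunts), dimnames = list(NULL, ids))
  uh <- u[cbind(seq_len(nrow(hunts)), match(hunts$catcher_group, ids))]
  uo <- u[cbind(seq_len(nrow(hunts)), match(other[hunts$catcher_group], ids))]
  data.frame(hunt_id = hunts$hunt_id, usage_hunt_group = uh,
             usage_other_group = uo, usage_difference = uo - uh)
}

#' Export a utilization distribution as a long table
#' @param ud a `utilization_distribution`.
#' @return data.frame `x`, `y`, `density`, `isopleth`.
#' @export
ud_to_table <- function(ud) {
  data.frame(x = rep(ud$x, times = length(ud$y)),
             y = rep(ud$y, each = length(ud$x)),
             density = as.vector(ud$density),
             isopleth = as.vector(ud$isopleth))
}

#' Write isopleth contours as GeoJSON
#'
#' One Feature per requested level, geometry a MultiPolygon of the region
#' outline (cell-edge resolution), properties `group` and `level`.
#'
#' @param ud a `utilization_distribution`.
#' @param levels isopleth levels, e.g. `c(50, 95)`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_isopleth_geojson <- function(ud, levels, path) {
  features <- lapply(levels, function(p) {
    reg <- percent_volume_region(ud, p)
    polys <- lapply(reg$polygons, function(r)
      list(lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))))
    list(type = "Feature",
         properties = list(group = ud$group_id, level = p,
                           area_km2 = reg$area_km2),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}

#' @export
print.utilization_distribution <- function(x, ...) {
  a95 <- percent_volume_region(x, 95)$area_km2
  a50 <- percent_volume_region(x, 50)$area_km2
  cat("Utilization distribution", if (!is.null(x$group_id)) x$group_id else "",
      "\n  fixes:", x$n, " bandwidth (km):",
      paste(signif(x$bandwidth, 3), collapse = ", "),
      "\n  grid:", length(x$x), "x", length(x$y), "cells of",
      x$cell_size, "km",
      "\n  95% kernel area:", round(a95, 1), "km^2; 50% core:",
      round(a50, 1), "km^2\n")
  invisible(x)
}
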