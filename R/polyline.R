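#' Polylines in the section plane
#'
#' Digitized structures in a tooth section (the enamel-dentine junction,
#' the outer enamel surface, incremental lines) are open polylines in a 2-D
#' section plane. Coordinates are in micrometres; by convention the cusp tip
#' sits at the origin and the cervical direction is +u.
#'
#' A polyline is stored as a numeric matrix with columns `u` and `v` and
#' class `"polyline"`. `as_polyline()` accepts a matrix or a data frame with
#' columns `u` and `v`.
#'
#' @param x A two-column numeric matrix or a data frame with columns `u`, `v`.
#' @return A `polyline` object (matrix with columns `u`, `v`).
#' @examples
#' pl <- as_polyline(data.frame(u = c(0, 3, 3), v = c(0, 0, 4)))
#' polyline_length(pl) # 7
#' @export
as_polyline <- function(x) {
  if (inherits(x, "polyline")) return(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("u", "v") %in% names(x)))
    x <- cbind(u = x$u, v = x$v)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("a polyline needs exactly two coordinate columns (u, v)")
  storage.mode(x) <- "double"
  colnames(x) <- c("u", "v")
  if (nrow(x) < 2L) stop("a polyline needs at least 2 points")
  if (any(!is.finite(x))) stop("polyline coordinates must be finite")
  seg <- sqrt(diff(x[, 1])^2 + diff(x[, 2])^2)
  if (any(seg == 0)) {
    # drop exactly repeated vertices rather than carrying zero-length segments
    keep <- c(TRUE, seg > 0)
    x <- x[keep, , drop = FALSE]
    if (nrow(x) < 2L) stop("polyline degenerates to a single point")
  }
  structure(x, class = c("polyline", class(x)))
}

#' @rdname as_polyline
#' @export
polyline_length <- function(x) {
  x <- as_polyline(x)
  sum(sqrt(diff(x[, 1])^2 + diff(x[, 2])^2))
}

# cumulative arc length at each vertex (starts at 0)
cum_arc <- function(x) {
  c(0, cumsum(sqrt(diff(x[, 1])^2 + diff(x[, 2])^2)))
}

#' Convert a polyline to a tibble
#'
#' @param x A `polyline`.
#' @param ... Unused.
#' @return A tibble with columns `u`, `v` and cumulative `arc` (micrometres).
#' @export
as_tibble.polyline <- function(x, ...) {
  tibble::tibble(u = x[, 1], v = x[, 2], arc = cum_arc(x))
}

#' Arc-length position of a point along a curve
#'
#' Projects a point onto a polyline (typically the EDJ, oriented from the
#' cusp tip to the cervix) and returns the arc length from the first vertex
#' to the nearest point of the curve. The point must lie within `tol` of the
#' curve: positions are meaningful only for points that sit on it, such as
#' intersections of incremental lines with the EDJ.
#'
#' @param curve A `polyline` (or coercible), oriented cusp to cervix.
#' @param pt Numeric length-2 vector `c(u, v)`, or a two-column matrix of
#'   points (one row per point).
#' @param tol Snapping tolerance in micrometres. Geometry at this layer is
#'   synthetic or pre-digitized, so the default is effectively exact.
#' @return Arc position(s) in micrometres from the curve's first vertex.
#' @examples
#' edj <- as_polyline(cbind(u = c(0, 100), v = c(0, 0)))
#' arc_position(edj, c(40, 0)) # 40
#' @export
arc_position <- function(curve, pt, tol = 1e-6) {
  curve <- as_polyline(curve)
  pts <- if (is.matrix(pt)) pt else matrix(pt, ncol = 2L)
  pr <- project_onto_polyline(curve, pts)
  bad <- pr$dist > tol
  if (any(bad)) {
    stop(sprintf(
      "point (%g, %g) is %.3g um from the curve (tolerance %.3g um)",
      pts[which(bad)[1], 1], pts[which(bad)[1], 2], max(pr$dist), tol
    ))
  }
  if (is.matrix(pt)) pr$arc else pr$arc[1]
}

# Project points onto a polyline; returns arc position, distance, and the
# projected coordinates. Vectorized over points and segments.
project_onto_polyline <- function(curve, pts) {
  p1 <- curve[-nrow(curve), , drop = FALSE]
  p2 <- curve[-1L, , drop = FALSE]
  d <- p2 - p1
  len2 <- d[, 1]^2 + d[, 2]^2
  s0 <- cum_arc(curve)[-nrow(curve)]
  n <- nrow(pts)
  arc <- dist <- numeric(n)
  proj <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    w1 <- pts[i, 1] - p1[, 1]
    w2 <- pts[i, 2] - p1[, 2]
    t <- pmin(pmax((w1 * d[, 1] + w2 * d[, 2]) / len2, 0), 1)
    qx <- p1[, 1] + t * d[, 1]
    qy <- p1[, 2] + t * d[, 2]
    dd <- (pts[i, 1] - qx)^2 + (pts[i, 2] - qy)^2
    k <- which.min(dd)
    arc[i] <- s0[k] + t[k] * sqrt(len2[k])
    dist[i] <- sqrt(dd[k])
    proj[i, ] <- c(qx[k], qy[k])
  }
  list(arc = arc, dist = dist, point = proj)
}

#' Point and local normal at a given arc position
#'
#' @param curve A `polyline` (or coercible).
#' @param s Arc position(s) in micrometres from the first vertex.
#' @return `point_at_arc()`: matrix of coordinates (one row per `s`).
#'   `normal_at_arc()`: matrix of unit normals, rotated +90 degrees from the
#'   local tangent (for an EDJ running cusp-to-cervix along +u this points
#'   into the enamel, +v).
#' @export
point_at_arc <- function(curve, s) {
  curve <- as_polyline(curve)
  ca <- cum_arc(curve)
  s <- pmin(pmax(s, 0), ca[length(ca)])
  k <- pmin(findInterval(s, ca, rightmost.closed = TRUE), nrow(curve) - 1L)
  seg_len <- ca[k + 1L] - ca[k]
  t <- ifelse(seg_len > 0, (s - ca[k]) / seg_len, 0)
  cbind(
    u = curve[k, 1] + t * (curve[k + 1L, 1] - curve[k, 1]),
    v = curve[k, 2] + t * (curve[k + 1L, 2] - curve[k, 2])
  )
}

# point_at_arc with linear extrapolation beyond the curve's ends, using the
# terminal tangents (needed when a tracing is continued past the EDJ)
point_at_arc_ext <- function(curve, s) {
  curve <- as_polyline(curve)
  L <- polyline_length(curve)
  out <- point_at_arc(curve, pmin(pmax(s, 0), L))
  lo <- s < 0
  if (any(lo)) {
    tang <- (curve[2, ] - curve[1, ]) / sqrt(sum((curve[2, ] - curve[1, ])^2))
    out[lo, ] <- rep(curve[1, ], each = sum(lo)) + outer(s[lo], tang)
  }
  hi <- s > L
  if (any(hi)) {
    m <- nrow(curve)
    tang <- (curve[m, ] - curve[m - 1, ]) / sqrt(sum((curve[m, ] - curve[m - 1, ])^2))
    out[hi, ] <- rep(curve[m, ], each = sum(hi)) + outer(s[hi] - L, tang)
  }
  out
}

#' @rdname point_at_arc
#' @export
normal_at_arc <- function(curve, s) {
  curve <- as_polyline(curve)
  ca <- cum_arc(curve)
  s <- pmin(pmax(s, 0), ca[length(ca)])
  k <- pmin(findInterval(s, ca, rightmost.closed = TRUE), nrow(curve) - 1L)
  du <- curve[k + 1L, 1] - curve[k, 1]
  dv <- curve[k + 1L, 2] - curve[k, 2]
  len <- sqrt(du^2 + dv^2)
  cbind(u = -dv / len, v = du / len)
}

#' All crossings of two polylines
#'
#' Exhaustive segment-pair intersection with a bounding-box prefilter.
#' Returns a tibble of proper crossings (touching within `tol` counts as a
#' crossing), with the arc position of each crossing along both inputs.
#'
#' @param a,b Polylines (or coercibles).
#' @param tol Intersection tolerance in micrometres.
#' @return Tibble with columns `u`, `v`, `arc_a`, `arc_b`; zero rows if the
#'   polylines do not cross.
#' @export
intersect_polylines <- function(a, b, tol = 1e-6) {
  a <- as_polyline(a); b <- as_polyline(b)
  a1 <- a[-nrow(a), , drop = FALSE]; a2 <- a[-1L, , drop = FALSE]
  b1 <- b[-nrow(b), , drop = FALSE]; b2 <- b[-1L, , drop = FALSE]
  ca <- cum_arc(a); cb <- cum_arc(b)
  # per-segment bounding boxes
  ax_lo <- pmin(a1[, 1], a2[, 1]) - tol; ax_hi <- pmax(a1[, 1], a2[, 1]) + tol
  ay_lo <- pmin(a1[, 2], a2[, 2]) - tol; ay_hi <- pmax(a1[, 2], a2[, 2]) + tol
  bx_lo <- pmin(b1[, 1], b2[, 1]) - tol; bx_hi <- pmax(b1[, 1], b2[, 1]) + tol
  by_lo <- pmin(b1[, 2], b2[, 2]) - tol; by_hi <- pmax(b1[, 2], b2[, 2]) + tol
  # prune segments outside the other polyline's overall extent before the
  # all-pairs test (digitized tracings are long; crossings are local)
  ia <- which(ax_lo <= max(bx_hi) & ax_hi >= min(bx_lo) &
                ay_lo <= max(by_hi) & ay_hi >= min(by_lo))
  ib <- which(bx_lo <= max(ax_hi[ia], -Inf) & bx_hi >= min(ax_lo[ia], Inf) &
                by_lo <= max(ay_hi[ia], -Inf) & by_hi >= min(ay_lo[ia], Inf))
  empty <- tibble::tibble(u = double(), v = double(),
                          arc_a = double(), arc_b = double())
  if (length(ia) == 0L || length(ib) == 0L) return(empty)
  cand <- which(
    outer(ax_lo[ia], bx_hi[ib], "<=") & outer(ax_hi[ia], bx_lo[ib], ">=") &
      outer(ay_lo[ia], by_hi[ib], "<=") & outer(ay_hi[ia], by_lo[ib], ">="),
    arr.ind = TRUE
  )
  cand <- cbind(ia[cand[, 1]], ib[cand[, 2]])
  if (nrow(cand) == 0L) {
    return(tibble::tibble(u = double(), v = double(), arc_a = double(), arc_b = double()))
  }
  i <- cand[, 1]; j <- cand[, 2]
  r1 <- a2[i, , drop = FALSE] - a1[i, , drop = FALSE]
  r2 <- b2[j, , drop = FALSE] - b1[j, , drop = FALSE]
  den <- r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1]
  w <- b1[j, , drop = FALSE] - a1[i, , drop = FALSE]
  ok <- abs(den) > 1e-12
  t <- ifelse(ok, (w[, 1] * r2[, 2] - w[, 2] * r2[, 1]) / den, NA_real_)
  s <- ifelse(ok, (w[, 1] * r1[, 2] - w[, 2] * r1[, 1]) / den, NA_real_)
  la <- sqrt(r1[, 1]^2 + r1[, 2]^2)
  lb <- sqrt(r2[, 1]^2 + r2[, 2]^2)
  eps_a <- tol / la; eps_b <- tol / lb
  hit <- ok & t >= -eps_a & t <= 1 + eps_a & s >= -eps_b & s <= 1 + eps_b
  if (!any(hit)) {
    return(tibble::tibble(u = double(), v = double(), arc_a = double(), arc_b = double()))
  }
  i <- i[hit]; j <- j[hit]; t <- pmin(pmax(t[hit], 0), 1); s <- pmin(pmax(s[hit], 0), 1)
  out <- tibble::tibble(
    u = a1[i, 1] + t * r1[hit, 1],
    v = a1[i, 2] + t * r1[hit, 2],
    arc_a = ca[i] + t * la[hit],
    arc_b = cb[j] + s * lb[hit]
  )
  # collapse near-duplicate hits at shared segment vertices
  out <- out[order(out$arc_a), , drop = FALSE]
  if (nrow(out) > 1L) {
    keep <- c(TRUE, diff(out$arc_a) > 10 * tol | abs(diff(out$arc_b)) > 10 * tol)
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Intersection of an incremental line with the EDJ
#'
#' Follows an incremental line back to its crossing with the enamel-dentine
#' junction. If the line crosses the EDJ more than once, the most cervical
#' crossing (largest arc position) is returned with a warning.
#'
#' @param line An incremental line (an `increment_line` or bare polyline).
#' @param edj The EDJ curve, oriented cusp to cervix.
#' @param tol Intersection tolerance in micrometres.
#' @return A list with `point` (length-2 named numeric) and `arc`
#'   (micrometres from the cusp tip), or `NULL` if the line does not reach
#'   the EDJ.
#' @export
intersect_with_edj <- function(line, edj, tol = 1e-6) {
  path <- if (inherits(line, "increment_line")) line$path else line
  hits <- intersect_polylines(path, edj, tol = tol)
  if (nrow(hits) == 0L) return(NULL)
  if (nrow(hits) > 1L) {
    warning(sprintf(
      "incremental line crosses the EDJ %d times; using the most cervical crossing",
      nrow(hits)
    ))
  }
  k <- which.max(hits$arc_b)
  list(point = c(u = unname(hits$u[k]), v = unname(hits$v[k])),
       arc = unname(hits$arc_b[k]))
}

# Cast a ray from `origin` along unit `direction` for `length` um and return
# crossings with `path`, ordered by distance from the origin.
ray_crossings <- function(origin, direction, length, path, tol = 1e-6) {
  ray <- rbind(origin, origin + direction * length)
  hits <- intersect_polylines(ray, path, tol = tol)
  hits[order(hits$arc_a), , drop = FALSE]
}
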