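# ---------------------------------------------------------------------------
# Planar geometry primitives.
#
# A "ring" is an unclosed 2-column numeric matrix of (x, y) vertices in km.
# A "geom" is a list of one or more rings treated as disjoint parts
# (a multipolygon without holes). All polygon fixtures the synthetic
# generator emits are hole-free, and dissolved PAs are represented as
# multi-part geoms rather than unioned outlines.
# ---------------------------------------------------------------------------

#' Build a rectangular ring
#'
#' @param x0,y0 lower-left corner (km).
#' @param w,h width and height (km).
#' @return A 4x2 matrix of vertices, counter-clockwise.
#' @export
rect_ring <- function(x0, y0, w, h) {
  stopifnot(w > 0, h > 0)
  cbind(x = c(x0, x0 + w, x0 + w, x0),
        y = c(y0, y0, y0 + h, y0 + h))
}

#' Build a square ring of a given area centred on a point
#'
#' @param cx,cy centre (km).
#' @param area_km2 target area (km^2).
#' @export
square_ring <- function(cx, cy, area_km2) {
  stopifnot(area_km2 > 0)
  s <- sqrt(area_km2)
  rect_ring(cx - s / 2, cy - s / 2, s, s)
}

#' Build a regular-polygon disc of exact area
#'
#' The circumradius is chosen so the *polygon* area equals `area_km2`
#' exactly (a regular n-gon of circumradius r has area n r^2 sin(2 pi/n)/2).
#'
#' @param cx,cy centre (km).
#' @param area_km2 target area (km^2).
#' @param n number of vertices.
#' @export
disc_ring <- function(cx, cy, area_km2, n = 32L) {
  stopifnot(area_km2 > 0, n >= 8L)
  r <- sqrt(2 * area_km2 / (n * sin(2 * pi / n)))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

signed_ring_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  j <- c(seq_len(nrow(ring))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Area of a ring (shoelace formula)
#' @param ring vertex matrix.
#' @return area in the square of the coordinate unit.
#' @export
ring_area <- function(ring) abs(signed_ring_area(ring))

ensure_ccw <- function(ring) {
  if (signed_ring_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

as_geom <- function(g) {
  if (is.matrix(g)) list(g) else g
}

#' Total area of a (multi-part) geometry
#' @param geom a ring matrix or list of ring matrices (disjoint parts).
#' @export
geom_area <- function(geom) sum(vapply(as_geom(geom), ring_area, numeric(1)))

#' Point-in-ring test (ray casting)
#' @param pt length-2 numeric.
#' @param ring vertex matrix.
#' @export
point_in_ring <- function(pt, ring) {
  n <- nrow(ring)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    if ((yi > pt[2L]) != (yj > pt[2L])) {
      xint <- (xj - xi) * (pt[2L] - yi) / (yj - yi) + xi
      if (pt[1L] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Distances from points (k x 2) to segments (m segments given by a ring).
pts_to_ring_dist <- function(pts, ring) {
  n <- nrow(ring)
  j <- c(seq_len(n)[-1L], 1L)
  ax <- ring[, 1L]; ay <- ring[, 2L]
  bx <- ring[j, 1L]; by <- ring[j, 2L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  # outer products: k x m
  px <- pts[, 1L]; py <- pts[, 2L]
  t_num <- outer(px, ax, "-") * rep(dx, each = length(px)) +
           outer(py, ay, "-") * rep(dy, each = length(py))
  tt <- pmin(1, pmax(0, sweep(t_num, 2L, len2, "/")))
  cx <- rep(ax, each = length(px)) + tt * rep(dx, each = length(px))
  cy <- rep(ay, each = length(py)) + tt * rep(dy, each = length(py))
  d2 <- (px - cx)^2 + (py - cy)^2
  sqrt(min(d2))
}

# TRUE if any boundary segment of r1 properly crosses/touches one of r2.
rings_cross <- function(r1, r2) {
  seg_ends <- function(r) {
    n <- nrow(r); j <- c(seq_len(n)[-1L], 1L)
    list(ax = r[, 1L], ay = r[, 2L], bx = r[j, 1L], by = r[j, 2L])
  }
  s1 <- seg_ends(r1); s2 <- seg_ends(r2)
  n1 <- length(s1$ax); n2 <- length(s2$ax)
  i <- rep(seq_len(n1), times = n2)
  k <- rep(seq_len(n2), each = n1)
  ax <- s1$ax[i]; ay <- s1$ay[i]; bx <- s1$bx[i]; by <- s1$by[i]
  cx <- s2$ax[k]; cy <- s2$ay[k]; dx <- s2$bx[k]; dy <- s2$by[k]
  orient <- function(ox, oy, px, py, qx, qy) {
    sign((px - ox) * (qy - oy) - (py - oy) * (qx - ox))
  }
  o1 <- orient(ax, ay, bx, by, cx, cy)
  o2 <- orient(ax, ay, bx, by, dx, dy)
  o3 <- orient(cx, cy, dx, dy, ax, ay)
  o4 <- orient(cx, cy, dx, dy, bx, by)
  any(o1 * o2 <= 0 & o3 * o4 <= 0 &
        # exclude fully collinear-disjoint false positives conservatively:
        !(o1 == 0 & o2 == 0 & o3 == 0 & o4 == 0 &
            (pmax(pmin(ax, bx), pmin(cx, dx)) >
               pmin(pmax(ax, bx), pmax(cx, dx)) + 0 |
             pmax(pmin(ay, by), pmin(cy, dy)) >
               pmin(pmax(ay, by), pmax(cy, dy)))))
}

ring_dist <- function(r1, r2) {
  # cheap bounding-box lower bound first
  b1 <- c(range(r1[, 1L]), range(r1[, 2L]))
  b2 <- c(range(r2[, 1L]), range(r2[, 2L]))
  gx <- max(b1[1L], b2[1L]) - min(b1[2L], b2[2L])
  gy <- max(b1[3L], b2[3L]) - min(b1[4L], b2[4L])
  if (gx <= 0 && gy <= 0) {
    if (rings_cross(r1, r2)) return(0)
    if (point_in_ring(r1[1L, ], r2) || point_in_ring(r2[1L, ], r1)) return(0)
  }
  min(pts_to_ring_dist(r1, r2), pts_to_ring_dist(r2, r1))
}

#' Edge-to-edge distance between two (multi-part) geometries
#'
#' Zero when boundaries touch, cross, or one part contains the other;
#' otherwise the minimum distance between the polygon boundaries.
#'
#' @param g1,g2 ring matrices or lists of ring matrices.
#' @return distance in the coordinate unit (km).
#' @export
geom_dist <- function(g1, g2) {
  d <- Inf
  for (r1 in as_geom(g1)) for (r2 in as_geom(g2)) {
    d <- min(d, ring_dist(r1, r2))
    if (d == 0) return(0)
  }
  d
}

is_convex_ring <- function(ring, tol = 1e-9) {
  r <- ensure_ccw(ring)
  n <- nrow(r)
  i <- seq_len(n)
  j <- c(i[-1L], 1L)
  k <- c(j[-1L], j[1L])
  cr <- (r[j, 1L] - r[i, 1L]) * (r[k, 2L] - r[j, 2L]) -
        (r[j, 2L] - r[i, 2L]) * (r[k, 1L] - r[j, 1L])
  all(cr >= -tol * max(1, max(abs(r))))
}

#' Clip a ring by a convex ring (Sutherland-Hodgman)
#'
#' @param subject ring matrix (any simple polygon).
#' @param clip ring matrix; must be convex.
#' @return the intersection ring matrix, or NULL when empty.
#' @export
clip_ring_convex <- function(subject, clip) {
  clip <- ensure_ccw(clip)
  out <- ensure_ccw(subject)
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    a <- clip[e, ]
    b <- clip[if (e == nc) 1L else e + 1L, ]
    ex <- b[1L] - a[1L]; ey <- b[2L] - a[2L]
    # left half-plane of the CCW clip edge is "inside"
    cross <- ex * (out[, 2L] - a[2L]) - ey * (out[, 1L] - a[1L])
    inside <- cross >= -1e-12
    n <- nrow(out)
    nxt <- c(seq_len(n)[-1L], 1L)
    new_pts <- list()
    for (i in seq_len(n)) {
      p <- out[i, ]; q <- out[nxt[i], ]
      pin <- inside[i]; qin <- inside[nxt[i]]
      if (pin) new_pts[[length(new_pts) + 1L]] <- p
      if (xor(pin, qin)) {
        cp <- cross[i]; cq <- cross[nxt[i]]
        t <- cp / (cp - cq)
        new_pts[[length(new_pts) + 1L]] <- p + t * (q - p)
      }
    }
    if (length(new_pts) < 3L) return(NULL)
    out <- do.call(rbind, new_pts)
    # drop duplicated consecutive vertices
    keep <- c(TRUE, rowSums(abs(diff(out))) > 1e-12)
    if (sum(abs(out[1L, ] - out[nrow(out), ])) <= 1e-12) keep[nrow(out)] <- FALSE
    out <- out[keep, , drop = FALSE]
  }
  if (is.null(out) || nrow(out) < 3L || ring_area(out) <= 1e-12) NULL else out
}

# Exact intersection area of a set of convex rings (iterated clipping).
convex_intersection_area <- function(rings) {
  cur <- rings[[1L]]
  for (r in rings[-1L]) {
    cur <- clip_ring_convex(cur, r)
    if (is.null(cur)) return(0)
  }
  ring_area(cur)
}

#' Union area of a set of convex rings (inclusion-exclusion)
#'
#' Exact for convex members; intended for small overlap groups found
#' during the dissolve step.
#'
#' @param rings list of convex ring matrices.
#' @param max_members guard on the inclusion-exclusion blow-up.
#' @export
convex_union_area <- function(rings, max_members = 14L) {
  k <- length(rings)
  if (k == 1L) return(ring_area(rings[[1L]]))
  if (k > max_members)
    stop("overlap group too large for exact union (", k, " members)")
  if (!all(vapply(rings, is_convex_ring, logical(1))))
    stop("union of overlapping non-convex polygons is not supported")
  total <- 0
  for (m in seq_len(k)) {
    for (comb in utils::combn(k, m, simplify = FALSE)) {
      a <- convex_intersection_area(rings[comb])
      if (a > 0) total <- total + (-1)^(m + 1L) * a
    }
  }
  total
}

# --- Douglas-Peucker simplification ---------------------------------------

dp_chain <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  a <- pts[1L, ]; b <- pts[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) {
    d <- sqrt(rowSums(sweep(pts, 2L, a)^2))
  } else {
    d <- abs((pts[, 1L] - a[1L]) * ab[2L] - (pts[, 2L] - a[2L]) * ab[1L]) / len
  }
  i <- which.max(d)
  if (d[i] <= tol) return(pts[c(1L, n), , drop = FALSE])
  left <- dp_chain(pts[1:i, , drop = FALSE], tol)
  right <- dp_chain(pts[i:n, , drop = FALSE], tol)
  rbind(left[-nrow(left), , drop = FALSE], right)
}

#' Simplify a closed ring (Douglas-Peucker)
#'
#' The ring is split at its two mutually farthest anchor vertices so the
#' classic open-chain algorithm applies to each half.
#'
#' @param ring vertex matrix.
#' @param tol_km tolerance in km (100 m = 0.1).
#' @export
simplify_ring <- function(ring, tol_km) {
  n <- nrow(ring)
  if (n <= 4L || tol_km <= 0) return(ring)
  d1 <- sqrt(rowSums(sweep(ring, 2L, ring[1L, ])^2))
  k <- which.max(d1)
  half1 <- dp_chain(ring[1:k, , drop = FALSE], tol_km)
  half2 <- dp_chain(ring[c(k:n, 1L), , drop = FALSE], tol_km)
  out <- rbind(half1, half2[-c(1L, nrow(half2)), , drop = FALSE])
  if (nrow(out) < 3L) ring else out
}

# --- Geodesic helpers (geosphere-backed) -----------------------------------

WGS84_A <- 6378137
WGS84_F <- 1 / 298.257223563

#' Ellipsoidal Mollweide forward projection
#'
#' Equal-area projection used as the area oracle in geodesic mode: geodetic
#' latitude is converted to authalic latitude, then the spherical Mollweide
#' formulas are applied on the authalic sphere, so ellipsoidal areas are
#' preserved.
#'
#' @param lonlat 2-column matrix of degrees (lon, lat).
#' @param lon0 central meridian, degrees.
#' @return 2-column matrix of (x, y) in km.
#' @export
mollweide_project <- function(lonlat, lon0 = 0) {
  a <- WGS84_A
  f <- WGS84_F
  e2 <- f * (2 - f)
  e <- sqrt(e2)
  qfun <- function(phi) {
    s <- sin(phi)
    (1 - e2) * (s / (1 - e2 * s^2) - (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
  }
  qp <- qfun(pi / 2)
  phi <- lonlat[, 2L] * pi / 180
  beta <- asin(pmin(1, pmax(-1, qfun(phi) / qp)))
  Rq <- a * sqrt(qp / 2)
  # solve 2*theta + sin(2*theta) = pi * sin(beta)
  theta <- beta
  for (i in 1:25) {
    delta <- -(2 * theta + sin(2 * theta) - pi * sin(beta)) / (2 + 2 * cos(2 * theta) + 1e-15)
    theta <- theta + delta
    if (max(abs(delta)) < 1e-13) break
  }
  lam <- (lonlat[, 1L] - lon0) * pi / 180
  x <- Rq * (2 * sqrt(2) / pi) * lam * cos(theta)
  y <- Rq * sqrt(2) * sin(theta)
  cbind(x = x / 1000, y = y / 1000)
}

#' Geodesic circular buffer of a given area
#'
#' Builds an n-vertex geodesic circle around a lon/lat point whose
#' ellipsoidal area equals `area_km2` (secant iteration on the radius
#' against [geosphere::areaPolygon()]).
#'
#' @param lon,lat centre in degrees.
#' @param area_km2 target area.
#' @param n vertices.
#' @param rel_tol relative area tolerance.
#' @return matrix of (lon, lat) vertices, unclosed.
#' @export
geodesic_circle <- function(lon, lat, area_km2, n = 180L, rel_tol = 1e-6) {
  stopifnot(area_km2 > 0)
  bearings <- seq(0, 360, length.out = n + 1L)[-(n + 1L)]
  mk <- function(r_m) geosphere::destPoint(c(lon, lat), bearings, r_m)
  area_of <- function(r_m) geosphere::areaPolygon(mk(r_m)) / 1e6
  r1 <- sqrt(area_km2 / pi) * 1000
  r2 <- r1 * 1.01
  f1 <- area_of(r1) - area_km2
  for (i in 1:30) {
    f2 <- area_of(r2) - area_km2
    if (abs(f2) <= rel_tol * area_km2) break
    r_new <- r2 - f2 * (r2 - r1) / (f2 - f1)
    r1 <- r2; f1 <- f2; r2 <- r_new
  }
  mk(r2)
}
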