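# From raw PA + land/country layers to the abstract network inputs:
# filtering rules, point buffering, dissolve of overlapping designations,
# clipping to land, explosion to single-part nodes with the 1 km^2 floor,
# portion/landmass labelling and the 500 km transboundary selection.

#' Filter raw PA sites by status and reporting rules
#'
#' Drops sites with a "proposed" or "not reported" status, point sites
#' without a positive reported area, and UNESCO Man and the Biosphere
#' reserves. Sites whose IUCN category is missing/"not reported"/"not
#' assigned" are kept. Unknown status strings are retained with a warning.
#'
#' @param pa_layer a [pc_layer()] of raw sites (columns `site_id`, `iso3`,
#'   `status`, `desig_type`, `is_point`, `reported_area`).
#' @return the filtered layer; a `filter_log` attribute counts the drops.
#' @export
filter_sites <- function(pa_layer) {
  status <- tolower(trimws(as.character(pa_layer$status)))
  known <- c("designated", "inscribed", "established", "adopted",
             "proposed", "not reported", "not_reported")
  unknown <- !(status %in% known)
  if (any(unknown))
    warning("unknown PA status retained: ",
            paste(unique(pa_layer$status[unknown]), collapse = ", "))
  drop_status <- status %in% c("proposed", "not reported", "not_reported")
  is_point <- isTRUE_vec(pa_layer$is_point)
  drop_point <- is_point & !(is.finite(pa_layer$reported_area) &
                               pa_layer$reported_area > 0)
  desig <- tolower(as.character(pa_layer$desig_type))
  drop_mab <- grepl("man and the biosphere|unesco-mab|mab", desig)
  keep <- !(drop_status | drop_point | drop_mab)
  out <- pa_layer[keep, , drop = FALSE]
  attr(out, "coord_mode") <- coord_mode(pa_layer)
  attr(out, "filter_log") <- c(dropped_status = sum(drop_status),
                               dropped_point_no_area = sum(drop_point & !drop_status),
                               dropped_mab = sum(drop_mab & !drop_status & !drop_point),
                               kept = sum(keep))
  out
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Replace point sites by circular buffers matching their reported area
#'
#' Planar layers get a regular-polygon disc of exactly the reported area;
#' lon/lat layers get a geodesic circle whose ellipsoidal area matches the
#' reported value (see [geodesic_circle()]).
#'
#' @param pa_layer a filtered [pc_layer()].
#' @return the layer with every point geometry replaced by a polygon.
#' @export
buffer_point_sites <- function(pa_layer) {
  is_point <- isTRUE_vec(pa_layer$is_point)
  for (i in which(is_point)) {
    p <- pa_layer$geometry[[i]][[1L]]
    stopifnot(pa_layer$reported_area[i] > 0)
    if (coord_mode(pa_layer) == "planar_km") {
      g <- disc_ring(p[1L, 1L], p[1L, 2L], pa_layer$reported_area[i])
    } else {
      g <- geodesic_circle(p[1L, 1L], p[1L, 2L], pa_layer$reported_area[i])
    }
    pa_layer$geometry[[i]] <- list(g)
  }
  pa_layer$is_point <- rep(FALSE, nrow(pa_layer))
  pa_layer
}

bbox_of <- function(geom) {
  xs <- unlist(lapply(as_geom(geom), function(r) range(r[, 1L])))
  ys <- unlist(lapply(as_geom(geom), function(r) range(r[, 2L])))
  c(min(xs), max(xs), min(ys), max(ys))
}

bbox_overlap <- function(b1, b2, tol = 0) {
  b1[1L] <= b2[2L] + tol && b2[1L] <= b1[2L] + tol &&
    b1[3L] <= b2[4L] + tol && b2[3L] <= b1[4L] + tol
}

rings_overlap_area <- function(r1, r2) {
  if (!bbox_overlap(bbox_of(r1), bbox_of(r2))) return(0)
  if (is_convex_ring(r1)) convex_intersection_area(list(r2, r1))
  else if (is_convex_ring(r2)) convex_intersection_area(list(r1, r2))
  else stop("overlap of two non-convex polygons is not supported")
}

#' Dissolve overlapping designations and simplify vertices
#'
#' Overlapping site polygons (e.g. the same land designated under several
#' instruments) are grouped into connected overlap components; each
#' component becomes one dissolved feature whose area is the exact union
#' area of its members, so no land is double counted. Member outlines are
#' kept as a multi-part geometry (edge distances take the minimum over
#' members). Rings are vertex-thinned with Douglas-Peucker.
#'
#' @param pa_layer buffered, filtered layer (single-ring polygon sites).
#' @param simplify_km simplification tolerance in km (default 0.1 = 100 m).
#' @return a [pc_layer()] with columns `dis_id`, `site_ids`, `iso3`,
#'   `area_km2`.
#' @export
dissolve_and_simplify <- function(pa_layer, simplify_km = 0.1) {
  n <- nrow(pa_layer)
  if (n == 0L)
    return(pc_layer(data.frame(dis_id = character(), site_ids = character(),
                               iso3 = character(), area_km2 = numeric(),
                               stringsAsFactors = FALSE), list(),
                    mode = coord_mode(pa_layer)))
  rings <- lapply(pa_layer$geometry, function(g) {
    r <- as_geom(g)[[1L]]
    if (nrow(r) < 3L) stop("invalid geometry (fewer than 3 vertices)")
    ensure_ccw(r)
  })
  if (simplify_km > 0)
    rings <- lapply(rings, simplify_ring, tol_km = simplify_km)
  boxes <- lapply(rings, bbox_of)
  # overlap graph: positive intersection area
  edges <- integer(0)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      if (!bbox_overlap(boxes[[a]], boxes[[b]])) next
      if (rings_overlap_area(rings[[a]], rings[[b]]) > 1e-9)
        edges <- c(edges, a, b)
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  out_rows <- list(); out_geoms <- list()
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    mem <- rings[idx]
    area <- if (length(mem) == 1L) ring_area(mem[[1L]]) else convex_union_area(mem)
    out_rows[[length(out_rows) + 1L]] <- data.frame(
      dis_id = sprintf("D%03d", length(out_rows) + 1L),
      site_ids = paste(sort(pa_layer$site_id[idx]), collapse = ";"),
      iso3 = paste(sort(unique(unlist(strsplit(pa_layer$iso3[idx], ";")))),
                   collapse = ";"),
      area_km2 = area, stringsAsFactors = FALSE)
    out_geoms[[length(out_geoms) + 1L]] <- mem
  }
  pc_layer(do.call(rbind, out_rows), out_geoms, mode = coord_mode(pa_layer))
}

#' Clip to land, explode to single parts and apply the minimum-area floor
#'
#' Marine parts (anything outside the non-disputed territories of the land
#' layer) are removed; remaining pieces are regrouped into connected
#' single-part nodes per country; nodes below `min_area_km2` are dropped.
#' Sites listing several ISO3 codes are split between countries by the
#' country boundaries; single-ISO3 sites keep their reported country.
#'
#' @param dissolved output of [dissolve_and_simplify()].
#' @param land_layer [pc_layer()] with `land_id`, `iso3`, `disputed`.
#' @param min_area_km2 minimum retained node area (default 1).
#' @return a [pc_layer()] of nodes: `node_id`, `iso3`, `area_km2`; a
#'   `clip_log` attribute counts drops.
#' @export
clip_explode_filter <- function(dissolved, land_layer, min_area_km2 = 1.0) {
  land <- land_layer[!isTRUE_vec(land_layer$disputed), , drop = FALSE]
  land_rings <- lapply(land$geometry, function(g) as_geom(g)[[1L]])
  land_boxes <- lapply(land_rings, bbox_of)
  pieces <- list()  # each: list(dis_id, iso3, ring)
  n_sea_dropped <- 0L
  for (i in seq_len(nrow(dissolved))) {
    multi_iso <- grepl(";", dissolved$iso3[i])
    any_land <- FALSE
    for (r in dissolved$geometry[[i]]) {
      rb <- bbox_of(r)
      for (t in seq_along(land_rings)) {
        if (!bbox_overlap(rb, land_boxes[[t]])) next
        piece <- clip_ring_convex(r, land_rings[[t]])
        if (is.null(piece)) next
        any_land <- TRUE
        pieces[[length(pieces) + 1L]] <- list(
          dis_id = dissolved$dis_id[i],
          iso3 = if (multi_iso) land$iso3[t] else dissolved$iso3[i],
          ring = piece)
      }
    }
    if (!any_land) n_sea_dropped <- n_sea_dropped + 1L
  }
  if (length(pieces) == 0L)
    return(pc_layer(data.frame(node_id = character(), iso3 = character(),
                               area_km2 = numeric(), stringsAsFactors = FALSE),
                    list(), mode = coord_mode(dissolved)))
  # regroup touching pieces of the same dissolved feature and country
  key <- vapply(pieces, function(p) paste(p$dis_id, p$iso3, sep = "|"), character(1))
  node_rows <- list(); node_geoms <- list()
  n_small_dropped <- 0L
  for (k in sort(unique(key))) {
    idx <- which(key == k)
    rings <- lapply(pieces[idx], `[[`, "ring")
    m <- length(rings)
    adj <- integer(0)
    if (m > 1L) {
      for (a in seq_len(m - 1L)) for (b in (a + 1L):m)
        if (geom_dist(rings[[a]], rings[[b]]) <= 1e-9) adj <- c(adj, a, b)
    }
    comp <- igraph::components(igraph::make_graph(adj, n = m, directed = FALSE))$membership
    for (cid in sort(unique(comp))) {
      mem <- rings[comp == cid]
      overlapping <- FALSE
      if (length(mem) > 1L) {
        for (a in seq_len(length(mem) - 1L)) for (b in (a + 1L):length(mem))
          if (rings_overlap_area(mem[[a]], mem[[b]]) > 1e-9) overlapping <- TRUE
      }
      area <- if (overlapping) convex_union_area(mem)
              else sum(vapply(mem, ring_area, numeric(1)))
      if (area < min_area_km2) { n_small_dropped <- n_small_dropped + 1L; next }
      node_rows[[length(node_rows) + 1L]] <- data.frame(
        node_id = "", iso3 = pieces[[idx[1L]]]$iso3, area_km2 = area,
        stringsAsFactors = FALSE)
      node_geoms[[length(node_geoms) + 1L]] <- mem
    }
  }
  if (length(node_rows) == 0L)
    return(pc_layer(data.frame(node_id = character(), iso3 = character(),
                               area_km2 = numeric(), stringsAsFactors = FALSE),
                    list(), mode = coord_mode(dissolved)))
  nodes <- do.call(rbind, node_rows)
  ord <- order(nodes$iso3, -nodes$area_km2)
  nodes <- nodes[ord, , drop = FALSE]
  node_geoms <- node_geoms[ord]
  nodes$node_id <- stats::ave(seq_len(nrow(nodes)), nodes$iso3,
                              FUN = seq_along)
  nodes$node_id <- sprintf("%s_%03d", nodes$iso3, nodes$node_id)
  rownames(nodes) <- NULL
  out <- pc_layer(nodes, node_geoms, mode = coord_mode(dissolved))
  attr(out, "clip_log") <- c(dropped_at_sea = n_sea_dropped,
                             dropped_small = n_small_dropped,
                             kept = nrow(nodes))
  out
}

#' Label nodes with land-portion and landmass membership
#'
#' A landmass is a connected component of all land polygons (contiguity =
#' boundary distance at most `contig_tol`); a land portion is a connected
#' component of one country's land, so two portions of a country differ
#' when separated by sea or by foreign territory. Each node inherits the
#' labels of the land polygon it overlaps most (majority area; ties broken
#' by lexicographic ISO3).
#'
#' @param nodes node layer from [clip_explode_filter()].
#' @param land_layer the land/country layer.
#' @param contig_tol land contiguity tolerance in km (default 0, meaning
#'   touching).
#' @return nodes with `portion_id` and `landmass_id` columns.
#' @export
label_portions_landmasses <- function(nodes, land_layer, contig_tol = 0) {
  land_rings <- lapply(land_layer$geometry, function(g) as_geom(g)[[1L]])
  nl <- length(land_rings)
  # landmass components over all land
  edges <- integer(0)
  if (nl > 1L) {
    for (a in seq_len(nl - 1L)) for (b in (a + 1L):nl)
      if (geom_dist(land_rings[[a]], land_rings[[b]]) <= contig_tol + 1e-9)
        edges <- c(edges, a, b)
  }
  lm_comp <- igraph::components(igraph::make_graph(edges, n = nl,
                                                   directed = FALSE))$membership
  landmass_id <- sprintf("LM%d", lm_comp)
  # portion components per country over non-disputed land
  portion_id <- rep(NA_character_, nl)
  not_disp <- !isTRUE_vec(land_layer$disputed)
  for (iso in sort(unique(land_layer$iso3[not_disp]))) {
    idx <- which(land_layer$iso3 == iso & not_disp)
    e2 <- integer(0)
    if (length(idx) > 1L) {
      for (a in seq_len(length(idx) - 1L)) for (b in (a + 1L):length(idx))
        if (geom_dist(land_rings[[idx[a]]], land_rings[[idx[b]]]) <= contig_tol + 1e-9)
          e2 <- c(e2, a, b)
    }
    pc <- igraph::components(igraph::make_graph(e2, n = length(idx),
                                                directed = FALSE))$membership
    portion_id[idx] <- sprintf("%s_P%d", iso, pc)
  }
  # majority-area assignment of nodes to land polygons
  land_boxes <- lapply(land_rings, bbox_of)
  nodes$portion_id <- NA_character_
  nodes$landmass_id <- NA_character_
  for (i in seq_len(nrow(nodes))) {
    best <- 0; best_t <- NA_integer_
    nb <- bbox_of(nodes$geometry[[i]])
    for (t in seq_len(nl)) {
      if (is.na(portion_id[t])) next
      if (!bbox_overlap(nb, land_boxes[[t]], tol = 1e-9)) next
      ov <- sum(vapply(nodes$geometry[[i]], function(r)
        rings_overlap_area(r, land_rings[[t]]), numeric(1)))
      if (ov > best + 1e-12 ||
          (abs(ov - best) <= 1e-12 && ov > 0 && !is.na(best_t) &&
             land_layer$iso3[t] < land_layer$iso3[best_t])) {
        best <- ov; best_t <- t
      }
    }
    if (is.na(best_t) || best <= 0)
      stop("node ", nodes$node_id[i], " lies on no land polygon (clip failed upstream)")
    nodes$portion_id[i] <- portion_id[best_t]
    nodes$landmass_id[i] <- landmass_id[best_t]
  }
  nodes
}

#' Pairwise edge-to-edge distance matrix between nodes
#'
#' @param nodes node layer (with geometries, in one planar projection).
#' @return symmetric matrix in km, dimnames = node ids.
#' @export
pairwise_edge_distances <- function(nodes) {
  n <- nrow(nodes)
  d <- matrix(0, n, n, dimnames = list(nodes$node_id, nodes$node_id))
  if (n < 2L) return(d)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    d[a, b] <- d[b, a] <- geom_dist(nodes$geometry[[a]], nodes$geometry[[b]])
  }
  d
}

#' Select transboundary nodes within a buffer of the focal country's PAs
#'
#' A foreign node is kept when its edge-to-edge distance to the nearest
#' focal PA is at most `buffer_km` (equivalently, it intersects the
#' `buffer_km` buffer around the focal PAs). Focal nodes are never flagged.
#'
#' @param nodes labelled node layer (all countries).
#' @param focal_iso3 focal country code.
#' @param buffer_km buffer distance (default 500).
#' @param dist optional precomputed distance matrix over `nodes`.
#' @return node layer restricted to the focal network, with an
#'   `is_transboundary` column; zero focal nodes give an empty layer with
#'   attribute `empty_network = TRUE`.
#' @export
select_transboundary <- function(nodes, focal_iso3, buffer_km = 500,
                                 dist = NULL) {
  focal <- nodes$iso3 == focal_iso3
  if (!any(focal)) {
    out <- nodes[integer(0), , drop = FALSE]
    out$is_transboundary <- logical(0)
    attr(out, "empty_network") <- TRUE
    return(out)
  }
  keep <- focal
  for (i in which(!focal)) {
    dmin <- if (!is.null(dist)) min(dist[i, focal]) else
      min(vapply(which(focal), function(f)
        geom_dist(nodes$geometry[[i]], nodes$geometry[[f]]), numeric(1)))
    if (dmin <= buffer_km + 1e-9) keep[i] <- TRUE
  }
  out <- nodes[keep, , drop = FALSE]
  attr(out, "coord_mode") <- coord_mode(nodes)
  out$is_transboundary <- out$iso3 != focal_iso3
  attr(out, "empty_network") <- FALSE
  out
}

#' Country context: land area and portion table
#'
#' @param land_layer the land/country layer.
#' @param iso3 country code.
#' @param region optional region label carried through to aggregation.
#' @return list with `iso3`, `A_L` (km^2, disputed territories excluded),
#'   `portions` (portion/landmass table) and `region`.
#' @export
country_context <- function(land_layer, iso3, region = NA_character_) {
  not_disp <- !isTRUE_vec(land_layer$disputed)
  idx <- which(land_layer$iso3 == iso3 & not_disp)
  if (length(idx) == 0L) stop("no land for country ", iso3)
  A_L <- sum(vapply(idx, function(i) geom_area(land_layer$geometry[[i]]),
                    numeric(1)))
  if (A_L <= 0) stop("country land area must be positive for ", iso3)
  lab <- label_portions_landmasses(
    pc_layer(data.frame(node_id = sprintf("ctx%d", seq_along(idx)),
                        iso3 = iso3,
                        area_km2 = NA_real_, stringsAsFactors = FALSE),
             lapply(idx, function(i) land_layer$geometry[[i]]),
             mode = coord_mode(land_layer)),
    land_layer)
  portions <- unique(data.frame(portion_id = lab$portion_id,
                                landmass_id = lab$landmass_id,
                                stringsAsFactors = FALSE))
  list(iso3 = iso3, A_L = A_L, portions = portions, region = region)
}

#' Preprocess raw layers into a country's network inputs
#'
#' Full chain: filter sites, buffer points, dissolve + simplify, clip to
#' land and explode, label portions/landmasses, select transboundary nodes
#' within the buffer, compute edge-to-edge distances.
#'
#' @param pa_layer raw PA layer.
#' @param land_layer land/country layer.
#' @param iso3 focal country.
#' @param min_area_km2,buffer_km,simplify_km,contig_tol the preprocessing
#'   parameters (defaults 1, 500, 0.1, 0).
#' @return list with `nodes` (focal + transboundary, labelled), `dist`
#'   (km matrix), `context` and `log` (filter/clip counters).
#' @export
preprocess_country <- function(pa_layer, land_layer, iso3,
                               min_area_km2 = 1, buffer_km = 500,
                               simplify_km = 0.1, contig_tol = 0) {
  filt <- filter_sites(pa_layer)
  filt <- buffer_point_sites(filt)
  dis <- dissolve_and_simplify(filt, simplify_km = simplify_km)
  nodes <- clip_explode_filter(dis, land_layer, min_area_km2 = min_area_km2)
  log <- c(attr(filt, "filter_log"), attr(nodes, "clip_log"))
  if (nrow(nodes) > 0L)
    nodes <- label_portions_landmasses(nodes, land_layer, contig_tol = contig_tol)
  net_nodes <- select_transboundary(nodes, iso3, buffer_km = buffer_km)
  d <- pairwise_edge_distances(net_nodes)
  list(nodes = net_nodes, dist = d,
       context = country_context(land_layer, iso3), log = log)
}
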