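# Lightweight vector layers: a data.frame of attributes plus a `geometry`
# list-column (each element a list of rings, or a 1-row matrix for point
# sites). Coordinates are planar km in synthetic mode, lon/lat degrees in
# geodesic mode; the mode travels with the layer.

#' Construct a vector layer
#'
#' @param df attribute data.frame.
#' @param geometry list of geometries (ring matrix, list of ring matrices,
#'   or a 1-row matrix for a point).
#' @param mode `"planar_km"` or `"lonlat"`.
#' @return `df` with a `geometry` list-column and a `coord_mode` attribute.
#' @export
pc_layer <- function(df, geometry, mode = "planar_km") {
  stopifnot(nrow(df) == length(geometry))
  mode <- match.arg(mode, c("planar_km", "lonlat"))
  df$geometry <- lapply(geometry, as_geom)
  attr(df, "coord_mode") <- mode
  class(df) <- c("pc_layer", class(df))
  df
}

#' @export
print.pc_layer <- function(x, ...) {
  cat("<pc_layer> ", nrow(x), " features, mode=", attr(x, "coord_mode"), "\n", sep = "")
  print(as.data.frame(x[, setdiff(names(x), "geometry"), drop = FALSE]), ...)
  invisible(x)
}

coord_mode <- function(layer) attr(layer, "coord_mode") %||% "planar_km"

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x) sprintf("%.15g", x)

#' Write a layer to GeoJSON
#'
#' Deterministic output (fixed number formatting) so identical inputs give
#' byte-identical files. Point features become GeoJSON Points, single-ring
#' geometries Polygons, multi-ring geometries MultiPolygons (each ring an
#' independent part; holes are not used by this package).
#'
#' @param layer a [pc_layer()].
#' @param path output file.
#' @export
write_geojson <- function(layer, path) {
  attrs <- as.data.frame(layer)[, setdiff(names(layer), "geometry"), drop = FALSE]
  feats <- vapply(seq_len(nrow(layer)), function(i) {
    g <- layer$geometry[[i]]
    is_point <- length(g) == 1L && is.matrix(g[[1L]]) && nrow(g[[1L]]) == 1L
    if (is_point) {
      gj <- sprintf('{"type":"Point","coordinates":[%s,%s]}',
                    fmt_num(g[[1L]][1, 1]), fmt_num(g[[1L]][1, 2]))
    } else {
      ring_txt <- vapply(g, function(r) {
        rc <- rbind(r, r[1L, ])
        sprintf("[[%s]]", paste(sprintf("[%s,%s]", fmt_num(rc[, 1L]), fmt_num(rc[, 2L])),
                                collapse = ","))
      }, character(1))
      if (length(g) == 1L) {
        gj <- sprintf('{"type":"Polygon","coordinates":%s}', ring_txt[[1L]])
      } else {
        gj <- sprintf('{"type":"MultiPolygon","coordinates":[%s]}',
                      paste(ring_txt, collapse = ","))
      }
    }
    props <- jsonlite::toJSON(as.list(attrs[i, , drop = FALSE]),
                              auto_unbox = TRUE, digits = NA, null = "null")
    sprintf('{"type":"Feature","properties":%s,"geometry":%s}', props, gj)
  }, character(1))
  txt <- sprintf('{"type":"FeatureCollection","coordinate_mode":"%s","features":[%s]}',
                 coord_mode(layer), paste(feats, collapse = ","))
  writeLines(txt, path)
  invisible(path)
}

#' Read a layer from GeoJSON written by [write_geojson()]
#' @param path input file.
#' @return a [pc_layer()].
#' @export
read_geojson <- function(path) {
  j <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = FALSE)
  stopifnot(identical(j$type, "FeatureCollection"))
  mode <- j$coordinate_mode %||% "planar_km"
  feats <- j$features
  geoms <- vector("list", length(feats))
  rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    g <- f$geometry
    to_ring <- function(coords) {
      m <- do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
      if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      colnames(m) <- c("x", "y")
      m
    }
    geoms[[i]] <- switch(g$type,
      Point = list(matrix(c(g$coordinates[[1L]], g$coordinates[[2L]]), nrow = 1L,
                          dimnames = list(NULL, c("x", "y")))),
      Polygon = list(to_ring(g$coordinates[[1L]])),
      MultiPolygon = lapply(g$coordinates, function(p) to_ring(p[[1L]])),
      stop("unsupported GeoJSON geometry type: ", g$type))
    rows[[i]] <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  pc_layer(df, geoms, mode = mode)
}
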