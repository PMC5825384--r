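# Shared fixtures and independent oracles, built in code at test time.

# Quick node-layer constructor for network-level tests (bypasses the
# geometry preprocessing; geometries optional).
make_nodes <- function(area, iso3 = "AAA", portion = "AAA_P1",
                       landmass = "LM1", trans = FALSE, geoms = NULL) {
  n <- length(area)
  df <- data.frame(node_id = sprintf("N%02d", seq_len(n)),
                   iso3 = rep_len(iso3, n), area_km2 = area,
                   portion_id = rep_len(portion, n),
                   landmass_id = rep_len(landmass, n),
                   is_transboundary = rep_len(trans, n),
                   stringsAsFactors = FALSE)
  if (is.null(geoms)) geoms <- replicate(n, rect_ring(0, 0, 1, 1), simplify = FALSE)
  protconn::pc_layer(df, geoms)
}

dist_from_matrix <- function(m, ids = sprintf("N%02d", seq_len(nrow(m)))) {
  dimnames(m) <- list(ids, ids)
  m
}

# Independent maximum-product oracle: exhaustive DFS over all simple paths.
brute_pstar <- function(pmat) {
  n <- nrow(pmat)
  out <- diag(1, n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    best <- 0
    visited <- rep(FALSE, n)
    dfs <- function(v, prod) {
      if (v == t) { best <<- max(best, prod); return(invisible()) }
      visited[v] <<- TRUE
      for (w in seq_len(n)) {
        if (!visited[w] && pmat[v, w] > 0) dfs(w, prod * pmat[v, w])
      }
      visited[v] <<- FALSE
    }
    dfs(s, 1)
    out[s, t] <- out[t, s] <- best
  }
  out
}

# Random admissible single-portion network expressed directly as links.
random_link_graph <- function(n, edge_prob = 0.35) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < edge_prob
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(i = pairs[, 1L], j = pairs[, 2L],
             d_km = stats::runif(nrow(pairs), 0, 60),
             p = stats::runif(nrow(pairs), 0.05, 1))
}

# Densified-boundary brute-force oracle for polygon edge distance.
densified_min_dist <- function(r1, r2, step = 0.02) {
  densify <- function(r) {
    n <- nrow(r)
    pts <- list()
    for (i in seq_len(n)) {
      a <- r[i, ]; b <- r[if (i == n) 1L else i + 1L, ]
      k <- max(2L, ceiling(sqrt(sum((b - a)^2)) / step))
      tt <- seq(0, 1, length.out = k)
      pts[[i]] <- cbind(a[1L] + tt * (b[1L] - a[1L]), a[2L] + tt * (b[2L] - a[2L]))
    }
    do.call(rbind, pts)
  }
  p1 <- densify(r1); p2 <- densify(r2)
  d2 <- outer(p1[, 1L], p2[, 1L], "-")^2 + outer(p1[, 2L], p2[, 2L], "-")^2
  sqrt(min(d2))
}

# Indicator rows built directly from components, for classification tests.
make_indicator_row <- function(iso3, protconn_value, sea = 0, outland = 0,
                               design = 0, within = 100, contig = 0,
                               unprot = 0, trans = 0, d_med = 10) {
  none <- protconn_value <= 0
  if (none) within <- contig <- unprot <- trans <- 0
  assemble_indicator_set(iso3, d_med, protconn_value, sea, outland, design,
                         within, contig, unprot, trans,
                         no_connected_land = none)
}
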