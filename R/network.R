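# The probabilistic PA graph. Direct dispersal between two PAs follows a
# negative-exponential kernel calibrated so p = 0.5 at the median dispersal
# distance d_med; best-path probabilities are maximum products over paths
# (shortest paths on -log p weights); connectivity is summarised by the
# Equivalent Connected Area ECA = sqrt(sum_ij a_i a_j p*_ij), with
# transboundary PAs carrying attribute 0 so they act only as stepping
# stones.

#' Negative-exponential dispersal kernel
#'
#' `p(d) = 0.5^(d / d_med)`: probability 1 at distance 0 and 0.5 at the
#' median dispersal distance.
#'
#' @param distance_km edge-to-edge distance(s), km; must be non-negative.
#' @param d_med median dispersal distance, km; must be positive.
#' @return dispersal probability in `[0, 1]`.
#' @export
kernel_probability <- function(distance_km, d_med) {
  if (any(!is.finite(d_med)) || any(d_med <= 0))
    stop("d_med must be positive")
  if (any(distance_km < 0)) stop("distance must be non-negative")
  0.5^(distance_km / d_med)
}

NETWORK_SCENARIOS <- c("WITHIN", "CONTIG", "COUNTRY", "FULL")

#' Admissible links of a scenario network
#'
#' A link i-j is admissible iff (a) i and j lie on the same landmass (the
#' sea is an absolute barrier to terrestrial movement), (b) they share a
#' land portion or at least one endpoint is a transboundary protected node
#' (direct links between focal PAs across unprotected foreign land are
#' barred; foreign protected stepping stones may bridge portions), and (c)
#' the scenario allows the link class: `WITHIN` has no links, `CONTIG` only
#' focal-focal links at contiguity distance, `COUNTRY` all admissible
#' focal-focal links, `FULL` adds links involving transboundary nodes.
#'
#' @param nodes labelled node layer (`portion_id`, `landmass_id`,
#'   `is_transboundary`).
#' @param dist distance matrix (km) over `nodes`.
#' @param scenario one of `"WITHIN"`, `"CONTIG"`, `"COUNTRY"`, `"FULL"`.
#' @param d_med median dispersal distance (km).
#' @param contig_tol contiguity tolerance (km, default 0).
#' @param prune_p links weaker than this probability are discarded.
#' @return data.frame with columns `i`, `j` (row indices), `d_km`, `p`.
#' @export
admissible_links <- function(nodes, dist, scenario, d_med, contig_tol = 0,
                             prune_p = 1e-6) {
  if (!scenario %in% NETWORK_SCENARIOS)
    stop("unknown scenario: ", scenario)
  n <- nrow(nodes)
  out <- data.frame(i = integer(), j = integer(), d_km = numeric(),
                    p = numeric())
  if (scenario == "WITHIN" || n < 2L) return(out)
  trans <- isTRUE_vec(nodes$is_transboundary)
  ii <- jj <- integer(0); dd <- numeric(0)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (nodes$landmass_id[a] != nodes$landmass_id[b]) next        # (a) sea
    same_portion <- nodes$portion_id[a] == nodes$portion_id[b]
    any_trans <- trans[a] || trans[b]
    if (!same_portion && !any_trans) next                         # (b) foreign land
    if (scenario == "CONTIG") {
      if (any_trans) next
      if (dist[a, b] > contig_tol + 1e-9) next
    } else if (scenario == "COUNTRY") {
      if (any_trans) next
    }
    ii <- c(ii, a); jj <- c(jj, b); dd <- c(dd, dist[a, b])
  }
  p <- kernel_probability(dd, d_med)
  keep <- p >= prune_p
  data.frame(i = ii[keep], j = jj[keep], d_km = dd[keep], p = p[keep])
}

#' Maximum-product path probabilities
#'
#' `p*_ij` is the maximum over paths of the product of link probabilities,
#' computed exactly as shortest paths on `-log p` weights; `p*_ii = 1` and
#' `p*_ij = 0` for disconnected pairs.
#'
#' @param n_nodes number of nodes.
#' @param links data.frame from [admissible_links()].
#' @return symmetric `n x n` matrix.
#' @export
max_product_paths <- function(n_nodes, links) {
  pstar <- diag(1, n_nodes)
  if (n_nodes == 0L || nrow(links) == 0L) return(pstar)
  g <- igraph::make_graph(rbind(links$i, links$j), n = n_nodes,
                          directed = FALSE)
  w <- -log(links$p)
  w[w < 0] <- 0   # guard against -0 from p = 1
  dmat <- igraph::distances(g, weights = w, algorithm = "dijkstra")
  p <- exp(-dmat)
  p[is.infinite(dmat)] <- 0
  diag(p) <- 1
  p
}

#' Build a scenario network
#'
#' @param nodes labelled node layer (focal + transboundary).
#' @param dist distance matrix (km).
#' @param d_med median dispersal distance (km).
#' @param scenario link-class scenario (default `"FULL"`).
#' @param contig_tol contiguity tolerance (km).
#' @return object of class `pa_network`: nodes, links, `pstar`, counts
#'   `n` (focal) and `t` (transboundary).
#' @export
pa_network <- function(nodes, dist, d_med, scenario = "FULL",
                       contig_tol = 0) {
  links <- admissible_links(nodes, dist, scenario, d_med,
                            contig_tol = contig_tol)
  pstar <- max_product_paths(nrow(nodes), links)
  trans <- isTRUE_vec(nodes$is_transboundary)
  structure(list(nodes = nodes, links = links, pstar = pstar,
                 d_med = d_med, scenario = scenario,
                 n = sum(!trans), t = sum(trans)),
            class = "pa_network")
}

#' @export
print.pa_network <- function(x, ...) {
  cat("<pa_network> scenario=", x$scenario, " d_med=", x$d_med,
      " km; n=", x$n, " focal + t=", x$t, " transboundary nodes, ",
      nrow(x$links), " links\n", sep = "")
  invisible(x)
}

#' Equivalent Connected Area of a network
#'
#' `ECA = sqrt(sum_ij a_i a_j p*_ij)` over all focal and transboundary
#' nodes, where the attribute `a` is the PA area for focal nodes and 0 for
#' transboundary nodes, and the `i = j` terms (intra-PA connectivity) are
#' included. ECA is the area of a single PA that would provide the same
#' connectivity value as the whole network.
#'
#' @param network a [pa_network()].
#' @return ECA in km^2 (0 for a network without focal nodes).
#' @export
equivalent_connected_area <- function(network) {
  nodes <- network$nodes
  if (nrow(nodes) == 0L) return(0)
  a <- ifelse(isTRUE_vec(nodes$is_transboundary), 0, nodes$area_km2)
  if (all(a == 0)) return(0)
  sqrt(max(0, drop(t(a) %*% network$pstar %*% a)))
}

# --- Conefor-style plain-text network files --------------------------------

#' Write Conefor-style node and connection files
#'
#' Nodes file: `node_index attribute` (attribute = area for focal nodes, 0
#' for transboundary). Connections file: `id1 id2 distance_km`. A side CSV
#' keeps the node ids and portion/landmass labels.
#'
#' @param nodes labelled node layer.
#' @param dist distance matrix (km).
#' @param prefix path prefix; writes `<prefix>_nodes.txt`,
#'   `<prefix>_connections.txt`, `<prefix>_labels.csv`.
#' @export
write_conefor <- function(nodes, dist, prefix) {
  trans <- isTRUE_vec(nodes$is_transboundary)
  attr_val <- ifelse(trans, 0, nodes$area_km2)
  idx <- seq_len(nrow(nodes))
  writeLines(sprintf("%d %.10g", idx, attr_val),
             paste0(prefix, "_nodes.txt"))
  lines <- character(0)
  if (nrow(nodes) > 1L) {
    for (a in seq_len(nrow(nodes) - 1L)) for (b in (a + 1L):nrow(nodes))
      lines <- c(lines, sprintf("%d %d %.10g", a, b, dist[a, b]))
  }
  writeLines(lines, paste0(prefix, "_connections.txt"))
  lab <- data.frame(index = idx, node_id = nodes$node_id, iso3 = nodes$iso3,
                    area_km2 = nodes$area_km2,
                    portion_id = nodes$portion_id %||% NA_character_,
                    landmass_id = nodes$landmass_id %||% NA_character_,
                    is_transboundary = trans, stringsAsFactors = FALSE)
  utils::write.csv(lab, paste0(prefix, "_labels.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read Conefor-style network files
#'
#' @param prefix path prefix used by [write_conefor()].
#' @return list with `nodes` (data.frame) and `dist` (matrix, km).
#' @export
read_conefor <- function(prefix) {
  nd <- utils::read.table(paste0(prefix, "_nodes.txt"),
                          col.names = c("index", "attribute"))
  lab_path <- paste0(prefix, "_labels.csv")
  if (file.exists(lab_path)) {
    lab <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
    nodes <- lab[order(lab$index), , drop = FALSE]
  } else {
    nodes <- data.frame(index = nd$index,
                        node_id = sprintf("N%03d", nd$index),
                        iso3 = NA_character_, area_km2 = nd$attribute,
                        portion_id = "P1", landmass_id = "LM1",
                        is_transboundary = nd$attribute == 0,
                        stringsAsFactors = FALSE)
  }
  n <- nrow(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes$node_id, nodes$node_id))
  diag(d) <- 0
  cn <- paste0(prefix, "_connections.txt")
  if (file.size(cn) > 0) {
    cc <- utils::read.table(cn, col.names = c("i", "j", "d_km"))
    for (r in seq_len(nrow(cc))) {
      d[cc$i[r], cc$j[r]] <- d[cc$j[r], cc$i[r]] <- cc$d_km[r]
    }
  }
  list(nodes = nodes, dist = d)
}
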