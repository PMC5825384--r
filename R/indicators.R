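# The Protected Connected indicator family for one country and one median
# dispersal distance:
#   Prot        = 100 * sum(a_i) / A_L
#   ProtConn    = 100 * ECA(FULL network) / A_L
#   ProtUnconn  = Prot - ProtConn, partitioned by cause through two
#                 intermediate network levels:
#     portion level  (per-portion ECAs, foreign stepping stones allowed)
#                    -> ProtConn_Bound = 100 * sum_g ECA_g / A_L
#     landmass level (per-landmass ECAs)
#                    -> ProtConn_LM    = 100 * sum_m ECA_m / A_L
#     ProtUnconn[Design]  = Prot - ProtConn_Bound
#     ProtUnconn[Outland] = ProtConn_Bound - ProtConn_LM
#     ProtUnconn[Sea]     = ProtConn_LM - ProtConn
#   so Sea + Outland + Design telescopes to ProtUnconn exactly.
# The four ProtConn fractions come from the nested WITHIN / CONTIG /
# COUNTRY / FULL scenario networks.

INDICATOR_COLUMNS <- c("iso3", "d_med", "prot", "protconn", "protconn_bound",
                       "protunconn", "protunconn_sea", "protunconn_outland",
                       "protunconn_design", "protconn_within",
                       "protconn_contig", "protconn_unprot",
                       "protconn_trans", "no_connected_land")

#' PA coverage of a country
#'
#' @param nodes node layer (focal + transboundary; transboundary nodes do
#'   not count towards coverage).
#' @param context a [country_context()].
#' @return percent of the country land area covered by PAs.
#' @export
prot <- function(nodes, context) {
  if (context$A_L <= 0) stop("country land area must be positive")
  focal <- !isTRUE_vec(nodes$is_transboundary)
  100 * sum(nodes$area_km2[focal]) / context$A_L
}

#' ProtConn of a FULL-scenario network
#'
#' @param network a [pa_network()] built with scenario `"FULL"`.
#' @param context a [country_context()].
#' @return percent of the country land area that is protected and connected.
#' @export
protconn <- function(network, context) {
  100 * equivalent_connected_area(network) / context$A_L
}

#' The four ProtConn fractions from the nested scenario networks
#'
#' With `P_k` the ProtConn value of the WITHIN, CONTIG, COUNTRY and FULL
#' networks: Within = 100 P1/P4, Contig = 100 (P2-P1)/P4,
#' Unprot = 100 (P3-P2)/P4, Trans = 100 (P4-P3)/P4; they sum to 100 when
#' ProtConn > 0, and are reported as flagged zeros otherwise.
#'
#' @param p_within,p_contig,p_country,p_full the four nested ProtConn
#'   values (percent of land area).
#' @return list with the four fractions and `no_connected_land`.
#' @export
protconn_fractions <- function(p_within, p_contig, p_country, p_full) {
  if (p_full <= 0)
    return(list(within = 0, contig = 0, unprot = 0, trans = 0,
                no_connected_land = TRUE))
  fr <- 100 * unname(c(p_within, p_contig - p_within, p_country - p_contig,
                       p_full - p_country)) / unname(p_full)
  if (any(fr < -1e-9))
    stop("negative ProtConn fraction: scenario networks are not nested")
  list(within = fr[1L], contig = fr[2L], unprot = fr[3L], trans = fr[4L],
       no_connected_land = FALSE)
}

# ECA of the subnetwork induced by a node subset, FULL admissibility.
subnetwork_eca <- function(nodes, dist, keep, d_med, contig_tol) {
  sub <- nodes[keep, , drop = FALSE]
  attr(sub, "coord_mode") <- coord_mode(nodes)
  net <- pa_network(sub, dist[keep, keep, drop = FALSE], d_med,
                    scenario = "FULL", contig_tol = contig_tol)
  equivalent_connected_area(net)
}

#' Partition of protected-not-connected land by cause
#'
#' Computes the portion-level and landmass-level ECA sums and derives
#' ProtConn_Bound and the Sea / Outland / Design fractions of ProtUnconn
#' (all as percent of the country land area). Per-portion subnetworks
#' include the transboundary nodes of the same landmass, so foreign
#' stepping stones can still contribute within a portion.
#'
#' @param nodes labelled node layer (focal + transboundary).
#' @param dist distance matrix (km).
#' @param context a [country_context()].
#' @param d_med median dispersal distance (km).
#' @param protconn_value the FULL-network ProtConn (percent).
#' @param prot_value the Prot coverage (percent).
#' @param contig_tol contiguity tolerance (km).
#' @return list with `bound`, `sea`, `outland`, `design` (percent).
#' @export
protunconn_partition <- function(nodes, dist, context, d_med,
                                 protconn_value, prot_value,
                                 contig_tol = 0) {
  focal <- !isTRUE_vec(nodes$is_transboundary)
  trans <- !focal
  if (!any(focal))
    return(list(bound = 0, sea = 0, outland = 0, design = 0))
  eca_sum <- function(group_by) {
    groups <- sort(unique(group_by[focal]))
    total <- 0
    for (g in groups) {
      in_group <- focal & group_by == g
      lm <- unique(nodes$landmass_id[in_group])
      keep <- in_group | (trans & nodes$landmass_id %in% lm)
      total <- total + subnetwork_eca(nodes, dist, keep, d_med, contig_tol)
    }
    total
  }
  bound <- 100 * eca_sum(nodes$portion_id) / context$A_L
  lm_level <- 100 * eca_sum(nodes$landmass_id) / context$A_L
  # guard the ordering ProtConn <= LM <= Bound <= Prot against violations
  tol <- 1e-9 * max(1, prot_value)
  if (lm_level < protconn_value - tol || bound < lm_level - tol ||
      prot_value < bound - tol)
    stop("ProtUnconn partition ordering violated ",
         "(an admissibility rule is inconsistent): ProtConn=", protconn_value,
         " LM=", lm_level, " Bound=", bound, " Prot=", prot_value)
  lm_level <- min(max(lm_level, protconn_value), prot_value)
  bound <- min(max(bound, lm_level), prot_value)
  list(bound = bound,
       sea = lm_level - protconn_value,
       outland = bound - lm_level,
       design = prot_value - bound)
}

#' Assemble and validate a country's indicator set
#'
#' Derives Prot, ProtUnconn and ProtConn_Bound from the additive
#' components (`Prot = ProtConn + Sea + Outland + Design`,
#' `ProtConn_Bound = Prot - Design`) and validates every identity.
#'
#' @param iso3 country code.
#' @param d_med median dispersal distance (km).
#' @param protconn_value ProtConn (percent of land area).
#' @param sea,outland,design the ProtUnconn fractions (percent of land).
#' @param within,contig,unprot,trans the ProtConn fractions (percent of
#'   ProtConn).
#' @param no_connected_land flag from [protconn_fractions()].
#' @return one-row data.frame with the `INDICATOR_COLUMNS` schema.
#' @export
assemble_indicator_set <- function(iso3, d_med, protconn_value, sea, outland,
                                   design, within = 100, contig = 0,
                                   unprot = 0, trans = 0,
                                   no_connected_land = FALSE) {
  prot_value <- protconn_value + sea + outland + design
  row <- data.frame(iso3 = iso3, d_med = d_med, prot = prot_value,
                    protconn = protconn_value,
                    protconn_bound = prot_value - design,
                    protunconn = prot_value - protconn_value,
                    protunconn_sea = sea, protunconn_outland = outland,
                    protunconn_design = design, protconn_within = within,
                    protconn_contig = contig, protconn_unprot = unprot,
                    protconn_trans = trans,
                    no_connected_land = no_connected_land,
                    stringsAsFactors = FALSE)
  validate_indicator_set(row)
  row
}

#' Validate the indicator-set identities
#'
#' Checks, per row: non-negativity; `Prot = ProtConn + ProtUnconn`;
#' `ProtUnconn = Sea + Outland + Design`;
#' `ProtConn <= ProtConn_Bound <= Prot`;
#' `ProtConn_Bound = Prot - Design`; the four ProtConn fractions sum to
#' 100 when ProtConn > 0 (flagged zeros otherwise).
#'
#' @param ind indicator data.frame (schema of [assemble_indicator_set()]).
#' @param tol absolute tolerance (default 1e-9 on percentages).
#' @return `ind`, invisibly; errors name the failing identity.
#' @export
validate_indicator_set <- function(ind, tol = 1e-9) {
  chk <- function(ok, what) {
    if (!all(ok)) stop("indicator identity violated: ", what,
                       " (rows ", paste(which(!ok), collapse = ","), ")")
  }
  num_cols <- setdiff(INDICATOR_COLUMNS, c("iso3", "d_med", "no_connected_land"))
  for (cn in num_cols) chk(ind[[cn]] >= -tol, paste(cn, ">= 0"))
  s <- 1 + abs(ind$prot)
  chk(abs(ind$prot - ind$protconn - ind$protunconn) <= tol * s,
      "Prot = ProtConn + ProtUnconn")
  chk(abs(ind$protunconn - ind$protunconn_sea - ind$protunconn_outland -
            ind$protunconn_design) <= tol * s,
      "ProtUnconn = Sea + Outland + Design")
  chk(ind$protconn <= ind$protconn_bound + tol * s,
      "ProtConn <= ProtConn_Bound")
  chk(ind$protconn_bound <= ind$prot + tol * s, "ProtConn_Bound <= Prot")
  chk(abs(ind$protconn_bound - (ind$prot - ind$protunconn_design)) <= tol * s,
      "ProtConn_Bound = Prot - ProtUnconn[Design]")
  fsum <- ind$protconn_within + ind$protconn_contig + ind$protconn_unprot +
    ind$protconn_trans
  has_conn <- !isTRUE_vec(ind$no_connected_land)
  chk(abs(fsum[has_conn] - 100) <= 1e-6, "ProtConn fractions sum to 100")
  chk(abs(fsum[!has_conn]) <= tol, "flagged fractions are zero")
  invisible(ind)
}

#' Full indicator set for one country and one dispersal distance
#'
#' Builds the four nested scenario networks, the portion- and
#' landmass-level subnetworks, and assembles the validated indicator row.
#'
#' @param nodes labelled node layer (focal + transboundary) from
#'   [preprocess_country()] or [select_transboundary()].
#' @param dist distance matrix (km).
#' @param context a [country_context()].
#' @param d_med median dispersal distance (km).
#' @param contig_tol contiguity tolerance (km, default 0).
#' @return one-row data.frame (see `INDICATOR_COLUMNS`).
#' @export
country_indicators <- function(nodes, dist, context, d_med, contig_tol = 0) {
  focal <- !isTRUE_vec(nodes$is_transboundary)
  prot_value <- prot(nodes, context)
  if (!any(focal))
    return(assemble_indicator_set(context$iso3, d_med, 0, 0, 0, 0,
                                  0, 0, 0, 0, no_connected_land = TRUE))
  p_k <- vapply(NETWORK_SCENARIOS, function(sc) {
    net <- pa_network(nodes, dist, d_med, scenario = sc,
                      contig_tol = contig_tol)
    100 * equivalent_connected_area(net) / context$A_L
  }, numeric(1))
  fr <- protconn_fractions(p_k[["WITHIN"]], p_k[["CONTIG"]],
                           p_k[["COUNTRY"]], p_k[["FULL"]])
  part <- protunconn_partition(nodes, dist, context, d_med,
                               protconn_value = p_k[["FULL"]],
                               prot_value = prot_value,
                               contig_tol = contig_tol)
  assemble_indicator_set(context$iso3, d_med,
                         protconn_value = p_k[["FULL"]],
                         sea = part$sea, outland = part$outland,
                         design = part$design,
                         within = fr$within, contig = fr$contig,
                         unprot = fr$unprot, trans = fr$trans,
                         no_connected_land = fr$no_connected_land)
}

#' Indicators for every country in a pair of layers
#'
#' Runs [preprocess_country()] once per country and
#' [country_indicators()] for every requested dispersal distance.
#'
#' @param pa_layer raw PA layer.
#' @param land_layer land/country layer.
#' @param d_med vector of median dispersal distances (km; default the
#'   1/10/30/100 ladder).
#' @param countries optional subset of ISO3 codes (default: all countries
#'   in the land layer with at least one retained PA node).
#' @param min_area_km2,buffer_km,simplify_km,contig_tol preprocessing
#'   parameters.
#' @return data.frame, one row per (iso3, d_med).
#' @export
compute_indicators <- function(pa_layer, land_layer,
                               d_med = c(1, 10, 30, 100),
                               countries = NULL, min_area_km2 = 1,
                               buffer_km = 500, simplify_km = 0.1,
                               contig_tol = 0) {
  not_disp <- !isTRUE_vec(land_layer$disputed)
  if (is.null(countries))
    countries <- sort(unique(land_layer$iso3[not_disp]))
  rows <- list()
  for (iso in countries) {
    prep <- preprocess_country(pa_layer, land_layer, iso,
                               min_area_km2 = min_area_km2,
                               buffer_km = buffer_km,
                               simplify_km = simplify_km,
                               contig_tol = contig_tol)
    for (dm in d_med) {
      rows[[length(rows) + 1L]] <-
        country_indicators(prep$nodes, prep$dist, prep$context, dm,
                           contig_tol = contig_tol)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
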