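# Area-weighted aggregation of country indicator sets to regional,
# continental or global values. Indicators expressed as a percent of
# country land area are averaged with weight A_L; the four ProtConn
# fractions (a percent of the ProtConn value) with weight A_L * ProtConn,
# so countries without connected land contribute zero fraction weight.

#' Aggregate country indicator sets over a grouping
#'
#' @param indicators data.frame of country indicator rows (one cohort; may
#'   span several `d_med` values, which are aggregated separately).
#' @param areas data.frame with `iso3` and `A_L` (country land area, km^2).
#' @param grouping data.frame with `iso3` and a `group` column (use
#'   `group = "Global"` for a world aggregate); every aggregated country
#'   must appear at most once per group level.
#' @return data.frame with one row per (group, d_med), same indicator
#'   columns as the input plus `group` and `n_countries`.
#' @export
aggregate_indicators <- function(indicators, areas, grouping) {
  stopifnot(all(c("iso3", "A_L") %in% names(areas)),
            all(c("iso3", "group") %in% names(grouping)))
  if (nrow(grouping) == 0L) stop("empty grouping")
  if (anyDuplicated(grouping[, c("iso3", "group")]))
    stop("country repeated within a group")
  missing_iso <- setdiff(grouping$iso3, indicators$iso3)
  if (length(missing_iso))
    stop("countries missing from the indicator table: ",
         paste(missing_iso, collapse = ", "))
  missing_area <- setdiff(grouping$iso3, areas$iso3)
  if (length(missing_area))
    stop("countries missing land areas: ", paste(missing_area, collapse = ", "))
  area_cols <- c("prot", "protconn", "protconn_bound", "protunconn",
                 "protunconn_sea", "protunconn_outland", "protunconn_design")
  frac_cols <- c("protconn_within", "protconn_contig", "protconn_unprot",
                 "protconn_trans")
  d_meds <- if (is.null(indicators$d_med)) NA else sort(unique(indicators$d_med))
  out <- list()
  for (g in unique(grouping$group)) {
    members <- grouping$iso3[grouping$group == g]
    for (dm in d_meds) {
      rows <- indicators[indicators$iso3 %in% members &
                           (is.na(dm) | indicators$d_med == dm), , drop = FALSE]
      rows <- rows[match(members, rows$iso3), , drop = FALSE]
      w <- areas$A_L[match(members, areas$iso3)]
      if (any(!is.finite(w)) || any(w <= 0))
        stop("non-positive land area in group ", g)
      agg <- data.frame(group = g, d_med = dm, stringsAsFactors = FALSE)
      for (cn in area_cols) agg[[cn]] <- sum(w * rows[[cn]]) / sum(w)
      wf <- w * rows$protconn
      for (cn in frac_cols) {
        agg[[cn]] <- if (sum(wf) > 0) sum(wf * rows[[cn]]) / sum(wf) else 0
      }
      agg$no_connected_land <- sum(wf) <= 0
      agg$n_countries <- length(members)
      out[[length(out) + 1L]] <- agg
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
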