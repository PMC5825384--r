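# Country priority classification against a coverage-and-connectivity
# target (17% by default):
#   A  (ProtConn_Bound < target): new PAs are needed.
#     A1 if (target - Prot) > ProtUnconn[Design]  -> general coverage increase
#     A2 otherwise                                -> strategic placement
#   B  (ProtConn_Bound >= target): design is adequate; focus on management.
#     B1 if ProtConn[Unprot] > median over B countries
#     B2 if ProtConn[Contig] > median over B countries (B1+B2 may co-occur)
#     B3 if neither
#   C  (can co-occur with any): ProtConn[Trans] in the top third over all
#      countries (inclusive nearest-rank cut, and positive).

#' Classify countries by their PA-connectivity priorities
#'
#' @param indicators data.frame of country indicator sets (schema of
#'   [assemble_indicator_set()]), covering one cohort.
#' @param target coverage/connectivity target in percent (default 17).
#' @param reference_dmed the dispersal distance whose rows are classified
#'   (default 10 km); ignored when `indicators` has no `d_med` column.
#' @return data.frame: `iso3`, logical flags `A1`, `A2`, `B1`, `B2`, `B3`,
#'   `C`, a combined `priority` label, and the diagnostic thresholds used.
#' @export
classify_priorities <- function(indicators, target = 17,
                                reference_dmed = 10) {
  ind <- indicators
  if (!is.null(ind$d_med)) {
    ind <- ind[ind$d_med == reference_dmed, , drop = FALSE]
    if (nrow(ind) == 0L)
      stop("no indicator rows at the reference d_med = ", reference_dmed)
  }
  if (anyDuplicated(ind$iso3))
    stop("duplicated countries in classification cohort")
  n <- nrow(ind)
  # countries at the target (within float noise) meet it: ">= target" is B
  is_a <- ind$protconn_bound < target - 1e-9
  a1 <- is_a & (target - ind$prot) > ind$protunconn_design
  a2 <- is_a & !a1
  b1 <- b2 <- b3 <- rep(FALSE, n)
  b_unprot_median <- b_contig_median <- NA_real_
  n_b <- sum(!is_a)
  if (n_b >= 2L) {
    b_unprot_median <- stats::median(ind$protconn_unprot[!is_a])
    b_contig_median <- stats::median(ind$protconn_contig[!is_a])
    b1 <- !is_a & ind$protconn_unprot > b_unprot_median
    b2 <- !is_a & ind$protconn_contig > b_contig_median
    b3 <- !is_a & !b1 & !b2
  } else if (n_b > 0L) {
    warning("fewer than 2 countries in class B; B-subclassification skipped")
  }
  # top third of ProtConn[Trans] over ALL countries, nearest-rank, inclusive
  k <- max(1L, ceiling(n / 3))
  trans_cut <- sort(ind$protconn_trans, decreasing = TRUE)[k]
  cc <- ind$protconn_trans >= trans_cut & ind$protconn_trans > 0
  label <- character(n)
  for (i in seq_len(n)) {
    parts <- c(if (a1[i]) "A1", if (a2[i]) "A2", if (b1[i]) "B1",
               if (b2[i]) "B2", if (b3[i]) "B3",
               if (!is_a[i] && n_b < 2L) "B")
    label[i] <- paste(c(parts, if (cc[i]) "C"), collapse = "+")
  }
  data.frame(iso3 = ind$iso3, A1 = a1, A2 = a2, B1 = b1, B2 = b2, B3 = b3,
             C = cc, priority = label, target = target,
             b_unprot_median = b_unprot_median,
             b_contig_median = b_contig_median, trans_cut = trans_cut,
             stringsAsFactors = FALSE)
}
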