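# Synthetic multi-landmass, multi-country PA systems with known
# ground-truth indicator values. Worlds are planar (flat km coordinates):
# landmasses are rectangles separated by sea, each partitioned into
# rectangular territories assigned to countries (repeating a country on
# several landmasses gives island portions; interleaving a foreign strip
# gives enclaves). PAs are squares or regular-polygon discs.

#' Build a scenario specification
#'
#' @param seed integer; fully determines any stochastic placement.
#' @param landmasses data.frame with columns `landmass`, `x0`, `y0`,
#'   `width`, `height` (km).
#' @param territories data.frame with columns `iso3`, `landmass`, `x0`,
#'   `y0`, `width`, `height` and optional `disputed` (logical). Territories
#'   of one landmass must lie inside it and not overlap each other.
#' @param pa_sites data.frame of deterministic placements: `site_id`,
#'   `iso3`, `shape` (`"square"`, `"disc"` or `"point"`), `area_km2`, `cx`,
#'   `cy`, and optional `status`, `desig_type`, `iucn`, `reported_area`.
#' @param random_pas optional data.frame of stochastic placement rules:
#'   `iso3`, `count`, `area_min`, `area_max`, `shape`; PAs are placed by
#'   rejection sampling inside the country's territories, without overlap
#'   among PAs of the same country.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed, landmasses, territories, pa_sites = NULL,
                          random_pas = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " missing columns: ", paste(miss, collapse = ", "))
  }
  req(landmasses, c("landmass", "x0", "y0", "width", "height"), "landmasses")
  req(territories, c("iso3", "landmass", "x0", "y0", "width", "height"), "territories")
  if (is.null(territories$disputed)) territories$disputed <- FALSE
  if (any(landmasses$width <= 0) || any(landmasses$height <= 0))
    stop("landmass dimensions must be positive")
  if (any(territories$width <= 0) || any(territories$height <= 0))
    stop("declared country areas must be positive")
  # territories inside their landmass
  for (i in seq_len(nrow(territories))) {
    t <- territories[i, ]
    lm <- landmasses[landmasses$landmass == t$landmass, ]
    if (nrow(lm) != 1L) stop("territory ", i, " references unknown landmass ", t$landmass)
    if (t$x0 < lm$x0 - 1e-9 || t$y0 < lm$y0 - 1e-9 ||
        t$x0 + t$width > lm$x0 + lm$width + 1e-9 ||
        t$y0 + t$height > lm$y0 + lm$height + 1e-9)
      stop("territory ", i, " (", t$iso3, ") extends beyond landmass ", t$landmass)
  }
  # non-overlap of territories within a landmass
  for (lm in unique(territories$landmass)) {
    tt <- territories[territories$landmass == lm, ]
    if (nrow(tt) < 2L) next
    for (a in seq_len(nrow(tt) - 1L)) for (b in (a + 1L):nrow(tt)) {
      ox <- min(tt$x0[a] + tt$width[a], tt$x0[b] + tt$width[b]) - max(tt$x0[a], tt$x0[b])
      oy <- min(tt$y0[a] + tt$height[a], tt$y0[b] + tt$height[b]) - max(tt$y0[a], tt$y0[b])
      if (ox > 1e-9 && oy > 1e-9)
        stop("overlapping countries on landmass ", lm, ": ",
             tt$iso3[a], " and ", tt$iso3[b])
    }
  }
  if (!is.null(pa_sites)) {
    req(pa_sites, c("site_id", "iso3", "shape", "area_km2", "cx", "cy"), "pa_sites")
    if (is.null(pa_sites$status)) pa_sites$status <- "designated"
    if (is.null(pa_sites$desig_type)) pa_sites$desig_type <- "National"
    if (is.null(pa_sites$iucn)) pa_sites$iucn <- "II"
    if (is.null(pa_sites$reported_area)) pa_sites$reported_area <- pa_sites$area_km2
  }
  if (!is.null(random_pas))
    req(random_pas, c("iso3", "count", "area_min", "area_max", "shape"), "random_pas")
  structure(list(seed = as.integer(seed), landmasses = landmasses,
                 territories = territories, pa_sites = pa_sites,
                 random_pas = random_pas),
            class = "scenario_spec")
}

site_geometry <- function(shape, area_km2, cx, cy) {
  switch(shape,
    square = square_ring(cx, cy, area_km2),
    disc = disc_ring(cx, cy, area_km2),
    point = matrix(c(cx, cy), nrow = 1L, dimnames = list(NULL, c("x", "y"))),
    stop("unknown PA shape: ", shape))
}

territory_of_point <- function(spec, x, y) {
  tt <- spec$territories
  hit <- which(x >= tt$x0 & x <= tt$x0 + tt$width &
               y >= tt$y0 & y <= tt$y0 + tt$height)
  if (length(hit)) hit[1L] else NA_integer_
}

place_random_pas <- function(spec) {
  out <- list()
  counter <- 0L
  for (r in seq_len(nrow(spec$random_pas))) {
    rule <- spec$random_pas[r, ]
    terr <- spec$territories[spec$territories$iso3 == rule$iso3 &
                               !spec$territories$disputed, , drop = FALSE]
    if (nrow(terr) == 0L) stop("random_pas rule for unknown country ", rule$iso3)
    placed <- list()
    for (k in seq_len(rule$count)) {
      ok <- FALSE
      for (try in 1:200) {
        area <- stats::runif(1, rule$area_min, rule$area_max)
        ti <- sample.int(nrow(terr), 1L, prob = terr$width * terr$height)
        half <- sqrt(area) / 2 * 1.3  # margin covers disc circumradius too
        if (terr$width[ti] <= 2 * half || terr$height[ti] <= 2 * half) next
        cx <- stats::runif(1, terr$x0[ti] + half, terr$x0[ti] + terr$width[ti] - half)
        cy <- stats::runif(1, terr$y0[ti] + half, terr$y0[ti] + terr$height[ti] - half)
        g <- site_geometry(rule$shape, area, cx, cy)
        clash <- any(vapply(placed, function(p) geom_dist(p, g) <= 0, logical(1)))
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) next  # rejection sampling exhausted; skip this PA
      placed[[length(placed) + 1L]] <- g
      counter <- counter + 1L
      out[[length(out) + 1L]] <- data.frame(
        site_id = sprintf("%s_R%03d", rule$iso3, counter), iso3 = rule$iso3,
        shape = rule$shape, area_km2 = area, cx = cx, cy = cy,
        status = "designated", desig_type = "National", iucn = "II",
        reported_area = area, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Generate the PA and land layers of a scenario
#'
#' @param spec a [scenario_spec()] (or preset name, see [preset_scenario()]).
#' @return list with `pa_layer`, `land_layer` (both [pc_layer()], planar km)
#'   and `truth` (a one-row indicator data.frame for closed-form presets,
#'   otherwise `NULL`).
#' @export
generate_scenario <- function(spec) {
  if (is.character(spec)) spec <- preset_scenario(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  sites <- spec$pa_sites
  if (!is.null(spec$random_pas)) {
    rp <- place_random_pas(spec)
    sites <- if (is.null(sites)) rp else rbind(sites, rp)
  }
  if (is.null(sites) || nrow(sites) == 0L)
    sites <- data.frame(site_id = character(), iso3 = character(),
                        shape = character(), area_km2 = numeric(),
                        cx = numeric(), cy = numeric(), status = character(),
                        desig_type = character(), iucn = character(),
                        reported_area = numeric(), stringsAsFactors = FALSE)
  # validate: PA must fit inside some territory's landmass
  for (i in seq_len(nrow(sites))) {
    ti <- territory_of_point(spec, sites$cx[i], sites$cy[i])
    if (is.na(ti)) next  # deliberately-at-sea fixtures are allowed through
    lm <- spec$landmasses[spec$landmasses$landmass ==
                            spec$territories$landmass[ti], ]
    if (sites$area_km2[i] > lm$width * lm$height)
      stop("PA ", sites$site_id[i], " larger than its landmass")
  }
  geoms <- lapply(seq_len(nrow(sites)), function(i)
    site_geometry(sites$shape[i], sites$area_km2[i], sites$cx[i], sites$cy[i]))
  pa_df <- data.frame(site_id = sites$site_id, iso3 = sites$iso3,
                      status = sites$status, desig_type = sites$desig_type,
                      iucn = sites$iucn,
                      is_point = sites$shape == "point",
                      reported_area = sites$reported_area,
                      stringsAsFactors = FALSE)
  pa_layer <- pc_layer(pa_df, geoms)
  tt <- spec$territories
  land_df <- data.frame(land_id = sprintf("T%02d", seq_len(nrow(tt))),
                        iso3 = tt$iso3, landmass = tt$landmass,
                        disputed = tt$disputed, stringsAsFactors = FALSE)
  land_geoms <- lapply(seq_len(nrow(tt)), function(i)
    rect_ring(tt$x0[i], tt$y0[i], tt$width[i], tt$height[i]))
  land_layer <- pc_layer(land_df, land_geoms)
  list(pa_layer = pa_layer, land_layer = land_layer,
       truth = attr(spec, "truth"))
}

#' Closed-form preset scenarios
#'
#' * `single_pa`: one 100x100 km single-country landmass with one 1700 km^2
#'   square PA; Prot = ProtConn = ProtConn_Bound = 17.
#' * `two_islands`: one country on two equal 100x100 km islands, one
#'   2000 km^2 PA per island (10% of country area each); the sea is the only
#'   cause of isolation, so ProtConn = 100*a*sqrt(2)/A_L and
#'   ProtUnconn_Sea = Prot - ProtConn.
#' * `enclave`: one landmass where a foreign strip without PAs splits the
#'   focal country into two portions, one 1500 km^2 PA per portion; foreign
#'   land is the only cause of isolation.
#'
#' @param name preset name.
#' @param seed seed stored in the spec (presets are deterministic anyway).
#' @return a [scenario_spec()] carrying a `truth` attribute.
#' @export
preset_scenario <- function(name = c("single_pa", "two_islands", "enclave"),
                            seed = 1L) {
  name <- match.arg(name)
  truth_row <- function(iso3, prot, protconn, bound, sea, outland, design,
                        within, contig, unprot, trans) {
    data.frame(iso3 = iso3, prot = prot, protconn = protconn,
               protconn_bound = bound, protunconn = prot - protconn,
               protunconn_sea = sea, protunconn_outland = outland,
               protunconn_design = design, protconn_within = within,
               protconn_contig = contig, protconn_unprot = unprot,
               protconn_trans = trans, stringsAsFactors = FALSE)
  }
  if (name == "single_pa") {
    spec <- scenario_spec(
      seed,
      landmasses = data.frame(landmass = "L1", x0 = 0, y0 = 0,
                              width = 100, height = 100),
      territories = data.frame(iso3 = "AAA", landmass = "L1", x0 = 0, y0 = 0,
                               width = 100, height = 100),
      pa_sites = data.frame(site_id = "S1", iso3 = "AAA", shape = "square",
                            area_km2 = 1700, cx = 50, cy = 50))
    attr(spec, "truth") <- truth_row("AAA", 17, 17, 17, 0, 0, 0, 100, 0, 0, 0)
  } else if (name == "two_islands") {
    a <- 2000; A_L <- 20000
    pc <- 100 * a * sqrt(2) / A_L
    spec <- scenario_spec(
      seed,
      landmasses = data.frame(landmass = c("L1", "L2"), x0 = c(0, 300),
                              y0 = 0, width = 100, height = 100),
      territories = data.frame(iso3 = "AAA", landmass = c("L1", "L2"),
                               x0 = c(0, 300), y0 = 0, width = 100, height = 100),
      pa_sites = data.frame(site_id = c("S1", "S2"), iso3 = "AAA",
                            shape = "square", area_km2 = a,
                            cx = c(50, 350), cy = 50))
    attr(spec, "truth") <- truth_row("AAA", 20, pc, 20, 20 - pc, 0, 0,
                                     100, 0, 0, 0)
  } else {
    a <- 1500; A_L <- 20000
    pc <- 100 * a * sqrt(2) / A_L
    spec <- scenario_spec(
      seed,
      landmasses = data.frame(landmass = "L1", x0 = 0, y0 = 0,
                              width = 300, height = 100),
      territories = data.frame(iso3 = c("AAA", "BBB", "AAA"), landmass = "L1",
                               x0 = c(0, 100, 200), y0 = 0,
                               width = 100, height = 100),
      pa_sites = data.frame(site_id = c("S1", "S2"), iso3 = "AAA",
                            shape = "square", area_km2 = a,
                            cx = c(50, 250), cy = 50))
    attr(spec, "truth") <- truth_row("AAA", 15, pc, 15, 0, 15 - pc, 0,
                                     100, 0, 0, 0)
  }
  spec
}

#' Random multi-country scenario for property testing
#'
#' Draws 1-3 landmasses laid out with sea gaps, splits each into vertical
#' territory strips assigned to a small pool of countries (repetition across
#' landmasses creates island portions; interleaving creates enclaves), and
#' scatters 0-4 non-overlapping PAs per country by rejection sampling.
#'
#' @param seed integer seed.
#' @param n_countries pool size (default 3).
#' @return a [scenario_spec()].
#' @export
random_scenario <- function(seed, n_countries = 3L) {
  set.seed(seed)
  iso_pool <- sprintf("C%02d", seq_len(n_countries))
  n_lm <- sample(1:3, 1L)
  x_cursor <- 0
  lm_rows <- list(); terr_rows <- list()
  for (m in seq_len(n_lm)) {
    w <- stats::runif(1, 150, 350)
    h <- stats::runif(1, 120, 250)
    lm_rows[[m]] <- data.frame(landmass = sprintf("L%d", m), x0 = x_cursor,
                               y0 = 0, width = w, height = h)
    n_strip <- sample(1:3, 1L)
    cuts <- sort(stats::runif(n_strip - 1L, 0.25, 0.75)) * w
    edges <- c(0, cuts, w)
    owners <- sample(iso_pool, n_strip, replace = TRUE)
    for (s in seq_len(n_strip)) {
      terr_rows[[length(terr_rows) + 1L]] <- data.frame(
        iso3 = owners[s], landmass = sprintf("L%d", m),
        x0 = x_cursor + edges[s], y0 = 0,
        width = edges[s + 1L] - edges[s], height = h)
    }
    x_cursor <- x_cursor + w + stats::runif(1, 30, 200)
  }
  terr <- do.call(rbind, terr_rows)
  present <- unique(terr$iso3)
  rules <- data.frame(iso3 = present,
                      count = sample(0:4, length(present), replace = TRUE),
                      area_min = 30,
                      area_max = 30 + stats::runif(length(present), 100, 900),
                      shape = sample(c("square", "disc"), length(present),
                                     replace = TRUE),
                      stringsAsFactors = FALSE)
  scenario_spec(seed, do.call(rbind, lm_rows), terr, random_pas = rules)
}
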