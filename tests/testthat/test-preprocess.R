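raw_site <- function(site_id, iso3 = "AAA", status = "designated",
                     desig = "National", iucn = "II", point = FALSE,
                     reported = 10, geom = rect_ring(0, 0, 3, 3)) {
  pc_layer(data.frame(site_id = site_id, iso3 = iso3, status = status,
                      desig_type = desig, iucn = iucn, is_point = point,
                      reported_area = reported, stringsAsFactors = FALSE),
           list(geom))
}

bind_sites <- function(...) {
  layers <- list(...)
  df <- do.call(rbind, lapply(layers, as.data.frame))
  out <- df
  attr(out, "coord_mode") <- "planar_km"
  class(out) <- c("pc_layer", class(df))
  out
}

test_that("site filtering applies the status, point and MAB rules", {
  pt <- matrix(c(1, 1), 1, dimnames = list(NULL, c("x", "y")))
  layer <- bind_sites(
    raw_site("keep1"),
    raw_site("drop_prop", status = "proposed"),
    raw_site("drop_nr", status = "not reported"),
    raw_site("drop_pt", point = TRUE, reported = NA, geom = pt),
    raw_site("keep_pt", point = TRUE, reported = 12, geom = pt),
    raw_site("drop_mab", desig = "UNESCO-MAB Biosphere Reserve"),
    raw_site("keep_noiucn", iucn = "Not Reported"))
  out <- filter_sites(layer)
  expect_setequal(out$site_id, c("keep1", "keep_pt", "keep_noiucn"))
  log <- attr(out, "filter_log")
  expect_equal(unname(log["dropped_status"]), 2)
  expect_equal(unname(log["dropped_point_no_area"]), 1)
  expect_equal(unname(log["dropped_mab"]), 1)
  expect_warning(filter_sites(bind_sites(raw_site("odd", status = "Wibble"))),
                 "unknown PA status")
})

test_that("point sites become buffers matching the reported area", {
  pt <- matrix(c(50, 50), 1, dimnames = list(NULL, c("x", "y")))
  layer <- bind_sites(raw_site("p1", point = TRUE, reported = 10, geom = pt))
  out <- buffer_point_sites(layer)
  expect_false(any(out$is_point))
  expect_equal(geom_area(out$geometry[[1]]), 10, tolerance = 1e-9)
  r <- sqrt(rowSums(sweep(out$geometry[[1]][[1]], 2, c(50, 50))^2))
  expect_equal(mean(r), sqrt(10 / pi), tolerance = 0.01)
})

test_that("dissolve removes double counting and keeps disjoint sites apart", {
  # the same 50 km^2 site designated twice
  g <- square_ring(10, 10, 50)
  layer <- bind_sites(raw_site("np", geom = g), raw_site("whs", geom = g),
                      raw_site("far", geom = square_ring(40, 40, 25)))
  dis <- dissolve_and_simplify(layer, simplify_km = 0)
  expect_equal(nrow(dis), 2)
  expect_equal(sort(dis$area_km2), c(25, 50))
  # partial overlap: union area, not the sum
  layer2 <- bind_sites(raw_site("a", geom = rect_ring(0, 0, 10, 10)),
                       raw_site("b", geom = rect_ring(5, 0, 10, 10)))
  dis2 <- dissolve_and_simplify(layer2, simplify_km = 0)
  expect_equal(nrow(dis2), 1)
  expect_equal(dis2$area_km2, 150)
  # dissolved output re-dissolves to the same areas (idempotence)
  dis3 <- dissolve_and_simplify(layer, simplify_km = 0)
  expect_equal(dis3$area_km2, dis$area_km2, tolerance = 1e-6)
})

simple_land <- function() {
  pc_layer(data.frame(land_id = "T01", iso3 = "AAA", disputed = FALSE,
                      stringsAsFactors = FALSE),
           list(rect_ring(0, 0, 100, 100)))
}

test_that("clipping drops marine parts, small parts, and splits by border", {
  land <- simple_land()
  # coastal square half on land
  coastal <- dissolve_and_simplify(
    bind_sites(raw_site("c", geom = rect_ring(-5, 0, 10, 10))), 0)
  nodes <- clip_explode_filter(coastal, land)
  expect_equal(nrow(nodes), 1)
  expect_equal(nodes$area_km2, 50)
  # multipart 3 + 0.4 km^2: only the 3 km^2 part survives
  two_land <- pc_layer(
    data.frame(land_id = c("T01", "T02"), iso3 = "AAA", disputed = FALSE,
               stringsAsFactors = FALSE),
    list(rect_ring(0, 0, 10, 10), rect_ring(20, 0, 10, 10)))
  mp <- dissolve_and_simplify(bind_sites(
    raw_site("m1", geom = rect_ring(1, 1, 3, 1)),
    raw_site("m2", geom = rect_ring(21, 1, 0.8, 0.5))), 0)
  nodes2 <- clip_explode_filter(mp, two_land)
  expect_equal(nrow(nodes2), 1)
  expect_equal(nodes2$area_km2, 3)
  # PA entirely at sea is dropped and logged
  sea <- dissolve_and_simplify(
    bind_sites(raw_site("s", geom = rect_ring(300, 300, 3, 3))), 0)
  nodes3 <- clip_explode_filter(sea, land)
  expect_equal(nrow(nodes3), 0)
  # a site listing two ISO3 codes straddling the border becomes two nodes
  border_land <- pc_layer(
    data.frame(land_id = c("T01", "T02"), iso3 = c("AAA", "BBB"),
               disputed = FALSE, stringsAsFactors = FALSE),
    list(rect_ring(0, 0, 50, 100), rect_ring(50, 0, 50, 100)))
  tb <- dissolve_and_simplify(
    bind_sites(raw_site("tb", iso3 = "AAA;BBB", geom = rect_ring(44, 0, 10, 10))), 0)
  nodes4 <- clip_explode_filter(tb, border_land)
  expect_equal(nrow(nodes4), 2)
  expect_setequal(nodes4$iso3, c("AAA", "BBB"))
  expect_equal(sort(nodes4$area_km2), c(40, 60))
})

test_that("portion and landmass labels follow sea and foreign-land splits", {
  # two islands of one country
  isl <- pc_layer(data.frame(land_id = c("T01", "T02"), iso3 = "AAA",
                             disputed = FALSE, stringsAsFactors = FALSE),
                  list(rect_ring(0, 0, 100, 100), rect_ring(200, 0, 100, 100)))
  dis <- dissolve_and_simplify(bind_sites(
    raw_site("i1", geom = square_ring(50, 50, 100)),
    raw_site("i2", geom = square_ring(250, 50, 100))), 0)
  nodes <- label_portions_landmasses(clip_explode_filter(dis, isl), isl)
  expect_equal(length(unique(nodes$portion_id)), 2)
  expect_equal(length(unique(nodes$landmass_id)), 2)
  # enclave: one landmass, country split by foreign strip
  enc <- pc_layer(data.frame(land_id = c("T01", "T02", "T03"),
                             iso3 = c("AAA", "BBB", "AAA"), disputed = FALSE,
                             stringsAsFactors = FALSE),
                  list(rect_ring(0, 0, 100, 100), rect_ring(100, 0, 100, 100),
                       rect_ring(200, 0, 100, 100)))
  dis2 <- dissolve_and_simplify(bind_sites(
    raw_site("e1", geom = square_ring(50, 50, 100)),
    raw_site("e2", geom = square_ring(250, 50, 100))), 0)
  nodes2 <- label_portions_landmasses(clip_explode_filter(dis2, enc), enc)
  expect_equal(length(unique(nodes2$portion_id)), 2)
  expect_equal(length(unique(nodes2$landmass_id)), 1)
  # single contiguous country
  dis3 <- dissolve_and_simplify(bind_sites(
    raw_site("s1", geom = square_ring(20, 20, 100)),
    raw_site("s2", geom = square_ring(70, 70, 100))), 0)
  nodes3 <- label_portions_landmasses(clip_explode_filter(dis3, simple_land()),
                                      simple_land())
  expect_equal(length(unique(nodes3$portion_id)), 1)
  expect_equal(length(unique(nodes3$landmass_id)), 1)
})

test_that("transboundary selection respects the 500 km buffer", {
  land <- pc_layer(data.frame(land_id = c("T01", "T02"),
                              iso3 = c("AAA", "BBB"), disputed = FALSE,
                              stringsAsFactors = FALSE),
                   list(rect_ring(0, 0, 100, 100), rect_ring(100, 0, 1000, 100)))
  dis <- dissolve_and_simplify(bind_sites(
    raw_site("f", geom = rect_ring(90, 40, 10, 10)),
    raw_site("near", iso3 = "BBB", geom = rect_ring(599, 40, 10, 10)),
    raw_site("far", iso3 = "BBB", geom = rect_ring(700, 40, 10, 10))), 0)
  nodes <- label_portions_landmasses(clip_explode_filter(dis, land), land)
  net <- select_transboundary(nodes, "AAA", buffer_km = 500)
  expect_equal(sum(!net$is_transboundary), 1)     # own PA never flagged
  expect_equal(sum(net$is_transboundary), 1)      # 499 km in, 600 km out
  ids <- net$node_id[net$is_transboundary]
  expect_equal(net$area_km2[net$node_id == ids], 100)
  empty <- select_transboundary(nodes, "ZZZ")
  expect_equal(nrow(empty), 0)
  expect_true(attr(empty, "empty_network"))
})

test_that("distance matrices are symmetric with zero diagonal", {
  sc <- generate_scenario(random_scenario(5))
  prep <- preprocess_country(sc$pa_layer, sc$land_layer,
                             sc$land_layer$iso3[1])
  d <- prep$dist
  expect_true(all(d >= 0))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("node areas reproduce country coverage by construction", {
  sc <- generate_scenario(preset_scenario("single_pa"))
  prep <- preprocess_country(sc$pa_layer, sc$land_layer, "AAA")
  focal <- !prep$nodes$is_transboundary
  expect_equal(sum(prep$nodes$area_km2[focal]),
               17 * prep$context$A_L / 100, tolerance = 1e-9)
})
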