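test_that("kernel is calibrated to 0.5 at the median dispersal distance", {
  expect_equal(kernel_probability(10, 10), 0.5)
  expect_equal(kernel_probability(0, 37), 1)
  expect_equal(kernel_probability(20, 10), 0.25)
  expect_equal(kernel_probability(500, 100), 0.03125)
  expect_equal(round(kernel_probability(500, 100), 2), 0.03)
  d <- seq(0, 200, by = 0.5)
  expect_true(all(diff(kernel_probability(d, 30)) < 0))
  expect_error(kernel_probability(-1, 10), "non-negative")
  expect_error(kernel_probability(5, 0), "positive")
})

test_that("admissibility enforces sea and foreign-land barriers", {
  dmat <- dist_from_matrix(matrix(c(0, 10, 30,
                                    10, 0, 15,
                                    30, 15, 0), 3, 3))
  # same portion: link admissible in COUNTRY
  nodes <- make_nodes(c(50, 60, 70))
  l <- admissible_links(nodes, dmat, "COUNTRY", d_med = 10)
  expect_equal(nrow(l), 3)
  expect_equal(l$p[l$i == 1 & l$j == 2], kernel_probability(10, 10))
  # different islands: never any link
  nodes2 <- make_nodes(c(50, 60), landmass = c("LM1", "LM2"),
                       portion = c("AAA_P1", "AAA_P2"))
  for (sc in c("CONTIG", "COUNTRY", "FULL"))
    expect_equal(nrow(admissible_links(nodes2, dmat[1:2, 1:2], sc, 10)), 0)
  # two portions of one landmass bridged only by a foreign node
  nodes3 <- make_nodes(c(50, 0, 60), iso3 = c("AAA", "BBB", "AAA"),
                       portion = c("AAA_P1", "BBB_P1", "AAA_P2"),
                       trans = c(FALSE, TRUE, FALSE))
  lf <- admissible_links(nodes3, dmat, "FULL", 10)
  pairs <- paste(lf$i, lf$j)
  expect_true(all(c("1 2", "2 3") %in% pairs))   # A-T and T-B admissible
  expect_false("1 3" %in% pairs)                 # direct A-B barred
  # COUNTRY drops transboundary links entirely
  expect_equal(nrow(admissible_links(nodes3, dmat, "COUNTRY", 10)), 0)
  expect_equal(nrow(admissible_links(nodes3, dmat, "WITHIN", 10)), 0)
  expect_error(admissible_links(nodes, dmat, "BOGUS", 10), "unknown scenario")
})

test_that("scenario link sets are nested", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    d <- matrix(runif(n * n, 0, 40), n, n); d <- (d + t(d)) / 2; diag(d) <- 0
    trans <- runif(n) < 0.3
    if (all(trans)) trans[1] <- FALSE
    nodes <- make_nodes(runif(n, 10, 100),
                        iso3 = ifelse(trans, "BBB", "AAA"),
                        portion = sample(c("P1", "P2"), n, replace = TRUE),
                        landmass = sample(c("LM1", "LM2"), n, replace = TRUE),
                        trans = trans)
    key <- function(sc) {
      l <- admissible_links(nodes, d, sc, 10, contig_tol = 5)
      paste(l$i, l$j)
    }
    k <- lapply(c("WITHIN", "CONTIG", "COUNTRY", "FULL"), key)
    expect_true(all(k[[1]] %in% k[[2]]))
    expect_true(all(k[[2]] %in% k[[3]]))
    expect_true(all(k[[3]] %in% k[[4]]))
  }
})

test_that("maximum-product paths beat direct links through stepping stones", {
  # chain A-B 10 km, B-C 10 km, direct A-C 30 km, d_med 10
  links <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3), d_km = c(10, 10, 30),
                      p = kernel_probability(c(10, 10, 30), 10))
  pstar <- max_product_paths(3, links)
  expect_equal(pstar[1, 3], 0.25)            # 0.5 * 0.5 via B
  expect_gt(pstar[1, 3], kernel_probability(30, 10))
  expect_equal(max_product_paths(1, data.frame(i = integer(), j = integer(),
                                               d_km = numeric(), p = numeric())),
               matrix(1, 1, 1))
})

test_that("path algorithm equals exhaustive enumeration on random graphs", {
  set.seed(99)
  for (rep in 1:150) {
    n <- sample(2:8, 1)
    links <- random_link_graph(n)
    pstar <- max_product_paths(n, links)
    pmat <- matrix(0, n, n)
    for (r in seq_len(nrow(links))) {
      pmat[links$i[r], links$j[r]] <- pmat[links$j[r], links$i[r]] <- links$p[r]
    }
    expect_equal(pstar, brute_pstar(pmat), tolerance = 1e-12)
  }
})

test_that("p* matrix satisfies its defining inequalities", {
  set.seed(12)
  n <- 7
  links <- random_link_graph(n, 0.5)
  pstar <- max_product_paths(n, links)
  expect_equal(diag(pstar), rep(1, n))
  expect_equal(pstar, t(pstar))
  for (r in seq_len(nrow(links)))
    expect_gte(pstar[links$i[r], links$j[r]], links$p[r])
  expect_true(all(pstar >= 0 & pstar <= 1))
})

test_that("ECA reproduces closed forms and its bounds", {
  # one PA of 100 km^2
  d1 <- dist_from_matrix(matrix(0, 1, 1))
  expect_equal(equivalent_connected_area(pa_network(make_nodes(100), d1, 10)), 100)
  # two isolated PAs of 30 and 40 km^2 -> sqrt(900 + 1600) = 50
  d2 <- dist_from_matrix(matrix(c(0, 1000, 1000, 0), 2, 2))
  expect_equal(equivalent_connected_area(pa_network(make_nodes(c(30, 40)), d2, 10)), 50)
  # k PAs all mutually at distance 0 -> sum of areas
  k <- 4
  dk <- dist_from_matrix(matrix(0, k, k))
  areas <- c(10, 20, 30, 40)
  expect_equal(equivalent_connected_area(pa_network(make_nodes(areas), dk, 10)), 100)
  # bounds on a random network
  set.seed(8)
  n <- 6
  dr <- matrix(runif(n * n, 0, 80), n, n); dr <- (dr + t(dr)) / 2; diag(dr) <- 0
  areas <- runif(n, 5, 50)
  eca <- equivalent_connected_area(pa_network(make_nodes(areas), dr, 30))
  expect_gte(eca, sqrt(sum(areas^2)) - 1e-9)
  expect_lte(eca, sum(areas) + 1e-9)
  # direct double-sum oracle
  net <- pa_network(make_nodes(areas), dr, 30)
  expect_equal(eca, sqrt(sum(outer(areas, areas) * net$pstar)), tolerance = 1e-12)
  # transboundary nodes carry attribute zero
  nodes_t <- make_nodes(c(50, 999), iso3 = c("AAA", "BBB"),
                        trans = c(FALSE, TRUE))
  dt <- dist_from_matrix(matrix(c(0, 5, 5, 0), 2, 2))
  expect_equal(equivalent_connected_area(pa_network(nodes_t, dt, 10)), 50)
})

test_that("merging two contiguous PAs leaves ECA unchanged", {
  two <- make_nodes(c(30, 20))
  d <- dist_from_matrix(matrix(c(0, 0, 0, 0), 2, 2))
  merged <- make_nodes(50)
  expect_equal(
    equivalent_connected_area(pa_network(two, d, 10)),
    equivalent_connected_area(pa_network(merged, dist_from_matrix(matrix(0, 1, 1)), 10)))
})

test_that("ECA is monotone in d_med and under link additions", {
  set.seed(77)
  n <- 6
  d <- matrix(runif(n * n, 0, 60), n, n); d <- (d + t(d)) / 2; diag(d) <- 0
  nodes <- make_nodes(runif(n, 5, 60))
  ecas <- vapply(c(1, 10, 30, 100), function(dm)
    equivalent_connected_area(pa_network(nodes, d, dm)), numeric(1))
  expect_true(all(diff(ecas) >= -1e-9))
  # raising a link probability (shrinking a distance) never decreases ECA
  d2 <- d; d2[1, 2] <- d2[2, 1] <- d[1, 2] / 2
  expect_gte(equivalent_connected_area(pa_network(nodes, d2, 10)),
             equivalent_connected_area(pa_network(nodes, d, 10)) - 1e-9)
})

test_that("Conefor-style files round-trip the network", {
  nodes <- make_nodes(c(40, 0, 25), iso3 = c("AAA", "BBB", "AAA"),
                      portion = c("AAA_P1", "BBB_P1", "AAA_P1"),
                      trans = c(FALSE, TRUE, FALSE))
  nodes$area_km2[2] <- 99  # true area survives via the labels CSV
  d <- dist_from_matrix(matrix(c(0, 4, 9, 4, 0, 6, 9, 6, 0), 3, 3))
  prefix <- file.path(tempdir(), "net")
  write_conefor(nodes, d, prefix)
  nd <- read.table(paste0(prefix, "_nodes.txt"))
  expect_equal(nd$V2, c(40, 0, 25))  # attribute 0 for the transboundary node
  back <- read_conefor(prefix)
  expect_equal(unname(back$dist[1, 3]), 9)
  expect_equal(back$nodes$area_km2, c(40, 99, 25))
  expect_equal(back$nodes$is_transboundary, c(FALSE, TRUE, FALSE))
})
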