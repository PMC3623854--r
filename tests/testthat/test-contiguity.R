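test_that("queen contiguity on grids has the expected degree structure", {
  g <- queen_from_grid(3, 3)
  deg <- table(graph_degrees(g))
  expect_equal(as.integer(deg[c("3", "5", "8")]), c(4L, 4L, 1L))

  g1 <- queen_from_grid(1, 1)
  expect_equal(graph_islands(g1), g1$ids)

  g2 <- queen_from_grid(2, 2)
  expect_true(all(graph_degrees(g2) == 3))  # diagonal vertex contact counts

  expect_error(queen_from_grid(0, 3), "positive integer")
})

test_that("polygon queen contiguity matches the grid fast path on unit-square lattices", {
  for (dims in list(c(2, 2), c(3, 3), c(4, 6), c(5, 7), c(7, 7))) {
    g_grid <- queen_from_grid(dims[1], dims[2])
    g_poly <- queen_from_polygons(grid_polygons(dims[1], dims[2]))
    expect_identical(g_poly$ids, g_grid$ids)
    expect_identical(g_poly$nb, g_grid$nb)
  }
})

test_that("polygon contiguity handles gaps, tolerance, vertex contact and bad input", {
  # two squares separated by a gap wider than the tolerance: both islands
  apart <- list(a = unit_square(1, 1),
                b = unit_square(1, 1) + cbind(rep(2.5, 4), 0))
  g <- queen_from_polygons(apart, tolerance = 0)
  expect_setequal(graph_islands(g), c("a", "b"))
  # ... but a tolerance covering the gap joins them
  g2 <- queen_from_polygons(apart, tolerance = 1.6)
  expect_length(graph_islands(g2), 0)

  # single shared vertex is enough (queen rule)
  diag_pair <- list(a = unit_square(1, 1), b = unit_square(2, 2))
  expect_equal(queen_from_polygons(diag_pair)$nb$a, 2L)

  expect_error(
    queen_from_polygons(stats::setNames(list(unit_square(1, 1),
                                             unit_square(1, 2)),
                                        c("a", "a"))),
    "duplicate")
  expect_error(queen_from_polygons(list(a = cbind(0, 0))), "invalid geometry")
})

test_that("GeoJSON polygons round-trip into the same graph", {
  polys <- grid_polygons(3, 3)
  feats <- lapply(names(polys), function(id) {
    ring <- polys[[id]]
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(area_id = id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.list(ring[i, ])))))
  })
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  g <- queen_from_polygons(path)
  expect_identical(g$nb, queen_from_grid(3, 3)$nb)
})

test_that("edge lists are symmetrized, de-duplicated and validated", {
  g <- queen_from_edgelist(data.frame(a = "a", b = "b"),
                           nodes = c("a", "b", "c"))
  expect_equal(graph_islands(g), "c")
  expect_equal(g$nb$a, 2L)
  expect_equal(g$nb$b, 1L)

  g2 <- queen_from_edgelist(data.frame(x = c("a", "b"), y = c("b", "a")),
                            nodes = c("a", "b"))
  expect_equal(sum(lengths(g2$nb)) / 2, 1)  # one undirected edge

  expect_warning(
    g3 <- queen_from_edgelist(data.frame(x = c("a", "a"), y = c("a", "b")),
                              nodes = c("a", "b")),
    "self-loop")
  expect_equal(g3$nb$a, 2L)

  expect_error(queen_from_edgelist(data.frame(x = "a", y = "z"),
                                   nodes = c("a", "b")),
               "not in node set")
})

test_that("spatial lag is the neighbour mean, reports islands, never imputes", {
  g <- queen_from_grid(3, 3)
  v <- stats::setNames(rep(7, 9), g$ids)
  expect_equal(unname(spatial_lag(v, g)$ald), rep(7, 9))

  # centre value 9, all others 1
  v2 <- stats::setNames(rep(1, 9), g$ids)
  v2["g2_2"] <- 9
  lag <- spatial_lag(v2, g)
  expect_equal(unname(lag$ald["g2_2"]), 1)
  expect_equal(unname(lag$ald["g1_1"]), (1 + 1 + 9) / 3)

  # brute-force oracle on a random 5x5 field
  g5 <- queen_from_grid(5, 5)
  set.seed(11)
  f <- stats::setNames(rnorm(25), g5$ids)
  expected <- vapply(seq_len(25), function(i) mean(f[g5$nb[[i]]]), numeric(1))
  expect_equal(unname(spatial_lag(f, g5)$ald), expected)

  # lag commutes with adding a constant
  expect_equal(spatial_lag(f + 3.7, g5)$ald, spatial_lag(f, g5)$ald + 3.7,
               tolerance = 1e-12)

  # islands get NA and are listed
  gi <- queen_from_edgelist(data.frame(a = "a", b = "b"),
                            nodes = c("a", "b", "c"))
  li <- spatial_lag(c(a = 1, b = 2, c = 3), gi)
  expect_equal(li$islands, "c")
  expect_true(is.na(li$ald["c"]))

  expect_error(spatial_lag(c(a = 1, b = 2), gi), "missing values")
})

test_that("custom per-edge weights are validated and used", {
  nb <- list(2L, 1L)
  w <- list(c(1), c(1))
  g <- depdiff:::new_contiguity_graph(c("a", "b"), nb, weights = w,
                                      weight_scheme = "custom")
  expect_equal(unname(spatial_lag(c(a = 2, b = 10), g)$ald), c(10, 2))
  expect_error(
    depdiff:::new_contiguity_graph(c("a", "b"), nb,
                                   weights = list(c(0.5), c(1)),
                                   weight_scheme = "custom"),
    "sum to 1")
})
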