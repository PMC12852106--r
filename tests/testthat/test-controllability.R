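test_that("maximum matching handles path, star and cycle structures", {
  path <- make_net(c("a", "b"), c("b", "c"))
  m <- max_matching(path)
  expect_equal(attr(m, "matching_size"), 2L)
  expect_equal(nrow(m), 2L)

  star <- make_net(rep("c", 3), c("v1", "v2", "v3"))
  expect_equal(attr(max_matching(star), "matching_size"), 1L)

  cyc <- make_net(c("a", "b", "c"), c("b", "c", "a"))
  expect_equal(attr(max_matching(cyc), "matching_size"), 3L)
})

test_that("driver counts follow N_D = max(N - |M*|, 1)", {
  edgeless <- grn_network(data.frame(source = character(),
                                     target = character()),
                          nodes = paste0("n", 1:5))
  d0 <- driver_nodes(edgeless)
  expect_equal(d0$n_drivers, 5L)
  expect_equal(d0$driver_fraction, 1)

  path <- make_net(c("a", "b"), c("b", "c"))
  dp <- driver_nodes(path)
  expect_equal(dp$n_drivers, 1L)
  expect_equal(dp$driver_set, "a")
  expect_equal(dp$driver_fraction, 1 / 3)

  # perfect matching: the floor forces one driver, chosen deterministically
  cyc <- make_net(c("a", "b", "c"), c("b", "c", "a"))
  dc <- driver_nodes(cyc)
  expect_equal(dc$matching_size, 3L)
  expect_equal(dc$n_drivers, 1L)
  expect_equal(dc$driver_set, "a")

  expect_error(driver_nodes(grn_network(
    data.frame(source = character(), target = character()))), "empty")
})

test_that("worked classifications: single edge, transitive triangle, cycle", {
  single <- make_net("a", "b")
  cs <- classify_edges(single)
  expect_equal(cs$l_c, 1)

  tri <- make_net(c("a", "b", "a"), c("b", "c", "c"))
  ct <- tidy(classify_edges(tri))
  lab <- setNames(as.character(ct$label), paste(ct$source, ct$target))
  expect_equal(lab[["a b"]], "critical")
  expect_equal(lab[["b c"]], "critical")
  expect_equal(lab[["a c"]], "redundant")
  expect_equal(glance(classify_edges(tri))[, c("l_c", "l_r", "l_o")],
               tibble::tibble(l_c = 2 / 3, l_r = 1 / 3, l_o = 0))

  # perfect matching: losing any cycle edge is absorbed by the floor
  cyc <- make_net(c("a", "b", "c"), c("b", "c", "a"))
  expect_true(all(tidy(classify_edges(cyc))$label == "ordinary"))

  expect_error(classify_edges(grn_network(
    data.frame(source = character(), target = character()),
    nodes = "a")), "L = 0")
})

test_that("matching size and edge labels match the exhaustive oracle", {
  for (seed in 1:200) {
    net <- random_small_net(seed, n_nodes = sample(3:7, 1), n_edges = 10)
    oracle <- brute_matching(net)
    expect_equal(attr(max_matching(net), "matching_size"), oracle$size,
                 info = paste("seed", seed))
    expect_equal(driver_nodes(net)$n_drivers, brute_n_drivers(net),
                 info = paste("seed", seed))
    if (nrow(net$edges) > 0) {
      got <- as.character(tidy(classify_edges(net))$label)
      expect_equal(got, brute_edge_labels(net), info = paste("seed", seed))
    }
  }
})

test_that("incremental and naive per-edge classification agree", {
  for (seed in c(1:10, 101:105)) {
    net <- random_small_net(seed, n_nodes = 12, n_edges = 30)
    a <- tidy(classify_edges(net, method = "incremental"))
    b <- tidy(classify_edges(net, method = "recompute"))
    expect_identical(a, b, info = paste("seed", seed))
  }
})

test_that("matching size agrees with igraph's bipartite matcher", {
  for (seed in 1:10) {
    net <- random_small_net(seed, n_nodes = 40, n_edges = 120)
    src <- net$edges$source
    tgt <- net$edges$target
    n <- length(net$nodes)
    g <- igraph::graph_from_data_frame(data.frame(
      from = paste0("out_", src), to = paste0("in_", tgt)
    ), directed = FALSE)
    types <- grepl("^in_", igraph::V(g)$name)
    m <- igraph::max_bipartite_match(g, types = types)$matching_size
    expect_equal(attr(max_matching(net), "matching_size"), m,
                 info = paste("seed", seed))
  }
})

test_that("removing a redundant edge leaves the matching and drivers intact", {
  checked <- 0
  for (seed in 1:60) {
    net <- random_small_net(seed, n_nodes = 6, n_edges = 10)
    if (nrow(net$edges) == 0) next
    cls <- tidy(classify_edges(net))
    nd <- driver_nodes(net)
    for (e in which(cls$label == "redundant")) {
      sub <- suppressWarnings(grn_network(net$edges[-e, ],
                                          nodes = net$nodes))
      expect_equal(driver_nodes(sub)$matching_size, nd$matching_size)
      expect_equal(driver_nodes(sub)$n_drivers, nd$n_drivers)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 20)
})

test_that("removing a critical edge raises the driver count by exactly one", {
  checked <- 0
  for (seed in 1:60) {
    net <- random_small_net(seed, n_nodes = 6, n_edges = 10)
    if (nrow(net$edges) == 0) next
    cls <- tidy(classify_edges(net))
    nd <- driver_nodes(net)
    for (e in which(cls$label == "critical")) {
      sub <- grn_network(net$edges[-e, ], nodes = net$nodes)
      expect_equal(driver_nodes(sub)$matching_size, nd$matching_size - 1L)
      expect_equal(driver_nodes(sub)$n_drivers, nd$n_drivers + 1L)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 20)
})

test_that("adding an edge never increases the driver count", {
  for (seed in 1:50) {
    net <- random_small_net(seed, n_nodes = 7, n_edges = 9)
    before <- driver_nodes(net)$n_drivers
    extra <- withr::with_seed(seed + 1000, {
      pairs <- expand.grid(source = net$nodes, target = net$nodes,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$source != pairs$target, ]
      key <- paste(pairs$source, pairs$target)
      have <- paste(net$edges$source, net$edges$target)
      pool <- pairs[!key %in% have, ]
      pool[sample(nrow(pool), 1), ]
    })
    grown <- grn_network(rbind(as.data.frame(net$edges), extra),
                         nodes = net$nodes)
    expect_lte(driver_nodes(grown)$n_drivers, before)
  }
})

test_that("a network at published phase-1 scale classifies quickly", {
  net <- generate_network(N = 503, L = 2711, tf_fraction = 0.4, seed = 42)
  elapsed <- system.time(cls <- classify_edges(net))["elapsed"]
  expect_lt(elapsed, 60)
  expect_equal(cls$l_c + cls$l_r + cls$l_o, 1, tolerance = 1e-12)
  expect_equal(round(cls$l_c * cls$L), cls$l_c * cls$L, tolerance = 1e-9)
})
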