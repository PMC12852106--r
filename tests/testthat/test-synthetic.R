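test_that("the generator is a pure function of seed and parameters", {
  a <- generate_network(300, 700, seed = 17)
  b <- generate_network(300, 700, seed = 17)
  expect_identical(a$edges, b$edges)
  c <- generate_network(300, 700, seed = 18)
  expect_false(identical(a$edges, c$edges))
})

test_that("generated networks are simple, exact-size, TF-sourced", {
  for (seed in 1:10) {
    net <- generate_network(120, 400, tf_fraction = 0.25, seed = seed)
    expect_equal(network_size(net), tibble::tibble(N = 120L, L = 400L))
    expect_false(any(net$edges$source == net$edges$target))
    expect_false(any(duplicated(paste(net$edges$source,
                                      net$edges$target))))
    expect_true(all(net$edges$source %in% net$tf_nodes))
    expect_length(net$tf_nodes, ceiling(0.25 * 120))
  }
})

test_that("a single-TF network is a star from that TF", {
  net <- generate_network(50, 30, tf_fraction = 1 / 50, seed = 4)
  expect_length(unique(net$edges$source), 1L)
  expect_equal(nrow(net$edges), 30L)
})

test_that("infeasible edge counts are refused", {
  expect_error(generate_network(10, 10 * 9 + 1, tf_fraction = 1, seed = 1),
               "infeasible")
  expect_error(generate_network(20, 100, tf_fraction = 0.05, seed = 1),
               "infeasible")  # 1 TF can reach at most 19 targets
})

test_that("the planted degree exponent is recovered by the CCDF fit", {
  # configuration-model setting: plain power-law out-degrees for all nodes
  gammas <- vapply(1:20, function(s) {
    net <- generate_network(N = 2000, L = 5400, gamma_target = 2.3,
                            tf_fraction = 1, k_min_hub = 1,
                            p_selective = 0, seed = s)
    degree_exponent(node_degrees(net, "out")$degree)$gamma
  }, numeric(1))
  expect_true(all(gammas >= 2.0 & gammas <= 2.6))
})

test_that("the default cohort reproduces the 3/5/7/25 phase design", {
  nets <- generate_cohort(seed = 8)
  expect_length(nets, 40L)
  phases <- vapply(nets, function(n) n$phase, integer(1))
  expect_equal(as.integer(table(phases)), c(3L, 5L, 7L, 25L))
  expect_false(any(duplicated(vapply(nets, function(n) n$name, ""))))
  sizes <- vapply(nets, function(n) length(n$nodes), integer(1))
  expect_true(all(sizes >= 259 & sizes <= 584))
  again <- generate_cohort(seed = 8)
  expect_identical(lapply(nets, `[[`, "edges"),
                   lapply(again, `[[`, "edges"))
  expect_error(generate_cohort(tibble::tibble(
    phase = 1, n_networks = 2L, n_min = 50L, n_max = 40L,
    k_min = 1, k_max = 2)), "phase 1")
})

test_that("identical phase parameters yield no spurious phase effect in n_D", {
  flat <- tibble::tibble(phase = 1:4, n_networks = c(3L, 5L, 7L, 25L),
                         n_min = 80L, n_max = 120L,
                         k_min = 2, k_max = 3)
  p_vals <- vapply(1:20, function(s) {
    nets <- generate_cohort(flat, seed = s)
    nd <- vapply(nets, function(n) driver_nodes(n)$driver_fraction,
                 numeric(1))
    ph <- vapply(nets, function(n) n$phase, integer(1))
    kruskal_wallis(data.frame(v = nd, g = ph), v, g)$p_value
  }, numeric(1))
  expect_gte(mean(p_vals >= 0.05), 0.9)
})

test_that("doubling final-phase density turns the density-n_D link negative", {
  shifted <- tibble::tibble(phase = 1:4, n_networks = c(3L, 5L, 7L, 25L),
                            n_min = 80L, n_max = 120L,
                            k_min = c(2, 2, 2, 4), k_max = c(3, 3, 3, 6))
  r_vals <- vapply(1:20, function(s) {
    nets <- generate_cohort(shifted, seed = s)
    d <- t(vapply(nets, function(n) {
      c(dens = network_density(n)$avg_degree,
        nd = driver_nodes(n)$driver_fraction)
    }, numeric(2)))
    cor_pearson(as.data.frame(d), dens, nd)$r
  }, numeric(1))
  expect_gte(mean(r_vals < 0), 0.95)
})

test_that("expression tables are reproducible and respect zero counts", {
  nets <- list(generate_network(40, 90, seed = 1, name = "s1"),
               generate_network(40, 90, seed = 2, name = "s2"))
  e1 <- generate_expression(nets, seed = 3)
  e2 <- generate_expression(nets, seed = 3)
  expect_identical(e1, e2)
  expect_setequal(unique(e1$sample), c("s1", "s2"))
  expect_true(all(e1$normalized[e1$count == 0] == 0))
  expect_true(all(e1$normalized >= 0))
})

test_that("with exchangeable means the strict upper-quartile rule flags ~25%", {
  net <- generate_network(200, 400, tf_fraction = 0.5, seed = 6, name = "s")
  cls <- classify_edges(net)
  fracs <- vapply(1:10, function(s) {
    expr <- generate_expression(list(net), seed = s, hub_boost = 0)
    flags <- categorize_tfs(net, cls, expr)
    mean(flags$is_high_expression)
  }, numeric(1))
  expect_equal(mean(fracs), 0.25, tolerance = 0.05)
})

test_that("the packaged table satisfies its internal consistency checks", {
  tab <- table1_metrics()
  expect_equal(nrow(tab), 40L)
  expect_equal(as.integer(table(tab$phase)), c(3L, 5L, 7L, 25L))
  expect_true(all(abs(tab$l_r + tab$l_o + tab$l_c - 1) < 1e-5))
  nd_counts <- tab$n_D * tab$N
  expect_true(all(abs(nd_counts - round(nd_counts)) < 0.01))
  row1 <- tab[1, ]
  expect_equal(row1$grn, "Enveloping Layer")
  expect_equal(c(row1$N, row1$L), c(503L, 2711L))
})
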