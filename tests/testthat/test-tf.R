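test_that("total-count normalization scales each sample and applies log1p", {
  m <- matrix(c(1, 3, 0, 0, 5, 0), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ex <- normalize_expression(m, scale = 100)
  v <- function(g, s) ex$normalized[ex$gene == g & ex$sample == s]
  expect_equal(v("g1", "s1"), log1p(25))
  expect_equal(v("g2", "s1"), log1p(75))
  expect_equal(v("g3", "s1"), 0)            # all-zero gene stays 0
  expect_equal(v("g2", "s2"), log1p(100))   # whole library in one gene
  # pre-log values sum to the scale factor within each sample
  pre <- tapply(expm1(ex$normalized), ex$sample, sum)
  expect_equal(as.numeric(pre), c(100, 100))

  expect_error(normalize_expression(
    matrix(0, 1, 1, dimnames = list("g", "s"))), "zero total")
  expect_error(normalize_expression(
    matrix(-1, 1, 1, dimnames = list("g", "s"))), "non-negative")
})

test_that("HE membership is invariant to the normalization scale factor", {
  nets <- list(generate_network(50, 120, seed = 21, name = "n1", phase = 1))
  cls <- classify_edges(nets[[1]])
  for (scale in c(1e4, 1e6)) {
    expr <- generate_expression(nets, seed = 5, scale = scale)
    flags <- categorize_tfs(nets[[1]], cls, expr)
    if (scale == 1e4) he_ref <- flags$is_high_expression
  }
  expr6 <- generate_expression(nets, seed = 5, scale = 1e6)
  expect_equal(categorize_tfs(nets[[1]], cls, expr6)$is_high_expression,
               he_ref)
})

test_that("category cuts: outdegree strictly above 50, quantile strict", {
  src <- c(rep("hub", 51), rep("edge50", 50))
  tgt <- c(paste0("t", 1:51), paste0("u", 1:50))
  net <- grn_network(data.frame(source = src, target = tgt),
                     tf_nodes = c("hub", "edge50"), name = "thresh")
  cls <- classify_edges(net)
  flags <- categorize_tfs(net, cls)
  expect_true(flags$is_high_outdegree[flags$tf == "hub"])
  expect_false(flags$is_high_outdegree[flags$tf == "edge50"])
})

test_that("critical TFs are exactly the sources of critical edges", {
  net <- grn_network(data.frame(source = c("a", "c", "d", "c"),
                                target = c("b", "d", "e", "e")),
                     name = "crit")
  cls <- classify_edges(net)
  flags <- categorize_tfs(net, cls)
  crit_sources <- unique(cls$edges$source[cls$edges$label == "critical"])
  expect_setequal(flags$tf[flags$is_critical], crit_sources)
  expect_true(all(flags$outdegree[flags$is_critical] >= 1))

  # a cycle has no critical edges at all
  cyc <- make_net(c("a", "b", "c"), c("b", "c", "a"))
  fc <- categorize_tfs(cyc, classify_edges(cyc))
  expect_false(any(fc$is_critical))
})

test_that("TFs missing from the expression sample are excluded from HE", {
  net <- make_net(c("a", "b"), c("b", "c"))
  cls <- classify_edges(net)
  expr <- normalize_expression(
    matrix(c(5, 10), 2, 1, dimnames = list(c("a", "x"), "network")))
  expect_warning(flags <- categorize_tfs(net, cls, expr), "absent")
  expect_true(flags$expr_missing[flags$tf == "b"])
  expect_false(flags$is_high_expression[flags$tf == "b"])
})

test_that("integration takes unions across networks into 7 disjoint regions", {
  f1 <- tibble::tibble(network = "n1", phase = 1L, tf = c("x", "y"),
                       outdegree = c(3L, 60L), expression = c(1, 2),
                       is_critical = c(TRUE, FALSE),
                       is_high_outdegree = c(FALSE, TRUE),
                       is_high_expression = c(FALSE, FALSE),
                       expr_missing = FALSE)
  f2 <- tibble::tibble(network = "n2", phase = 2L, tf = c("x", "z"),
                       outdegree = c(1L, 2L), expression = c(9, 1),
                       is_critical = c(FALSE, FALSE),
                       is_high_outdegree = c(FALSE, FALSE),
                       is_high_expression = c(TRUE, FALSE),
                       expr_missing = FALSE)
  cat12 <- integrate_categories(list(f1, f2))
  tt <- tidy(cat12)
  expect_equal(as.character(tt$region[tt$tf == "x"]), "C_HE")  # union rule
  expect_equal(as.character(tt$region[tt$tf == "y"]), "HO_only")
  expect_false("z" %in% tt$tf)  # never categorized
  expect_equal(sum(cat12$venn$n), nrow(tt))  # partition covers everything

  # single-network integration reproduces the per-network flags
  cat1 <- integrate_categories(f1)
  expect_equal(tidy(cat1)$is_critical,
               f1$is_critical[order(f1$tf)])
})

test_that("venn gene lists are written one region per file", {
  f <- tibble::tibble(network = "n", phase = 1L, tf = c("a", "b"),
                      outdegree = 1L, expression = 1,
                      is_critical = c(TRUE, TRUE),
                      is_high_outdegree = c(FALSE, TRUE),
                      is_high_expression = FALSE, expr_missing = FALSE)
  dir <- withr::local_tempdir()
  paths <- write_venn_gene_lists(integrate_categories(f), dir)
  expect_length(paths, 7)
  expect_equal(readLines(file.path(dir, "C_only.txt")), "a")
  expect_equal(readLines(file.path(dir, "C_HO.txt")), "b")
})

test_that("hub ranking is by outdegree with stable lexicographic ties", {
  star <- grn_network(data.frame(source = rep("c", 5),
                                 target = paste0("v", 1:5)),
                      tf_nodes = "c")
  expect_equal(hub_genes(star), tibble::tibble(tf = "c", outdegree = 5L))

  net <- grn_network(data.frame(
    source = c(rep("b", 7), rep("a", 3), rep("z", 3)),
    target = paste0("t", 1:13)),
    tf_nodes = c("a", "b", "z"))
  hubs <- hub_genes(net, k = 3)
  expect_equal(hubs$tf, c("b", "a", "z"))  # 7, then tie 3-3 alphabetical
  expect_equal(hubs$outdegree, c(7L, 3L, 3L))

  sink <- grn_network(data.frame(source = "x", target = "y"),
                      tf_nodes = "y")
  expect_warning(empty <- hub_genes(sink), "no TF sources")
  expect_equal(nrow(empty), 0L)
})
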