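test_that("fixture catalogue matches its closed-form oracles", {
  fx <- fixture_graphs()
  for (nm in names(fx)) {
    g <- fx[[nm]]
    o <- g$oracle
    m <- network_measures(g)
    expect_equal(m$clustering, o$clustering, info = nm)
    expect_equal(m$fragmentation, o$fragmentation, info = nm)
    expect_equal(m$mean_degree, o$mean_degree, info = nm)
    if (is.na(o$assortativity)) expect_true(is.na(m$assortativity), info = nm)
    else expect_equal(m$assortativity, o$assortativity, info = nm)
  }
})

test_that("measures agree with brute-force enumeration on random graphs", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(5:14, 1)
    m <- sample(0:(n * (n - 1) / 2), 1)
    edges <- random_graph(n, m)
    g <- as_specnet(n, edges)
    expect_equal(avg_clustering(g), clustering_oracle(n, g$edges), info = i)
    expect_equal(fragmentation_index(g), fragmentation_oracle(n, g$edges),
                 tolerance = 1e-9, info = i)
    a <- degree_assortativity(g)
    ao <- assortativity_oracle(n, g$edges)
    if (is.na(ao)) expect_true(is.na(a), info = i)
    else expect_equal(a, ao, tolerance = 1e-9, info = i)
  }
})

test_that("measures agree with igraph on larger random graphs", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (i in 1:160) {
    n <- sample(10:80, 1)
    m <- sample(0:min(200, n * (n - 1) / 2), 1)
    g <- as_specnet(n, random_graph(n, m))
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    expect_equal(avg_clustering(g),
                 igraph::transitivity(ig, type = "localaverageundirected",
                                      isolates = "zero"),
                 tolerance = 1e-9, info = i)
    a <- degree_assortativity(g)
    ai <- igraph::assortativity_degree(ig)
    if (is.nan(ai) || is.na(ai)) expect_true(is.na(a), info = i)
    else expect_equal(a, ai, tolerance = 1e-9, info = i)
    comp <- igraph::components(ig)
    expect_equal(fragmentation_index(g),
                 1 - sum(comp$csize * (comp$csize - 1)) / (n * (n - 1)),
                 tolerance = 1e-9, info = i)
    expect_equal(mean_degree_and_density(g)$mean_degree,
                 mean(igraph::degree(ig)), info = i)
  }
})

test_that("fragmentation endpoints and monotonicity under edge addition", {
  empty <- as_specnet(500, matrix(integer(0), 0, 2))
  expect_identical(fragmentation_index(empty), 1)
  path <- as_specnet(100, cbind(1:99, 2:100))
  expect_identical(fragmentation_index(path), 0)
  expect_error(fragmentation_index(as_specnet(1, matrix(integer(0), 0, 2))),
               "two nodes")

  set.seed(5)
  n <- 30
  perm <- random_graph(n, n * (n - 1) / 2)
  perm <- perm[sample.int(nrow(perm)), , drop = FALSE]
  prev <- 1
  for (m in c(0, 5, 10, 20, 40, 80, nrow(perm))) {
    fr <- fragmentation_index(as_specnet(n, perm[seq_len(m), , drop = FALSE]))
    expect_lte(fr, prev)
    prev <- fr
  }
})

test_that("measure ranges and conventions hold", {
  set.seed(8)
  for (i in 1:20) {
    g <- as_specnet(20, random_graph(20, sample(0:60, 1)))
    m <- network_measures(g)
    expect_gte(m$clustering, 0); expect_lte(m$clustering, 1)
    expect_gte(m$fragmentation, 0); expect_lte(m$fragmentation, 1)
    if (!is.na(m$assortativity)) {
      expect_gte(m$assortativity, -1); expect_lte(m$assortativity, 1)
    }
    expect_equal(m$mean_degree, 19 * m$link_density)
  }
  # undefined assortativity propagates as NA, never 0
  cyc <- fixture_graphs()$cycle5
  expect_true(is.na(degree_assortativity(cyc)))
  # degree<2 convention: excluding isolates changes the average as documented
  g <- as_specnet(4, rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(avg_clustering(g, isolates = "zero"), 3 / 4)
  expect_equal(avg_clustering(g, isolates = "exclude"), 1)
})
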