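test_that("global metrics on canonical small graphs", {
  tri <- triangle_net()
  expect_equal(net_density(complete_net(4)), 1)
  expect_equal(net_density(tri), 1)
  expect_equal(global_transitivity(tri)$value, 1)
  expect_equal(net_diameter(complete_net(5)), 1L)
  expect_equal(net_diameter(path_net(5)), 4L)
  expect_equal(avg_shortest_path(triangle_net()), 1)
  expect_equal(avg_shortest_path(path_net(3)), 4 / 3)

  p3 <- path_net(3)
  expect_equal(global_transitivity(p3)$value, 0)
  # triangle plus pendant: one triangle, sum C(deg,2) = 1+1+3 = 5
  tp <- build_network(edge_tbl(c("a", "b", "a", "c"), c("b", "c", "c", "d"),
                               r = rep(0.8, 4)))
  expect_equal(global_transitivity(tp)$value, 0.6)
  # a single edge has no connected triple: undefined, flagged
  one <- build_network(edge_tbl("a", "b", 0.9))
  tr <- global_transitivity(one)
  expect_equal(tr$value, 0)
  expect_false(tr$defined)

  # two disjoint triangles: diameter over the largest component
  two <- build_network(edge_tbl(c("a", "b", "a", "x", "y", "x"),
                                c("b", "c", "c", "y", "z", "z"),
                                r = rep(0.8, 6)))
  expect_equal(net_diameter(two), 1L)
  expect_equal(analyze_topology(two)$global$components, 2)
})

test_that("degrees, betweenness, and clustering on canonical graphs", {
  star <- star_net(4)
  deg <- vertex_degrees(star)
  expect_equal(unname(deg["hub"]), 4)
  expect_true(all(deg[paste0("leaf", 1:4)] == 1))
  expect_equal(sum(deg), 2 * igraph::ecount(star))

  # star center carries every shortest path; complete-graph vertices none
  expect_equal(unname(vertex_betweenness(star)["hub"]), 1)
  expect_true(all(vertex_betweenness(complete_net(5)) == 0))
  p3 <- path_net(3)
  b3 <- vertex_betweenness(p3)
  expect_equal(unname(b3[c("p1", "p2", "p3")]), c(0, 1, 0))

  expect_equal(unname(clustering_coefficients(triangle_net())), rep(1, 3))
  expect_equal(unname(clustering_coefficients(p3)["p2"]), 0)

  # P3 edge betweenness: each edge lies on 2 of the 3 pair paths
  expect_equal(edge_betweenness_values(p3), c(2, 2))
  expect_equal(edge_betweenness_values(triangle_net()), rep(1, 3))
  # barbell bridge carries all 9 cross-triangle pairs
  bar <- barbell_net()
  et <- analyze_topology(bar)$edges
  bridge <- et[et$source == "c" & et$target == "d", ]
  expect_equal(bridge$betweenness, 9)
})

test_that("topology metrics match brute-force oracles on random graphs", {
  withr::local_seed(1234)
  for (rep in 1:40) {
    adj <- drop_isolated(rand_adjacency(sample(4:8, 1), runif(1, 0.3, 0.8)))
    if (nrow(adj) < 3) next
    net <- adjacency_to_network(adj)
    expect_equal(by_adj_order(vertex_betweenness(net), adj),
                 stats::setNames(oracle_betweenness(adj),
                                 sprintf("v%02d", seq_len(nrow(adj)))),
                 tolerance = 1e-9)
    expect_equal(by_adj_order(clustering_coefficients(net), adj),
                 stats::setNames(oracle_clustering(adj),
                                 sprintf("v%02d", seq_len(nrow(adj)))),
                 tolerance = 1e-9)
    tr <- global_transitivity(net)
    otr <- oracle_transitivity(adj)
    if (is.na(otr)) expect_false(tr$defined) else {
      expect_equal(tr$value, otr, tolerance = 1e-9)
    }
    expect_equal(net_diameter(net), as.integer(oracle_diameter(adj)))
    expect_equal(avg_shortest_path(net), oracle_avg_path(adj),
                 tolerance = 1e-9)
    eb <- analyze_topology(net)$edges
    oeb <- oracle_edge_betweenness(adj)
    labels <- sprintf("v%02d", seq_len(nrow(adj)))
    key <- paste(match(eb$source, labels), match(eb$target, labels),
                 sep = "-")
    expect_equal(eb$betweenness, unname(oeb[key]), tolerance = 1e-9)
  }
})

test_that("power-law fit guards and behaves on a scale-free graph", {
  expect_true(is.na(fit_power_law(star_net(5))$exponent))   # 2 distinct degrees
  expect_true(is.na(fit_power_law(triangle_net())$exponent)) # regular

  withr::local_seed(77)
  g <- igraph::sample_pa(200, m = 2, directed = FALSE)
  igraph::V(g)$name <- paste0("v", seq_len(200))
  pl <- fit_power_law(g)
  expect_gt(pl$exponent, 1.5)
  expect_lt(pl$exponent, 3.5)
  expect_gt(pl$r_squared, 0.5)
})

test_that("analyze_topology aggregates consistently and deterministically", {
  k4 <- complete_net(4)
  rep1 <- analyze_topology(k4)
  expect_equal(rep1$global$density, 1)
  expect_equal(rep1$global$diameter, 1L)
  expect_equal(rep1$global$transitivity, 1)
  expect_equal(sum(rep1$vertices$degree), 2 * rep1$global$edges)

  bar <- barbell_net()
  r1 <- analyze_topology(bar)
  r2 <- analyze_topology(bar)
  expect_identical(r1$global, r2$global)
  expect_identical(r1$vertices, r2$vertices)
  expect_identical(r1$edges, r2$edges)
  expect_equal(sum(r1$vertices$degree), 2 * igraph::ecount(bar))
})

test_that("rank_hubs orders by betweenness, then degree, then label", {
  rep <- analyze_topology(barbell_net())
  hubs <- rank_hubs(rep)
  expect_equal(hubs$label[1:2], c("c", "d")) # bridge endpoints lead
  expect_true(all(diff(hubs$betweenness) <= 0))

  # all-equal betweenness falls back to degree, then label
  star <- star_net(3)
  h2 <- rank_hubs(analyze_topology(star))
  expect_equal(h2$label[1], "hub")
  expect_equal(h2$label[-1], sort(h2$label[-1]))
})

test_that("topology report files mirror the per-vertex and global tables", {
  prefix <- paste0(withr::local_tempdir(), "/")
  rep <- analyze_topology(barbell_net())
  files <- write_topology(rep, prefix)
  per_vertex <- read.csv(files[["vertices"]])
  expect_equal(nrow(per_vertex), 6)
  expect_equal(names(per_vertex),
               c("label", "class", "degree", "betweenness", "clustering"))
  glob <- read.csv(files[["global"]])
  expect_equal(glob$vertices, 6)
  expect_equal(glob$edges, 7)
})
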