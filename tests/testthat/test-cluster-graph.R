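test_that("mean shift separates distant aggregates into the right clusters", {
  set.seed(3)
  g1 <- cbind(runif(10, 90, 130), runif(10, 90, 130))
  g2 <- cbind(runif(10, 590, 630), runif(10, 90, 130))
  ns <- circles_at(rbind(g1, g2), r = 5, image_size = c(800, 300))
  cg <- build_cluster_graph(ns, cluster_graph_config(bandwidth = 40))
  expect_length(cg$clusters, 2)
  sizes <- sort(vapply(cg$clusters, function(cl) length(cl$members), numeric(1)))
  expect_equal(sizes, c(10, 10))
  # oracle: connected components of the 40-px linkage graph
  D <- as.matrix(stats::dist(rbind(g1, g2)))
  expect_true(all(D[1:10, 11:20] > 40))
})

test_that("a single nucleus forms one cluster with no edges", {
  ns <- circles_at(rbind(c(100, 100)), r = 5, image_size = c(256, 256))
  cg <- build_cluster_graph(ns)
  expect_length(cg$clusters, 1)
  expect_equal(nrow(cg$edges), 0)
  f <- cluster_graph_features(cg)
  expect_equal(unname(f["graph_cluster.node_count"]), 1)
  expect_equal(unname(f["graph_cluster.pct_isolated"]), 100)
})

test_that("cluster graph construction is deterministic", {
  p <- phenotype_preset("recurrent")
  ns <- generate_nuclei(p, c(320, 320), seed = 6)
  expect_identical(build_cluster_graph(ns), build_cluster_graph(ns))
})

test_that("complete-graph features match exhaustive BFS values", {
  # four tight groups 100 px apart pairwise-linked (link radius ~237 px)
  ctr <- rbind(c(100, 100), c(200, 100), c(100, 200), c(200, 200))
  pts <- do.call(rbind, lapply(seq_len(4), function(i) {
    sweep(matrix(c(-6, 6, 0, 0, 0, 0, -6, 6), 4, 2), 2, ctr[i, ], "+")
  }))
  ns <- circles_at(pts, r = 4, image_size = c(400, 400))
  cg <- build_cluster_graph(ns)
  expect_length(cg$clusters, 4)
  f <- cluster_graph_features(cg)
  expect_equal(unname(f["graph_cluster.avg_degree"]), 3)
  expect_equal(unname(f["graph_cluster.diameter"]), 1)
  expect_equal(unname(f["graph_cluster.n_components"]), 1)
  expect_equal(unname(f["graph_cluster.giant_ratio"]), 1)
  expect_equal(unname(f["graph_cluster.clustering_c"]), 1)
  expect_equal(unname(f["graph_cluster.clustering_d"]), 1)
  expect_equal(unname(f["graph_cluster.clustering_e"]), 1)
})

test_that("path-graph metrics match all-pairs shortest paths by hand", {
  # A - B - C in a line, 230 px apart: AB and BC link, AC (460) does not
  pts <- rbind(c(100, 100), c(330, 100), c(560, 100))
  ns <- circles_at(pts, r = 5, image_size = c(700, 200))
  cg <- build_cluster_graph(ns)
  expect_equal(nrow(cg$edges), 2)
  f <- cluster_graph_features(cg)
  expect_equal(unname(f["graph_cluster.avg_path_length"]), 4 / 3, tolerance = 1e-12)
  expect_equal(unname(f["graph_cluster.diameter"]), 2)
  expect_equal(unname(f["graph_cluster.radius"]), 1)
  expect_equal(unname(f["graph_cluster.n_central_points"]), 1)  # the middle node
  expect_equal(unname(f["graph_cluster.pct_end_nodes"]), 200 / 3, tolerance = 1e-12)
})

test_that("isolated clusters report 100% isolation and zero edges", {
  pts <- cbind(seq(100, 1300, by = 300), rep(100, 5))
  ns <- circles_at(pts, r = 5, image_size = c(1400, 200))
  cg <- build_cluster_graph(ns, cluster_graph_config(bandwidth = 40, r = 0.1))
  expect_length(cg$clusters, 5)
  f <- cluster_graph_features(cg)
  expect_equal(nrow(cg$edges), 0)
  expect_equal(unname(f["graph_cluster.pct_isolated"]), 100)
  expect_equal(unname(f["graph_cluster.edge_count"]), 0)
  expect_equal(unname(f["graph_cluster.avg_path_length"]), 0)
})

test_that("cluster metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:10) {
    set.seed(s)
    pts <- matrix(runif(24, 50, 450), 12, 2)
    ns <- circles_at(pts, r = 4, image_size = c(512, 512))
    cg <- build_cluster_graph(ns, cluster_graph_config(bandwidth = 20, r = 0.08))
    f <- cluster_graph_features(cg)
    k <- length(cg$clusters)
    g <- igraph::make_empty_graph(n = k, directed = FALSE)
    if (nrow(cg$edges) > 0) {
      g <- igraph::add_edges(g, as.vector(t(as.matrix(cg$edges[, 1:2]))))
    }
    expect_equal(unname(f["graph_cluster.avg_degree"]),
                 mean(igraph::degree(g)))
    expect_equal(unname(f["graph_cluster.n_components"]),
                 igraph::components(g)$no)
    loc <- igraph::transitivity(g, type = "local", isolates = "zero")
    loc[!is.finite(loc)] <- 0
    expect_equal(unname(f["graph_cluster.clustering_c"]), mean(loc),
                 tolerance = 1e-12)
    gt <- igraph::transitivity(g, type = "global")
    expect_equal(unname(f["graph_cluster.clustering_e"]),
                 ifelse(is.finite(gt), gt, 0), tolerance = 1e-12)
    # node-weighted diameter oracle from igraph distances
    D <- igraph::distances(g)
    cmp <- igraph::components(g)$membership
    diam <- sum(vapply(unique(cmp), function(ci) {
      vs <- which(cmp == ci)
      d <- if (length(vs) == 1) 0 else max(D[vs, vs])
      d * length(vs) / k
    }, numeric(1)))
    expect_equal(unname(f["graph_cluster.diameter"]), diam, tolerance = 1e-12)
  }
})
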