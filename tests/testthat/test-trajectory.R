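## small helper: a spot matrix whose panel genes follow two archetypes
archetype_matrix <- function(n_per = 30) {
  panel <- microglial_panel()
  reactive <- c("Trem2", "Cst7", "Lpl", "Axl", "Itgax")
  homeo <- c("P2ry12", "Cx3cr1", "Tmem119", "Hexb")
  x <- matrix(1, length(panel), 2 * n_per,
              dimnames = list(panel, sprintf("s%03d", seq_len(2 * n_per))))
  x[reactive, seq_len(n_per)] <- 5          # DAM-high archetype
  x[homeo, n_per + seq_len(n_per)] <- 5     # homeostatic-high archetype
  x
}

test_that("panel embedding separates expression archetypes on noiseless data", {
  x <- archetype_matrix()
  emb <- suppressWarnings(panel_embedding(x, n_pcs = 3))
  lab <- rep(c(TRUE, FALSE), each = 30)
  expect_equal(helper_auc(emb[, 1], lab) %in% c(0, 1), TRUE)  # AUC exactly 0 or 1
})

test_that("panel embedding enforces panel coverage and rank bounds", {
  x <- archetype_matrix()
  expect_error(panel_embedding(x[1:5, ], n_pcs = 2), "half")
  expect_warning(emb <- panel_embedding(x[, 1:10], panel = rownames(x)[1:2],
                                        n_pcs = 5), "rank|reduced")
  expect_lte(ncol(emb), 2)
  ## identical spots embed identically
  same <- matrix(2, 28, 12, dimnames = list(microglial_panel(), paste0("s", 1:12)))
  emb2 <- suppressWarnings(panel_embedding(same, n_pcs = 2))
  expect_lt(max(abs(sweep(emb2, 2, emb2[1, ]))), 1e-10)
})

test_that("a 1-D segment yields a path graph with coordinate-ordered projections", {
  set.seed(3)
  t <- sort(runif(200, 0, 10))
  emb <- cbind(t, 0)
  g <- learn_principal_graph(emb, n_nodes = 6, seed = 1)
  expect_identical(nrow(g$edges), nrow(g$nodes) - 1L)
  expect_true(igraph::is_connected(g$graph))
  ## path: exactly 2 leaves
  expect_identical(sum(igraph::degree(g$graph) == 1), 2L)
  pt <- compute_pseudotime(g, which.min(g$nodes[, 1]))
  expect_gt(cor(pt$pseudotime, t, method = "spearman"), 0.99)
})

test_that("Y-shaped data produce a tree with three leaves", {
  set.seed(4)
  arm <- function(dx, dy) cbind(runif(80, 0, 5) * dx, runif(80, 0, 5) * dy) +
    matrix(rnorm(160, 0, 0.02), 80, 2)
  emb <- rbind(arm(1, 0), arm(-0.5, 0.87), arm(-0.5, -0.87))
  g <- learn_principal_graph(emb, n_nodes = 9, seed = 2)
  expect_identical(sum(igraph::degree(g$graph) == 1), 3L)
  ## MST invariants
  expect_identical(nrow(g$edges), nrow(g$nodes) - 1L)
  expect_true(igraph::is_connected(g$graph))
})

test_that("degenerate embeddings collapse to a single node with a warning", {
  emb <- matrix(1, 50, 3)
  expect_warning(g <- learn_principal_graph(emb, seed = 1), "degenerate")
  expect_identical(nrow(g$nodes), 1L)
  expect_warning(br <- extract_branches(g, 1), "single-node")
  expect_identical(br, list())
})

test_that("select_root picks the leaf least enriched in the late group", {
  emb <- cbind(c(sort(runif(100, 0, 10))), 0)
  g <- learn_principal_graph(emb, n_nodes = 5, seed = 1)
  late <- emb[, 1] > 7
  rt <- select_root(g, late)
  leaves <- which(igraph::degree(g$graph) == 1)
  fr <- rt$enrichment$late_fraction[leaves]
  expect_equal(rt$enrichment$late_fraction[rt$root], min(fr, na.rm = TRUE))
  expect_lt(mean(emb[g$projection$node == rt$root, 1]), 5)
  ## all-equal fractions tie-break to the smallest node id with a warning
  expect_warning(rt2 <- select_root(g, rep(FALSE, 100)), "tie")
  expect_identical(rt2$root, min(leaves[rt2$enrichment$n[leaves] > 0]))
})

test_that("pseudotime is a rooted tree geodesic with the expected symmetries", {
  ## hand-built path graph via colinear points
  emb <- cbind(rep(0:4, each = 20) + rnorm(100, 0, 0.01), 0)
  g <- learn_principal_graph(emb, n_nodes = 5, seed = 1)
  root <- which.min(g$nodes[, 1])
  pt <- compute_pseudotime(g, root)
  node_order <- order(g$nodes[, 1])
  nt <- pt$node_time[node_order]
  expect_true(all(diff(nt) > 0))
  expect_equal(nt[1], 0)
  ## re-rooting at the opposite leaf reverses the ranking
  other <- which.max(g$nodes[, 1])
  pt2 <- compute_pseudotime(g, other)
  expect_equal(cor(pt$pseudotime, pt2$pseudotime, method = "spearman"), -1,
               tolerance = 1e-9)
  expect_error(compute_pseudotime(g, 99), "root")
})

test_that("pseudotime is 1-Lipschitz along the tree", {
  set.seed(8)
  emb <- matrix(rnorm(600), 200, 3)
  g <- learn_principal_graph(emb, n_nodes = 12, seed = 3)
  leaves <- which(igraph::degree(g$graph) == 1)
  pt <- compute_pseudotime(g, leaves[1])
  d <- igraph::distances(g$graph, weights = igraph::E(g$graph)$weight)
  pr <- g$projection
  ## |pt(a) - pt(b)| <= geodesic between their projection nodes + edge slack
  for (i in seq_len(50)) {
    a <- sample(200, 1); b <- sample(200, 1)
    slack <- g$edges$length[pr$edge[a]] + g$edges$length[pr$edge[b]]
    expect_lte(abs(pt$pseudotime[a] - pt$pseudotime[b]),
               d[pr$node[a], pr$node[b]] + slack + 1e-9)
  }
})

test_that("branches decompose the rooted tree and spatial maps are exact", {
  ## path -> one branch; Y rooted at a leaf -> two branches
  emb_path <- cbind(sort(runif(100, 0, 10)), 0)
  gp <- learn_principal_graph(emb_path, n_nodes = 5, seed = 1)
  rootp <- which.min(gp$nodes[, 1])
  ptp <- compute_pseudotime(gp, rootp)
  expect_identical(length(ptp$branches), 1L)

  set.seed(4)
  arm <- function(dx, dy) cbind(runif(80, 0.2, 5) * dx, runif(80, 0.2, 5) * dy)
  emb <- rbind(cbind(runif(30, -0.1, 0.1), runif(30, -0.1, 0.1)),
               arm(1, 0), arm(-0.5, 0.87), arm(-0.5, -0.87))
  g <- learn_principal_graph(emb, n_nodes = 10, seed = 2)
  leaves <- which(igraph::degree(g$graph) == 1)
  pt <- compute_pseudotime(g, leaves[1])
  expect_identical(length(pt$branches), length(leaves) - 1L)

  positions <- data.frame(barcode = sprintf("b%03d", seq_len(nrow(emb))),
                          x_px = emb[, 1], y_px = emb[, 2])
  tab <- map_pseudotime_spatial(pt, positions, 1)
  member <- pt$edge %in% pt$branches[[1]]$edges
  expect_identical(nrow(tab), sum(member))
  expect_identical(tab$pseudotime, pt$pseudotime[member])
  expect_error(map_pseudotime_spatial(pt, positions, 99), "branch")
  ## trunk spots shared by several branches are flagged
  if (length(pt$branches) > 1) {
    shared_edges <- intersect(pt$branches[[1]]$edges, pt$branches[[2]]$edges)
    if (length(shared_edges))
      expect_true(all(pt$shared[pt$edge %in% shared_edges]))
  }
})

test_that("expression-vs-pseudotime curves respect windowing rules", {
  x <- matrix(c(rep(2, 100), seq(0, 5, length.out = 100)), 2, 100, byrow = TRUE,
              dimnames = list(c("flat", "rising"), sprintf("s%03d", 1:100)))
  pt <- seq(0, 1, length.out = 100)
  cur <- expression_along_pseudotime(x, pt, c("flat", "rising"), n_windows = 10)
  flat <- cur[cur$gene == "flat", ]
  expect_true(all(abs(flat$mean - 2) < 1e-12))
  rising <- cur[cur$gene == "rising", ]
  tau <- cor(rising$window, rising$mean, method = "kendall")
  expect_gte(tau, 0.8)
  ## single window = global mean
  one <- expression_along_pseudotime(x, pt, "rising", n_windows = 1)
  expect_equal(one$mean, mean(x["rising", ]), tolerance = 1e-12)
  expect_error(expression_along_pseudotime(x, pt, "nope"), "present")
})

test_that("a gene linear in the truth activation rises monotonically in windows", {
  gr <- simulate_activation_gradient(seed = 9)
  norm <- log_normalize(gr)
  emb <- panel_embedding(norm)
  g <- learn_principal_graph(emb, seed = 9)
  rt <- suppressWarnings(select_root(g, gr$truth$late))
  pt <- compute_pseudotime(g, rt$root)
  ## construct a probe gene linear in the truth activation and window it
  set.seed(9)
  probe <- rbind(norm, Probe = gr$truth$activation + rnorm(ncol(norm), 0, 0.05))
  cur <- expression_along_pseudotime(probe, pt, "Probe", n_windows = 10)
  expect_gte(cor(cur$window, cur$mean, method = "kendall"), 0.8)
  ## branch ranking helper orders branches by marker expression
  rb <- rank_branches_by_gene(norm, pt, "Trem2")
  expect_identical(nrow(rb), length(pt$branches))
})
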