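## ---------------------------------------------------------------------------
## Signature-restricted pseudotime: panel PCA, principal tree (k-means + MST +
## edge projection), late-group root rule, branch decomposition, spatial
## mapping and expression-vs-pseudotime curves.
## ---------------------------------------------------------------------------

#' Panel-restricted PCA embedding
#'
#' Log-normalizes (if given a `spot_dataset`), restricts to the panel genes,
#' z-scores each gene and embeds spots by PCA. At least half of the panel
#' must be present; missing genes are dropped with a warning.
#'
#' @param x a `spot_dataset` or a gene x spot log-normalized matrix
#' @param panel character vector of panel genes (default the 28-gene
#'   microglial panel, [microglial_panel()])
#' @param n_pcs number of components (capped at the panel rank, with a
#'   warning when capped)
#' @return spots x PCs score matrix
#' @export
panel_embedding <- function(x, panel = microglial_panel(), n_pcs = 10) {
  normalized <- if (inherits(x, "spot_dataset")) log_normalize(x) else x
  present <- intersect(panel, rownames(normalized))
  if (length(present) < max(2, length(panel) / 2))
    stopf("fewer than half of the panel present; missing: %s",
          paste(setdiff(panel, present), collapse = ", "))
  if (length(present) < length(panel))
    warnf("panel gene(s) absent, dropped: %s",
          paste(setdiff(panel, present), collapse = ", "))
  sub <- as.matrix(normalized[present, , drop = FALSE])
  scaled <- suppressWarnings(scale_and_regress(sub, covariates = NULL))
  k <- min(n_pcs, min(dim(scaled)))
  if (k < n_pcs)
    warnf("n_pcs reduced to %d (panel rank bound)", k)
  embed_pca(scaled, n_pcs = k)$scores
}

#' Learn a principal tree over an embedding
#'
#' K-means centroids (`n_nodes = clamp(ceiling(n_spots / 50), 5, 100)` by
#' default) joined by a Euclidean minimum spanning tree; every spot is
#' projected to the nearest point on any tree edge. Deterministic under a
#' fixed seed. A degenerate embedding (all points equal) yields a single-node
#' graph with a warning.
#'
#' @param embedding spots x dims matrix
#' @param n_nodes `"auto"` or an integer number of tree nodes
#' @param seed RNG seed for k-means
#' @return object of class `principal_graph`: `nodes` (coords), `edges`
#'   (data.frame from/to/length), `projection` (per spot: `edge`, `t` along
#'   edge in [0,1], `node` = nearer endpoint, `dist`), `graph` (igraph tree)
#' @export
learn_principal_graph <- function(embedding, n_nodes = "auto", seed = 0) {
  emb <- as.matrix(embedding)
  n <- nrow(emb)
  if (n < 10) stopf("need >= 10 spots")
  if (identical(n_nodes, "auto"))
    n_nodes <- min(max(ceiling(n / 50), 5), 100)
  if (all(apply(emb, 2, stats::sd) < 1e-12)) {
    warnf("degenerate embedding: all points equal; single-node graph")
    nodes <- emb[1, , drop = FALSE]
    proj <- data.frame(edge = NA_integer_, t = 0, node = 1L, dist = 0)
    proj <- proj[rep(1, n), ]; rownames(proj) <- NULL
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = integer(), to = integer(),
                                             length = numeric()),
                          projection = proj,
                          graph = igraph::make_empty_graph(1, directed = FALSE)),
                     class = "principal_graph"))
  }
  set.seed(seed)
  n_nodes <- min(n_nodes, nrow(unique(emb)))
  km <- stats::kmeans(emb, centers = n_nodes, nstart = 10, iter.max = 100)
  nodes <- km$centers
  d <- as.matrix(stats::dist(nodes))
  g_full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                weighted = TRUE)
  tree <- igraph::mst(g_full)
  el <- igraph::as_edgelist(tree, names = FALSE)
  len <- igraph::E(tree)$weight
  edges <- data.frame(from = el[, 1], to = el[, 2], length = len)
  ## project each spot onto the nearest point of any edge segment
  best_d2 <- rep(Inf, n); best_e <- integer(n); best_t <- numeric(n)
  for (e in seq_len(nrow(edges))) {
    a <- nodes[edges$from[e], ]; b <- nodes[edges$to[e], ]
    ab <- b - a
    denom <- sum(ab^2)
    t_e <- if (denom == 0) rep(0, n) else
      pmin(pmax(sweep(emb, 2, a) %*% ab / denom, 0), 1)
    px <- outer(as.numeric(t_e), ab) + rep(a, each = n)
    d2 <- rowSums((emb - px)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; best_e[upd] <- e; best_t[upd] <- t_e[upd]
  }
  node_assign <- ifelse(best_t < 0.5, edges$from[best_e], edges$to[best_e])
  structure(list(nodes = nodes, edges = edges,
                 projection = data.frame(edge = best_e, t = best_t,
                                         node = node_assign,
                                         dist = sqrt(best_d2)),
                 graph = tree),
            class = "principal_graph")
}

## leaves = degree-1 nodes of the tree
graph_leaves <- function(graph) as.integer(which(igraph::degree(graph$graph) == 1))

#' Select the trajectory root by late-group enrichment
#'
#' For every tree node, computes the fraction of spots projected to it that
#' belong to the late disease group; the root is the leaf with the minimal
#' late fraction (the opposite pole of disease progression) and the late pole
#' the leaf with the maximal fraction. Leaves holding no projected spots are
#' excluded from candidacy; ties break to the smallest node id with a
#' warning.
#'
#' @param graph a `principal_graph`
#' @param late_mask logical per-spot membership of the late group (e.g.
#'   AD & 7M)
#' @return list with `root` (node id), `late_pole`, `enrichment` (per-node
#'   late fraction and spot count)
#' @export
select_root <- function(graph, late_mask) {
  leaves <- graph_leaves(graph)
  if (length(leaves) < 2) stopf("graph needs >= 2 leaves")
  node <- graph$projection$node
  n_at <- tabulate(node, nbins = nrow(graph$nodes))
  late_at <- vapply(seq_len(nrow(graph$nodes)),
                    function(v) sum(late_mask[node == v]), numeric(1))
  frac <- ifelse(n_at > 0, late_at / n_at, NA_real_)
  cand <- leaves[n_at[leaves] > 0]
  if (!length(cand)) stopf("no leaf has projected spots")
  fr <- frac[cand]
  if (sum(fr == min(fr)) > 1)
    warnf("tied root candidates; choosing smallest node id")
  root <- unname(cand[which.min(fr)])
  late_pole <- unname(cand[which.max(fr)])
  list(root = root, late_pole = late_pole,
       enrichment = data.frame(node = seq_len(nrow(graph$nodes)),
                               n = n_at, late_fraction = frac))
}

#' Pseudotime as geodesic distance from the root
#'
#' Each spot's pseudotime is the tree geodesic distance from the root node to
#' the spot's projection point on its edge (root-adjacent projections get the
#' smallest values; pseudotime is monotone along any root-to-leaf path and
#' 1-Lipschitz along the tree).
#'
#' @param graph a `principal_graph`
#' @param root a node id of the graph
#' @return list of class `pseudotime_assignment`: `pseudotime` (per spot),
#'   `node_time` (per node), `root`, `branch` (per-spot branch id, see
#'   [extract_branches()]), `branches`
#' @export
compute_pseudotime <- function(graph, root) {
  if (root < 1 || root > nrow(graph$nodes)) stopf("root is not a graph node")
  if (nrow(graph$edges) == 0) {
    pt <- rep(0, nrow(graph$projection))
    return(structure(list(pseudotime = pt, node_time = 0, root = root,
                          branch = rep(NA_integer_, length(pt)),
                          branches = list()),
                     class = "pseudotime_assignment"))
  }
  node_time <- as.numeric(igraph::distances(graph$graph, v = root,
                                            weights = igraph::E(graph$graph)$weight))
  pr <- graph$projection
  ta <- node_time[graph$edges$from[pr$edge]] + pr$t * graph$edges$length[pr$edge]
  tb <- node_time[graph$edges$to[pr$edge]] + (1 - pr$t) * graph$edges$length[pr$edge]
  pt <- pmin(ta, tb)
  br <- extract_branches(graph, root)
  edge_branch <- matrix(FALSE, nrow(graph$edges), length(br))
  for (j in seq_along(br)) edge_branch[br[[j]]$edges, j] <- TRUE
  spot_branch <- apply(edge_branch[pr$edge, , drop = FALSE], 1,
                       function(z) if (any(z)) which(z)[1] else NA_integer_)
  shared <- rowSums(edge_branch[pr$edge, , drop = FALSE]) > 1
  structure(list(pseudotime = pt, node_time = node_time, root = root,
                 branch = spot_branch, shared = shared, edge = pr$edge,
                 branches = br),
            class = "pseudotime_assignment")
}

#' Decompose a rooted tree into root-to-leaf branches
#'
#' One branch per leaf other than the root: the node path from the root to
#' that leaf plus the ids of the edges along it. Spots whose projection edge
#' lies on a branch belong to it; spots on the shared trunk lie on several
#' branches and are flagged via the `shared` element of
#' [compute_pseudotime()].
#'
#' @param graph a `principal_graph`
#' @param root root node id
#' @return list of branches, each with `leaf`, `nodes` (path), `edges`
#'   (edge ids along the path)
#' @export
extract_branches <- function(graph, root) {
  if (nrow(graph$edges) == 0) {
    warnf("single-node graph: no branches")
    return(list())
  }
  leaves <- setdiff(graph_leaves(graph), root)
  edge_key <- paste(pmin(graph$edges$from, graph$edges$to),
                    pmax(graph$edges$from, graph$edges$to))
  lapply(seq_along(leaves), function(j) {
    path <- igraph::shortest_paths(graph$graph, from = root, to = leaves[j],
                                   weights = igraph::E(graph$graph)$weight)$vpath[[1]]
    path <- as.integer(path)
    steps <- cbind(utils::head(path, -1), utils::tail(path, -1))
    eids <- match(paste(pmin(steps[, 1], steps[, 2]),
                        pmax(steps[, 1], steps[, 2])), edge_key)
    list(leaf = leaves[j], nodes = path, edges = eids)
  })
}

#' Spatial map of one branch's pseudotime
#'
#' Subsets the assignment to the spots of one branch (including shared-trunk
#' spots that lie on it) and exports coordinates plus pseudotime, one record
#' per member spot, values bit-equal to the assignment — no interpolation.
#'
#' @param assignment a `pseudotime_assignment`
#' @param positions positions data.frame aligned with the spots
#' @param branch branch index (into `assignment$branches`)
#' @return data.frame `barcode`, `x_px`, `y_px`, `pseudotime`, `shared`
#' @export
map_pseudotime_spatial <- function(assignment, positions, branch) {
  if (!length(assignment$branches) || branch < 1 ||
      branch > length(assignment$branches))
    stopf("unknown branch id: %s", branch)
  on_branch <- assignment$edge %in% assignment$branches[[branch]]$edges
  data.frame(barcode = positions$barcode[on_branch],
             x_px = positions$x_px[on_branch],
             y_px = positions$y_px[on_branch],
             pseudotime = assignment$pseudotime[on_branch],
             shared = assignment$shared[on_branch])
}

#' Expression along pseudotime (windowed means)
#'
#' Orders spots by pseudotime, cuts them into `n_windows` equal-count
#' windows, and reports each gene's per-window mean and sd of log-normalized
#' expression.
#'
#' @param normalized gene x spot log-normalized matrix
#' @param assignment a `pseudotime_assignment` (or numeric pseudotime vector)
#' @param genes genes to profile (must be present)
#' @param n_windows number of equal-count windows (>= 1)
#' @return data.frame `gene`, `window`, `pseudotime` (window mean), `mean`,
#'   `sd`, `n`
#' @export
expression_along_pseudotime <- function(normalized, assignment, genes,
                                        n_windows = 20) {
  pt <- if (inherits(assignment, "pseudotime_assignment"))
    assignment$pseudotime else as.numeric(assignment)
  missing <- setdiff(genes, rownames(normalized))
  if (length(missing)) stopf("gene(s) not present: %s",
                             paste(missing, collapse = ", "))
  if (!length(genes) || !length(pt)) stopf("empty selection")
  n_windows <- max(1L, min(n_windows, length(pt)))
  win <- floor((rank(pt, ties.method = "first") - 1) * n_windows /
                 length(pt)) + 1L
  out <- list()
  x <- as.matrix(normalized[genes, , drop = FALSE])
  for (g in seq_along(genes)) for (wd in seq_len(n_windows)) {
    v <- x[g, win == wd]
    out[[length(out) + 1]] <- data.frame(
      gene = genes[g], window = wd, pseudotime = mean(pt[win == wd]),
      mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  do.call(rbind, out)
}

#' Rank branches by a marker gene
#'
#' Reporting helper for naming trajectories by their marker profile: ranks
#' branches by the mean expression of a query gene over their member spots.
#'
#' @param normalized gene x spot log-normalized matrix
#' @param assignment a `pseudotime_assignment`
#' @param gene a gene symbol
#' @return data.frame `branch`, `mean_expr`, sorted decreasing
#' @export
rank_branches_by_gene <- function(normalized, assignment, gene) {
  if (!gene %in% rownames(normalized)) stopf("gene '%s' not present", gene)
  v <- as.numeric(normalized[gene, ])
  res <- do.call(rbind, lapply(seq_along(assignment$branches), function(j) {
    sel <- !is.na(assignment$branch) & assignment$branch == j
    data.frame(branch = j, mean_expr = mean(v[sel]))
  }))
  res[order(-res$mean_expr), ]
}
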