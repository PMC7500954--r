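#' Train a self-organizing map on lineage proteins
#'
#' Batch-mode SOM training on the arcsinh-scale expression of the
#' lineage-class proteins, the common first stage of cytometry clustering.
#' The codebook is initialized from a random sample of cells (seeded), then
#' refined by \code{rlen} batch updates in which every cell is assigned to
#' its best-matching node and each node is moved to the mean of the cells
#' within a shrinking grid neighborhood. Batch updates make the result
#' deterministic given the seed.
#'
#' @param cells an arcsinh-scale [cell_table].
#' @param lineage character vector of lineage protein names
#'   (default: the panel's lineage-class proteins).
#' @param grid_dims integer (rows, cols) of the map (default \code{c(10, 10)}).
#' @param rlen number of batch training epochs (default 10).
#' @param seed integer seed for codebook initialization.
#' @return An object of class \code{som_grid}: \code{codebook}
#'   (nodes x proteins), \code{grid_dims}, \code{lineage}, \code{seed}.
#' @export
train_som <- function(cells, lineage = lineage_proteins(cells),
                      grid_dims = c(10L, 10L), rlen = 10L, seed = 1L) {
  if (length(lineage) == 0) stop("lineage protein list is empty")
  unknown <- setdiff(lineage, colnames(cells$values))
  if (length(unknown))
    stop("unknown lineage protein(s): ", paste(unknown, collapse = ", "))
  X <- cells$values[, lineage, drop = FALSE]
  n_nodes <- prod(grid_dims)
  if (nrow(X) < n_nodes)
    stop("need at least ", n_nodes, " cells to train a ",
         grid_dims[1], "x", grid_dims[2], " map")

  # grid coordinates and inter-node grid distances for the neighborhood
  gx <- rep(seq_len(grid_dims[2]), each = grid_dims[1])
  gy <- rep(seq_len(grid_dims[1]), times = grid_dims[2])
  gd <- sqrt(outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  codes <- X[sample.int(nrow(X), n_nodes), , drop = FALSE]

  r0 <- stats::quantile(gd[gd > 0], 0.67)
  for (epoch in seq_len(rlen)) {
    radius <- r0 * (1 - (epoch - 1) / rlen)  # linear decay to ~0
    bmu <- nearest_code(X, codes)
    # Gaussian neighborhood: each node always weights its own cells most,
    # so codes cannot collapse onto a shared mean under batch updates
    H <- exp(-(gd / max(radius, 1e-8))^2)
    H[gd > radius] <- 0
    # members-per-node weights: counts of cells mapped to each node
    counts <- tabulate(bmu, nbins = n_nodes)
    sums <- matrix(0, n_nodes, ncol(X))
    occupied <- rowsum(X, bmu)
    sums[as.integer(rownames(occupied)), ] <- occupied
    num <- H %*% sums
    den <- as.vector(H %*% counts)
    upd <- den > 0
    codes[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  rownames(codes) <- NULL
  structure(list(codebook = codes, grid_dims = as.integer(grid_dims),
                 lineage = lineage, seed = as.integer(seed)),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat("<som_grid> ", x$grid_dims[1], "x", x$grid_dims[2], " map on ",
      length(x$lineage), " lineage proteins (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# nearest codebook row per data row; ties broken by lowest node index
nearest_code <- function(X, codes) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(codes))) -
    2 * X %*% t(codes) + outer(rep(1, nrow(X)), rowSums(codes^2))
  max.col(-d2, ties.method = "first")
}

#' Group SOM nodes into metaclusters
#'
#' Hierarchical clustering (average linkage, Euclidean) of the codebook
#' rows, cut at \code{n_meta} groups. Deterministic: no resampling layer.
#' Metacluster ids are relabelled to be contiguous in order of first
#' appearance along the node index.
#'
#' @param grid a trained [train_som()] map.
#' @param n_meta number of metaclusters, between 1 and the node count.
#' @return Integer vector mapping each node to a metacluster in
#'   \code{1..n_meta}.
#' @export
metacluster <- function(grid, n_meta) {
  n_nodes <- nrow(grid$codebook)
  if (n_meta < 1 || n_meta > n_nodes)
    stop("n_meta must be between 1 and the number of nodes (", n_nodes, ")")
  if (n_meta == n_nodes) return(seq_len(n_nodes))
  hc <- stats::hclust(stats::dist(grid$codebook), method = "average")
  raw <- stats::cutree(hc, k = n_meta)
  as.integer(factor(raw, levels = unique(raw)))
}

#' Assign cells to SOM nodes and metaclusters
#'
#' Each cell is mapped to the nearest codebook row (Euclidean distance on
#' the lineage proteins, ties to the lowest node index) and then to that
#' node's metacluster.
#'
#' @param cells an arcsinh-scale [cell_table].
#' @param grid a trained [train_som()] map.
#' @param mapping node-to-metacluster vector from [metacluster()]
#'   (default: every node its own metacluster).
#' @return An object of class \code{cluster_assignment}: \code{node_id},
#'   \code{metacluster_id} (per cell), \code{n_meta}, \code{mapping}.
#' @export
assign_clusters <- function(cells, grid, mapping = NULL) {
  if (is.null(mapping)) mapping <- seq_len(nrow(grid$codebook))
  if (length(mapping) != nrow(grid$codebook))
    stop("mapping length must equal the number of SOM nodes")
  X <- cells$values[, grid$lineage, drop = FALSE]
  node <- nearest_code(X, grid$codebook)
  meta <- as.integer(mapping[node])
  structure(list(node_id = node, metacluster_id = meta,
                 n_meta = max(mapping), mapping = as.integer(mapping)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$node_id), " cells, ",
      x$n_meta, " metaclusters\n", sep = "")
  invisible(x)
}

#' End-to-end clustering of a study
#'
#' Convenience wrapper: [train_som()] on the lineage proteins, then
#' [metacluster()] to \code{n_meta} groups, then [assign_clusters()].
#'
#' @inheritParams train_som
#' @param n_meta number of metaclusters (default 20).
#' @return A \code{cluster_assignment} with the trained grid attached as
#'   attribute \code{"grid"}.
#' @export
cluster_study <- function(cells, n_meta = 20L, grid_dims = c(10L, 10L),
                          rlen = 10L, seed = 1L,
                          lineage = lineage_proteins(cells)) {
  grid <- train_som(cells, lineage = lineage, grid_dims = grid_dims,
                    rlen = rlen, seed = seed)
  mapping <- metacluster(grid, n_meta)
  out <- assign_clusters(cells, grid, mapping)
  attr(out, "grid") <- grid
  out
}

#' Per-sample metacluster proportions
#'
#' @param assignment a \code{cluster_assignment} aligned to \code{cells}.
#' @param cells the [cell_table] the assignment was computed on.
#' @return A samples x metaclusters matrix; each row sums to 1 and clusters
#'   absent from a sample appear with proportion 0.
#' @export
cluster_proportions <- function(assignment, cells) {
  if (length(assignment$metacluster_id) != nrow(cells$values))
    stop("assignment is not aligned to the cell table")
  tab <- table(factor(cells$sample_id, levels = unique(cells$sample_id)),
               factor(assignment$metacluster_id,
                      levels = seq_len(assignment$n_meta)))
  props <- unclass(tab / rowSums(tab))
  dimnames(props) <- list(rownames(tab), paste0("mc", seq_len(assignment$n_meta)))
  props
}
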