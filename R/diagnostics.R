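#' Per-sample median protein expression
#'
#' @param cells an arcsinh-scale [cell_table].
#' @return A samples x proteins matrix of exact medians (even counts: mean
#'   of the two middle values).
#' @export
median_expression <- function(cells) {
  samples <- unique(cells$sample_id)
  out <- t(vapply(samples, function(s) {
    i <- cells$sample_id == s
    if (!any(i)) stop("sample ", s, " has no cells")
    apply(cells$values[i, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(cells$values))))
  rownames(out) <- samples
  out
}

#' Classical MDS of sample median profiles
#'
#' Torgerson double-centering MDS on Euclidean distances between per-sample
#' median expression vectors; configurations of intrinsic dimension <= 2
#' are reproduced exactly up to rigid motion.
#'
#' @param medians a [median_expression()] matrix (>= 3 samples).
#' @return Samples x 2 coordinate matrix.
#' @export
mds_coordinates <- function(medians) {
  if (nrow(medians) < 3) stop("MDS requires at least 3 samples")
  coords <- stats::cmdscale(stats::dist(medians), k = 2)
  # cmdscale may drop trailing zero-eigenvalue dimensions
  if (ncol(coords) < 2)
    coords <- cbind(coords, matrix(0, nrow(coords), 2 - ncol(coords)))
  colnames(coords) <- c("MDS1", "MDS2")
  coords
}

#' Heatmap leaf orders for the median-expression matrix
#'
#' Average-linkage Euclidean dendrograms for samples (rows) and proteins
#' (columns); deterministic and invariant to input row order.
#'
#' @param medians a [median_expression()] matrix.
#' @return A list with \code{sample_order}, \code{protein_order} (leaf
#'   orders) and the two \code{hclust} objects.
#' @export
hierarchical_order <- function(medians) {
  if (nrow(medians) < 2) stop("need at least 2 samples")
  hr <- stats::hclust(stats::dist(medians), method = "average")
  hc <- stats::hclust(stats::dist(t(medians)), method = "average")
  list(sample_order = rownames(medians)[hr$order],
       protein_order = colnames(medians)[hc$order],
       sample_hclust = hr, protein_hclust = hc)
}

#' Nonlinear 2D embedding of subsampled cells
#'
#' Subsamples up to \code{per_sample} cells from each sample and embeds
#' them in 2D with t-SNE on the lineage proteins (arcsinh scale). The
#' embedding is display-only — no metric in the package consumes its
#' coordinates — and reproducible given the seed.
#'
#' @param cells an arcsinh-scale [cell_table].
#' @param per_sample cells per sample (>= 10, default 2000).
#' @param seed subsampling and embedding seed.
#' @param perplexity t-SNE perplexity (default 30, lowered automatically
#'   for small subsamples).
#' @return A list: \code{coords} (cells x 2), \code{index} (row indices of
#'   the embedded cells), \code{seed}.
#' @export
embed_cells <- function(cells, per_sample = 2000L, seed = 1L,
                        perplexity = 30) {
  if (per_sample < 10) stop("per_sample must be >= 10")
  if (!requireNamespace("Rtsne", quietly = TRUE))
    stop("embed_cells requires the Rtsne package")
  idx <- subsample_by_sample(cells$sample_id, per_sample, seed)
  X <- cells$values[idx, lineage_proteins(cells), drop = FALSE]
  perplexity <- min(perplexity, floor((nrow(X) - 1) / 3))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fit <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                      check_duplicates = FALSE, pca = TRUE, verbose = FALSE)
  coords <- fit$Y
  colnames(coords) <- c("TSNE1", "TSNE2")
  list(coords = coords, index = idx, seed = seed)
}

#' Fisher linear discriminant projection of selected cells
#'
#' Fisher's discriminant coordinates on all panel proteins for cells of the
#' selected metaclusters, labelled either by batch or by metacluster. With
#' \code{g} classes at most \code{g - 1} discriminant directions exist; for
#' 2D display the projection is padded with the leading principal component
#' of the within-class residual, orthogonal to the discriminants. A
#' singular within-class scatter is ridge-regularized with a warning.
#'
#' @param cells an arcsinh-scale [cell_table].
#' @param assignment a \code{cluster_assignment}.
#' @param cluster_ids metaclusters to include (default: all).
#' @param label \code{"batch"} or \code{"cluster"} grouping.
#' @param ridge regularization added when the within-class scatter is
#'   numerically singular.
#' @return A list: \code{coords} (cells x 2), \code{labels}, \code{index},
#'   \code{scaling} (protein loadings).
#' @export
lda_projection <- function(cells, assignment,
                           cluster_ids = seq_len(assignment$n_meta),
                           label = c("batch", "cluster"), ridge = 1e-6) {
  label <- match.arg(label)
  index <- which(assignment$metacluster_id %in% cluster_ids)
  if (!length(index)) stop("no cells in the selected metaclusters")
  X <- cells$values[index, , drop = FALSE]
  y <- if (label == "batch") cells$batch[index]
       else assignment$metacluster_id[index]
  y <- factor(y)
  if (nlevels(y) < 2 || any(table(y) < 2))
    stop("LDA requires >= 2 label classes with >= 2 cells each")

  mu <- colMeans(X)
  Sw <- matrix(0, ncol(X), ncol(X))
  Sb <- matrix(0, ncol(X), ncol(X))
  for (lv in levels(y)) {
    Xi <- X[y == lv, , drop = FALSE]
    mi <- colMeans(Xi)
    Ci <- sweep(Xi, 2, mi, "-")
    Sw <- Sw + crossprod(Ci)
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  if (rcond(Sw) < 1e-12) {
    warning("within-class scatter is numerically singular; ",
            "applying ridge regularization")
    Sw <- Sw + ridge * mean(diag(Sw)) * diag(ncol(X))
  }
  eig <- eigen(solve(Sw, Sb))
  n_disc <- min(nlevels(y) - 1L, ncol(X))
  scaling <- Re(eig$vectors[, seq_len(n_disc), drop = FALSE])
  coords <- X %*% scaling
  if (ncol(coords) < 2) {
    # pad with the top variance direction of the residual, orthogonal to
    # the discriminant
    q <- qr.Q(qr(scaling))
    resid <- X - X %*% q %*% t(q)
    pc1 <- stats::prcomp(resid, rank. = 1)$x[, 1]
    coords <- cbind(coords, pc1)
  }
  coords <- coords[, 1:2, drop = FALSE]
  colnames(coords) <- c("LD1", "LD2")
  list(coords = coords, labels = y, index = index, scaling = scaling)
}

#' Assemble a diagnostic bundle for one dataset
#'
#' Computes all four diagnostic plot classes for a study (one of the
#' raw/normalized pair): median-expression matrix with MDS coordinates and
#' heatmap orders; per-sample per-protein expression density tables; a 2D
#' cell embedding (optional); and per-sample cluster proportions.
#'
#' @param cells an arcsinh-scale [cell_table].
#' @param sheet the study sample sheet.
#' @param assignment a \code{cluster_assignment}.
#' @param tag \code{"raw"} or \code{"norm"}.
#' @param embed_per_sample cells per sample for the embedding; \code{0}
#'   skips the embedding.
#' @param seed seed for subsampling/embedding.
#' @return An object of class \code{diagnostic_bundle}.
#' @export
diagnostic_bundle <- function(cells, sheet, assignment,
                              tag = c("raw", "norm"),
                              embed_per_sample = 200L, seed = 1L) {
  tag <- match.arg(tag)
  med <- median_expression(cells)
  dens <- expression_densities(cells)
  emb <- if (embed_per_sample >= 10)
    embed_cells(cells, per_sample = embed_per_sample, seed = seed) else NULL
  structure(list(tag = tag,
                 medians = med,
                 mds = if (nrow(med) >= 3) mds_coordinates(med) else NULL,
                 orders = hierarchical_order(med),
                 densities = dens,
                 embedding = emb,
                 proportions = cluster_proportions(assignment, cells),
                 sheet = validate_sample_sheet(sheet),
                 assignment = assignment,
                 seed = seed),
            class = "diagnostic_bundle")
}

# long-format kernel density tables per sample x protein
expression_densities <- function(cells, n_grid = 128L) {
  samples <- unique(cells$sample_id)
  rows <- list()
  for (s in samples) {
    v <- cells$values[cells$sample_id == s, , drop = FALSE]
    for (j in colnames(v)) {
      d <- stats::density(v[, j], n = n_grid)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, protein = j, x = d$x, density = d$y,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Render a static diagnostic report
#'
#' Writes a self-contained HTML report with the four diagnostic plot
#' classes (median-expression MDS + heatmap, expression distributions,
#' clustering embedding, cluster proportions) side by side for the raw and
#' normalized bundles, plus all underlying tables as CSV files next to it.
#' Plot data files are deterministic given the bundle seeds.
#'
#' @param bundle_raw a \code{diagnostic_bundle} with tag \code{"raw"}.
#' @param bundle_norm optional \code{diagnostic_bundle} with tag
#'   \code{"norm"}; omit for a raw-only report.
#' @param out output directory (created if needed).
#' @param metrics optional named list of metric data.frames (e.g. the
#'   [emd_study()] / [hellinger_study()] outputs) appended as summary
#'   tables.
#' @return The path of the written \code{report.html}, invisibly.
#' @export
render_report <- function(bundle_raw, bundle_norm = NULL, out,
                          metrics = NULL) {
  stopifnot(inherits(bundle_raw, "diagnostic_bundle"))
  if (!is.null(bundle_norm)) {
    stopifnot(inherits(bundle_norm, "diagnostic_bundle"))
    if (!identical(sort(rownames(bundle_raw$medians)),
                   sort(rownames(bundle_norm$medians))))
      stop("raw and normalized bundles describe different studies")
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  bundles <- Filter(Negate(is.null), list(raw = bundle_raw,
                                          norm = bundle_norm))

  csv <- function(x, name) {
    path <- file.path(out, name)
    utils::write.csv(x, path, row.names = FALSE)
    name
  }
  png_plot <- function(name, expr) {
    path <- file.path(out, name)
    grDevices::png(path, width = 1400, height = 640, res = 110)
    on.exit(grDevices::dev.off())
    force(expr)
    name
  }
  sections <- character(0)
  add <- function(title, img, files) {
    sections <<- c(sections, sprintf(
      "<h2>%s</h2><img src='%s' style='max-width:100%%'/><p>Data: %s</p>",
      title, img, paste(sprintf("<a href='%s'>%s</a>", files, files),
                        collapse = ", ")))
  }
  two_panel <- function(draw) {
    graphics::par(mfrow = c(1, length(bundles)), mar = c(4, 4, 3, 1))
    for (nm in names(bundles)) draw(bundles[[nm]], nm)
  }
  batch_of_sample <- function(b)
    b$sheet$batch[match(rownames(b$medians), b$sheet$sample_id)]

  files <- character(0)
  for (nm in names(bundles)) {
    b <- bundles[[nm]]
    files <- c(files,
               csv(data.frame(sample_id = rownames(b$medians), b$medians,
                              check.names = FALSE),
                   paste0("median_expression_", nm, ".csv")),
               csv(b$densities, paste0("densities_", nm, ".csv")),
               csv(data.frame(sample_id = rownames(b$proportions),
                              b$proportions, check.names = FALSE),
                   paste0("proportions_", nm, ".csv")))
    if (!is.null(b$mds))
      files <- c(files, csv(data.frame(sample_id = rownames(b$medians),
                                       b$mds), paste0("mds_", nm, ".csv")))
    if (!is.null(b$embedding))
      files <- c(files, csv(data.frame(cell_index = b$embedding$index,
                                       b$embedding$coords),
                            paste0("embedding_", nm, ".csv")))
  }

  img1 <- png_plot("mds.png", two_panel(function(b, nm) {
    if (is.null(b$mds)) return(invisible())
    bt <- batch_of_sample(b)
    graphics::plot(b$mds, col = bt + 1, pch = 19,
                   main = paste("Median-expression MDS —", nm))
    graphics::text(b$mds, labels = rownames(b$medians), pos = 3, cex = 0.6)
  }))
  add("Median protein expression (MDS of per-sample medians)", img1,
      grep("^(median_expression|mds)_", files, value = TRUE))

  img2 <- png_plot("densities.png", two_panel(function(b, nm) {
    pr <- colnames(b$medians)[1]
    d <- b$densities[b$densities$protein == pr, ]
    bt <- b$sheet$batch[match(d$sample_id, b$sheet$sample_id)]
    graphics::plot(NA, xlim = range(d$x), ylim = range(d$density),
                   xlab = pr, ylab = "density",
                   main = paste("Expression distributions —", nm))
    for (s in unique(d$sample_id)) {
      ds <- d[d$sample_id == s, ]
      graphics::lines(ds$x, ds$density, col = bt[match(s, d$sample_id)] + 1)
    }
  }))
  add("Protein expression distributions (first panel protein shown)", img2,
      grep("^densities_", files, value = TRUE))

  if (!is.null(bundle_raw$embedding)) {
    img3 <- png_plot("embedding.png", two_panel(function(b, nm) {
      if (is.null(b$embedding)) return(invisible())
      cl <- b$assignment$metacluster_id[b$embedding$index]
      graphics::plot(b$embedding$coords, col = cl, pch = ".", cex = 2,
                     main = paste("Cell embedding by metacluster —", nm))
    }))
    add("Clustering results (2D embedding)", img3,
        grep("^embedding_", files, value = TRUE))
  }

  img4 <- png_plot("proportions.png", two_panel(function(b, nm) {
    graphics::barplot(t(b$proportions), beside = FALSE,
                      col = grDevices::rainbow(ncol(b$proportions)),
                      las = 2, cex.names = 0.6,
                      main = paste("Cluster proportions —", nm))
  }))
  add("Cluster proportions per sample", img4,
      grep("^proportions_", files, value = TRUE))

  metric_html <- ""
  if (!is.null(metrics)) {
    for (nm in names(metrics)) {
      f <- csv(metrics[[nm]], paste0("metric_", nm, ".csv"))
      files <- c(files, f)
      metric_html <- paste0(metric_html, sprintf(
        "<li><a href='%s'>%s</a> (%d rows)</li>", f, nm,
        nrow(metrics[[nm]])))
    }
    metric_html <- paste0("<h2>Metric tables</h2><ul>", metric_html, "</ul>")
  }

  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Batch-effect diagnostic report</title></head><body>",
    "<h1>Batch-effect diagnostic report</h1>",
    "<p>Datasets: ", paste(names(bundles), collapse = " vs "),
    ". Subsampling seed(s): ",
    paste(vapply(bundles, function(b) as.character(b$seed), ""),
          collapse = ", "), ".</p>",
    paste(sections, collapse = "\n"), metric_html, "</body></html>")
  path <- file.path(out, "report.html")
  writeLines(html, path)
  invisible(path)
}
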