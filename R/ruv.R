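#' Build the pseudo-replicate structure
#'
#' Pseudo-replicates are cells of a replicated reference patient that fall
#' in the same metacluster but were acquired in different batches: under
#' the replication design any systematic expression difference among them
#' is unwanted (batch) variation. One group is formed per
#' (reference patient, metacluster) pair, pooling that patient's cells in
#' that cluster across all batches; groups with fewer than 2 cells are
#' dropped and every other cell is a singleton.
#'
#' @param assignment a \code{cluster_assignment} for \code{cells}.
#' @param cells the [cell_table] the assignment was computed on.
#' @param sheet the study's sample sheet.
#' @param reference_samples character vector of reference
#'   \code{patient_id}s; each must appear in at least 2 batches.
#' @param clusters_to_use metacluster ids to use, or \code{"all"}.
#' @return An object of class \code{replicate_map}: \code{group_of_cell}
#'   (integer per cell, 0 = singleton) and \code{groups}, a list of
#'   \code{(patient, metacluster, members, batches, single_batch)}.
#' @export
build_replicate_map <- function(assignment, cells, sheet, reference_samples,
                                clusters_to_use = "all") {
  sheet <- validate_sample_sheet(sheet)
  missing_ref <- setdiff(reference_samples, sheet$patient_id)
  if (length(missing_ref))
    stop("reference patient(s) not in sample sheet: ",
         paste(missing_ref, collapse = ", "))
  for (p in reference_samples) {
    nb <- length(unique(sheet$batch[sheet$patient_id == p]))
    if (nb < 2)
      stop("reference patient ", p, " appears in only ", nb, " batch")
  }
  if (identical(clusters_to_use, "all"))
    clusters_to_use <- seq_len(assignment$n_meta)
  bad <- setdiff(clusters_to_use, seq_len(assignment$n_meta))
  if (length(bad))
    stop("invalid metacluster id(s) in clusters_to_use: ",
         paste(bad, collapse = ", "))

  patient_of_cell <- sheet$patient_id[match(cells$sample_id, sheet$sample_id)]
  m <- nrow(cells$values)
  group_of_cell <- integer(m)
  groups <- list()
  for (p in reference_samples) {
    for (cl in clusters_to_use) {
      members <- which(patient_of_cell == p &
                         assignment$metacluster_id == cl)
      if (length(members) < 2) next
      batches <- sort(unique(cells$batch[members]))
      gid <- length(groups) + 1L
      groups[[gid]] <- list(patient = p, metacluster = cl,
                            members = members, batches = batches,
                            single_batch = length(batches) < 2)
      group_of_cell[members] <- gid
    }
  }
  if (!length(groups) || all(vapply(groups, `[[`, TRUE, "single_batch")))
    stop("no shared subpopulation across batches: no pseudo-replicate ",
         "group spans >= 2 batches")
  n_single <- sum(vapply(groups, `[[`, TRUE, "single_batch"))
  if (n_single > 0)
    message(n_single, " pseudo-replicate group(s) cover a single batch only")
  structure(list(group_of_cell = group_of_cell, groups = groups),
            class = "replicate_map")
}

#' @export
print.replicate_map <- function(x, ...) {
  sizes <- lengths(lapply(x$groups, `[[`, "members"))
  cat("<replicate_map> ", length(x$groups), " pseudo-replicate groups, ",
      sum(sizes), " of ", length(x$group_of_cell), " cells grouped",
      " (group sizes ", min(sizes), "-", max(sizes), ")\n", sep = "")
  invisible(x)
}

# subtract each group's column means from its member rows; ungrouped rows -> 0
replicate_residuals <- function(Y, map) {
  R <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (g in map$groups) {
    rows <- Y[g$members, , drop = FALSE]
    R[g$members, ] <- sweep(rows, 2, colMeans(rows), "-")
  }
  R
}

#' Fit the low-rank unwanted-variation model
#'
#' Fits the RUV-III decomposition on a standardized cells x proteins matrix
#' \code{Y}: writing \code{Y = X beta + W alpha + eps}, the biological part
#' \code{X beta} is never estimated; instead the unwanted component
#' \code{W alpha} is estimated from the pseudo-replicate structure and
#' subtracted. Steps: (1) residuals \code{R} are formed by subtracting each
#' pseudo-replicate group's mean from its members (all other cells
#' contribute zero rows, so only replicate disagreement informs the fit);
#' (2) \code{alpha} (k x n) is taken from the top-k right singular
#' directions of \code{R}, scaled by the singular values; (3) \code{W}
#' (m x k) is obtained for every cell by regressing its full protein
#' profile on \code{alpha} — all proteins act as negative controls. The
#' product \code{W alpha} is invariant to the scaling convention of
#' \code{alpha}. When cells far outnumber proteins the singular directions
#' are computed from the n x n cross-product of \code{R} rather than the
#' full SVD; the two routes agree to numerical precision.
#'
#' @param Y standardized numeric matrix (cells x proteins): zero column
#'   means, unit column sds.
#' @param map a [build_replicate_map()] result (or any object with
#'   \code{groups} of member indices).
#' @param k dimension of the unwanted-variation space; \code{k = 0} yields
#'   an empty fit whose adjustment is the identity. A \code{k} above the
#'   numerical rank of the residual matrix is capped with a warning.
#' @return An object of class \code{ruv_fit} with components \code{alpha}
#'   (k x n), \code{W} (m x k), \code{k} (effective), \code{d} (singular
#'   value spectrum of the residuals), \code{n_groups}. Methods:
#'   \code{coef} (alpha), \code{fitted} (the estimated unwanted component
#'   \code{W alpha}), \code{residuals} (the adjusted data
#'   \code{Y - W alpha}), \code{print}, \code{summary}.
#' @export
ruv_fit <- function(Y, map, k) {
  Y <- as.matrix(Y)
  m <- nrow(Y); n <- ncol(Y)
  if (k < 0) stop("k must be >= 0")
  if (k > min(m, n)) stop("k cannot exceed min(cells, proteins)")

  if (k == 0) {
    fit <- list(alpha = matrix(0, 0, n), W = matrix(0, m, 0), k = 0L,
                d = numeric(0), n_groups = length(map$groups), Y = Y)
    class(fit) <- "ruv_fit"
    return(fit)
  }
  if (!length(map$groups))
    stop("all cells are singletons: no residual information to fit")

  R <- replicate_residuals(Y, map)
  if (m > 5L * n) {
    # cells >> proteins: eigen-decompose the n x n cross-product instead of
    # the full m x n SVD; right singular directions and values coincide
    eig <- eigen(crossprod(R), symmetric = TRUE)
    ev <- eig$values
    # eigenvalues at machine-precision level are exact zeros of R'R
    ev[ev < .Machine$double.eps * max(ev, 0) * m] <- 0
    d <- sqrt(pmax(ev, 0))
    V <- eig$vectors
  } else {
    sv <- svd(R)
    d <- sv$d
    V <- sv$v
  }
  rank_R <- sum(d > 1e-10 * d[1])
  if (rank_R == 0) stop("residual matrix is numerically zero; nothing to fit")
  if (k > rank_R) {
    warning("k = ", k, " exceeds the numerical rank of the residuals (",
            rank_R, "); using k = ", rank_R)
    k <- rank_R
  }
  Vk <- V[, seq_len(k), drop = FALSE]
  dk <- d[seq_len(k)]
  alpha <- dk * t(Vk)                      # k x n, rows scaled by sing. values
  W <- (Y %*% Vk) %*% diag(1 / dk, k, k)   # = Y alpha' (alpha alpha')^{-1}
  fit <- list(alpha = alpha, W = W, k = as.integer(k), d = d,
              n_groups = length(map$groups), Y = Y)
  class(fit) <- "ruv_fit"
  fit
}

#' @export
print.ruv_fit <- function(x, ...) {
  cat("<ruv_fit> k = ", x$k, " unwanted factor(s) from ", x$n_groups,
      " pseudo-replicate group(s); ", nrow(x$Y), " cells x ", ncol(x$Y),
      " proteins\n", sep = "")
  invisible(x)
}

#' @export
summary.ruv_fit <- function(object, ...) {
  d <- object$d
  out <- list(k = object$k, n_groups = object$n_groups,
              dim = dim(object$Y),
              singular_values = utils::head(d, 10),
              removed_frobenius = sqrt(sum(fitted(object)^2)),
              variance_explained = if (length(d))
                sum(d[seq_len(object$k)]^2) / sum(d^2) else 0)
  class(out) <- "summary.ruv_fit"
  out
}

#' @export
print.summary.ruv_fit <- function(x, ...) {
  cat("Unwanted-variation fit (RUV-III)\n")
  cat("  cells x proteins   :", x$dim[1], "x", x$dim[2], "\n")
  cat("  pseudo-rep groups  :", x$n_groups, "\n")
  cat("  k                  :", x$k, "\n")
  cat("  leading sing. vals :",
      paste(signif(x$singular_values, 4), collapse = " "), "\n")
  cat("  residual variance captured by k factors:",
      sprintf("%.1f%%", 100 * x$variance_explained), "\n")
  cat("  ||W alpha||_F      :", signif(x$removed_frobenius, 5), "\n")
  invisible(x)
}

#' @export
coef.ruv_fit <- function(object, ...) object$alpha

#' @export
fitted.ruv_fit <- function(object, ...) {
  if (object$k == 0) matrix(0, nrow(object$Y), ncol(object$Y),
                            dimnames = dimnames(object$Y))
  else object$W %*% object$alpha
}

#' @export
residuals.ruv_fit <- function(object, ...) object$Y - fitted(object)

#' Subtract the estimated unwanted component
#'
#' \code{adjust(Y, fit)} returns \code{Y - W alpha}. For the matrix the fit
#' was computed on this equals \code{residuals(fit)}; for a new matrix with
#' the same proteins, \code{W} is re-estimated by the same all-protein
#' regression on \code{alpha}.
#'
#' @param Y standardized matrix (cells x proteins).
#' @param fit a [ruv_fit()] object.
#' @return The adjusted standardized matrix.
#' @export
adjust <- function(Y, fit) {
  Y <- as.matrix(Y)
  if (fit$k == 0) return(Y)
  if (ncol(Y) != ncol(fit$alpha))
    stop("protein dimension of Y does not match the fit")
  A <- fit$alpha
  W <- Y %*% t(A) %*% solve(A %*% t(A))
  Y - W %*% A
}

#' Normalize a multi-batch study
#'
#' The full pipeline on an arcsinh-scale study: (1) cluster all cells
#' (SOM + metaclustering on lineage proteins), (2) define pseudo-replicates
#' from the replicated reference patients, (3) standardize every protein
#' globally, (4-6) fit the unwanted-variation model with [ruv_fit()] and
#' subtract \code{W alpha}, then map back to the arcsinh scale.
#'
#' @param cells an arcsinh-scale [cell_table].
#' @param sheet the study sample sheet.
#' @param reference_samples reference \code{patient_id}s replicated across
#'   batches.
#' @param k unwanted-variation dimension.
#' @param n_meta number of metaclusters (default 20).
#' @param grid_dims SOM grid (default 10 x 10).
#' @param clusters_to_use metacluster ids used for pseudo-replicates, or
#'   \code{"all"}.
#' @param seed seed for SOM initialization.
#' @param assignment optionally, a precomputed \code{cluster_assignment}
#'   (skips clustering — used when sweeping k).
#' @return An object of class \code{cytof_norm}: \code{adjusted}
#'   (arcsinh-scale [cell_table]), \code{fit} ([ruv_fit()]),
#'   \code{assignment}, \code{map}, \code{std_params}, \code{config}.
#' @export
normalize_study <- function(cells, sheet, reference_samples, k,
                            n_meta = 20L, grid_dims = c(10L, 10L),
                            clusters_to_use = "all", seed = 1L,
                            assignment = NULL) {
  if (cells$scale != "arcsinh")
    stop("normalize_study expects an arcsinh-scale cell table")
  sheet <- validate_sample_sheet(sheet)
  missing_ref <- setdiff(reference_samples, sheet$patient_id)
  if (length(missing_ref))
    stop("reference patient(s) not in sample sheet: ",
         paste(missing_ref, collapse = ", "))
  if (length(unique(sheet$batch)) < 2)
    stop("normalization requires >= 2 batches")

  if (is.null(assignment))
    assignment <- cluster_study(cells, n_meta = n_meta,
                                grid_dims = grid_dims, seed = seed)
  map <- build_replicate_map(assignment, cells, sheet, reference_samples,
                             clusters_to_use = clusters_to_use)
  std <- standardize(cells)
  fit <- ruv_fit(std$cells$values, map, k)
  adj_std <- residuals(fit)
  adjusted <- cells
  adjusted$values <- unstandardize(adj_std, std$params)
  structure(list(adjusted = adjusted, fit = fit, assignment = assignment,
                 map = map, std_params = std$params,
                 config = list(reference_samples = reference_samples,
                               k = fit$k, n_meta = assignment$n_meta,
                               grid_dims = grid_dims,
                               clusters_to_use = clusters_to_use,
                               seed = seed)),
            class = "cytof_norm")
}

#' @export
print.cytof_norm <- function(x, ...) {
  cat("<cytof_norm> study normalized with k = ", x$fit$k,
      ", references: ", paste(x$config$reference_samples, collapse = ", "),
      "\n", sep = "")
  print(x$adjusted)
  invisible(x)
}

#' @export
summary.cytof_norm <- function(object, ...) summary(object$fit, ...)

#' Percentile-scaling baseline correction
#'
#' A simple batch-correction baseline: for every protein, each batch's raw
#' intensities are multiplied by the ratio of the reference sample's 95th
#' percentile in batch 1 to the same percentile in that batch, so the
#' reference percentiles line up across batches. No transformation is
#' applied to the data before scaling.
#'
#' @param cells a raw-scale [cell_table].
#' @param sheet the study sample sheet.
#' @param reference_samples reference \code{patient_id}(s); their cells in
#'   each batch define the percentile anchors.
#' @param percentile percentile in (0, 100), default 95.
#' @return The scaled raw-scale [cell_table].
#' @export
percentile_scale_baseline <- function(cells, sheet, reference_samples,
                                      percentile = 95) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  if (cells$scale != "raw")
    stop("the percentile baseline operates on raw intensities")
  sheet <- validate_sample_sheet(sheet)
  patient_of_cell <- sheet$patient_id[match(cells$sample_id, sheet$sample_id)]
  is_ref <- patient_of_cell %in% reference_samples
  batches <- sort(unique(cells$batch))
  if (!all(batches %in% unique(cells$batch[is_ref])))
    stop("reference sample(s) must be present in every batch")
  p <- percentile / 100
  target <- apply(cells$values[is_ref & cells$batch == batches[1], ,
                               drop = FALSE], 2, stats::quantile, probs = p)
  out <- cells
  for (b in batches) {
    ref_b <- apply(cells$values[is_ref & cells$batch == b, , drop = FALSE],
                   2, stats::quantile, probs = p)
    factor_b <- target / ref_b
    # a non-positive anchor cannot be equalized by a positive scale factor
    zero <- !is.finite(factor_b) | ref_b <= 0 | target <= 0
    if (any(zero)) {
      warning("non-positive reference percentile in batch ", b, " for: ",
              paste(colnames(cells$values)[zero], collapse = ", "),
              "; protein(s) left unscaled")
      factor_b[zero] <- 1
    }
    rows <- cells$batch == b
    out$values[rows, ] <- sweep(cells$values[rows, , drop = FALSE],
                                2, factor_b, "*")
  }
  out
}
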