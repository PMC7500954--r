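#' Binned 1D earth mover's distance
#'
#' The 1D Wasserstein-1 distance between two empirical distributions after
#' binning on a shared grid spanning the pooled range:
#' \code{sum over bins |CDF_x - CDF_y| * bin_width}. With the default bin
#' width of 0.1 on the arcsinh scale this is the conventional cytometry
#' cross-batch comparison; as the bin width shrinks it converges to the
#' exact W1 (for a pure location shift the error is at most one bin width).
#'
#' @param x,y nonempty numeric vectors.
#' @param bin_width positive bin width (default 0.1).
#' @return Nonnegative scalar distance.
#' @export
emd_1d <- function(x, y, bin_width = 0.1) {
  if (!length(x) || !length(y)) stop("emd_1d requires nonempty inputs")
  if (bin_width <= 0) stop("bin_width must be positive")
  lo <- floor(min(x, y) / bin_width) * bin_width
  hi <- max(x, y)
  # one closing bin so a value at the pooled maximum keeps its full
  # distance from the rest
  n_bins <- floor((hi - lo) / bin_width + 1e-9) + 1L
  bx <- pmin(floor((x - lo) / bin_width + 1e-9) + 1L, n_bins)
  by <- pmin(floor((y - lo) / bin_width + 1e-9) + 1L, n_bins)
  cdf_x <- cumsum(tabulate(bx, n_bins)) / length(x)
  cdf_y <- cumsum(tabulate(by, n_bins)) / length(y)
  sum(abs(cdf_x - cdf_y)) * bin_width
}

# replicated patients: those with samples in >= 2 batches
replicated_pairings <- function(sheet) {
  sheet <- validate_sample_sheet(sheet)
  keep <- vapply(split(sheet$batch, sheet$patient_id),
                 function(b) length(unique(b)) >= 2, TRUE)
  names(keep)[keep]
}

#' Cross-batch EMD tables for a study
#'
#' For every replicated patient (present in >= 2 batches), every batch
#' pair and every protein, computes the binned EMD between that patient's
#' expression distributions in the two batches, on the arcsinh scale, for
#' the raw and (optionally) normalized data. With \code{by_cluster = TRUE}
#' the comparison is additionally stratified by metacluster; a cluster
#' empty for the patient in either batch yields a missing (\code{NA})
#' entry, never zero.
#'
#' @param raw arcsinh-scale [cell_table] before correction.
#' @param norm arcsinh-scale [cell_table] after correction (same cells), or
#'   \code{NULL} for a raw-only table.
#' @param sheet the study sample sheet.
#' @param assignment \code{cluster_assignment}, required when
#'   \code{by_cluster = TRUE}.
#' @param by_cluster stratify by metacluster (default FALSE).
#' @param bin_width EMD bin width (default 0.1).
#' @return A data.frame with columns patient, batch_a, batch_b, protein,
#'   metacluster (NA for the overall rows), dataset ("raw"/"norm"), emd.
#' @export
emd_study <- function(raw, norm = NULL, sheet, assignment = NULL,
                      by_cluster = FALSE, bin_width = 0.1) {
  if (raw$scale != "arcsinh") stop("EMD is computed on the arcsinh scale")
  if (by_cluster && is.null(assignment))
    stop("by_cluster = TRUE requires a cluster assignment")
  sheet <- validate_sample_sheet(sheet)
  patients <- replicated_pairings(sheet)
  if (!length(patients)) stop("no patient is replicated across batches")
  patient_of_cell <- sheet$patient_id[match(raw$sample_id, sheet$sample_id)]
  datasets <- list(raw = raw)
  if (!is.null(norm)) datasets$norm <- norm

  strata <- if (by_cluster) seq_len(assignment$n_meta) else NA_integer_
  rows <- list()
  for (p in patients) {
    in_p <- patient_of_cell == p
    bs <- sort(unique(raw$batch[in_p]))
    for (a_i in seq_len(length(bs) - 1)) for (b_i in (a_i + 1):length(bs)) {
      ba <- bs[a_i]; bb <- bs[b_i]
      for (cl in strata) {
        ia <- in_p & raw$batch == ba
        ib <- in_p & raw$batch == bb
        if (!is.na(cl)) {
          ia <- ia & assignment$metacluster_id == cl
          ib <- ib & assignment$metacluster_id == cl
        }
        empty <- sum(ia) == 0 || sum(ib) == 0
        for (ds in names(datasets)) {
          v <- datasets[[ds]]$values
          e <- if (empty) rep(NA_real_, ncol(v)) else
            vapply(seq_len(ncol(v)), function(j)
              emd_1d(v[ia, j], v[ib, j], bin_width), numeric(1))
          rows[[length(rows) + 1L]] <- data.frame(
            patient = p, batch_a = ba, batch_b = bb,
            protein = colnames(v), metacluster = cl,
            dataset = ds, emd = e, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Hellinger distance between two probability vectors
#'
#' \code{H(p, q) = sqrt(1/2 * sum (sqrt(p_i) - sqrt(q_i))^2)}, in [0, 1]:
#' 0 for identical vectors, 1 exactly when the supports are disjoint. Used
#' on per-sample cluster proportion vectors across batches.
#'
#' @param p,q nonnegative vectors of equal length summing to 1.
#' @return Scalar in [0, 1].
#' @export
hellinger <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("proportions must each sum to 1")
  min(1, sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2)))
}

#' Cross-batch Hellinger distances on cluster proportions
#'
#' For every replicated patient and batch pair, the Hellinger distance
#' between the metacluster proportion vectors of that patient's two
#' samples.
#'
#' @param assignment a \code{cluster_assignment}.
#' @param cells the [cell_table] it was computed on.
#' @param sheet the study sample sheet.
#' @return A data.frame with patient, batch_a, batch_b, hellinger.
#' @export
hellinger_study <- function(assignment, cells, sheet) {
  sheet <- validate_sample_sheet(sheet)
  props <- cluster_proportions(assignment, cells)
  patients <- replicated_pairings(sheet)
  rows <- list()
  for (p in patients) {
    sub <- sheet[sheet$patient_id == p & sheet$sample_id %in% rownames(props), ]
    sub <- sub[order(sub$batch), ]
    if (nrow(sub) < 2) next
    for (a_i in seq_len(nrow(sub) - 1)) for (b_i in (a_i + 1):nrow(sub)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient = p, batch_a = sub$batch[a_i], batch_b = sub$batch[b_i],
        hellinger = hellinger(props[sub$sample_id[a_i], ],
                              props[sub$sample_id[b_i], ]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# exact silhouette widths from a distance matrix and integer labels
silhouette_widths <- function(D, labels) {
  labels <- as.integer(factor(labels))
  groups <- sort(unique(labels))
  m <- length(labels)
  # mean distance from each point to each group
  gmean <- sapply(groups, function(g) {
    idx <- labels == g
    rowSums(D[, idx, drop = FALSE]) / sum(idx)
  })
  sizes <- tabulate(labels)
  a <- numeric(m); b <- numeric(m)
  for (gi in seq_along(groups)) {
    pts <- labels == groups[gi]
    # own-group mean excludes self (diagonal is 0)
    a[pts] <- gmean[pts, gi] * sizes[gi] / (sizes[gi] - 1)
    b[pts] <- apply(gmean[pts, -gi, drop = FALSE], 1, min)
  }
  s <- (b - a) / pmax(a, b)
  s[!is.finite(s)] <- 0
  list(s = s, a = a, b = b)
}

#' Batch and biology silhouette scores
#'
#' Computes per-cell silhouette widths \code{s_i = (b_i - a_i) /
#' max(a_i, b_i)} under a grouping, with Euclidean distances over all panel
#' proteins on the arcsinh scale: \code{a_i} is the mean distance to the
#' cell's own group (excluding itself), \code{b_i} the smallest mean
#' distance to another group. The mean over cells is the silhouette score.
#' Computed with batch labels it measures residual batch structure
#' (\code{s_batch}, lower is better after correction); with metacluster
#' labels it measures preserved biological structure (\code{s_biology},
#' should not drop). Cells are subsampled per sample before the quadratic
#' distance computation.
#'
#' @param cells an arcsinh-scale [cell_table].
#' @param grouping per-cell labels (e.g. \code{cells$batch} or
#'   \code{assignment$metacluster_id}).
#' @param subsample cells retained per sample (default 100); use
#'   \code{Inf} for all cells.
#' @param seed subsampling seed.
#' @return An object of class \code{silhouette_result}: \code{score} (mean
#'   silhouette), \code{s}, \code{a}, \code{b} (per subsampled cell),
#'   \code{grouping}, \code{index} (subsampled cell indices).
#' @export
silhouette_scores <- function(cells, grouping, subsample = 100, seed = 1L) {
  if (length(grouping) != nrow(cells$values))
    stop("grouping must have one label per cell")
  idx <- subsample_by_sample(cells$sample_id, subsample, seed)
  labels <- grouping[idx]
  tab <- table(labels)
  if (length(tab) < 2)
    stop("silhouette needs >= 2 groups after subsampling")
  if (any(tab < 2))
    stop("group(s) with < 2 cells after subsampling (",
         paste(names(tab)[tab < 2], collapse = ", "),
         "); increase `subsample`")
  D <- as.matrix(stats::dist(cells$values[idx, , drop = FALSE]))
  sw <- silhouette_widths(D, labels)
  structure(list(score = mean(sw$s), s = sw$s, a = sw$a, b = sw$b,
                 grouping = labels, index = idx),
            class = "silhouette_result")
}

#' @export
print.silhouette_result <- function(x, ...) {
  cat("<silhouette_result> mean s = ", sprintf("%.4f", x$score), " over ",
      length(x$s), " cells, ", length(unique(x$grouping)), " groups\n",
      sep = "")
  invisible(x)
}

subsample_by_sample <- function(sample_id, per_sample, seed) {
  if (is.infinite(per_sample)) return(seq_along(sample_id))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  idx <- unlist(lapply(split(seq_along(sample_id), sample_id), function(i) {
    if (length(i) <= per_sample) i else sort(sample(i, per_sample))
  }), use.names = FALSE)
  sort(idx)
}

#' Batch vs biology silhouette summary
#'
#' Runs [silhouette_scores()] twice on the same subsample: once with batch
#' labels (\code{s_batch}) and once with metacluster labels
#' (\code{s_biology}).
#'
#' @inheritParams silhouette_scores
#' @param assignment a \code{cluster_assignment} providing the biology
#'   labels.
#' @return A list with \code{s_batch}, \code{s_biology} and the two full
#'   \code{silhouette_result} objects.
#' @export
batch_biology_silhouette <- function(cells, assignment, subsample = 100,
                                     seed = 1L) {
  sb <- silhouette_scores(cells, cells$batch, subsample, seed)
  so <- silhouette_scores(cells, assignment$metacluster_id, subsample, seed)
  list(s_batch = sb$score, s_biology = so$score,
       batch = sb, biology = so)
}

#' Cross-batch median differences before and after normalization
#'
#' For a two-batch design: per marker, the median expression over all cells
#' of replicated patients is computed in each batch; the cross-batch
#' difference is \code{delta = M_2 - M_1}, and the table reports
#' \code{delta_raw}, \code{delta_norm} and their difference
#' \code{delta_delta = delta_raw - delta_norm} — the reduction in
#' cross-batch median shift attributable to normalization (0 when
#' normalization is the identity). Signs are kept as defined; set
#' \code{absolute = TRUE} for an |delta|-based variant.
#'
#' @param raw,norm arcsinh-scale [cell_table]s (same cells).
#' @param sheet the study sample sheet (exactly 2 batches).
#' @param assignment optional \code{cluster_assignment}; with
#'   \code{clusters} restricts the cells to the given metaclusters.
#' @param clusters optional metacluster filter.
#' @param absolute report |delta| differences instead (default FALSE).
#' @return A data.frame: marker, median_b1_raw, median_b2_raw, delta_raw,
#'   delta_norm, delta_delta.
#' @export
delta_delta_medians <- function(raw, norm, sheet, assignment = NULL,
                                clusters = NULL, absolute = FALSE) {
  sheet <- validate_sample_sheet(sheet)
  batches <- sort(unique(sheet$batch))
  if (length(batches) != 2)
    stop("delta_delta_medians is defined for exactly 2 batches")
  patients <- replicated_pairings(sheet)
  patient_of_cell <- sheet$patient_id[match(raw$sample_id, sheet$sample_id)]
  keep <- patient_of_cell %in% patients
  if (!is.null(clusters)) {
    if (is.null(assignment)) stop("cluster filter requires an assignment")
    keep <- keep & assignment$metacluster_id %in% clusters
  }
  med <- function(tbl, b) apply(tbl$values[keep & tbl$batch == b, ,
                                           drop = FALSE], 2, stats::median)
  m1r <- med(raw, batches[1]);  m2r <- med(raw, batches[2])
  m1n <- med(norm, batches[1]); m2n <- med(norm, batches[2])
  d_raw <- m2r - m1r
  d_norm <- m2n - m1n
  dd <- if (absolute) abs(d_raw) - abs(d_norm) else d_raw - d_norm
  data.frame(marker = colnames(raw$values),
             median_b1_raw = m1r, median_b2_raw = m2r,
             delta_raw = d_raw, delta_norm = d_norm, delta_delta = dd,
             row.names = NULL, stringsAsFactors = FALSE)
}
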