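#' Configuration for a synthetic multi-batch study
#'
#' Describes a simulated CyTOF-like study: Gaussian subpopulations in
#' arcsinh space, per-sample subpopulation abundances, and per-batch affine
#' distortions (scale then additive shift, optionally subpopulation
#' specific) applied in arcsinh space. Batch 1 is the identity batch (zero
#' shift, unit scale) so the injected effect is well defined, and every
#' patient keeps one abundance profile across batches so replicated
#' reference samples differ across batches only through the injected
#' distortion plus sampling noise.
#'
#' @param n_proteins total proteins; the first \code{n_lineage} are lineage
#'   class.
#' @param n_lineage number of lineage proteins.
#' @param n_subpops number of ground-truth subpopulations.
#' @param n_batches number of batches.
#' @param patients data.frame with columns \code{patient_id},
#'   \code{condition}; every patient is measured once per batch.
#' @param cells_per_sample events per sample.
#' @param subpop_means subpops x proteins matrix of arcsinh-scale means.
#' @param subpop_sds scalar or subpops x proteins matrix of sds.
#' @param abundance patients x subpops matrix, rows on the simplex.
#' @param batch_shift batches x proteins additive shifts (row 1 zero).
#' @param batch_scale batches x proteins positive factors (row 1 one).
#' @param cluster_shift optional subpops x batches x proteins array of
#'   additional subpopulation-specific shifts (slice \code{[, 1, ]} zero).
#' @param outlier_fraction fraction of cells replaced by uniform
#'   heavy-tail contamination (default 0, off).
#' @param seed simulation seed.
#' @return A validated object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_proteins, n_lineage, n_subpops, n_batches,
                             patients, cells_per_sample,
                             subpop_means, subpop_sds, abundance,
                             batch_shift, batch_scale, cluster_shift = NULL,
                             outlier_fraction = 0, seed = 1L) {
  if (is.numeric(subpop_sds) && length(subpop_sds) == 1)
    subpop_sds <- matrix(subpop_sds, n_subpops, n_proteins)
  cfg <- structure(list(
    n_proteins = as.integer(n_proteins), n_lineage = as.integer(n_lineage),
    n_subpops = as.integer(n_subpops), n_batches = as.integer(n_batches),
    patients = patients, cells_per_sample = as.integer(cells_per_sample),
    subpop_means = as.matrix(subpop_means), subpop_sds = as.matrix(subpop_sds),
    abundance = as.matrix(abundance), batch_shift = as.matrix(batch_shift),
    batch_scale = as.matrix(batch_scale), cluster_shift = cluster_shift,
    outlier_fraction = outlier_fraction, seed = as.integer(seed)),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_lineage >= 1, n_lineage <= n_proteins, n_subpops >= 1,
              n_batches >= 1, cells_per_sample >= 1)
    if (!all(c("patient_id", "condition") %in% names(patients)))
      stop("patients must have columns patient_id, condition")
    if (!identical(dim(subpop_means), c(n_subpops, n_proteins)))
      stop("subpop_means must be n_subpops x n_proteins")
    if (!identical(dim(subpop_sds), c(n_subpops, n_proteins)))
      stop("subpop_sds must be n_subpops x n_proteins")
    if (any(subpop_sds <= 0)) stop("subpop_sds must be positive")
    if (!identical(dim(abundance), c(nrow(patients), n_subpops)))
      stop("abundance must be patients x subpops")
    if (any(abundance < 0) || any(abs(rowSums(abundance) - 1) > 1e-8))
      stop("abundance rows must lie on the simplex")
    if (!identical(dim(batch_shift), c(n_batches, n_proteins)))
      stop("batch_shift must be batches x proteins")
    if (!identical(dim(batch_scale), c(n_batches, n_proteins)))
      stop("batch_scale must be batches x proteins")
    if (any(batch_scale <= 0)) stop("batch_scale must be positive")
    if (any(batch_shift[1, ] != 0) || any(batch_scale[1, ] != 1))
      stop("batch 1 must be the identity batch (zero shift, unit scale)")
    if (!is.null(cluster_shift)) {
      if (!identical(dim(cluster_shift),
                     c(n_subpops, n_batches, n_proteins)))
        stop("cluster_shift must be subpops x batches x proteins")
      if (any(cluster_shift[, 1, ] != 0))
        stop("cluster_shift must be zero for batch 1")
    }
    if (outlier_fraction < 0 || outlier_fraction >= 1)
      stop("outlier_fraction must be in [0, 1)")
  })
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", nrow(x$patients), " patients x ", x$n_batches,
      " batches, ", x$cells_per_sample, " cells/sample, ", x$n_proteins,
      " proteins (", x$n_lineage, " lineage), ", x$n_subpops,
      " subpopulations, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Preset synthetic study configurations
#'
#' \code{two_batch_paper_like}: 12 patients (9 healthy controls, 3 CLL)
#' each replicated across 2 batches — 24 samples, 31 proteins (19
#' lineage), 20 subpopulations, 850 cells per sample (about 20k cells), and
#' a rank-2 additive batch effect in arcsinh space (a global batch-2 shift
#' direction plus a subpopulation-modulated second direction).
#' \code{twelve_batch}: one donor's stimulated/unstimulated pair replicated
#' across 12 batches, same panel and effect structure, 500 cells/sample.
#'
#' @param kind preset name.
#' @param seed simulation seed (default 1).
#' @return A [synthetic_config()].
#' @export
default_study <- function(kind = c("two_batch_paper_like", "twelve_batch"),
                          seed = 1L) {
  kind <- match.arg(kind)
  n_proteins <- 31L; n_lineage <- 19L; n_subpops <- 20L
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed + 1000L)

  # lineage markers: bimodal on/off patterns give well-separated subpopulations
  on_off <- matrix(stats::rbinom(n_subpops * n_lineage, 1, 0.4),
                   n_subpops, n_lineage)
  while (anyDuplicated(on_off)) {
    dup <- which(duplicated(on_off))
    on_off[dup, ] <- stats::rbinom(length(dup) * n_lineage, 1, 0.4)
  }
  lineage_means <- 0.4 + 2.8 * on_off +
    matrix(stats::runif(n_subpops * n_lineage, -0.15, 0.15),
           n_subpops, n_lineage)
  functional_means <- matrix(stats::runif(n_subpops * (n_proteins - n_lineage),
                                          0.5, 2.5),
                             n_subpops, n_proteins - n_lineage)
  subpop_means <- cbind(lineage_means, functional_means)

  # rank-2 additive effect: a global direction plus a
  # subpopulation-modulated one. Batch effects in this assay are of the
  # same order as biological differences; they are strongest on the
  # functional markers (per-channel sensitivity drift) and mild on the
  # lineage markers, so subpopulation identity stays shared across
  # batches — the assumption the correction itself relies on.
  fun_idx <- (n_lineage + 1):n_proteins
  n_fun <- length(fun_idx)
  dir1 <- numeric(n_proteins)
  dir1[fun_idx] <- stats::runif(n_fun, 1.2, 2.2) *
    sample(c(-1, 1), n_fun, replace = TRUE)
  dir1[seq_len(n_lineage)] <- stats::runif(n_lineage, 0.15, 0.40) *
    sample(c(-1, 1), n_lineage, replace = TRUE) *
    stats::rbinom(n_lineage, 1, 0.9)
  dir2 <- numeric(n_proteins)
  dir2[fun_idx] <- stats::runif(n_fun, 0.6, 1.2) *
    sample(c(-1, 1), n_fun, replace = TRUE) *
    stats::rbinom(n_fun, 1, 0.7)
  subpop_weight <- stats::runif(n_subpops, 0.4, 1.2)

  if (kind == "two_batch_paper_like") {
    n_batches <- 2L
    patients <- data.frame(
      patient_id = c(paste0("HC", 1:9), paste0("CLL", 1:3)),
      condition = c(rep("HC", 9), rep("CLL", 3)),
      stringsAsFactors = FALSE)
    cells_per_sample <- 850L
  } else {
    n_batches <- 12L
    patients <- data.frame(patient_id = c("Stim1", "Unstim1"),
                           condition = c("stim", "unstim"),
                           stringsAsFactors = FALSE)
    cells_per_sample <- 500L
  }

  # condition-specific abundance profiles with per-patient jitter,
  # constant across batches
  base <- list()
  for (cond in unique(patients$condition)) {
    w <- stats::rgamma(n_subpops, shape = 1.2)
    base[[cond]] <- w / sum(w)
  }
  abundance <- t(vapply(seq_len(nrow(patients)), function(i) {
    w <- base[[patients$condition[i]]] *
      exp(stats::rnorm(n_subpops, 0, 0.25))
    w / sum(w)
  }, numeric(n_subpops)))

  batch_shift <- matrix(0, n_batches, n_proteins)
  batch_scale <- matrix(1, n_batches, n_proteins)
  cluster_shift <- array(0, dim = c(n_subpops, n_batches, n_proteins))
  for (b in seq_len(n_batches)[-1]) {
    fb <- (b - 1) / max(1, n_batches - 1)   # batch-severity ramp
    batch_shift[b, ] <- fb * dir1
    for (s in seq_len(n_subpops))
      cluster_shift[s, b, ] <- fb * subpop_weight[s] * dir2
  }

  synthetic_config(n_proteins, n_lineage, n_subpops, n_batches,
                   patients, cells_per_sample,
                   subpop_means, subpop_sds = 0.30, abundance,
                   batch_shift, batch_scale, cluster_shift,
                   outlier_fraction = 0, seed = seed)
}

#' Simulate a multi-batch study with ground truth
#'
#' Draws cells subpopulation-wise as Gaussians in arcsinh space, applies
#' the per-batch affine distortion (scale, then additive global and
#' subpopulation-specific shifts), records the injected per-cell offset as
#' ground truth, and inverse-transforms to the raw intensity scale for FCS
#' realism. Raw values are floored at float range but not truncated at 0:
#' asinh is defined on all reals.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional directory: when given, FCS files plus the panel
#'   and sample sheet CSVs are written so the study exercises the real I/O
#'   path.
#' @param cofactor arcsinh cofactor used for the raw-scale inverse
#'   transform (default 5).
#' @return A list: \code{cells} (raw-scale [cell_table]), \code{sheet},
#'   \code{panel}, and \code{truth} (class \code{synthetic_truth}:
#'   per-cell \code{subpop}, the injected \code{offset} matrix on the
#'   arcsinh scale, \code{arcsinh_values} pre-distortion, and the config).
#' @export
simulate_study <- function(config, out_dir = NULL, cofactor = 5) {
  cfg <- validate_synthetic_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  panel <- data.frame(
    metal = sprintf("M%03d", seq_len(cfg$n_proteins)),
    antigen = sprintf("%s%02d",
                      ifelse(seq_len(cfg$n_proteins) <= cfg$n_lineage,
                             "LIN", "FUN"),
                      c(seq_len(cfg$n_lineage),
                        seq_len(cfg$n_proteins - cfg$n_lineage))),
    class = ifelse(seq_len(cfg$n_proteins) <= cfg$n_lineage,
                   "lineage", "functional"),
    stringsAsFactors = FALSE)

  n_pat <- nrow(cfg$patients)
  sheet <- data.frame(
    sample_id = paste0(rep(cfg$patients$patient_id, cfg$n_batches), "_B",
                       rep(seq_len(cfg$n_batches), each = n_pat)),
    patient_id = rep(cfg$patients$patient_id, cfg$n_batches),
    condition = rep(cfg$patients$condition, cfg$n_batches),
    batch = rep(seq_len(cfg$n_batches), each = n_pat),
    file_path = NA_character_, stringsAsFactors = FALSE)

  m <- nrow(sheet) * cfg$cells_per_sample
  values <- matrix(0, m, cfg$n_proteins)
  offset <- matrix(0, m, cfg$n_proteins)
  subpop <- integer(m)
  sample_id <- character(m)
  batch <- integer(m)
  row0 <- 0L
  for (r in seq_len(nrow(sheet))) {
    pat <- match(sheet$patient_id[r], cfg$patients$patient_id)
    b <- sheet$batch[r]
    nc <- cfg$cells_per_sample
    sp <- sample(cfg$n_subpops, nc, replace = TRUE,
                 prob = cfg$abundance[pat, ])
    clean <- cfg$subpop_means[sp, , drop = FALSE] +
      matrix(stats::rnorm(nc * cfg$n_proteins), nc) *
      cfg$subpop_sds[sp, , drop = FALSE]
    if (cfg$outlier_fraction > 0) {
      n_out <- round(cfg$outlier_fraction * nc)
      if (n_out > 0) {
        rows <- sample(nc, n_out)
        clean[rows, ] <- matrix(stats::runif(n_out * cfg$n_proteins, -1, 7),
                                n_out)
      }
    }
    distorted <- sweep(clean, 2, cfg$batch_scale[b, ], "*")
    distorted <- sweep(distorted, 2, cfg$batch_shift[b, ], "+")
    if (!is.null(cfg$cluster_shift))
      distorted <- distorted + cfg$cluster_shift[sp, b, , drop = FALSE][, 1, ]
    idx <- row0 + seq_len(nc)
    values[idx, ] <- distorted
    offset[idx, ] <- distorted - clean
    subpop[idx] <- sp
    sample_id[idx] <- sheet$sample_id[r]
    batch[idx] <- b
    row0 <- row0 + nc
  }
  colnames(values) <- panel$antigen
  cells_arcsinh <- cell_table(values, sample_id, batch, panel,
                              scale = "arcsinh")
  cells_raw <- inverse_arcsinh(cells_arcsinh, cofactor)

  truth <- structure(list(subpop = subpop, offset = offset,
                          arcsinh_values = values, config = cfg),
                     class = "synthetic_truth")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_adjusted_fcs(cells_raw, out_dir, back_transform = FALSE)
    sheet$file_path <- unname(paths[sheet$sample_id])
    utils::write.csv(panel, file.path(out_dir, "panel.csv"),
                     row.names = FALSE)
    utils::write.csv(sheet, file.path(out_dir, "samples.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(cell_index = seq_len(m), sample_id = sample_id,
                                batch = batch, subpop = subpop),
                     file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  list(cells = cells_raw, sheet = sheet, panel = panel, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", length(x$subpop), " cells, ",
      x$config$n_subpops, " subpopulations; injected offset rank ",
      qr(x$offset)$rank, "\n", sep = "")
  invisible(x)
}
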