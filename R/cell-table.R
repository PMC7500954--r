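#' Cell table container
#'
#' The central container of the package: a cells x proteins expression
#' matrix with per-cell sample and batch labels and the antibody panel.
#' Values live on one of two scales, tracked in the \code{scale} field:
#' \code{"raw"} (ion counts as stored in FCS files) or \code{"arcsinh"}
#' (\code{asinh(raw / cofactor)}, the variance-stabilizing scale on which
#' clustering, normalization and all metrics operate).
#'
#' @param values numeric matrix, cells in rows, proteins in columns; column
#'   names must match \code{panel$antigen} in order.
#' @param sample_id character vector, one entry per cell.
#' @param batch integer vector (>= 1), one entry per cell.
#' @param panel panel data.frame as returned by [read_panel()].
#' @param scale `"raw"` or `"arcsinh"`.
#' @return An object of class \code{cell_table}.
#' @export
cell_table <- function(values, sample_id, batch, panel,
                       scale = c("raw", "arcsinh")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (nrow(values) != length(sample_id) || nrow(values) != length(batch))
    stop("sample_id/batch length must equal the number of cells")
  if (ncol(values) != nrow(panel))
    stop("column count must equal the panel size")
  if (is.null(colnames(values))) colnames(values) <- panel$antigen
  if (!identical(colnames(values), panel$antigen))
    stop("column names must match panel antigens in order")
  if (any(!is.finite(values))) stop("cell table values must be finite")
  structure(list(values = values,
                 sample_id = as.character(sample_id),
                 batch = as.integer(batch),
                 panel = panel,
                 scale = scale),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", nrow(x$values), " cells x ", ncol(x$values),
      " proteins (", sum(x$panel$class == "lineage"), " lineage), ",
      length(unique(x$sample_id)), " samples, ",
      length(unique(x$batch)), " batches, scale: ", x$scale, "\n", sep = "")
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$values)

#' Subset a cell table by cell index
#' @param cells a [cell_table].
#' @param i integer or logical index over cells.
#' @return The subsetted [cell_table].
#' @export
ct_subset <- function(cells, i) {
  cell_table(cells$values[i, , drop = FALSE], cells$sample_id[i],
             cells$batch[i], cells$panel, cells$scale)
}

#' Names of lineage-class proteins in a cell table or panel
#' @param x a [cell_table] or panel data.frame.
#' @return Character vector of antigens with panel class `"lineage"`.
#' @export
lineage_proteins <- function(x) {
  panel <- if (inherits(x, "cell_table")) x$panel else x
  panel$antigen[panel$class == "lineage"]
}

#' Read an antibody panel sheet
#'
#' The panel CSV must have columns \code{metal}, \code{antigen},
#' \code{class}, with \code{class} one of \code{lineage}, \code{functional},
#' \code{none}. Lineage proteins drive clustering; all panel proteins enter
#' normalization and the metrics.
#'
#' @param path path to the panel CSV.
#' @return A validated panel data.frame.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_panel(panel)
}

validate_panel <- function(panel) {
  need <- c("metal", "antigen", "class")
  if (!all(need %in% names(panel)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  panel <- panel[, need]
  if (anyDuplicated(panel$antigen))
    stop("panel antigen names must be unique")
  bad <- setdiff(unique(panel$class), c("lineage", "functional", "none"))
  if (length(bad))
    stop("unknown panel class values: ", paste(bad, collapse = ", "))
  if (!any(panel$class == "lineage"))
    stop("panel must contain at least one lineage protein")
  panel
}

#' Read a sample metadata sheet
#'
#' The sample CSV must have columns \code{sample_id}, \code{patient_id},
#' \code{condition}, \code{batch}, \code{file_path}. A patient replicated
#' across batches appears as one row per (batch, sample).
#'
#' @param path path to the sample sheet CSV.
#' @param check_files error if a listed FCS file does not exist
#'   (default TRUE; set FALSE for sheets describing in-memory studies).
#' @return A validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path, check_files = TRUE) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet, check_files = check_files)
}

validate_sample_sheet <- function(sheet, check_files = FALSE) {
  need <- c("sample_id", "patient_id", "condition", "batch", "file_path")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sheet <- sheet[, need]
  sheet$batch <- as.integer(sheet$batch)
  if (anyDuplicated(sheet$sample_id)) stop("sample_id values must be unique")
  if (any(is.na(sheet$batch)) || any(sheet$batch < 1L))
    stop("batch must be an integer >= 1")
  if (check_files) {
    missing <- sheet$file_path[!file.exists(sheet$file_path)]
    if (length(missing))
      stop("sample sheet lists missing files: ",
           paste(missing, collapse = ", "))
  }
  sheet
}

#' Load a multi-batch study from FCS files
#'
#' Reads every FCS file in the sample sheet, restricts channels to the panel
#' antigens (matched against \code{$PnS} descriptions first, then
#' \code{$PnN} names), and concatenates the events into one raw-intensity
#' [cell_table] in sheet order, preserving within-file event order.
#'
#' @param sheet sample sheet (data.frame or path to CSV).
#' @param panel panel (data.frame or path to CSV).
#' @param verbose log per-file event counts (default TRUE).
#' @return A raw-scale [cell_table] with attribute \code{event_counts}
#'   (named per-sample event counts).
#' @export
load_study <- function(sheet, panel, verbose = TRUE) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  else sheet <- validate_sample_sheet(sheet, check_files = TRUE)
  if (is.character(panel)) panel <- read_panel(panel)
  else panel <- validate_panel(panel)

  blocks <- vector("list", nrow(sheet))
  counts <- integer(nrow(sheet))
  for (r in seq_len(nrow(sheet))) {
    fcs <- read_fcs(sheet$file_path[r])
    idx <- match(panel$antigen, fcs$params$desc)
    miss <- is.na(idx)
    idx[miss] <- match(panel$antigen[miss], fcs$params$name)
    if (any(is.na(idx)))
      stop("file ", sheet$file_path[r], " lacks panel channel(s): ",
           paste(panel$antigen[is.na(idx)], collapse = ", "))
    blocks[[r]] <- fcs$exprs[, idx, drop = FALSE]
    counts[r] <- nrow(fcs$exprs)
    if (verbose)
      message(sprintf("loaded %s: %d events", sheet$sample_id[r], counts[r]))
  }
  values <- do.call(rbind, blocks)
  colnames(values) <- panel$antigen
  out <- cell_table(values,
                    sample_id = rep(sheet$sample_id, counts),
                    batch = rep(sheet$batch, counts),
                    panel = panel, scale = "raw")
  names(counts) <- sheet$sample_id
  attr(out, "event_counts") <- counts
  out
}

#' Arcsinh transform of raw intensities
#'
#' Applies \code{asinh(x / cofactor)} to every value, the standard
#' variance-stabilizing transform for mass cytometry (cofactor 5). Strictly
#' increasing, odd, and invertible via [inverse_arcsinh()].
#'
#' @param cells a raw-scale [cell_table].
#' @param cofactor positive scaling constant (default 5).
#' @return The [cell_table] on the arcsinh scale.
#' @export
arcsinh_transform <- function(cells, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0)
    stop("cofactor must be a positive number")
  cells$values <- asinh(cells$values / cofactor)
  cells$scale <- "arcsinh"
  cells
}

#' Inverse arcsinh transform
#' @param cells an arcsinh-scale [cell_table].
#' @param cofactor the cofactor used in the forward transform.
#' @return The [cell_table] on the raw scale (\code{cofactor * sinh(v)}).
#' @export
inverse_arcsinh <- function(cells, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0)
    stop("cofactor must be a positive number")
  cells$values <- cofactor * sinh(cells$values)
  cells$scale <- "raw"
  cells
}

#' Standardize protein columns to zero mean and unit standard deviation
#'
#' Column means and sample standard deviations (divisor m - 1) are computed
#' globally across all cells of the run, then subtracted/divided. The model
#' fit operates on this scale; [unstandardize()] inverts it exactly.
#'
#' @param cells an arcsinh-scale [cell_table] (or numeric matrix).
#' @return A list with \code{cells} (standardized) and \code{params}, an
#'   object of class \code{standardization_params} holding \code{mean} and
#'   \code{sd} per protein.
#' @export
standardize <- function(cells) {
  values <- if (inherits(cells, "cell_table")) cells$values else as.matrix(cells)
  if (nrow(values) < 2) stop("standardization requires at least 2 cells")
  mu <- colMeans(values)
  sdv <- apply(values, 2, stats::sd)
  if (any(sdv == 0))
    stop("constant protein column(s), sd = 0: ",
         paste(colnames(values)[sdv == 0], collapse = ", "))
  std <- sweep(sweep(values, 2, mu, "-"), 2, sdv, "/")
  params <- structure(list(mean = mu, sd = sdv),
                      class = "standardization_params")
  if (inherits(cells, "cell_table")) {
    cells$values <- std
    list(cells = cells, params = params)
  } else {
    list(cells = std, params = params)
  }
}

#' Invert a standardization
#' @param cells standardized [cell_table] or matrix.
#' @param params a \code{standardization_params} object from [standardize()].
#' @return The input on its original scale.
#' @export
unstandardize <- function(cells, params) {
  stopifnot(inherits(params, "standardization_params"))
  values <- if (inherits(cells, "cell_table")) cells$values else as.matrix(cells)
  if (ncol(values) != length(params$mean)) stop("parameter/column mismatch")
  orig <- sweep(sweep(values, 2, params$sd, "*"), 2, params$mean, "+")
  if (inherits(cells, "cell_table")) {
    cells$values <- orig
    cells
  } else orig
}

#' Write a (possibly adjusted) study back to FCS files
#'
#' Writes one FCS 3.1 file per sample. With \code{back_transform = TRUE}
#' (the default for arcsinh-scale tables) values are mapped back to the raw
#' intensity scale as \code{cofactor * sinh(v)} before writing, so the files
#' round-trip through [load_study()] + [arcsinh_transform()].
#'
#' @param cells a [cell_table].
#' @param out_dir output directory (created if needed).
#' @param back_transform write raw-scale values (default: TRUE when the
#'   table is on the arcsinh scale).
#' @param cofactor cofactor for the back transform.
#' @param suffix appended to sample ids to form file names.
#' @return Invisibly, a named character vector of written paths per sample.
#' @export
write_adjusted_fcs <- function(cells, out_dir,
                               back_transform = cells$scale == "arcsinh",
                               cofactor = 5, suffix = "") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  values <- cells$values
  if (back_transform) {
    if (cells$scale != "arcsinh")
      stop("back_transform requires an arcsinh-scale table")
    values <- cofactor * sinh(values)
  }
  samples <- unique(cells$sample_id)
  paths <- character(length(samples))
  names(paths) <- samples
  for (s in samples) {
    i <- cells$sample_id == s
    paths[s] <- file.path(out_dir, paste0(s, suffix, ".fcs"))
    write_fcs(paths[s], values[i, , drop = FALSE],
              channel_names = cells$panel$metal,
              channel_desc = cells$panel$antigen,
              extra_keywords = c("SAMPLE_ID" = s,
                                 "BATCH" = as.character(cells$batch[i][1])))
  }
  invisible(paths)
}
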