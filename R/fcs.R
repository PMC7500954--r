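#' Read an FCS file
#'
#' Minimal reader for FCS 3.0 / 3.1 list-mode files as produced by mass
#' cytometry acquisition software. Supports floating point (\code{$DATATYPE}
#' F or D) and fixed-width integer (\code{$DATATYPE} I with a uniform
#' \code{$PnB} of 16, 32 or 64 bits) data segments, in either byte order.
#' Compensation/spillover keywords are ignored: CyTOF data are not
#' compensated.
#'
#' @param path path to an FCS file.
#' @return A list with components \code{exprs} (events x parameters numeric
#'   matrix, columns named by \code{$PnN}), \code{params} (data.frame with
#'   \code{name} = \code{$PnN}, \code{desc} = \code{$PnS} or \code{NA}), and
#'   \code{keywords} (named character vector of the TEXT segment).
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("FCS file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  header <- readChar(con, 58, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!grepl("^FCS[23]\\.[01]", version))
    stop("not an FCS file (bad magic '", version, "'): ", path)
  off <- function(i) {
    s <- trimws(substr(header, 11 + (i - 1) * 8, 18 + (i - 1) * 8))
    if (s == "") 0 else as.numeric(s)
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)

  seek(con, text_beg)
  text_raw <- readBin(con, "raw", text_end - text_beg + 1)
  text <- rawToChar(text_raw)
  Encoding(text) <- "latin1"
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  parts <- parts[!is.na(parts)]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- trimws(parts[seq(2, length(parts), by = 2)])
  names(kw) <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))

  get_kw <- function(key, default = NA_character_) {
    if (key %in% names(kw)) kw[[key]] else default
  }
  n_par <- as.integer(get_kw("$PAR"))
  n_tot <- as.integer(get_kw("$TOT"))
  if (is.na(n_par) || is.na(n_tot))
    stop("FCS TEXT segment lacks $PAR/$TOT: ", path)
  if (n_tot == 0L) stop("FCS file contains no events: ", path)

  # header offsets may be 0 for large files; TEXT keywords take precedence
  bd <- suppressWarnings(as.numeric(get_kw("$BEGINDATA")))
  ed <- suppressWarnings(as.numeric(get_kw("$ENDDATA")))
  if (!is.na(bd) && bd > 0) data_beg <- bd
  if (!is.na(ed) && ed > 0) data_end <- ed

  dtype <- toupper(get_kw("$DATATYPE", "F"))
  byteord <- get_kw("$BYTEORD", "1,2,3,4")
  endian <- if (grepl("^4", byteord)) "big" else "little"

  bits <- unique(as.integer(kw[sprintf("$P%dB", seq_len(n_par))]))
  seek(con, data_beg)
  n_val <- n_par * n_tot
  vals <- switch(dtype,
    F = readBin(con, "numeric", n = n_val, size = 4, endian = endian),
    D = readBin(con, "numeric", n = n_val, size = 8, endian = endian),
    I = {
      if (length(bits) != 1 || !bits %in% c(16L, 32L, 64L))
        stop("integer FCS data require a uniform $PnB of 16/32/64: ", path)
      readBin(con, "integer", n = n_val, size = bits / 8,
              signed = bits > 16, endian = endian)
    },
    stop("unsupported $DATATYPE '", dtype, "' in ", path)
  )
  if (length(vals) < n_val)
    stop("truncated FCS data segment in ", path)

  pn <- vapply(seq_len(n_par),
               function(i) get_kw(sprintf("$P%dN", i), sprintf("P%d", i)),
               character(1))
  ps <- vapply(seq_len(n_par),
               function(i) get_kw(sprintf("$P%dS", i)), character(1))
  exprs <- matrix(as.numeric(vals), nrow = n_tot, ncol = n_par, byrow = TRUE,
                  dimnames = list(NULL, pn))
  list(exprs = exprs,
       params = data.frame(name = pn, desc = ps, stringsAsFactors = FALSE),
       keywords = kw)
}

#' Write an FCS 3.1 file
#'
#' Writes an events x parameters matrix as an FCS 3.1 list-mode file with
#' 32-bit float values (\code{$DATATYPE} F, little-endian), the dialect read
#' back by [read_fcs()]. Values are stored at float32 precision.
#'
#' @param path output path.
#' @param exprs numeric matrix, events in rows.
#' @param channel_names \code{$PnN} short names (default: column names).
#' @param channel_desc optional \code{$PnS} descriptions (e.g. antigens).
#' @param extra_keywords optional named character vector merged into TEXT.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(path, exprs, channel_names = colnames(exprs),
                      channel_desc = NULL, extra_keywords = NULL) {
  exprs <- as.matrix(exprs)
  if (any(!is.finite(exprs))) stop("non-finite values cannot be written to FCS")
  n_tot <- nrow(exprs); n_par <- ncol(exprs)
  if (is.null(channel_names)) channel_names <- sprintf("P%d", seq_len(n_par))

  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0",
          "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot))
  rng <- pmax(1, ceiling(apply(exprs, 2, function(v) max(v, 0)) + 1))
  for (i in seq_len(n_par)) {
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dN", i)] <- channel_names[i]
    kw[sprintf("$P%dR", i)] <- format(rng[i], scientific = FALSE)
    if (!is.null(channel_desc) && !is.na(channel_desc[i]))
      kw[sprintf("$P%dS", i)] <- channel_desc[i]
  }
  if (!is.null(extra_keywords)) kw[names(extra_keywords)] <- extra_keywords
  if (any(grepl("/", c(names(kw), kw), fixed = TRUE)))
    stop("keyword names/values may not contain the delimiter '/'")

  # fixed-width data offsets so the TEXT length is stable across the two passes
  build_text <- function(beg, end) {
    kw2 <- c(kw, "$BEGINDATA" = sprintf("%010d", beg),
             "$ENDDATA" = sprintf("%010d", end))
    paste0("/", paste0(names(kw2), "/", unname(kw2), collapse = "/"), "/")
  }
  text0 <- build_text(0, 0)
  text_beg <- 58L
  text_end <- text_beg + nchar(text0, type = "bytes") - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * n_par * n_tot - 1L
  text <- build_text(data_beg, data_end)
  stopifnot(nchar(text, type = "bytes") == nchar(text0, type = "bytes"))

  fmt8 <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ",
                   fmt8(text_beg), fmt8(text_end),
                   fmt8(if (data_end <= 99999999) data_beg else 0),
                   fmt8(if (data_end <= 99999999) data_end else 0),
                   fmt8(0), fmt8(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  writeBin(as.numeric(t(exprs)), con, size = 4, endian = "little")
  invisible(path)
}
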