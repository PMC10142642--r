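# Minimal FCS 3.0 reader/writer (list-mode, 32-bit float) and a TSV
# fallback dialect. Only what faithful export/import of event data needs:
# one dataset per file, $DATATYPE F, no ANALYSIS segment. Ground-truth
# columns are never written into the FCS payload; they travel in a sidecar
# TSV (see write_truth_sidecar).

FCS_DELIM <- "/"

fcs_text_segment <- function(keywords) {
  paste0(FCS_DELIM,
         paste0(vapply(names(keywords), function(k) {
           paste0(k, FCS_DELIM, keywords[[k]])
         }, ""), collapse = FCS_DELIM),
         FCS_DELIM)
}

#' Write an event table to an FCS 3.0 file
#'
#' Emits a single list-mode dataset with 32-bit little-endian float data
#' (\code{$DATATYPE F}, \code{$MODE L}, \code{$BYTEORD 1,2,3,4}). Channel
#' names go to \code{$PnN}; ground-truth columns are silently excluded.
#'
#' @param events Event table (channel columns numeric, finite, >= 0).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fcs <- function(events, path) {
  ch <- channel_names(events)
  if (length(ch) == 0L) stop("no channel columns to write", call. = FALSE)
  mat <- as.matrix(events[, ch, drop = FALSE])
  storage.mode(mat) <- "double"
  if (nrow(mat) > 0L && any(!is.finite(mat)))
    stop("cannot write non-finite channel values to FCS", call. = FALSE)
  n <- nrow(mat)
  p <- ncol(mat)
  data_len <- 4L * n * p

  kw <- list(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(p), "$TOT" = as.character(n),
    # fixed-width so the text length does not depend on the values
    "$BEGINDATA" = sprintf("%08d", 0L), "$ENDDATA" = sprintf("%08d", 0L))
  for (i in seq_len(p)) {
    kw[[sprintf("$P%dN", i)]] <- ch[i]
    kw[[sprintf("$P%dB", i)]] <- "32"
    kw[[sprintf("$P%dE", i)]] <- "0,0"
    kw[[sprintf("$P%dR", i)]] <- "16777216"
  }
  text <- fcs_text_segment(kw)
  text_begin <- 58L
  text_end <- text_begin + nchar(text, type = "bytes") - 1L
  data_begin <- if (data_len > 0L) text_end + 1L else 0L
  data_end <- if (data_len > 0L) data_begin + data_len - 1L else 0L
  kw[["$BEGINDATA"]] <- sprintf("%08d", data_begin)
  kw[["$ENDDATA"]] <- sprintf("%08d", data_end)
  text <- fcs_text_segment(kw)

  header <- paste0("FCS3.0    ",
                   sprintf("%8d", text_begin), sprintf("%8d", text_end),
                   sprintf("%8d", data_begin), sprintf("%8d", data_end),
                   sprintf("%8d", 0L), sprintf("%8d", 0L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (data_len > 0L) {
    writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

parse_fcs_text <- function(raw_text) {
  delim <- rawToChar(raw_text[1L])
  body <- rawToChar(raw_text[-1L])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L && parts[length(parts)] == "")
    parts <- parts[-length(parts)]
  if (length(parts) %% 2L == 1L)
    stop("corrupt FCS TEXT segment (odd key/value count)", call. = FALSE)
  keys <- parts[seq(1L, length(parts), by = 2L)]
  vals <- parts[seq(2L, length(parts), by = 2L)]
  stats::setNames(as.list(vals), toupper(keys))
}

#' Read an FCS 3.0 file written in the float list-mode dialect
#'
#' @param path Input path.
#' @return Event table with one column per \code{$PnN} channel, names
#'   normalized via \code{\link{normalize_channel_names}}.
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 58L)
    stop("corrupt FCS header: file shorter than 58 bytes", call. = FALSE)
  version <- rawToChar(raw[1:6])
  if (!grepl("^FCS3\\.", version))
    stop("unsupported FCS version '", trimws(rawToChar(raw[1:10])), "'",
         call. = FALSE)
  off <- function(i) {
    s <- trimws(rawToChar(raw[(10L + 8L * (i - 1L) + 1L):(10L + 8L * i)]))
    if (s == "") 0L else as.integer(s)
  }
  text_begin <- off(1); text_end <- off(2)
  data_begin <- off(3); data_end <- off(4)
  if (is.na(text_begin) || is.na(text_end) || text_end <= text_begin ||
      text_end + 1L > length(raw))
    stop("corrupt FCS header: invalid TEXT offsets", call. = FALSE)
  # FCS offsets are 0-based byte positions
  kw <- parse_fcs_text(raw[(text_begin + 1L):(text_end + 1L)])

  dtype <- kw[["$DATATYPE"]] %||% ""
  if (!identical(dtype, "F"))
    stop("unsupported $DATATYPE '", dtype,
         "': only 32-bit float (F) list mode is supported", call. = FALSE)
  if (!identical(kw[["$MODE"]] %||% "L", "L"))
    stop("unsupported $MODE '", kw[["$MODE"]], "'", call. = FALSE)
  byteord <- kw[["$BYTEORD"]] %||% "1,2,3,4"
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stop("unsupported $BYTEORD '", byteord, "'",
                        call. = FALSE))
  p <- as.integer(kw[["$PAR"]])
  n <- as.integer(kw[["$TOT"]])
  if (is.na(p) || p <= 0L) stop("missing or invalid $PAR", call. = FALSE)
  if (is.na(n) || n < 0L) stop("missing or invalid $TOT", call. = FALSE)
  ch <- vapply(seq_len(p), function(i) {
    nm <- kw[[sprintf("$P%dN", i)]]
    if (is.null(nm)) stop("missing $P", i, "N", call. = FALSE)
    nm
  }, "")
  if (anyDuplicated(normalize_channel_names(ch)))
    stop("duplicate channel names in FCS file", call. = FALSE)
  bd <- as.integer(kw[["$BEGINDATA"]] %||% "0")
  ed <- as.integer(kw[["$ENDDATA"]] %||% "0")
  if (bd == 0L) { bd <- data_begin; ed <- data_end }

  if (n == 0L) {
    mat <- matrix(numeric(0), ncol = p)
  } else {
    expected <- 4L * n * p
    avail <- ed - bd + 1L
    if (bd <= 0L || ed + 1L > length(raw) || avail != expected)
      stop("$TOT mismatch: declared ", n, " events (", expected,
           " bytes) but DATA segment holds ", max(avail, 0L), " bytes",
           call. = FALSE)
    vals <- readBin(raw[(bd + 1L):(ed + 1L)], "numeric", n = n * p,
                    size = 4L, endian = endian)
    mat <- matrix(vals, ncol = p, byrow = TRUE)
  }
  out <- as.data.frame(mat)
  names(out) <- normalize_channel_names(ch)
  out
}

#' Read and write event tables (FCS 3.0 or TSV)
#'
#' The TSV dialect is a plain tab-separated table with one header row of
#' channel names; values survive at full double precision, while FCS stores
#' 32-bit floats. \code{format = "auto"} dispatches on the file extension
#' for writing and on extension/magic bytes for reading.
#'
#' @param path File path.
#' @param events Event table to write; channel values must be finite.
#' @param format \code{"auto"}, \code{"fcs"} or \code{"tsv"}.
#' @return \code{read_events}: an event table; \code{write_events}:
#'   \code{path}, invisibly.
#' @export
read_events <- function(path, format = c("auto", "fcs", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "fcs") "fcs"
    else if (ext %in% c("tsv", "txt")) "tsv"
    else {
      magic <- readBin(path, "raw", n = 6L)
      if (identical(rawToChar(magic), "FCS3.0") ||
          grepl("^FCS", rawToChar(magic))) "fcs" else "tsv"
    }
  }
  if (format == "fcs") return(read_fcs(path))
  out <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ch <- setdiff(names(out), TRUTH_COLUMNS)
  names(out)[match(ch, names(out))] <- normalize_channel_names(ch)
  out
}

#' @rdname read_events
#' @export
write_events <- function(events, path, format = c("auto", "fcs", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "fcs") "fcs" else "tsv"
  }
  ch <- channel_names(events)
  if (length(ch) == 0L) stop("no channel columns to write", call. = FALSE)
  if (nrow(events) > 0L &&
      any(!is.finite(as.matrix(events[, ch, drop = FALSE]))))
    stop("refusing to write non-finite channel values", call. = FALSE)
  if (format == "fcs") return(write_fcs(events, path))
  tab <- events[, ch, drop = FALSE]
  tab[] <- lapply(tab, function(v) format(v, digits = 15, trim = TRUE,
                                          scientific = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write simulation ground truth as a sidecar TSV
#'
#' Ground-truth labels never enter the FCS payload; they are written row
#' aligned with the event file so oracle checks can join on row order.
#'
#' @param events Labeled event table.
#' @param path Sidecar path.
#' @return \code{path}, invisibly.
#' @export
write_truth_sidecar <- function(events, path) {
  cols <- intersect(TRUTH_COLUMNS, names(events))
  if (length(cols) == 0L)
    stop("events carry no ground-truth columns", call. = FALSE)
  utils::write.table(events[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
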