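# Export of the single-cell measurement table: TSV, XLSX (one sheet per
# channel plus a merged sheet) and FCS 3.1 (one event per cell) so the
# results open in any cytometry software.

TABLE_COLUMNS <- c("Cell", "Label", "Area", "Mean", "X", "Y", "Circ.",
                   "IntDen", "RawIntDen", "AR", "Round", "Solidity", "CTCF")

check_records <- function(records) {
  miss <- setdiff(TABLE_COLUMNS, names(records))
  if (length(miss))
    stop("measurement table is missing column(s): ", paste(miss, collapse = ", "))
  records[TABLE_COLUMNS]
}

#' Write the measurement table as TSV
#'
#' Tab-separated, header row, UTF-8, `.` decimal separator.
#'
#' @param records long measurement table ([measure_cells()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_tsv <- function(records, path) {
  records <- check_records(records)
  if (nrow(records) == 0) warning("writing header-only TSV (no records)")
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", dec = ".")
  invisible(path)
}

#' Read a measurement TSV written by [write_cell_tsv()]
#'
#' @param path file path.
#' @return data.frame in Table column order.
#' @export
read_cell_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  check_records(df)
}

#' Write the measurement table as XLSX
#'
#' One sheet per channel label plus a `merged` sheet with all rows. The
#' workbook is produced through the system `python` + `openpyxl` (no
#' XLSX-capable R package is assumed); an informative error is raised when
#' that bridge is unavailable.
#'
#' @param records long measurement table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_xlsx <- function(records, path) {
  records <- check_records(records)
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("write_cell_xlsx needs a `python` with openpyxl on the PATH")
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  utils::write.table(records, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  script <- tempfile(fileext = ".py")
  on.exit(unlink(script), add = TRUE)
  writeLines(c(
    "import csv, sys",
    "from openpyxl import Workbook",
    "tsv, out = sys.argv[1], sys.argv[2]",
    "rows = list(csv.reader(open(tsv, newline='', encoding='utf-8'), delimiter='\\t'))",
    "header, data = rows[0], rows[1:]",
    "def conv(r):",
    "    out = []",
    "    for i, v in enumerate(r):",
    "        if i == 1: out.append(v); continue",  # Label stays text
    "        try: out.append(float(v) if '.' in v or 'e' in v.lower() or 'NA' != v else int(v))",
    "        except ValueError: out.append(None if v == 'NA' else v)",
    "    return out",
    "wb = Workbook()",
    "ws = wb.active; ws.title = 'merged'; ws.append(header)",
    "for r in data: ws.append(conv(r))",
    "labels = []",
    "for r in data:",
    "    if r[1] not in labels: labels.append(r[1])",
    "for lab in labels:",
    "    ws = wb.create_sheet(title=str(lab)[:31])",
    "    ws.append(header)",
    "    for r in data:",
    "        if r[1] == lab: ws.append(conv(r))",
    "wb.save(out)"), script)
  status <- system2(py, c(script, tmp, path), stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0)
    stop("openpyxl export failed: ", paste(status, collapse = "\n"))
  invisible(path)
}

#' Pivot the long measurement table to one row per cell
#'
#' Geometry columns (Area, X, Y, Circ., AR, Round, Solidity) are taken from
#' the first channel's rows and asserted identical across channels;
#' intensity columns become `<channel>_Mean`, `<channel>_IntDen`,
#' `<channel>_RawIntDen`, `<channel>_CTCF`.
#'
#' @param records long measurement table.
#' @return wide data.frame, one row per cell.
#' @export
pivot_records_wide <- function(records) {
  records <- check_records(records)
  if (nrow(records) == 0) stop("no records to pivot")
  channels <- unique(records$Label)
  cells <- sort(unique(records$Cell))
  per_ch <- lapply(channels, function(ch) {
    sub <- records[records$Label == ch, ]
    if (!identical(sort(sub$Cell), cells))
      stop("cell ", paste(setdiff(cells, sub$Cell), collapse = ","),
           " missing a row for channel ", ch)
    sub[order(sub$Cell), ]
  })
  geom_cols <- c("Area", "X", "Y", "Circ.", "AR", "Round", "Solidity")
  base <- per_ch[[1]][c("Cell", geom_cols)]
  for (k in seq_along(per_ch)[-1]) {
    same <- vapply(geom_cols, function(cn)
      isTRUE(all.equal(per_ch[[k]][[cn]], base[[cn]])), logical(1))
    if (!all(same))
      stop("geometry differs across channels (", channels[k], "): ",
           paste(geom_cols[!same], collapse = ", "))
  }
  for (k in seq_along(channels)) {
    for (cn in c("Mean", "IntDen", "RawIntDen", "CTCF"))
      base[[paste0(channels[k], "_", cn)]] <- per_ch[[k]][[cn]]
  }
  names(base)[names(base) == "Circ."] <- "Circ"
  base
}

#' Merge the measurement table into one FCS 3.1 file
#'
#' One event per cell; parameters are Area, X, Y, Circ, AR, Round, Solidity
#' plus, per channel, `<name>_Mean`, `<name>_IntDen`, `<name>_RawIntDen`
#' and `<name>_CTCF` (`7 + 4 * n_channels` in total). Data are 32-bit
#' little-endian floats (`$DATATYPE/F`, `$MODE/L`, `$BYTEORD/1,2,3,4`),
#' list mode, single dataset.
#'
#' @param records long measurement table with CTCF filled.
#' @param path output path.
#' @param roi_name stored in `$SRC`.
#' @return `path`, invisibly.
#' @export
merge_to_fcs <- function(records, path, roi_name = "ROI") {
  wide <- pivot_records_wide(records)
  mat <- as.matrix(wide[, setdiff(names(wide), "Cell")])
  if (anyNA(mat)) {
    warning("NA values in FCS export replaced by 0")
    mat[is.na(mat)] <- 0
  }
  write_fcs(mat, path, roi_name = roi_name)
}

sanitize_pnn <- function(x) gsub("[/\\\\,]", "_", x)

#' Write a numeric event matrix as FCS 3.1
#'
#' @param mat numeric matrix, events in rows, parameters in columns (column
#'   names become `$PnN`/`$PnS`).
#' @param path output path.
#' @param roi_name stored in `$SRC`.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(mat, path, roi_name = "ROI") {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  n_events <- nrow(mat); n_par <- ncol(mat)
  delim <- "/"
  kv <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "@@@@@@@@@@", "$ENDDATA" = "##########",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$TOT" = as.character(n_events), "$PAR" = as.character(n_par),
    "$SRC" = sanitize_pnn(roi_name))
  for (j in seq_len(n_par)) {
    rng <- max(1, ceiling(max(mat[, j], 0, na.rm = TRUE)))
    kv[[sprintf("$P%dN", j)]] <- sanitize_pnn(colnames(mat)[j])
    kv[[sprintf("$P%dS", j)]] <- sanitize_pnn(colnames(mat)[j])
    kv[[sprintf("$P%dB", j)]] <- "32"
    kv[[sprintf("$P%dE", j)]] <- "0,0"
    kv[[sprintf("$P%dR", j)]] <- format(rng, scientific = FALSE)
  }
  text <- paste0(delim, paste0(names(kv), delim, unname(kv), delim,
                               collapse = ""))
  header_len <- 58L
  text_start <- header_len
  text_end <- text_start + nchar(text, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n_events * n_par - 1L
  text <- sub("@@@@@@@@@@", sprintf("%010d", data_start), text, fixed = TRUE)
  text <- sub("##########", sprintf("%010d", data_end), text, fixed = TRUE)
  off <- function(x) {
    if (x > 99999999) "       0" else sprintf("%8d", x)
  }
  header <- paste0("FCS3.1    ", off(text_start), off(text_end),
                   off(data_start), off(data_end), off(0), off(0))
  stopifnot(nchar(header, type = "bytes") == 58L)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}
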