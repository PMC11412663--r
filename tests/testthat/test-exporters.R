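make_records <- function(n_cells = 3, channels = c("DAPI", "CD4"), seed = 40) {
  set.seed(seed)
  # geometry is a per-cell property shared by all channel rows
  area <- sample(20:120, n_cells)
  x <- round(runif(n_cells, 0, 200), 2)
  y <- round(runif(n_cells, 0, 200), 2)
  circ <- round(runif(n_cells, 0.4, 1), 4)
  ar <- round(runif(n_cells, 1, 2), 3)
  rnd <- round(runif(n_cells, 0.5, 1), 3)
  sol <- round(runif(n_cells, 0.9, 1), 3)
  do.call(rbind, lapply(channels, function(ch) {
    mn <- round(runif(n_cells, 5, 500), 3)
    data.frame(Cell = seq_len(n_cells), Label = ch, Area = area, Mean = mn,
               X = x, Y = y, `Circ.` = circ,
               IntDen = area * mn, RawIntDen = area * mn,
               AR = ar, Round = rnd, Solidity = sol,
               CTCF = round(area * mn - area * 2, 3),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
}

test_that("TSV export round-trips and keeps the schema", {
  rec <- make_records()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_cell_tsv(rec, p)
  lines <- readLines(p)
  expect_equal(length(lines), 1 + 6)             # header + 3 cells x 2 channels
  expect_equal(strsplit(lines[1], "\t")[[1]],
               c("Cell", "Label", "Area", "Mean", "X", "Y", "Circ.",
                 "IntDen", "RawIntDen", "AR", "Round", "Solidity", "CTCF"))
  back <- read_cell_tsv(p)
  expect_equal(back, rec, ignore_attr = TRUE)
  # empty set: header-only with warning
  p2 <- withr::local_tempfile(fileext = ".tsv")
  expect_warning(write_cell_tsv(rec[0, ], p2), "header-only")
  expect_equal(length(readLines(p2)), 1)
  expect_error(write_cell_tsv(data.frame(a = 1), p2), "missing column")
})

test_that("XLSX export writes one sheet per channel plus a merged sheet", {
  rec <- make_records()
  p <- withr::local_tempfile(fileext = ".xlsx")
  write_cell_xlsx(rec, p)
  expect_true(file.size(p) > 0)
  py <- python_bin()
  script <- withr::local_tempfile(fileext = ".py")
  out_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "import sys",
    "from openpyxl import load_workbook",
    "wb = load_workbook(sys.argv[1])",
    "print('|'.join(wb.sheetnames))",
    "ws = wb['merged']",
    "with open(sys.argv[2], 'w') as fh:",
    "    for row in ws.iter_rows(values_only=True):",
    "        fh.write('\\t'.join('' if v is None else str(v) for v in row) + '\\n')"),
    script)
  out <- system2(py, c(script, p, out_tsv), stdout = TRUE, stderr = TRUE)
  expect_null(attr(out, "status"))
  expect_equal(sort(strsplit(out[1], "|", fixed = TRUE)[[1]]),
               sort(c("merged", "DAPI", "CD4")))
  merged <- read.delim(out_tsv, check.names = FALSE)
  expect_equal(nrow(merged), 6)
  expect_equal(merged$IntDen, rec$IntDen)
})

test_that("wide pivot keeps geometry and errors on missing channel rows", {
  rec <- make_records(n_cells = 4)
  wide <- pivot_records_wide(rec)
  expect_equal(nrow(wide), 4)
  expect_true(all(c("Area", "X", "Y", "Circ", "AR", "Round", "Solidity",
                    "DAPI_Mean", "CD4_CTCF") %in% names(wide)))
  broken <- rec[-2, ]
  expect_error(pivot_records_wide(broken), "missing a row")
})

test_that("FCS export round-trips through an independent reader", {
  rec <- make_records(n_cells = 5, channels = c("DAPI", "CD4"))
  p <- withr::local_tempfile(fileext = ".fcs")
  merge_to_fcs(rec, p, roi_name = "ROI-7")
  fcs <- oracle_read_fcs(p)
  expect_equal(fcs$version, "FCS3.1")
  expect_equal(as.integer(fcs$keywords[["$TOT"]]), 5)
  expect_equal(as.integer(fcs$keywords[["$PAR"]]), 7 + 4 * 2)
  expect_equal(fcs$keywords[["$SRC"]], "ROI-7")
  wide <- pivot_records_wide(rec)
  for (cn in colnames(fcs$data))
    expect_equal(fcs$data[, cn], wide[[cn]], tolerance = 1e-6,
                 ignore_attr = TRUE)  # float32 precision
  # centroids are exact (values representable or within float32 eps)
  expect_equal(max(abs(fcs$data[, "X"] - wide$X)), 0, tolerance = 1e-4)
})

test_that("gating the FCS equals filtering the TSV", {
  rec <- make_records(n_cells = 50, channels = c("DAPI", "CD4"), seed = 41)
  p <- withr::local_tempfile(fileext = ".fcs")
  merge_to_fcs(rec, p)
  fcs <- oracle_read_fcs(p)
  gate_fcs <- fcs$data[, "Area"] > 60.5 & fcs$data[, "DAPI_Mean"] > 250.25
  tsv <- pivot_records_wide(rec)
  gate_tsv <- tsv$Area > 60.5 & tsv$DAPI_Mean > 250.25
  expect_equal(unname(gate_fcs), gate_tsv)
})

test_that("write_fcs validates input and handles many parameters", {
  set.seed(42)
  mat <- matrix(runif(7 * 39, 0, 1e4), 7, 39)
  colnames(mat) <- paste0("P", 1:39)
  p <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(mat, p)
  fcs <- oracle_read_fcs(p)
  expect_equal(dim(fcs$data), c(7L, 39L))
  expect_equal(fcs$data, mat, tolerance = 1e-6, ignore_attr = TRUE)
})
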