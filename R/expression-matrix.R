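#' Construct an expression matrix
#'
#' The basic container for raw counts: a dense numeric matrix of
#' non-negative values with cells in rows and genes in columns, carrying
#' unique gene names and cell identifiers. All downstream preprocessing,
#' selection and evaluation functions consume this class.
#'
#' @param counts Numeric matrix, cells x genes, non-negative, no missing
#'   values.
#' @param gene_names Character vector of unique gene names (length
#'   `ncol(counts)`). Taken from `colnames(counts)` when omitted.
#' @param cell_ids Character vector of unique cell identifiers (length
#'   `nrow(counts)`). Taken from `rownames(counts)` when omitted.
#' @return An `expr_mat` object: a list with elements `counts`,
#'   `gene_names`, `cell_ids`.
#' @examples
#' m <- matrix(rpois(6, 2), 3, 2, dimnames = list(NULL, c("g1", "g2")))
#' em <- expression_matrix(m)
#' dim(em)
#' @export
expression_matrix <- function(counts, gene_names = NULL, cell_ids = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  gene_names <- gene_names %||% colnames(counts)
  cell_ids <- cell_ids %||% rownames(counts)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (length(gene_names) != ncol(counts))
    stopf("gene_names has length %d but counts has %d genes",
          length(gene_names), ncol(counts))
  if (length(cell_ids) != nrow(counts))
    stopf("cell_ids has length %d but counts has %d cells",
          length(cell_ids), nrow(counts))
  if (anyNA(counts)) stopf("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stopf("counts must be non-negative; first negative entry at cell '%s', gene '%s'",
          cell_ids[bad[1L]], gene_names[bad[2L]])
  }
  dup <- unique(gene_names[duplicated(gene_names)])
  if (length(dup))
    stopf("duplicate gene names: %s", paste(dup, collapse = ", "))
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup))
    stopf("duplicate cell ids: %s", paste(dup, collapse = ", "))
  dimnames(counts) <- list(cell_ids, gene_names)
  structure(list(counts = counts, gene_names = gene_names, cell_ids = cell_ids),
            class = "expr_mat")
}

#' @export
dim.expr_mat <- function(x) dim(x$counts)

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  cat("genes: ", paste(utils::head(x$gene_names, 5L), collapse = ", "),
      if (length(x$gene_names) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Subset an expression matrix by gene
#'
#' @param em An `expr_mat`.
#' @param genes Character vector of gene names or integer indices to keep
#'   (order preserved as given).
#' @return An `expr_mat` restricted to the requested genes.
#' @export
subset_genes <- function(em, genes) {
  stopifnot(inherits(em, "expr_mat"))
  if (is.character(genes)) {
    missing <- setdiff(genes, em$gene_names)
    if (length(missing))
      stopf("genes absent from matrix: %s", paste(missing, collapse = ", "))
    idx <- match(genes, em$gene_names)
  } else {
    idx <- as.integer(genes)
    if (any(idx < 1L | idx > length(em$gene_names)))
      stopf("gene index out of range")
  }
  expression_matrix(em$counts[, idx, drop = FALSE],
                    em$gene_names[idx], em$cell_ids)
}

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.h5ad$", low)) return("h5ad")
  if (grepl("\\.mtx$", low)) return("mtx")
  if (grepl("\\.csv(\\.gz)?$", low)) return("csv")
  stopf("cannot guess format of '%s'; pass format explicitly", path)
}

#' Read an expression matrix
#'
#' Supports three on-disk layouts: dense CSV (header row of gene names,
#' first column the cell id), MatrixMarket MTX with companion
#' `genes.tsv`/`barcodes.tsv` files (10x convention, genes x cells on disk),
#' and AnnData h5ad (converted through the system `python` with `anndata`).
#' Orientation is normalised to cells x genes on ingestion regardless of the
#' on-disk layout.
#'
#' @param path Path to the file (for MTX, the `.mtx` file; companions are
#'   looked up alongside it).
#' @param format One of `"auto"`, `"csv"`, `"mtx"`, `"h5ad"`.
#' @param layer For h5ad only: name of a layer to read instead of `X`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "csv", "mtx", "h5ad"),
                            layer = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         csv = read_expression_csv(path),
         mtx = read_expression_mtx(path),
         h5ad = read_expression_h5ad(path, layer = layer))
}

read_expression_csv <- function(path) {
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stopf("failed to parse CSV '%s': %s", path, conditionMessage(e)))
  if (ncol(df) < 2L)
    stopf("CSV '%s' must have a cell-id column followed by gene columns", path)
  cell_ids <- as.character(df[[1L]])
  counts <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(counts)) {
    bad <- colnames(df[, -1L])[!vapply(df[, -1L], is.numeric, logical(1))]
    stopf("non-numeric gene column(s) in '%s': %s", path,
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  expression_matrix(counts, colnames(df)[-1L], cell_ids)
}

mtx_companions <- function(path) {
  dir <- dirname(path)
  genes <- c(file.path(dir, "genes.tsv"), file.path(dir, "features.tsv"))
  genes <- genes[file.exists(genes)][1L]
  barcodes <- file.path(dir, "barcodes.tsv")
  if (is.na(genes) || !file.exists(barcodes))
    stopf("MTX '%s' needs companion genes.tsv (or features.tsv) and barcodes.tsv in %s",
          path, dir)
  list(genes = genes, barcodes = barcodes)
}

read_expression_mtx <- function(path) {
  comp <- mtx_companions(path)
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stopf("failed to parse MTX '%s': %s",
                                          path, conditionMessage(e)))
  genes <- readr::read_tsv(comp$genes, col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)[[1L]]
  cells <- readr::read_tsv(comp$barcodes, col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)[[1L]]
  # 10x layout stores genes x cells; transpose to cells x genes.
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    m <- Matrix::t(m)
  } else if (!(nrow(m) == length(cells) && ncol(m) == length(genes))) {
    stopf("MTX dimensions %dx%d match neither genes.tsv (%d) x barcodes.tsv (%d) nor its transpose",
          nrow(m), ncol(m), length(genes), length(cells))
  }
  expression_matrix(as.matrix(m), as.character(genes), as.character(cells))
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; integer counts round-trip exactly in all
#' three formats.
#'
#' @param em An `expr_mat`.
#' @param path Output path (for MTX, the `.mtx` file; companions are written
#'   alongside it).
#' @param format One of `"auto"`, `"csv"`, `"mtx"`, `"h5ad"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, format = c("auto", "csv", "mtx", "h5ad")) {
  stopifnot(inherits(em, "expr_mat"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         csv = {
           df <- tibble::as_tibble(em$counts)
           df <- tibble::add_column(df, cell_id = em$cell_ids, .before = 1L)
           readr::write_csv(df, path, progress = FALSE)
         },
         mtx = {
           dir <- dirname(path)
           sp <- Matrix::Matrix(t(em$counts), sparse = TRUE)  # genes x cells on disk
           Matrix::writeMM(sp, path)
           readr::write_tsv(tibble::tibble(x = em$gene_names),
                            file.path(dir, "genes.tsv"), col_names = FALSE,
                            progress = FALSE)
           readr::write_tsv(tibble::tibble(x = em$cell_ids),
                            file.path(dir, "barcodes.tsv"), col_names = FALSE,
                            progress = FALSE)
         },
         h5ad = write_expression_h5ad(em, path))
  invisible(path)
}

h5ad_bridge_path <- function() {
  p <- system.file("python", "h5ad_bridge.py", package = "panelselect")
  if (p == "") stopf("h5ad bridge script not found in the installed package")
  p
}

check_python <- function() {
  py <- Sys.which("python")
  if (py == "") stopf("h5ad support needs a 'python' interpreter with the anndata package on PATH")
  py
}

read_expression_h5ad <- function(path, layer = NULL) {
  py <- check_python()
  tmp <- tempfile("h5ad_export_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  args <- c(h5ad_bridge_path(), "export", path, file.path(tmp, "matrix.mtx"))
  if (!is.null(layer)) args <- c(args, layer)
  out <- suppressWarnings(system2(py, shQuote(args), stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0L)
    stopf("h5ad conversion failed: %s", paste(out, collapse = "; "))
  read_expression_mtx(file.path(tmp, "matrix.mtx"))
}

write_expression_h5ad <- function(em, path) {
  py <- check_python()
  tmp <- tempfile("h5ad_import_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  mtx <- file.path(tmp, "matrix.mtx")
  write_expression(em, mtx, format = "mtx")
  out <- suppressWarnings(system2(py, shQuote(c(h5ad_bridge_path(), "import", mtx, path)),
                                  stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0L)
    stopf("h5ad conversion failed: %s", paste(out, collapse = "; "))
  invisible(path)
}

#' Read / write a gene panel
#'
#' Panels are stored as a two-column TSV (`rank`, `gene_name`) with an
#' optional JSON sidecar carrying run metadata (seed, panel size, mode,
#' validation loss).
#'
#' @param path Path to the panel TSV.
#' @return `read_panel()`: a tibble with columns `rank` and `gene_name`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  df <- tryCatch(
    suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
      rank = readr::col_integer(), gene_name = readr::col_character()))),
    error = function(e) stopf("failed to parse panel TSV '%s': %s",
                              path, conditionMessage(e)))
  if (!all(c("rank", "gene_name") %in% names(df)))
    stopf("panel TSV '%s' must have columns 'rank' and 'gene_name'", path)
  prob <- readr::problems(df)
  if (nrow(prob))
    stopf("panel TSV '%s' parse error at line %d: expected %s, got %s",
          path, prob$row[1L] + 1L, prob$expected[1L], prob$actual[1L])
  if (anyNA(df$gene_name) || anyNA(df$rank))
    stopf("panel TSV '%s' has missing rank or gene_name entries", path)
  df
}

#' @param genes Character vector of panel genes, in rank order.
#' @param metadata Optional named list written as a JSON sidecar
#'   (`<path>.json`).
#' @rdname read_panel
#' @export
write_panel <- function(genes, path, metadata = NULL) {
  df <- tibble::tibble(rank = seq_along(genes), gene_name = as.character(genes))
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(metadata)) {
    jsonlite::write_json(metadata, paste0(path, ".json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}
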