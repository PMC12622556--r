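#' Read and align expression plus metadata inputs
#'
#' Accepts either a MatrixMarket triplet (`matrix.mtx` with `features.tsv`
#' and `barcodes.tsv` in the same directory) or a dense delimited table with
#' a `cell_id` column, plus a metadata table (TSV/CSV) with a `cell_id`
#' column. Cells are aligned between matrix and metadata by id; mismatches
#' raise an error naming the first offending ids.
#'
#' @param expression Path to `matrix.mtx`, its directory, or a dense
#'   CSV/TSV.
#' @param metadata Path to the per-cell metadata table.
#' @param cells_as `"rows"` (default) or `"columns"`: orientation of the
#'   MTX matrix.
#' @return List with `expression` (cells x features matrix, rownames cell
#'   ids) and `meta` (data frame, one row per cell, matrix order).
#' @export
read_inputs <- function(expression, metadata, cells_as = c("rows", "columns")) {
  cells_as <- match.arg(cells_as)
  if (!file.exists(expression)) stop("expression input not found: ", expression)
  if (!file.exists(metadata)) stop("metadata input not found: ", metadata)

  if (dir.exists(expression) || grepl("\\.mtx$", expression)) {
    dir <- if (dir.exists(expression)) expression else dirname(expression)
    mtx <- if (dir.exists(expression)) file.path(dir, "matrix.mtx") else expression
    feats <- readLines(file.path(dir, "features.tsv"))
    cells <- readLines(file.path(dir, "barcodes.tsv"))
    m <- as.matrix(Matrix::readMM(mtx))
    if (cells_as == "columns") m <- t(m)
    if (nrow(m) != length(cells) || ncol(m) != length(feats)) {
      stop("matrix dimensions (", nrow(m), " x ", ncol(m),
           ") do not match barcodes/features files")
    }
    dimnames(m) <- list(cells, feats)
  } else {
    sep <- if (grepl("\\.tsv$", expression)) "\t" else ","
    tab <- utils::read.delim(expression, sep = sep, check.names = FALSE)
    if (!"cell_id" %in% names(tab)) stop("dense expression needs a cell_id column")
    m <- as.matrix(tab[, setdiff(names(tab), "cell_id"), drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in the expression matrix")
    rownames(m) <- tab$cell_id
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate cell ids in expression: ",
         paste(utils::head(unique(rownames(m)[duplicated(rownames(m))]), 5),
               collapse = ", "))
  }

  sep <- if (grepl("\\.csv$", metadata)) "," else "\t"
  meta <- utils::read.delim(metadata, sep = sep)
  if (!"cell_id" %in% names(meta)) stop("metadata needs a cell_id column")
  if (anyDuplicated(meta$cell_id)) {
    stop("duplicate cell ids in metadata: ",
         paste(utils::head(unique(meta$cell_id[duplicated(meta$cell_id)]), 5),
               collapse = ", "))
  }
  missing <- setdiff(rownames(m), meta$cell_id)
  if (length(missing)) {
    stop("metadata is missing ", length(missing), " matrix cell(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  extra <- setdiff(meta$cell_id, rownames(m))
  if (length(extra)) {
    stop("matrix is missing ", length(extra), " metadata cell(s): ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  meta <- meta[match(rownames(m), meta$cell_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(expression = m, meta = meta)
}
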