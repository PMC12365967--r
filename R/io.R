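#' Construct a validated expression matrix
#'
#' Wraps a genes-by-cells count matrix (dense or sparse) together with a batch
#' tag. Counts must be non-negative and gene/cell identifiers unique; sparse
#' input stays sparse.
#'
#' @param counts numeric matrix or \code{Matrix::Matrix} with genes as rows and
#'   cells as columns; \code{rownames} are gene IDs, \code{colnames} cell IDs.
#' @param batch single string tagging the batch, typically \code{"reference"}
#'   or \code{"query"}.
#' @return An object of class \code{"expr_matrix"}: a list with elements
#'   \code{counts}, \code{gene_ids}, \code{cell_ids}, \code{batch}.
#' @export
expression_matrix <- function(counts, batch = "reference") {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!(is.matrix(counts) || methods::is(counts, "Matrix")))
    stop("`counts` must be a matrix or Matrix")
  if (methods::is(counts, "sparseMatrix"))  # normalize pattern/logical storage
    counts <- methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix")
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("`counts` must have rownames (gene IDs) and colnames (cell IDs)")
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene IDs: ", paste(utils::head(dup_g, 5L), collapse = ", "))
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c))
    stop("duplicate cell IDs: ", paste(utils::head(dup_c, 5L), collapse = ", "))
  if (min_value(counts) < 0) stop("counts contain negative entries")
  if (!is.character(batch) || length(batch) != 1L || is.na(batch) || !nzchar(batch))
    stop("`batch` must be a single non-empty string")
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids, batch = batch),
    class = "expr_matrix"
  )
}

# minimum over dense or sparse storage without densifying
min_value <- function(m) {
  if (methods::is(m, "sparseMatrix")) {
    x <- methods::slot(methods::as(m, "generalMatrix"), "x")
    if (length(x) == 0L) return(0)
    min(min(x), 0)
  } else {
    if (length(m) == 0L) 0 else min(m)
  }
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, batch \"%s\" (%s)\n",
              length(x$gene_ids), length(x$cell_ids), x$batch,
              if (methods::is(x$counts, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Read a count matrix from disk
#'
#' Supports the 10x-style MatrixMarket triplet directory layout
#' (\code{matrix.mtx[.gz]}, \code{features.tsv[.gz]} or \code{genes.tsv[.gz]},
#' \code{barcodes.tsv[.gz]}) and dense CSV/TSV with genes as rows, cells as
#' columns and a header row of cell IDs. Gzip-compressed triplet members are
#' read transparently.
#'
#' @param path directory (for \code{mtx_dir}) or file (for \code{csv_dense}).
#' @param format \code{"auto"} picks \code{mtx_dir} for a directory and
#'   \code{csv_dense} for a file.
#' @param batch batch tag stored on the result.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "mtx_dir", "csv_dense"),
                        batch = "reference") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "mtx_dir" else "csv_dense"
  if (format == "mtx_dir") read_counts_mtx(path, batch) else read_counts_csv(path, batch)
}

find_member <- function(dir, stems) {
  for (stem in stems) for (ext in c("", ".gz")) {
    f <- file.path(dir, paste0(stem, ext))
    if (file.exists(f)) return(f)
  }
  stop("missing file: none of ", paste(stems, collapse = "/"),
       "[.gz] found in ", dir)
}

read_tsv_col1 <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

read_counts_mtx <- function(dir, batch) {
  if (!dir.exists(dir)) stop("missing directory: ", dir)
  mtx <- find_member(dir, "matrix.mtx")
  feat <- find_member(dir, c("features.tsv", "genes.tsv"))
  bc <- find_member(dir, "barcodes.tsv")
  m <- if (grepl("\\.gz$", mtx)) {
    # decompress to a scratch file; readMM manages plain paths cleanly
    tmp <- tempfile(fileext = ".mtx")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(readLines(gzfile(mtx)), tmp)
    Matrix::readMM(tmp)
  } else Matrix::readMM(mtx)
  m <- methods::as(m, "CsparseMatrix")
  genes <- read_tsv_col1(feat)
  cells <- read_tsv_col1(bc)
  if (nrow(m) != length(genes))
    stop("matrix has ", nrow(m), " rows but ", length(genes), " gene IDs")
  if (ncol(m) != length(cells))
    stop("matrix has ", ncol(m), " columns but ", length(cells), " barcodes")
  dimnames(m) <- list(genes, cells)
  expression_matrix(m, batch = batch)
}

read_counts_csv <- function(path, batch) {
  if (!file.exists(path)) stop("missing file: ", path)
  sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("dense count file needs a gene-ID column plus >=1 cell column: ", path)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in count file: ", path)
  rownames(m) <- genes
  expression_matrix(m, batch = batch)
}

#' Write a count matrix to disk
#'
#' @param x an [expression_matrix()].
#' @param path output file (\code{csv_dense}) or directory (\code{mtx_dir}).
#' @param format on-disk layout; genes are rows, cells columns in both.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(x, path, format = c("csv_dense", "mtx_dir")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expr_matrix"))
  if (format == "csv_dense") {
    df <- data.frame(gene_id = x$gene_ids, as.matrix(x$counts),
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(x$counts, "dMatrix"), "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(x$gene_ids, file.path(path, "features.tsv"))
    writeLines(x$cell_ids, file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read a cell-type label table
#'
#' Two-column CSV with a header: cell barcode, cell-type label. Labels are
#' whitespace-trimmed; duplicate barcodes and empty labels are errors.
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{cell_id}, \code{label}.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (ncol(df) < 2L) stop("label file must have two columns (cell_id,label): ", path)
  label_table(data.frame(cell_id = as.character(df[[1L]]),
                         label = as.character(df[[2L]]),
                         stringsAsFactors = FALSE))
}

#' Validate a label table
#'
#' @param df data.frame whose first two columns are cell ID and label.
#' @return data.frame with columns \code{cell_id}, \code{label}.
#' @export
label_table <- function(df) {
  df <- data.frame(cell_id = trimws(as.character(df[[1L]])),
                   label = trimws(as.character(df[[2L]])),
                   stringsAsFactors = FALSE)
  dup <- unique(df$cell_id[duplicated(df$cell_id)])
  if (length(dup))
    stop("duplicate cell IDs in labels: ", paste(utils::head(dup, 5L), collapse = ", "))
  if (any(!nzchar(df$label) | is.na(df$label)))
    stop("empty labels for cells: ",
         paste(utils::head(df$cell_id[!nzchar(df$label) | is.na(df$label)], 5L), collapse = ", "))
  df
}

annotation_meta_path <- function(path) {
  paste0(sub("\\.csv$", "", path), ".meta.json")
}

#' Write per-cell annotations plus run metadata
#'
#' Writes one CSV row per query cell (\code{cell_id}, \code{final_label},
#' \code{classifier_label}, \code{max_probability}, \code{cluster_id},
#' \code{confident}) and a sidecar JSON (\code{<path minus .csv>.meta.json})
#' holding the selected confidence threshold, run parameters, seed and package
#' versions.
#'
#' @param result a \code{"hicat_annotation"} object (see [resolve_labels()] or
#'   the \code{annotation} element of a [hicat()] fit).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(result, path) {
  stopifnot(inherits(result, "hicat_annotation"))
  df <- as.data.frame(result)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    threshold = attr(result, "threshold")$threshold,
    threshold_spec = unclass(attr(result, "threshold")),
    params = attr(result, "params"),
    seed = attr(result, "params")$seed,
    versions = list(hicat = as.character(utils::packageVersion("hicat")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  )
  jsonlite::write_json(meta, annotation_meta_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an annotation CSV written by [write_annotation()]
#'
#' @param path the annotation CSV path; the sidecar JSON is read when present.
#' @return a \code{"hicat_annotation"} data.frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "final_label", "classifier_label", "max_probability",
            "cluster_id", "confident")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation file lacks columns: ", paste(miss, collapse = ", "))
  df$confident <- as.logical(df$confident)
  mp <- annotation_meta_path(path)
  thr <- NULL
  params <- NULL
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    if (!is.null(meta$threshold_spec))
      thr <- structure(meta$threshold_spec, class = "hicat_threshold")
    params <- meta$params
  }
  structure(df, class = c("hicat_annotation", "data.frame"),
            threshold = thr, params = params)
}
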