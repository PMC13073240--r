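#' Read a count matrix from a 10x-style MTX triplet or a dense table
#'
#' A directory is treated as a 10x triplet (\code{matrix.mtx[.gz]},
#' \code{features.tsv[.gz]} or \code{genes.tsv[.gz]}, \code{barcodes.tsv[.gz]});
#' on disk the MTX stores genes x cells and is transposed to cells x genes in
#' memory. A file is read as a dense table with genes as rows and cells as
#' columns (the on-disk convention; orientation is never auto-detected, set
#' \code{genes_as_rows = FALSE} only if your file is transposed).
#'
#' @param path directory (triplet) or file (TSV/CSV, first column = gene id).
#' @param genes_as_rows logical; dense files only.
#' @return an \code{ExpressionMatrix} with \code{layer = "counts"}.
#' @export
read_counts <- function(path, genes_as_rows = TRUE) {
  if (dir.exists(path)) return(read_counts_mtx(path))
  if (!file.exists(path)) stop("no such file or directory: ", path)
  read_counts_dense(path, genes_as_rows = genes_as_rows)
}

find_triplet_member <- function(dir, stems) {
  for (stem in stems) for (ext in c("", ".gz")) {
    f <- file.path(dir, paste0(stem, ext))
    if (file.exists(f)) return(f)
  }
  stop("missing triplet member (looked for ", paste(stems, collapse = "/"),
       ") in ", dir)
}

read_counts_mtx <- function(dir) {
  mtx <- find_triplet_member(dir, "matrix.mtx")
  feat <- find_triplet_member(dir, c("features.tsv", "genes.tsv"))
  bar <- find_triplet_member(dir, "barcodes.tsv")
  sp <- Matrix::readMM(mtx)
  features <- utils::read.table(feat, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.table(bar, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  # 10x convention: column 2 of features.tsv is the symbol; 1-column files are symbols
  genes <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  if (nrow(sp) != length(genes))
    stop(sprintf("dimension mismatch: MTX has %d rows but %d features listed",
                 nrow(sp), length(genes)))
  if (ncol(sp) != length(barcodes))
    stop(sprintf("dimension mismatch: MTX has %d columns but %d barcodes listed",
                 ncol(sp), length(barcodes)))
  dense <- t(as.matrix(sp))
  dimnames(dense) <- list(barcodes, genes)
  if (length(dense) == 0) stop("empty matrix file: ", mtx)
  expression_matrix(dense, layer = "counts")
}

read_counts_dense <- function(path, genes_as_rows = TRUE) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty matrix file: ", path)
  m <- as.matrix(df)
  if (genes_as_rows) m <- t(m)
  expression_matrix(m, layer = "counts")
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' @param m an \code{ExpressionMatrix} with \code{layer = "counts"}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_counts_mtx <- function(m, dir) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("MTX output expects the counts layer")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- methods::as(Matrix::Matrix(t(m$values), sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  g <- gene_ids(m)
  utils::write.table(data.frame(g, g, "Gene Expression"),
                     file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(cell_ids(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a count matrix as a dense TSV (genes as rows)
#'
#' @param m an \code{ExpressionMatrix}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_counts_dense <- function(m, path) {
  v <- t(m$values)
  df <- data.frame(gene = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell annotation TSV
#'
#' Expects a header; the first column is the cell id and a \code{compartment}
#' column is required. Every other column is exposed as a covariate.
#'
#' @param path TSV path.
#' @param label_set optional declared compartment label set; default is the
#'   sorted unique observed values.
#' @return a \code{CellAnnotation}.
#' @export
read_annotations <- function(path, label_set = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!"compartment" %in% names(df))
    stop("annotation file lacks required column 'compartment': ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate cell ids in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  covars <- df[setdiff(names(df), c(names(df)[1], "compartment"))]
  cell_annotation(ids, df$compartment,
                  covariates = if (ncol(covars)) covars else NULL,
                  label_set = label_set)
}

#' Write a per-cell annotation TSV
#' @param ann a \code{CellAnnotation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(ann, path) {
  df <- data.frame(cell_id = rownames(ann), as.data.frame(ann),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene symbols. Duplicate symbols
#' within a line are dropped keeping the first occurrence.
#'
#' @param path GMT path.
#' @return a named list of \code{GeneSet} (provenance \code{custom}).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    gs <- gene_set(fields[1], fields[-(1:2)], provenance = "custom")
    out[[gs$name]] <- gs
  }
  out
}

#' Write gene sets to a GMT file
#' @param sets a \code{GeneSet} or list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(gs)
    paste(c(gs$name, gs$provenance, gs$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a homology table from a two-column TSV
#'
#' @param path TSV with header \code{source<TAB>target}.
#' @return a \code{HomologyTable}.
#' @export
read_homology_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("source", "target") %in% names(df)))
    stop("homology table needs columns 'source' and 'target': ", path)
  homology_table(df$source, df$target)
}
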