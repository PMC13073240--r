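#' Construct an expression matrix
#'
#' The package's central container: a dense cells x genes numeric matrix with
#' a layer tag recording which transform it carries. Cell ids live in the
#' rownames, gene symbols in the colnames; both must be unique within their
#' axis. The \code{counts} layer must contain non-negative integers; no layer
#' may contain NA/NaN.
#'
#' @param values numeric matrix, cells in rows and genes in columns; may carry
#'   dimnames, otherwise supply \code{cell_ids}/\code{gene_ids}.
#' @param layer one of \code{"counts"}, \code{"lognorm"}, \code{"zscore"}.
#' @param cell_ids,gene_ids optional character vectors overriding dimnames.
#' @return an object of class \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(values, layer = c("counts", "lognorm", "zscore"),
                              cell_ids = NULL, gene_ids = NULL) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(cell_ids)) rownames(values) <- cell_ids
  if (!is.null(gene_ids)) colnames(values) <- gene_ids
  if (is.null(rownames(values)) && nrow(values) > 0)
    rownames(values) <- paste0("cell", seq_len(nrow(values)))
  if (is.null(colnames(values)) && ncol(values) > 0)
    colnames(values) <- paste0("gene", seq_len(ncol(values)))
  m <- structure(list(values = values, layer = layer), class = "ExpressionMatrix")
  validate_expression_matrix(m)
  m
}

validate_expression_matrix <- function(m) {
  v <- m$values
  if (anyDuplicated(rownames(v)))
    stop("duplicate cell ids: ", paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicate gene ids: ", paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  if (anyNA(v)) stop("expression matrix contains NA/NaN values")
  if (m$layer == "counts") {
    if (any(v < 0)) {
      bad <- which(v < 0, arr.ind = TRUE)[1, ]
      stop(sprintf("negative count at cell '%s', gene '%s'",
                   rownames(v)[bad[1]], colnames(v)[bad[2]]))
    }
    if (any(v != round(v))) {
      bad <- which(v != round(v), arr.ind = TRUE)[1, ]
      stop(sprintf("non-integer count at cell '%s', gene '%s'",
                   rownames(v)[bad[1]], colnames(v)[bad[2]]))
    }
  }
  invisible(m)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [layer=%s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Cell and gene identifiers of an expression matrix
#' @param m an \code{ExpressionMatrix}.
#' @return character vector of ids.
#' @export
cell_ids <- function(m) rownames(m$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(m) colnames(m$values)

#' Subset an expression matrix
#'
#' @param m an \code{ExpressionMatrix}.
#' @param cells,genes character, integer or logical index on the respective
#'   axis; \code{NULL} keeps all.
#' @return an \code{ExpressionMatrix} with the same layer.
#' @export
subset_matrix <- function(m, cells = NULL, genes = NULL) {
  v <- m$values
  if (!is.null(cells)) v <- v[cells, , drop = FALSE]
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  expression_matrix(v, layer = m$layer)
}

#' Construct a per-cell annotation table
#'
#' Holds one compartment label per cell plus optional categorical covariates
#' (dataset, sex, cell type, timepoint, ...). The declared label set defaults
#' to the sorted unique compartment values.
#'
#' @param cell_ids unique character ids.
#' @param compartment character/factor of length \code{length(cell_ids)}.
#' @param covariates optional data.frame (or named list) of per-cell columns.
#' @param label_set optional declared label set; every compartment value must
#'   belong to it.
#' @return an object of class \code{CellAnnotation}: a data.frame with a
#'   \code{compartment} factor, rownames = cell ids.
#' @export
cell_annotation <- function(cell_ids, compartment, covariates = NULL,
                            label_set = NULL) {
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ", paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  compartment <- as.character(compartment)
  if (length(compartment) != length(cell_ids))
    stop("compartment length does not match cell_ids")
  if (is.null(label_set)) label_set <- sort(unique(compartment))
  if (!all(compartment %in% label_set))
    stop("compartment values outside declared label set: ",
         paste(setdiff(compartment, label_set), collapse = ", "))
  df <- data.frame(compartment = factor(compartment, levels = label_set),
                   row.names = cell_ids, stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    stopifnot(nrow(covariates) == length(cell_ids))
    for (nm in names(covariates)) df[[nm]] <- covariates[[nm]]
  }
  class(df) <- c("CellAnnotation", "data.frame")
  df
}

#' @export
print.CellAnnotation <- function(x, ...) {
  cat(sprintf("CellAnnotation: %d cells, compartments {%s}, covariates {%s}\n",
              nrow(x), paste(levels(x$compartment), collapse = ", "),
              paste(setdiff(names(x), "compartment"), collapse = ", ")))
  invisible(x)
}

#' Align an annotation to an expression matrix
#'
#' @param ann a \code{CellAnnotation}.
#' @param m an \code{ExpressionMatrix} whose cells must all be annotated.
#' @return the annotation reordered to \code{cell_ids(m)}.
#' @export
align_annotation <- function(ann, m) {
  ids <- cell_ids(m)
  missing <- setdiff(ids, rownames(ann))
  if (length(missing))
    stop("cells missing from annotation: ", paste(utils::head(missing, 5), collapse = ", "))
  out <- ann[ids, , drop = FALSE]
  class(out) <- c("CellAnnotation", "data.frame")
  out
}

#' Construct a gene set
#'
#' A named, de-duplicated, ordered list of gene symbols with a provenance tag
#' saying which selector produced it.
#'
#' @param name character scalar.
#' @param genes character vector of symbols; duplicates removed keeping the
#'   first occurrence.
#' @param provenance one of hvg, fam, rfe, mir, random, custom.
#' @return an object of class \code{GeneSet}.
#' @export
gene_set <- function(name, genes,
                     provenance = c("custom", "hvg", "fam", "rfe", "mir", "random")) {
  provenance <- match.arg(provenance)
  genes <- as.character(genes)
  genes <- genes[!duplicated(genes)]
  if (!length(genes)) stop("gene set '", name, "' is empty")
  if (any(!nzchar(genes))) stop("gene set '", name, "' contains empty symbols")
  structure(list(name = as.character(name), genes = genes, provenance = provenance),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s' [%s]: %d genes\n", x$name, x$provenance, length(x$genes)))
  invisible(x)
}

#' @export
length.GeneSet <- function(x) length(x$genes)

#' Construct a homology mapping table
#'
#' Two-column source -> target symbol mapping (e.g. mouse -> human). Source
#' symbols must be unique; symbols are matched case-sensitively unless
#' downstream callers opt into case-insensitive merging.
#'
#' @param source,target character vectors of equal length, no empty symbols.
#' @return an object of class \code{HomologyTable} (a data.frame).
#' @export
homology_table <- function(source, target) {
  source <- as.character(source); target <- as.character(target)
  stopifnot(length(source) == length(target))
  if (any(!nzchar(source)) || any(!nzchar(target)))
    stop("homology table contains empty symbols")
  if (anyDuplicated(source))
    stop("duplicate source symbols in homology table: ",
         paste(unique(source[duplicated(source)]), collapse = ", "))
  structure(data.frame(source = source, target = target, stringsAsFactors = FALSE),
            class = c("HomologyTable", "data.frame"))
}
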