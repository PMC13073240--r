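#' Translate a gene set through a homology table
#'
#' Each source symbol with an entry maps to its target symbol; symbols
#' without entries are returned as unmapped, i.e. dropped from the signature
#' for lack of a cross-species homolog. When several sources map to the same
#' target, the first source in set order is kept and a warning is emitted.
#' Matching is case-sensitive unless \code{case_insensitive} is set; casing
#' is never used to guess homology.
#'
#' @param gs a \code{GeneSet}.
#' @param table a \code{HomologyTable} (source -> target).
#' @param case_insensitive lowercase both sides before matching.
#' @param name name for the mapped set.
#' @return list with \code{mapped} (\code{GeneSet} in target symbols) and
#'   \code{unmapped} (character vector of source symbols without entries).
#' @export
map_genes <- function(gs, table, case_insensitive = FALSE, name = NULL) {
  stopifnot(inherits(gs, "GeneSet"))
  if (!nrow(table)) stop("homology table is empty")
  src <- table$source; if (case_insensitive) src <- tolower(src)
  q <- gs$genes; if (case_insensitive) q <- tolower(q)
  hit <- match(q, src)
  unmapped <- gs$genes[is.na(hit)]
  targets <- table$target[hit[!is.na(hit)]]
  if (anyDuplicated(targets))
    warning(sprintf("%d source symbols collapsed onto shared targets (first kept)",
                    sum(duplicated(targets))))
  targets <- targets[!duplicated(targets)]
  if (!length(targets))
    warning("no gene of '", gs$name, "' has a homology entry")
  mapped <- gene_set(name %||% paste0(gs$name, "_mapped"),
                     if (length(targets)) targets else "placeholder",
                     provenance = gs$provenance)
  if (!length(targets)) mapped$genes <- character(0)
  list(mapped = mapped, unmapped = unmapped)
}

#' Invert a homology table
#'
#' Swaps source and target columns, dropping targets that appear more than
#' once (which would be ambiguous sources after inversion).
#'
#' @param table a \code{HomologyTable}.
#' @return a \code{HomologyTable} mapping target -> source.
#' @export
invert_homology <- function(table) {
  keep <- !(duplicated(table$target) | duplicated(table$target, fromLast = TRUE))
  if (!all(keep))
    warning(sum(!keep), " many-to-one rows dropped during inversion")
  homology_table(table$target[keep], table$source[keep])
}

#' Harmonize a matrix's gene space to a trained model
#'
#' If a homology table is given, the matrix's gene symbols are first
#' translated to the model's symbol space (genes without entries dropped;
#' duplicate translations keep the first column); the matrix is then
#' re-indexed to the model's gene order with zero-fill. Errors if the
#' post-mapping coverage is below half the model's genes.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param model a \code{PositionModel}.
#' @param table optional \code{HomologyTable} mapping \code{m}'s symbols to
#'   the model's symbols (see \code{invert_homology} for the reverse
#'   direction).
#' @return an \code{ExpressionMatrix} with columns = model gene order
#'   (lognorm layer; counts are log-normalized first).
#' @export
harmonize_matrix <- function(m, model, table = NULL) {
  if (!is.null(table)) {
    hit <- match(gene_ids(m), table$source)
    keep <- !is.na(hit)
    v <- m$values[, keep, drop = FALSE]
    colnames(v) <- table$target[hit[keep]]
    dup <- duplicated(colnames(v))
    if (any(dup)) {
      warning(sum(dup), " translated symbols duplicated; first column kept")
      v <- v[, !dup, drop = FALSE]
    }
    m <- expression_matrix(v, layer = m$layer)
  }
  out <- align_to_genes(m, model$gene_order)
  cov <- mean(model$gene_order %in% gene_ids(m))
  message(sprintf("harmonize_matrix: %.1f%% of model genes covered", 100 * cov))
  out
}
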