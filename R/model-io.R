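MODEL_FORMAT_VERSION <- "sclocate-model-1"

# A model archive is one file: a JSON header (format version, gene and class
# order, training config, seed, fingerprint, and a manifest of named numeric
# blocks with their dims), a single NUL delimiter byte, then the blocks as
# raw little-endian float64 in manifest order. Fixed field order makes two
# saves of the same model byte-identical.

model_blocks <- function(model) {
  blocks <- list(stats_mean = model$stats$mean, stats_sd = model$stats$sd)
  for (nm in names(model$weights)) blocks[[paste0("w_", nm)]] <- model$weights[[nm]]
  blocks
}

#' Save a trained position model to a single archive file
#'
#' The archive self-describes gene order, class order, standardization stats,
#' seed and config; weights are stored as raw float64 so that
#' \code{load_model(save_model(m))} reproduces predictions exactly and two
#' saves of the same model are byte-identical.
#'
#' @param model a \code{PositionModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "PositionModel"))
  blocks <- model_blocks(model)
  manifest <- lapply(blocks, function(b) {
    d <- dim(b); if (is.null(d)) d <- length(b); as.integer(d)
  })
  header <- list(
    format = MODEL_FORMAT_VERSION,
    gene_order = model$gene_order,
    class_order = model$class_order,
    config = unclass(model$config),
    fingerprint = model$fingerprint,
    blocks = manifest
  )
  json <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(as.character(json)), con)
  writeBin(as.raw(0L), con)
  for (b in blocks) writeBin(as.numeric(b), con, size = 8, endian = "little")
  invisible(path)
}

#' Load a position model saved by \code{save_model}
#'
#' @param path archive path.
#' @return a \code{PositionModel} whose predictions are identical to those of
#'   the saved model.
#' @export
load_model <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  nul <- which(raw == as.raw(0L))[1]
  if (is.na(nul)) stop("truncated or corrupt model file (no header delimiter): ", path)
  header <- jsonlite::fromJSON(rawToChar(raw[seq_len(nul - 1L)]),
                               simplifyVector = TRUE)
  if (is.null(header$format) || header$format != MODEL_FORMAT_VERSION)
    stop("model file version mismatch: expected ", MODEL_FORMAT_VERSION,
         ", found ", header$format %||% "<none>")
  for (req in c("gene_order", "class_order", "blocks"))
    if (is.null(header[[req]])) stop("model file missing block: ", req)
  body <- raw[-seq_len(nul)]
  need <- sum(vapply(header$blocks, prod, numeric(1))) * 8
  if (length(body) < need) stop("truncated model file: ", path)
  vals <- readBin(body, what = "double", n = length(body) / 8, size = 8,
                  endian = "little")
  blocks <- list(); at <- 0L
  for (nm in names(header$blocks)) {
    d <- header$blocks[[nm]]
    n <- prod(d)
    x <- vals[at + seq_len(n)]; at <- at + n
    if (length(d) > 1) x <- matrix(x, nrow = d[1], ncol = d[2])
    blocks[[nm]] <- x
  }
  stats <- list(mean = blocks$stats_mean, sd = blocks$stats_sd)
  names(stats$mean) <- names(stats$sd) <- header$gene_order
  wnames <- sub("^w_", "", grep("^w_", names(blocks), value = TRUE))
  weights <- blocks[paste0("w_", wnames)]
  names(weights) <- wnames
  cfg <- header$config
  structure(list(gene_order = header$gene_order,
                 class_order = header$class_order,
                 stats = stats, weights = weights,
                 config = do.call(training_config, cfg[names(cfg) %in%
                   names(formals(training_config))]),
                 fingerprint = header$fingerprint),
            class = "PositionModel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
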