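#' Run the full positional-inference workflow from a config
#'
#' Executes the five-step workflow: load or simulate datasets, preprocess
#' (QC + log-normalization), select a feature gene set (method per config),
#' train the classifier on the declared training datasets, externally
#' validate on the held-out datasets, then optionally map the signature
#' across species and produce downstream readouts. Every artifact (gene
#' sets, model, evaluation report, tables) is written under \code{out_dir}
#' together with a manifest of content hashes, the seed and the package
#' version; reruns with the same config reproduce all outputs exactly.
#'
#' @param config path to a YAML config, or an equivalent named list. Top
#'   sections: \code{seed}; \code{data} (either \code{simulate}: sim_config
#'   fields, or \code{datasets}: list of \code{name}/\code{counts}/
#'   \code{annotations} paths); \code{training_datasets} /
#'   \code{validation_datasets} (names); \code{preprocess} (\code{qc},
#'   qc_filter fields, \code{scale}); \code{features} (\code{method} in
#'   hvg/fam/rfe/mir/random plus method fields, optional \code{cell_type}
#'   filter); \code{model} (training_config fields); optional
#'   \code{homology} (\code{table} TSV path); optional \code{apply}
#'   (\code{genesets} GMT path, \code{group_by}).
#' @param out_dir output directory (created).
#' @param seed optional override of the config seed.
#' @return invisibly, a list with the gene set, model, per-dataset
#'   evaluation reports and the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  check_pipeline_config(cfg)
  if (!is.null(seed)) cfg$seed <- seed
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[sclocate] ", sprintf(...))

  # -- step 1: datasets ------------------------------------------------------
  if (!is.null(cfg$data$simulate)) {
    sc_args <- cfg$data$simulate
    sc_args$seed <- sc_args$seed %||% cfg$seed
    sim <- simulate_positional(do.call(sim_config, sc_args))
    datasets <- sim$datasets
    log_msg("simulated %d datasets", length(datasets))
  } else {
    datasets <- list()
    for (d in cfg$data$datasets) {
      datasets[[d$name]] <- list(matrix = read_counts(d$counts),
                                 annotation = read_annotations(d$annotations))
    }
    log_msg("loaded %d datasets", length(datasets))
  }

  # -- step 2: preprocess ----------------------------------------------------
  pp <- cfg$preprocess %||% list()
  scale <- pp$scale %||% 1e4
  for (nm in names(datasets)) {
    ds <- datasets[[nm]]
    if (isTRUE(pp$qc %||% TRUE)) {
      qc <- qc_filter(ds$matrix,
                      min_genes = pp$min_genes %||% 200L,
                      max_genes = pp$max_genes %||% 4000L,
                      max_mito_frac = pp$max_mito_frac %||% 0.20)
      ds$matrix <- qc$matrix
      ds$annotation <- align_annotation(ds$annotation, ds$matrix)
      log_msg("%s: QC removed %d cells", nm, nrow(qc$report))
    }
    ds$lognorm <- log_normalize(ds$matrix, scale = scale)
    datasets[[nm]] <- ds
  }

  train_names <- unlist(cfg$training_datasets)
  valid_names <- unlist(cfg$validation_datasets %||% list())

  # -- step 3: feature selection --------------------------------------------
  fs <- cfg$features %||% list(method = "hvg")
  subset_celltype <- function(ds) {
    if (is.null(fs$cell_type)) return(ds)
    keep <- ds$annotation[["cell_type"]] == fs$cell_type
    list(lognorm = subset_matrix(ds$lognorm, cells = keep),
         annotation = ds$annotation[keep, , drop = FALSE])
  }
  geneset <- switch(fs$method %||% "hvg",
    hvg = {
      per_ds <- lapply(train_names, function(nm) {
        ds <- subset_celltype(datasets[[nm]])
        hvg_rank(ds$lognorm, n_top = fs$n_top %||% 100L,
                 n_bins = fs$n_bins %||% 20L, name = paste0("hvg_", nm))$geneset
      })
      merge_union(per_ds, name = "hvg_union")
    },
    fam = {
      ds <- pool_datasets(datasets[train_names])
      de_markers(ds$lognorm, ds$annotation,
                 min_logfc = fs$min_logfc %||% 0.25,
                 max_fdr = fs$max_fdr %||% 0.05,
                 top_per_class = fs$top_per_class, name = "fam")$geneset
    },
    rfe = {
      ds <- pool_datasets(datasets[train_names])
      start <- gene_set("universe", detected_universe(ds$lognorm))
      rfe_select(ds$lognorm, ds$annotation, start,
                 target_size = fs$target_size %||% 100L)
    },
    mir = {
      ds <- pool_datasets(datasets[train_names])
      start <- gene_set("universe", detected_universe(ds$lognorm))
      mi_rank(ds$lognorm, ds$annotation, start,
              target_size = fs$target_size %||% 100L)$geneset
    },
    random = {
      ds <- pool_datasets(datasets[train_names])
      random_set(detected_universe(ds$lognorm), n = fs$target_size %||% 100L,
                 seed = cfg$seed)
    },
    stop("unknown feature method: ", fs$method)
  )
  write_gmt(geneset, file.path(out_dir, "geneset.gmt"))
  log_msg("selected %d genes by %s", length(geneset$genes), fs$method %||% "hvg")

  # -- step 4: training ------------------------------------------------------
  train_pool <- pool_datasets(datasets[train_names])
  mc <- cfg$model %||% list()
  mc$seed <- mc$seed %||% cfg$seed
  tcfg <- do.call(training_config, mc[names(mc) %in% names(formals(training_config))])
  model <- train_position_model(train_pool$lognorm, train_pool$annotation,
                                geneset, tcfg)
  save_model(model, file.path(out_dir, "model.bin"))

  # -- step 5: external validation ------------------------------------------
  homology <- if (!is.null(cfg$homology$table))
    read_homology_table(cfg$homology$table) else NULL
  reports <- list()
  for (nm in valid_names) {
    ds <- datasets[[nm]]
    mat <- if (is.null(homology)) ds$lognorm
           else harmonize_matrix(ds$lognorm, model, table = homology)
    pred <- predict(model, mat)
    reports[[nm]] <- evaluate(pred, ds$annotation)
    utils::write.table(reports[[nm]]$confusion,
                       file.path(out_dir, paste0("confusion_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    log_msg("%s: accuracy %.4f", nm, reports[[nm]]$overall_accuracy)
  }
  eval_json <- lapply(reports, function(r)
    list(overall_accuracy = r$overall_accuracy,
         per_class_auc = as.list(r$per_class_auc), n_cells = r$n_cells))
  jsonlite::write_json(eval_json, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- optional downstream readouts -----------------------------------------
  if (!is.null(cfg$apply)) {
    nm <- valid_names[1] %||% train_names[1]
    ds <- datasets[[nm]]
    ann <- assign_positions(model, ds$lognorm, ds$annotation)
    fr <- compartment_fractions(ann, group_by = cfg$apply$group_by %||% "dataset")
    utils::write.table(fr, file.path(out_dir, "compartment_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cfg$apply$genesets)) {
      sets <- read_gmt(cfg$apply$genesets)
      rows <- lapply(sets, function(gs) {
        sc <- module_score(ds$lognorm, gs)
        cbind(set = gs$name,
              score_summary(sc, ann, cfg$apply$group_by %||% "dataset"))
      })
      utils::write.table(do.call(rbind, rows),
                         file.path(out_dir, "module_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # -- manifest --------------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("sclocate")),
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(geneset = geneset, model = model, reports = reports,
                 manifest = manifest))
}

check_pipeline_config <- function(cfg) {
  if (is.null(cfg$data) || (is.null(cfg$data$simulate) && is.null(cfg$data$datasets)))
    stop("config error at data: declare either data.simulate or data.datasets")
  if (!is.null(cfg$data$datasets)) {
    for (i in seq_along(cfg$data$datasets)) {
      d <- cfg$data$datasets[[i]]
      for (fld in c("name", "counts", "annotations"))
        if (is.null(d[[fld]]))
          stop(sprintf("config error at data.datasets[%d].%s: missing", i, fld))
      if (!file.exists(d$counts) && !dir.exists(d$counts))
        stop(sprintf("config error at data.datasets[%d].counts: no such path %s",
                     i, d$counts))
      if (!file.exists(d$annotations))
        stop(sprintf("config error at data.datasets[%d].annotations: no such path %s",
                     i, d$annotations))
    }
  }
  if (is.null(cfg$training_datasets))
    stop("config error at training_datasets: missing")
  invisible(TRUE)
}

# pool datasets over their common genes (cells stacked)
pool_datasets <- function(ds_list) {
  genes <- Reduce(intersect, lapply(ds_list, function(d) gene_ids(d$lognorm)))
  mats <- lapply(unname(ds_list), function(d) d$lognorm$values[, genes, drop = FALSE])
  anns <- lapply(unname(ds_list), function(d) as.data.frame(d$annotation))
  ann_all <- do.call(rbind, anns)
  labels <- levels(ds_list[[1]]$annotation$compartment)
  list(lognorm = expression_matrix(do.call(rbind, mats), layer = "lognorm"),
       annotation = cell_annotation(rownames(ann_all), ann_all$compartment,
                                    covariates = ann_all[setdiff(names(ann_all),
                                                                 "compartment")],
                                    label_set = labels))
}
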