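#' Read an expression matrix from disk
#'
#' Reads genes x observations matrices from dense TSV/CSV (first column
#' gene identifiers, header row observation identifiers) or sparse
#' MatrixMarket MTX with `genes.tsv`/`samples.tsv` sidecar files (one
#' identifier per line, genes as MTX rows). Duplicate gene identifiers are
#' collapsed by summation with a warning; negative entries are an error.
#'
#' @param path path to the matrix file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; `NULL` guesses from the file
#'   extension.
#' @param unit measurement unit recorded on the result.
#' @param genes_file,samples_file sidecar paths for MTX (default
#'   `genes.tsv` / `samples.tsv` next to the matrix).
#' @return An `expr_mat`.
#' @export
read_matrix <- function(path, format = NULL,
                        unit = c("unknown", "count", "cpm", "tpm", "rank"),
                        genes_file = NULL, samples_file = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("cannot guess format from extension of ", path))
  }
  if (format == "mtx") {
    gf <- if (is.null(genes_file)) file.path(dirname(path), "genes.tsv")
          else genes_file
    sf <- if (is.null(samples_file)) file.path(dirname(path), "samples.tsv")
          else samples_file
    if (!file.exists(gf) || !file.exists(sf)) {
      stop("MTX input needs sidecar id files: ", gf, " and ", sf)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gf)
    samples <- readLines(sf)
    if (length(genes) != nrow(m)) {
      stop("genes sidecar has ", length(genes), " ids but matrix has ",
           nrow(m), " rows")
    }
    if (length(samples) != ncol(m)) {
      stop("samples sidecar has ", length(samples), " ids but matrix has ",
           ncol(m), " columns")
    }
    dimnames(m) <- list(genes, samples)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("malformed matrix file (need id column + data): ",
                            path)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
    rownames(m) <- ids
  }
  if (min(m) < 0) stop("negative entries in ", path)
  if (anyDuplicated(rownames(m))) {
    warning("duplicate gene ids collapsed by summation")
    m <- rowsum(m, group = rownames(m), reorder = FALSE)
  }
  expr_matrix(m, unit = unit)
}

#' Write an expression matrix as TSV
#'
#' Dense genes x observations TSV with a leading `gene` id column; values
#' are written at 12 significant digits so a write/read round trip is
#' lossless at that precision.
#'
#' @param x matrix or `expr_mat`.
#' @param path output file path.
#' @export
write_matrix <- function(x, path) {
  x <- as_expr(x)
  df <- data.frame(gene = rownames(x),
                   signif(unclass(x), 12L),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column label table
#'
#' @param path TSV with observation id in column 1 and label in column 2
#'   (header optional, detected).
#' @return Named character vector (id -> label).
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs two columns: ", path)
  # drop a header row if the first line does not look like data
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Serialize / restore an atlas directory
#'
#' Writes an `atlas_model` as a directory of plain-text tables
#' (`loadings.tsv`, `scores.tsv`, `centering.tsv`, `hd.tsv`, `ranked.tsv`,
#' `labels.tsv`) plus `meta.yaml` (eigenvalues, dimensions), and reads it
#' back.
#'
#' @param atlas an `atlas_model`.
#' @param dir directory path (created if missing).
#' @return `write_atlas` returns `dir` invisibly; `read_atlas` an
#'   `atlas_model`.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "atlas_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(m, f) {
    df <- data.frame(id = rownames(m), signif(as.matrix(m), 12L),
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(atlas$loadings, "loadings.tsv")
  wt(atlas$scores, "scores.tsv")
  wt(cbind(mean = atlas$centering_means), "centering.tsv")
  wt(cbind(hd = atlas$hd_scores), "hd.tsv")
  write_matrix(atlas$ranked, file.path(dir, "ranked.tsv"))
  utils::write.table(
    data.frame(id = names(atlas$sample_labels),
               label = unname(atlas$sample_labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  yaml::write_yaml(list(eigenvalues = as.numeric(atlas$eigenvalues),
                        n_pc = ncol(atlas$loadings),
                        n_genes = length(atlas$genes)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  rt <- function(f) {
    df <- utils::read.table(file.path(dir, f), header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
  loadings <- rt("loadings.tsv")
  scores <- rt("scores.tsv")
  centering <- rt("centering.tsv")
  hd <- rt("hd.tsv")
  labels_df <- utils::read.table(file.path(dir, "labels.tsv"), header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  ranked <- read_matrix(file.path(dir, "ranked.tsv"), format = "tsv",
                        unit = "rank")
  structure(
    list(genes = rownames(loadings),
         hd_scores = stats::setNames(hd[, 1L], rownames(hd)),
         centering_means = stats::setNames(centering[, 1L],
                                           rownames(centering)),
         loadings = loadings,
         scores = scores,
         eigenvalues = as.numeric(meta$eigenvalues),
         sample_labels = stats::setNames(as.character(labels_df$label),
                                         labels_df$id),
         ranked = ranked),
    class = "atlas_model")
}

#' Run the full projection pipeline
#'
#' Composite driver: build (or load) the atlas, prepare the query by
#' pseudo-bulk aggregation or graph-diffusion imputation (mutually
#' exclusive; `"none"` projects raw), project onto the atlas, score
#' identities and evaluate the projection against the query labels when
#' available. All artifacts are written to `out_dir` as plain-text tables
#' and the effective configuration is echoed to `config.yaml`.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   `ref`, `ref_labels`, `query` (matrices, paths or `expr_mat`s),
#'   `query_clusters` (required for aggregation), `prepare` (one of
#'   `"aggregate"`, `"impute"`, `"none"`), `n_genes`, `n_pc`, `kappa`,
#'   `kappa_mode` (`"default"`, `"connectivity"`, `"sparsity"`), `t`,
#'   `post_scale`, `score_mode`, `dm`, `seed`, `out_dir`.
#' @return A list with the atlas, projection, identity scores, metrics and
#'   the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(prepare = "none", n_genes = 2000L, n_pc = NULL,
                   kappa = 30L, kappa_mode = "default", t = 3L,
                   post_scale = TRUE, score_mode = "subcluster_medoid",
                   dm = FALSE, seed = 1L, out_dir = tempfile("atlascast_run_"))
  config <- utils::modifyList(defaults, config)
  if (!config$prepare %in% c("aggregate", "impute", "none")) {
    stop("prepare must be one of 'aggregate', 'impute', 'none' ",
         "(aggregation and imputation are mutually exclusive)")
  }
  load_mat <- function(x, unit = "unknown") {
    if (is.character(x)) read_matrix(x, unit = unit) else as_expr(x)
  }
  load_labels <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      read_labels(x)
    } else {
      x
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ref <- load_mat(config$ref)
  ref_labels <- load_labels(config$ref_labels)
  query <- load_mat(config$query, unit = "count")

  atlas <- fit_atlas(ref, ref_labels, n_genes = config$n_genes,
                     n_pc = config$n_pc)
  write_atlas(atlas, file.path(config$out_dir, "atlas"))

  query_labels <- NULL
  prepared <- query
  if (config$prepare == "aggregate") {
    if (is.null(config$query_clusters)) {
      stop("aggregation requires query_clusters")
    }
    clusters <- load_labels(config$query_clusters)
    agg <- aggregate_cells(query, clusters[colnames(query)],
                           seed = config$seed)
    prepared <- agg$pseudobulk
    query_labels <- agg$labels
    sp <- cluster_sparsity(prepared, query_labels)
    utils::write.table(sp, file.path(config$out_dir, "sparsity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (any(sp$flagged)) {
      message("sparsity flag raised for cluster(s): ",
              paste(sp$cluster[sp$flagged], collapse = ", "))
    }
  } else if (config$prepare == "impute") {
    norm <- normalize_library(query)
    kappa <- switch(config$kappa_mode,
                    default = config$kappa,
                    connectivity = choose_kappa(norm, "connectivity"),
                    sparsity = choose_kappa(norm, "sparsity"),
                    stop("unknown kappa_mode: ", config$kappa_mode))
    g <- diffusion_graph(norm, kappa = kappa, eigen = FALSE)
    imp <- impute_expression(norm, g, t = config$t)
    prepared <- if (isTRUE(config$post_scale)) post_scale(norm, imp) else imp
    if (!is.null(config$query_clusters)) {
      query_labels <- load_labels(config$query_clusters)[colnames(query)]
    }
  } else if (!is.null(config$query_clusters)) {
    query_labels <- load_labels(config$query_clusters)[colnames(prepared)]
  }
  write_matrix(prepared, file.path(config$out_dir, "prepared_query.tsv"))

  proj <- project_query(atlas, prepared)
  sc_df <- data.frame(obs_id = c(rownames(proj$ref_scores),
                                 rownames(proj$query_scores)),
                      rbind(proj$ref_scores, proj$query_scores),
                      source = c(rep("reference", nrow(proj$ref_scores)),
                                 rep("query", nrow(proj$query_scores))),
                      check.names = FALSE)
  utils::write.table(sc_df, file.path(config$out_dir, "scores_pc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (isTRUE(config$dm)) {
    dm <- dm_embed(proj, atlas_eigenvalues = atlas$eigenvalues)
    utils::write.table(
      data.frame(obs_id = rownames(dm$coords), dm$coords,
                 source = dm$source, check.names = FALSE),
      file.path(config$out_dir, "dm.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  preds <- build_predictors(atlas, mode = config$score_mode)
  scores <- capybara_score(proj$query_ranked, preds,
                           weights = atlas$hd_scores,
                           query_scores = proj$query_scores)
  utils::write.table(
    data.frame(cell = rownames(scores$beta), scores$beta,
               residual_norm = scores$residual_norm, check.names = FALSE),
    file.path(config$out_dir, "scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  metrics <- NULL
  if (!is.null(query_labels) && length(unique(query_labels)) >= 2L) {
    metrics <- evaluate_projection(proj$query_scores, query_labels)
    jsonlite::write_json(
      list(msi = metrics$msi, ari = metrics$ari,
           distance_ratio = metrics$distance_ratio),
      file.path(config$out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA)
  }

  echo <- config[!vapply(config, function(v) is.matrix(v) ||
                           inherits(v, "expr_mat") || is.function(v),
                         logical(1))]
  echo <- lapply(echo, function(v) {
    if (is.null(v)) NULL
    else if (length(v) > 20L) paste0("<", length(v), " values>")
    else v
  })
  yaml::write_yaml(echo, file.path(config$out_dir, "config.yaml"))

  invisible(list(atlas = atlas, projection = proj, scores = scores,
                 metrics = metrics, out_dir = config$out_dir))
}
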