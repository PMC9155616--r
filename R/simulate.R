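#' Configuration for the paired atlas/query simulator
#'
#' Bundles the parameters of the synthetic-data generator with defaults
#' that emulate the setting the projection framework assumes: a modest,
#' well-replicated bulk reference with distinct cell-type niches, and a
#' sparse, shallowly sequenced single-cell query drawn from the same type
#' means. The defaults (5 types, 1000 genes, 5% markers per type with
#' 8-fold up-shift, 10 bulk replicates per type, 200 cells per type,
#' library size 1500, dropout shape 1) give a query with roughly
#' half-zero entries - the bulk-versus-single-cell gap in library size and
#' zero composition that the method is designed to bridge.
#'
#' @param n_types number of cell types (>= 2).
#' @param genes number of genes.
#' @param marker_frac fraction of genes that are markers of each type
#'   (disjoint marker blocks per type).
#' @param bulk_reps_per_type bulk replicates simulated per type.
#' @param cells_per_type query cells simulated per pure type (and per
#'   mixture pair).
#' @param library_size total counts per query cell.
#' @param dropout_shape rate of the mean-dependent dropout (> 0 enables
#'   dropout; larger keeps more: the per-gene dropout probability is
#'   `exp(-dropout_shape * rel_expr)`). Use 0 to disable.
#' @param mixture_pairs optional list of `list(a =, b =, alpha =)` entries;
#'   each generates `cells_per_type` transitional cells from the profile
#'   `alpha * mu_a + (1 - alpha) * mu_b`.
#' @param marker_fold fold-change applied to marker genes.
#' @param bulk_dispersion negative-binomial size parameter of the bulk
#'   replicate noise (larger = less noisy).
#' @param bulk_depth mean total counts scale of a bulk replicate.
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_types = 5L, genes = 1000L, marker_frac = 0.05,
                       bulk_reps_per_type = 10L, cells_per_type = 200L,
                       library_size = 1500L, dropout_shape = 1,
                       mixture_pairs = NULL, marker_fold = 8,
                       bulk_dispersion = 20, bulk_depth = 1e5, seed = 1L) {
  stopifnot(n_types >= 2L, genes >= 10L, marker_frac >= 0, marker_frac < 1,
            bulk_reps_per_type >= 1L, cells_per_type >= 1L,
            library_size >= 1L, dropout_shape >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# deterministic per-config type mean profiles (genes x types)
sim_type_means <- function(cfg) {
  with_seed(cfg$seed, {
    base <- stats::rlnorm(cfg$genes, meanlog = 1, sdlog = 1.2)
    names(base) <- paste0("g", seq_len(cfg$genes))
    n_marker <- round(cfg$marker_frac * cfg$genes)
    means <- matrix(base, cfg$genes, cfg$n_types,
                    dimnames = list(names(base),
                                    paste0("T", seq_len(cfg$n_types))))
    if (n_marker > 0L) {
      for (ty in seq_len(cfg$n_types)) {
        block <- ((ty - 1L) * n_marker + seq_len(n_marker) - 1L) %%
          cfg$genes + 1L
        means[block, ty] <- means[block, ty] * cfg$marker_fold
      }
    }
    means
  })
}

#' Simulate a bulk reference atlas
#'
#' Draws a log-normal baseline mean profile shared by all types, up-shifts
#' a disjoint block of marker genes per type by `marker_fold`, and
#' generates bulk replicates with negative-binomial noise around the
#' (depth-scaled) type means. With `marker_frac = 0` all types share one
#' mean and no gene discriminates them.
#'
#' @param cfg a [sim_config()].
#' @return List with `expr` (genes x samples `expr_mat`, unit count),
#'   `labels` (per-sample type) and `means` (genes x types mean profiles,
#'   the ground truth reused by [simulate_query()]).
#' @export
simulate_atlas <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  means <- sim_type_means(cfg)
  scaled <- sweep(means, 2L, colSums(means) / cfg$bulk_depth, "/")
  n_s <- cfg$n_types * cfg$bulk_reps_per_type
  with_seed(cfg$seed + 1L, {
    expr <- matrix(0, cfg$genes, n_s)
    labels <- character(n_s)
    col <- 0L
    for (ty in seq_len(cfg$n_types)) {
      for (r in seq_len(cfg$bulk_reps_per_type)) {
        col <- col + 1L
        expr[, col] <- stats::rnbinom(cfg$genes, mu = scaled[, ty],
                                      size = cfg$bulk_dispersion)
        labels[col] <- colnames(means)[ty]
      }
    }
    dimnames(expr) <- list(rownames(means),
                           paste0(labels, "_s", seq_len(n_s)))
    list(expr = expr_matrix(expr, unit = "count"),
         labels = stats::setNames(labels, colnames(expr)),
         means = means)
  })
}

#' Simulate a single-cell query matched to a simulated atlas
#'
#' Each cell draws `library_size` counts multinomially from its type's
#' mean profile (so per-cell count frequencies converge to the type mean
#' frequencies as the library grows), then zeroes genes by Bernoulli
#' dropout with probability `exp(-dropout_shape * rel_expr)` - high for
#' lowly expressed genes, vanishing for highly expressed ones. Mixture
#' pairs produce transitional cells sampled from the convex combination of
#' two parent means. Together the shallow libraries and dropout reproduce
#' the library-size and zero-composition gap between single-cell and bulk
#' data.
#'
#' @param cfg a [sim_config()].
#' @param atlas_means genes x types mean matrix from [simulate_atlas()]
#'   (defaults to regenerating it from `cfg`).
#' @return List with `expr` (genes x cells `expr_mat`, unit count),
#'   `truth` (data.frame: `cell`, `type` - mixtures labelled
#'   `"a|b|alpha"` -, `parent_a`, `parent_b`, `alpha`) and `sparsity`
#'   (overall zero fraction).
#' @export
simulate_query <- function(cfg, atlas_means = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  means <- if (is.null(atlas_means)) sim_type_means(cfg) else atlas_means
  groups <- lapply(colnames(means), function(ty) {
    list(name = ty, mu = means[, ty], parent_a = ty, parent_b = NA,
         alpha = NA_real_)
  })
  for (mx in cfg$mixture_pairs) {
    mu <- mx$alpha * means[, mx$a] + (1 - mx$alpha) * means[, mx$b]
    groups <- c(groups, list(list(
      name = paste(mx$a, mx$b, mx$alpha, sep = "|"),
      mu = mu, parent_a = mx$a, parent_b = mx$b, alpha = mx$alpha)))
  }
  n_cells <- cfg$cells_per_type * length(groups)
  with_seed(cfg$seed + 2L, {
    expr <- matrix(0L, cfg$genes, n_cells)
    truth <- data.frame(cell = paste0("c", seq_len(n_cells)),
                        type = character(n_cells),
                        parent_a = character(n_cells),
                        parent_b = NA_character_,
                        alpha = NA_real_, stringsAsFactors = FALSE)
    col <- 0L
    for (gr in groups) {
      p <- gr$mu / sum(gr$mu)
      rel <- gr$mu / mean(gr$mu)
      p_drop <- if (cfg$dropout_shape > 0) {
        exp(-cfg$dropout_shape * rel)
      } else {
        rep(0, cfg$genes)
      }
      for (i in seq_len(cfg$cells_per_type)) {
        col <- col + 1L
        counts <- stats::rmultinom(1L, cfg$library_size, p)[, 1L]
        if (cfg$dropout_shape > 0) {
          counts <- counts * stats::rbinom(cfg$genes, 1L, 1 - p_drop)
        }
        expr[, col] <- counts
        truth$type[col] <- gr$name
        truth$parent_a[col] <- gr$parent_a
        truth$parent_b[col] <- gr$parent_b
        truth$alpha[col] <- gr$alpha
      }
    }
    dimnames(expr) <- list(rownames(means), truth$cell)
    list(expr = expr_matrix(expr, unit = "count"),
         truth = truth,
         sparsity = mean(expr == 0))
  })
}
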