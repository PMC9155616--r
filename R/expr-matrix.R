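#' Expression matrix container
#'
#' A light wrapper around a numeric genes x observations matrix that carries
#' the measurement unit of its values. Rows are genes, columns are
#' observations (bulk samples, single cells or pseudo-bulk samples). All
#' values must be non-negative and row/column names must be unique.
#'
#' @param values numeric matrix, genes in rows, observations in columns.
#'   Must be non-negative and carry unique `rownames`/`colnames` (defaults
#'   `g1..gG` / `obs1..obsN` are filled in when missing).
#' @param unit measurement unit of `values`: one of `"count"`, `"cpm"`,
#'   `"tpm"`, `"rank"`, `"unknown"`.
#' @return A numeric matrix of class `expr_mat` with a `unit` attribute.
#' @examples
#' m <- expr_matrix(matrix(rpois(12, 5), 3, 4), unit = "count")
#' expr_unit(m)
#' @export
expr_matrix <- function(values,
                        unit = c("unknown", "count", "cpm", "tpm", "rank")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (length(values) == 0L) {
    stop("expression matrix is empty")
  }
  if (!is.numeric(values)) {
    stop("expression values must be numeric")
  }
  if (anyNA(values)) {
    stop("expression values contain NA")
  }
  if (min(values) < 0) {
    stop("expression values must be non-negative")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("obs", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    stop("gene identifiers (rownames) must be unique")
  }
  if (anyDuplicated(colnames(values))) {
    stop("observation identifiers (colnames) must be unique")
  }
  structure(values, unit = unit, class = c("expr_mat", class(values)))
}

#' @rdname expr_matrix
#' @param x an `expr_mat` or plain matrix.
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) "unknown" else u
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d observations, unit = %s\n",
              nrow(x), ncol(x), expr_unit(x)))
  invisible(x)
}

# Coerce input to a validated expr_mat, preserving an existing unit attribute.
as_expr <- function(x, unit = NULL) {
  if (inherits(x, "expr_mat") && is.null(unit)) {
    return(x)
  }
  expr_matrix(unclass(as.matrix(x)),
              unit = if (is.null(unit)) expr_unit(x) else unit)
}

#' Library-size normalization to counts per million
#'
#' Scales every observation (column) to a common library size. Used before
#' graph construction and imputation so that cell-to-cell distances are not
#' dominated by sequencing depth.
#'
#' @param x genes x observations matrix of additive values (counts, TPM,
#'   CPM).
#' @param scale target column sum (default `1e6`, i.e. CPM).
#' @return An `expr_mat` with unit `"cpm"`.
#' @export
normalize_library <- function(x, scale = 1e6) {
  x <- as_expr(x)
  cs <- colSums(x)
  if (any(cs == 0)) {
    stop("cannot library-normalize observations with zero total: ",
         paste(colnames(x)[cs == 0], collapse = ", "))
  }
  expr_matrix(sweep(unclass(x), 2L, cs / scale, "/"), unit = "cpm")
}

# Run code with a temporary RNG state seeded from `seed`; restores the
# caller's RNG afterwards so package functions do not disturb user RNG flow.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic 31-bit hash of a string, for per-cluster seed substreams.
str_seed <- function(s) {
  h <- 0
  for (v in utf8ToInt(as.character(s))) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}
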