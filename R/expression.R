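#' Construct a validated expression matrix
#'
#' Expression data throughout the package is a plain numeric matrix with genes
#' as rows and observations (spatial spots or single cells) as columns, carrying
#' unique row and column names. This constructor validates those invariants and
#' records whether the observations are spots or cells.
#'
#' @param values numeric matrix, genes x observations.
#' @param gene_ids optional character vector of gene identifiers; defaults to
#'   `rownames(values)`.
#' @param obs_ids optional character vector of observation identifiers; defaults
#'   to `colnames(values)`.
#' @param obs_kind `"spot"` or `"cell"`; stored as the `obs_kind` attribute.
#' @return the validated matrix with dimnames set and an `obs_kind` attribute.
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("c1", "c2", "c3"))), obs_kind = "cell")
#' attr(m, "obs_kind")
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              obs_ids = colnames(values),
                              obs_kind = c("cell", "spot")) {
  obs_kind <- match.arg(obs_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (genes x observations)")
  }
  if (is.null(gene_ids) || is.null(obs_ids)) {
    stop("gene and observation identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  obs_ids <- as.character(obs_ids)
  if (length(gene_ids) != nrow(values) || length(obs_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(obs_ids)) {
    stop("duplicate observation ids: ", paste(unique(obs_ids[duplicated(obs_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) stop("expression values must all be finite")
  dimnames(values) <- list(gene_ids, obs_ids)
  attr(values, "obs_kind") <- obs_kind
  values
}

#' Harmonize a reference and a query expression matrix
#'
#' Restricts both matrices to their shared genes (in a common order), optionally
#' normalises each observation to a total of 1e4 followed by log1p, and
#' optionally restricts to the most variable genes computed on the concatenated
#' normalised data. This is the preprocessing step ahead of [tca()].
#'
#' @param ref,query genes x observations numeric matrices with dimnames
#'   (see [expression_matrix()]).
#' @param normalize logical; total-count scale each observation to 1e4 then
#'   log1p. Default `TRUE`.
#' @param hvg_n number of highly-variable genes to keep (variance ranking on
#'   the concatenated, normalised data); `0` keeps all genes. Clamped to the
#'   shared gene count. Default `2000`.
#' @return list with elements `ref` and `query`, gene rows identical and
#'   identically ordered.
#' @export
harmonize <- function(ref, query, normalize = TRUE, hvg_n = 2000) {
  stopifnot(is.matrix(ref), is.matrix(query))
  if (ncol(ref) == 0L || ncol(query) == 0L) stop("empty expression matrix")
  shared <- intersect(rownames(ref), rownames(query))
  if (length(shared) == 0L) stop("no shared genes")
  ref <- ref[shared, , drop = FALSE]
  query <- query[shared, , drop = FALSE]
  if (normalize) {
    ref <- normalize_counts(ref)
    query <- normalize_counts(query)
  }
  if (hvg_n > 0 && hvg_n < length(shared)) {
    v <- apply(cbind(ref, query), 1L, stats::var)
    keep <- names(sort(v, decreasing = TRUE))[seq_len(hvg_n)]
    keep <- shared[shared %in% keep]  # preserve shared-gene order
    ref <- ref[keep, , drop = FALSE]
    query <- query[keep, , drop = FALSE]
  }
  list(ref = ref, query = query)
}

# total-count 1e4 scaling followed by log1p, per observation (column)
normalize_counts <- function(x) {
  tot <- colSums(x)
  if (any(tot == 0)) {
    stop("observation with zero total count: ",
         paste(colnames(x)[tot == 0], collapse = ", "))
  }
  log1p(sweep(x, 2L, tot / 1e4, "/"))
}
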