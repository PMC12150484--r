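#' Anchor query cells into a reference 2-D embedding
#'
#' Correlation-kNN median anchoring: each query cell is correlated (Pearson)
#' with every reference cell over the reference's variable genes, its `k`
#' best-correlated reference cells are found (ties at rank `k` resolved by
#' reference cell order, deterministically), and its initial position is the
#' coordinate-wise median of those neighbours' embedding coordinates.
#'
#' @param ref_embedding reference cells x 2 coordinate matrix with cell ids as
#'   rownames.
#' @param ref_expr,query_expr genes x cells expression matrices.
#' @param variable_genes gene ids (chosen from the reference stage) over which
#'   correlations are computed; must be present in both matrices.
#' @param k number of nearest neighbours, between 1 and the reference size.
#'   Default 10.
#' @return query cells x 2 matrix of initial coordinates.
#' @export
anchor_positions <- function(ref_embedding, ref_expr, query_expr, variable_genes, k = 10) {
  if (k < 1 || k > ncol(ref_expr)) stop("k must lie in [1, reference size]")
  miss <- setdiff(variable_genes, intersect(rownames(ref_expr), rownames(query_expr)))
  if (length(miss)) {
    stop("variable gene(s) absent: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  ref_embedding <- as.matrix(ref_embedding)
  if (!identical(sort(rownames(ref_embedding)), sort(colnames(ref_expr)))) {
    stop("ref_embedding rows must cover exactly the reference cells")
  }
  r <- ref_expr[variable_genes, , drop = FALSE]
  q <- query_expr[variable_genes, , drop = FALSE]
  qsd <- apply(q, 2L, stats::sd)
  if (any(qsd == 0)) {
    stop("zero-variance query cell(s) over the variable genes: ",
         paste(utils::head(colnames(q)[qsd == 0], 5), collapse = ", "))
  }
  cc <- suppressWarnings(stats::cor(r, q))  # ref cells x query cells
  coords <- t(vapply(seq_len(ncol(q)), function(j) {
    ord <- order(-cc[, j], seq_len(nrow(cc)))
    nb <- colnames(r)[ord[seq_len(k)]]
    apply(ref_embedding[nb, , drop = FALSE], 2L, stats::median)
  }, numeric(2)))
  rownames(coords) <- colnames(q)
  colnames(coords) <- c("x", "y")
  coords
}

#' Identity embedding backend
#'
#' Returns the initial coordinates unchanged; useful for testing the anchoring
#' scheme in isolation and as the exactness baseline of the backend contract.
#'
#' @param pcs cells x components matrix (ignored).
#' @param init cells x 2 initial coordinates.
#' @param seed integer seed (ignored).
#' @param ... embedding parameters (ignored).
#' @return `init`, unchanged.
#' @export
embed_backend_identity <- function(pcs, init, seed, ...) init

#' PCA embedding backend
#'
#' Lays cells out on the first two principal components of the supplied
#' scores, ignoring any initialisation; deterministic. Serves as the default
#' stage-one layout when no t-SNE optimiser backend is plugged in.
#'
#' @inheritParams embed_backend_identity
#' @return cells x 2 coordinate matrix.
#' @export
embed_backend_pca <- function(pcs, init, seed, ...) {
  out <- pcs[, 1:2, drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Serial anchored embedding across ordered stages
#'
#' Builds a time-resolved 2-D map: the first stage is embedded from a PCA
#' initialisation of its principal-component scores; every later stage is
#' initialised by [anchor_positions()] against the preceding stage's embedding
#' and then refined by the backend. The backend is pluggable — any function
#' `(pcs, init, seed, ...)` returning refined 2-D coordinates deterministically
#' for a fixed seed satisfies the contract (a t-SNE optimiser honouring
#' exaggeration 4 and the cosine metric is the intended production backend;
#' with [embed_backend_identity()] the output equals the anchored
#' initialisation exactly).
#'
#' @param stages ordered list of stages, each a list with `expr` (genes x
#'   cells), `variable_genes` (chosen from that stage, used when it serves as
#'   reference) and `pcs` (cells x components principal-component scores,
#'   typically 20 components).
#' @param backend embedding backend function. Default
#'   [embed_backend_identity()].
#' @param k anchoring neighbourhood size. Default 10.
#' @param seed integer seed forwarded to the backend.
#' @param exaggeration,metric embedding parameters recorded and forwarded to
#'   the backend. Defaults 4 and `"cosine"`.
#' @return list of per-stage results, each with `coords` (cells x 2) and
#'   `params` (exaggeration, metric, init_mode).
#' @export
serial_embed <- function(stages, backend = embed_backend_identity, k = 10,
                         seed = 1L, exaggeration = 4, metric = "cosine") {
  if (!length(stages)) stop("need at least one stage")
  out <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    init_mode <- if (i == 1L) "pca" else "anchored"
    init <- if (i == 1L) {
      ini <- st$pcs[, 1:2, drop = FALSE]
      colnames(ini) <- c("x", "y")
      ini
    } else {
      prev <- stages[[i - 1L]]
      anchor_positions(out[[i - 1L]]$coords, prev$expr, st$expr,
                       prev$variable_genes, k = k)
    }
    coords <- tryCatch(
      backend(st$pcs, init, seed, exaggeration = exaggeration, metric = metric),
      error = function(e) stop("embedding backend failed at stage ", i, ": ",
                               conditionMessage(e))
    )
    if (!all(is.finite(coords)) || nrow(coords) != ncol(st$expr)) {
      stop("backend returned invalid coordinates at stage ", i)
    }
    rownames(coords) <- colnames(st$expr)
    out[[i]] <- list(coords = coords,
                     params = list(exaggeration = exaggeration, metric = metric,
                                   init_mode = init_mode))
  }
  names(out) <- names(stages)
  out
}
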