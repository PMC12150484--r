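#' Configuration for a synthetic single-cell spatial tissue
#'
#' Validates and completes the parameters of the tissue generator. Cells are
#' scattered uniformly over a rectangle partitioned into spatial domains
#' (vertical stripes or a rectangular block grid); each domain has its own
#' cell-type mixture; counts follow a negative-binomial model with per-type
#' marker genes and log-normal library-size variation.
#'
#' @param width,height tissue extent in coordinate units. Defaults 1000 x 1000.
#' @param n_domains number of spatial domains. Default 4.
#' @param domain_layout `"stripes"` (equal-width vertical bands) or `"blocks"`
#'   (an equal rectangular grid; `n_domains` must factor into a near-square
#'   grid). Default `"stripes"`.
#' @param n_types number of cell types. Default 6.
#' @param type_mixtures optional `n_domains` x `n_types` matrix of per-domain
#'   type probabilities (rows sum to 1). By default each domain is dominated
#'   (80%) by one type, cycling through the types, with the remainder spread
#'   evenly — giving every domain a distinct dominant type when
#'   `n_types >= n_domains`.
#' @param n_cells total cells. Default 2000.
#' @param n_genes total genes. Default 200.
#' @param markers_per_type genes elevated in each type's marker block;
#'   `markers_per_type * n_types` may not exceed `n_genes`. Default: 10, or
#'   `n_genes %/% n_types` when the gene budget is smaller.
#' @param marker_fold mean fold-elevation of a type's markers (> 1). Default 5.
#' @param base_mean baseline negative-binomial mean per gene. Default 2.
#' @param dispersion negative-binomial size parameter theta
#'   (`var = mu + mu^2 / theta`); larger values approach Poisson. Default 2.
#' @param libsize_sigma sdlog of the log-normal per-cell library-size factor
#'   (mean 1); 0 disables depth variation. Default 0.3.
#' @param seed integer seed; every draw of the generator is governed by it.
#' @return a validated list of class `"tissue_config"`.
#' @export
tissue_config <- function(width = 1000, height = 1000, n_domains = 4,
                          domain_layout = c("stripes", "blocks"), n_types = 6,
                          type_mixtures = NULL, n_cells = 2000, n_genes = 200,
                          markers_per_type = NULL, marker_fold = 5, base_mean = 2,
                          dispersion = 2, libsize_sigma = 0.3, seed = 1L) {
  domain_layout <- match.arg(domain_layout)
  if (is.null(markers_per_type)) markers_per_type <- min(10, n_genes %/% n_types)
  stopifnot(width > 0, height > 0, n_domains >= 1, n_types >= 1, n_cells >= 1,
            n_genes >= 1, markers_per_type >= 0, marker_fold > 1,
            base_mean > 0, dispersion > 0, libsize_sigma >= 0)
  if (markers_per_type * n_types > n_genes) {
    stop("markers_per_type * n_types exceeds n_genes")
  }
  if (is.null(type_mixtures)) {
    type_mixtures <- matrix(0.2 / max(n_types - 1, 1), n_domains, n_types)
    for (dm in seq_len(n_domains)) {
      dominant <- (dm - 1L) %% n_types + 1L
      type_mixtures[dm, dominant] <- if (n_types == 1) 1 else 0.8
    }
  }
  type_mixtures <- as.matrix(type_mixtures)
  if (!all(dim(type_mixtures) == c(n_domains, n_types))) {
    stop("type_mixtures must be n_domains x n_types")
  }
  if (any(type_mixtures < 0) || any(abs(rowSums(type_mixtures) - 1) > 1e-8)) {
    stop("each domain's type mixture must be a probability vector")
  }
  if (domain_layout == "blocks") {
    bf <- block_factors(n_domains)
    if (is.null(bf)) stop("n_domains has no rectangular factorisation for block layout")
  }
  structure(list(width = width, height = height, n_domains = n_domains,
                 domain_layout = domain_layout, n_types = n_types,
                 type_mixtures = type_mixtures, n_cells = n_cells,
                 n_genes = n_genes, markers_per_type = markers_per_type,
                 marker_fold = marker_fold, base_mean = base_mean,
                 dispersion = dispersion, libsize_sigma = libsize_sigma,
                 seed = as.integer(seed)),
            class = "tissue_config")
}

# most-square factor pair (rows, cols) of n, rows <= cols
block_factors <- function(n) {
  for (r in floor(sqrt(n)):1) {
    if (n %% r == 0) return(c(r, n %/% r))
  }
  NULL
}

#' Generate a synthetic single-cell spatial tissue
#'
#' Draws a seeded tissue realisation under a [tissue_config()]: uniform cell
#' positions, geometric domain labels, per-domain cell-type draws, and
#' negative-binomial counts with mean `s_c * mu[type, gene]` where each type's
#' marker block is elevated by `marker_fold` over `base_mean` and `s_c` is a
#' log-normal library-size factor with unit mean. Identical seeds give
#' bit-identical tissues; the global RNG state is never touched.
#'
#' @param config a [tissue_config()].
#' @return list of class `"synthetic_tissue"` with `expr` (genes x cells
#'   integer counts), `coords` (cells x 2 with rownames), `type_label` and
#'   `domain_label` (named vectors) and the `config`.
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "tissue_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    cell_ids <- sprintf("cell%0*d", nchar(cfg$n_cells), seq_len(cfg$n_cells))
    x <- stats::runif(cfg$n_cells, 0, cfg$width)
    y <- stats::runif(cfg$n_cells, 0, cfg$height)
    domain <- domain_of(x, y, cfg)
    type <- vapply(domain, function(dm) {
      sample.int(cfg$n_types, 1L, prob = cfg$type_mixtures[dm, ])
    }, integer(1))
    mu <- matrix(cfg$base_mean, cfg$n_types, cfg$n_genes)
    if (cfg$markers_per_type > 0) {
      for (tp in seq_len(cfg$n_types)) {
        block <- (tp - 1L) * cfg$markers_per_type + seq_len(cfg$markers_per_type)
        mu[tp, block] <- cfg$base_mean * cfg$marker_fold
      }
    }
    s <- if (cfg$libsize_sigma > 0) {
      stats::rlnorm(cfg$n_cells, meanlog = -cfg$libsize_sigma^2 / 2,
                    sdlog = cfg$libsize_sigma)
    } else rep(1, cfg$n_cells)
    counts <- vapply(seq_len(cfg$n_cells), function(i) {
      stats::rnbinom(cfg$n_genes, size = cfg$dispersion, mu = s[i] * mu[type[i], ])
    }, numeric(cfg$n_genes))
    dimnames(counts) <- list(sprintf("gene%0*d", nchar(cfg$n_genes), seq_len(cfg$n_genes)),
                             cell_ids)
    coords <- cbind(x = x, y = y)
    rownames(coords) <- cell_ids
    structure(list(
      expr = counts,
      coords = coords,
      type_label = stats::setNames(sprintf("type%d", type), cell_ids),
      domain_label = stats::setNames(sprintf("domain%d", domain), cell_ids),
      config = cfg
    ), class = "synthetic_tissue")
  })
}

# geometric domain index for each (x, y)
domain_of <- function(x, y, cfg) {
  if (cfg$domain_layout == "stripes") {
    pmin(floor(x / (cfg$width / cfg$n_domains)), cfg$n_domains - 1L) + 1L
  } else {
    bf <- block_factors(cfg$n_domains)
    r <- pmin(floor(y / (cfg$height / bf[1])), bf[1] - 1L)
    cl <- pmin(floor(x / (cfg$width / bf[2])), bf[2] - 1L)
    as.integer(r * bf[2] + cl + 1L)
  }
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic tissue: %d cells, %d genes, %d %s domain(s), %d type(s), seed %d\n",
              cfg$n_cells, cfg$n_genes, cfg$n_domains, cfg$domain_layout,
              cfg$n_types, cfg$seed))
  invisible(x)
}

#' Derive a benchmark reference/query pair from a tissue
#'
#' Grids the tissue into pseudo-bulk spots with dominant-type ground truth
#' (the reference role) and draws a seeded subsample of the single cells (the
#' query role), so the full alignment-and-mapping pipeline can be scored
#' against known labels.
#'
#' @param tissue a [generate_tissue()] result.
#' @param grid_size,min_cells passed to [gridify()].
#' @param query_fraction fraction of cells sampled as the query, in `(0, 1]`.
#'   Default 1 (all cells).
#' @param seed integer seed for the query subsample.
#' @return list with `reference` (a `"pseudo_spots"` object), `query` (genes x
#'   cells counts) and `query_types` (named vector).
#' @export
make_benchmark_pair <- function(tissue, grid_size = 100, min_cells = 1,
                                query_fraction = 1, seed = 1L) {
  stopifnot(inherits(tissue, "synthetic_tissue"))
  if (query_fraction <= 0 || query_fraction > 1) {
    stop("query_fraction must lie in (0, 1]")
  }
  reference <- gridify(tissue$coords, tissue$type_label, tissue$expr,
                       grid_size = grid_size, min_cells = min_cells)
  n_query <- max(1L, round(query_fraction * ncol(tissue$expr)))
  query <- downsample(tissue$expr, n_query, seed = seed)
  if (ncol(query) == 0L) stop("empty query")
  list(reference = reference, query = query,
       query_types = tissue$type_label[colnames(query)])
}
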