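#' Aggregate per-cell activity scores onto spatial spots
#'
#' Projects any per-cell score matrix (typically SCENIC regulon activity, one
#' AUC value per cell and regulon) onto the reference spots through a cell-spot
#' mapping: the activity of a score at a spot is the arithmetic mean over the
#' assigned cells that landed there. Spots with no contributing cells carry
#' missing values, never zeros.
#'
#' @param scores cells x scores numeric matrix with cell ids as rownames.
#' @param mapping a mapping table from [map_cells()].
#' @param spots optional spot id vector fixing the row set and order.
#' @return list with `values` (spots x scores mean activity) and `coverage`
#'   (named integer vector of contributing-cell counts per spot).
#' @export
aggregate_scores <- function(scores, mapping, spots = NULL) {
  check_mapping(mapping)
  scores <- as.matrix(scores)
  asg <- mapping[mapping$assigned, , drop = FALSE]
  absent <- setdiff(asg$cell_id, rownames(scores))
  if (length(absent)) {
    stop("assigned cell(s) absent from the score matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  if (is.null(spots)) spots <- sort(unique(mapping$best_spot_id[!is.na(mapping$best_spot_id)]))
  values <- matrix(NA_real_, length(spots), ncol(scores),
                   dimnames = list(spots, colnames(scores)))
  coverage <- stats::setNames(integer(length(spots)), spots)
  by_spot <- split(asg$cell_id, factor(asg$best_spot_id, levels = spots))
  for (s in spots) {
    m <- by_spot[[s]]
    coverage[s] <- length(m)
    if (length(m)) values[s, ] <- colMeans(scores[m, , drop = FALSE])
  }
  list(values = values, coverage = coverage)
}

#' Jensen-Shannon regulon specificity score
#'
#' For each score (regulon) and spot, `RSS = 1 - sqrt(JSD(p, e_s))`, where `p`
#' is the regulon's spatial activity normalised to sum 1 over spots, `e_s` the
#' indicator distribution of spot `s`, and JSD the Jensen-Shannon divergence
#' with base-2 logarithms. RSS lies in `[0, 1]` and equals 1 exactly when the
#' regulon is active in that spot alone; it is invariant to positive rescaling
#' of a regulon's activities. Spots without coverage (missing activity) are
#' excluded from the distribution and receive missing RSS.
#'
#' @param spot_scores a spots x scores matrix of mean activities, or the list
#'   returned by [aggregate_scores()]. Activities must be non-negative.
#' @return spots x scores matrix of specificity scores; an all-zero regulon
#'   yields a missing column with a warning.
#' @export
regulon_specificity <- function(spot_scores) {
  values <- if (is.list(spot_scores) && !is.data.frame(spot_scores)) spot_scores$values else as.matrix(spot_scores)
  rss <- matrix(NA_real_, nrow(values), ncol(values), dimnames = dimnames(values))
  for (j in seq_len(ncol(values))) {
    act <- values[, j]
    ok <- !is.na(act)
    if (any(act[ok] < 0)) stop("activities must be non-negative for specificity scoring")
    tot <- sum(act[ok])
    if (tot <= 0) {
      warning("all-zero activity for score '", colnames(values)[j], "'; RSS undefined")
      next
    }
    p <- act[ok] / tot
    idx <- which(ok)
    for (i in seq_along(idx)) {
      e <- numeric(length(p))
      e[i] <- 1
      rss[idx[i], j] <- 1 - sqrt(js_divergence(p, e))
    }
  }
  rss
}

# Jensen-Shannon divergence, log base 2; bounded in [0, 1]
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  max((kl(p, m) + kl(q, m)) / 2, 0)
}

#' Top-scoring names per spot
#'
#' Ranks scores within each spot by specificity and returns the `k` best,
#' descending, ties broken lexicographically by score name.
#'
#' @param rss spots x scores matrix from [regulon_specificity()].
#' @param k how many names per spot. Default 5.
#' @return named list, spot id -> ordered character vector of score names.
#' @export
top_scores_per_spot <- function(rss, k = 5) {
  nm <- colnames(rss)
  out <- lapply(seq_len(nrow(rss)), function(i) {
    v <- rss[i, ]
    ok <- !is.na(v)
    ord <- order(-v[ok], nm[ok])
    utils::head(nm[ok][ord], k)
  })
  stats::setNames(out, rownames(rss))
}
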