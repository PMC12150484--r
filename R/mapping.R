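#' Latent-space correlation between every spot and every cell
#'
#' Pearson correlation of each reference spot's transfer-component profile with
#' each query cell's, across the `d` latent coordinates. This is the mapping
#' correlation used for assignment, distinct from the expression-space
#' evaluation correlation of [expression_pcc()].
#'
#' @param model a fitted `"tca"` model with `d >= 3`.
#' @return spots x cells matrix of correlations in `[-1, 1]`; rows or columns
#'   with zero variance across components give `NA`, never a number.
#' @export
latent_pcc_matrix <- function(model) {
  stopifnot(inherits(model, "tca"))
  if (model$config$d < 3) stop("latent correlation needs d >= 3")
  p <- suppressWarnings(stats::cor(t(model$TC_R), t(model$TC_Q)))
  dimnames(p) <- list(rownames(model$TC_R), rownames(model$TC_Q))
  p
}

#' Assign each query cell to its best-matching spot
#'
#' For every cell, the spot with the highest latent-space Pearson correlation
#' is its spatial match; pairs whose correlation falls below `pcc_threshold`
#' are retained in the table but flagged unassigned, acting as a quality
#' filter against spurious matches. Ties go to the lexicographically smallest
#' spot id. Cells whose correlation is undefined against every spot get a
#' missing correlation and are unassigned.
#'
#' @param model a fitted `"tca"` model.
#' @param pcc_threshold minimum correlation for a mapping to count, in
#'   `[-1, 1]`. Default 0.7.
#' @return a data.frame with columns `cell_id`, `best_spot_id`, `pcc`,
#'   `assigned`, one row per query cell in query order.
#' @export
map_cells <- function(model, pcc_threshold = 0.7) {
  if (!is.numeric(pcc_threshold) || pcc_threshold < -1 || pcc_threshold > 1) {
    stop("pcc_threshold must lie in [-1, 1]")
  }
  p <- latent_pcc_matrix(model)
  spot_ids <- rownames(p)
  res <- lapply(seq_len(ncol(p)), function(j) {
    col <- p[, j]
    if (all(is.na(col))) {
      return(list(best = NA_character_, pcc = NA_real_))
    }
    m <- max(col, na.rm = TRUE)
    cand <- spot_ids[!is.na(col) & col == m]
    list(best = min(cand), pcc = m)
  })
  pcc <- vapply(res, `[[`, numeric(1), "pcc")
  data.frame(
    cell_id = colnames(p),
    best_spot_id = vapply(res, `[[`, character(1), "best"),
    pcc = pcc,
    assigned = !is.na(pcc) & pcc >= pcc_threshold,
    stringsAsFactors = FALSE
  )
}

# shared validation: mapping table with required columns
check_mapping <- function(mapping) {
  need <- c("cell_id", "best_spot_id", "pcc", "assigned")
  if (!is.data.frame(mapping) || !all(need %in% names(mapping))) {
    stop("mapping must be a data.frame with columns ", paste(need, collapse = ", "))
  }
  mapping
}

# labels for the assigned cells of a mapping, with per-cell error reporting
assigned_labels <- function(mapping, cell_types) {
  asg <- mapping[mapping$assigned, , drop = FALSE]
  lab <- cell_types[asg$cell_id]
  bad <- asg$cell_id[is.na(lab)]
  if (length(bad)) {
    stop("assigned cell(s) missing a type label: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  data.frame(cell_id = asg$cell_id, spot = asg$best_spot_id, type = unname(lab),
             pcc = asg$pcc, stringsAsFactors = FALSE)
}

#' Cell-type composition of each spot
#'
#' Deconvolution summary: for each reference spot, the fraction of its
#' assigned cells belonging to each cell type, optionally weighted by the
#' mapping correlation. Unassigned cells are excluded; spots with no assigned
#' cells report an all-zero row rather than renormalised noise.
#'
#' @param mapping a mapping table from [map_cells()].
#' @param cell_types named character vector, cell id -> type label.
#' @param spots optional character vector of spot ids fixing the row set and
#'   order; defaults to the spots appearing in the mapping.
#' @param weight_by_pcc weight each cell's contribution by its mapping
#'   correlation instead of counting it once. Default `FALSE`.
#' @return spots x types matrix of fractions; populated rows sum to 1.
#' @export
spot_composition <- function(mapping, cell_types, spots = NULL, weight_by_pcc = FALSE) {
  check_mapping(mapping)
  al <- assigned_labels(mapping, cell_types)
  if (is.null(spots)) spots <- sort(unique(mapping$best_spot_id[!is.na(mapping$best_spot_id)]))
  types <- sort(unique(unname(cell_types)))
  comp <- matrix(0, length(spots), length(types), dimnames = list(spots, types))
  if (nrow(al)) {
    w <- if (weight_by_pcc) al$pcc else rep(1, nrow(al))
    tab <- tapply(w, list(factor(al$spot, levels = spots), factor(al$type, levels = types)),
                  sum, default = 0)
    comp[rownames(tab), colnames(tab)] <- tab
    rs <- rowSums(comp)
    pos <- rs > 0
    comp[pos, ] <- comp[pos, , drop = FALSE] / rs[pos]
  }
  comp
}

#' Dominant cell type per spot
#'
#' @param composition spots x types fraction matrix from [spot_composition()].
#' @return named character vector spot -> winning type label; ties go to the
#'   lexicographically smallest label and all-zero rows give `"unassigned"`.
#' @export
dominant_type <- function(composition) {
  types <- colnames(composition)
  out <- apply(composition, 1L, function(row) {
    if (all(row == 0)) return("unassigned")
    min(types[row == max(row)])
  })
  stats::setNames(as.character(out), rownames(composition))
}

#' Spatial distribution of each cell type
#'
#' The transpose view of deconvolution: for each cell type, the fraction of
#' its assigned cells landing on each spot.
#'
#' @inheritParams spot_composition
#' @return types x spots matrix; populated rows sum to 1, types with no
#'   assigned cells give zero rows.
#' @export
celltype_location_fractions <- function(mapping, cell_types, spots = NULL) {
  check_mapping(mapping)
  al <- assigned_labels(mapping, cell_types)
  if (is.null(spots)) spots <- sort(unique(mapping$best_spot_id[!is.na(mapping$best_spot_id)]))
  types <- sort(unique(unname(cell_types)))
  loc <- matrix(0, length(types), length(spots), dimnames = list(types, spots))
  if (nrow(al)) {
    tab <- table(factor(al$type, levels = types), factor(al$spot, levels = spots))
    loc[] <- as.numeric(tab)
    rs <- rowSums(loc)
    pos <- rs > 0
    loc[pos, ] <- loc[pos, , drop = FALSE] / rs[pos]
  }
  loc
}

#' Expression-space correlation of matched cell-spot pairs
#'
#' Evaluation correlation: for every assigned cell, the Pearson correlation
#' between its expression vector and its matched spot's expression vector over
#' the shared (harmonized) genes. Used to score mapping quality; distinct from
#' the latent-space correlation that produced the assignment.
#'
#' @param ref,query harmonized genes x observations matrices with identical
#'   gene order (e.g. from [harmonize()], or the `ref`/`query` components of a
#'   fitted `"tca"` model).
#' @param mapping a mapping table from [map_cells()].
#' @return named numeric vector over assigned cells; a zero-variance vector
#'   yields `NA` with a warning.
#' @export
expression_pcc <- function(ref, query, mapping) {
  check_mapping(mapping)
  if (!identical(rownames(ref), rownames(query))) {
    stop("ref and query must share an identical gene order; run harmonize() first")
  }
  asg <- mapping[mapping$assigned, , drop = FALSE]
  out <- vapply(seq_len(nrow(asg)), function(i) {
    cellv <- query[, asg$cell_id[i]]
    spotv <- ref[, asg$best_spot_id[i]]
    if (stats::sd(cellv) == 0 || stats::sd(spotv) == 0) {
      warning("zero-variance expression vector for pair (",
              asg$cell_id[i], ", ", asg$best_spot_id[i], ")")
      return(NA_real_)
    }
    stats::cor(cellv, spotv)
  }, numeric(1))
  stats::setNames(out, asg$cell_id)
}
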