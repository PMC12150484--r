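#' Read an expression matrix
#'
#' Reads genes x observations expression data from Matrix-Market triplets
#' (with companion gene/barcode text files, 1-based indices honoured) or dense
#' TSV/CSV with ids in the first column and a header of observation ids.
#' Gzipped files are read transparently. Matrices stored observations-first
#' are transposed via `genes_as_rows = FALSE`.
#'
#' @param path file path (`.mtx[.gz]`, `.tsv[.gz]`, `.csv[.gz]`).
#' @param format `"auto"` (by extension), `"mtx"`, `"tsv"` or `"csv"`.
#' @param genes_path,obs_path for MTX input: row (gene) and column
#'   (observation) id files, one id per line; default `<prefix>.genes.txt` and
#'   `<prefix>.obs.txt` beside the matrix.
#' @param genes_as_rows whether the stored matrix has genes as rows. Default
#'   `TRUE`.
#' @param obs_kind `"cell"` or `"spot"`, recorded on the result.
#' @return a validated dense matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path, format = c("auto", "mtx", "tsv", "csv"),
                            genes_path = NULL, obs_path = NULL,
                            genes_as_rows = TRUE, obs_kind = "cell") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- switch(tolower(tools::file_ext(base)),
                     mtx = "mtx", tsv = "tsv", txt = "tsv", csv = "csv",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    prefix <- sub("\\.mtx(\\.gz)?$", "", path)
    if (is.null(genes_path)) genes_path <- paste0(prefix, ".genes.txt")
    if (is.null(obs_path)) obs_path <- paste0(prefix, ".obs.txt")
    rn <- readLines(genes_path)
    cn <- readLines(obs_path)
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      stop("dimension mismatch between matrix (", nrow(m), " x ", ncol(m),
           ") and id files (", length(rn), ", ", length(cn), ")")
    }
    dimnames(m) <- list(rn, cn)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                            row.names = 1, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("malformed table: non-numeric expression values in ", path)
  }
  if (!genes_as_rows) m <- t(m)
  expression_matrix(m, obs_kind = if (identical(obs_kind, "spot")) "spot" else "cell")
}

#' Write an expression matrix
#'
#' Dense TSV/CSV (gene ids in the first column), or Matrix-Market with
#' companion `<prefix>.genes.txt` / `<prefix>.obs.txt` id files.
#'
#' @param m genes x observations matrix with dimnames.
#' @param path output path; format inferred from the extension
#'   (`.mtx` / `.tsv` / `.csv`, optionally `.gz` for the dense formats).
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  base <- sub("\\.gz$", "", path)
  fmt <- tolower(tools::file_ext(base))
  if (fmt == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    prefix <- sub("\\.mtx$", "", base)
    writeLines(rownames(m), paste0(prefix, ".genes.txt"))
    writeLines(colnames(m), paste0(prefix, ".obs.txt"))
  } else if (fmt %in% c("tsv", "csv", "txt")) {
    sep <- if (fmt == "csv") "," else "\t"
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("gene_id", colnames(m)), collapse = sep), con)
    utils::write.table(m, con, sep = sep, quote = FALSE, col.names = FALSE,
                       row.names = TRUE, append = TRUE)
  } else {
    stop("unsupported output format: ", fmt)
  }
  invisible(path)
}

#' Read observation coordinates
#'
#' TSV/CSV with columns `id`, `x`, `y` (header required); extra columns are
#' ignored with a message.
#'
#' @param path file path; comma or tab separation inferred from the extension.
#' @return matrix with columns `x`, `y` and ids as rownames.
#' @export
read_coordinates <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("coordinate file must have columns id, x, y (missing: ",
         paste(setdiff(need, names(df)), collapse = ", "), ")")
  }
  extra <- setdiff(names(df), need)
  if (length(extra)) message("ignoring extra coordinate column(s): ", paste(extra, collapse = ", "))
  if (anyDuplicated(df$id)) {
    stop("duplicated observation id(s): ", paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) {
      stop("non-numeric ", cc, " coordinate at row ", which(is.na(v))[1])
    }
    df[[cc]] <- v
  }
  out <- cbind(x = df$x, y = df$y)
  rownames(out) <- as.character(df$id)
  out
}

#' Read observation labels
#'
#' TSV/CSV with columns `id` and `label`.
#'
#' @param path file path.
#' @return named character vector, id -> label.
#' @export
read_labels <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df))) stop("label file must have columns id, label")
  if (anyDuplicated(df$id)) stop("duplicated id(s) in label file")
  stats::setNames(as.character(df$label), as.character(df$id))
}

#' Persist a fitted alignment as a directory of delimited tables
#'
#' Writes `A.tsv`, `eigenvalues.tsv`, `TC_R.tsv`, `TC_Q.tsv` and a JSON
#' snapshot of the configuration; [load_tca()] restores a model usable for
#' mapping.
#'
#' @param model a fitted `"tca"` model.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_tca <- function(model, dir) {
  stopifnot(inherits(model, "tca"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                                          file.path(dir, f), sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wr(model$A, "A.tsv")
  utils::write.table(data.frame(component = colnames(model$A), eigenvalue = model$eta),
                     file.path(dir, "eigenvalues.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wr(model$TC_R, "TC_R.tsv")
  wr(model$TC_Q, "TC_Q.tsv")
  snap <- c(model$config, list(n1 = model$n1, n2 = model$n2, gene_order = model$gene_order))
  jsonlite::write_json(snap, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Restore a fitted alignment saved by [save_tca()]
#'
#' The restored object carries the transformation, eigenvalues and latent rows
#' (sufficient for mapping and aggregation); the kernel and training matrices
#' are not persisted, so [predict.tca()] is only available for primal models.
#'
#' @param dir directory written by [save_tca()].
#' @return a `"tca"` model.
#' @export
load_tca <- function(dir) {
  rd <- function(f) {
    df <- utils::read.table(file.path(dir, f), header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  a <- rd("A.tsv")
  structure(list(
    A = a,
    eta = utils::read.table(file.path(dir, "eigenvalues.tsv"), header = TRUE,
                            sep = "\t")$eigenvalue,
    TC_R = rd("TC_R.tsv"), TC_Q = rd("TC_Q.tsv"),
    K = NULL, X = NULL,
    n1 = cfg$n1, n2 = cfg$n2, gene_order = cfg$gene_order,
    ref = NULL, query = NULL,
    config = cfg[c("kernel", "d", "lambda", "gamma", "normalize", "hvg_n")]
  ), class = "tca")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

matrix_as_df <- function(m, id_col) {
  data.frame(stats::setNames(list(rownames(m)), id_col), m, check.names = FALSE,
             row.names = NULL)
}

#' Run the full alignment-and-mapping pipeline
#'
#' Orchestrates harmonisation, TCA fitting, cell-to-spot mapping and the
#' requested downstream summaries, writing every artifact plus a
#' machine-readable run manifest under `out_dir`. Inputs may be given in
#' memory (matrices / named vectors) or as file paths, which are read with the
#' package readers. Identical configuration and seed produce byte-identical
#' outputs.
#'
#' @param config a list:
#'   \describe{
#'     \item{reference, query}{genes x observations matrices or file paths.}
#'     \item{cell_types}{optional named vector or label file path (enables
#'       composition / localisation outputs).}
#'     \item{spot_truth}{optional named vector or label file path of
#'       ground-truth spot labels (enables classification metrics).}
#'     \item{scores}{optional cells x scores matrix or dense table path
#'       (enables spatial score aggregation and specificity ranking).}
#'     \item{tca}{list of arguments for [tca()] (kernel, d, lambda, gamma,
#'       normalize, hvg_n).}
#'     \item{mapping}{list: pcc_threshold, weight_by_pcc.}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{integer seed recorded in the manifest.}
#'   }
#' @param quiet suppress per-stage log lines. Default `FALSE`.
#' @return list with the fitted model, mapping table, written file paths and
#'   the manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  t0 <- Sys.time()
  log_line <- function(...) if (!quiet) message("[tcamap] ", sprintf(...))
  stage <- function(name, f) {
    st <- Sys.time()
    out <- tryCatch(f(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_line("%-12s %.2fs", name, as.numeric(Sys.time() - st, units = "secs"))
    timings[[name]] <<- round(as.numeric(Sys.time() - st, units = "secs"), 3)
    out
  }
  timings <- list()

  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  is_path <- function(x) is.character(x) && length(x) == 1L && is.null(names(x))
  ref <- stage("read", function() {
    if (is_path(cfg$reference)) read_expression(cfg$reference, obs_kind = "spot") else cfg$reference
  })
  qry <- if (is_path(cfg$query)) read_expression(cfg$query) else cfg$query
  cell_types <- if (is_path(cfg$cell_types)) read_labels(cfg$cell_types) else cfg$cell_types
  spot_truth <- if (is_path(cfg$spot_truth)) read_labels(cfg$spot_truth) else cfg$spot_truth
  scores <- if (is_path(cfg$scores)) {
    sm <- read_expression(cfg$scores, genes_as_rows = FALSE)
    t(sm)
  } else cfg$scores

  model <- stage("fit", function() {
    do.call(tca, c(list(ref = ref, query = qry), cfg$tca))
  })
  mapping <- stage("map", function() {
    map_cells(model, pcc_threshold = cfg$mapping$pcc_threshold)
  })
  files["mapping"] <- write_tsv(mapping, file.path(cfg$out_dir, "mapping.tsv"))

  if (!is.null(cell_types)) {
    comp <- stage("deconvolve", function() {
      spot_composition(mapping, cell_types, spots = rownames(model$TC_R),
                       weight_by_pcc = cfg$mapping$weight_by_pcc)
    })
    files["composition"] <- write_tsv(matrix_as_df(comp, "spot_id"),
                                      file.path(cfg$out_dir, "composition.tsv"))
    dom <- dominant_type(comp)
    files["dominant"] <- write_tsv(data.frame(spot_id = names(dom), dominant_type = dom,
                                              row.names = NULL),
                                   file.path(cfg$out_dir, "dominant_type.tsv"))
    loc <- celltype_location_fractions(mapping, cell_types, spots = rownames(model$TC_R))
    files["location"] <- write_tsv(matrix_as_df(loc, "cell_type"),
                                   file.path(cfg$out_dir, "location_fractions.tsv"))
    if (!is.null(spot_truth)) {
      metrics <- stage("metrics", function() {
        ep <- expression_pcc(model$ref, model$query, mapping)
        cm <- classification_metrics(dom, spot_truth[names(dom)])
        ps <- if (sum(is.finite(ep)) >= 2) pcc_summary(ep) else NULL
        list(acc = cm$acc, f1_macro = cm$f1_macro,
             sensitivity_macro = cm$sensitivity_macro,
             specificity_macro = cm$specificity_macro, ari = cm$ari,
             pcc_mean = ps$mean, pcc_ci_low = ps$ci_low, pcc_ci_high = ps$ci_high,
             n_assigned = sum(mapping$assigned), n_cells = nrow(mapping))
      })
      files["metrics"] <- file.path(cfg$out_dir, "metrics.json")
      jsonlite::write_json(metrics, files["metrics"], auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
  }

  if (!is.null(scores)) {
    agg <- stage("aggregate", function() {
      aggregate_scores(scores, mapping, spots = rownames(model$TC_R))
    })
    files["spot_scores"] <- write_tsv(matrix_as_df(agg$values, "spot_id"),
                                      file.path(cfg$out_dir, "spot_scores.tsv"))
    rss <- regulon_specificity(agg)
    files["rss"] <- write_tsv(matrix_as_df(rss, "spot_id"),
                              file.path(cfg$out_dir, "rss.tsv"))
    files["top_scores"] <- file.path(cfg$out_dir, "top_scores.json")
    jsonlite::write_json(top_scores_per_spot(rss), files["top_scores"],
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
  }

  manifest <- list(
    package = "tcamap",
    version = as.character(utils::packageVersion("tcamap")),
    seed = cfg$seed,
    config = list(tca = cfg$tca, mapping = cfg$mapping),
    n_reference = model$n1, n_query = model$n2, n_genes = length(model$gene_order),
    stage_seconds = timings,
    outputs = as.list(files)
  )
  files["manifest"] <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_line("done in %.2fs; %d artifact(s) under %s",
           as.numeric(Sys.time() - t0, units = "secs"), length(files), cfg$out_dir)
  invisible(list(model = model, mapping = mapping, files = files, manifest = manifest))
}

# validates the run configuration before any compute happens
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  if (is.null(config$reference) || is.null(config$query)) {
    stop("config requires 'reference' and 'query'")
  }
  if (is.null(config$out_dir)) stop("config requires 'out_dir'")
  tca_defaults <- list(kernel = "primal", d = 30, lambda = 1, gamma = "median",
                       normalize = TRUE, hvg_n = 2000)
  config$tca <- utils::modifyList(tca_defaults, as.list(config$tca))
  if (!config$tca$kernel %in% c("primal", "linear", "rbf")) {
    stop("invalid kernel '", config$tca$kernel, "'; must be primal, linear or rbf")
  }
  if (config$tca$d < 3) stop("d must be at least 3")
  map_defaults <- list(pcc_threshold = 0.7, weight_by_pcc = FALSE)
  config$mapping <- utils::modifyList(map_defaults, as.list(config$mapping))
  if (config$mapping$pcc_threshold < -1 || config$mapping$pcc_threshold > 1) {
    stop("pcc_threshold must lie in [-1, 1]")
  }
  for (p in c("reference", "query", "cell_types", "spot_truth", "scores")) {
    if (is.character(config[[p]]) && length(config[[p]]) == 1L &&
        !file.exists(config[[p]])) {
      stop("input path for '", p, "' does not exist: ", config[[p]])
    }
  }
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config
}

#' Write a pseudo-spot set to disk
#'
#' Pseudo-bulk matrix (TSV or MTX by extension) plus a `spots.tsv` table
#' (spot_id, row, col, centroid_x, centroid_y, member_count, truth_label).
#'
#' @param ps a `"pseudo_spots"` object from [gridify()].
#' @param dir output directory.
#' @param matrix_format `"tsv"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
write_pseudo_spots <- function(ps, dir, matrix_format = c("tsv", "mtx")) {
  stopifnot(inherits(ps, "pseudo_spots"))
  matrix_format <- match.arg(matrix_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(ps$pseudo_bulk, file.path(dir, paste0("pseudo_bulk.", matrix_format)))
  write_tsv(ps$spots, file.path(dir, "spots.tsv"))
  invisible(dir)
}
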