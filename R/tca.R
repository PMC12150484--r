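#' Domain-discrepancy weight matrix
#'
#' Builds the rank-one weight matrix L used by transfer component analysis to
#' express the squared distance between domain means: entries are `1/n1^2`
#' within the reference block, `1/n2^2` within the query block and
#' `-1/(n1*n2)` across, with reference observations ordered first. Equivalently
#' `L = u %o% u` with `u_i = 1/n1` on reference rows and `-1/n2` on query rows.
#'
#' @param n1,n2 number of reference and query observations.
#' @return an `(n1+n2) x (n1+n2)` matrix; every row sums to zero.
#' @export
build_weight_matrix <- function(n1, n2) {
  if (n1 < 1 || n2 < 1) stop("domain sizes must be positive")
  u <- domain_indicator(n1, n2)
  tcrossprod(u)
}

# u vector with 1/n1 on reference rows, -1/n2 on query rows
domain_indicator <- function(n1, n2) {
  c(rep(1 / n1, n1), rep(-1 / n2, n2))
}

#' Centering matrix
#'
#' `H = I - (1/n) 11'`, the projector that removes the grand mean; symmetric
#' and idempotent, with `H %*% rep(1, n)` identically zero.
#'
#' @param n number of observations, at least 2.
#' @return an `n x n` matrix.
#' @export
build_centering_matrix <- function(n) {
  if (n < 2) stop("centering requires n >= 2")
  diag(n) - 1 / n
}

#' Kernel matrix over combined observations
#'
#' Computes the Gram matrix over the stacked reference and query observations.
#' The linear kernel is the pairwise dot product; the RBF kernel is
#' `exp(-gamma * ||x_i - x_j||^2)`. The result is symmetrised as `(K + K')/2`.
#' The primal formulation works directly in gene-feature space and never forms
#' a kernel, so requesting it here is an error.
#'
#' @param x observations x features numeric matrix.
#' @param kernel `"linear"` or `"rbf"`.
#' @param gamma RBF bandwidth: a positive number, or `"median"` for
#'   `1 / median(squared pairwise distances)` (a scale-free heuristic).
#' @return list with `values` (the symmetrised kernel matrix) and the resolved
#'   `gamma` (NA for linear).
#' @export
compute_kernel <- function(x, kernel = c("linear", "rbf"), gamma = "median") {
  kernel <- match.arg(kernel, c("linear", "rbf", "primal"))
  if (kernel == "primal") {
    stop("the primal formulation bypasses kernel construction")
  }
  if (!all(is.finite(x))) stop("non-finite values in kernel input")
  if (kernel == "linear") {
    k <- tcrossprod(x)
    gamma <- NA_real_
  } else {
    d2 <- as.matrix(stats::dist(x))^2
    gamma <- resolve_gamma(gamma, d2)
    k <- exp(-gamma * d2)
    diag(k) <- 1
  }
  list(values = (k + t(k)) / 2, gamma = gamma)
}

resolve_gamma <- function(gamma, d2) {
  if (identical(gamma, "median")) {
    med <- stats::median(d2[upper.tri(d2)])
    if (!is.finite(med) || med <= 0) med <- 1
    gamma <- 1 / med
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a positive number or \"median\"")
  }
  gamma
}

# Generalized symmetric eigensolve S a = eta (B) a with B symmetric positive
# definite, via Cholesky whitening: B = R'R, W = R^{-T} S R^{-1}, a = R^{-1} v.
# Returns eigenvalues descending; eigenvectors satisfy a' B a = 1.
gen_eigen <- function(s, b) {
  r <- tryCatch(chol(b), error = function(e) {
    stop("generalized eigensolver failed: regularised discrepancy matrix not positive definite (",
         conditionMessage(e), ")")
  })
  ri <- backsolve(r, diag(nrow(b)))
  w <- crossprod(ri, s %*% ri)
  w <- (w + t(w)) / 2
  e <- eigen(w, symmetric = TRUE)
  list(values = pmax(e$values, -1e-10), vectors = ri %*% e$vectors)
}

#' Fit a transfer component analysis alignment
#'
#' Finds a `d`-dimensional shared latent space in which the maximum mean
#' discrepancy (MMD) between a spatial reference and a single-cell query is
#' minimised while retained variance is preserved, by solving the regularised
#' generalized eigenproblem
#' \deqn{(K H K)\,a = \eta\,(K L K + \lambda I)\,a}
#' (primal formulation: `K H K` and `K L K` are replaced by `X' H X` and
#' `X' L X` with `X` the combined observations x genes matrix). `L` is the
#' rank-one domain-discrepancy weight matrix ([build_weight_matrix()]), `H` the
#' centering matrix ([build_centering_matrix()]). The eigenvectors of the `d`
#' largest eigenvalues form the transformation `A`, rescaled so that
#' `A'(KHK)A = I`; latent rows are `Z = K A` (primal: `Z = X A`), split into
#' the reference rows `TC_R` and query rows `TC_Q`.
#'
#' @param ref,query genes x observations numeric matrices with unique
#'   dimnames; `ref` columns are spatial spots, `query` columns are cells.
#' @param kernel `"primal"` (gene-feature space, the default), `"linear"` or
#'   `"rbf"`.
#' @param d number of transfer components (latent dimensions), at least 3
#'   (Pearson correlation over 2 coordinates is degenerate). Default 30.
#' @param lambda positive regularisation weight on `tr(A'A)`. Default 1.
#' @param gamma RBF bandwidth (see [compute_kernel()]); ignored otherwise.
#' @param normalize,hvg_n preprocessing, passed to [harmonize()]. Use
#'   `normalize = FALSE, hvg_n = 0` to fit on the matrices as given.
#' @return an object of class `"tca"`: a list with the transformation matrix
#'   `A`, eigenvalues `eta` (descending), latent rows `TC_R` and `TC_Q`, the
#'   kernel matrix `K` (`NULL` for primal), the harmonized gene order, domain
#'   sizes `n1`/`n2`, and the configuration. Methods: [print.tca()],
#'   [summary.tca()], [coef.tca()], [predict.tca()], [plot.tca()].
#' @examples
#' set.seed(1)
#' ref <- matrix(rpois(200, 5), 20, 10,
#'   dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' qry <- matrix(rpois(300, 5), 20, 15,
#'   dimnames = list(paste0("g", 1:20), paste0("c", 1:15)))
#' fit <- tca(ref, qry, d = 3, normalize = FALSE, hvg_n = 0)
#' fit
#' @export
tca <- function(ref, query, kernel = c("primal", "linear", "rbf"), d = 30,
                lambda = 1, gamma = "median", normalize = TRUE, hvg_n = 2000) {
  kernel <- match.arg(kernel)
  if (!is.numeric(d) || d < 3) stop("d must be at least 3")
  d <- as.integer(d)
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be positive")

  h <- harmonize(ref, query, normalize = normalize, hvg_n = hvg_n)
  n1 <- ncol(h$ref)
  n2 <- ncol(h$query)
  n <- n1 + n2
  if (n <= d) stop("n1 + n2 must exceed d")
  x <- rbind(t(h$ref), t(h$query))  # observations x genes
  u <- domain_indicator(n1, n2)

  if (kernel == "primal") {
    xc <- scale(x, center = TRUE, scale = FALSE)
    s <- crossprod(xc)                       # X' H X
    w <- drop(crossprod(x, u))               # X' u
    b <- tcrossprod(w) + diag(lambda, ncol(x))
    k <- NULL
    gamma <- NA_real_
  } else {
    kern <- compute_kernel(x, kernel, gamma)
    k <- kern$values
    gamma <- kern$gamma
    kc <- k - matrix(colMeans(k), n, n, byrow = TRUE)  # H K
    s <- k %*% kc                            # K H K
    s <- (s + t(s)) / 2
    ku <- drop(k %*% u)
    b <- tcrossprod(ku) + diag(lambda, n)    # K L K + lambda I
  }

  ge <- gen_eigen(s, b)
  # a' B a = 1 for every eigenvector, so eta_j equals a_j' S a_j
  usable <- sum(ge$values > 1e-12)
  if (d > usable) {
    stop("requested d = ", d, " exceeds achievable rank ", usable)
  }
  eta <- ge$values[seq_len(d)]
  a <- ge$vectors[, seq_len(d), drop = FALSE]
  # rescale so a'(KHK)a = 1; near-null directions are unusable for the
  # constraint and are dropped (defensive: the rank check above precedes this)
  keep <- eta > 1e-12
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " near-null transfer component(s); d reduced to ",
            sum(keep))
    eta <- eta[keep]
    a <- a[, keep, drop = FALSE]
    d <- sum(keep)
  }
  a <- sweep(a, 2L, sqrt(eta), "/")

  z <- if (kernel == "primal") x %*% a else k %*% a
  colnames(z) <- paste0("TC", seq_len(d))
  colnames(a) <- paste0("TC", seq_len(d))
  rownames(a) <- if (kernel == "primal") rownames(h$ref) else rownames(x)

  structure(list(
    A = a,
    eta = eta,
    TC_R = z[seq_len(n1), , drop = FALSE],
    TC_Q = z[n1 + seq_len(n2), , drop = FALSE],
    K = k,
    X = x,
    n1 = n1, n2 = n2,
    gene_order = rownames(h$ref),
    ref = h$ref, query = h$query,
    config = list(kernel = kernel, d = d, lambda = lambda, gamma = gamma,
                  normalize = normalize, hvg_n = hvg_n)
  ), class = "tca")
}

#' Empirical maximum mean discrepancy between two latent point sets
#'
#' Squared Euclidean distance between the mean latent row of each set:
#' `|| mean(Z_R) - mean(Z_Q) ||^2`. For a fitted model this equals the
#' minimised objective term `tr(A' K L K A)`.
#'
#' @param z_r,z_q numeric matrices with one row per observation and matching
#'   column counts.
#' @return a non-negative scalar.
#' @export
compute_mmd <- function(z_r, z_q) {
  z_r <- as.matrix(z_r)
  z_q <- as.matrix(z_q)
  if (nrow(z_r) == 0L || nrow(z_q) == 0L) stop("empty latent set")
  if (ncol(z_r) != ncol(z_q)) stop("latent dimensionalities differ")
  sum((colMeans(z_r) - colMeans(z_q))^2)
}

#' @export
print.tca <- function(x, ...) {
  cat("Transfer component analysis alignment\n")
  cat(sprintf("  kernel: %s   d: %d   lambda: %g%s\n", x$config$kernel,
              x$config$d, x$config$lambda,
              if (x$config$kernel == "rbf") sprintf("   gamma: %.4g", x$config$gamma) else ""))
  cat(sprintf("  reference spots: %d   query cells: %d   genes: %d\n",
              x$n1, x$n2, length(x$gene_order)))
  cat(sprintf("  latent-space MMD: %.6g\n", compute_mmd(x$TC_R, x$TC_Q)))
  invisible(x)
}

#' Summarise a fitted alignment
#'
#' @param object a fitted `"tca"` model.
#' @param ... unused.
#' @return a list with domain sizes, eigenvalue spectrum, the latent-space MMD
#'   and the objective decomposition, classed `"summary.tca"`.
#' @export
summary.tca <- function(object, ...) {
  mmd <- compute_mmd(object$TC_R, object$TC_Q)
  out <- list(
    config = object$config,
    n1 = object$n1, n2 = object$n2, n_genes = length(object$gene_order),
    eta = object$eta,
    mmd = mmd,
    penalty = object$config$lambda * sum(object$A^2),
    objective = mmd + object$config$lambda * sum(object$A^2)
  )
  class(out) <- "summary.tca"
  out
}

#' @export
print.summary.tca <- function(x, ...) {
  cat("Transfer component analysis alignment\n")
  cat(sprintf("  kernel %s, d = %d, lambda = %g; %d genes\n",
              x$config$kernel, x$config$d, x$config$lambda, x$n_genes))
  cat(sprintf("  %d reference spots, %d query cells\n", x$n1, x$n2))
  cat(sprintf("  objective tr(A'KLKA) + lambda tr(A'A) = %.6g + %.6g = %.6g\n",
              x$mmd, x$penalty, x$objective))
  cat("  leading eigenvalues:\n")
  print(utils::head(signif(x$eta, 4), 10))
  invisible(x)
}

#' @export
coef.tca <- function(object, ...) object$A

#' Project new observations into a fitted latent space
#'
#' For the primal formulation new observations are projected as `X_new A`; for
#' kernel formulations the cross-kernel between new and training observations
#' is formed (with the fitted bandwidth for RBF) and multiplied by `A`. New
#' data must be on the same scale as the data the model was fitted on: apply
#' the same normalisation before calling.
#'
#' @param object a fitted `"tca"` model.
#' @param newdata genes x observations matrix containing at least the fitted
#'   gene set.
#' @param ... unused.
#' @return observations x d matrix of latent coordinates.
#' @export
predict.tca <- function(object, newdata, ...) {
  missing_genes <- setdiff(object$gene_order, rownames(newdata))
  if (length(missing_genes)) {
    stop("newdata lacks fitted genes: ", paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  xn <- t(newdata[object$gene_order, , drop = FALSE])
  if (object$config$kernel == "primal") {
    return(xn %*% object$A)
  }
  kx <- if (object$config$kernel == "linear") {
    tcrossprod(xn, object$X)
  } else {
    d2 <- outer(rowSums(xn^2), rowSums(object$X^2), "+") - 2 * tcrossprod(xn, object$X)
    exp(-object$config$gamma * pmax(d2, 0))
  }
  kx %*% object$A
}

#' Plot the shared latent space
#'
#' Scatter of two transfer components with reference spots and query cells
#' distinguished by colour and symbol.
#'
#' @param x a fitted `"tca"` model.
#' @param dims length-2 integer vector of components to show. Default `c(1, 2)`.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.tca <- function(x, dims = c(1, 2), ...) {
  stopifnot(length(dims) == 2, all(dims <= x$config$d))
  z <- rbind(x$TC_R[, dims, drop = FALSE], x$TC_Q[, dims, drop = FALSE])
  grp <- rep(c("reference", "query"), c(x$n1, x$n2))
  graphics::plot(z, col = ifelse(grp == "reference", "#1b6ca8", "#d1495b"),
                 pch = ifelse(grp == "reference", 17, 1),
                 xlab = colnames(x$TC_R)[dims[1]], ylab = colnames(x$TC_R)[dims[2]], ...)
  graphics::legend("topright", legend = c("reference spot", "query cell"),
                   col = c("#1b6ca8", "#d1495b"), pch = c(17, 1), bty = "n")
  invisible(x)
}
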