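# fixtures are generated in code; every stochastic draw is seeded

rand_expr <- function(n_genes, n_obs, seed = 1, obs_prefix = "c",
                      gene_prefix = "g", rfun = function(n) stats::rnorm(n)) {
  withr::with_seed(seed, {
    m <- matrix(rfun(n_genes * n_obs), n_genes, n_obs)
    dimnames(m) <- list(paste0(gene_prefix, seq_len(n_genes)),
                        sprintf("%s%02d", obs_prefix, seq_len(n_obs)))
    m
  })
}

rand_counts <- function(n_genes, n_obs, seed = 1, obs_prefix = "c") {
  rand_expr(n_genes, n_obs, seed, obs_prefix,
            rfun = function(n) stats::rpois(n, 5))
}

# random alignment instance fitted without preprocessing
fit_random_instance <- function(seed, n1 = 25, n2 = 25, g = 40,
                                kernel = "linear", d = 5, lambda = 1) {
  tca(rand_expr(g, n1, seed, "s"), rand_expr(g, n2, seed + 5000, "c"),
      kernel = kernel, d = d, lambda = lambda, normalize = FALSE, hvg_n = 0)
}

# literal matrix-product evaluation of the discrepancy and constraint terms,
# independent of the solver's internal shortcuts
literal_terms <- function(fit) {
  l <- build_weight_matrix(fit$n1, fit$n2)
  h <- build_centering_matrix(fit$n1 + fit$n2)
  if (fit$config$kernel == "primal") {
    s <- t(fit$X) %*% h %*% fit$X
    m_lk <- t(fit$X) %*% l %*% fit$X
  } else {
    s <- fit$K %*% h %*% fit$K
    m_lk <- fit$K %*% l %*% fit$K
  }
  list(
    constraint = t(fit$A) %*% s %*% fit$A,                    # should be I_d
    discrepancy = t(fit$A) %*% m_lk %*% fit$A,                # tr() is the MMD term
    b_inner = t(fit$A) %*% (m_lk + fit$config$lambda * diag(nrow(fit$A))) %*% fit$A
  )
}

# a minimal mapping-capable model stub with prescribed latent rows
fake_tca <- function(tc_r, tc_q, d = ncol(tc_r)) {
  structure(list(TC_R = tc_r, TC_Q = tc_q, n1 = nrow(tc_r), n2 = nrow(tc_q),
                 config = list(kernel = "primal", d = d, lambda = 1)),
            class = "tca")
}
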