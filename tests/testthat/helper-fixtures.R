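# Small deterministic fixtures and independent oracles used across tests.

tiny_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# The 8-line, 2-replicate design as a sample sheet with arbitrary values.
toy_sheet <- function(n_replicates = 2) {
  d <- cohort_design()
  do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    data.frame(sample_id = paste(d$cell_line[i], seq_len(n_replicates),
                                 sep = "_r"),
               cell_line = d$cell_line[i],
               replicate = seq_len(n_replicates),
               status = d$status[i],
               parent_line = d$parent_line[i],
               phenotype = d$phenotype[i])
  }))
}

# Rank-mean quantile normalization oracle by explicit sorting (tie-free data).
oracle_quantile_normalize <- function(m) {
  ranks <- apply(m, 2, rank, ties.method = "first")
  sorted <- apply(m, 2, sort)
  rank_means <- rowMeans(sorted)
  out <- apply(ranks, 2, function(r) rank_means[r])
  dimnames(out) <- dimnames(m)
  out
}

# Upper-tail hypergeometric probability by explicit summation of the mass.
oracle_hyper_upper <- function(k, N, K, n) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Upper-tail probability by exhaustive enumeration of every possible draw.
oracle_hyper_enumerate <- function(k, background, term, n) {
  draws <- utils::combn(length(background), n)
  hits <- apply(draws, 2, function(d) sum(background[d] %in% term))
  mean(hits >= k)
}

# Soft-margin linear SVM primal objective minimized numerically; independent
# of the libsvm solver. Returns c(w, b).
oracle_svm_primal <- function(x, y, cost = 1) {
  obj <- function(par) {
    w <- par[-length(par)]
    b <- par[length(par)]
    margins <- 1 - y * (x %*% w + b)
    0.5 * sum(w^2) + cost * sum(pmax(margins, 0))
  }
  best <- NULL
  for (s in 1:5) {
    set.seed(s)
    fit <- optim(rnorm(ncol(x) + 1, sd = 0.5), obj, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$par
}

# Principal components by explicit eigendecomposition of the scaled
# covariance matrix (observations = rows of x).
oracle_pca <- function(x) {
  xs <- scale(x, center = TRUE, scale = TRUE)
  ev <- eigen(stats::cov(xs), symmetric = TRUE)
  list(scores = xs %*% ev$vectors,
       var_explained = 100 * ev$values / sum(ev$values))
}
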