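# Brute-force graph oracles (exhaustive simple-path enumeration, p <= 7)
# and small model builders shared across tests.

all_simple_paths_brute <- function(W, s, t) {
  p <- nrow(W)
  res <- list()
  rec <- function(path, len) {
    v <- path[length(path)]
    if (v == t) {
      res[[length(res) + 1]] <<- list(path = path, len = len)
      return(invisible())
    }
    for (u in seq_len(p)) {
      if (W[v, u] != 0 && !(u %in% path)) {
        rec(c(path, u), len + 1 / abs(W[v, u]))
      }
    }
  }
  rec(s, 0)
  res
}

# distances, strength, closeness and betweenness by path enumeration
brute_centrality <- function(W, tol = 1e-9) {
  p <- nrow(W)
  D <- matrix(Inf, p, p)
  diag(D) <- 0
  btw <- rep(0, p)
  for (s in seq_len(p - 1)) {
    for (t in seq(s + 1, p)) {
      paths <- all_simple_paths_brute(W, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      dmin <- min(lens)
      D[s, t] <- dmin
      D[t, s] <- dmin
      short <- paths[lens - dmin < tol]
      for (sp in short) {
        inter <- setdiff(sp$path, c(s, t))
        btw[inter] <- btw[inter] + 1 / length(short)
      }
    }
  }
  closeness <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / mean(d)
  }, numeric(1))
  list(D = D, strength = rowSums(abs(W)), closeness = closeness,
       betweenness = btw)
}

# random sparse symmetric weight matrix for oracle comparisons
random_weight_matrix <- function(p, edge_prob = 0.5) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (runif(1) < edge_prob) {
        w <- runif(1, 0.1, 0.9) * sample(c(-1, 1), 1)
        W[i, j] <- w
        W[j, i] <- w
      }
    }
  }
  W
}

# chain precision matrix: unit diagonal, -partial on the first off-diagonal
chain_precision <- function(p = 6, partial = 0.4) {
  theta <- diag(p)
  for (i in seq_len(p - 1)) {
    theta[i, i + 1] <- -partial
    theta[i + 1, i] <- -partial
  }
  stopifnot(min(eigen(theta, symmetric = TRUE,
                      only.values = TRUE)$values) > 0)
  theta
}

# latent Gaussian sample with covariance = inverse precision
sample_latent <- function(n, theta) {
  MASS::mvrnorm(n, mu = rep(0, nrow(theta)), Sigma = solve(theta))
}

# analytic mean of a thresholded normal: scores 0..3 at cut points `thr`
discretized_normal_mean <- function(mu, sd, thr) {
  pr <- diff(c(0, pnorm(thr, mean = mu, sd = sd), 1))
  sum((0:3) * pr)
}

# 3-node path network: edges (1,2) and (2,3), both weight w
path3 <- function(w = 0.5) {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- w
  W[2, 3] <- W[3, 2] <- w
  W
}

# write a small cohort CSV and return its path
write_toy_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

toy_cohort_df <- function(n = 4, p = 3) {
  set.seed(42)
  df <- as.data.frame(matrix(sample(0:3, n * p, replace = TRUE), n, p))
  names(df) <- paste0("item_", seq_len(p))
  df$age <- seq(30, 30 + n - 1)
  df$sex <- rep(c(0, 1), length.out = n)
  df$group <- rep(c("A", "B"), length.out = n)
  df
}
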