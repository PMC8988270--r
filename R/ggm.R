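#' Pearson correlation matrix of residualized items
#'
#' @param resid A `symptom_residuals` tibble or a numeric matrix
#'   (observations x items).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `R` (p x p correlation matrix, unit diagonal) and `n`
#'   (rows used).
#' @export
sample_correlation <- function(resid, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- residual_matrix(resid)
  if (nrow(X) < 3) stop("sample_correlation: need n >= 3", call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[which(sds == 0)]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("sample_correlation: zero-variance column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  R <- cor(X, method = method)
  diag(R) <- 1
  dimnames(R) <- NULL
  list(R = R, n = nrow(X))
}

#' Fit the graphical LASSO at one penalty
#'
#' L1-penalized Gaussian maximum-likelihood estimate of the precision matrix,
#' by block coordinate descent on the penalized covariance. Off-diagonal
#' entries of the estimate can be exactly zero; entries with absolute value
#' below `zero_tol` are hard-thresholded to zero so that "nonzero edge" is
#' well defined.
#'
#' @param R Correlation (or covariance) matrix.
#' @param lam Penalty, >= 0.
#' @param tol Convergence tolerance on the mean absolute change of the
#'   working covariance, relative to the mean absolute off-diagonal of `R`.
#' @param maxit Iteration cap.
#' @param zero_tol Hard-threshold below which off-diagonal precision entries
#'   are set to exactly zero.
#' @param penalize_diagonal Apply the L1 penalty to the precision diagonal
#'   (default `TRUE`, the classical penalized-covariance formulation)?
#'   `FALSE` leaves the diagonal unpenalized, which makes EBIC selection
#'   noticeably more conservative at small n.
#' @return The p x p precision estimate, with attributes `converged` and
#'   `iterations`.
#' @export
#' @examples
#' glasso_fit(diag(3), lam = 0.1)
glasso_fit <- function(R, lam, tol = 1e-4, maxit = 10000, zero_tol = 1e-10,
                       penalize_diagonal = TRUE) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R), lam >= 0)
  fit <- .glasso_cpp(R, lam, tol, as.integer(maxit), penalize_diagonal)
  if (!fit$converged) {
    stop(sprintf(
      "glasso_fit: no convergence at lambda = %g after %d iterations",
      lam, fit$iterations
    ), call. = FALSE)
  }
  theta <- fit$theta
  off <- abs(theta) < zero_tol
  diag(off) <- FALSE
  theta[off] <- 0
  structure(theta, converged = fit$converged, iterations = fit$iterations)
}

#' Partial correlations implied by a precision matrix
#'
#' `W[i,j] = -Theta[i,j] / sqrt(Theta[i,i] * Theta[j,j])` off the diagonal;
#' the diagonal of `W` is zero. Exact zeros in `Theta` stay exact zeros.
#'
#' @param theta Symmetric precision matrix with positive diagonal.
#' @return The p x p partial-correlation weight matrix.
#' @export
#' @examples
#' partials_from_precision(matrix(c(2, -1, 0, -1, 2, -1, 0, -1, 2), 3))
partials_from_precision <- function(theta) {
  stopifnot(is.matrix(theta), nrow(theta) == ncol(theta))
  d <- diag(theta)
  if (any(d <= 0)) {
    stop("partials_from_precision: precision diagonal must be positive",
         call. = FALSE)
  }
  s <- 1 / sqrt(d)
  W <- matrix(-as.numeric(theta) * as.numeric(outer(s, s)), nrow(theta))
  diag(W) <- 0
  W
}

#' Extended Bayesian information criterion of a precision estimate
#'
#' `EBIC = -2 * loglik + E * log(n) + 4 * gamma * E * log(p)` where
#' `loglik = (n/2) * (log det Theta - trace(R Theta))` and `E` is the number
#' of nonzero off-diagonal pairs (i < j) of `Theta`. `gamma = 0` reduces to
#' the ordinary BIC penalty.
#'
#' @param theta Precision estimate (positive definite).
#' @param R Correlation matrix the model was fit to.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter, conventionally 0.5.
#' @return Scalar EBIC value.
#' @export
ebic_score <- function(theta, R, n, gamma = 0.5) {
  stopifnot(is.matrix(theta), is.matrix(R), n > 0, gamma >= 0)
  ld <- determinant(theta, logarithm = TRUE)
  if (ld$sign <= 0) {
    stop("ebic_score: precision estimate is not positive definite",
         call. = FALSE)
  }
  loglik <- (n / 2) * (as.numeric(ld$modulus) - sum(R * theta))
  E <- sum(theta[upper.tri(theta)] != 0)
  -2 * loglik + E * log(n) + 4 * gamma * E * log(nrow(theta))
}

#' Estimate a regularized partial-correlation network
#'
#' The full estimation step of the pipeline: Pearson correlation of the
#' residualized items, a descending log-spaced penalty path from
#' `lambda_max = max |r_ij|` down to `lambda_min_ratio * lambda_max`,
#' a graphical-LASSO fit at each penalty, EBIC scoring, and the
#' partial-correlation weight matrix of the EBIC-minimizing fit.
#'
#' @param resid A `symptom_residuals` tibble or numeric matrix (rows =
#'   participants). If several groups are present they are pooled; use
#'   [estimate_group_networks()] for per-group estimation.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda Number of penalties on the path (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of `lambda_max`.
#' @param method Correlation type, `"pearson"` or `"spearman"`.
#' @param tol,maxit,penalize_diagonal Solver controls, see [glasso_fit()].
#' @param zero_tol Hard-threshold for exact zeros.
#' @return A `symptom_network` object: list with the weight matrix `W`,
#'   `lambda_selected`, `lambda_path`, `ebic_path`, `edge_count_path`,
#'   `gamma`, `n`, `p`, `nonzero_edge_count`.
#' @export
#' @examples
#' fx <- four_group_fixture(seed = 1, p = 5,
#'                          sizes = c(CD = 60, RD = 30, SD = 30, HC = 30))
#' net <- fx$cohort |> residualize_items() |> estimate_network()
#' glance(net)
estimate_network <- function(resid, gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01,
                             method = c("pearson", "spearman"),
                             tol = 1e-4, maxit = 10000, zero_tol = 1e-10,
                             penalize_diagonal = TRUE) {
  sc <- sample_correlation(resid, method = match.arg(method))
  estimate_network_from_correlation(
    sc$R, sc$n, gamma = gamma, n_lambda = n_lambda,
    lambda_min_ratio = lambda_min_ratio, tol = tol, maxit = maxit,
    zero_tol = zero_tol, penalize_diagonal = penalize_diagonal
  )
}

# path fit + EBIC selection from a precomputed correlation matrix
estimate_network_from_correlation <- function(R, n, gamma = 0.5,
                                              n_lambda = 100,
                                              lambda_min_ratio = 0.01,
                                              tol = 1e-4, maxit = 10000,
                                              zero_tol = 1e-10,
                                              penalize_diagonal = TRUE) {
  p <- nrow(R)
  lambda_max <- max(abs(R[upper.tri(R)]), 0)
  if (lambda_max <= 0) lambda_max <- 1e-4
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambda))
  path <- .glasso_path_cpp(R, lambdas, tol, as.integer(maxit),
                           penalize_diagonal)
  if (!all(path$converged)) {
    bad <- which(!path$converged)[1]
    stop(sprintf(
      "estimate_network: glasso did not converge at lambda = %g (%d iterations)",
      lambdas[bad], path$iterations[bad]
    ), call. = FALSE)
  }
  ebic <- numeric(n_lambda)
  edges <- integer(n_lambda)
  thetas <- path$thetas
  for (l in seq_len(n_lambda)) {
    th <- thetas[, , l]
    off <- abs(th) < zero_tol
    diag(off) <- FALSE
    th[off] <- 0
    thetas[, , l] <- th
    ebic[l] <- ebic_score(th, R, n, gamma)
    edges[l] <- sum(th[upper.tri(th)] != 0)
  }
  best <- which.min(ebic)
  theta <- thetas[, , best]
  W <- partials_from_precision(theta)
  new_symptom_network(
    W = W, theta = theta, lambda_selected = lambdas[best],
    lambda_path = lambdas, ebic_path = ebic, edge_count_path = edges,
    gamma = gamma, n = n, R = R
  )
}

new_symptom_network <- function(W, theta, lambda_selected, lambda_path,
                                ebic_path, edge_count_path, gamma, n, R) {
  structure(
    list(
      W = W, theta = theta, p = nrow(W),
      nonzero_edge_count = sum(W[upper.tri(W)] != 0),
      lambda_selected = lambda_selected, lambda_path = lambda_path,
      ebic_path = ebic_path, edge_count_path = edge_count_path,
      gamma = gamma, n = n, R = R
    ),
    class = "symptom_network"
  )
}

#' Estimate one network per group
#'
#' Groups are estimated fully independently: each group's rows are extracted
#' from the residual table and passed to [estimate_network()].
#'
#' @param resid A `symptom_residuals` tibble with a `group` column.
#' @param ... Passed to [estimate_network()].
#' @return Named list of `symptom_network`s, one per group level present.
#' @export
estimate_group_networks <- function(resid, ...) {
  stopifnot("group" %in% names(resid))
  groups <- if (is.factor(resid$group)) {
    intersect(levels(resid$group), unique(as.character(resid$group)))
  } else {
    unique(as.character(resid$group))
  }
  nets <- lapply(groups, function(g) {
    estimate_network(residuals_for_group(resid, g), ...)
  })
  names(nets) <- groups
  nets
}

#' @export
print.symptom_network <- function(x, ...) {
  cat("<symptom_network> ", x$p, " nodes, ", x$nonzero_edge_count,
      " nonzero edges (of ", x$p * (x$p - 1) / 2, ")\n",
      "  n = ", x$n, ", gamma = ", x$gamma,
      ", lambda = ", signif(x$lambda_selected, 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn estimate_network Tidy the edge list of a fitted network:
#'   one row per node pair i < j (nonzero edges only unless `dense = TRUE`)
#'   with columns `item_i`, `item_j`, `weight`.
#' @param x A `symptom_network`.
#' @param dense Include zero-weight pairs?
#' @param ... Unused.
#' @export
tidy.symptom_network <- function(x, dense = FALSE, ...) {
  idx <- which(upper.tri(x$W), arr.ind = TRUE)
  out <- tibble::tibble(
    item_i = as.integer(idx[, 1]),
    item_j = as.integer(idx[, 2]),
    weight = x$W[idx]
  )
  if (!dense) out <- out[out$weight != 0, , drop = FALSE]
  dplyr::arrange(out, .data$item_i, .data$item_j)
}

#' @describeIn estimate_network One-row model summary: nodes, sample size,
#'   selected penalty, EBIC hyperparameter, nonzero edge count, density and
#'   global strength.
#' @export
glance.symptom_network <- function(x, ...) {
  tibble::tibble(
    p = x$p, n = x$n, gamma = x$gamma,
    lambda_selected = x$lambda_selected,
    nonzero_edges = x$nonzero_edge_count,
    density = x$nonzero_edge_count / (x$p * (x$p - 1) / 2),
    global_strength = global_strength(x)
  )
}
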