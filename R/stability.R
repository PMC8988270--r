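#' Nonparametric bootstrap confidence intervals for edge weights
#'
#' Resamples participants with replacement `B` times, re-estimates the
#' network on every resample with the full penalty-path + EBIC procedure, and
#' returns percentile confidence intervals per node pair, sorted by the
#' sample edge weight in descending order. An edge whose CI excludes zero is
#' flagged as sufficiently strong. The nonparametric bootstrap is used
#' because LASSO regularization biases parametric resampling.
#'
#' @param resid Residualized item data (`symptom_residuals` tibble or
#'   matrix); if a `group` column with several levels is present the rows are
#'   pooled — bootstrap one group at a time.
#' @param B Number of bootstrap resamples (the study default is 2,500).
#' @param seed Integer seed.
#' @param conf Confidence level of the percentile interval (default 0.95).
#' @param gamma,n_lambda,lambda_min_ratio Estimator settings.
#' @param max_redraws Cap on resamples redrawn after estimation failure.
#' @return A tibble of class `edge_bootstrap` with columns `item_i`,
#'   `item_j`, `sample`, `boot_mean`, `ci_lower`, `ci_upper`,
#'   `excludes_zero`; attributes `B`, `seed`, `conf`, `redraws`.
#' @export
bootstrap_edges <- function(resid, B = 2500, seed = NULL, conf = 0.95,
                            gamma = 0.5, n_lambda = 100,
                            lambda_min_ratio = 0.01, max_redraws = 100) {
  if (B < 2) stop("bootstrap_edges: B must be >= 2", call. = FALSE)
  X <- residual_matrix(resid)
  n <- nrow(X)
  est <- function(M) {
    estimate_network(M, gamma = gamma, n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio)
  }
  net <- est(X)
  ut <- upper.tri(net$W)
  idx <- which(ut, arr.ind = TRUE)
  run <- function() {
    draws <- matrix(NA_real_, B, nrow(idx))
    redraws <- 0L
    b <- 1L
    while (b <= B) {
      rows <- sample.int(n, n, replace = TRUE)
      ok <- tryCatch({
        nb <- est(X[rows, , drop = FALSE])
        draws[b, ] <- nb$W[ut]
        TRUE
      }, error = function(e) FALSE)
      if (ok) b <- b + 1L else {
        redraws <- redraws + 1L
        if (redraws > max_redraws) {
          stop("bootstrap_edges: too many failed resample estimations",
               call. = FALSE)
        }
      }
    }
    list(draws = draws, redraws = redraws)
  }
  bs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  alpha <- (1 - conf) / 2
  lo <- apply(bs$draws, 2, quantile, probs = alpha, names = FALSE)
  hi <- apply(bs$draws, 2, quantile, probs = 1 - alpha, names = FALSE)
  out <- tibble::tibble(
    item_i = as.integer(idx[, 1]),
    item_j = as.integer(idx[, 2]),
    sample = net$W[ut],
    boot_mean = colMeans(bs$draws),
    ci_lower = lo,
    ci_upper = hi
  )
  out$excludes_zero <- out$ci_lower > 0 | out$ci_upper < 0
  out <- dplyr::arrange(out, dplyr::desc(.data$sample))
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "conf") <- conf
  attr(out, "redraws") <- bs$redraws
  attr(out, "network") <- net
  class(out) <- c("edge_bootstrap", class(out))
  out
}

#' Case-dropping bootstrap for centrality stability
#'
#' For each drop proportion `q`, draws `B` subsamples without replacement of
#' size `ceiling((1 - q) * n)`, re-estimates the network and its centralities,
#' and records the Pearson correlation between the subsample centralities and
#' the full-sample centralities, per measure. A constant centrality vector in
#' a replicate makes the correlation undefined; such replicates are recorded
#' as `NA` and counted.
#'
#' @inheritParams bootstrap_edges
#' @param proportions Strictly increasing drop proportions in (0, 1); `0` is
#'   allowed and returns correlation 1 by construction.
#' @param measures Centrality measures to track.
#' @return A `case_drop_result`: list with `correlations` (tibble `q`,
#'   `replicate`, `measure`, `correlation`), `full` (full-sample centrality
#'   table), `n`, `B`, `seed`.
#' @export
case_dropping <- function(resid, proportions = seq(0.05, 0.75, by = 0.05),
                          B = 1000, seed = NULL,
                          measures = c("strength", "closeness", "betweenness"),
                          gamma = 0.5, n_lambda = 100,
                          lambda_min_ratio = 0.01) {
  stopifnot(all(proportions >= 0), all(proportions < 1),
            !is.unsorted(proportions, strictly = TRUE))
  measures <- match.arg(measures, several.ok = TRUE)
  X <- residual_matrix(resid)
  n <- nrow(X)
  p <- ncol(X)
  too_few <- proportions[ceiling((1 - proportions) * n) < p + 2]
  if (length(too_few) > 0) {
    stop("case_dropping: proportion(s) ",
         paste(too_few, collapse = ", "),
         " leave fewer than p + 2 rows", call. = FALSE)
  }
  est <- function(M) {
    estimate_network(M, gamma = gamma, n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio)
  }
  cents <- function(net) {
    cbind(strength = strength(net),
          closeness = closeness_centrality(net),
          betweenness = betweenness_centrality(net))[, measures, drop = FALSE]
  }
  full_net <- est(X)
  full_cent <- cents(full_net)

  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }
  run <- function() {
    recs <- list()
    k <- 1L
    for (q in proportions) {
      m <- ceiling((1 - q) * n)
      for (b in seq_len(B)) {
        if (m == n) {
          # identity subsample: the refit reproduces the full-sample
          # centralities, so the correlation is 1 by construction
          recs[[k]] <- tibble::tibble(q = q, replicate = b,
                                      measure = measures, correlation = 1)
          k <- k + 1L
          next
        }
        rows <- sample.int(n, m)
        cc <- tryCatch(cents(est(X[rows, , drop = FALSE])),
                       error = function(e) NULL)
        corr <- if (is.null(cc)) rep(NA_real_, length(measures)) else {
          vapply(measures, function(ms) safe_cor(full_cent[, ms], cc[, ms]),
                 numeric(1))
        }
        recs[[k]] <- tibble::tibble(q = q, replicate = b,
                                    measure = measures,
                                    correlation = corr)
        k <- k + 1L
      }
    }
    dplyr::bind_rows(recs)
  }
  correlations <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(correlations = correlations,
         full = centrality_table(full_net),
         proportions = proportions, measures = measures,
         n = n, B = B, seed = seed),
    class = "case_drop_result"
  )
}

#' Correlation-stability (CS) coefficient
#'
#' The largest tested drop proportion `q` at which at least `prob` of the
#' subsample centralities still correlate at least `cor_floor` with the
#' full-sample centralities; 0 if no tested proportion qualifies. Replicates
#' with undefined correlations are excluded from the denominator (their count
#' is returned). A CS-coefficient above 0.25 is the conventional cutoff for
#' interpretable centrality order.
#'
#' @param result A [case_dropping()] result.
#' @param cor_floor Correlation threshold (default 0.7).
#' @param prob Required fraction of replicates at or above the floor
#'   (default 0.95).
#' @return Tibble `measure`, `cs`, `n_undefined`.
#' @export
cs_coefficient <- function(result, cor_floor = 0.7, prob = 0.95) {
  stopifnot(inherits(result, "case_drop_result"))
  cc <- result$correlations
  out <- lapply(result$measures, function(ms) {
    sub <- cc[cc$measure == ms, , drop = FALSE]
    qs <- sort(unique(sub$q))
    ok_q <- vapply(qs, function(q) {
      r <- sub$correlation[sub$q == q]
      r <- r[!is.na(r)]
      length(r) > 0 && mean(r >= cor_floor) >= prob
    }, logical(1))
    cs <- if (any(ok_q)) max(qs[ok_q]) else 0
    tibble::tibble(measure = ms, cs = cs,
                   n_undefined = sum(is.na(sub$correlation)))
  })
  dplyr::bind_rows(out)
}

#' @describeIn case_dropping Tidy per-proportion summary: mean correlation
#'   and the share of replicates at or above a correlation floor.
#' @param x A `case_drop_result`.
#' @param cor_floor Correlation floor used for the share column.
#' @param ... Unused.
#' @export
tidy.case_drop_result <- function(x, cor_floor = 0.7, ...) {
  x$correlations |>
    dplyr::group_by(.data$measure, .data$q) |>
    dplyr::summarise(
      mean_correlation = mean(.data$correlation, na.rm = TRUE),
      share_above_floor = mean(.data$correlation[!is.na(.data$correlation)]
                               >= cor_floor),
      n_undefined = sum(is.na(.data$correlation)),
      .groups = "drop"
    )
}
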