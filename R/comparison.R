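#' Global strength of a network
#'
#' Sum of absolute edge weights over node pairs i < j; equals half the sum of
#' node strengths.
#'
#' @inheritParams strength
#' @return Scalar.
#' @export
global_strength <- function(network) {
  W <- weight_matrix(network)
  sum(abs(W[upper.tri(W)]))
}

# maximum absolute single-edge difference between two weight matrices
structure_statistic <- function(WA, WB) {
  max(abs(WA - WB)[upper.tri(WA)], 0)
}

# Pearson chi-square (no continuity correction) on a 2x2 count table
pearson_chisq_2x2 <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    return(list(statistic = NA_real_, p = 1, degenerate = TRUE))
  }
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Chi-square tests on nonzero-edge ratios between groups
#'
#' For every group pair, tests whether the two networks differ in the
#' proportion of the p(p-1)/2 possible edges that are nonzero, using a
#' Pearson chi-square on the 2x2 table (nonzero, zero) x (group A, group B)
#' without continuity correction, followed by Holm step-down adjustment
#' across all pairs tested. A degenerate table (both networks saturated or
#' both empty in the same way, leaving a zero margin) is reported with p = 1
#' and a degeneracy flag.
#'
#' @param networks Named list of `symptom_network`s (>= 2, equal p).
#' @param pairs Optional 2-column character matrix of group pairs; default
#'   all unordered pairs.
#' @return Tibble of class `edge_count_test` with columns `group_a`,
#'   `group_b`, `nonzero_a`, `nonzero_b`, `n_pairs`, `statistic`, `p_value`,
#'   `p_adjusted`, `degenerate`.
#' @export
edge_count_test <- function(networks, pairs = NULL) {
  stopifnot(length(networks) >= 2)
  ps <- vapply(networks, function(x) x$p, numeric(1))
  stopifnot(length(unique(ps)) == 1)
  n_pairs <- ps[1] * (ps[1] - 1) / 2
  groups <- names(networks)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(groups, 2))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    ea <- networks[[a]]$nonzero_edge_count
    eb <- networks[[b]]$nonzero_edge_count
    tab <- rbind(c(ea, n_pairs - ea), c(eb, n_pairs - eb))
    ct <- pearson_chisq_2x2(tab)
    tibble::tibble(
      group_a = a, group_b = b, nonzero_a = ea, nonzero_b = eb,
      n_pairs = n_pairs, statistic = ct$statistic, p_value = ct$p,
      degenerate = ct$degenerate
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "holm")
  class(out) <- c("edge_count_test", class(out))
  out[, c("group_a", "group_b", "nonzero_a", "nonzero_b", "n_pairs",
          "statistic", "p_value", "p_adjusted", "degenerate")]
}

#' Permutation network comparison test for two groups
#'
#' Compares two groups' networks on two indicators: the global-strength
#' difference `|S_A - S_B|` and the structure statistic
#' `M = max_{i<j} |W_A[i,j] - W_B[i,j]|`. Both networks are estimated with
#' the full penalty-path + EBIC procedure; the null distribution is built by
#' pooling the residualized rows and reassigning them at random to
#' pseudo-groups of the original sizes, re-estimating both networks each
#' time. p-values use the add-one convention
#' `p = (1 + #\{permuted >= observed\}) / (B + 1)`, so they are never zero.
#'
#' @param resid_a,resid_b Residualized item data for the two groups
#'   (`symptom_residuals` tibbles or numeric matrices with equal p).
#' @param B Number of permutations (the study default is 5,000).
#' @param seed Integer seed; the test is deterministic given it.
#' @param gamma,n_lambda,lambda_min_ratio Estimator settings, see
#'   [estimate_network()].
#' @param max_redraws Failed estimations inside a permutation are redrawn up
#'   to this many times in total (count reported in the result).
#' @return An `nct_result` list: observed statistics, permutation p-values,
#'   the permutation draws, `B`, `seed` and settings.
#' @export
nct <- function(resid_a, resid_b, B = 5000, seed = NULL, gamma = 0.5,
                n_lambda = 100, lambda_min_ratio = 0.01, max_redraws = 100) {
  if (B < 1) stop("nct: B must be >= 1", call. = FALSE)
  XA <- residual_matrix(resid_a)
  XB <- residual_matrix(resid_b)
  stopifnot(ncol(XA) == ncol(XB))
  est <- function(X) {
    estimate_network(X, gamma = gamma, n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio)
  }
  net_a <- est(XA)
  net_b <- est(XB)
  obs_strength <- abs(global_strength(net_a) - global_strength(net_b))
  obs_structure <- structure_statistic(net_a$W, net_b$W)

  pool <- rbind(XA, XB)
  n_a <- nrow(XA)
  n_tot <- nrow(pool)
  run <- function() {
    perm_strength <- numeric(B)
    perm_structure <- numeric(B)
    redraws <- 0L
    b <- 1L
    while (b <= B) {
      idx <- sample.int(n_tot, n_a)
      ok <- tryCatch({
        na <- est(pool[idx, , drop = FALSE])
        nb <- est(pool[-idx, , drop = FALSE])
        perm_strength[b] <- abs(global_strength(na) - global_strength(nb))
        perm_structure[b] <- structure_statistic(na$W, nb$W)
        TRUE
      }, error = function(e) FALSE)
      if (ok) {
        b <- b + 1L
      } else {
        redraws <- redraws + 1L
        if (redraws > max_redraws) {
          stop("nct: too many failed permutation estimations", call. = FALSE)
        }
      }
    }
    list(strength = perm_strength, structure = perm_structure,
         redraws = redraws)
  }
  perms <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  structure(
    list(
      observed = c(strength = obs_strength, structure = obs_structure),
      p_value = c(
        strength = (1 + sum(perms$strength >= obs_strength)) / (B + 1),
        structure = (1 + sum(perms$structure >= obs_structure)) / (B + 1)
      ),
      permuted = tibble::tibble(strength = perms$strength,
                                structure = perms$structure),
      network_a = net_a, network_b = net_b,
      n_a = n_a, n_b = n_tot - n_a, B = B, seed = seed,
      redraws = perms$redraws,
      settings = list(gamma = gamma, n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio)
    ),
    class = "nct_result"
  )
}

#' @export
print.nct_result <- function(x, ...) {
  cat("<nct_result> permutation network comparison, B =", x$B, "\n")
  cat(sprintf("  global strength: |S_A - S_B| = %.4f, p = %.4g\n",
              x$observed["strength"], x$p_value["strength"]))
  cat(sprintf("  structure:       M = %.4f, p = %.4g\n",
              x$observed["structure"], x$p_value["structure"]))
  invisible(x)
}

#' @describeIn nct Tidy one-row-per-indicator summary of an `nct_result`.
#' @param x An `nct_result`.
#' @param ... Unused.
#' @export
tidy.nct_result <- function(x, ...) {
  tibble::tibble(
    indicator = c("global_strength", "structure"),
    observed = as.numeric(x$observed),
    p_value = as.numeric(x$p_value),
    B = x$B
  )
}

#' All pairwise network comparison tests with Holm correction
#'
#' Runs [nct()] for every pair of groups in a residual table and adjusts the
#' p-values by Holm's step-down method, with the global-strength tests and
#' the structure tests corrected as two separate families.
#'
#' @param resid A `symptom_residuals` tibble with a `group` column.
#' @param B Permutations per pair.
#' @param seed Integer seed (per-pair seeds are derived from it).
#' @param ... Estimator settings passed to [nct()].
#' @return Tibble `group_a`, `group_b`, `statistic`, `observed`, `p_value`,
#'   `p_adjusted`, `B`.
#' @export
compare_networks <- function(resid, B = 5000, seed = NULL, ...) {
  groups <- if (is.factor(resid$group)) {
    intersect(levels(resid$group), unique(as.character(resid$group)))
  } else {
    unique(as.character(resid$group))
  }
  stopifnot(length(groups) >= 2)
  prs <- t(utils::combn(groups, 2))
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(prs)) else {
    as.list(derive_seeds(seed, nrow(prs)))
  }
  rows <- lapply(seq_len(nrow(prs)), function(k) {
    a <- prs[k, 1]; b <- prs[k, 2]
    res <- nct(residuals_for_group(resid, a), residuals_for_group(resid, b),
               B = B, seed = seeds[[k]], ...)
    out <- tidy(res)
    out$group_a <- a
    out$group_b <- b
    out
  })
  out <- dplyr::bind_rows(rows)
  out <- out |>
    dplyr::group_by(.data$indicator) |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p_value, method = "holm")) |>
    dplyr::ungroup()
  out[, c("group_a", "group_b", "indicator", "observed", "p_value",
          "p_adjusted", "B")]
}
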