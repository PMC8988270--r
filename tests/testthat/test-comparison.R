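make_net <- function(edges, p) {
  W <- matrix(0, p, p)
  if (length(edges) > 0) {
    for (e in edges) {
      W[e[1], e[2]] <- W[e[2], e[1]] <- e[3]
    }
  }
  structure(list(W = W, p = p,
                 nonzero_edge_count = sum(W[upper.tri(W)] != 0)),
            class = "symptom_network")
}

# fabricate a network object with a given nonzero edge count (for count tests)
count_net <- function(k, p = 21) {
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  edges <- lapply(seq_len(k), function(i) c(pairs[i, 1], pairs[i, 2], 0.1))
  make_net(edges, p)
}

test_that("global strength sums absolute weights and halves total strength", {
  expect_equal(global_strength(matrix(0, 4, 4)), 0)
  W <- path3(0.5)
  expect_equal(global_strength(W), 1.0)
  set.seed(2)
  Wr <- random_weight_matrix(6, 0.5)
  expect_equal(global_strength(Wr), sum(strength(Wr)) / 2)
})

test_that("the chi-square edge-ratio test reproduces the printed group counts", {
  # 119/210 vs 1/210 nonzero edges: the densest and emptiest group networks
  nets <- list(CD = count_net(119), HC = count_net(1))
  res <- edge_count_test(nets)
  # independent oracle: stats::chisq.test without continuity correction
  tab <- rbind(c(119, 91), c(1, 209))
  oracle <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-10)
  expect_equal(res$statistic, 162.4, tolerance = 0.05)
  expect_lt(res$p_adjusted, 0.001)
})

test_that("identical and degenerate count tables are handled", {
  nets <- list(A = count_net(20), B = count_net(20))
  res <- edge_count_test(nets)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$degenerate)

  empty <- list(A = count_net(0), B = count_net(0))
  res0 <- edge_count_test(empty)
  expect_true(res0$degenerate)
  expect_equal(res0$p_value, 1)
})

test_that("Holm adjustment matches the hand-computed step-down example", {
  raw <- c(0.01, 0.04, 0.03, 0.2, 0.5, 0.9)
  adjusted <- p.adjust(raw, method = "holm")
  # step-down by hand: sorted raws (.01,.03,.04,.2,.5,.9) scaled by
  # (6,5,4,3,2,1) give (.06,.15,.16,.6,1,.9), cummax -> (.06,.15,.16,.6,1,1)
  expect_equal(adjusted, c(0.06, 0.16, 0.15, 0.6, 1, 1))
  # monotone non-decreasing in the raw ordering and each >= raw
  ord <- order(raw)
  expect_true(!is.unsorted(adjusted[ord]))
  expect_true(all(adjusted >= raw))

  nets <- list(A = count_net(119), B = count_net(106), C = count_net(20),
               D = count_net(1))
  res <- edge_count_test(nets)
  expect_equal(nrow(res), 6)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$p_adjusted <= 1))
})

test_that("the NCT on two copies of the same data gives p = 1", {
  set.seed(12)
  X <- sample_latent(80, chain_precision(4, 0.4))
  res <- nct(X, X, B = 50, seed = 1)
  expect_equal(unname(res$observed), c(0, 0))
  expect_equal(unname(res$p_value), c(1, 1))
})

test_that("NCT p-values are never zero and are label-swap symmetric", {
  set.seed(13)
  XA <- sample_latent(60, chain_precision(4, 0.45))
  XB <- matrix(rnorm(60 * 4), 60, 4)
  ab <- nct(XA, XB, B = 60, seed = 42)
  ba <- nct(XB, XA, B = 60, seed = 42)
  expect_true(all(ab$p_value > 0))
  expect_equal(ab$observed, ba$observed)
  # swapping group labels relabels pseudo-group A as size nB, but the
  # statistics are symmetric, so equal-size groups give identical p-values
  XA2 <- XA[1:60, ]
  expect_equal(nct(XA2, XB, B = 60, seed = 7)$p_value,
               nct(XB, XA2, B = 60, seed = 7)$p_value)
})

test_that("tiny-sample NCT matches exhaustive label enumeration", {
  set.seed(14)
  XA <- matrix(rnorm(3 * 2), 3, 2)
  XB <- matrix(rnorm(3 * 2, mean = 1), 3, 2)
  pool <- rbind(XA, XB)
  est <- function(M) estimate_network(M, n_lambda = 20)
  obs_net_a <- est(XA); obs_net_b <- est(XB)
  obs <- c(
    abs(global_strength(obs_net_a) - global_strength(obs_net_b)),
    max(abs(obs_net_a$W - obs_net_b$W))
  )
  combos <- utils::combn(6, 3)
  enum <- apply(combos, 2, function(idx) {
    na <- est(pool[idx, , drop = FALSE])
    nb <- est(pool[-idx, , drop = FALSE])
    c(abs(global_strength(na) - global_strength(nb)),
      max(abs(na$W - nb$W)))
  })
  res <- nct(XA, XB, B = 400, seed = 3, n_lambda = 20)
  # every permuted statistic lies in the enumerated support
  expect_true(all(vapply(res$permuted$strength, function(v) {
    any(abs(v - enum[1, ]) < 1e-8)
  }, logical(1))))
  # permutation p approximates the exhaustive p for both indicators
  for (k in 1:2) {
    exact <- mean(enum[k, ] >= obs[k] - 1e-12)
    perm <- res$p_value[k]
    expect_lt(abs(perm - exact), 0.1)
  }
})

test_that("pairwise comparisons correct the two statistic families separately", {
  fx <- four_group_fixture(seed = 6, p = 4,
                           sizes = c(CD = 40, RD = 40, SD = 40, HC = 40))
  resid <- residualize_items(fx$cohort)
  comp <- compare_networks(resid, B = 20, seed = 9, n_lambda = 20)
  expect_equal(nrow(comp), 12)  # 6 pairs x 2 statistics
  expect_true(all(comp$p_value > 0 & comp$p_value <= 1))
  expect_true(all(comp$p_adjusted >= comp$p_value))
  for (fam in c("global_strength", "structure")) {
    sub <- comp[comp$indicator == fam, ]
    expect_equal(sub$p_adjusted,
                 p.adjust(sub$p_value, method = "holm"))
  }
})
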