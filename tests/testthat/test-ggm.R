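test_that("sample correlations match the direct Pearson formula", {
  X <- matrix(c(0, 1, 2, 3, 1,
                1, 0, 2, 2, 3,
                3, 2, 1, 0, 2), 5, 3)
  sc <- sample_correlation(X)
  # hand-coded product-moment formula
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:3) for (j in 1:3) {
    expected <- if (i == j) 1 else pearson(X[, i], X[, j])
    expect_equal(sc$R[i, j], expected, tolerance = 1e-12)
  }
  expect_equal(sc$n, 5)

  # perfectly collinear columns
  Y <- cbind(X[, 1], X[, 1], -X[, 1])
  scy <- sample_correlation(Y)
  expect_equal(scy$R[1, 2], 1)
  expect_equal(scy$R[1, 3], -1)

  expect_error(sample_correlation(cbind(X, 0)), "zero-variance")
})

test_that("glasso recovers the identity and the fully sparse solution", {
  for (lam in c(0, 0.1, 0.5)) {
    th <- glasso_fit(diag(4), lam)
    expect_equal(unclass(th)[upper.tri(th)], rep(0, 6))
    expect_equal(partials_from_precision(th), matrix(0, 4, 4))
  }
  # lam >= max |r| forces a diagonal solution on random correlation inputs
  set.seed(17)
  for (k in 1:5) {
    X <- matrix(rnorm(60 * 5), 60, 5)
    R <- cor(X)
    lam_max <- max(abs(R[upper.tri(R)]))
    th <- glasso_fit(R, lam_max + 1e-6)
    expect_true(all(th[upper.tri(th)] == 0))
    th2 <- glasso_fit(R, lam_max * 0.5)
    expect_gt(sum(th2[upper.tri(th2)] != 0), 0)
  }
})

test_that("unpenalized glasso equals the inverse correlation matrix", {
  set.seed(31)
  X <- matrix(rnorm(400 * 5), 400, 5)
  R <- cor(X)
  th <- glasso_fit(R, 0)
  expect_lt(max(abs(th - solve(R))), 1e-5)
})

test_that("partials_from_precision implements the standard identity", {
  theta <- matrix(c(2, -1, 0, -1, 2, -1, 0, -1, 2), 3)
  W <- partials_from_precision(theta)
  expect_equal(W[1, 2], 0.5)
  expect_equal(W[2, 3], 0.5)
  expect_equal(W[1, 3], 0)
  expect_equal(diag(W), rep(0, 3))

  expect_equal(partials_from_precision(diag(c(1, 2, 3))), matrix(0, 3, 3))
  # positive precision off-diagonal implies negative partial correlation
  theta2 <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_lt(partials_from_precision(theta2)[1, 2], 0)
  expect_error(partials_from_precision(diag(c(1, -1))), "positive")
})

test_that("ebic_score matches an independently coded formula", {
  # diagonal precision: zero edges, EBIC = -2 * loglik
  R0 <- diag(3)
  th0 <- diag(3)
  n <- 50
  expect_equal(ebic_score(th0, R0, n, gamma = 0.5),
               -2 * (n / 2) * (0 - 3))
  # gamma = 0 reduces to BIC
  r <- 0.5
  R <- matrix(c(1, r, r, 1), 2)
  th <- solve(R)
  ll <- (100 / 2) * (log(det(th)) - sum(diag(R %*% th)))
  E <- 1
  expect_equal(ebic_score(th, R, 100, gamma = 0),
               -2 * ll + E * log(100), tolerance = 1e-8)
  expect_equal(ebic_score(th, R, 100, gamma = 0.5),
               -2 * ll + E * log(100) + 4 * 0.5 * E * log(2),
               tolerance = 1e-8)
  expect_error(ebic_score(matrix(c(1, 2, 2, 1), 2), R, 100), "positive")
})

test_that("a strong chain structure is fully recovered with signs", {
  theta <- chain_precision(p = 6, partial = 0.4)
  truth <- partials_from_precision(theta)
  for (seed in 1:10) {
    set.seed(seed)
    net <- estimate_network(sample_latent(2000, theta))
    for (i in 1:5) {
      expect_gt(net$W[i, i + 1], 0)  # true edge present, correct sign
    }
  }
})

test_that("independent data yield (near-)empty selected networks", {
  spurious <- integer(10)
  for (seed in 1:10) {
    set.seed(100 + seed)
    X <- matrix(rnorm(1000 * 6), 1000, 6)
    net <- estimate_network(X)
    spurious[seed] <- net$nonzero_edge_count
  }
  expect_lte(mean(spurious), 2)
})

test_that("the edge count grows monotonically as the penalty decreases", {
  set.seed(55)
  theta <- chain_precision(6, 0.35)
  net <- estimate_network(sample_latent(400, theta))
  # lambda_path is descending, so counts along it grow, up to transient
  # single-edge exits where a coefficient crosses zero
  expect_true(all(diff(net$lambda_path) < 0))
  expect_lte(max(cummax(net$edge_count_path) - net$edge_count_path), 1)
  expect_equal(net$lambda_selected,
               net$lambda_path[which.min(net$ebic_path)])
  expect_equal(net$nonzero_edge_count, sum(net$W[upper.tri(net$W)] != 0))
})

test_that("estimation is invariant to permuting participant rows", {
  set.seed(66)
  theta <- chain_precision(5, 0.4)
  X <- sample_latent(300, theta)
  a <- estimate_network(X)
  b <- estimate_network(X[sample(nrow(X)), ])
  expect_equal(a$W, b$W, tolerance = 1e-10)
  expect_equal(a$lambda_selected, b$lambda_selected)
})

test_that("zeros in the precision estimate are exact zeros in W", {
  set.seed(77)
  X <- matrix(rnorm(200 * 6), 200, 6)
  R <- cor(X)
  th <- glasso_fit(R, 0.15)
  W <- partials_from_precision(th)
  expect_identical(which(th[upper.tri(th)] == 0),
                   which(W[upper.tri(W)] == 0))
  expect_true(all(W[upper.tri(W)][th[upper.tri(th)] == 0] == 0))
})

test_that("specificity stays high while sensitivity grows with n", {
  m <- make_precision_model(p = 10, density = 0.2,
                            weight_range = c(0.12, 0.3), seed = 2)
  truth <- m$partials != 0
  ut <- upper.tri(truth)
  sens <- spec <- numeric(3)
  ns <- c(100, 500, 2000)
  for (k in seq_along(ns)) {
    s1 <- s2 <- numeric(5)
    for (seed in 1:5) {
      set.seed(1000 * ns[k] + seed)
      net <- estimate_network(sample_latent(ns[k], m$precision))
      found <- net$W != 0
      s1[seed] <- sum(found[ut] & truth[ut]) / sum(truth[ut])
      s2[seed] <- sum(!found[ut] & !truth[ut]) / sum(!truth[ut])
    }
    sens[k] <- mean(s1)
    spec[k] <- mean(s2)
  }
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3], 0.95)
  expect_true(all(spec > 0.7))
})

test_that("group networks are estimated independently", {
  fx <- four_group_fixture(seed = 2, p = 5,
                           sizes = c(CD = 60, RD = 50, SD = 50, HC = 50))
  resid <- residualize_items(fx$cohort)
  nets <- estimate_group_networks(resid)
  expect_named(nets, c("CD", "RD", "SD", "HC"))
  solo <- estimate_network(resid[resid$group == "CD", ])
  expect_equal(nets$CD$W, solo$W)
})
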