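#' Build a random sparse precision model with known partial correlations
#'
#' Draws a random edge set of `floor(density * p(p-1)/2)` node pairs and
#' assigns each a partial correlation with magnitude uniform in
#' `weight_range`, signs drawn at random by default (`positive_only = TRUE`
#' makes every edge positive, but strongly limits how large the partials of a
#' dense positive-definite graph can be). A precision matrix is
#' assembled with unit diagonal and off-diagonal entries `-partial[i,j]`; if
#' it is not positive definite, all off-diagonal entries are shrunk by a
#' factor 0.9 repeatedly until the smallest eigenvalue is positive, which
#' preserves the zero pattern. The true partial correlations are always
#' recomputed from the final precision matrix.
#'
#' @param p Number of items (nodes).
#' @param density Fraction of the p(p-1)/2 pairs that carry an edge.
#' @param weight_range Length-2 numeric, absolute partial-correlation range.
#' @param positive_only If `TRUE` all partial correlations are positive.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @param max_shrink Iteration cap for the positive-definiteness shrinkage.
#' @return A `precision_model`: list with `precision`, `partials`,
#'   `edge_set` (tibble `i`, `j`, `partial`), `density`, `p`.
#' @export
#' @examples
#' m <- make_precision_model(p = 6, density = 0.3, seed = 1)
#' min(eigen(m$precision, symmetric = TRUE, only.values = TRUE)$values) > 0
make_precision_model <- function(p = 21, density = 0.2,
                                 weight_range = c(0.1, 0.3),
                                 positive_only = FALSE, seed = NULL,
                                 max_shrink = 200) {
  stopifnot(p >= 1, density >= 0, density <= 1,
            length(weight_range) == 2,
            weight_range[1] > 0 || density == 0,
            weight_range[1] <= weight_range[2], weight_range[2] < 1)
  run <- function() {
    n_pairs <- p * (p - 1L) / 2L
    n_edges <- floor(density * n_pairs)
    pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
    chosen <- if (n_edges > 0) sample.int(n_pairs, n_edges) else integer(0)
    partial <- matrix(0, p, p)
    if (n_edges > 0) {
      mag <- runif(n_edges, weight_range[1], weight_range[2])
      sgn <- if (positive_only) 1 else sample(c(-1, 1), n_edges, replace = TRUE)
      w <- mag * sgn
      ij <- pairs[chosen, , drop = FALSE]
      partial[ij] <- w
      partial[ij[, 2:1, drop = FALSE]] <- w
    }
    theta <- diag(p) - partial
    diag(theta) <- 1
    shrunk <- 0L
    while (min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8) {
      if (shrunk >= max_shrink) {
        stop("could not reach a positive-definite precision matrix; ",
             "try smaller weights or lower density", call. = FALSE)
      }
      off <- theta - diag(diag(theta))
      theta <- diag(diag(theta)) + 0.9 * off
      shrunk <- shrunk + 1L
    }
    partials <- partials_from_precision(theta)
    edge_idx <- which(upper.tri(partials) & partials != 0, arr.ind = TRUE)
    structure(
      list(
        precision = theta,
        partials = partials,
        edge_set = tibble::tibble(
          i = as.integer(edge_idx[, 1]),
          j = as.integer(edge_idx[, 2]),
          partial = partials[edge_idx]
        ),
        density = nrow(edge_idx) / max(1L, p * (p - 1L) / 2L),
        p = as.integer(p),
        shrink_steps = shrunk
      ),
      class = "precision_model"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Describe one simulated group
#'
#' An archetype bundles everything that distinguishes a simulated group apart
#' from its conditional-independence structure: its size, a per-item (or
#' scalar) latent severity shift, linear age and sex effects on the latent
#' scale, and the covariate distributions.
#'
#' @param name Group label.
#' @param n Group size.
#' @param mean_shift Scalar or length-p latent mean offset (severity).
#' @param age_effect,sex_effect Scalar or length-p linear coefficients on the
#'   latent scale (age effect is per year, applied to centred age).
#' @param age_mean,age_sd Normal age distribution parameters (years).
#' @param sex_prob Bernoulli probability of sex = 1.
#' @return A `group_archetype` list.
#' @export
group_archetype <- function(name, n, mean_shift = 0,
                            age_effect = 0, sex_effect = 0,
                            age_mean = 45, age_sd = 12, sex_prob = 0.5) {
  stopifnot(n >= 1, sex_prob >= 0, sex_prob <= 1, age_sd >= 0)
  structure(
    list(name = name, n = as.integer(n), mean_shift = mean_shift,
         age_effect = age_effect, sex_effect = sex_effect,
         age_mean = age_mean, age_sd = age_sd, sex_prob = sex_prob),
    class = "group_archetype"
  )
}

#' Latent-to-ordinal discretization rule
#'
#' Three strictly increasing cut points map a latent continuous value to the
#' ordinal scores 0/1/2/3. The default `(-0.5, 0.5, 1.5)` gives right-skewed
#' item distributions typical of community samples on a standard-normal
#' latent scale.
#'
#' @param thresholds Numeric length 3, strictly increasing.
#' @return A `discretization_rule` list.
#' @export
discretization_rule <- function(thresholds = c(-0.5, 0.5, 1.5)) {
  stopifnot(length(thresholds) == 3, all(diff(thresholds) > 0))
  structure(list(thresholds = thresholds), class = "discretization_rule")
}

# monotone latent -> {0,1,2,3}
discretize_latent <- function(x, rule) {
  findInterval(x, rule$thresholds)
}

#' Sample one group's cohort from a precision model
#'
#' Draws ages from the archetype's normal distribution and sex from a
#' Bernoulli, draws latent item vectors from the zero-mean multivariate
#' normal whose covariance is the inverse of the model precision, adds
#' `mean_shift + age_effect * (age - mean(age)) + sex_effect * sex` per item
#' on the latent scale, and discretizes with the rule's thresholds. The draw
#' is deterministic given `seed`.
#'
#' @param model A [make_precision_model()] result.
#' @param archetype A [group_archetype()].
#' @param rule A [discretization_rule()].
#' @param seed Optional integer seed.
#' @return A `cohort_tbl` with `archetype$n` rows and `model$p` items.
#' @export
sample_group <- function(model, archetype, rule = discretization_rule(),
                         seed = NULL) {
  stopifnot(inherits(model, "precision_model"),
            inherits(archetype, "group_archetype"),
            inherits(rule, "discretization_rule"))
  p <- model$p
  expand <- function(x, what) {
    if (length(x) == 1) rep(x, p)
    else if (length(x) == p) x
    else stop("archetype ", what, " must have length 1 or p", call. = FALSE)
  }
  shift <- expand(archetype$mean_shift, "mean_shift")
  b_age <- expand(archetype$age_effect, "age_effect")
  b_sex <- expand(archetype$sex_effect, "sex_effect")
  run <- function() {
    n <- archetype$n
    age <- rnorm(n, archetype$age_mean, archetype$age_sd)
    sex <- rbinom(n, 1, archetype$sex_prob)
    sigma <- solve(model$precision)
    latent <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma)
    latent <- matrix(latent, nrow = n, ncol = p)
    age_c <- age - mean(age)
    mu <- matrix(shift, n, p, byrow = TRUE) +
      outer(age_c, b_age) + outer(as.numeric(sex), b_sex)
    scores <- discretize_latent(latent + mu, rule)
    dim(scores) <- c(n, p)
    df <- as.data.frame(scores)
    names(df) <- paste0("item_", seq_len(p))
    df$age <- age
    df$sex <- sex
    df$group <- archetype$name
    as_cohort(df, cohort_schema(items = paste0("item_", seq_len(p))))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Default four-group study archetypes
#'
#' The shipped conditions mirror a four-group depression study: two clinical
#' groups (current and remitted depression) sharing one dense
#' conditional-dependence structure but differing in severity, a sparse
#' subthreshold-depression group, and a near-empty healthy-control group.
#' Group sizes default to 294/118/184/257.
#'
#' @param sizes Named integer vector of group sizes (CD, RD, SD, HC).
#' @return Named list of [group_archetype()]s.
#' @export
four_group_archetypes <- function(sizes = c(CD = 294, RD = 118,
                                            SD = 184, HC = 257)) {
  stopifnot(all(c("CD", "RD", "SD", "HC") %in% names(sizes)))
  list(
    CD = group_archetype("CD", sizes[["CD"]], mean_shift = 1.0,
                         age_effect = 0.01, sex_effect = 0.2),
    RD = group_archetype("RD", sizes[["RD"]], mean_shift = -0.1,
                         age_effect = 0.01, sex_effect = 0.2),
    SD = group_archetype("SD", sizes[["SD"]], mean_shift = 0.5,
                         age_effect = 0.01, sex_effect = 0.2),
    HC = group_archetype("HC", sizes[["HC"]], mean_shift = 0,
                         age_effect = 0.01, sex_effect = 0.2)
  )
}

#' Simulate the four-group synthetic study cohort
#'
#' Generates the package's standard test-bed: current depression (CD) and
#' remitted depression (RD) share one dense precision model (same structure,
#' different severity shift — the "trace" scenario), subthreshold depression
#' (SD) has its own sparse model, and healthy controls (HC) have an
#' empty-graph model (no true edges). Edge densities of the dense and sparse
#' structures default to 119 and 20 edges out of 210.
#'
#' The dense structure is redrawn (rejection sampling on the ground truth)
#' until its implied total covariation, `-log det` of the latent correlation
#' matrix, is at least `min_dependence_per_node * p` nats: a "dense" clinical
#' structure whose implied covariation is trivially weak would not emulate
#' the strongly interconnected symptom system the clinical groups display.
#' The sparse structure uses a stronger per-edge weight range
#' (`sparse_weight_range`): it represents the few retained connections of a
#' subthreshold group, which are its strongest ones.
#'
#' @param seed Integer seed; the whole fixture is deterministic given it.
#' @param p Number of items.
#' @param sizes Named group sizes, see [four_group_archetypes()].
#' @param dense_edges,sparse_edges,hc_edges Edge counts of the three true
#'   structures.
#' @param weight_range Absolute partial-correlation range of dense-structure
#'   edges.
#' @param sparse_weight_range Absolute partial-correlation range of
#'   sparse-structure edges.
#' @param min_dependence_per_node Rejection floor for the dense structure's
#'   total covariation, in nats per node (see Details).
#' @param rule Discretization rule.
#' @return List with `cohort` (all groups bound, a `cohort_tbl`), `cohorts`
#'   (per-group list), `models` (named list of `precision_model`s per group)
#'   and `archetypes`.
#' @export
#' @examples
#' fx <- four_group_fixture(seed = 1, p = 6, sizes = c(CD = 40, RD = 30,
#'                                                     SD = 30, HC = 30))
#' table(fx$cohort$group)
four_group_fixture <- function(seed = 1, p = 21,
                               sizes = c(CD = 294, RD = 118,
                                         SD = 184, HC = 257),
                               dense_edges = NULL, sparse_edges = NULL,
                               hc_edges = 0,
                               weight_range = c(0.12, 0.3),
                               sparse_weight_range = c(0.25, 0.4),
                               min_dependence_per_node = 0.6,
                               rule = discretization_rule()) {
  n_pairs <- p * (p - 1) / 2
  # default densities scale the study's 119/20 edge counts to p nodes
  if (is.null(dense_edges)) dense_edges <- round(n_pairs * 119 / 210)
  if (is.null(sparse_edges)) sparse_edges <- round(n_pairs * 20 / 210)
  archetypes <- four_group_archetypes(sizes)
  seeds <- derive_seeds(seed, 8)
  dense <- draw_dense_model(p, dense_edges / n_pairs, weight_range,
                            min_dependence_per_node * p, seed = seeds[1])
  sparse <- make_precision_model(p, sparse_edges / n_pairs,
                                 sparse_weight_range, seed = seeds[2])
  empty <- make_precision_model(p, hc_edges / n_pairs, weight_range,
                                seed = seeds[3])
  models <- list(CD = dense, RD = dense, SD = sparse, HC = empty)
  cohorts <- list(
    CD = sample_group(dense, archetypes$CD, rule, seed = seeds[4]),
    RD = sample_group(dense, archetypes$RD, rule, seed = seeds[5]),
    SD = sample_group(sparse, archetypes$SD, rule, seed = seeds[6]),
    HC = sample_group(empty, archetypes$HC, rule, seed = seeds[7])
  )
  cohort <- dplyr::bind_rows(lapply(cohorts, as.data.frame))
  cohort <- as_cohort(cohort,
                      cohort_schema(items = paste0("item_", seq_len(p))))
  cohort$group <- factor(cohort$group, levels = c("CD", "RD", "SD", "HC"))
  list(cohort = cohort, cohorts = cohorts, models = models,
       archetypes = archetypes, seed = seed)
}

# spawn reproducible child seeds below 2^31 from one master seed
derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, k))
}

# total covariation of a precision model: -log det of the implied latent
# correlation matrix (0 for independence, grows with overall dependence)
total_dependence <- function(model) {
  cor_mat <- stats::cov2cor(solve(model$precision))
  -as.numeric(determinant(cor_mat, logarithm = TRUE)$modulus)
}

# draw dense precision models until the implied total covariation reaches
# the floor; if no candidate qualifies within the draw budget (e.g. at small
# p, where the floor is out of reach) the strongest candidate is kept.
# Selection operates on the ground truth only.
draw_dense_model <- function(p, density, weight_range, min_dependence,
                             seed, max_draws = 50) {
  sub_seeds <- derive_seeds(seed, max_draws)
  best <- NULL
  best_dep <- -Inf
  for (s in sub_seeds) {
    m <- make_precision_model(p, density, weight_range, seed = s)
    dep <- total_dependence(m)
    if (dep >= min_dependence) return(m)
    if (dep > best_dep) {
      best <- m
      best_dep <- dep
    }
  }
  best
}
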