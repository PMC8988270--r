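#' Average Fruchterman-Reingold layout across group networks
#'
#' Computes a single force-directed layout on the element-wise mean of the
#' groups' absolute weight matrices, so all group networks can be drawn with
#' identical node positions. Coordinates are rescaled to the unit square and
#' are deterministic given `seed`.
#'
#' @param networks A `symptom_network`, a weight matrix, or a (named) list of
#'   either.
#' @param seed Integer seed for the layout's random initialisation.
#' @return A p x 2 matrix of coordinates in `[0, 1]^2`.
#' @export
average_layout <- function(networks, seed = NULL) {
  if (inherits(networks, "symptom_network") || is.matrix(networks)) {
    networks <- list(networks)
  }
  stopifnot(length(networks) >= 1)
  mats <- lapply(networks, function(x) abs(weight_matrix(x)))
  p <- nrow(mats[[1]])
  stopifnot(all(vapply(mats, nrow, numeric(1)) == p))
  A <- Reduce(`+`, mats) / length(mats)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  run <- function() {
    if (igraph::ecount(g) > 0) {
      igraph::layout_with_fr(g, weights = igraph::E(g)$weight)
    } else {
      igraph::layout_in_circle(g)
    }
  }
  xy <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  rescale01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0.5, length(v)) else (v - rng[1]) / diff(rng)
  }
  out <- cbind(x = rescale01(xy[, 1]), y = rescale01(xy[, 2]))
  rownames(out) <- NULL
  out
}

#' Configuration of the full analysis pipeline
#'
#' @param scope Residualization scope, `"per_group"` or `"pooled"`.
#' @param gamma,n_lambda,lambda_min_ratio Estimator settings.
#' @param nct_B Permutations per network comparison test.
#' @param boot_B Bootstrap resamples for edge CIs.
#' @param casedrop_B Subsamples per drop proportion.
#' @param casedrop_proportions Drop-proportion grid.
#' @param cs_cor_floor,cs_prob CS-coefficient parameters.
#' @param run_nct,run_stability Stage toggles.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scope = "per_group", gamma = 0.5,
                            n_lambda = 100, lambda_min_ratio = 0.01,
                            nct_B = 5000, boot_B = 2500, casedrop_B = 1000,
                            casedrop_proportions = seq(0.05, 0.75, by = 0.05),
                            cs_cor_floor = 0.7, cs_prob = 0.95,
                            run_nct = TRUE, run_stability = TRUE, seed = 1) {
  structure(
    list(scope = scope, gamma = gamma, n_lambda = n_lambda,
         lambda_min_ratio = lambda_min_ratio, nct_B = nct_B,
         boot_B = boot_B, casedrop_B = casedrop_B,
         casedrop_proportions = casedrop_proportions,
         cs_cor_floor = cs_cor_floor, cs_prob = cs_prob,
         run_nct = run_nct, run_stability = run_stability,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("read_pipeline_config: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Run the full four-group network analysis
#'
#' Orchestrates the pipeline end to end: residualize item scores on age and
#' sex, estimate one regularized partial-correlation network per group,
#' compute centralities, compare groups (chi-square on nonzero-edge ratios
#' with Holm correction; permutation network comparison tests on global
#' strength and structure, each family Holm-corrected), run the stability
#' stage (bootstrap edge CIs and case-dropping CS-coefficients per group),
#' and compute a group-average layout. Stage errors abort with a
#' stage-named message. Every stochastic stage gets a seed derived from
#' `config$seed`, so the report is deterministic given the config.
#'
#' @param cohort A `cohort_tbl` (see [as_cohort()], [read_cohort_csv()]).
#' @param config A [pipeline_config()].
#' @return A `symptomnet_report` list: `networks`, `edges`, `centrality`,
#'   `residual_means`, `edge_count_tests`, `nct`, `stability`, `layout`,
#'   `provenance`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 4)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  resid <- stage("residualize", residualize_items(cohort, scope = config$scope))
  # descriptive residual means use a pooled adjustment so group contrasts
  # are visible (per-group residuals are mean-zero by construction)
  res_means <- stage("residual_means", {
    residual_means(residualize_items(cohort, scope = "pooled"))
  })
  networks <- stage("estimate", estimate_group_networks(
    resid, gamma = config$gamma, n_lambda = config$n_lambda,
    lambda_min_ratio = config$lambda_min_ratio
  ))
  edges <- purrr::imap(networks, function(net, g) {
    out <- tidy(net)
    out$group <- g
    out
  })
  edges <- dplyr::bind_rows(edges)[, c("group", "item_i", "item_j", "weight")]
  cent <- stage("centrality", centrality_by_group(networks))
  ect <- stage("edge_count_test", edge_count_test(networks))
  nct_tab <- if (config$run_nct) {
    stage("nct", compare_networks(
      resid, B = config$nct_B, seed = seeds[1], gamma = config$gamma,
      n_lambda = config$n_lambda, lambda_min_ratio = config$lambda_min_ratio
    ))
  } else NULL
  stability <- if (config$run_stability) {
    stage("stability", {
      boot_seeds <- derive_seeds(seeds[2], length(networks))
      drop_seeds <- derive_seeds(seeds[3], length(networks))
      purrr::imap(networks, function(net, g) {
        gr <- residuals_for_group(resid, g)
        eb <- bootstrap_edges(gr, B = config$boot_B,
                              seed = boot_seeds[match(g, names(networks))],
                              gamma = config$gamma,
                              n_lambda = config$n_lambda,
                              lambda_min_ratio = config$lambda_min_ratio)
        cd <- case_dropping(gr, proportions = config$casedrop_proportions,
                            B = config$casedrop_B,
                            seed = drop_seeds[match(g, names(networks))],
                            gamma = config$gamma,
                            n_lambda = config$n_lambda,
                            lambda_min_ratio = config$lambda_min_ratio)
        list(edge_bootstrap = eb,
             case_dropping = cd,
             cs = cs_coefficient(cd, cor_floor = config$cs_cor_floor,
                                 prob = config$cs_prob))
      })
    })
  } else NULL
  layout <- stage("layout", average_layout(networks, seed = seeds[4]))

  structure(
    list(
      networks = networks, edges = edges, centrality = cent,
      residual_means = res_means, edge_count_tests = ect, nct = nct_tab,
      stability = stability, layout = layout,
      provenance = list(
        seed = config$seed, config = unclass(config),
        groups = names(networks),
        n_per_group = as.list(table(cohort$group)),
        package_version = as.character(utils::packageVersion("symptomnet"))
      )
    ),
    class = "symptomnet_report"
  )
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (everything, including provenance) plus flat CSVs:
#' per-group `edges_<group>.csv`, `centrality.csv`, `comparisons.csv`,
#' `stability_<group>.csv` and `layout.csv`.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "symptomnet_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(report$networks)) {
    write_edge_list(report$networks[[g]],
                    file.path(dir, paste0("edges_", g, ".csv")))
  }
  readr::write_csv(report$centrality, file.path(dir, "centrality.csv"),
                   progress = FALSE)
  comparisons <- dplyr::bind_rows(
    dplyr::mutate(as.data.frame(report$edge_count_tests),
                  test = "edge_count_chisq"),
    if (!is.null(report$nct)) {
      dplyr::mutate(as.data.frame(report$nct), test = "nct")
    }
  )
  readr::write_csv(comparisons, file.path(dir, "comparisons.csv"),
                   progress = FALSE)
  if (!is.null(report$stability)) {
    for (g in names(report$stability)) {
      readr::write_csv(
        as.data.frame(report$stability[[g]]$edge_bootstrap),
        file.path(dir, paste0("stability_", g, ".csv")), progress = FALSE
      )
    }
  }
  layout_df <- tibble::tibble(item = seq_len(nrow(report$layout)),
                              x = report$layout[, 1], y = report$layout[, 2])
  readr::write_csv(layout_df, file.path(dir, "layout.csv"), progress = FALSE)

  json <- list(
    provenance = report$provenance,
    networks = purrr::map(report$networks, function(net) {
      list(p = net$p, n = net$n, gamma = net$gamma,
           lambda_selected = net$lambda_selected,
           nonzero_edge_count = net$nonzero_edge_count,
           global_strength = global_strength(net),
           weights = net$W)
    }),
    residual_means = report$residual_means,
    centrality = report$centrality,
    edge_count_tests = as.data.frame(report$edge_count_tests),
    nct = if (!is.null(report$nct)) as.data.frame(report$nct),
    stability = if (!is.null(report$stability)) {
      purrr::map(report$stability, function(s) {
        list(edge_bootstrap = as.data.frame(s$edge_bootstrap),
             case_dropping = as.data.frame(tidy(s$case_dropping)),
             cs = as.data.frame(s$cs))
      })
    },
    layout = report$layout
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(dir)
}

#' @export
print.symptomnet_report <- function(x, ...) {
  cat("<symptomnet_report>", length(x$networks), "group network(s)\n")
  for (g in names(x$networks)) {
    net <- x$networks[[g]]
    cat(sprintf("  %-4s n = %4d, nonzero edges = %3d, global strength = %.3f\n",
                g, net$n, net$nonzero_edge_count, global_strength(net)))
  }
  invisible(x)
}
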