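#' Remove linear age and sex effects from item scores
#'
#' Regresses every item score on an intercept, age and sex by ordinary least
#' squares and returns the residuals, which are the inputs to all network
#' estimation. By default each group gets its own regressions
#' (`scope = "per_group"`); `scope = "pooled"` fits one regression per item
#' across the full sample. A covariate that is constant within the regression
#' sample is dropped from the design (with a message), so with both
#' covariates constant the residual is simply the deviation from the item
#' mean.
#'
#' @param cohort A `cohort_tbl` (see [as_cohort()]).
#' @param scope `"per_group"` or `"pooled"`.
#' @return A tibble of class `symptom_residuals` with one column per item
#'   (residual scores) plus `group`; attributes `items` and `scope`.
#' @export
#' @examples
#' fx <- four_group_fixture(seed = 1, p = 5,
#'                          sizes = c(CD = 30, RD = 30, SD = 30, HC = 30))
#' r <- residualize_items(fx$cohort)
#' colMeans(as.matrix(r[r$group == "CD", attr(r, "items")]))
residualize_items <- function(cohort, scope = c("per_group", "pooled")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(cohort))
  item_cols <- attr(cohort, "items")
  if (is.null(item_cols)) {
    item_cols <- grep("^item_", names(cohort), value = TRUE)
  }
  stopifnot(length(item_cols) >= 1,
            all(c("age", "sex", "group") %in% names(cohort)))
  if (nrow(cohort) < 4) {
    stop("residualize_items: need at least 4 rows", call. = FALSE)
  }

  resid_block <- function(block) {
    n <- nrow(block)
    X <- cbind(intercept = rep(1, n))
    dropped <- character(0)
    for (cv in c("age", "sex")) {
      v <- as.numeric(block[[cv]])
      if (length(unique(v)) > 1) X <- cbind(X, v) else dropped <- c(dropped, cv)
    }
    if (length(dropped) > 0) {
      message("residualize_items: constant covariate(s) dropped from design: ",
              paste(dropped, collapse = ", "))
    }
    if (n <= ncol(X)) {
      stop("residualize_items: fewer rows (", n,
           ") than design columns (", ncol(X), ")", call. = FALSE)
    }
    Y <- as.matrix(block[, item_cols, drop = FALSE])
    storage.mode(Y) <- "double"
    fit <- lm.fit(X, Y)
    R <- as.matrix(fit$residuals)
    colnames(R) <- item_cols
    R
  }

  if (scope == "pooled") {
    res <- resid_block(cohort)
    group <- cohort$group
  } else {
    groups <- unique(cohort$group)
    parts <- vector("list", length(groups))
    idx <- vector("list", length(groups))
    for (g in seq_along(groups)) {
      sel <- which(cohort$group == groups[g])
      parts[[g]] <- resid_block(cohort[sel, , drop = FALSE])
      idx[[g]] <- sel
    }
    res <- matrix(NA_real_, nrow(cohort), length(item_cols),
                  dimnames = list(NULL, item_cols))
    for (g in seq_along(groups)) res[idx[[g]], ] <- parts[[g]]
    group <- cohort$group
  }

  out <- tibble::as_tibble(as.data.frame(res))
  out$group <- group
  attr(out, "items") <- item_cols
  attr(out, "scope") <- scope
  class(out) <- c("symptom_residuals", class(out))
  out
}

# numeric residual matrix of a symptom_residuals tibble (or plain matrix)
residual_matrix <- function(resid) {
  if (is.matrix(resid)) return(resid)
  item_cols <- attr(resid, "items")
  if (is.null(item_cols)) {
    item_cols <- setdiff(names(resid), "group")
  }
  as.matrix(resid[, item_cols, drop = FALSE])
}

# subset a symptom_residuals tibble to one group, keeping attributes
residuals_for_group <- function(resid, group) {
  out <- resid[resid$group == group, , drop = FALSE]
  attr(out, "items") <- attr(resid, "items")
  attr(out, "scope") <- attr(resid, "scope")
  class(out) <- unique(c("symptom_residuals", class(out)))
  out
}

#' Per-group mean residual item scores
#'
#' Descriptive table of the covariate-adjusted item means per group (the
#' pipeline's analogue of a residual-score table).
#'
#' @param resid A `symptom_residuals` tibble.
#' @return A tibble `group`, `item`, `mean_residual`.
#' @export
residual_means <- function(resid) {
  item_cols <- attr(resid, "items")
  resid |>
    tidyr::pivot_longer(dplyr::all_of(item_cols),
                        names_to = "item", values_to = "residual") |>
    dplyr::group_by(.data$group, .data$item) |>
    dplyr::summarise(mean_residual = mean(.data$residual), .groups = "drop")
}
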