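#' Item metadata for the 21-item depression inventory
#'
#' Returns the bundled item table: 1-based item id, short label, and the
#' three-factor symptom category (`negative_attitude`,
#' `performance_difficulty`, `somatic_elements`) used to colour nodes in
#' network figures.
#'
#' @return A tibble with columns `item_id`, `label`, `category`.
#' @export
#' @examples
#' bdi_items()
bdi_items <- function() {
  path <- system.file("extdata", "bdi_items.yaml", package = "symptomnet")
  raw <- yaml::read_yaml(path)$items
  out <- tibble::tibble(
    item_id = vapply(raw, function(x) as.integer(x$id), integer(1)),
    label = vapply(raw, function(x) x$label, character(1)),
    category = vapply(raw, function(x) x$category, character(1))
  )
  stopifnot(
    identical(out$item_id, 1:21),
    all(out$category %in% c(
      "negative_attitude", "performance_difficulty", "somatic_elements"
    ))
  )
  out
}

#' Describe the columns of a cohort CSV
#'
#' A schema maps the columns of an arbitrary cohort file onto the fields the
#' pipeline needs: `p` item-score columns (ordinal 0-3), an age column, a sex
#' column (any two-level coding) and a group label column.
#'
#' @param items Character vector of item column names, in item order.
#' @param age,sex,group Names of the covariate and group columns.
#' @return A `cohort_schema` list.
#' @export
cohort_schema <- function(items = paste0("item_", 1:21),
                          age = "age", sex = "sex", group = "group") {
  stopifnot(length(items) >= 1, !anyDuplicated(items))
  structure(
    list(items = items, age = age, sex = sex, group = group),
    class = "cohort_schema"
  )
}

#' Construct a validated cohort table from a data frame
#'
#' Coerces a participant-level data frame into the cohort format used by the
#' pipeline: `p` integer item scores in 0-3, numeric `age`, binary `sex` and
#' a `group` factor. Rows with any missing value in a mapped column are
#' dropped listwise (the count is reported via a message). A two-level `sex`
#' column of any type is recoded to 0/1 by sorted level order.
#'
#' @param data A data frame.
#' @param schema A [cohort_schema()] describing which columns hold what.
#' @return A tibble of class `cohort_tbl` with item columns named
#'   `item_1 ... item_p` plus `age`, `sex`, `group`; the item-column names are
#'   kept in `attr(, "items")`.
#' @export
as_cohort <- function(data, schema = cohort_schema()) {
  stopifnot(is.data.frame(data), inherits(schema, "cohort_schema"))
  needed <- c(schema$items, schema$age, schema$sex, schema$group)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- data[, needed, drop = FALSE]
  p <- length(schema$items)
  names(df) <- c(paste0("item_", seq_len(p)), "age", "sex", "group")

  keep <- stats::complete.cases(df)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message("as_cohort: dropped ", dropped,
            " row(s) with missing values (listwise deletion)")
  }
  df <- df[keep, , drop = FALSE]

  item_cols <- paste0("item_", seq_len(p))
  for (col in item_cols) {
    v <- df[[col]]
    bad <- which(!(v %in% 0:3))
    if (length(bad) > 0) {
      stop(sprintf(
        "cohort validation error: %s has value %s at row %d (item scores must be in 0..3)",
        col, format(v[bad[1]]), bad[1]
      ), call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }

  df$age <- as.numeric(df$age)
  sex_levels <- sort(unique(df$sex))
  if (length(sex_levels) > 2) {
    stop("cohort validation error: sex column has more than 2 levels",
         call. = FALSE)
  }
  if (!all(as.character(sex_levels) %in% c("0", "1"))) {
    message("as_cohort: sex recoded by sorted level order: ",
            paste0(format(sex_levels), " -> ",
                   seq_along(sex_levels) - 1L, collapse = ", "))
  }
  df$sex <- as.integer(match(df$sex, sex_levels) - 1L)
  df$group <- factor(df$group)

  out <- tibble::as_tibble(df)
  attr(out, "items") <- item_cols
  attr(out, "n_dropped") <- dropped
  class(out) <- c("cohort_tbl", class(out))
  out
}

#' Read a cohort CSV
#'
#' Reads a comma-separated, UTF-8, header-first cohort file and validates it
#' via [as_cohort()]: item scores must lie in 0-3, rows with missing mapped
#' values are dropped listwise, and sex is recoded to 0/1.
#'
#' @param path Path to the CSV file.
#' @param schema A [cohort_schema()]; defaults to 21 items named
#'   `item_1 ... item_21`.
#' @return A `cohort_tbl` tibble.
#' @export
read_cohort_csv <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_cohort(raw, schema)
}

#' Write a cohort table to CSV
#'
#' @param cohort A `cohort_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(as.data.frame(cohort), path, progress = FALSE)
  invisible(path)
}

# item-score matrix of a cohort (n x p, integer)
cohort_items <- function(cohort) {
  item_cols <- attr(cohort, "items")
  if (is.null(item_cols)) {
    item_cols <- grep("^item_", names(cohort), value = TRUE)
  }
  as.matrix(cohort[, item_cols, drop = FALSE])
}

#' Write the edge list of an estimated network
#'
#' Serialises a symptom network as a CSV with columns `item_i`, `item_j`,
#' `weight` for node pairs i < j. By default only nonzero edges are written;
#' `dense = TRUE` writes all p(p-1)/2 pairs including zero weights.
#'
#' @param network A `symptom_network` from [estimate_network()].
#' @param path Output path.
#' @param dense Write zero-weight pairs too?
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path, dense = FALSE) {
  edges <- tidy(network, dense = dense)
  readr::write_csv(edges, path, progress = FALSE)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path CSV path with columns `item_i`, `item_j`, `weight`.
#' @param p Number of nodes; defaults to the largest index present.
#' @return A symmetric p x p weight matrix with zero diagonal.
#' @export
read_edge_list <- function(path, p = NULL) {
  edges <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("item_i", "item_j", "weight") %in% names(edges)))
  if (is.null(p)) p <- max(0L, edges$item_i, edges$item_j)
  W <- matrix(0, p, p)
  if (nrow(edges) > 0) {
    W[cbind(edges$item_i, edges$item_j)] <- edges$weight
    W[cbind(edges$item_j, edges$item_i)] <- edges$weight
  }
  W
}
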