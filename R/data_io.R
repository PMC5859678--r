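#' Construct a multilevel dataset
#'
#' A `mlcfa_data` object holds continuous indicator scores for lowest-level
#' units (e.g. pupils) nested in clusters (e.g. schools). Rows are sorted
#' ascending by cluster then case identifier; identifiers are treated as
#' opaque character labels (so `"01"` and `"1"` are distinct clusters).
#'
#' @param values numeric matrix or data frame, one row per lowest-level
#'   unit, one column per indicator. Cells equal to `missing_code` are
#'   recoded to `NA` internally.
#' @param cluster_id vector of cluster (between-level unit) labels, one per
#'   row.
#' @param case_id vector of case labels, unique within cluster. Defaults to
#'   the running row number within each cluster.
#' @param labels indicator names; defaults to `colnames(values)`.
#' @param missing_code numeric sentinel marking missing cells
#'   (default -999999).
#' @return An object of class `mlcfa_data` with components `values`
#'   (numeric matrix, `NA` for missing), `cluster_id`, `case_id`, `labels`,
#'   `missing_code`, `N`, `G`, `p` and `n_g` (named per-cluster sizes).
#' @examples
#' d <- multilevel_dataset(matrix(rnorm(20), 10, 2,
#'                                dimnames = list(NULL, c("a", "b"))),
#'                         cluster_id = rep(1:2, each = 5))
#' d$G
#' @export
multilevel_dataset <- function(values, cluster_id, case_id = NULL,
                               labels = NULL, missing_code = -999999) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("indicator values must be numeric", call. = FALSE)
  if (is.null(labels)) labels <- colnames(values)
  if (is.null(labels)) labels <- paste0("y", seq_len(ncol(values)))
  labels <- as.character(labels)
  if (anyDuplicated(labels) || any(!nzchar(labels)))
    stop("indicator labels must be unique and non-empty", call. = FALSE)
  if (length(labels) != ncol(values))
    stop("length of 'labels' must match the number of indicator columns",
         call. = FALSE)
  colnames(values) <- labels
  cluster_id <- as.character(cluster_id)
  if (length(cluster_id) != nrow(values))
    stop("'cluster_id' must have one entry per row", call. = FALSE)
  if (is.null(case_id)) {
    case_id <- stats::ave(seq_along(cluster_id), cluster_id,
                          FUN = seq_along)
    case_id <- formatC(case_id, width = max(nchar(case_id)), flag = "0")
  }
  case_id <- as.character(case_id)
  if (length(case_id) != nrow(values))
    stop("'case_id' must have one entry per row", call. = FALSE)
  if (anyDuplicated(paste(cluster_id, case_id, sep = "\r")))
    stop("case_id must be unique within cluster", call. = FALSE)

  values[!is.na(values) & values == missing_code] <- NA_real_

  ord <- order(cluster_id, case_id)
  values <- values[ord, , drop = FALSE]
  cluster_id <- cluster_id[ord]
  case_id <- case_id[ord]

  n_g <- table(cluster_id)
  if (length(n_g) < 2)
    stop("at least 2 distinct clusters are required (found ",
         length(n_g), ")", call. = FALSE)

  structure(list(values = values, cluster_id = cluster_id,
                 case_id = case_id, labels = labels,
                 missing_code = missing_code,
                 N = nrow(values), G = length(n_g), p = ncol(values),
                 n_g = c(n_g)),
            class = "mlcfa_data")
}

#' Read a long-format clustered dataset from delimited text
#'
#' Reads a CSV or TSV file (auto-detected from the extension: `.tsv`/`.txt`
#' are tab-delimited, anything else comma-delimited) with a header row, one
#' row per lowest-level unit. All columns other than the cluster and case
#' identifier columns are taken as indicators and must be numeric apart
#' from cells equal to `missing_code`.
#'
#' @param path path to the delimited text file.
#' @param cluster_col,case_col names of the cluster and case identifier
#'   columns. `case_col = NULL` generates case labels by row order within
#'   cluster.
#' @param missing_code numeric sentinel for missing cells.
#' @return A validated [multilevel_dataset()].
#' @export
read_dataset <- function(path, cluster_col = "cluster", case_col = "case",
                         missing_code = -999999) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c(cluster_col, if (!is.null(case_col)) case_col)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("column(s) not found in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  ind_cols <- setdiff(names(raw), need)
  if (!length(ind_cols))
    stop("no indicator columns left after removing identifier columns",
         call. = FALSE)
  vals <- matrix(NA_real_, nrow(raw), length(ind_cols),
                 dimnames = list(NULL, ind_cols))
  for (j in ind_cols) {
    x <- trimws(raw[[j]])
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(num) & nzchar(x) & !is.na(x))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s', data row %d",
                   x[bad[1]], j, bad[1]), call. = FALSE)
    vals[, j] <- num
  }
  multilevel_dataset(vals, cluster_id = raw[[cluster_col]],
                     case_id = if (!is.null(case_col)) raw[[case_col]],
                     missing_code = missing_code)
}

#' Write a multilevel dataset to delimited text
#'
#' Inverse of [read_dataset()]: writes a header row, the cluster and case
#' identifier columns, and the indicator columns, with missing cells
#' written as the dataset's `missing_code`. `read_dataset()` on the result
#' reproduces the values exactly for finite inputs.
#'
#' @param ds a `mlcfa_data` object.
#' @param path output path (`.tsv`/`.txt` for tab-delimited, else CSV).
#' @param cluster_col,case_col column names used for the identifiers.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, cluster_col = "cluster",
                          case_col = "case") {
  stopifnot(inherits(ds, "mlcfa_data"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  vals <- ds$values
  vals[is.na(vals)] <- ds$missing_code
  out <- data.frame(ds$cluster_id, ds$case_id, vals,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[1:2] <- c(cluster_col, case_col)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Apply a missing-data policy
#'
#' `listwise` drops every row with at least one missing indicator and
#' revalidates (a cluster losing all its rows is removed with a warning).
#' `pairwise` keeps all rows and records, for every indicator pair, the
#' number of rows on which both are observed; the covariance decomposition
#' then uses pairwise-complete sums, and the effective sample size carried
#' into likelihoods is the minimum pairwise complete count (a conservative
#' choice, since pairwise matrices need not be positive semidefinite).
#'
#' @param ds a `mlcfa_data` object.
#' @param policy `"listwise"` (default) or `"pairwise"`.
#' @return For `listwise`, a filtered `mlcfa_data`. For `pairwise`, the
#'   input with attributes `na_policy = "pairwise"`, `pairwise_n` (p x p
#'   complete-pair counts) and `effective_n` (minimum pairwise count).
#' @export
apply_missing_policy <- function(ds, policy = c("listwise", "pairwise")) {
  stopifnot(inherits(ds, "mlcfa_data"))
  policy <- match.arg(policy)
  obs <- !is.na(ds$values)
  if (any(colSums(obs) == 0))
    stop("all rows missing for indicator(s): ",
         paste(ds$labels[colSums(obs) == 0], collapse = ", "),
         call. = FALSE)
  if (policy == "listwise") {
    keep <- rowSums(!obs) == 0
    if (all(keep)) return(ds)
    lost <- setdiff(unique(ds$cluster_id), unique(ds$cluster_id[keep]))
    if (length(lost))
      warning("cluster(s) removed entirely by listwise deletion: ",
              paste(lost, collapse = ", "), call. = FALSE)
    multilevel_dataset(ds$values[keep, , drop = FALSE],
                       cluster_id = ds$cluster_id[keep],
                       case_id = ds$case_id[keep],
                       labels = ds$labels,
                       missing_code = ds$missing_code)
  } else {
    pn <- crossprod(obs)
    dimnames(pn) <- list(ds$labels, ds$labels)
    attr(ds, "na_policy") <- "pairwise"
    attr(ds, "pairwise_n") <- pn
    attr(ds, "effective_n") <- min(pn)
    ds
  }
}

#' @export
print.mlcfa_data <- function(x, ...) {
  cat("Multilevel dataset:", x$N, "cases in", x$G, "clusters,",
      x$p, "indicators\n")
  cat("  indicators:", paste(x$labels, collapse = ", "), "\n")
  cat("  cluster sizes: min", min(x$n_g), "/ mean",
      round(mean(x$n_g), 2), "/ max", max(x$n_g), "\n")
  nm <- sum(is.na(x$values))
  if (nm) cat("  missing cells:", nm, "\n")
  invisible(x)
}
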