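#' Run the three-step multilevel CFA workflow
#'
#' Executes the full screening-and-comparison pipeline on a clustered
#' dataset: (1) covariance decomposition and ICC screening, with an
#' advisory when no indicator ICC exceeds the threshold (multilevel
#' modeling then not indicated); (2) the requested model fits — one-level
#' CFA and the maximum model for the step-1 congruence check, MCFA for
#' the step-3 between-level assessment; (3) level-appropriate fit
#' statistics and the tabulated comparison with congruence diagnostics.
#' A congruence flag is raised when any within-loading relative
#' difference exceeds 10 percent in magnitude or any contrast has
#' `|t| > 1.96`.
#'
#' @param data a `mlcfa_data` object or a path for [read_dataset()].
#' @param within a [factor_pattern()] for the within level (also used as
#'   the one-level CFA structure).
#' @param between a [factor_pattern()] for the between level (required
#'   when `"mcfa"` is among `models`).
#' @param models character subset of `c("cfa", "max_mcfa", "mcfa")`.
#' @param na_policy `"listwise"` or `"pairwise"`.
#' @param icc_threshold advisory threshold on the largest indicator ICC
#'   (default 0.05).
#' @param cluster_col,case_col,missing_code passed to [read_dataset()]
#'   when `data` is a path.
#' @return An object of class `mlcfa_bundle`: `decomp`, `icc`, `fits`
#'   (named list), `comparison`, `advisories` (character), `log`
#'   (character).
#' @export
run_workflow <- function(data, within, between = NULL,
                         models = c("cfa", "max_mcfa", "mcfa"),
                         na_policy = c("listwise", "pairwise"),
                         icc_threshold = 0.05,
                         cluster_col = "cluster", case_col = "case",
                         missing_code = -999999) {
  na_policy <- match.arg(na_policy)
  models <- match.arg(models, c("cfa", "max_mcfa", "mcfa"),
                      several.ok = TRUE)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  if (is.character(data)) {
    data <- read_dataset(data, cluster_col, case_col, missing_code)
    note("read dataset: N = ", data$N, ", G = ", data$G)
  }
  stopifnot(inherits(data, "mlcfa_data"))
  if (anyNA(data$values)) {
    data <- apply_missing_policy(data, na_policy)
    note("missing-data policy: ", na_policy)
  }
  decomp <- compute_decomposition(data)
  note(sprintf("decomposition: N = %d, G = %d, c = %.4f",
               decomp$N, decomp$G, decomp$c))
  icc <- icc_table(decomp)
  advisories <- character(0)
  if (max(icc$icc) <= icc_threshold) {
    advisories <- c(advisories, "multilevel modeling not indicated")
    note("all indicator ICCs <= ", icc_threshold,
         ": multilevel modeling not indicated")
  } else {
    note(sprintf("max ICC = %.3f (> %.2f): multilevel structure indicated",
                 max(icc$icc), icc_threshold))
  }

  if ("mcfa" %in% models && is.null(between))
    stop("'between' pattern required when fitting an MCFA", call. = FALSE)

  fits <- list()
  for (m in models) {
    model <- switch(m,
      cfa = build_model("cfa", within = within),
      max_mcfa = build_model("max_mcfa", within = within),
      mcfa = build_model("mcfa", within = within, between = between))
    fits[[m]] <- fit_model(model, decomp)
    note(m, ": F_min = ", format(fits[[m]]$F_min, digits = 6),
         if (fits[[m]]$converged) ", converged" else ", NOT converged")
  }

  comparison <- if (length(fits)) build_comparison(fits, decomp)
  if (!is.null(comparison$diagnostics)) {
    incongruent <-
      any(abs(comparison$diagnostics$rel_diff_pct) > 10, na.rm = TRUE) ||
      any(abs(comparison$diagnostics$t) > 1.96, na.rm = TRUE)
    if (incongruent) {
      advisories <- c(advisories,
                      "CFA and within-level estimates incongruent")
      note("congruence flag raised: CFA vs within-level estimates ",
           "differ (|rel diff| > 10% or |t| > 1.96)")
    } else note("congruence check passed")
  }
  structure(list(decomp = decomp, icc = icc, fits = fits,
                 comparison = comparison, advisories = advisories,
                 log = log),
            class = "mlcfa_bundle")
}

write_matrix <- function(M, path) {
  utils::write.table(data.frame(indicator = rownames(M), M,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Export a workflow bundle to files
#'
#' Writes a deterministic report set: the three decomposition matrices as
#' labeled TSV, a JSON summary (N, G, c, per-indicator ICC), per-model
#' JSON results at full precision, the comparison table as TSV, and a
#' plain-text report rounded to 3 decimals. Every number in the text
#' report is present unrounded in the JSON output.
#'
#' @param bundle a `mlcfa_bundle` from [run_workflow()].
#' @param dir output directory (created if absent).
#' @param formats subset of `c("text", "tsv", "json")`.
#' @return invisibly, the paths written.
#' @export
export_report <- function(bundle, dir,
                          formats = c("text", "tsv", "json")) {
  stopifnot(inherits(bundle, "mlcfa_bundle"))
  formats <- match.arg(formats, c("text", "tsv", "json"),
                       several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(p) { paths <<- c(paths, p); p }

  if ("tsv" %in% formats) {
    for (nm in c("S_T", "S_PW", "S_B"))
      write_matrix(bundle$decomp[[nm]],
                   put(file.path(dir, paste0(nm, ".tsv"))))
    if (!is.null(bundle$comparison)) {
      utils::write.table(bundle$comparison$fit_block,
                         put(file.path(dir, "fit_block.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(bundle$comparison$param_block,
                         put(file.path(dir, "param_block.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  if ("json" %in% formats) {
    dec <- bundle$decomp
    summary <- list(N = dec$N, G = dec$G, c = dec$c,
                    icc = stats::setNames(as.list(bundle$icc$icc),
                                          bundle$icc$indicator),
                    advisories = bundle$advisories)
    jsonlite::write_json(summary, put(file.path(dir, "summary.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res <- lapply(bundle$fits, function(f)
      list(kind = f$model$kind,
           estimates = as.list(f$estimates),
           se = as.list(f$se),
           F_min = f$F_min, converged = f$converged,
           n_iter = f$n_iter, gradient_norm = f$gradient_norm))
    jsonlite::write_json(res, put(file.path(dir, "fits.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(bundle$comparison))
      jsonlite::write_json(
        list(fit_block = bundle$comparison$fit_block,
             param_block = bundle$comparison$param_block,
             diagnostics = bundle$comparison$diagnostics,
             n_flagged = bundle$comparison$n_flagged),
        put(file.path(dir, "comparison.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  }
  if ("text" %in% formats) {
    p <- put(file.path(dir, "report.txt"))
    con <- file(p, "w"); on.exit(close(con))
    writeLines(c("Multilevel CFA workflow report", "",
                 bundle$log, ""), con)
    sink(con)
    print(bundle$icc, digits = 3)
    if (!is.null(bundle$comparison)) print(bundle$comparison)
    sink()
  }
  invisible(paths)
}

#' @export
print.mlcfa_bundle <- function(x, ...) {
  cat("Multilevel CFA workflow bundle\n")
  for (l in x$log) cat("  -", l, "\n")
  if (length(x$advisories))
    cat("advisories:", paste(x$advisories, collapse = "; "), "\n")
  if (!is.null(x$comparison)) { cat("\n"); print(x$comparison) }
  invisible(x)
}
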