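#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, multiply `p_(i)` by `n/i`, take
#' the running minimum from the largest rank down (monotone enforcement),
#' cap at 1, and return in the original order.
#'
#' @param pvalues Numeric vector, all in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("argument error: p-values must all lie in [0, 1]")
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Filter a differential-expression table
#'
#' Retains genes with `padj < padj_max` (strict, as printed), absolute
#' log2 fold change at least `abs_lfc_min` (inclusive) and sign matching
#' `direction`. Rows lacking `padj` are adjusted from `pvalue` via
#' [bh_adjust()] first (over the whole table); rows lacking both are a
#' validation error. Input order is preserved.
#'
#' @param records data.frame with columns `gene_id`, `log2fc`, and `padj`
#'   and/or `pvalue`.
#' @param padj_max Adjusted-significance cutoff (strict `<`), default 0.05.
#' @param abs_lfc_min Absolute log2 fold-change cutoff (inclusive `>=`),
#'   default 1.5.
#' @param direction `"both"`, `"up"` (log2fc > 0) or `"down"` (< 0).
#' @return The retained rows, original order and columns (with `padj`
#'   filled in when it had to be computed).
#' @export
filter_degs <- function(records, padj_max = 0.05, abs_lfc_min = 1.5,
                        direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(records))
  if (!nrow(records)) return(records)
  if (!all(c("gene_id", "log2fc") %in% names(records)))
    stop("records must have columns gene_id and log2fc")
  if (is.null(records$padj) || all(is.na(records$padj))) {
    if (is.null(records$pvalue))
      stop("validation error: records lack both pvalue and padj")
    records$padj <- bh_adjust(records$pvalue)
  } else if (anyNA(records$padj)) {
    if (is.null(records$pvalue) || anyNA(records$pvalue[is.na(records$padj)]))
      stop("validation error: records lack both pvalue and padj")
    records$padj[is.na(records$padj)] <-
      bh_adjust(records$pvalue)[is.na(records$padj)]
  }
  keep <- records$padj < padj_max & abs(records$log2fc) >= abs_lfc_min
  keep <- keep & switch(direction,
                        both = TRUE,
                        up = records$log2fc > 0,
                        down = records$log2fc < 0)
  records[which(keep), , drop = FALSE]
}

norm_gene <- function(x) toupper(trimws(x))

#' Cross-reference differential genes with an ASD gene-category list
#'
#' Intersects a (filtered) differential-expression table with a SFARI-style
#' category table after case-normalizing gene symbols. Duplicate gene ids
#' are deduplicated with a logged count: within the expression table the
#' smallest `padj` wins; within the category table the higher-confidence
#' category (1 > 2 > 3 > other) wins. The top table ranks intersection
#' genes by report count, breaking ties by `|log2fc|` descending and then
#' lexicographically.
#'
#' @param degs data.frame of differential genes: `gene_id`, `log2fc`,
#'   optionally `padj`.
#' @param sfari data.frame: `gene_id`, `category` (1, 2, 3 or "other"),
#'   optionally `n_reports`.
#' @param top_n Rows in the top table (default 50).
#' @return A `crossref_result`: `n_de`, `n_asd`, `category_counts`,
#'   `top_table`, `n_dedup` (rows dropped as duplicates).
#' @export
crossref_sfari <- function(degs, sfari, top_n = 50) {
  stopifnot(is.data.frame(degs), is.data.frame(sfari))
  degs$gene_id <- norm_gene(degs$gene_id)
  sfari$gene_id <- norm_gene(sfari$gene_id)
  n_dedup <- 0L
  if (anyDuplicated(degs$gene_id)) {
    n_dedup <- n_dedup + sum(duplicated(degs$gene_id))
    o <- if (!is.null(degs$padj)) order(degs$gene_id, degs$padj)
         else order(degs$gene_id)
    degs <- degs[o, ][!duplicated(degs$gene_id[o]), , drop = FALSE]
  }
  sfari$category <- as.character(sfari$category)
  cat_rank <- match(sfari$category, c("1", "2", "3", "other"))
  if (anyNA(cat_rank))
    stop("validation error: category must be one of 1, 2, 3, other")
  if (anyDuplicated(sfari$gene_id)) {
    n_dedup <- n_dedup + sum(duplicated(sfari$gene_id))
    o <- order(sfari$gene_id, cat_rank)
    sfari <- sfari[o, ][!duplicated(sfari$gene_id[o]), , drop = FALSE]
  }
  if (n_dedup) message("crossref_sfari: dropped ", n_dedup, " duplicate row(s)")

  hit <- merge(degs, sfari, by = "gene_id")
  counts <- table(factor(hit$category, levels = c("1", "2", "3", "other")))
  if (is.null(hit$n_reports)) hit$n_reports <- 0L
  o <- order(-hit$n_reports, -abs(hit$log2fc), hit$gene_id)
  top <- hit[o, c("gene_id", "category", "n_reports", "log2fc")]
  top <- utils::head(top, top_n)
  rownames(top) <- NULL
  structure(list(n_de = nrow(degs), n_asd = nrow(hit),
                 category_counts = stats::setNames(as.integer(counts), names(counts)),
                 top_table = top, n_dedup = n_dedup),
            class = "crossref_result")
}

#' @export
print.crossref_result <- function(x, ...) {
  cat("ASD cross-reference:", x$n_asd, "of", x$n_de,
      "differential genes in the category list\n")
  cat("  per category:",
      paste(sprintf("%s: %d", names(x$category_counts), x$category_counts),
            collapse = ", "), "\n")
  if (nrow(x$top_table)) {
    cat("  top genes by report count:\n")
    print(utils::head(x$top_table, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Read DE / category tables, write crossref summaries
#'
#' The expression table is tabular text with header
#' `gene_id,log2fc,pvalue,padj`; the category list has
#' `gene_id,category,n_reports`.
#'
#' @param path File path (tab separation for `.tsv`/`.tab`).
#' @return A data.frame.
#' @export
read_de_table <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' @rdname read_de_table
#' @export
read_sfari_table <- read_de_table

#' @rdname read_de_table
#' @param result A `crossref_result`.
#' @export
write_crossref <- function(result, path) {
  jsonlite::write_json(list(
    n_de = result$n_de, n_asd = result$n_asd,
    category_counts = as.list(result$category_counts),
    n_dedup = result$n_dedup,
    top_table = result$top_table),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
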