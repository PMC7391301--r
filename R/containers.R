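#' Expression matrix with per-sample condition labels
#'
#' Bundles a genes-by-samples matrix of log-scale expression values with a
#' two-level condition label per sample (e.g. tumour/normal). This is the
#' substrate for all hub--partner correlation statistics.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). No missing values.
#' @param condition Character or factor of length \code{ncol(values)} with
#'   exactly two levels; each level must have at least 3 samples.
#' @return An object of class \code{"expr_matrix"}: a list with elements
#'   \code{values} and \code{condition} (a factor).
#' @export
expression_matrix <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("`values` must have unique rownames (gene ids)", call. = FALSE)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("`values` must have unique colnames (sample ids)", call. = FALSE)
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "missing value at gene '%s', sample '%s'",
      rownames(values)[bad[1L]], colnames(values)[bad[2L]]
    ), call. = FALSE)
  }
  condition <- as.factor(condition)
  if (length(condition) != ncol(values)) {
    stop("`condition` must have one label per sample", call. = FALSE)
  }
  if (nlevels(condition) != 2L) {
    stop("`condition` must have exactly two levels", call. = FALSE)
  }
  if (any(table(condition) < 3L)) {
    stop("each condition level needs at least 3 samples", call. = FALSE)
  }
  structure(list(values = values, condition = condition),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf(
    "Expression matrix: %d genes x %d samples (%s)\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}

#' Undirected gene interaction network
#'
#' Builds a validated undirected \pkg{igraph} graph from an edge list,
#' dropping self-loops and duplicate edges (with a warning).
#'
#' @param edges Two-column character matrix or data frame of gene-id pairs,
#'   or an existing \code{igraph} object to validate/simplify.
#' @return An undirected, simple \code{igraph} graph.
#' @export
gene_network <- function(edges) {
  if (inherits(edges, "igraph")) {
    g <- edges
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L) stop("edge list needs two columns", call. = FALSE)
    em <- cbind(as.character(edges[[1L]]), as.character(edges[[2L]]))
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
  }
  n_loop <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  if (n_loop > 0L) warning(sprintf("dropped %d self-loop(s)", n_loop))
  if (n_multi > 0L) warning(sprintf("dropped %d duplicate edge(s)", n_multi))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Pooled-screen count container
#'
#' Bundles an shRNA-by-sample count matrix with the shRNA-to-gene map and
#' per-sample metadata (cell line, timepoint T0/tumor, replicate index).
#'
#' @param counts Non-negative numeric matrix, shRNAs in rows (rownames =
#'   shRNA ids), samples in columns (colnames = sample ids).
#' @param gene_of Named character vector mapping every shRNA id to exactly
#'   one gene.
#' @param samples Data frame with columns \code{sample_id},
#'   \code{cell_line}, \code{timepoint} (one of \code{"T0"},
#'   \code{"tumor"}) and \code{replicate}; one row per column of
#'   \code{counts}. Every cell line with tumour samples must also have a
#'   T0 sample.
#' @return An object of class \code{"screen_counts"}.
#' @export
screen_counts <- function(counts, gene_of, samples) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "negative count at shRNA '%s', sample '%s'",
      rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]
    ), call. = FALSE)
  }
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("`counts` must have unique rownames (shRNA ids)", call. = FALSE)
  }
  missing_map <- setdiff(rownames(counts), names(gene_of))
  if (length(missing_map) > 0L) {
    stop(sprintf(
      "shRNA(s) without a gene mapping: %s",
      paste(utils::head(missing_map, 3L), collapse = ", ")
    ), call. = FALSE)
  }
  gene_of <- gene_of[rownames(counts)]
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_line", "timepoint", "replicate")
  if (!all(need %in% names(samples))) {
    stop(sprintf("`samples` needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (!identical(colnames(counts), as.character(samples$sample_id))) {
    stop("`samples$sample_id` must match colnames(counts) in order",
         call. = FALSE)
  }
  if (!all(samples$timepoint %in% c("T0", "tumor"))) {
    stop("`timepoint` must be 'T0' or 'tumor'", call. = FALSE)
  }
  for (cl in unique(samples$cell_line[samples$timepoint == "tumor"])) {
    if (!any(samples$cell_line == cl & samples$timepoint == "T0")) {
      stop(sprintf("cell line '%s' has tumour samples but no T0 sample", cl),
           call. = FALSE)
    }
  }
  structure(list(counts = counts, gene_of = gene_of, samples = samples),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf(
    "Screen counts: %d shRNAs / %d genes, %d samples (%d T0, %d tumour) in %d cell line(s)\n",
    nrow(x$counts), length(unique(x$gene_of)), ncol(x$counts),
    sum(x$samples$timepoint == "T0"), sum(x$samples$timepoint == "tumor"),
    length(unique(x$samples$cell_line))
  ))
  invisible(x)
}
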