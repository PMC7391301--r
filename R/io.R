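# Strict readers and writers for the pipeline's plain-text dialects:
# TSV for matrices and networks, CSV for dose-response tables. Readers
# validate and report malformed content with its location.

stop_io <- function(path, msg) {
  stop(sprintf("%s: %s", path, msg), call. = FALSE)
}

read_table_checked <- function(path, sep, header = TRUE) {
  if (!file.exists(path)) stop_io(path, "file not found")
  if (file.size(path) == 0L) stop_io(path, "empty file")
  utils::read.table(path, sep = sep, header = header,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", comment.char = "")
}

#' Read an expression matrix with sample conditions
#'
#' Expression TSV: first column gene id, header row of sample ids,
#' numeric log-scale values. Metadata TSV: columns \code{sample_id},
#' \code{condition}.
#'
#' @param path Expression TSV path.
#' @param metadata_path Sample-metadata TSV path.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path, metadata_path) {
  tab <- read_table_checked(path, "\t")
  ids <- as.character(tab[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop_io(path, sprintf("duplicate gene id(s): %s",
                          paste(utils::head(dup, 3L), collapse = ", ")))
  }
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop_io(path, sprintf("non-numeric value in column '%s', row %d",
                            names(vals)[j], bad))
    }
    nas <- which(is.na(vals[[j]]))
    if (length(nas) > 0L) {
      stop_io(path, sprintf("missing value in column '%s', row %d",
                            names(vals)[j], nas[1L]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  meta <- read_table_checked(metadata_path, "\t")
  if (!all(c("sample_id", "condition") %in% names(meta))) {
    stop_io(metadata_path, "needs columns sample_id, condition")
  }
  idx <- match(colnames(m), meta$sample_id)
  if (anyNA(idx)) {
    stop_io(metadata_path, sprintf("no condition for sample(s): %s",
                                   paste(colnames(m)[is.na(idx)][1:1],
                                         collapse = ", ")))
  }
  expression_matrix(m, meta$condition[idx])
}

#' Write an expression matrix and its sample metadata
#'
#' @param expr An \code{\link{expression_matrix}}.
#' @param path Expression TSV path.
#' @param metadata_path Sample-metadata TSV path.
#' @export
write_expression <- function(expr, path, metadata_path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(expr$values),
                     condition = as.character(expr$condition))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an undirected network from an edge list or SIF file
#'
#' Two-column TSV (optionally headered \code{from}/\code{to}) or
#' three-column SIF (node, relation, node). Duplicate edges are merged
#' and self-loops dropped, each with a warning.
#'
#' @param path File path.
#' @param format \code{"auto"} (by extension), \code{"tsv"} or
#'   \code{"sif"}.
#' @return An \pkg{igraph} network.
#' @export
read_network <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  tab <- read_table_checked(path, "\t", header = FALSE)
  if (format == "sif") {
    if (ncol(tab) < 3L) stop_io(path, "SIF needs 3 columns")
    edges <- tab[, c(1L, 3L)]
  } else {
    if (ncol(tab) < 2L) stop_io(path, "edge list needs 2 columns")
    edges <- tab[, 1:2]
    # tolerate a header line
    if (identical(tolower(as.character(unlist(edges[1L, ]))),
                  c("from", "to"))) {
      edges <- edges[-1L, , drop = FALSE]
    }
  }
  gene_network(edges)
}

#' Write a network as a two-column TSV edge list
#'
#' @param net An \pkg{igraph} network.
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read pooled-screen counts with gene map and sample metadata
#'
#' Counts TSV: columns \code{shrna_id}, \code{gene}, then one numeric
#' column per sample. Metadata TSV: columns \code{sample_id},
#' \code{cell_line}, \code{timepoint}, \code{replicate}.
#'
#' @param path Counts TSV path.
#' @param metadata_path Sample-metadata TSV path.
#' @return A \code{\link{screen_counts}} object.
#' @export
read_counts <- function(path, metadata_path) {
  tab <- read_table_checked(path, "\t")
  if (ncol(tab) < 3L || !all(c("shrna_id", "gene") %in% names(tab)[1:2])) {
    stop_io(path, "needs columns shrna_id, gene, then sample columns")
  }
  vals <- tab[, -(1:2), drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]]) || anyNA(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(vals[[j]])))) |
                     is.na(vals[[j]]))[1L]
      stop_io(path, sprintf("non-numeric or missing count in column '%s', row %d",
                            names(vals)[j], bad))
    }
    neg <- which(vals[[j]] < 0)
    if (length(neg) > 0L) {
      stop_io(path, sprintf("negative count in column '%s', row %d",
                            names(vals)[j], neg[1L]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- as.character(tab$shrna_id)
  meta <- read_table_checked(metadata_path, "\t")
  screen_counts(m, stats::setNames(as.character(tab$gene), rownames(m)),
                meta[match(colnames(m), meta$sample_id), , drop = FALSE])
}

#' Write pooled-screen counts and sample metadata
#'
#' @param x A \code{\link{screen_counts}} object.
#' @param path Counts TSV path.
#' @param metadata_path Sample-metadata TSV path.
#' @export
write_counts <- function(x, path, metadata_path) {
  df <- data.frame(shrna_id = rownames(x$counts),
                   gene = unname(x$gene_of[rownames(x$counts)]),
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a dose-response / combination table
#'
#' CSV with columns \code{drug1_dose}, \code{drug2_dose},
#' \code{drug3_dose} (0 when absent), \code{effect_type} (one of
#' \code{cell_number}, \code{apoptotic_index}, \code{radiance}),
#' \code{effect_value}, \code{control_value}, \code{batch}.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_doseresponse <- function(path) {
  tab <- read_table_checked(path, ",")
  need <- c("drug1_dose", "drug2_dose", "drug3_dose", "effect_type",
            "effect_value", "control_value", "batch")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop_io(path, sprintf("missing column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  }
  for (col in c("drug1_dose", "drug2_dose", "drug3_dose", "effect_value",
                "control_value")) {
    if (!is.numeric(tab[[col]]) || anyNA(tab[[col]])) {
      stop_io(path, sprintf("non-numeric or missing value in column '%s'", col))
    }
  }
  if (any(tab$drug1_dose < 0 | tab$drug2_dose < 0 | tab$drug3_dose < 0)) {
    stop_io(path, "doses must be non-negative")
  }
  ok_types <- c("cell_number", "apoptotic_index", "radiance")
  if (!all(tab$effect_type %in% ok_types)) {
    stop_io(path, sprintf("effect_type must be one of: %s",
                          paste(ok_types, collapse = ", ")))
  }
  tab
}

#' Write a dose-response / combination table
#'
#' @param tbl Data frame in the combination dialect.
#' @param path CSV output path.
#' @export
write_doseresponse <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ortholog map
#'
#' Two-column TSV: species-A id, species-B id (optional header).
#'
#' @param path TSV path.
#' @return Data frame with columns \code{species_a}, \code{species_b}.
#' @export
read_orthologs <- function(path) {
  tab <- read_table_checked(path, "\t", header = FALSE)
  if (ncol(tab) < 2L) stop_io(path, "ortholog map needs 2 columns")
  out <- data.frame(species_a = as.character(tab[[1L]]),
                    species_b = as.character(tab[[2L]]),
                    stringsAsFactors = FALSE)
  if (identical(tolower(out[1L, 1L]), "species_a")) out <- out[-1L, ]
  out
}

#' Write an ortholog map
#'
#' @param map Two-column data frame.
#' @param path TSV output path.
#' @export
write_orthologs <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
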