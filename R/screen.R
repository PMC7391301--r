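# Pooled in-vivo shRNA dropout-screen scoring: normalisation, log
# transform, robust-Z outlier-tumour exclusion, fold-change Z-scoring /
# log-ratio cutoff calling, gene tiering and Fisher validation.

#' Normalise screen counts to a common library size
#'
#' Scales every sample (column) so its total equals \code{target_total},
#' preserving within-sample proportions and rank order.
#'
#' @param raw A \code{\link{screen_counts}} object.
#' @param target_total Post-normalisation column total.
#' @return A \code{\link{screen_counts}} object with normalised counts.
#' @export
normalize_counts <- function(raw, target_total = 1e7) {
  stopifnot(inherits(raw, "screen_counts"))
  check_scalar(target_total, "target_total", lower = 0, open_lower = TRUE)
  totals <- colSums(raw$counts)
  if (any(totals <= 0)) {
    stop(sprintf("sample(s) with zero total count: %s",
                 paste(colnames(raw$counts)[totals <= 0], collapse = ", ")),
         call. = FALSE)
  }
  raw$counts <- sweep(raw$counts, 2L, target_total / totals, "*")
  raw
}

#' Log-transform screen counts
#'
#' Applies \code{log10(x + pseudocount)} for data linearisation. The
#' default pseudocount 0.1 keeps zero counts representable on the log
#' scale.
#'
#' @param x A \code{\link{screen_counts}} object.
#' @param pseudocount Non-negative offset added before the log.
#' @return A \code{\link{screen_counts}} object with log10 values.
#' @export
log_transform <- function(x, pseudocount = 0.1) {
  stopifnot(inherits(x, "screen_counts"))
  check_scalar(pseudocount, "pseudocount", lower = 0)
  x$counts <- log10(x$counts + pseudocount)
  x
}

# Robust Z of a numeric vector: (x - median) / (1.4826 * MAD). When the
# MAD collapses to zero with unequal values, fall back to the mean
# absolute deviation scaled by 1.2533 (its normal-consistency constant).
robust_z <- function(x) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 > 0) {
    return((x - med) / (1.4826 * mad0))
  }
  if (all(x == x[1L])) {
    return(rep(0, length(x)))
  }
  message("MAD = 0 with unequal values; falling back to scaled mean absolute deviation")
  (x - med) / (1.2533 * mean(abs(x - med)))
}

#' Robust-Z outlier exclusion across tumour replicates
#'
#' For every (shRNA, cell line), computes robust Z-scores of the
#' log-transformed tumour replicate values, flags replicates with
#' \code{|Z| > threshold}, and excludes at most \code{max_excluded} of
#' them (the largest |Z| first, ties broken by sample order). Exclusions
#' are additionally capped so that at least 4 tumour replicates always
#' remain.
#'
#' @param log_counts A log-transformed \code{\link{screen_counts}} object
#'   (see \code{\link{log_transform}}).
#' @param threshold Robust-Z magnitude above which a replicate is an
#'   outlier candidate.
#' @param max_excluded Maximum replicates excluded per (shRNA, cell
#'   line).
#' @return A list with one entry per cell line, each a list with
#'   \code{robust_z} (shRNA x tumour-replicate matrix) and
#'   \code{excluded} (logical matrix of the same shape).
#' @export
robust_z_exclude <- function(log_counts, threshold = 5, max_excluded = 2) {
  stopifnot(inherits(log_counts, "screen_counts"))
  check_scalar(threshold, "threshold", lower = 0, open_lower = TRUE)
  check_scalar(max_excluded, "max_excluded", lower = 0, integer = TRUE)
  out <- list()
  for (cl in unique(log_counts$samples$cell_line)) {
    tum <- log_counts$samples$timepoint == "tumor" &
      log_counts$samples$cell_line == cl
    if (!any(tum)) next
    n_rep <- sum(tum)
    if (n_rep < 4L) {
      stop(sprintf("cell line '%s' has %d tumour replicates; at least 4 are required",
                   cl, n_rep), call. = FALSE)
    }
    x <- log_counts$counts[, tum, drop = FALSE]
    z <- t(apply(x, 1L, robust_z))
    dimnames(z) <- dimnames(x)
    cap <- min(max_excluded, n_rep - 4L)
    excl <- matrix(FALSE, nrow(z), ncol(z), dimnames = dimnames(z))
    if (cap > 0L) {
      flag_n <- rowSums(abs(z) > threshold)
      for (i in which(flag_n > 0L)) {
        cand <- which(abs(z[i, ]) > threshold)
        cand <- cand[order(-abs(z[i, cand]), cand)]
        excl[i, cand[seq_len(min(cap, length(cand)))]] <- TRUE
      }
    }
    out[[cl]] <- list(robust_z = z, excluded = excl)
  }
  out
}

#' Omnibus skewness-kurtosis normality check
#'
#' D'Agostino-Pearson K-squared test: combines the transformed sample
#' skewness and kurtosis into a statistic that is chi-squared with 2
#' degrees of freedom under normality. The check is advisory: a failure
#' emits a warning rather than aborting the pipeline.
#'
#' @param values Numeric vector (at least 20 values).
#' @param alpha Significance level below which the check fails.
#' @return A list with \code{statistic} (K-squared), \code{p} and
#'   \code{pass}.
#' @export
check_gaussian <- function(values, alpha = 0.01) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 20L) stop("normality check needs at least 20 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  g1 <- mean((values - m)^3) / m2^1.5
  g2 <- mean((values - m)^4) / m2^2
  # skewness transform (D'Agostino)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  a <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / a)
  # kurtosis transform (Anscombe-Glynn)
  eg2 <- 3 * (n - 1) / (n + 1)
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eg2) / sqrt(vg2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z2 <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))
  k2 <- z1^2 + z2^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  pass <- p >= alpha
  if (!pass) {
    warning(sprintf("distribution departs from a Gaussian pattern (K2 = %.2f, p = %.3g)",
                    k2, p), call. = FALSE)
  }
  list(statistic = k2, p = p, pass = pass)
}

#' Fold-change Z-score dropout calling
#'
#' For every (shRNA, cell line): the mean of the retained tumour-replicate
#' normalised counts is divided by the T0 normalised count and
#' log10-transformed (with \code{pseudocount} added to numerator and
#' denominator); the log ratios are then standardised across all shRNAs
#' within the cell line, and shRNAs with \code{z < z_cut} are called
#' dropouts.
#'
#' @param counts_norm A normalised (not log-transformed)
#'   \code{\link{screen_counts}} object.
#' @param exclusions Optional output of \code{\link{robust_z_exclude}};
#'   excluded replicates are dropped from the tumour mean.
#' @param z_cut Dropout threshold on the standardised score (default
#'   -1.96, two-tailed p < 0.05).
#' @param pseudocount Offset guarding the ratio against zero counts.
#' @param check_normality If \code{TRUE}, the pooled log-ratio
#'   distribution is checked with \code{\link{check_gaussian}} (advisory).
#' @return An object of class \code{"screen_scores"}: a list with
#'   \code{table} (data frame: shrna, gene, cell_line, n_used,
#'   log_ratio, z, dropout), \code{gene_of} and \code{params}.
#' @export
dropout_z <- function(counts_norm, exclusions = NULL, z_cut = -1.96,
                      pseudocount = 0.1, check_normality = FALSE) {
  lr <- screen_log_ratios(counts_norm, exclusions, pseudocount)
  rows <- list()
  for (cl in colnames(lr$log_ratio)) {
    x <- lr$log_ratio[, cl]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      stop(sprintf("zero variance of log ratios in cell line '%s'; Z-scores undefined", cl),
           call. = FALSE)
    }
    if (check_normality) check_gaussian(x)
    z <- (x - mean(x)) / s
    rows[[cl]] <- data.frame(
      shrna = rownames(lr$log_ratio), gene = unname(lr$gene_of),
      cell_line = cl, n_used = lr$n_used[, cl], log_ratio = x, z = z,
      dropout = z < z_cut, stringsAsFactors = FALSE, row.names = NULL
    )
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 gene_of = lr$gene_of,
                 params = list(z_cut = z_cut, pseudocount = pseudocount)),
            class = "screen_scores")
}

#' Averaged tumour/T0 log ratios per shRNA and cell line
#'
#' For each (shRNA, cell line): mean of the retained tumour-replicate
#' normalised counts, divided by the T0 normalised count,
#' log10-transformed (with \code{pseudocount} added to numerator and
#' denominator). Shared by \code{\link{dropout_z}} and directly usable
#' with \code{\link{gene_hits_screen2}}.
#'
#' @inheritParams dropout_z
#' @return A list with \code{log_ratio} (shRNA x cell-line matrix),
#'   \code{n_used} (retained replicate counts) and \code{gene_of}.
#' @export
screen_log_ratios <- function(counts_norm, exclusions = NULL,
                              pseudocount = 0.1) {
  stopifnot(inherits(counts_norm, "screen_counts"))
  check_scalar(pseudocount, "pseudocount", lower = 0)
  sm <- counts_norm$samples
  lines <- unique(sm$cell_line[sm$timepoint == "tumor"])
  n_sh <- nrow(counts_norm$counts)
  lrat <- matrix(NA_real_, n_sh, length(lines),
                 dimnames = list(rownames(counts_norm$counts), lines))
  nuse <- matrix(NA_integer_, n_sh, length(lines), dimnames = dimnames(lrat))
  for (cl in lines) {
    tum <- which(sm$timepoint == "tumor" & sm$cell_line == cl)
    t0 <- which(sm$timepoint == "T0" & sm$cell_line == cl)
    if (length(t0) != 1L) {
      stop(sprintf("cell line '%s' must have exactly one T0 sample", cl),
           call. = FALSE)
    }
    x <- counts_norm$counts[, tum, drop = FALSE]
    keep <- matrix(TRUE, n_sh, length(tum))
    if (!is.null(exclusions) && !is.null(exclusions[[cl]])) {
      keep <- !exclusions[[cl]]$excluded
    }
    tum_mean <- rowSums(x * keep) / rowSums(keep)
    lrat[, cl] <- log10((tum_mean + pseudocount) /
                          (counts_norm$counts[, t0] + pseudocount))
    nuse[, cl] <- rowSums(keep)
  }
  list(log_ratio = lrat, n_used = nuse, gene_of = counts_norm$gene_of)
}

#' @export
print.screen_scores <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Screen scores: %d shRNAs x %d cell line(s), z_cut = %g\n",
              length(unique(tab$shrna)), length(unique(tab$cell_line)),
              x$params$z_cut))
  for (cl in unique(tab$cell_line)) {
    cat(sprintf("  %s: %d dropout shRNA(s)\n", cl,
                sum(tab$dropout[tab$cell_line == cl])))
  }
  invisible(x)
}

#' @export
summary.screen_scores <- function(object, ...) {
  print(object)
  invisible(object$table)
}

#' Gene-level hits from Z-score dropout calls
#'
#' A gene is a hit in a cell line if at least \code{min_shrnas} of its
#' shRNAs are dropouts there; genes hitting in every scored line are
#' flagged.
#'
#' @param scores A \code{"screen_scores"} object from
#'   \code{\link{dropout_z}}.
#' @param min_shrnas Minimum dropout shRNAs per gene per line.
#' @return Data frame: gene, one logical hit column per cell line,
#'   \code{n_lines_hit}, \code{all_lines}.
#' @export
gene_hits_screen1 <- function(scores, min_shrnas = 2) {
  stopifnot(inherits(scores, "screen_scores"))
  check_scalar(min_shrnas, "min_shrnas", lower = 1, integer = TRUE)
  tab <- scores$table
  lines <- unique(tab$cell_line)
  genes <- unique(tab$gene)
  hit <- sapply(lines, function(cl) {
    sub <- tab[tab$cell_line == cl & tab$dropout, ]
    cnt <- table(factor(sub$gene, levels = genes))
    as.vector(cnt) >= min_shrnas
  })
  hit <- matrix(hit, nrow = length(genes),
                dimnames = list(NULL, paste0("hit_", lines)))
  res <- data.frame(gene = genes, hit, stringsAsFactors = FALSE,
                    row.names = NULL)
  res$n_lines_hit <- rowSums(hit)
  res$all_lines <- res$n_lines_hit == length(lines)
  res[order(-res$n_lines_hit, res$gene), , drop = FALSE]
}

#' Gene-level hits and tiers from log-ratio cutoffs
#'
#' Used when Z-scores are unavailable (non-Gaussian log ratios): an shRNA
#' scores in a line if its averaged log10(tumour/T0) ratio is at or below
#' \code{cutoff} (the default -0.69 is a fivefold reduction in tumour
#' growth); a gene is a line hit if at least \code{min_shrnas} of its
#' shRNAs score; and the gene's tier counts hit lines (high for 3 or
#' more, medium for exactly 2, low for exactly 1).
#'
#' @param log_ratios Numeric matrix of averaged log10(tumour/T0) ratios,
#'   shRNAs in rows, cell lines in columns (e.g.
#'   \code{screen_log_ratios()$log_ratio}), or the list that function
#'   returns.
#' @param gene_of Named character vector mapping shRNA ids to genes
#'   (ignored when \code{log_ratios} carries its own).
#' @param cutoff Scoring threshold on the log ratio.
#' @param min_shrnas Minimum scoring shRNAs per gene per line.
#' @return Data frame: gene, one logical hit column per cell line,
#'   \code{n_lines_hit}, \code{tier} (high/medium/low/none).
#' @export
gene_hits_screen2 <- function(log_ratios, gene_of = NULL, cutoff = -0.69,
                              min_shrnas = 2) {
  if (is.list(log_ratios) && !is.null(log_ratios$log_ratio)) {
    gene_of <- log_ratios$gene_of
    log_ratios <- log_ratios$log_ratio
  }
  stopifnot(is.matrix(log_ratios), !is.null(gene_of))
  gene_of <- gene_of[rownames(log_ratios)]
  genes <- unique(unname(gene_of))
  lines <- colnames(log_ratios)
  scoremat <- log_ratios <= cutoff
  hit <- sapply(lines, function(cl) {
    cnt <- tapply(scoremat[, cl], factor(gene_of, levels = genes), sum)
    as.vector(cnt) >= min_shrnas
  })
  hit <- matrix(hit, nrow = length(genes),
                dimnames = list(NULL, paste0("hit_", lines)))
  n_hit <- rowSums(hit)
  tier <- cut(n_hit, breaks = c(-Inf, 0, 1, 2, Inf),
              labels = c("none", "low", "medium", "high"))
  res <- data.frame(gene = genes, hit, n_lines_hit = n_hit,
                    tier = as.character(tier), stringsAsFactors = FALSE,
                    row.names = NULL)
  res[order(-res$n_lines_hit, res$gene), , drop = FALSE]
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Probability-mass two-sided rule: the p-value sums the hypergeometric
#' probabilities of every table with the observed margins whose
#' probability does not exceed that of the observed table.
#'
#' @param a,b,c,d Non-negative integer cells (row-wise), or a 2x2 matrix
#'   passed as \code{a}.
#' @return Two-sided p-value. Any zero margin yields p = 1 with a
#'   warning.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), 2L, 2L)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("a margin is zero; p = 1 by convention")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}
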