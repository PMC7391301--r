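# Synthetic-data generators. Each generator is a pure function of its
# arguments including the mandatory seed, so fixtures are reproducible by
# construction.

#' Simulate hub-structured co-expression data for two conditions
#'
#' Generates a genes-by-samples log-scale expression matrix organised as
#' independent hub/partner blocks, together with the matching interaction
#' network and the ground-truth set of disrupted hubs. Within a block the
#' hub and each partner are bivariate normal with correlation
#' \code{r_normal} in normal samples; for disrupted hubs the tumour-sample
#' correlation is \code{r_tumor_disrupted} instead, while non-disrupted
#' hubs keep \code{r_normal} in both conditions. The default sample sizes
#' (21 tumours, 12 normals) mirror a typical tumour-versus-fetal-tissue
#' microarray design.
#'
#' @param n_hubs Number of hub genes.
#' @param partners_per_hub Partners per hub (at least 5 for the default
#'   hub definition of more than 4 partners).
#' @param n_tumor,n_normal Samples per condition (each at least 3).
#' @param r_normal Hub--partner Pearson correlation in normal samples,
#'   strictly inside (-1, 1).
#' @param r_tumor_disrupted Tumour-sample correlation of disrupted hubs.
#' @param disrupted_hubs Character vector of hub ids to disrupt (subset of
#'   the generated ids \code{"hub001"}, \code{"hub002"}, ...), or an
#'   integer count meaning "the first k hubs".
#' @param noise_sd Marginal standard deviation of every gene (log-intensity
#'   units).
#' @param baseline Marginal mean log intensity.
#' @param seed Integer RNG seed (mandatory).
#' @return A list with elements \code{expr} (an
#'   \code{\link{expression_matrix}}), \code{net} (an \pkg{igraph}
#'   network linking each hub to its partners) and \code{truth} (character
#'   vector of disrupted hub ids).
#' @export
sim_expression <- function(n_hubs = 20, partners_per_hub = 5,
                           n_tumor = 21, n_normal = 12,
                           r_normal = 0.8, r_tumor_disrupted = 0,
                           disrupted_hubs = character(),
                           noise_sd = 1, baseline = 8, seed) {
  check_scalar(n_hubs, "n_hubs", lower = 1, integer = TRUE)
  check_scalar(partners_per_hub, "partners_per_hub", lower = 1, integer = TRUE)
  check_scalar(n_tumor, "n_tumor", lower = 3, integer = TRUE)
  check_scalar(n_normal, "n_normal", lower = 3, integer = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0, open_lower = TRUE)
  for (r in c(r_normal = r_normal, r_tumor = r_tumor_disrupted)) {
    if (!is.finite(r) || abs(r) >= 1) {
      stop("correlations must lie strictly inside (-1, 1): |r| = 1 gives a degenerate covariance",
           call. = FALSE)
    }
  }
  hub_ids <- sprintf("hub%03d", seq_len(n_hubs))
  if (is.numeric(disrupted_hubs)) {
    check_scalar(disrupted_hubs, "disrupted_hubs", lower = 0,
                 upper = n_hubs, integer = TRUE)
    disrupted_hubs <- hub_ids[seq_len(disrupted_hubs)]
  }
  if (!all(disrupted_hubs %in% hub_ids)) {
    stop("`disrupted_hubs` must be a subset of the generated hub ids",
         call. = FALSE)
  }

  n <- n_tumor + n_normal
  condition <- factor(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                      levels = c("tumor", "normal"))
  is_tumor <- condition == "tumor"
  sample_ids <- c(sprintf("T%02d", seq_len(n_tumor)),
                  sprintf("N%02d", seq_len(n_normal)))

  with_seed(seed, {
    blocks <- vector("list", n_hubs)
    edges <- vector("list", n_hubs)
    for (i in seq_len(n_hubs)) {
      hub <- stats::rnorm(n)
      r <- rep(r_normal, n)
      if (hub_ids[i] %in% disrupted_hubs) r[is_tumor] <- r_tumor_disrupted
      part <- matrix(stats::rnorm(partners_per_hub * n), partners_per_hub, n)
      # partner_j = r * hub + sqrt(1 - r^2) * eps  => cor(hub, partner) = r
      part <- sweep(part, 2L, sqrt(1 - r^2), "*") +
        matrix(rep(r * hub, each = partners_per_hub), partners_per_hub, n)
      block <- rbind(hub, part) * noise_sd + baseline
      rownames(block) <- c(hub_ids[i],
                           sprintf("%s_p%02d", hub_ids[i],
                                   seq_len(partners_per_hub)))
      blocks[[i]] <- block
      edges[[i]] <- cbind(hub_ids[i], rownames(block)[-1L])
    }
    values <- do.call(rbind, blocks)
    colnames(values) <- sample_ids
    list(
      expr = expression_matrix(values, condition),
      net = gene_network(do.call(rbind, edges)),
      truth = disrupted_hubs
    )
  })
}

#' Simulate a pooled shRNA dropout screen
#'
#' Generates negative-binomial (Poisson-gamma) counts for a pooled screen
#' with one T0 baseline sample and \code{n_tumor_reps} tumour replicates
#' per cell line. Each shRNA draws a latent abundance from a log-normal
#' spread around \code{mean_t0_count} (pooled libraries are never uniform;
#' the spread cancels in tumour/T0 ratios). Tumour counts for shRNAs
#' targeting depleted genes have their mean multiplied by
#' \code{depletion_factor}; a fraction \code{outlier_rate} of
#' (shRNA, tumour) cells is multiplied by \code{outlier_factor} and the
#' coordinates recorded in the truth.
#'
#' @param n_genes Number of genes.
#' @param shrnas_per_gene shRNAs per gene.
#' @param n_tumor_reps Tumour replicates per cell line (at least 4;
#'   default 6).
#' @param cell_lines Character vector of cell-line names.
#' @param mean_t0_count Expected T0 count per shRNA.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param depleted_genes Character vector of gene ids (subset of the
#'   generated \code{"g001"}, ...) whose shRNAs drop out in tumours, or an
#'   integer count meaning "the first k genes".
#' @param depletion_factor Tumour-mean fold change for depleted genes,
#'   in (0, 1).
#' @param outlier_rate Probability that a (shRNA, tumour) cell is an
#'   injected outlier, in [0, 1).
#' @param outlier_factor Multiplier applied to injected outliers.
#' @param abundance_sdlog Log-normal sdlog of the per-shRNA abundance
#'   spread.
#' @param seed Integer RNG seed (mandatory).
#' @return A list with elements \code{counts} (a
#'   \code{\link{screen_counts}} object), \code{truth} (depleted gene
#'   ids) and \code{outliers} (data frame of injected outlier
#'   coordinates: shrna, sample).
#' @export
sim_screen <- function(n_genes = 100, shrnas_per_gene = 5, n_tumor_reps = 6,
                       cell_lines = "line1", mean_t0_count = 1000,
                       dispersion = 0.2, depleted_genes = character(),
                       depletion_factor = 0.1, outlier_rate = 0,
                       outlier_factor = 50, abundance_sdlog = 1, seed) {
  check_scalar(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_scalar(shrnas_per_gene, "shrnas_per_gene", lower = 1, integer = TRUE)
  check_scalar(n_tumor_reps, "n_tumor_reps", lower = 4, integer = TRUE)
  check_scalar(mean_t0_count, "mean_t0_count", lower = 0, open_lower = TRUE)
  check_scalar(dispersion, "dispersion", lower = 0, open_lower = TRUE)
  check_scalar(depletion_factor, "depletion_factor", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(outlier_rate, "outlier_rate", lower = 0, upper = 1,
               open_upper = TRUE)
  check_scalar(outlier_factor, "outlier_factor", lower = 0, open_lower = TRUE)

  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  if (is.numeric(depleted_genes)) {
    check_scalar(depleted_genes, "depleted_genes", lower = 0, upper = n_genes,
                 integer = TRUE)
    depleted_genes <- gene_ids[seq_len(depleted_genes)]
  }
  if (!all(depleted_genes %in% gene_ids)) {
    stop("`depleted_genes` must be a subset of the generated gene ids",
         call. = FALSE)
  }
  n_sh <- n_genes * shrnas_per_gene
  shrna_ids <- sprintf("%s_sh%d", rep(gene_ids, each = shrnas_per_gene),
                       rep(seq_len(shrnas_per_gene), n_genes))
  gene_of <- stats::setNames(rep(gene_ids, each = shrnas_per_gene), shrna_ids)
  depleted_sh <- gene_of %in% depleted_genes
  size <- 1 / dispersion

  with_seed(seed, {
    cols <- list()
    meta <- list()
    out_rec <- list()
    for (cl in cell_lines) {
      # latent abundance; mean-corrected so E[count] = mean_t0_count
      mu <- mean_t0_count *
        stats::rlnorm(n_sh, meanlog = -abundance_sdlog^2 / 2,
                      sdlog = abundance_sdlog)
      t0 <- stats::rnbinom(n_sh, mu = mu, size = size)
      cols[[paste0(cl, "_T0")]] <- t0
      meta[[length(meta) + 1L]] <-
        data.frame(sample_id = paste0(cl, "_T0"), cell_line = cl,
                   timepoint = "T0", replicate = 0L,
                   stringsAsFactors = FALSE)
      mu_tum <- mu * ifelse(depleted_sh, depletion_factor, 1)
      for (r in seq_len(n_tumor_reps)) {
        sid <- sprintf("%s_tumor%d", cl, r)
        x <- stats::rnbinom(n_sh, mu = mu_tum, size = size)
        if (outlier_rate > 0) {
          hit <- stats::runif(n_sh) < outlier_rate
          if (any(hit)) {
            x[hit] <- x[hit] * outlier_factor
            out_rec[[length(out_rec) + 1L]] <-
              data.frame(shrna = shrna_ids[hit], sample = sid,
                         stringsAsFactors = FALSE)
          }
        }
        cols[[sid]] <- x
        meta[[length(meta) + 1L]] <-
          data.frame(sample_id = sid, cell_line = cl, timepoint = "tumor",
                     replicate = r, stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- shrna_ids
    outliers <- if (length(out_rec) > 0L) {
      do.call(rbind, out_rec)
    } else {
      data.frame(shrna = character(), sample = character(),
                 stringsAsFactors = FALSE)
    }
    list(
      counts = screen_counts(counts, gene_of, do.call(rbind, meta)),
      truth = depleted_genes,
      outliers = outliers
    )
  })
}

# Effective single-drug dose reaching fraction affected `fa` under the
# median-effect model with slope m and median-effect dose dm.
me_dose <- function(fa, m, dm) dm * (fa / (1 - fa))^(1 / m)

# Fraction affected at dose D under the median-effect model.
me_fa <- function(d, m, dm) {
  z <- (d / dm)^m
  z / (1 + z)
}

# Solve the Loewe relation sum_i D_i / Dx_i(fa) = 1/alpha for fa.
solve_loewe_fa <- function(doses, m, dm, alpha) {
  g <- function(fa) sum(doses / me_dose(fa, m, dm)) - 1 / alpha
  lo <- 1e-9
  hi <- 1 - 1e-9
  if (g(lo) < 0 || g(hi) > 0) {
    stop("cannot bracket the combination effect: doses are far outside the response range",
         call. = FALSE)
  }
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' Simulate median-effect dose-response and combination data
#'
#' Generates a dose-response table in the standard combination dialect
#' (columns \code{drug1_dose}, \code{drug2_dose}, \code{drug3_dose},
#' \code{effect_type}, \code{effect_value}, \code{control_value},
#' \code{batch}). Single-drug rows follow the median-effect equation
#' fa/(1-fa) = (D/Dm)^m with multiplicative log-normal noise of
#' coefficient of variation \code{cv_noise} on the measured cell number.
#' Combination rows (constant dose ratio) carry the fraction affected that
#' solves the Loewe relation sum(D_i / Dx_i(fa)) = 1/alpha, so the
#' ground-truth Combination Index is exactly \code{1/alpha}. For three
#' drugs the first two form a fixed-ratio pair that is additive internally
#' (the pair entity is then itself exactly median-effect when the drugs
#' share a slope) and \code{alpha} acts between the pair and the third
#' drug.
#'
#' @param m Median-effect slope(s); scalar or length \code{n_drugs}. Three
#'   drug designs require a shared slope.
#' @param dm Median-effect dose(s) Dm; scalar or length \code{n_drugs}.
#' @param doses Positive dose grid for drug 1 (and the combination
#'   series); defaults to a two-fold dilution series spanning
#'   \code{dm[1] * 2^(-3..3)}.
#' @param cv_noise Coefficient of variation of multiplicative measurement
#'   noise (0 = noiseless).
#' @param alpha Interaction scalar: ground-truth CI of the combination is
#'   \code{1/alpha} (1 = Loewe-additive, 2 = synergy at CI 0.5).
#' @param ratio Dose ratio drug2:drug1 in combination rows (and third
#'   drug : pair for three-drug designs).
#' @param n_drugs Number of drugs in the design (1, 2 or 3).
#' @param x_ctl Control (vehicle) cell number.
#' @param replicates Replicate measurements per row.
#' @param seed Integer RNG seed (mandatory).
#' @return A data frame in the combination dialect, with attributes
#'   \code{true_ci} (= 1/alpha) and \code{true_params}.
#' @export
sim_dose_response <- function(m = 1.5, dm = 1, doses = NULL, cv_noise = 0,
                              alpha = 1, ratio = 1, n_drugs = 1,
                              x_ctl = 10000, replicates = 1, seed) {
  check_scalar(n_drugs, "n_drugs", lower = 1, upper = 3, integer = TRUE)
  check_scalar(alpha, "alpha", lower = 0, open_lower = TRUE)
  check_scalar(ratio, "ratio", lower = 0, open_lower = TRUE)
  check_scalar(cv_noise, "cv_noise", lower = 0)
  check_scalar(replicates, "replicates", lower = 1, integer = TRUE)
  m <- rep_len(m, n_drugs)
  dm <- rep_len(dm, n_drugs)
  if (any(m <= 0) || any(dm <= 0)) {
    stop("`m` and `dm` must be positive", call. = FALSE)
  }
  if (n_drugs == 3L && length(unique(m)) != 1L) {
    stop("three-drug designs require a shared median-effect slope `m`",
         call. = FALSE)
  }
  if (is.null(doses)) doses <- dm[1L] * 2^(-3:3)
  if (any(doses <= 0)) stop("all doses must be positive", call. = FALSE)

  sdlog <- if (cv_noise > 0) sqrt(log(1 + cv_noise^2)) else 0
  row <- function(d1, d2, d3, fa) {
    data.frame(drug1_dose = d1, drug2_dose = d2, drug3_dose = d3,
               effect_type = "cell_number",
               effect_value = NA_real_, control_value = x_ctl,
               batch = "sim", fa_true = fa, stringsAsFactors = FALSE)
  }

  rows <- list()
  # single-drug series for every drug
  for (i in seq_len(n_drugs)) {
    di <- if (i == 1L) doses else doses * dm[i] / dm[1L]
    fa <- me_fa(di, m[i], dm[i])
    d123 <- matrix(0, length(di), 3L)
    d123[, i] <- di
    rows[[length(rows) + 1L]] <- row(d123[, 1L], d123[, 2L], d123[, 3L], fa)
  }
  if (n_drugs == 2L) {
    fa <- vapply(doses, function(d) {
      solve_loewe_fa(c(d, d * ratio), m, dm, alpha)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- row(doses, doses * ratio, 0, fa)
  } else if (n_drugs == 3L) {
    w <- c(1, ratio) / (1 + ratio)           # pair composition at fixed ratio
    dm_pair <- 1 / sum(w / dm[1:2])          # exact entity Dm at shared slope
    # pair-alone series (additive internally)
    fa_pair <- me_fa(doses, m[1L], dm_pair)
    rows[[length(rows) + 1L]] <- row(doses * w[1L], doses * w[2L], 0, fa_pair)
    # triple series: pair entity + third drug, interaction alpha between them
    d3 <- doses * dm[3L] / dm_pair
    fa <- vapply(seq_along(doses), function(i) {
      solve_loewe_fa(c(doses[i], d3[i]), rep(m[1L], 2L), c(dm_pair, dm[3L]),
                     alpha)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- row(doses * w[1L], doses * w[2L], d3, fa)
  }

  tbl <- do.call(rbind, rows)
  tbl <- tbl[rep(seq_len(nrow(tbl)), each = replicates), , drop = FALSE]
  with_seed(seed, {
    noise <- if (sdlog > 0) {
      stats::rlnorm(nrow(tbl), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, nrow(tbl))
    }
    tbl$effect_value <- x_ctl * (1 - tbl$fa_true) * noise
    rownames(tbl) <- NULL
    structure(tbl,
              true_ci = 1 / alpha,
              true_params = list(m = m, dm = dm, alpha = alpha,
                                 ratio = ratio, n_drugs = n_drugs))
  })
}
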