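# Umbrella pipeline runner: a structured config drives the stages, every
# stochastic stage receives an explicit seed, and a machine-readable JSON
# manifest records what ran.

known_config_keys <- c(
  "seed", "stages", "output_dir",
  # hubscan
  "expression", "expression_metadata", "network", "retain_fraction",
  "alpha", "n_runs", "subsample_fraction", "n_perm", "min_partners",
  # screen
  "counts", "counts_metadata", "target_total", "pseudocount", "z_cut",
  "ratio_cut", "min_shrnas", "robust_z_threshold", "max_excluded",
  # synergy
  "doseresponse", "fa_min", "ci_max", "exclusive_ci"
)

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages (\code{"hubscan"}, \code{"screen"},
#' \code{"synergy"}) against the input files named in the config, writes
#' per-stage TSV/CSV outputs under \code{output_dir}, and emits a JSON
#' run manifest (parameters, input checksums, per-stage record counts).
#' Re-running with an identical config and inputs reproduces identical
#' outputs: all randomness flows from the config seed.
#'
#' @param config Path to a YAML file or a named list. Unknown keys are
#'   rejected. Required: \code{seed}, \code{stages}, \code{output_dir},
#'   plus the input paths of the requested stages (see the readers'
#'   documentation for the dialects).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  } else {
    config_path <- NULL
  }
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (key in c("seed", "stages", "output_dir")) {
    if (is.null(config[[key]])) {
      stop(sprintf("config is missing required key '%s'", key), call. = FALSE)
    }
  }
  stages <- config$stages
  bad <- setdiff(stages, c("hubscan", "screen", "synergy"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  inputs <- unlist(config[c("expression", "expression_metadata", "network",
                            "counts", "counts_metadata", "doseresponse")])
  for (p in inputs) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p),
                              call. = FALSE)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_default <- function(key, default) {
    if (is.null(config[[key]])) default else config[[key]]
  }
  manifest <- list(
    tool = "rbscreen",
    version = as.character(utils::packageVersion("rbscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[setdiff(names(config), "output_dir")],
    input_md5 = as.list(tools::md5sum(inputs)),
    stages = list()
  )

  log_msg <- function(...) message(sprintf(...))

  if ("hubscan" %in% stages) {
    expr <- read_expression(config$expression, config$expression_metadata)
    net <- read_network(config$network)
    rf <- cfg_default("retain_fraction", 1)
    if (rf < 1) net <- extract_skeleton(net, rf)
    scan <- consensus_scan(
      expr, net,
      n_runs = cfg_default("n_runs", 3),
      subsample_fraction = cfg_default("subsample_fraction", 2 / 3),
      alpha = cfg_default("alpha", 0.05),
      n_perm = cfg_default("n_perm", 1000),
      min_partners = cfg_default("min_partners", 5),
      seed = config$seed
    )
    out <- file.path(config$output_dir, "hubscan_results.tsv")
    utils::write.table(scan$table, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_msg("hubscan: %d hubs scanned, %d disrupted -> %s",
            nrow(scan$table), length(scan$disrupted_hubs), out)
    manifest$stages$hubscan <- list(
      n_hubs = nrow(scan$table),
      n_disrupted = length(scan$disrupted_hubs), output = out
    )
  }

  if ("screen" %in% stages) {
    raw <- read_counts(config$counts, config$counts_metadata)
    norm <- normalize_counts(raw, cfg_default("target_total", 1e7))
    pc <- cfg_default("pseudocount", 0.1)
    excl <- robust_z_exclude(log_transform(norm, pc),
                             threshold = cfg_default("robust_z_threshold", 5),
                             max_excluded = cfg_default("max_excluded", 2))
    scores <- dropout_z(norm, excl, z_cut = cfg_default("z_cut", -1.96),
                        pseudocount = pc)
    hits1 <- gene_hits_screen1(scores,
                               min_shrnas = cfg_default("min_shrnas", 2))
    lr <- screen_log_ratios(norm, excl, pc)
    hits2 <- gene_hits_screen2(lr, cutoff = cfg_default("ratio_cut", -0.69),
                               min_shrnas = cfg_default("min_shrnas", 2))
    out_s <- file.path(config$output_dir, "screen_shrna_scores.tsv")
    out_g1 <- file.path(config$output_dir, "screen_gene_hits_z.tsv")
    out_g2 <- file.path(config$output_dir, "screen_gene_hits_ratio.tsv")
    utils::write.table(scores$table, out_s, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(hits1, out_g1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(hits2, out_g2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_msg("screen: %d shRNA scores, %d Z-hit genes, %d ratio-hit genes",
            nrow(scores$table), sum(hits1$n_lines_hit > 0),
            sum(hits2$n_lines_hit > 0))
    manifest$stages$screen <- list(
      n_shrna_scores = nrow(scores$table),
      n_gene_hits_z = sum(hits1$n_lines_hit > 0),
      n_gene_hits_ratio = sum(hits2$n_lines_hit > 0),
      outputs = c(out_s, out_g1, out_g2)
    )
  }

  if ("synergy" %in% stages) {
    tbl <- read_doseresponse(config$doseresponse)
    fa <- fa_growth(tbl$effect_value, tbl$control_value)
    single <- list()
    for (i in 1:3) {
      di <- tbl[[paste0("drug", i, "_dose")]]
      only <- di > 0 &
        rowSums(as.matrix(tbl[paste0("drug", setdiff(1:3, i), "_dose")])) == 0
      if (sum(only) >= 2L) {
        single[[as.character(i)]] <-
          fit_median_effect(di[only], fa[only], drug = paste0("drug", i))
      }
    }
    combo_rows <- which(rowSums(as.matrix(
      tbl[paste0("drug", 1:3, "_dose")]) > 0) >= 2L)
    points <- lapply(combo_rows, function(r) {
      dr <- as.numeric(tbl[r, paste0("drug", 1:3, "_dose")])
      active <- which(dr > 0)
      if (!all(as.character(active) %in% names(single))) return(NULL)
      cp <- combination_index(dr[active], fa = clamp_fa(fa[r]),
                              fits = single[as.character(active)],
                              exclusive = cfg_default("exclusive_ci", TRUE))
      data.frame(row = r, fa = cp$fa, ci = cp$ci)
    })
    points <- do.call(rbind, points)
    assessment <- if (!is.null(points) && nrow(points) > 0L) {
      classify_potent(points, fa_min = cfg_default("fa_min", 0.7),
                      ci_max = cfg_default("ci_max", 0.7))
    } else {
      NULL
    }
    out <- file.path(config$output_dir, "synergy_fa_ci.csv")
    fits <- data.frame(
      drug = vapply(single, function(f) f$drug, character(1)),
      m = vapply(single, function(f) f$m, numeric(1)),
      dm = vapply(single, function(f) f$dm, numeric(1)),
      r_fit = vapply(single, function(f) f$r_fit, numeric(1))
    )
    utils::write.csv(points, out, row.names = FALSE)
    out_f <- file.path(config$output_dir, "synergy_fits.csv")
    utils::write.csv(fits, out_f, row.names = FALSE)
    log_msg("synergy: %d fits, %d combination points%s", nrow(fits),
            if (is.null(points)) 0L else nrow(points),
            if (!is.null(assessment) && assessment$potent) ", POTENT" else "")
    manifest$stages$synergy <- list(
      n_fits = nrow(fits),
      n_points = if (is.null(points)) 0L else nrow(points),
      potent = if (is.null(assessment)) NA else assessment$potent,
      outputs = c(out, out_f)
    )
  }

  manifest_path <- file.path(config$output_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  log_msg("manifest -> %s", manifest_path)
  invisible(manifest)
}
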