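# Differential hub co-expression scanning: per-hub
# mean-absolute-correlation-difference statistic, label-permutation
# p-values and subsample consensus calling.

#' Extract the high-betweenness skeleton of a network
#'
#' Keeps the top \code{ceiling(retain_fraction * |E|)} edges by edge
#' betweenness centrality, then removes nodes left with degree zero. The
#' skeleton preserves the modular backbone of a densely entangled
#' interaction network while greatly simplifying it.
#'
#' @param net Undirected \pkg{igraph} network (see
#'   \code{\link{gene_network}}).
#' @param retain_fraction Fraction of edges to keep, in (0, 1]. At 1 the
#'   edge set is unchanged and only pre-existing singletons are dropped.
#' @return The skeleton as an \pkg{igraph} network.
#' @export
extract_skeleton <- function(net, retain_fraction = 0.2) {
  check_scalar(retain_fraction, "retain_fraction", lower = 0, upper = 1,
               open_lower = TRUE)
  ne <- igraph::ecount(net)
  if (ne == 0L) stop("network has no edges", call. = FALSE)
  eb <- igraph::edge_betweenness(net, directed = FALSE)
  k <- ceiling(retain_fraction * ne)
  keep <- order(-eb, seq_len(ne))[seq_len(k)]   # ties broken by edge order
  skel <- igraph::subgraph_from_edges(net, keep, delete.vertices = FALSE)
  igraph::delete_vertices(skel, igraph::V(skel)[igraph::degree(skel) == 0])
}

#' Identify network hubs by degree
#'
#' A hub is a node with more than \code{min_partners - 1} interaction
#' partners; the default (degree at least 5) matches the convention
#' "more than 4 known partners".
#'
#' @param net Undirected \pkg{igraph} network.
#' @param min_partners Minimum degree for hub status.
#' @return Character vector of hub ids.
#' @export
identify_hubs <- function(net, min_partners = 5) {
  check_scalar(min_partners, "min_partners", lower = 1, integer = TRUE)
  deg <- igraph::degree(net)
  names(deg)[deg >= min_partners]
}

# Split an expression matrix into the two condition groups restricted to
# the given genes; returns NULL for genes missing from the matrix.
cond_split <- function(expr, genes) {
  present <- genes %in% rownames(expr$values)
  list(present = present,
       a = expr$values[genes[present], expr$condition == levels(expr$condition)[1L], drop = FALSE],
       b = expr$values[genes[present], expr$condition == levels(expr$condition)[2L], drop = FALSE])
}

#' Hub disruption statistic
#'
#' Computes the per-hub score S: the mean over usable partners of the
#' absolute difference between the hub--partner Pearson correlation in
#' condition A and in condition B. Partners absent from the matrix or with
#' zero variance in either condition are dropped from the mean (their
#' count is reported); if no usable partner remains the score is
#' \code{NA} and the result is flagged rather than silently zero.
#'
#' @param hub Hub gene id (must be present in \code{expr}).
#' @param partners Character vector of partner gene ids.
#' @param expr An \code{\link{expression_matrix}}.
#' @return A list with \code{hub_id}, \code{partner_ids} (usable
#'   partners), \code{score} (in [0, 2] or NA), \code{n_partners_used}
#'   and \code{usable} (logical flag).
#' @export
hub_statistic <- function(hub, partners, expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!hub %in% rownames(expr$values)) {
    stop(sprintf("hub '%s' not in expression matrix", hub), call. = FALSE)
  }
  sp <- cond_split(expr, c(hub, partners))
  if (!sp$present[1L]) stop("hub missing", call. = FALSE)
  ha <- sp$a[1L, ]
  hb <- sp$b[1L, ]
  pa <- sp$a[-1L, , drop = FALSE]
  pb <- sp$b[-1L, , drop = FALSE]
  ok_var <- function(x) stats::sd(x) > 0
  hub_ok <- ok_var(ha) && ok_var(hb)
  usable <- hub_ok & apply(pa, 1L, ok_var) & apply(pb, 1L, ok_var)
  kept <- rownames(pa)[usable]
  if (length(kept) == 0L) {
    return(list(hub_id = hub, partner_ids = character(), score = NA_real_,
                n_partners_used = 0L, usable = FALSE))
  }
  ra <- as.vector(stats::cor(ha, t(pa[kept, , drop = FALSE])))
  rb <- as.vector(stats::cor(hb, t(pb[kept, , drop = FALSE])))
  list(hub_id = hub, partner_ids = kept,
       score = mean(abs(ra - rb)),
       n_partners_used = length(kept), usable = TRUE)
}

# Vectorised permutation null for one hub: S for `n_perm` random
# relabelings of the samples, preserving group sizes. h: hub values (n);
# p: partners x n matrix; ga: logical group-A membership per permutation
# (n_perm x n).
perm_scores <- function(h, p, ga) {
  n <- length(h)
  na <- rowSums(ga)            # constant across rows by construction
  nb <- n - na
  ph <- sweep(p, 2L, h, "*")
  tg <- t(ga)
  sh_a <- as.vector(ga %*% h)
  shh_a <- as.vector(ga %*% h^2)
  sp_a <- p %*% tg
  spp_a <- (p^2) %*% tg
  sph_a <- ph %*% tg
  corr_from <- function(nn, sh, shh, sp, spp, sph) {
    num <- nn * sph - sweep(sp, 2L, sh, "*")
    den <- sweep(sqrt(pmax(nn * spp - sp^2, 0)), 2L,
                 sqrt(pmax(nn * shh - sh^2, 0)), "*")
    r <- num / den
    r[!is.finite(r)] <- NA_real_
    r
  }
  ra <- corr_from(na[1L], sh_a, shh_a, sp_a, spp_a, sph_a)
  sh_b <- sum(h) - sh_a
  shh_b <- sum(h^2) - shh_a
  sp_b <- rowSums(p) - sp_a
  spp_b <- rowSums(p^2) - spp_a
  sph_b <- rowSums(ph) - sph_a
  rb <- corr_from(nb[1L], sh_b, shh_b, sp_b, spp_b, sph_b)
  colMeans(abs(ra - rb), na.rm = TRUE)
}

#' Permutation p-value for a hub's disruption score
#'
#' Compares the observed statistic S against its null distribution under
#' random permutation of the condition labels (group sizes preserved).
#' The p-value uses add-one smoothing, p = (1 + #\{S_perm >= S_obs\}) /
#' (1 + n_perm), so it is always strictly positive.
#'
#' @inheritParams hub_statistic
#' @param n_perm Number of label permutations.
#' @param seed Integer RNG seed, or \code{NULL} to draw from the current
#'   RNG stream (used inside \code{\link{consensus_scan}}).
#' @return The \code{\link{hub_statistic}} list extended with
#'   \code{p_value} and \code{n_perm}.
#' @export
permutation_pvalue <- function(hub, partners, expr, n_perm = 1000,
                               seed = NULL) {
  check_scalar(n_perm, "n_perm", lower = 1, integer = TRUE)
  obs <- hub_statistic(hub, partners, expr)
  if (!obs$usable) {
    obs$p_value <- NA_real_
    obs$n_perm <- n_perm
    return(obs)
  }
  n <- ncol(expr$values)
  na <- sum(expr$condition == levels(expr$condition)[1L])
  vals <- expr$values[c(hub, obs$partner_ids), , drop = FALSE]
  with_seed(seed, {
    ga <- matrix(FALSE, n_perm, n)
    for (i in seq_len(n_perm)) ga[i, sample.int(n, na)] <- TRUE
    s_perm <- perm_scores(vals[1L, ], vals[-1L, , drop = FALSE], ga)
    obs$p_value <- (1 + sum(s_perm >= obs$score, na.rm = TRUE)) / (1 + n_perm)
    obs$n_perm <- n_perm
    obs
  })
}

#' Consensus scan for disrupted hubs
#'
#' Runs the hub-disruption permutation test \code{n_runs} times, each time
#' on a stratified random subsample of the samples
#' (\code{ceiling(subsample_fraction * n)} per condition), and calls a hub
#' disrupted only if it is significant at \code{alpha} in every run. With
#' the default two-thirds fraction a 21 + 12 design subsamples to
#' 14 + 8.
#'
#' @param expr An \code{\link{expression_matrix}}.
#' @param net Undirected \pkg{igraph} network; hubs are its nodes with
#'   degree at least \code{min_partners}.
#' @param n_runs Number of consensus runs.
#' @param subsample_fraction Fraction of samples drawn per condition each
#'   run, in (0, 1].
#' @param alpha Per-run significance level.
#' @param n_perm Permutations per hub per run.
#' @param min_partners Minimum degree for hub status.
#' @param seed Integer RNG seed; all subsampling and permutation
#'   randomness flows from it.
#' @return An object of class \code{"hub_scan"}: a list with
#'   \code{table} (per-hub data frame: score and p per run, per-run
#'   significance flags, consensus flag), \code{runs} (list of per-run
#'   significant-hub id sets), \code{disrupted_hubs} (their
#'   intersection) and \code{params}.
#' @export
consensus_scan <- function(expr, net, n_runs = 3, subsample_fraction = 2 / 3,
                           alpha = 0.05, n_perm = 1000, min_partners = 5,
                           seed) {
  stopifnot(inherits(expr, "expr_matrix"))
  check_scalar(n_runs, "n_runs", lower = 1, integer = TRUE)
  check_scalar(subsample_fraction, "subsample_fraction", lower = 0, upper = 1,
               open_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  hubs <- identify_hubs(net, min_partners)
  hubs <- hubs[hubs %in% rownames(expr$values)]
  if (length(hubs) == 0L) stop("no hubs present in the expression matrix",
                               call. = FALSE)
  lev <- levels(expr$condition)
  idx_by_cond <- lapply(lev, function(l) which(expr$condition == l))
  n_take <- vapply(idx_by_cond, function(ix) {
    as.integer(ceiling(subsample_fraction * length(ix)))
  }, integer(1))
  if (any(n_take < 3L)) {
    stop("subsample leaves fewer than 3 samples in a condition",
         call. = FALSE)
  }
  partner_of <- lapply(hubs, function(h) {
    names(igraph::neighbors(net, h))
  })
  names(partner_of) <- hubs

  with_seed(seed, {
    runs <- vector("list", n_runs)
    pmat <- matrix(NA_real_, length(hubs), n_runs,
                   dimnames = list(hubs, paste0("run", seq_len(n_runs))))
    smat <- pmat
    for (r in seq_len(n_runs)) {
      take <- unlist(lapply(seq_along(idx_by_cond), function(i) {
        sample(idx_by_cond[[i]], n_take[i])
      }))
      sub <- expression_matrix(expr$values[, take, drop = FALSE],
                               droplevels(expr$condition[take]))
      for (h in hubs) {
        res <- permutation_pvalue(h, partner_of[[h]], sub, n_perm,
                                  seed = NULL)
        pmat[h, r] <- res$p_value
        smat[h, r] <- res$score
      }
      runs[[r]] <- hubs[!is.na(pmat[, r]) & pmat[, r] <= alpha]
    }
    disrupted <- Reduce(intersect, runs)
    sig <- !is.na(pmat) & pmat <= alpha
    colnames(sig) <- paste0("sig_", colnames(pmat))
    tab <- data.frame(
      hub = hubs,
      n_partners = lengths(partner_of[hubs]),
      score_mean = rowMeans(smat, na.rm = TRUE),
      p_max = apply(pmat, 1L, max),
      stringsAsFactors = FALSE
    )
    tab <- cbind(tab, pmat, sig,
                 consensus = hubs %in% disrupted)
    rownames(tab) <- NULL
    structure(list(table = tab, runs = runs, disrupted_hubs = disrupted,
                   params = list(n_runs = n_runs,
                                 subsample_fraction = subsample_fraction,
                                 alpha = alpha, n_perm = n_perm,
                                 min_partners = min_partners, seed = seed)),
              class = "hub_scan")
  })
}

#' @export
print.hub_scan <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Consensus hub scan: %d hubs, %d run(s) at %.0f%% subsamples, %d permutations, alpha = %g\n",
    nrow(x$table), p$n_runs, 100 * p$subsample_fraction, p$n_perm, p$alpha
  ))
  cat(sprintf("Disrupted hubs (significant in all runs): %d\n",
              length(x$disrupted_hubs)))
  if (length(x$disrupted_hubs) > 0L) {
    cat(" ", paste(x$disrupted_hubs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.hub_scan <- function(object, ...) {
  print(object)
  sig_runs <- rowSums(object$table[, grep("^sig_", names(object$table)),
                                   drop = FALSE])
  cat("Hubs by number of significant runs:\n")
  print(table(sig_runs))
  invisible(object$table)
}

#' Cross-species confirmation of disrupted hubs
#'
#' Intersects two disrupted-hub sets through a one-to-one ortholog map:
#' a hub from the first scan is confirmed if its ortholog is disrupted in
#' the second. Ortholog pairs that are many-to-many are dropped, and hubs
#' without a mapping are skipped (both reported via \code{message}).
#'
#' @param result_a,result_b \code{"hub_scan"} objects (or plain character
#'   vectors of disrupted hub ids).
#' @param map Two-column data frame: species-A id, species-B id.
#' @return Character vector of confirmed species-A hub ids.
#' @export
cross_species_confirm <- function(result_a, result_b, map) {
  hits_a <- if (inherits(result_a, "hub_scan")) result_a$disrupted_hubs else result_a
  hits_b <- if (inherits(result_b, "hub_scan")) result_b$disrupted_hubs else result_b
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (ncol(map) < 2L) stop("`map` needs two columns", call. = FALSE)
  a <- as.character(map[[1L]])
  b <- as.character(map[[2L]])
  many <- a %in% a[duplicated(a)] | b %in% b[duplicated(b)]
  if (any(many)) {
    message(sprintf("dropped %d many-to-many ortholog pair(s)", sum(many)))
    a <- a[!many]
    b <- b[!many]
  }
  ortho <- stats::setNames(b, a)
  unmapped <- setdiff(hits_a, names(ortho))
  if (length(unmapped) > 0L) {
    message(sprintf("skipped %d hub(s) without an ortholog mapping: %s",
                    length(unmapped),
                    paste(utils::head(unmapped, 5L), collapse = ", ")))
  }
  mapped <- intersect(hits_a, names(ortho))
  mapped[ortho[mapped] %in% hits_b]
}
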