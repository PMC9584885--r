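# PSI quantification, variable-event summaries, differential exon skipping
# with coverage/effect-size filters, the permutation null for the number of
# significant events, spliceosome~PSI correlation, and exon-level usage.

#' Percent-spliced-in (PSI) matrix from junction counts
#'
#' Length-normalized convention: `PSI = (I/lI) / (I/lI + S/lS)`. PSI is
#' missing exactly when both counts are zero.
#'
#' @param events a [splice_event_table()].
#' @return numeric events x samples matrix with values in \[0, 1\] or NA.
#' @export
compute_psi <- function(events) {
  stopifnot(inherits(events, "splice_event_table"))
  lI <- events$events$incl_len
  lS <- events$events$skip_len
  inorm <- events$incl / lI
  snorm <- events$skip / lS
  psi <- inorm / (inorm + snorm)
  psi[events$incl + events$skip == 0] <- NA_real_
  psi
}

#' Most variable events of a category
#'
#' Selects the `n` events of the given category with the largest
#' missing-aware across-sample PSI variance; ties (including the
#' all-constant degenerate case, which is flagged with a warning) are broken
#' by event id.
#'
#' @param events a [splice_event_table()].
#' @param category event category (`"SE"`, `"A3SS"`, ...).
#' @param n number of events to keep.
#' @param psi optional precomputed [compute_psi()] matrix.
#' @return character vector of event ids.
#' @export
top_variable_events <- function(events, category, n = 1000, psi = NULL) {
  if (n <= 0) stopf("n must be positive")
  if (is.null(psi)) psi <- compute_psi(events)
  sel <- events$events$category == category
  if (!any(sel)) stopf("no events of category %s", category)
  ids <- events$events$event_id[sel]
  v <- apply(psi[sel, , drop = FALSE], 1, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0
  if (all(v == 0)) warnf("all PSI variances are zero; selection by id order")
  sort(ids[order(-v, ids)][seq_len(min(n, length(ids)))])
}

#' Per-sample mean PSI over an event subset
#'
#' @param psi_subset PSI matrix (events x samples).
#' @return named per-sample means (missing-aware); a sample with all-missing
#'   PSI yields NA with a warning.
#' @export
mean_psi <- function(psi_subset) {
  if (!nrow(psi_subset)) stopf("need at least one event")
  out <- colMeans(psi_subset, na.rm = TRUE)
  all_na <- colSums(!is.na(psi_subset)) == 0
  if (any(all_na)) {
    warnf("%d sample(s) have all-missing PSI", sum(all_na))
    out[all_na] <- NA_real_
  }
  out
}

# Vectorized two-sided Wilcoxon rank-sum over matrix rows (normal
# approximation with tie correction and continuity correction, matching
# wilcox.test(exact = FALSE, correct = TRUE)). Ranks and tie terms depend
# only on the data, so they are computed once and reused across many label
# permutations via matrix products.
rank_sum_core <- function(values) {
  ranks <- t(apply(values, 1, rank, na.last = "keep"))
  valid <- !is.na(values)
  ranks0 <- ranks
  ranks0[!valid] <- 0
  tie_term <- apply(values, 1, function(v) {
    t <- table(v[!is.na(v)])
    sum(t^3 - t)
  })
  list(ranks0 = ranks0, valid = valid, tie_term = tie_term)
}

rank_sum_p <- function(core, g) {
  g <- as.numeric(g)
  n1 <- core$valid %*% g
  n2 <- core$valid %*% (1 - g)
  N <- n1 + n2
  W1 <- core$ranks0 %*% g
  U <- W1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((N + 1) - core$tie_term / (N * (N - 1)))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sig2)
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(p)] <- NA_real_
  pmin(as.vector(p), 1)
}

#' Differential exon skipping between a group and the rest
#'
#' Per-event two-sided rank-sum test on PSI with BH adjustment across
#' events, combined with two filters: groupwise mean PSI difference
#' `|dPSI| > min_dpsi`, and mean raw inclusion counts across all samples
#' `> min_mean_incl` (events at or below the coverage bound are excluded
#' regardless of significance).
#'
#' @param events a [splice_event_table()].
#' @param labels logical per sample: in the group of interest.
#' @param fdr BH-adjusted p threshold (default 0.01).
#' @param min_dpsi minimum absolute groupwise mean PSI difference.
#' @param min_mean_incl coverage bound on mean inclusion counts.
#' @param category optional category restriction (default `"SE"`).
#' @return data.frame `event_id, category, dpsi, mean_incl, p, p_adj,
#'   significant`.
#' @export
differential_psi <- function(events, labels, fdr = 0.01, min_dpsi = 0.1,
                             min_mean_incl = 20, category = "SE") {
  labels <- as.logical(labels)
  if (sum(labels) < 3 || sum(!labels) < 3) {
    stopf("both groups need at least 3 samples")
  }
  sel <- if (is.null(category)) rep(TRUE, nrow(events$events)) else
    events$events$category == category
  psi <- compute_psi(events)[sel, , drop = FALSE]
  incl <- events$incl[sel, , drop = FALSE]
  core <- rank_sum_core(psi)
  p <- rank_sum_p(core, labels)
  dpsi <- rowMeans(psi[, labels, drop = FALSE], na.rm = TRUE) -
    rowMeans(psi[, !labels, drop = FALSE], na.rm = TRUE)
  mean_incl <- rowMeans(incl)
  p_adj <- bh_adjust(p)
  sig <- !is.na(p_adj) & p_adj < fdr & abs(dpsi) > min_dpsi &
    mean_incl > min_mean_incl
  data.frame(event_id = events$events$event_id[sel],
             category = events$events$category[sel],
             dpsi = dpsi, mean_incl = mean_incl, p = p, p_adj = p_adj,
             significant = sig, stringsAsFactors = FALSE)
}

#' Permutation null for the number of significant splicing events
#'
#' Repeatedly relabels the group of interest by drawing the same number of
#' samples uniformly without replacement, reruns the full
#' [differential_psi()] decision rule, and records the count of significant
#' events N_e. The permutation p-value uses the add-one convention
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams differential_psi
#' @param n_perm number of permutations (>= 19).
#' @param seed RNG seed.
#' @return list with `observed`, `null` (length `n_perm`), `p`, `n_perm`,
#'   `seed`.
#' @export
permutation_null <- function(events, labels, n_perm = 200, seed = 1L,
                             fdr = 0.01, min_dpsi = 0.1, min_mean_incl = 20,
                             category = "SE") {
  if (n_perm < 19) stopf("n_perm must be at least 19")
  labels <- as.logical(labels)
  sel <- if (is.null(category)) rep(TRUE, nrow(events$events)) else
    events$events$category == category
  psi <- compute_psi(events)[sel, , drop = FALSE]
  incl <- events$incl[sel, , drop = FALSE]
  core <- rank_sum_core(psi)
  mean_incl <- rowMeans(incl)
  n <- length(labels)
  k <- sum(labels)
  count_ne <- function(g) {
    p <- rank_sum_p(core, g)
    dpsi <- rowMeans(psi[, g, drop = FALSE], na.rm = TRUE) -
      rowMeans(psi[, !g, drop = FALSE], na.rm = TRUE)
    p_adj <- bh_adjust(p)
    sum(!is.na(p_adj) & p_adj < fdr & abs(dpsi) > min_dpsi &
          mean_incl > min_mean_incl)
  }
  observed <- count_ne(labels)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- rep(FALSE, n)
      g[sample.int(n, k)] <- TRUE
      count_ne(g)
    }, numeric(1))
  })
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  list(observed = observed, null = null, p = p, n_perm = n_perm, seed = seed)
}

#' Spliceosome abundance versus mean PSI, per category
#'
#' Correlates per-sample mean spliceosomal protein abundance with the
#' per-sample mean PSI of each event category (Spearman).
#'
#' @param protein an [omics_matrix()].
#' @param spliceosome_set character vector of spliceosome feature ids.
#' @param mean_psi_by_category named list of per-sample mean PSI vectors
#'   (as produced by [mean_psi()] on per-category subsets).
#' @return data.frame `category, rho, p`.
#' @export
spliceosome_psi_correlation <- function(protein, spliceosome_set,
                                        mean_psi_by_category) {
  idx <- intersect(spliceosome_set, feature_ids(protein))
  if (!length(idx)) stopf("empty spliceosome set")
  spl <- colMeans(protein$values[idx, , drop = FALSE], na.rm = TRUE)
  rows <- lapply(names(mean_psi_by_category), function(cat) {
    mp <- mean_psi_by_category[[cat]][names(spl)]
    ct <- suppressWarnings(stats::cor.test(spl, mp, method = "spearman",
                                           exact = FALSE))
    data.frame(category = cat, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exon-level relative usage tests
#'
#' For each exon with enough presence, the deviation from its gene's mean
#' profile is tested for a group-versus-rest shift with the moderated t
#' machinery of [moderated_fit()]; exons significant at `fdr` and
#' `|log2FC| > lfc_cut` are counted per group and group enrichment is
#' assessed by one-sided Fisher tests.
#'
#' @param exon_quant exon x sample log2 matrix.
#' @param gene_map data.frame `exon_id, gene_symbol`.
#' @param labels group label per sample (factor/character, >= 2 groups).
#' @param min_presence exons quantified in `min_presence` or fewer batches
#'   are excluded; `batches` defaults to one batch per sample.
#' @param batches optional batch assignment per sample.
#' @param fdr,lfc_cut significance thresholds (defaults 0.01, 0.5).
#' @return list with `per_group` (named list of per-exon tables) and
#'   `enrichment` (`group, n_sig, p, p_adj`).
#' @export
diffsplice_exons <- function(exon_quant, gene_map, labels, min_presence = 2,
                             batches = NULL, fdr = 0.01, lfc_cut = 0.5) {
  stopifnot(ncol(exon_quant) == length(labels))
  if (is.null(batches)) batches <- colnames(exon_quant)
  presence <- apply(!is.na(exon_quant), 1, function(ok) {
    length(unique(batches[ok]))
  })
  keep <- presence > min_presence
  exon_quant <- exon_quant[keep, , drop = FALSE]
  gm <- gene_map[match(rownames(exon_quant), gene_map$exon_id), , drop = FALSE]
  n_ex <- table(gm$gene_symbol)
  single <- names(n_ex)[n_ex < 2]
  if (length(single)) {
    warnf("%d single-exon gene(s) skipped", length(single))
  }
  keep2 <- !(gm$gene_symbol %in% single)
  exon_quant <- exon_quant[keep2, , drop = FALSE]
  gm <- gm[keep2, , drop = FALSE]
  # deviation of each exon from its gene's per-sample mean profile
  gene_mean <- rowsum(exon_quant, gm$gene_symbol, na.rm = TRUE) /
    rowsum((!is.na(exon_quant)) * 1, gm$gene_symbol)
  dev <- exon_quant - gene_mean[gm$gene_symbol, , drop = FALSE]
  dev_m <- omics_matrix(dev)
  groups <- sort(unique(as.character(labels)))
  per_group <- list()
  n_sig <- integer(length(groups))
  for (gi in seq_along(groups)) {
    g <- as.integer(labels == groups[gi])
    design <- cbind(intercept = 1, group = g)
    res <- moderated_fit(dev_m, design, "group")
    res$hit <- !is.na(res$p_adj) & res$p_adj < fdr & abs(res$log2FC) > lfc_cut
    per_group[[groups[gi]]] <- res
    n_sig[gi] <- sum(res$hit)
  }
  n_tests <- nrow(dev)
  p_enr <- vapply(seq_along(groups), function(gi) {
    other_sig <- sum(n_sig[-gi])
    mat <- matrix(c(n_sig[gi], n_tests - n_sig[gi],
                    other_sig, n_tests * (length(groups) - 1) - other_sig), 2)
    stats::fisher.test(mat, alternative = "greater")$p.value
  }, numeric(1))
  list(per_group = per_group,
       enrichment = data.frame(group = groups, n_sig = n_sig, p = p_enr,
                               p_adj = bh_adjust(p_enr),
                               stringsAsFactors = FALSE))
}
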