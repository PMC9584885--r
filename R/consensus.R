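# Resampling-based (Monti-style) consensus clustering, k selection,
# final labels, genotype enrichment, and PCA embedding.

# samples x features matrix for clustering: transpose, impute per-feature
# median for missing values, keep the top-variance features.
clustering_input <- function(x, n_top_features) {
  vals <- x$values
  med <- apply(vals, 1, stats::median, na.rm = TRUE)
  nas <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(nas)) vals[nas] <- med[nas[, 1L]]
  v <- apply(vals, 1, stats::var)
  keep <- order(-v, rownames(vals))[seq_len(min(n_top_features, nrow(vals)))]
  t(vals[keep, , drop = FALSE])
}

inner_cluster <- function(X, k, method) {
  if (method == "kmeans") {
    stats::kmeans(X, centers = k, nstart = 10, iter.max = 50)$cluster
  } else {
    d <- stats::as.dist(1 - stats::cor(t(X)))
    stats::cutree(stats::hclust(d, method = "average"), k)
  }
}

#' Consensus clustering by subsampled re-clustering
#'
#' Monti-style resampling: at each iteration a fraction of samples is drawn
#' without replacement and clustered; the consensus for a sample pair is the
#' number of co-clusterings divided by the number of co-samplings. Run for
#' each k in `k_range`; per-k consensus matrices, CDF areas and final labels
#' (average-linkage cut of 1 - consensus) are returned.
#'
#' @param x an [omics_matrix()].
#' @param k_range integer vector of cluster numbers (each in `[2, n-1]`).
#' @param n_iter resampling iterations (>= 10).
#' @param item_frac fraction of samples drawn per iteration.
#' @param inner inner algorithm, `"kmeans"` (10 restarts) or
#'   `"hierarchical"` (1 - Pearson, average linkage).
#' @param n_top_features cluster on this many top-variance features.
#' @param seed RNG seed.
#' @return A `consensus_result`: list with `consensus` (per-k matrices),
#'   `area`, `delta_area`, `labels` (per-k), `k_range`, `params`.
#' @export
consensus_cluster <- function(x, k_range = 2:8, n_iter = 1000,
                              item_frac = 0.8, inner = c("kmeans", "hierarchical"),
                              n_top_features = 2000, seed = 1L) {
  inner <- match.arg(inner)
  X <- clustering_input(x, n_top_features)
  n <- nrow(X)
  if (any(k_range < 2 | k_range > n - 1)) stopf("k_range must lie in [2, n-1]")
  if (n_iter < 10) stopf("n_iter must be at least 10")
  m <- ceiling(item_frac * n)
  res <- with_seed(seed, {
    cons <- list()
    for (k in k_range) {
      tally <- denom <- matrix(0, n, n)
      for (it in seq_len(n_iter)) {
        idx <- if (m >= n) seq_len(n) else sort(sample.int(n, m))
        cl <- inner_cluster(X[idx, , drop = FALSE], k, inner)
        co <- outer(cl, cl, "==")
        denom[idx, idx] <- denom[idx, idx] + 1
        tally[idx, idx] <- tally[idx, idx] + co
      }
      never <- denom == 0
      if (any(never[upper.tri(never)])) {
        warnf("some sample pairs were never co-sampled; consensus set to 0")
        denom[never] <- 1
      }
      C <- tally / denom
      diag(C) <- 1
      dimnames(C) <- list(rownames(X), rownames(X))
      stopifnot(isTRUE(all.equal(C, t(C))), all(C >= 0 & C <= 1))
      cons[[as.character(k)]] <- C
    }
    cons
  })
  area <- vapply(res, consensus_cdf_area, numeric(1))
  delta <- if (length(area) > 1) {
    c(area[1L], diff(area) / area[-length(area)])
  } else {
    area
  }
  labels <- lapply(seq_along(k_range), function(i) {
    final_labels(res[[i]], k_range[i])
  })
  names(labels) <- names(res)
  structure(list(consensus = res, area = area, delta_area = delta,
                 labels = labels, k_range = k_range,
                 params = list(n_iter = n_iter, item_frac = item_frac,
                               inner = inner, n_top_features = n_top_features,
                               seed = seed)),
            class = "consensus_result")
}

# Area under the empirical CDF of the upper-triangle consensus entries.
consensus_cdf_area <- function(C) {
  v <- sort(C[upper.tri(C)])
  xs <- unique(c(0, v, 1))
  cdf <- stats::ecdf(v)
  sum(diff(xs) * cdf(xs[-length(xs)]))
}

#' Choose the number of clusters from consensus stability
#'
#' Delta-area elbow rule: the smallest k whose relative CDF-area increase to
#' k+1 falls below `tol`; a biologically motivated `override` wins when
#' provided and is recorded in the `provenance` attribute. Flat consensus
#' (no k clears the elbow and stability is uninformative) returns the
#' smallest k with a warning.
#'
#' @param result a [consensus_cluster()] result.
#' @param override optional integer k to force (must be in `k_range`).
#' @param tol relative delta-area threshold (default 0.1; beyond the true
#'   cluster count the relative area gain settles just above 0.05 even on
#'   cleanly separated data, so the elbow cut sits at 0.1).
#' @return chosen k with attribute `provenance` (`"elbow"` or `"override"`).
#' @export
choose_k <- function(result, override = NULL, tol = 0.1) {
  kr <- result$k_range
  if (!is.null(override)) {
    if (!override %in% kr) stopf("override k=%d outside evaluated range", override)
    return(structure(override, provenance = "override"))
  }
  if (length(kr) < 2) stopf("need at least 2 evaluated k values")
  rel <- result$delta_area[-1L]  # relative increase from k to k+1
  below <- which(rel < tol)
  if (!length(below)) {
    warnf("no elbow found; returning the largest evaluated k")
    return(structure(kr[length(kr)], provenance = "elbow"))
  }
  k <- kr[below[1L]]
  cm <- result$consensus[[as.character(k)]]
  spread <- stats::sd(cm[upper.tri(cm)])
  if (k == kr[1L] && below[1L] == 1L && all(rel < tol) && spread < 0.15) {
    warnf("flat consensus; returning the smallest k")
  }
  structure(k, provenance = "elbow")
}

#' Final labels from a consensus matrix
#'
#' Average-linkage hierarchical clustering on `1 - consensus`, cut at k.
#'
#' @param consensus symmetric consensus matrix.
#' @param k number of clusters (`k <= n`).
#' @return integer labels named by sample.
#' @export
final_labels <- function(consensus, k) {
  n <- nrow(consensus)
  if (k > n) stopf("k exceeds number of samples")
  if (k == 1) return(setNames(rep(1L, n), rownames(consensus)))
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  stats::cutree(hc, k)
}

#' Genotype enrichment of cluster groups
#'
#' Two-sided Fisher tests of each (group vs rest) x (lesion vs not) 2x2
#' table, BH-adjusted across all pairs; both enrichment and depletion are
#' reported (odds ratio > 1 or < 1). Constant lesion columns are skipped
#' with a warning.
#'
#' @param labels cluster labels per sample.
#' @param lesions data.frame of 0/1 lesion columns, rows aligned to labels.
#' @param fdr hit threshold on adjusted p (default 0.10).
#' @return data.frame `group, lesion, in_group, out_group, odds_ratio, p,
#'   p_adj, hit, direction`.
#' @export
genotype_enrichment <- function(labels, lesions, fdr = 0.10) {
  stopifnot(length(labels) == nrow(lesions))
  rows <- list()
  for (lesion in names(lesions)) {
    v <- lesions[[lesion]]
    if (length(unique(v[!is.na(v)])) < 2) {
      warnf("lesion '%s' is constant; skipped", lesion)
      next
    }
    for (g in sort(unique(labels))) {
      ing <- labels == g
      tab <- table(factor(ing, c(TRUE, FALSE)), factor(v == 1, c(TRUE, FALSE)))
      ft <- stats::fisher.test(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, lesion = lesion,
        in_group = sum(v[ing] == 1, na.rm = TRUE),
        out_group = sum(v[!ing] == 1, na.rm = TRUE),
        odds_ratio = unname(ft$estimate), p = min(ft$p.value, 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$hit <- out$p_adj < fdr
  out$direction <- ifelse(out$odds_ratio > 1, "enriched", "depleted")
  out[order(out$p), ]
}

#' PCA embedding of samples
#'
#' Centered PCA via singular value decomposition with a deterministic sign
#' convention (the largest-magnitude loading of each component is positive).
#' Missing values are imputed at the per-feature median.
#'
#' @param x an [omics_matrix()].
#' @param n_comp number of components (`<= min(features, samples)`).
#' @return list with `coords` (samples x n_comp) and `var_explained`.
#' @export
pca_embed <- function(x, n_comp = 2) {
  X <- clustering_input(x, nrow(x$values))
  if (n_comp < 1 || n_comp > min(dim(X))) stopf("invalid n_comp")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation[, seq_len(n_comp), drop = FALSE], 2, function(v) {
    sign(v[which.max(abs(v))])
  })
  coords <- sweep(pc$x[, seq_len(n_comp), drop = FALSE], 2, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = coords, var_explained = ve[seq_len(n_comp)])
}
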