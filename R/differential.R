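# Moderated differential abundance, dosage profiling, mRNA~protein
# correlation structure, over-representation tests, and chr12-based
# trisomy-12 inference.

#' Build a design matrix from annotation columns
#'
#' Accepts a formula-like string such as `"IGHV + trisomy12 + IGHV:trisomy12"`
#' and returns the model matrix (with intercept) over the annotation table.
#'
#' @param annotation data.frame of per-sample covariates.
#' @param terms character, right-hand side of the model formula.
#' @return numeric design matrix, samples x coefficients.
#' @export
build_design <- function(annotation, terms) {
  f <- stats::as.formula(paste("~", terms))
  mm <- stats::model.matrix(f, data = annotation)
  rownames(mm) <- annotation$sample_id
  mm
}

# Method-of-moments fit of a scaled inverse-chi-square prior to observed
# residual variances s2 with df degrees of freedom (moment matching on
# log s2, Smyth 2004). Returns prior df d0 (possibly Inf) and prior
# variance s02.
fit_variance_prior <- function(s2, df) {
  ok <- df > 0 & is.finite(s2) & s2 > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2) return(list(d0 = 0, s02 = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(df / 2))
  if (evar <= 0) {
    # no excess spread in the observed variances: infinite prior df; the
    # prior variance is the geometric mean, so identical variances shrink
    # to themselves
    return(list(d0 = Inf, s02 = exp(mean(z))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton solve of trigamma(y) = x.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Moderated differential fit over an arbitrary design
#'
#' Per-feature least squares of the abundance matrix on the design, with
#' empirical-Bayes variance moderation: a scaled inverse-chi-square prior is
#' fitted to the residual variances by method of moments and each feature's
#' posterior variance is the df-weighted combination
#' `(d0*s0^2 + d*s^2) / (d0 + d)`. Missing values are handled per feature by
#' casewise deletion; features with fewer than 1 residual df are dropped
#' with a warning. P-values use the moderated t on `d0 + d` df; adjustment
#' is Benjamini-Hochberg across features.
#'
#' @param x an [omics_matrix()] (features x samples, log2 scale).
#' @param design samples x coefficients design matrix (see [build_design()]);
#'   must be full column rank.
#' @param coefficient column name of the coefficient to test.
#' @param prior_df optional fixed prior df; `NULL` (default) estimates it,
#'   `0` disables moderation (ordinary t).
#' @return data.frame with `feature_id, log2FC, s2, s2_post, t, df_total,
#'   p, p_adj`; prior parameters in attributes `d0` and `s02`.
#' @export
moderated_fit <- function(x, design, coefficient, prior_df = NULL) {
  stopifnot(inherits(x, "omics_matrix"), is.matrix(design))
  if (!coefficient %in% colnames(design)) {
    stopf("coefficient '%s' not in design", coefficient)
  }
  if (qr(design)$rank < ncol(design)) stopf("design matrix is rank deficient")
  vals <- x$values
  if (!is.null(rownames(design))) {
    if (!identical(rownames(design), colnames(vals))) {
      design <- design[colnames(vals), , drop = FALSE]
    }
  }
  j <- match(coefficient, colnames(design))
  p <- ncol(design)
  nfeat <- nrow(vals)
  beta <- se_unscaled <- s2 <- df <- rep(NA_real_, nfeat)
  for (i in seq_len(nfeat)) {
    yi <- vals[i, ]
    ok <- !is.na(yi)
    di <- sum(ok) - p
    if (di < 1) next
    Xi <- design[ok, , drop = FALSE]
    if (qr(Xi)$rank < p) next
    fit <- stats::lm.fit(Xi, yi[ok])
    beta[i] <- fit$coefficients[j]
    rss <- sum(fit$residuals^2)
    s2[i] <- rss / di
    xtxi <- chol2inv(chol(crossprod(Xi)))
    se_unscaled[i] <- sqrt(xtxi[j, j])
    df[i] <- di
  }
  dropped <- which(is.na(df))
  if (length(dropped)) {
    warnf("%d feature(s) dropped (insufficient residual df after missingness)",
          length(dropped))
  }
  keep <- which(!is.na(df))
  prior <- if (is.null(prior_df)) {
    fit_variance_prior(s2[keep], df[keep])
  } else if (prior_df == 0) {
    list(d0 = 0, s02 = NA_real_)
  } else {
    list(d0 = prior_df, s02 = fit_variance_prior(s2[keep], df[keep])$s02)
  }
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (d0 == 0) {
    s2
  } else if (is.infinite(d0)) {
    rep(s02, nfeat)
  } else {
    (d0 * s02 + df * s2) / (d0 + df)
  }
  tstat <- beta / (se_unscaled * sqrt(s2_post))
  df_total <- pmin(df + d0, 1e6)
  pval <- 2 * stats::pt(-abs(tstat), df_total)
  out <- data.frame(feature_id = rownames(vals), log2FC = beta, s2 = s2,
                    s2_post = s2_post, t = tstat, df_total = df_total,
                    p = pval, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, order-preserving.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential hits by FDR and fold-change thresholds
#'
#' @param results a [moderated_fit()] table.
#' @param lfc_cut minimum absolute log2 fold change (exclusive).
#' @param fdr_cut maximum BH-adjusted p (exclusive).
#' @return list with `n_hits` and `hits` (feature ids); the input table with
#'   a logical `hit` column is in `$table`.
#' @export
call_hits <- function(results, lfc_cut = 0.5, fdr_cut = 0.001) {
  if (lfc_cut < 0 || fdr_cut < 0) stopf("thresholds must be non-negative")
  hit <- !is.na(results$p_adj) & results$p_adj < fdr_cut &
    abs(results$log2FC) > lfc_cut
  results$hit <- hit
  list(n_hits = sum(hit), hits = results$feature_id[hit], table = results)
}

#' Positional abundance profile and off-chromosome hit fraction
#'
#' Per-sample LOWESS curves of abundance versus genomic position on one
#' chromosome, averaged per group; optionally, the fraction of a hit list
#' located off that chromosome (the gene-dosage "trans" fraction).
#'
#' @param x an [omics_matrix()] with positional feature metadata.
#' @param chromosome chromosome name, e.g. `"chr12"`.
#' @param group logical per sample (e.g. trisomy-12 carrier).
#' @param hits optional character vector of hit feature ids.
#' @param span LOWESS smoother span (fraction of chromosome features).
#' @return list with `position`, `curve_group`, `curve_rest`, `gap`
#'   (mean curve difference), and `off_chromosome_fraction` (NA without hits).
#' @export
dosage_profile <- function(x, chromosome, group, hits = NULL, span = 0.3) {
  meta <- x$feature_meta
  if (is.null(meta)) stopf("feature metadata required")
  on_chr <- meta$chromosome == chromosome
  if (!any(on_chr)) stopf("no features on %s", chromosome)
  pos <- (meta$start[on_chr] + meta$end[on_chr]) / 2
  ord <- order(pos)
  vals <- x$values[on_chr, , drop = FALSE][ord, , drop = FALSE]
  pos <- pos[ord]
  smooth_one <- function(v) {
    ok <- !is.na(v)
    stats::lowess(pos[ok], v[ok], f = span)$y[match(pos, pos[ok])]
  }
  curves <- apply(vals, 2, smooth_one)
  curve_group <- rowMeans(curves[, group, drop = FALSE], na.rm = TRUE)
  curve_rest <- rowMeans(curves[, !group, drop = FALSE], na.rm = TRUE)
  off_frac <- NA_real_
  if (!is.null(hits)) {
    hit_chr <- meta$chromosome[match(hits, meta$feature_id)]
    off_frac <- mean(hit_chr != chromosome)
  }
  list(position = pos, curve_group = curve_group, curve_rest = curve_rest,
       gap = mean(curve_group - curve_rest, na.rm = TRUE),
       off_chromosome_fraction = off_frac)
}

#' Per-gene mRNA~protein Spearman correlation
#'
#' Matches protein and transcript features by gene symbol, aligns shared
#' samples, and computes per-gene Spearman correlation (average-rank ties)
#' with BH adjustment. Genes with fewer than 3 complete pairs are skipped
#' with a warning.
#'
#' @param prot,rna [omics_matrix()] objects with `gene_symbol` metadata.
#' @return list with `table` (gene, rho, p, p_adj, class) and `summary`
#'   (median rho overall and per class, fraction significant positive).
#' @export
mrna_protein_spearman <- function(prot, rna) {
  shared_samples <- intersect(sample_ids(prot), sample_ids(rna))
  if (length(shared_samples) < 3) stopf("need at least 3 shared samples")
  pg <- prot$feature_meta$gene_symbol
  rg <- rna$feature_meta$gene_symbol
  genes <- intersect(pg, rg)
  pv <- prot$values[match(genes, pg), shared_samples, drop = FALSE]
  rv <- rna$values[match(genes, rg), shared_samples, drop = FALSE]
  cls <- prot$feature_meta$class
  if (is.null(cls)) cls <- rep("background", length(pg))
  cls <- cls[match(genes, pg)]
  rho <- p <- rep(NA_real_, length(genes))
  skipped <- 0L
  for (i in seq_along(genes)) {
    ok <- !is.na(pv[i, ]) & !is.na(rv[i, ])
    if (sum(ok) < 3) { skipped <- skipped + 1L; next }
    ct <- suppressWarnings(stats::cor.test(pv[i, ok], rv[i, ok],
                                           method = "spearman", exact = FALSE))
    rho[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  if (skipped) warnf("%d gene(s) skipped (<3 paired samples)", skipped)
  keep <- !is.na(rho)
  tab <- data.frame(gene = genes[keep], rho = rho[keep], p = p[keep],
                    class = cls[keep], stringsAsFactors = FALSE)
  tab$p_adj <- bh_adjust(tab$p)
  med_class <- tapply(tab$rho, tab$class, stats::median)
  list(table = tab,
       summary = list(median_rho = stats::median(tab$rho),
                      median_rho_by_class = med_class,
                      frac_significant_positive =
                        mean(tab$p_adj < 0.05 & tab$rho > 0)))
}

#' Compare two correlation distributions by Kolmogorov-Smirnov
#'
#' @param rho_class,rho_other numeric vectors (e.g. per-gene correlations of
#'   one feature class versus the rest).
#' @return list with `D` and `p` (two-sample, two-sided, asymptotic).
#' @export
correlation_cdf_compare <- function(rho_class, rho_other) {
  if (!length(rho_class) || !length(rho_other)) stopf("empty input vector")
  kt <- suppressWarnings(stats::ks.test(rho_class, rho_other))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Scaled-protein coefficient from the interaction regression
#'
#' Ordinary least squares of z-scored mRNA on z-scored protein, IGHV status,
#' trisomy-12 status and their interaction; returns the scaled-protein
#' coefficient (a per-gene coupling estimate adjusted for the two genotypes).
#'
#' @param prot_gene,rna_gene numeric vectors over samples for one gene.
#' @param ighv,tris12 0/1 indicators per sample.
#' @return the scaled-protein coefficient (numeric scalar).
#' @export
scaled_interaction_lm <- function(prot_gene, rna_gene, ighv, tris12) {
  n <- length(prot_gene)
  if (n < 5) stopf("need at least 5 samples")
  d <- data.frame(y = as.numeric(scale(rna_gene)),
                  x = as.numeric(scale(prot_gene)),
                  ighv = ighv, tris12 = tris12)
  X <- stats::model.matrix(~ x + ighv + tris12 + ighv:tris12, d)
  if (qr(X)$rank < ncol(X)) stopf("collinear design")
  fit <- stats::lm.fit(X, d$y)
  unname(fit$coefficients["x"])
}

#' One-sided Fisher over-representation test
#'
#' Hypergeometric upper-tail probability of seeing the observed overlap or
#' more between a hit list and a gene set within a universe.
#'
#' @param hits character vector of hit features (subset of `universe`).
#' @param universe character vector of all tested features.
#' @param gene_set character vector of set members.
#' @return one-sided p-value.
#' @export
fisher_overrepresentation <- function(hits, universe, gene_set) {
  if (!all(hits %in% universe)) stopf("hits must be a subset of the universe")
  gene_set <- intersect(gene_set, universe)
  k <- length(intersect(hits, gene_set))
  stats::phyper(k - 1, length(gene_set), length(universe) - length(gene_set),
                length(hits), lower.tail = FALSE)
}

#' Over-representation across a gene set collection, BH-adjusted
#'
#' @param hits,universe as in [fisher_overrepresentation()].
#' @param gsc a [gene_set_collection()].
#' @return data.frame `set, overlap, size, p, p_adj`.
#' @export
fisher_overrepresentation_sets <- function(hits, universe, gsc) {
  p <- vapply(gsc$sets, function(s) fisher_overrepresentation(hits, universe, s),
              numeric(1))
  ov <- vapply(gsc$sets, function(s) length(intersect(hits, s)), integer(1))
  data.frame(set = names(gsc$sets), overlap = ov,
             size = vapply(gsc$sets, length, integer(1)),
             p = p, p_adj = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Infer trisomy-12 carriers from chr12 abundance
#'
#' Flags the samples with the highest mean chr12 feature abundance: the top
#' `ceiling((1 - quantile) * n)` samples, ties broken deterministically by
#' sample id (with a warning when the boundary is tied).
#'
#' @param x an [omics_matrix()].
#' @param chr12_set character vector of chr12 feature ids.
#' @param quantile flagging quantile (default 0.8: top 20% flagged).
#' @return named logical vector per sample.
#' @export
infer_trisomy12 <- function(x, chr12_set, quantile = 0.8) {
  if (!length(chr12_set)) stopf("empty chr12 feature set")
  idx <- intersect(chr12_set, feature_ids(x))
  if (!length(idx)) stopf("chr12 set has no overlap with matrix features")
  score <- colMeans(x$values[idx, , drop = FALSE], na.rm = TRUE)
  n <- length(score)
  k <- ceiling((1 - quantile) * n)
  flags <- setNames(rep(FALSE, n), names(score))
  if (k >= 1) {
    ord <- order(-score, names(score))
    if (k < n && score[ord[k]] == score[ord[k + 1]]) {
      warnf("tie at the flagging boundary; broken by sample id")
    }
    flags[ord[seq_len(k)]] <- TRUE
  }
  flags
}
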