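# Moderated differential statistics, correlation structure, enrichment,
# and trisomy-12 inference.

# Stepwise BH by definition, used as the independent oracle.
bh_stepwise <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

test_that("bh_adjust matches the step-up definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_stepwise(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH adjustment is permutation-equivariant and dominates raw p", {
  set.seed(2)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
})

make_two_group <- function(nf = 20, n1 = 5, n2 = 5, shift = 1, seed = 3,
                           sd = NULL) {
  set.seed(seed)
  if (is.null(sd)) sd <- runif(nf, 0.2, 1.5)  # heterogeneous variances
  v <- cbind(matrix(rnorm(nf * n1, 10, sd), nf),
             matrix(rnorm(nf * n2, 10 + shift, sd), nf))
  dimnames(v) <- list(sprintf("F%02d", 1:nf), sprintf("S%02d", 1:(n1 + n2)))
  list(m = omics_matrix(v),
       design = cbind(intercept = 1, group = rep(c(0, 1), c(n1, n2))))
}

test_that("moderated_fit log2FC equals group mean difference and the posterior variance is hand-computable", {
  d <- make_two_group(shift = 1)
  res <- moderated_fit(d$m, d$design, "group")
  gm <- rowMeans(d$m$values[, 6:10]) - rowMeans(d$m$values[, 1:5])
  expect_equal(res$log2FC, unname(gm), tolerance = 1e-9)
  d0 <- attr(res, "d0"); s02 <- attr(res, "s02")
  expect_true(d0 > 0 && is.finite(d0))
  expect_equal(res$s2_post, (d0 * s02 + 8 * res$s2) / (d0 + 8), tolerance = 1e-12)
  # posterior variance lies between each s2 and the prior
  expect_true(all(res$s2_post > pmin(res$s2, s02) - 1e-12 &
                    res$s2_post < pmax(res$s2, s02) + 1e-12))
  expect_true(all(res$p_adj >= res$p))
})

test_that("zero prior df reduces the moderated t to the ordinary t", {
  d <- make_two_group(shift = 0.5, seed = 4)
  res <- moderated_fit(d$m, d$design, "group", prior_df = 0)
  n1 <- 5; n2 <- 5
  ord_t <- vapply(seq_len(20), function(i) {
    x <- d$m$values[i, 1:5]; y <- d$m$values[i, 6:10]
    sp <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    (mean(y) - mean(x)) / sqrt(sp * (1 / n1 + 1 / n2))
  }, numeric(1))
  expect_true(all(abs(res$t - ord_t) < 1e-10))
})

test_that("identical residual variances shrink to themselves", {
  # every feature has the same residual pattern, hence identical s2
  resid <- c(-1, 1, -1, 1, -2, 2, -1.5, 1.5, 0.5, -0.5)
  v <- t(sapply(1:10, function(i) i + rep(c(0, 1), each = 5) + resid))
  dimnames(v) <- list(sprintf("F%02d", 1:10), sprintf("S%02d", 1:10))
  m <- omics_matrix(v)
  design <- cbind(intercept = 1, group = rep(c(0, 1), each = 5))
  res <- moderated_fit(m, design, "group")
  expect_equal(res$s2_post, res$s2, tolerance = 1e-12)
  ord <- moderated_fit(m, design, "group", prior_df = 0)
  expect_equal(res$t, ord$t, tolerance = 1e-10)
})

test_that("moderated_fit agrees with the limma oracle on random data", {
  skip_if_not_installed("limma")
  set.seed(8)
  v <- matrix(rnorm(200 * 12, 15, runif(200, 0.3, 1.5)), 200, 12)
  dimnames(v) <- list(sprintf("F%03d", 1:200), sprintf("S%02d", 1:12))
  design <- cbind(intercept = 1, group = rep(c(0, 1), each = 6))
  res <- moderated_fit(omics_matrix(v), design, "group")
  fit <- limma::eBayes(limma::lmFit(v, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$s2_post, unname(fit$s2.post), tolerance = 1e-8)
  expect_equal(res$t, unname(fit$t[, "group"]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, "group"]), tolerance = 1e-8)
})

test_that("moderated_fit validates the design and handles missingness", {
  d <- make_two_group()
  bad <- cbind(d$design, group2 = d$design[, "group"])
  expect_error(moderated_fit(d$m, bad, "group"), "rank deficient")
  expect_error(moderated_fit(d$m, d$design, "nope"), "not in design")
  v <- d$m$values
  v[1, ] <- NA
  expect_warning(res <- moderated_fit(omics_matrix(v), d$design, "group"),
                 "dropped")
  expect_false("F01" %in% res$feature_id)
})

test_that("call_hits applies both thresholds", {
  tab <- data.frame(feature_id = c("a", "b", "c"),
                    log2FC = c(0.6, 2.0, 0.6),
                    p = c(1, 1, 1e-5), p_adj = c(1, 1, 5e-4))
  expect_equal(call_hits(tab, 0.5, 1e-3)$n_hits, 1L)
  expect_equal(call_hits(tab, 0.5, 1e-3)$hits, "c")
  tab$p_adj <- 1
  expect_equal(call_hits(tab, 0.5, 1e-3)$n_hits, 0L)
  expect_error(call_hits(tab, -1, 0.1), "non-negative")
})

test_that("planted group-responsive features are recovered at stringent FDR", {
  # 50 features shifted by 0.8 log2 units among 1000 nulls, 30 vs 38 samples
  set.seed(20)
  nf <- 1000; n1 <- 30; n2 <- 38
  v <- matrix(rnorm(nf * (n1 + n2), 15, 0.5), nf)
  v[1:50, (n1 + 1):(n1 + n2)] <- v[1:50, (n1 + 1):(n1 + n2)] + 0.8
  dimnames(v) <- list(sprintf("F%04d", 1:nf), sprintf("S%02d", 1:(n1 + n2)))
  design <- cbind(intercept = 1, group = rep(c(0, 1), c(n1, n2)))
  res <- moderated_fit(omics_matrix(v), design, "group")
  hits <- call_hits(res, lfc_cut = 0.5, fdr_cut = 0.001)
  expect_gte(sum(hits$hits %in% sprintf("F%04d", 1:50)), 45)
  expect_lte(length(setdiff(hits$hits, sprintf("F%04d", 1:50))), 2)
})

test_that("dosage profile recovers the planted chr12 gap and off-chromosome fraction", {
  b <- default_bundle(seed = 7)
  tris <- b$annotation$trisomy12 == 1
  chr12 <- b$gene_sets$sets$CHR12
  prof <- dosage_profile(b$protein, "chr12", tris, hits = chr12)
  expect_equal(prof$gap, log2(3 / 2), tolerance = 0.05 / log2(3 / 2))
  expect_equal(prof$off_chromosome_fraction, 0)
  # no dosage effect: flat gap on another chromosome
  prof2 <- dosage_profile(b$protein, "chr5", tris)
  expect_lt(abs(prof2$gap), 0.1)
  expect_error(dosage_profile(b$protein, "chrZ", tris), "no features")
})

test_that("Spearman correlation table behaves on analytic cases", {
  mk <- function(vp, vr) {
    meta <- data.frame(feature_id = "f1", gene_symbol = "g1",
                       chromosome = "chr1", start = 1L, end = 2L,
                       class = "background")
    list(p = omics_matrix(matrix(vp, 1, dimnames = list("f1", paste0("s", seq_along(vp)))), meta),
         r = omics_matrix(matrix(vr, 1, dimnames = list("f1", paste0("s", seq_along(vr)))), meta))
  }
  x <- mk(c(1, 2, 3, 4), c(1, 3, 2, 4))
  res <- mrna_protein_spearman(x$p, x$r)
  expect_equal(res$table$rho, 0.8)
  mono <- mk(c(1, 2, 3, 4, 5), exp(c(1, 2, 3, 4, 5)))
  expect_equal(mrna_protein_spearman(mono$p, mono$r)$table$rho, 1)
})

test_that("KS comparison of correlation distributions matches ECDF enumeration", {
  expect_equal(suppressWarnings(correlation_cdf_compare(c(1, 2, 3), c(1, 2, 3)))$D, 0)
  expect_equal(correlation_cdf_compare(c(1, 2), c(5, 6))$D, 1)
  expect_equal(suppressWarnings(
    correlation_cdf_compare(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4)))$D, 1 / 3,
    tolerance = 1e-12)
  expect_error(correlation_cdf_compare(numeric(0), 1), "empty")
})

test_that("the scaled interaction model returns the OLS protein coefficient", {
  set.seed(10)
  ighv <- rep(c(0, 1), 4); tris <- rep(c(0, 0, 1, 1), 2)
  prot <- rnorm(8)
  expect_equal(scaled_interaction_lm(prot, prot * 3 + 5, ighv, tris), 1,
               tolerance = 1e-9)
  # normal-equations oracle on an 8-sample toy
  rna <- rnorm(8)
  X <- cbind(1, as.numeric(scale(prot)), ighv, tris, ighv * tris)
  beta <- solve(t(X) %*% X, t(X) %*% as.numeric(scale(rna)))
  expect_equal(scaled_interaction_lm(prot, rna, ighv, tris), beta[2L],
               tolerance = 1e-9)
  expect_error(scaled_interaction_lm(prot, rna, rep(1, 8), rep(1, 8)),
               "collinear")
})

test_that("Fisher over-representation equals hypergeometric enumeration", {
  universe <- letters[1:8]
  gene_set <- letters[1:4]
  hits <- c("a", "b", "c", "h")
  expect_equal(fisher_overrepresentation(hits, universe, gene_set), 17 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_overrepresentation(character(0), universe, gene_set), 1)
  # zero overlap with positive expectation is never significant
  expect_gte(fisher_overrepresentation(c("e", "f"), universe, gene_set), 0.5)
  expect_error(fisher_overrepresentation("z", universe, gene_set), "subset")
})

test_that("trisomy-12 inference from chr12 abundance matches planted truth", {
  b <- default_bundle(seed = 7)
  flags <- infer_trisomy12(b$protein, b$gene_sets$sets$CHR12,
                           quantile = 1 - mean(b$annotation$trisomy12))
  expect_gte(mean(flags == (b$annotation$trisomy12 == 1)), 0.9)
  # degenerate: constant matrix, deterministic tie-break
  v <- matrix(5, 3, 10, dimnames = list(paste0("f", 1:3), paste0("s", 1:10)))
  expect_warning(fl <- infer_trisomy12(omics_matrix(v), "f1"), "tie")
  expect_equal(sum(fl), 2L)  # ceiling(0.2 * 10)
  expect_equal(names(which(fl)), c("s1", "s10"))  # id order
  expect_equal(sum(infer_trisomy12(b$protein, b$gene_sets$sets$CHR12,
                                   quantile = 1)), 0L)
})
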