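# PSI quantification, variable events, differential splicing with filters,
# the permutation null, and exon-level usage.

test_that("PSI formula matches direct arithmetic and the missingness rule", {
  ev <- toy_events(incl = rbind(5, 0, 10, 0),
                   skip = rbind(0, 7, 10, 0))
  psi <- compute_psi(ev)
  expect_equal(psi[1, 1], 1)
  expect_equal(psi[2, 1], 0)
  expect_equal(psi[3, 1], (10 / 2) / (10 / 2 + 10 / 1))  # 1/3
  expect_true(is.na(psi[4, 1]))
  # property over random count tables
  set.seed(1)
  incl <- matrix(rpois(1000 * 3, 5), 1000)
  skip <- matrix(rpois(1000 * 3, 5), 1000)
  lI <- 3; lS <- 2
  ev2 <- toy_events(incl, skip, incl_len = lI, skip_len = lS)
  psi2 <- compute_psi(ev2)
  direct <- (incl / lI) / (incl / lI + skip / lS)
  direct[incl + skip == 0] <- NA
  expect_equal(unname(psi2), direct)
  expect_true(all(psi2 >= 0 & psi2 <= 1, na.rm = TRUE))
  expect_identical(unname(is.na(psi2)), incl + skip == 0)
  expect_error(toy_events(incl, skip, incl_len = 0), "positive")
})

test_that("top_variable_events ranks by missing-aware variance with id tie-breaks", {
  set.seed(2)
  incl <- matrix(rbinom(5 * 8, 40, 0.5), 5)
  skip <- 40 - incl
  incl[2, ] <- round(seq(2, 38, length.out = 8))  # high variance event
  skip[2, ] <- 40 - incl[2, ]
  incl[3, ] <- 20; skip[3, ] <- 20              # constant event
  ev <- toy_events(incl, skip, incl_len = 1, skip_len = 1)
  expect_equal(top_variable_events(ev, "SE", 1), "E002")
  expect_equal(top_variable_events(ev, "SE", 99), sort(rownames(ev$incl))[1:5])
  # all-constant matrix: id order with a warning
  evc <- toy_events(matrix(10, 4, 6), matrix(10, 4, 6))
  expect_warning(ids <- top_variable_events(evc, "SE", 2), "zero")
  expect_equal(ids, c("E001", "E002"))
  expect_error(top_variable_events(ev, "SE", 0), "positive")
  expect_error(top_variable_events(ev, "RI", 1), "no events")
})

test_that("mean_psi is a missing-aware per-sample mean", {
  psi <- rbind(c(0.2, 0.5), c(0.4, NA))
  colnames(psi) <- c("s1", "s2")
  expect_equal(unname(mean_psi(psi)), c(0.3, 0.5))
  expect_equal(unname(mean_psi(matrix(0.5, 3, 2))), c(0.5, 0.5))
  psi_na <- rbind(c(0.2, NA), c(0.4, NA))
  expect_warning(mp <- mean_psi(psi_na), "all-missing")
  expect_true(is.na(mp[2L]))
})

test_that("the vectorized rank-sum test matches wilcox.test", {
  set.seed(3)
  vals <- matrix(runif(50 * 20), 50)
  vals[sample(1000, 30)] <- NA
  g <- rep(c(TRUE, FALSE), c(6, 14))
  core <- proteostrat:::rank_sum_core(vals)
  p <- proteostrat:::rank_sum_p(core, g)
  oracle <- apply(vals, 1, function(v) {
    suppressWarnings(stats::wilcox.test(v[g], v[!g], exact = FALSE,
                                        correct = TRUE)$p.value)
  })
  expect_equal(p, unname(oracle), tolerance = 1e-12)
})

test_that("differential_psi applies significance, effect-size and coverage filters", {
  # identical groups: nothing significant
  ev <- random_events(200, 30, seed = 4)
  dp <- differential_psi(ev, rep(c(TRUE, FALSE), c(5, 25)))
  expect_equal(sum(dp$significant), 0L)
  expect_error(differential_psi(ev, rep(c(TRUE, FALSE), c(2, 28))),
               "at least 3")
  # an event at mean inclusion exactly 20 is excluded regardless of p
  n <- 20
  incl <- rbind(rep(20L, n), rep(40L, n))
  skip <- rbind(c(rep(0L, 10), rep(60L, 10)), c(rep(5L, 10), rep(80L, 10)))
  ev2 <- toy_events(incl, skip)
  g <- rep(c(TRUE, FALSE), each = 10)
  dp2 <- differential_psi(ev2, g, min_mean_incl = 20)
  expect_equal(dp2$mean_incl[1L], 20)
  expect_lt(dp2$p_adj[1L], 0.01)        # would pass on significance alone
  expect_false(dp2$significant[1L])     # excluded by coverage
  expect_true(dp2$significant[2L])
})

test_that("planted differential events are recovered with few false discoveries", {
  n <- 59
  g <- rep(c(TRUE, FALSE), c(9, 50))
  ev <- random_events(1000, n, n_shift = 60, group = g, dpsi_logit = 1.3,
                      seed = 5)
  dp <- differential_psi(ev, g)
  found <- which(dp$significant)
  planted <- 1:60
  # recall over planted events that pass the coverage filter
  eligible <- planted[dp$mean_incl[planted] > 20]
  expect_gte(mean(eligible %in% found), 0.7)
  expect_lte(length(setdiff(found, planted)), 5)
})

test_that("the permutation null uses the add-one convention and detects planted signal", {
  n <- 40
  g <- rep(c(TRUE, FALSE), c(8, 32))
  ev <- random_events(400, n, n_shift = 50, group = g, dpsi_logit = 1.6,
                      seed = 6)
  pn <- permutation_null(ev, g, n_perm = 99, seed = 10)
  expect_equal(length(pn$null), 99L)
  expect_gt(pn$observed, max(pn$null))
  expect_equal(pn$p, 1 / 100)
  # at the study's implied permutation count the signal stays significant
  pn57 <- permutation_null(ev, g, n_perm = 57, seed = 11)
  expect_lte(pn57$p, 1 / 58)  # the add-one floor, printed as p < 0.0172
  expect_error(permutation_null(ev, g, n_perm = 5), "at least 19")
})

test_that("permutation pipeline is reproducible under a fixed seed", {
  ev <- random_events(200, 30, seed = 7)
  g <- rep(c(TRUE, FALSE), c(6, 24))
  p1 <- permutation_null(ev, g, n_perm = 25, seed = 3)
  p2 <- permutation_null(ev, g, n_perm = 25, seed = 3)
  expect_identical(p1$null, p2$null)
  expect_identical(p1$p, p2$p)
})

test_that("spliceosome~PSI correlation tracks construction", {
  b <- default_bundle(seed = 7)
  psi <- compute_psi(b$events)
  spl_mean <- colMeans(b$protein$values[b$gene_sets$sets$SPLICEOSOME, ],
                       na.rm = TRUE)
  # monotone function of the spliceosome mean: rho = 1
  fake <- list(X = setNames(rank(spl_mean) / 100, names(spl_mean)))
  res <- spliceosome_psi_correlation(b$protein, b$gene_sets$sets$SPLICEOSOME,
                                     fake)
  expect_equal(res$rho, 1)
  # planted directions: SE down, alternative splice sites up in ASB
  mpc <- lapply(c(SE = "SE", A3SS = "A3SS", A5SS = "A5SS"), function(cat) {
    ids <- top_variable_events(b$events, cat, 200, psi = psi)
    mean_psi(psi[ids, , drop = FALSE])
  })
  res2 <- spliceosome_psi_correlation(b$protein, b$gene_sets$sets$SPLICEOSOME,
                                      mpc)
  expect_gt(res2$rho[res2$category == "A3SS"], 0)
  expect_gt(res2$rho[res2$category == "A5SS"], 0)
})

test_that("ASB mean PSI over variable skipped exons shifts in the planted direction", {
  b <- default_bundle(seed = 7)
  psi <- compute_psi(b$events)
  ids <- top_variable_events(b$events, "SE", 1000, psi = psi)
  mp <- mean_psi(psi[ids, , drop = FALSE])
  asb <- b$truth == "ASB"
  test <- group_rank_tests(mp, ifelse(asb, "ASB", "other"))
  expect_lt(test$p, 0.01)
  expect_lt(mean(mp[asb]), mean(mp[!asb]))
})

test_that("exon-level usage flags single shifted exons but not whole-gene shifts", {
  set.seed(8)
  n <- 40
  g <- rep(c("grp", "rest"), each = 20)
  # gene A: one exon of three shifted in grp; gene B: all exons shifted
  base <- matrix(rnorm(6 * n, 20, 0.1), 6, n)
  base[1, g == "grp"] <- base[1, g == "grp"] + 1          # A exon 1
  base[4:6, g == "grp"] <- base[4:6, g == "grp"] + 1      # B all exons
  dimnames(base) <- list(paste0("x", 1:6), paste0("s", 1:n))
  map <- data.frame(exon_id = paste0("x", 1:6),
                    gene_symbol = rep(c("A", "B"), each = 3))
  res <- diffsplice_exons(base, map, g, min_presence = 0)
  tab <- res$per_group$grp
  expect_true(tab$hit[tab$feature_id == "x1"])
  expect_false(any(tab$hit[tab$feature_id %in% paste0("x", 4:6)]))
  # deviation magnitude: 1 - 1/3
  expect_equal(tab$log2FC[tab$feature_id == "x1"], 2 / 3, tolerance = 0.15)
})

test_that("exon presence and single-exon-gene filters are applied", {
  set.seed(9)
  n <- 12
  vals <- matrix(rnorm(4 * n, 20), 4, n,
                 dimnames = list(paste0("x", 1:4), paste0("s", 1:n)))
  vals[1, 4:n] <- NA  # present in 3 samples only
  map <- data.frame(exon_id = paste0("x", 1:4),
                    gene_symbol = c("A", "A", "A", "B"))
  g <- rep(c("grp", "rest"), each = 6)
  expect_warning(res <- diffsplice_exons(vals, map, g, min_presence = 3),
                 "single-exon")
  tested <- res$per_group$grp$feature_id
  expect_false("x1" %in% tested)  # too few batches
  expect_false("x4" %in% tested)  # single-exon gene
})
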