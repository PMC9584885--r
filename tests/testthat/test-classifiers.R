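# k-TSP and PLS-DA classifiers.

test_that("pair scores equal exhaustive enumeration on random toys", {
  set.seed(1)
  for (rep in 1:10) {
    nf <- sample(5:10, 1)
    X <- matrix(rnorm(nf * 12), nf, 12,
                dimnames = list(sprintf("F%02d", 1:nf), sprintf("S%02d", 1:12)))
    if (rep > 5) X[sample(length(X), 5)] <- NA
    y <- rep(c("pos", "neg"), each = 6)
    sc <- tsp_pair_scores(X, y, positive = "pos")
    orc <- tsp_oracle(X, y, "pos")
    key <- paste(sc$a, sc$b)
    expect_equal(sc$delta, orc$delta[match(key, paste(orc$a, orc$b))],
                 tolerance = 1e-12)
  }
})

test_that("perfect and uninformative pairs score 1 and about 0", {
  X <- rbind(a = c(1, 1, 1, 5, 5, 5), b = c(2, 2, 2, 4, 4, 4),
             c = c(9, 9, 9, 9, 9, 9) + 0.1 * (1:6))
  colnames(X) <- paste0("s", 1:6)
  y <- rep(c("pos", "neg"), each = 3)
  sc <- tsp_pair_scores(X, y, "pos")
  ab <- sc[sc$a == "a" & sc$b == "b", ]
  expect_equal(ab$delta, 1)  # a<b in every pos sample, never in neg
  expect_error(tsp_pair_scores(X, rep(c("pos", "neg"), c(2, 4)), "pos"),
               "at least 3")
})

test_that("greedy selection is disjoint with documented tie-breaks", {
  sc <- data.frame(a = c("f1", "f1", "f3", "f5", "f7"),
                   b = c("f2", "f3", "f4", "f6", "f8"),
                   p_pos = 1, p_neg = 0,
                   delta = c(0.9, 0.8, 0.8, 0.5, 0.5),
                   gamma = c(5, 4, 4, 2, 2),
                   vote_when_a_lt_b = "positive")
  sel <- tsp_select(sc, 2)
  expect_equal(sel$a, c("f1", "f3"))  # f1/f3 pair skipped (shares f1)
  # full tie: lexicographically smaller pair wins
  sc2 <- sc[4:5, ]
  expect_equal(tsp_select(sc2, 1)$a, "f5")
  expect_warning(sel3 <- tsp_select(sc, 10), "only .* disjoint")
  expect_equal(nrow(sel3), 4L)  # (f1,f2), (f3,f4), (f5,f6), (f7,f8)
})

test_that("prediction applies the missing-pair threshold-lowering rule", {
  # 8 perfect pairs: a_i < b_i in positives, a_i > b_i in negatives
  pairs <- data.frame(a = sprintf("a%d", 1:8), b = sprintf("b%d", 1:8),
                      delta = 1, gamma = 1)
  model <- structure(list(pairs = pairs, k = 8L, vote_threshold = 4L,
                          classes = c("other", "pos"), positive = "pos"),
                     class = "tsp_model")
  X <- matrix(0, 16, 4, dimnames = list(c(pairs$a, pairs$b), paste0("s", 1:4)))
  X[pairs$a, c(1, 2)] <- 1; X[pairs$b, c(1, 2)] <- 2   # all pairs vote pos
  X[pairs$a, c(3, 4)] <- 2; X[pairs$b, c(3, 4)] <- 1   # no pair votes pos
  p0 <- tsp_predict(model, X)
  expect_equal(p0$label, c("pos", "pos", "other", "other"))
  expect_equal(p0$votes, c(8L, 8L, 0L, 0L))
  # remove one pair's feature entirely: 7 pairs, threshold 3, same labels
  expect_warning(p1 <- tsp_predict(model, X[-1, ]), "threshold lowered")
  expect_equal(unique(p1$threshold), 3L)
  expect_equal(p1$label, p0$label)
  # votes exactly at the effective threshold call the positive class
  X2 <- X
  X2[pairs$a[1:4], 1] <- 3  # only pairs 5..8 vote for sample 1
  expect_equal(tsp_predict(model, X2)$votes[1L], 4L)
  expect_equal(tsp_predict(model, X2)$label[1L], "pos")
  # all pairs unevaluable: NA with warning
  X3 <- X; X3[, 1] <- NA
  expect_warning(p3 <- tsp_predict(model, X3), "no evaluable pair")
  expect_true(is.na(p3$label[1L]))
})

test_that("k-TSP predictions are invariant to per-sample monotone transforms", {
  b <- default_bundle(seed = 7)
  panel <- unlist(b$gene_sets$sets[c("BCR", "SPLICEOSOME")])
  model <- suppressWarnings(
    tsp_train_mccv(b$protein$values, b$truth, positive = "ASB", panel = panel,
                   k_grid = c(3, 5), n_splits = 8, seed = 2))
  X <- b$protein$values
  p1 <- suppressWarnings(tsp_predict(model, X))
  transformed <- sweep(exp(X / 5), 2, runif(ncol(X), 0.5, 2), "*")
  p2 <- suppressWarnings(tsp_predict(model, transformed))
  expect_identical(p1$label, p2$label)
  expect_identical(p1$votes, p2$votes)
})

test_that("MCCV selects the smallest k on clean ties and degrades to chance on shuffled labels", {
  set.seed(4)
  # cleanly separable toy: 10 redundant perfect pairs
  n <- 24
  y <- rep(c("pos", "neg"), each = n / 2)
  X <- matrix(rnorm(20 * n, 10, 0.1), 20, n,
              dimnames = list(sprintf("F%02d", 1:20), sprintf("S%02d", 1:n)))
  X[seq(1, 20, 2), ] <- X[seq(1, 20, 2), ] + 1            # odd above even
  X[seq(1, 20, 2), y == "pos"] <- X[seq(1, 20, 2), y == "pos"] - 5
  m <- tsp_train_mccv(X, y, "pos", k_grid = c(3, 5, 7, 9), n_splits = 10,
                      seed = 5)
  expect_equal(m$k, 3L)
  expect_equal(max(m$cv), 1)
  # shuffled labels: balanced accuracy near 0.5
  b <- default_bundle(seed = 7)
  panel <- unlist(b$gene_sets$sets[c("BCR", "SPLICEOSOME")])
  ysh <- sample(b$truth)
  msh <- suppressWarnings(
    tsp_train_mccv(b$protein$values, ysh, positive = "ASB", panel = panel,
                   k_grid = c(3, 5), n_splits = 10, seed = 6))
  expect_lt(max(msh$cv), 0.72)
})

test_that("AUROC equals pairwise win counting", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(0, 1), 3)), 0.5)
  set.seed(7)
  for (i in 1:25) {
    s <- rnorm(20); y <- rbinom(20, 1, 0.4)
    if (sum(y) %in% c(0, 20)) next
    wins <- mean(outer(s[y == 1], s[y == 0], function(a, b) {
      (a > b) + 0.5 * (a == b)
    }))
    expect_equal(roc_auc(s, y), wins, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("PLS-DA separates linearly separable toys perfectly", {
  set.seed(8)
  n <- 20
  y <- rep(c("pos", "neg"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:10)))
  X[y == "pos", 1:3] <- X[y == "pos", 1:3] + 6
  m <- plsda_train(X, y, "pos")
  expect_equal(m$auc_loo, 1)
  pred <- plsda_predict(m, X)
  expect_equal(pred$label, ifelse(y == "pos", "pos", "other"))
  # independent response: LOO AUROC near 0.5
  m0 <- plsda_train(X, sample(y), "pos", max_comp = 2)
  expect_lt(m0$auc_loo, 0.8)
})

test_that("the first PLS component weight is proportional to X'y", {
  set.seed(9)
  X <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(paste0("s", 1:30), paste0("f", 1:8)))
  y <- rbinom(30, 1, 0.5)
  fit <- proteostrat:::pls1_fit(X, y, 1)
  Xc <- scale(X)
  w_closed <- crossprod(Xc, y - mean(y))
  w_closed <- w_closed / sqrt(sum(w_closed^2))
  cosine <- abs(sum(fit$W[, 1] * w_closed))
  expect_gte(cosine, 1 - 1e-8)
})

test_that("PLS-DA prediction handles absent features and all-missing samples", {
  set.seed(10)
  n <- 20
  y <- rep(c("pos", "neg"), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:6)))
  X[y == "pos", 1:4] <- X[y == "pos", 1:4] + 5
  m <- suppressWarnings(plsda_train(X, y, "pos"))
  expect_warning(pr <- plsda_predict(m, X[, 1:4]), "absent")
  expect_gte(mean(pr$label == ifelse(y == "pos", "pos", "other")), 0.9)
  Xna <- X; Xna[1, ] <- NA
  expect_warning(pna <- plsda_predict(m, Xna), "all-missing")
  expect_true(is.na(pna$label[1L]))
  expect_error(plsda_predict(m, X[, 0]), "no overlapping")
})

test_that("models survive JSON round-trips", {
  b <- default_bundle(seed = 7)
  panel <- unlist(b$gene_sets$sets[c("BCR", "SPLICEOSOME")])
  m <- suppressWarnings(
    tsp_train_mccv(b$protein$values, b$truth, positive = "ASB", panel = panel,
                   k_grid = 5, n_splits = 5, seed = 11))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  p1 <- suppressWarnings(tsp_predict(m, b$protein$values))
  p2 <- suppressWarnings(tsp_predict(m2, b$protein$values))
  expect_identical(p1$label, p2$label)

  set.seed(12)
  X <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(paste0("s", 1:40), paste0("f", 1:5)))
  y <- rep(c("pos", "neg"), 20)
  X[y == "pos", 1] <- X[y == "pos", 1] + 4
  pm <- plsda_train(X, y, "pos")
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model(pm, path2)
  pm2 <- read_model(path2)
  expect_equal(plsda_predict(pm2, X)$score, plsda_predict(pm, X)$score,
               tolerance = 1e-12)
})
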