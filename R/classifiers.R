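# Rank-based k-top-scoring-pairs classifier (training with Monte Carlo CV,
# prediction with a missing-pair vote-threshold rule) and PLS-DA with
# leave-one-out AUROC model selection.

#' Score all feature pairs for top-scoring-pair discrimination
#'
#' For every unordered pair (i, j) of candidate features the primary score is
#' `delta = |P(Xi < Xj | positive) - P(Xi < Xj | negative)|`, estimated by
#' within-class frequencies with pairwise exclusion of missing values; the
#' secondary (tie-break) score is the between-class difference of
#' within-sample rank differences. The orientation voting for the positive
#' class is recorded per pair.
#'
#' @param X features x samples numeric matrix.
#' @param y class labels per sample.
#' @param positive label of the positive class (e.g. the ASB-like subgroup).
#' @param candidates optional candidate feature ids (default: all rows).
#' @return data.frame `a, b, p_pos, p_neg, delta, gamma, vote_when_a_lt_b`
#'   sorted by decreasing `delta`, then `gamma`, then pair id.
#' @export
tsp_pair_scores <- function(X, y, positive, candidates = rownames(X)) {
  stopifnot(is.matrix(X), length(y) == ncol(X))
  miss <- setdiff(candidates, rownames(X))
  if (length(miss)) stopf("candidate feature %s absent from matrix", miss[1L])
  X <- X[candidates, , drop = FALSE]
  pos <- y == positive
  if (sum(pos) < 3 || sum(!pos) < 3) stopf("each class needs at least 3 samples")
  class_freq <- function(cols) {
    f <- nrow(X)
    lt <- matrix(0, f, f)
    cnt <- matrix(0, f, f)
    for (s in which(cols)) {
      v <- X[, s]
      ok <- !is.na(v)
      cmp <- outer(v[ok], v[ok], "<")
      lt[ok, ok] <- lt[ok, ok] + cmp
      cnt[ok, ok] <- cnt[ok, ok] + 1
    }
    lt / pmax(cnt, 1)
  }
  p1 <- class_freq(pos)
  p2 <- class_freq(!pos)
  ranks <- apply(X, 2, rank, na.last = "keep")
  m1 <- rowMeans(ranks[, pos, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(ranks[, !pos, drop = FALSE], na.rm = TRUE)
  ut <- which(upper.tri(p1), arr.ind = TRUE)
  a <- rownames(X)[ut[, 1L]]
  b <- rownames(X)[ut[, 2L]]
  pp <- p1[ut]; pn <- p2[ut]
  delta <- abs(pp - pn)
  gamma <- abs((m1[ut[, 1L]] - m1[ut[, 2L]]) - (m2[ut[, 1L]] - m2[ut[, 2L]]))
  out <- data.frame(a = a, b = b, p_pos = pp, p_neg = pn, delta = delta,
                    gamma = unname(gamma),
                    vote_when_a_lt_b = ifelse(pp >= pn, "positive", "negative"),
                    stringsAsFactors = FALSE)
  out[order(-out$delta, -out$gamma, out$a, out$b), ]
}

#' Greedy disjoint selection of top-scoring pairs
#'
#' Takes the highest-delta pairs in order, skipping any pair sharing a
#' feature with an already-chosen pair; ties resolved by secondary score and
#' then lexicographic pair id. Pairs are oriented so that `a < b` votes for
#' the positive class.
#'
#' @param scores a [tsp_pair_scores()] table.
#' @param k requested number of pairs; if fewer disjoint pairs exist the
#'   maximum achievable is returned with a warning.
#' @return data.frame of `k` oriented pairs (`a, b, delta, gamma`).
#' @export
tsp_select <- function(scores, k) {
  used <- character(0)
  picked <- integer(0)
  for (i in seq_len(nrow(scores))) {
    if (length(picked) == k) break
    if (scores$a[i] %in% used || scores$b[i] %in% used) next
    picked <- c(picked, i)
    used <- c(used, scores$a[i], scores$b[i])
  }
  if (length(picked) < k) {
    warnf("only %d disjoint pairs available (requested %d)", length(picked), k)
  }
  sel <- scores[picked, , drop = FALSE]
  flip <- sel$vote_when_a_lt_b == "negative"
  tmp <- sel$a[flip]; sel$a[flip] <- sel$b[flip]; sel$b[flip] <- tmp
  rownames(sel) <- NULL
  sel[, c("a", "b", "delta", "gamma")]
}

balanced_accuracy <- function(truth, pred) {
  mean(c(mean(pred[truth], na.rm = TRUE), mean(!pred[!truth], na.rm = TRUE)))
}

#' Train a k-TSP classifier with Monte Carlo cross-validation
#'
#' Restricts features to a panel (e.g. the BcR + spliceosome sets), scores
#' pairs, and uses repeated stratified holdouts to choose the pair count k
#' from `k_grid` by mean balanced accuracy (smallest k on ties). The final
#' model is refitted on all data; the base vote threshold is `ceiling(k/2)`.
#'
#' @param X features x samples matrix.
#' @param y class labels.
#' @param positive positive class label.
#' @param panel character vector of panel feature ids (intersected with
#'   `rownames(X)`; empty intersection is an error).
#' @param k_grid odd candidate pair counts.
#' @param n_splits Monte Carlo splits (default 100).
#' @param holdout_frac holdout fraction per split (default 0.25).
#' @param seed RNG seed.
#' @return A `tsp_model`: list with `pairs`, `k`, `vote_threshold`,
#'   `classes`, `positive`, `cv` (per-k mean balanced accuracy), `seed`.
#' @export
tsp_train_mccv <- function(X, y, positive, panel = rownames(X),
                           k_grid = c(3, 5, 7, 9, 11), n_splits = 100,
                           holdout_frac = 0.25, seed = 1L) {
  feats <- intersect(panel, rownames(X))
  if (!length(feats)) stopf("empty panel intersection with matrix features")
  X <- X[feats, , drop = FALSE]
  pos <- which(y == positive)
  neg <- which(y != positive)
  cv <- with_seed(seed, {
    acc <- matrix(NA_real_, n_splits, length(k_grid),
                  dimnames = list(NULL, paste0("k", k_grid)))
    for (s in seq_len(n_splits)) {
      hp <- sample(pos, max(1, round(holdout_frac * length(pos))))
      hn <- sample(neg, max(1, round(holdout_frac * length(neg))))
      hold <- c(hp, hn)
      sc <- tsp_pair_scores(X[, -hold, drop = FALSE], y[-hold], positive)
      for (ki in seq_along(k_grid)) {
        pairs <- suppressWarnings(tsp_select(sc, k_grid[ki]))
        thr <- ceiling(nrow(pairs) / 2)
        pred <- tsp_votes(pairs, X[, hold, drop = FALSE]) >= thr
        acc[s, ki] <- balanced_accuracy(y[hold] == positive, pred)
      }
    }
    acc
  })
  mean_acc <- round(colMeans(cv, na.rm = TRUE), 12)
  k <- k_grid[which.max(mean_acc)]  # which.max takes the smallest on ties
  sc <- tsp_pair_scores(X, y, positive)
  pairs <- tsp_select(sc, k)
  structure(list(pairs = pairs, k = nrow(pairs),
                 vote_threshold = ceiling(nrow(pairs) / 2),
                 classes = sort(unique(as.character(y))), positive = positive,
                 cv = mean_acc, panel = feats, seed = seed),
            class = "tsp_model")
}

# Vote counts for oriented pairs; NA-aware (missing comparisons do not vote).
tsp_votes <- function(pairs, X) {
  votes <- rep(0L, ncol(X))
  for (i in seq_len(nrow(pairs))) {
    if (!(pairs$a[i] %in% rownames(X)) || !(pairs$b[i] %in% rownames(X))) next
    cmp <- X[pairs$a[i], ] < X[pairs$b[i], ]
    votes <- votes + ifelse(is.na(cmp), 0L, as.integer(cmp))
  }
  votes
}

#' Predict with a k-TSP model under the missing-pair rule
#'
#' Each evaluable pair votes for the positive class when its oriented
#' comparison `A < B` holds within the sample. Pairs with a feature absent
#' from the matrix, or missing in a given sample, are dropped for that
#' prediction and the vote threshold is lowered by one per dropped pair
#' (floor 1). The positive class is called when votes reach the effective
#' threshold; a sample with no evaluable pair gets an NA label with a
#' warning.
#'
#' @param model a [tsp_train_mccv()] model.
#' @param X features x samples matrix (may lack model features).
#' @return data.frame `sample_id, votes, evaluable_pairs, threshold, label`.
#' @export
tsp_predict <- function(model, X) {
  stopifnot(inherits(model, "tsp_model"))
  pairs <- model$pairs
  present <- pairs$a %in% rownames(X) & pairs$b %in% rownames(X)
  if (!all(present)) {
    warnf("%d pair(s) unevaluable (feature absent); vote threshold lowered",
          sum(!present))
  }
  pairs_p <- pairs[present, , drop = FALSE]
  n <- ncol(X)
  votes <- integer(n); evaluable <- integer(n)
  for (s in seq_len(n)) {
    va <- X[pairs_p$a, s]; vb <- X[pairs_p$b, s]
    ok <- !is.na(va) & !is.na(vb)
    evaluable[s] <- sum(ok)
    votes[s] <- sum(va[ok] < vb[ok])
  }
  threshold <- pmax(1L, model$vote_threshold - (model$k - evaluable))
  label <- ifelse(votes >= threshold, model$positive, "other")
  none <- evaluable == 0
  if (any(none)) {
    warnf("%d sample(s) had no evaluable pair; label set to NA", sum(none))
    label[none] <- NA_character_
  }
  data.frame(sample_id = colnames(X), votes = votes,
             evaluable_pairs = evaluable, threshold = threshold,
             label = label, stringsAsFactors = FALSE)
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation with ties counted one half.
#'
#' @param scores numeric predictor scores.
#' @param y logical or 0/1 labels (TRUE/1 = positive); both classes required.
#' @return AUROC in \[0, 1\].
#' @export
roc_auc <- function(scores, y) {
  y <- as.logical(y)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train a PLS-DA classifier with LOO-AUROC component selection
#'
#' Features are centered and scaled (constant features dropped with a
#' warning); partial least squares components are extracted by the NIPALS
#' scheme with the class coded 0/1, and the component count is chosen by
#' leave-one-out cross-validated AUROC of the predicted scores. The decision
#' cutoff is the midpoint of the class mean fitted scores.
#'
#' @param X samples x features matrix (e.g. PSI values of the signature
#'   events).
#' @param y class labels.
#' @param positive positive class label.
#' @param max_comp maximum number of components to consider.
#' @return A `plsda_model`: centering/scaling vectors, regression
#'   coefficients per chosen component count, `ncomp`, `cutoff`, `auc_loo`.
#' @export
plsda_train <- function(X, y, positive, max_comp = 5) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (nrow(X) < 6) stopf("need at least 6 samples")
  yy <- as.numeric(y == positive)
  if (all(yy == 0) || all(yy == 1)) stopf("single-class response")
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warnf("%d constant feature(s) dropped", sum(const))
    X <- X[, !const, drop = FALSE]
  }
  max_comp <- min(max_comp, ncol(X), nrow(X) - 2)
  n <- nrow(X)
  loo_scores <- matrix(NA_real_, n, max_comp)
  for (i in seq_len(n)) {
    fit <- pls1_fit(X[-i, , drop = FALSE], yy[-i], max_comp)
    for (m in seq_len(max_comp)) {
      loo_scores[i, m] <- pls1_score(fit, X[i, , drop = FALSE], m)
    }
  }
  auc <- vapply(seq_len(max_comp), function(m) roc_auc(loo_scores[, m], yy == 1),
                numeric(1))
  ncomp <- which.max(round(auc, 12))
  fit <- pls1_fit(X, yy, ncomp)
  fitted <- vapply(seq_len(n), function(i) pls1_score(fit, X[i, , drop = FALSE], ncomp),
                   numeric(1))
  cutoff <- (mean(fitted[yy == 1]) + mean(fitted[yy == 0])) / 2
  structure(list(center = fit$center, scale = fit$scale,
                 weights = fit$W, loadings = fit$P, yloads = fit$q,
                 coefs = pls1_coefs(fit, ncomp), intercept = fit$ymean,
                 ncomp = ncomp, cutoff = cutoff, auc_loo = auc[ncomp],
                 auc_by_ncomp = auc, positive = positive,
                 features = colnames(X)),
            class = "plsda_model")
}

# NIPALS PLS1 on centered/scaled X and centered y.
pls1_fit <- function(X, y, ncomp) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  Xc <- sweep(sweep(X, 2, center), 2, scale, "/")
  ymean <- mean(y)
  yc <- y - ymean
  p <- ncol(Xc)
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  E <- Xc
  f <- yc
  for (m in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { W <- W[, seq_len(m - 1), drop = FALSE]; break }
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    pl <- crossprod(E, t) / tt
    qm <- sum(f * t) / tt
    E <- E - t %*% t(pl)
    f <- f - qm * t
    W[, m] <- w; P[, m] <- pl; q[m] <- qm
  }
  list(center = center, scale = scale, W = W, P = P, q = q, ymean = ymean)
}

pls1_coefs <- function(fit, ncomp) {
  W <- fit$W[, seq_len(ncomp), drop = FALSE]
  P <- fit$P[, seq_len(ncomp), drop = FALSE]
  q <- fit$q[seq_len(ncomp)]
  W %*% solve(crossprod(P, W), q)
}

pls1_score <- function(fit, xnew, ncomp) {
  xs <- (xnew - fit$center) / fit$scale
  xs[is.na(xs)] <- 0
  as.numeric(xs %*% pls1_coefs(fit, ncomp)) + fit$ymean
}

#' Predict with a PLS-DA model
#'
#' Features are matched by name; model features absent from the input are
#' imputed at zero after scaling (with a warning). Samples with no observed
#' model feature get an NA label.
#'
#' @param model a [plsda_train()] model.
#' @param X samples x features matrix.
#' @return data.frame `sample_id, score, label`.
#' @export
plsda_predict <- function(model, X) {
  stopifnot(inherits(model, "plsda_model"))
  feats <- model$features
  overlap <- intersect(feats, colnames(X))
  if (!length(overlap)) stopf("no overlapping features")
  if (length(overlap) < length(feats)) {
    warnf("%d model feature(s) absent; imputed at 0 after scaling",
          length(feats) - length(overlap))
  }
  Xa <- matrix(NA_real_, nrow(X), length(feats),
               dimnames = list(rownames(X), feats))
  Xa[, overlap] <- X[, overlap]
  observed <- rowSums(!is.na(Xa)) > 0
  Xs <- sweep(sweep(Xa, 2, model$center), 2, model$scale, "/")
  Xs[is.na(Xs)] <- 0
  score <- as.numeric(Xs %*% model$coefs) + model$intercept
  label <- ifelse(score >= model$cutoff, model$positive, "other")
  label[!observed] <- NA_character_
  if (any(!observed)) warnf("%d all-missing sample(s); label set to NA", sum(!observed))
  data.frame(sample_id = rownames(X) %||% seq_len(nrow(X)), score = score,
             label = label, stringsAsFactors = FALSE)
}

#' Serialize a classifier model to JSON
#' @param model a `tsp_model` or `plsda_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- if (inherits(model, "tsp_model")) {
    list(type = "ktsp", classes = model$classes, positive = model$positive,
         pairs = lapply(seq_len(nrow(model$pairs)), function(i) {
           list(a = model$pairs$a[i], b = model$pairs$b[i],
                vote = model$positive)
         }),
         k = model$k, threshold = model$vote_threshold)
  } else if (inherits(model, "plsda_model")) {
    list(type = "plsda", positive = model$positive,
         mean = as.numeric(model$center), sd = as.numeric(model$scale),
         features = model$features, ncomp = model$ncomp,
         coefs = as.numeric(model$coefs), intercept = model$intercept,
         cutoff = model$cutoff, auc_loo = model$auc_loo)
  } else stopf("unknown model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deserialize a classifier model from JSON
#' @param path JSON path written by [write_model()].
#' @return a `tsp_model` or `plsda_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "ktsp") {
    pr <- obj$pairs  # simplifies to a data.frame or stays a list
    if (!is.data.frame(pr)) {
      pr <- data.frame(a = vapply(pr, `[[`, character(1), "a"),
                       b = vapply(pr, `[[`, character(1), "b"),
                       stringsAsFactors = FALSE)
    }
    pairs <- data.frame(a = pr$a, b = pr$b, delta = NA_real_,
                        gamma = NA_real_, stringsAsFactors = FALSE)
    structure(list(pairs = pairs, k = obj$k, vote_threshold = obj$threshold,
                   classes = obj$classes, positive = obj$positive),
              class = "tsp_model")
  } else if (obj$type == "plsda") {
    structure(list(center = setNames(obj$mean, obj$features),
                   scale = setNames(obj$sd, obj$features),
                   coefs = matrix(obj$coefs, ncol = 1),
                   intercept = obj$intercept, ncomp = obj$ncomp,
                   cutoff = obj$cutoff, auc_loo = obj$auc_loo,
                   positive = obj$positive, features = obj$features),
              class = "plsda_model")
  } else stopf("unknown model type: %s", obj$type)
}
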