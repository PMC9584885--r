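# Shared fixtures, built in code.

# Memoized default synthetic cohorts so several test files can reuse them.
.bundle_cache <- new.env(parent = emptyenv())
default_bundle <- function(seed = 7, n_samples = 68) {
  key <- paste0("s", seed, "n", n_samples)
  if (is.null(.bundle_cache[[key]])) {
    .bundle_cache[[key]] <- simulate_cohort(
      cohort_config(n_samples = n_samples, seed = seed))
  }
  .bundle_cache[[key]]
}

# Small abundance matrix with metadata.
toy_matrix <- function(nf = 4, ns = 3, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(nf * ns, 20), nf, ns,
              dimnames = list(sprintf("P%02d", seq_len(nf)),
                              sprintf("S%02d", seq_len(ns))))
  meta <- data.frame(feature_id = rownames(v),
                     gene_symbol = sprintf("G%02d", seq_len(nf)),
                     chromosome = "chr1", start = seq_len(nf) * 100L,
                     end = seq_len(nf) * 100L + 10L,
                     stringsAsFactors = FALSE)
  omics_matrix(v, meta)
}

# Event table from explicit count matrices.
toy_events <- function(incl, skip, category = "SE", incl_len = 2, skip_len = 1) {
  m <- nrow(incl)
  if (is.null(rownames(incl))) {
    rownames(incl) <- rownames(skip) <- sprintf("E%03d", seq_len(m))
  }
  if (is.null(colnames(incl))) {
    colnames(incl) <- colnames(skip) <- sprintf("S%02d", seq_len(ncol(incl)))
  }
  splice_event_table(
    data.frame(event_id = rownames(incl),
               category = rep_len(category, m),
               incl_len = incl_len, skip_len = skip_len,
               stringsAsFactors = FALSE),
    incl, skip)
}

# Exhaustive oracle for k-TSP pair scores: loop over all pairs and samples.
tsp_oracle <- function(X, y, positive) {
  f <- rownames(X)
  out <- list()
  for (i in seq_along(f)) for (j in seq_along(f)) {
    if (j <= i) next
    p1 <- mean(X[i, y == positive] < X[j, y == positive], na.rm = TRUE)
    p2 <- mean(X[i, y != positive] < X[j, y != positive], na.rm = TRUE)
    out[[length(out) + 1L]] <- data.frame(a = f[i], b = f[j],
                                          delta = abs(p1 - p2))
  }
  do.call(rbind, out)
}

# Random event table with PSI shifted in a planted group.
random_events <- function(m, n, n_shift = 0, shift_idx = NULL, group = NULL,
                          dpsi_logit = 0, seed = 1, mu_total = 60) {
  set.seed(seed)
  psi0 <- runif(m, 0.15, 0.85)
  lp <- matrix(qlogis(psi0), m, n)
  if (n_shift > 0) {
    if (is.null(shift_idx)) shift_idx <- seq_len(n_shift)
    lp[shift_idx, group] <- lp[shift_idx, group] + dpsi_logit
  }
  psi <- plogis(lp)
  total <- matrix(rnbinom(m * n, mu = mu_total, size = 1 / 0.3), m, n)
  f <- 2 * psi / (1 + psi)
  incl <- matrix(rbinom(m * n, as.vector(total), as.vector(f)), m, n)
  toy_events(incl, total - incl)
}
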