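# End-to-end orchestration: discovery (simulate -> cluster -> characterize ->
# splice -> survival -> network) and validation (apply classifiers to an
# independent cohort -> survival). Per-stage seeds are derived
# deterministically from the global seed so stages can be rerun in isolation.

# The ASB-like cluster is the one with the largest spliceosome-minus-BcR
# mean abundance contrast, mirroring how the subgroup is recognized.
identify_asb_cluster <- function(protein, labels, gene_sets) {
  spl <- colMeans(protein$values[gene_sets$sets$SPLICEOSOME, , drop = FALSE],
                  na.rm = TRUE)
  bcr <- colMeans(protein$values[gene_sets$sets$BCR, , drop = FALSE],
                  na.rm = TRUE)
  contrast <- tapply(spl - bcr, labels, mean)
  as.integer(names(which.max(contrast)))
}

#' Run the discovery analysis on a (synthetic) cohort
#'
#' Executes simulation, consensus clustering, differential characterization
#' of the ASB-like cluster, splicing statistics with the permutation null,
#' survival comparisons, and the protein network, and returns a
#' machine-readable report. Every stage draws its seed deterministically
#' from `seed`; given identical inputs the report is byte-identical.
#'
#' @param config a [cohort_config()]; its `seed` is replaced by a stage seed
#'   derived from `seed`.
#' @param seed global seed.
#' @param out_dir optional output directory for the report JSON and stage
#'   TSVs.
#' @param stages stages to run (subset of simulate, cluster, differential,
#'   splicing, survival, network); skipped stages are marked in the report.
#' @param k_range,n_iter,override_k consensus clustering controls.
#' @param n_perm permutations for the splicing null.
#' @return the report, a named list (invisibly written to
#'   `out_dir/report.json` when `out_dir` is given).
#' @export
run_discovery <- function(config = cohort_config(), seed = 1L, out_dir = NULL,
                          stages = c("cluster", "differential", "splicing",
                                     "survival", "network"),
                          k_range = 2:8, n_iter = 200, override_k = 6L,
                          n_perm = 200) {
  report <- list(seed = seed)
  config$seed <- derive_seed(seed, 1L)
  bundle <- simulate_cohort(config)
  report$cohort <- list(n_samples = config$n_samples,
                        group_sizes = as.list(table(bundle$truth)))
  labels <- NULL
  asb_cluster <- NULL
  asb_flag <- NULL

  if ("cluster" %in% stages) {
    cc <- consensus_cluster(bundle$protein, k_range = k_range, n_iter = n_iter,
                            seed = derive_seed(seed, 2L))
    k_rule <- choose_k(cc)
    k <- as.integer(choose_k(cc, override = override_k))
    labels <- cc$labels[[as.character(k)]]
    asb_cluster <- identify_asb_cluster(bundle$protein, labels, bundle$gene_sets)
    asb_flag <- labels == asb_cluster
    enr <- genotype_enrichment(labels, bundle$annotation[
      , c("IGHV", "trisomy12", "TP53mut", "SF3B1mut", "del17p13",
          "del11q22", "del13q14", "gain8q24", "pretreated")])
    report$cluster <- list(
      chosen_k = k, elbow_k = as.integer(k_rule),
      ari_vs_truth = adjusted_rand(labels, bundle$truth),
      asb_cluster = asb_cluster, asb_size = sum(asb_flag),
      asb_jaccard = best_jaccard(labels, which(bundle$truth == "ASB")),
      n_enriched_lesions = sum(enr$hit))
    if (!is.null(out_dir)) {
      utils::write.table(data.frame(sample_id = names(labels), group = labels),
                         file.path(out_dir, "cluster_labels.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  } else report$cluster <- "skipped"

  if ("differential" %in% stages && !is.null(asb_flag)) {
    design <- cbind(intercept = 1, asb = as.integer(asb_flag))
    rownames(design) <- bundle$annotation$sample_id
    fit <- suppressWarnings(moderated_fit(bundle$protein, design, "asb"))
    hits <- call_hits(fit, lfc_cut = 0.5, fdr_cut = 0.001)
    cor_res <- suppressWarnings(mrna_protein_spearman(bundle$protein, bundle$mrna))
    ora <- fisher_overrepresentation_sets(
      hits$hits, fit$feature_id, bundle$gene_sets)
    report$differential <- list(
      n_hits = hits$n_hits,
      median_rho = cor_res$summary$median_rho,
      median_rho_by_class = as.list(cor_res$summary$median_rho_by_class),
      frac_significant_positive = cor_res$summary$frac_significant_positive,
      top_enriched_set = ora$set[which.min(ora$p)])
    if (!is.null(out_dir)) {
      utils::write.table(hits$table, file.path(out_dir, "differential_asb.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else report$differential <- "skipped"

  if ("splicing" %in% stages && !is.null(asb_flag)) {
    psi <- compute_psi(bundle$events)
    dp <- differential_psi(bundle$events, asb_flag)
    pn <- permutation_null(bundle$events, asb_flag, n_perm = n_perm,
                           seed = derive_seed(seed, 3L))
    top <- top_variable_events(bundle$events, "SE", 1000, psi = psi)
    mp <- mean_psi(psi[top, , drop = FALSE])
    mp_test <- group_rank_tests(mp, ifelse(asb_flag, "ASB", "other"))
    report$splicing <- list(
      n_significant_events = sum(dp$significant),
      permutation_p = pn$p,
      mean_psi_se_p = mp_test$p)
    if (!is.null(out_dir)) {
      utils::write.table(dp[dp$significant, ],
                         file.path(out_dir, "significant_events.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else report$splicing <- "skipped"

  if ("survival" %in% stages && !is.null(labels)) {
    ep <- endpoint_from_annotation(bundle$annotation, "TTNT")
    lr <- logrank(ep$time_days, ep$event, labels)
    growth <- lymphocyte_growth(bundle$lymph_series)
    g_ok <- growth$rates$sample_id
    gr_test <- group_rank_tests(
      growth$rates$slope,
      bundle$truth[g_ok])
    report$survival <- list(logrank_ttnt_p = lr$p,
                            growth_rate_p = gr_test$p,
                            n_growth_excluded = nrow(growth$excluded))
  } else report$survival <- "skipped"

  if ("network" %in% stages) {
    net <- build_network(bundle$protein,
                         n_top_sd = min(1047L, nrow(bundle$protein$values)))
    net <- kcore(net, 3)
    if (igraph::vcount(net$graph) > 0) {
      net <- network_modules(net, resolution = 0.8,
                             seed = derive_seed(seed, 4L))
      report$network <- list(n_nodes = length(net$nodes),
                             n_modules = length(unique(net$modules)))
    } else report$network <- list(n_nodes = 0L, n_modules = 0L)
  } else report$network <- "skipped"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Apply trained subtype classifiers to an independent cohort
#'
#' Predicts the ASB-like subgroup with a k-TSP model on the protein matrix
#' (and optionally a PLS-DA model on signature-event PSI values), then
#' compares overall survival between predicted groups (Kaplan-Meier,
#' log-rank, and Cox models with TP53 and IGHV interactions).
#'
#' @param tsp_model a [tsp_train_mccv()] model.
#' @param bundle validation `cohort_bundle`.
#' @param plsda_model optional [plsda_train()] model.
#' @param signature_events event ids for the PLS-DA predictor (required with
#'   `plsda_model`).
#' @param out_dir optional output directory for the report JSON.
#' @return report list with predicted prevalence, survival statistics and
#'   Cox tables.
#' @export
run_validation <- function(tsp_model, bundle, plsda_model = NULL,
                           signature_events = NULL, out_dir = NULL) {
  pred <- tsp_predict(tsp_model, bundle$protein$values)
  asb <- !is.na(pred$label) & pred$label == tsp_model$positive
  report <- list(
    n_samples = nrow(pred),
    ktsp = list(prevalence_pct = 100 * mean(asb),
                n_asb = sum(asb),
                mean_votes = mean(pred$votes)))
  ep <- endpoint_from_annotation(bundle$annotation, "OS")
  if (length(unique(asb)) == 2) {
    lr <- logrank(ep$time_days, ep$event, ifelse(asb, "ASB", "other"))
    report$ktsp$logrank_os_p <- lr$p
    interaction_cox <- function(lesion, name) {
      cov <- data.frame(lesion = lesion, ASB = as.integer(asb))
      names(cov)[1L] <- name
      cov[[paste0(name, "_ASB")]] <- lesion * cov$ASB
      # drop covariates without variation (e.g. no lesion carrier among
      # the predicted ASB samples)
      keep <- vapply(cov, function(v) length(unique(v)) > 1, logical(1))
      if (!any(keep)) return(NULL)
      if (!all(keep)) {
        message(sprintf("dropping constant covariate(s): %s",
                        paste(names(cov)[!keep], collapse = ", ")))
      }
      out <- try(suppressWarnings(cox_fit(ep, cov[, keep, drop = FALSE])),
                 silent = TRUE)
      if (inherits(out, "try-error")) NULL else out
    }
    report$cox_tp53_interaction <-
      interaction_cox(bundle$annotation$TP53mut, "TP53")
    report$cox_ighv_interaction <-
      interaction_cox(bundle$annotation$IGHV, "IGHV")
  }
  if (!is.null(plsda_model)) {
    if (is.null(signature_events)) stopf("signature_events required for PLS-DA")
    psi <- compute_psi(bundle$events)
    Xv <- t(psi[intersect(signature_events, rownames(psi)), , drop = FALSE])
    pp <- suppressWarnings(plsda_predict(plsda_model, Xv))
    asb2 <- !is.na(pp$label) & pp$label == plsda_model$positive
    report$plsda <- list(prevalence_pct = 100 * mean(asb2), n_asb = sum(asb2))
    if (length(unique(asb2)) == 2) {
      lr2 <- logrank(ep$time_days, ep$event, ifelse(asb2, "ASB", "other"))
      report$plsda$logrank_os_p <- lr2$p
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "validation_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
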