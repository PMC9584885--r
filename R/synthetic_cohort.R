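# Synthetic multi-omics CLL cohort generator. Plants the subgroup structure,
# gene-dosage effects, class-dependent mRNA~protein coupling, ASB-specific
# pathway and splicing shifts, and group-dependent survival hazards that the
# downstream analyses are designed to detect.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the analyses assume: a 68-sample
#' discovery cohort with six subgroups (four genotype-driven, one TP53-driven,
#' one ASB-like at ~18% prevalence), a chr12 dosage effect of log2(3/2),
#' class-dependent mRNA~protein Spearman coupling targets (trisomy-12 0.69,
#' IGHV 0.86, SF3B1 0.29, background tuned so the cohort-wide median is near
#' 0.243), ASB-specific spliceosome-up/BcR-down protein shifts and PSI shifts,
#' and subgroup-dependent survival hazards.
#'
#' @param n_samples cohort size.
#' @param subgroup_proportions named fractions over
#'   `Tris12M, Tris12U, M, U, TP53, ASB`; must sum to 1.
#' @param lesion_prevalences background probabilities for lesions not fixed
#'   by subgroup membership.
#' @param dosage_log2fc log2 fold change on chr12 features in trisomy-12
#'   carriers (default `log2(3/2)`).
#' @param asb_spliceosome_shift,asb_bcr_shift,asb_proteasome_shift,asb_bcaa_shift
#'   log2 shifts applied to the respective gene sets in ASB samples.
#' @param coupling_by_class target mRNA~protein Spearman rho per feature class.
#' @param delta_psi_asb logit-scale PSI shift for ASB-affected splice events
#'   (default 0.85, giving mean |dPSI| near 0.15).
#' @param n_features_protein,n_features_rna,n_events feature/event counts.
#' @param survival_loghr named log hazard ratios per subgroup.
#' @param noise_sd residual SD of log2 abundances.
#' @param missing_rate completely-at-random missingness rate in the protein
#'   matrix.
#' @param seed integer RNG seed for cohort-level randomness (group
#'   assignment, noise, counts, outcomes); identical config + seed gives
#'   bit-identical bundles.
#' @param feature_seed integer RNG seed for the feature space (baseline
#'   abundances, chromosome assignment, planted shift directions, event
#'   baselines). Cohorts sharing `feature_seed` share the same "biology",
#'   which is what lets classifiers trained on one cohort transfer to
#'   another; change it only to draw a different universe of features.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(
    n_samples = 68,
    subgroup_proportions = c(Tris12M = 0.13, Tris12U = 0.12, M = 0.26,
                             U = 0.25, TP53 = 0.06, ASB = 0.18),
    lesion_prevalences = c(trisomy12 = 0.25, IGHV_mutated = 0.55,
                           TP53mut = 0.08, SF3B1mut = 0.20, del17p13 = 0.08,
                           del11q22 = 0.15, del13q14 = 0.55, gain8q24 = 0.05),
    dosage_log2fc = log2(3 / 2),
    asb_spliceosome_shift = 0.7,
    asb_bcr_shift = -0.7,
    asb_proteasome_shift = -0.4,
    asb_bcaa_shift = 0.4,
    coupling_by_class = c(trisomy12 = 0.69, IGHV = 0.86, SF3B1 = 0.29,
                          background = 0.21),
    delta_psi_asb = 0.85,
    n_features_protein = 2000,
    n_features_rna = 2000,
    n_events = 2000,
    survival_loghr = c(Tris12M = 0.2, Tris12U = 0.5, M = -0.6, U = 0.3,
                       TP53 = 1.0, ASB = 1.2),
    noise_sd = 0.5,
    missing_rate = 0.05,
    seed = 1L,
    feature_seed = 104729L) {
  cfg <- list(
    n_samples = n_samples, subgroup_proportions = subgroup_proportions,
    lesion_prevalences = lesion_prevalences, dosage_log2fc = dosage_log2fc,
    asb_spliceosome_shift = asb_spliceosome_shift, asb_bcr_shift = asb_bcr_shift,
    asb_proteasome_shift = asb_proteasome_shift, asb_bcaa_shift = asb_bcaa_shift,
    coupling_by_class = coupling_by_class, delta_psi_asb = delta_psi_asb,
    n_features_protein = n_features_protein, n_features_rna = n_features_rna,
    n_events = n_events, survival_loghr = survival_loghr, noise_sd = noise_sd,
    missing_rate = missing_rate, seed = as.integer(seed),
    feature_seed = as.integer(feature_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_config <- function(cfg) {
  groups <- c("Tris12M", "Tris12U", "M", "U", "TP53", "ASB")
  if (!setequal(names(cfg$subgroup_proportions), groups)) {
    stopf("configuration error: 'subgroup_proportions' must name %s",
          paste(groups, collapse = ", "))
  }
  check_prob(cfg$subgroup_proportions, "subgroup_proportions")
  if (abs(sum(cfg$subgroup_proportions) - 1) > 1e-9) {
    stopf("configuration error: 'subgroup_proportions' must sum to 1")
  }
  check_prob(cfg$lesion_prevalences, "lesion_prevalences")
  check_prob(cfg$missing_rate, "missing_rate")
  check_count(cfg$n_samples, "n_samples")
  check_count(cfg$n_features_protein, "n_features_protein")
  check_count(cfg$n_features_rna, "n_features_rna")
  check_count(cfg$n_events, "n_events")
  check_prob(abs(cfg$coupling_by_class), "coupling_by_class")
  if (cfg$noise_sd <= 0) stopf("configuration error: 'noise_sd' must be positive")
  invisible(cfg)
}

# Largest-remainder rounding of proportions to integer counts summing to n.
proportions_to_counts <- function(props, n) {
  raw <- props * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  setNames(as.integer(counts), names(props))
}

# Fixed design of the planted feature panels (sizes in features). The set
# sizes mirror typical KEGG pathway sizes; effect sizes for the panels the
# source data do not pin down are free parameters documented in the vignette.
panel_design <- function() {
  list(
    CHR12 = list(n = 100, class = "trisomy12"),
    TRIS12_TRANS = list(n = 170, class = "trisomy12", shift = 0.6, frac_up = 0.8),
    IGHV_SET = list(n = 120, class = "IGHV", shift = 0.7, frac_up = 0.5),
    SF3B1_SET = list(n = 80, class = "SF3B1", shift = 0.5, frac_up = 0.5),
    TP53_SET = list(n = 80, class = "background", shift = 0.9, frac_up = 0.5),
    SPLICEOSOME = list(n = 130, class = "background"),
    BCR = list(n = 75, class = "background"),
    PROTEASOME = list(n = 45, class = "background"),
    BCAA = list(n = 45, class = "background")
  )
}

# Convert a target Spearman rho to the Pearson r of the underlying
# (approximately) bivariate normal pair.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Simulate a multi-omics cohort with planted subgroup structure
#'
#' Generates sample annotation (lesions, endpoints, true labels), a protein
#' and an mRNA log2 abundance matrix, a splice event count table, an
#' exon-level quantification matrix, a drug-screen well table, lymphocyte
#' count series, and the gene sets naming the planted panels. See
#' [cohort_config()] for the planted effect sizes.
#'
#' Proteins are `baseline + planted shifts + Normal noise`; mRNA shares each
#' protein's non-constant signal through a class-specific mixing weight
#' solved against the target Spearman coupling. Splice-event totals are
#' negative binomial (mean 60, dispersion 0.3) with binomial inclusion
#' counts at subgroup-shifted PSI. Survival times are exponential with
#' subgroup log hazard ratios under independent uniform censoring (~30%).
#'
#' @param config a [cohort_config()].
#' @return A `cohort_bundle`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_config(config)
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  sid <- sprintf("S%03d", seq_len(n))
  groups <- names(cfg$subgroup_proportions)

  counts <- proportions_to_counts(cfg$subgroup_proportions, n)
  group <- sample(rep(names(counts), counts))

  ann <- build_annotation(cfg, sid, group)
  fs <- with_seed(cfg$feature_seed, feature_space(cfg))
  prot <- simulate_protein(cfg, ann, fs)
  mrna <- simulate_mrna(cfg, prot, fs)

  # inject MCAR missingness into the protein matrix only
  pv <- prot$values
  miss <- runif(length(pv)) < cfg$missing_rate
  pv[miss] <- NA_real_
  protein <- omics_matrix(pv, prot$feature_meta)

  events <- simulate_events(cfg, ann, fs)
  exon <- simulate_exons(cfg, ann, fs)
  drug <- simulate_drug_plate(cfg, ann)
  lymph <- simulate_lymph(cfg, ann)

  gs <- gene_set_collection(fs$sets[c("BCR", "SPLICEOSOME", "PROTEASOME",
                                          "BCAA", "CHR12")],
                            setNames(c("B-cell receptor signaling panel",
                                       "Spliceosome panel", "Proteasome panel",
                                       "BCAA degradation panel",
                                       "Chromosome 12 features"),
                                     c("BCR", "SPLICEOSOME", "PROTEASOME",
                                       "BCAA", "CHR12")))

  new_cohort_bundle(ann, protein, mrna, events, exon$quant, exon$map,
                    drug, lymph, gs, config = cfg)
}

build_annotation <- function(cfg, sid, group) {
  n <- length(sid)
  prev <- cfg$lesion_prevalences
  trisomy12 <- as.integer(group %in% c("Tris12M", "Tris12U"))
  ighv <- integer(n)
  ighv[group %in% c("Tris12M", "M")] <- 1L
  ighv[group %in% c("Tris12U", "U")] <- 0L
  free <- group %in% c("TP53", "ASB")
  ighv[free] <- rbinom(sum(free), 1, prev[["IGHV_mutated"]])
  tp53 <- ifelse(group == "TP53", 1L, rbinom(n, 1, 0.04))
  sf3b1 <- rbinom(n, 1, prev[["SF3B1mut"]])
  del17 <- ifelse(tp53 == 1L, rbinom(n, 1, 0.5), rbinom(n, 1, prev[["del17p13"]] / 2))
  del11 <- rbinom(n, 1, prev[["del11q22"]])
  del13 <- rbinom(n, 1, prev[["del13q14"]])
  gain8 <- rbinom(n, 1, prev[["gain8q24"]])
  pretreated <- rbinom(n, 1, ifelse(group %in% c("Tris12M", "Tris12U", "M"), 0.15, 0.45))

  loghr <- cfg$survival_loghr[group]
  surv <- function(base_rate, hr_scale = 1) {
    t <- ceiling(rexp(n, base_rate * exp(hr_scale * loghr)))
    cmax <- 3 / base_rate
    cens <- ceiling(runif(n, 1, cmax))
    data.frame(days = pmax(1, pmin(t, cens)), event = as.integer(t <= cens))
  }
  ttnt <- surv(1 / 1500)
  ttft <- surv(1 / 2000)
  os <- surv(1 / 4000, hr_scale = 0.8)

  data.frame(
    sample_id = sid, cohort = "synthetic_discovery",
    IGHV = ighv, trisomy12 = trisomy12, TP53mut = tp53, SF3B1mut = sf3b1,
    del17p13 = del17, del11q22 = del11, del13q14 = del13, gain8q24 = gain8,
    pretreated = pretreated, true_group = group,
    ttnt_days = ttnt$days, ttnt_event = ttnt$event,
    ttft_days = ttft$days, ttft_event = ttft$event,
    os_days = os$days, os_event = os$event,
    stringsAsFactors = FALSE
  )
}

# The fixed feature space: panel membership, chromosome/position metadata,
# baseline abundances, planted shift directions, splice-event baselines and
# exon structure. Drawn under `feature_seed` so that cohorts generated with
# different cohort seeds still share the same underlying "biology" -- the
# property that makes classifiers transferable across cohorts.
feature_space <- function(cfg) {
  p <- cfg$n_features_protein
  design <- panel_design()
  need <- sum(vapply(design, `[[`, numeric(1), "n"))
  if (p < need + 100) {
    stopf("configuration error: 'n_features_protein' must be at least %d", need + 100)
  }
  fid <- sprintf("P%04d", seq_len(p))
  gene <- sprintf("G%04d", seq_len(p))
  idx <- seq_len(p)
  sets <- list(); meta_class <- rep("background", p)
  cursor <- 1L
  for (nm in names(design)) {
    take <- idx[cursor:(cursor + design[[nm]]$n - 1L)]
    cursor <- cursor + design[[nm]]$n
    sets[[nm]] <- fid[take]
    meta_class[take] <- design[[nm]]$class
  }
  chrom <- sample(paste0("chr", setdiff(1:22, 12)), p, replace = TRUE)
  chrom[fid %in% sets$CHR12] <- "chr12"
  pos <- integer(p)
  for (ch in unique(chrom)) {
    on_ch <- which(chrom == ch)
    pos[on_ch] <- sort(sample.int(130e6, length(on_ch)))
  }
  meta <- data.frame(feature_id = fid, gene_symbol = gene, chromosome = chrom,
                     start = pos, end = pos + 1000L, class = meta_class,
                     stringsAsFactors = FALSE)
  signs <- lapply(design, function(d) {
    if (is.null(d$frac_up)) return(NULL)
    ifelse(runif(d$n) < d$frac_up, 1, -1)
  })
  mu_protein <- rnorm(p, 20, 2)
  mu_rna <- rnorm(p, 10, 1.5)

  # six co-abundance blocks (complex/co-regulation structure) planted on the
  # trailing background features: a shared latent factor per block gives
  # within-block Pearson r around 0.75 and high total variance, so the
  # blocks dominate the high-SD correlation network
  n_blocks <- 6L; block_size <- 40L
  block_feats <- fid[(p - n_blocks * block_size + 1L):p]
  cor_block <- integer(p)
  cor_block[match(block_feats, fid)] <- rep(seq_len(n_blocks), each = block_size)
  meta$cor_block <- cor_block

  edes <- event_design(cfg$n_events)
  category <- rep(names(edes$cat_n), edes$cat_n)
  m <- length(category)
  affected <- logical(m); dir <- numeric(m)
  for (cat in names(edes$cat_n)) {
    i <- which(category == cat)
    aff <- i[seq_len(edes$affected[[cat]])]
    affected[aff] <- TRUE
    dir[aff] <- edes$dir[[cat]]
  }
  event <- list(event_id = sprintf("E%05d", seq_len(m)), category = category,
                affected = affected, dir = dir, psi0 = runif(m, 0.15, 0.85))

  n_genes <- 300L
  n_exons <- sample(2:8, n_genes, replace = TRUE)
  exon_gene <- rep(sprintf("XG%03d", seq_len(n_genes)), n_exons)
  target_genes <- which(n_exons >= 2)[1:60]
  exon <- list(gene = exon_gene, gene_index = rep(seq_len(n_genes), n_exons),
               exon_id = sprintf("X%04d", seq_along(exon_gene)),
               mu = rnorm(length(exon_gene), 20, 2), n_genes = n_genes,
               target = match(sprintf("XG%03d", target_genes), exon_gene))

  list(sets = sets, meta = meta, design = design, signs = signs,
       mu_protein = mu_protein, mu_rna = mu_rna, event = event, exon = exon)
}

# Planted log2-shift matrix (features x samples); shift directions are part
# of the fixed feature space.
shift_matrix <- function(cfg, ann, fs) {
  meta <- fs$meta; sets <- fs$sets; design <- fs$design
  p <- nrow(meta); n <- nrow(ann)
  delta <- matrix(0, p, n, dimnames = list(meta$feature_id, ann$sample_id))
  add_shift <- function(delta, panel, carriers) {
    i <- match(sets[[panel]], meta$feature_id)
    delta[i, carriers] <- delta[i, carriers] +
      design[[panel]]$shift * fs$signs[[panel]]
    delta
  }
  tris <- ann$trisomy12 == 1
  i12 <- match(sets$CHR12, meta$feature_id)
  delta[i12, tris] <- delta[i12, tris] + cfg$dosage_log2fc
  delta <- add_shift(delta, "TRIS12_TRANS", tris)
  delta <- add_shift(delta, "IGHV_SET", ann$IGHV == 1)
  delta <- add_shift(delta, "SF3B1_SET", ann$SF3B1mut == 1)
  delta <- add_shift(delta, "TP53_SET", ann$true_group == "TP53")
  asb <- ann$true_group == "ASB"
  for (spec in list(c("SPLICEOSOME", cfg$asb_spliceosome_shift),
                    c("BCR", cfg$asb_bcr_shift),
                    c("PROTEASOME", cfg$asb_proteasome_shift),
                    c("BCAA", cfg$asb_bcaa_shift))) {
    i <- match(sets[[spec[1L]]], meta$feature_id)
    delta[i, asb] <- delta[i, asb] + as.numeric(spec[2L])
  }
  delta
}

simulate_protein <- function(cfg, ann, fs) {
  p <- cfg$n_features_protein; n <- nrow(ann)
  delta <- shift_matrix(cfg, ann, fs)
  noise <- matrix(rnorm(p * n, 0, cfg$noise_sd), p, n)
  # co-abundance blocks: per-block shared latent factor (partly aligned with
  # one subgroup, so module mean abundances differ by group) + small residual
  blocks <- fs$meta$cor_block
  groups <- names(cfg$subgroup_proportions)
  for (bl in setdiff(sort(unique(blocks)), 0L)) {
    i <- which(blocks == bl)
    aligned <- groups[((bl - 1L) %% length(groups)) + 1L]
    latent <- 0.6 * (ann$true_group == aligned) + rnorm(n, 0, sqrt(0.14))
    noise[i, ] <- matrix(latent, length(i), n, byrow = TRUE) +
      rnorm(length(i) * n, 0, sqrt(0.09))
  }
  vals <- fs$mu_protein + delta + noise
  dimnames(vals) <- dimnames(delta)
  m <- omics_matrix(vals, fs$meta)
  attr(m, "signal") <- delta + noise  # non-constant part, reused for coupling
  m
}

# mRNA shares each gene's protein signal with a class-specific mixing weight
# solved against the target Spearman coupling (via the bivariate-normal
# Spearman/Pearson relation), plus independent noise.
simulate_mrna <- function(cfg, prot, fs) {
  signal <- attr(prot, "signal")
  p <- nrow(signal); n <- ncol(signal)
  n_rna <- cfg$n_features_rna
  if (n_rna > p) n_rna <- p  # shared gene space; transcripts subset proteins
  keep <- seq_len(n_rna)
  meta <- fs$meta[keep, , drop = FALSE]
  cls <- meta$class
  rho <- cfg$coupling_by_class[cls]
  rho[is.na(rho)] <- cfg$coupling_by_class[["background"]]
  r <- spearman_to_pearson(pmin(rho, 0.995))
  sigma_d <- cfg$noise_sd
  sigma_s <- apply(signal[keep, , drop = FALSE], 1, stats::sd)
  beta <- (r / sqrt(1 - r^2)) * sigma_d / sigma_s
  noise <- matrix(rnorm(n_rna * n, 0, sigma_d), n_rna, n)
  vals <- fs$mu_rna[keep] + beta * signal[keep, , drop = FALSE] + noise
  rmeta <- data.frame(feature_id = sprintf("T%04d", keep),
                      gene_symbol = meta$gene_symbol,
                      chromosome = meta$chromosome, start = meta$start,
                      end = meta$end, class = cls, stringsAsFactors = FALSE)
  rownames(vals) <- rmeta$feature_id
  colnames(vals) <- colnames(signal)
  omics_matrix(vals, rmeta)
}

# Event categories and the number of ASB-affected events per category.
# Direction: skipped-exon PSI shifts down in ASB, alternative splice-site
# usage up, matching the subgroup's splicing phenotype.
event_design <- function(n_events) {
  cat_n <- round(n_events * c(SE = 0.60, A3SS = 0.15, A5SS = 0.15,
                              RI = 0.06, MXE = 0.04))
  cat_n[1L] <- n_events - sum(cat_n[-1L])
  affected <- c(SE = 150L, A3SS = 80L, A5SS = 80L, RI = 0L, MXE = 0L)
  dir <- c(SE = -1, A3SS = 1, A5SS = 1, RI = 0, MXE = 0)
  list(cat_n = cat_n, affected = pmin(affected, cat_n), dir = dir)
}

simulate_events <- function(cfg, ann, fs) {
  ed <- fs$event
  n <- nrow(ann)
  category <- ed$category
  m <- length(category)
  event_id <- ed$event_id
  affected <- ed$affected; dir <- ed$dir
  asb <- ann$true_group == "ASB"
  lp <- matrix(logit(ed$psi0), m, n) +
    matrix(rnorm(m * n, 0, 0.2), m, n) +
    outer(dir * affected * cfg$delta_psi_asb, as.numeric(asb))
  psi <- expit(lp)
  lI <- 2; lS <- 1
  total <- matrix(rnbinom(m * n, mu = 60, size = 1 / 0.3), m, n)
  # inclusion-read fraction implied by PSI under the length convention
  f <- (lI * psi) / (lI * psi + lS * (1 - psi))
  incl <- matrix(rbinom(m * n, as.vector(total), as.vector(f)), m, n)
  skip <- total - incl
  dimnames(incl) <- dimnames(skip) <- list(event_id, ann$sample_id)
  ev <- splice_event_table(
    data.frame(event_id = event_id, category = category,
               incl_len = lI, skip_len = lS, stringsAsFactors = FALSE),
    incl, skip)
  ev$events$asb_affected <- affected
  ev
}

# Exon-level log2 quantifications: genes with 2-8 exons, a shared per-gene
# sample effect, and 60 ASB-specific single-exon usage shifts.
simulate_exons <- function(cfg, ann, fs) {
  ex <- fs$exon
  n <- nrow(ann)
  m <- length(ex$exon_id)
  gene_eff <- matrix(rnorm(ex$n_genes * n, 0, 0.4), ex$n_genes, n)
  vals <- ex$mu + gene_eff[ex$gene_index, ] +
    matrix(rnorm(m * n, 0, 0.3), m, n)
  # one exon in each of 60 target genes has elevated usage in ASB
  asb <- ann$true_group == "ASB"
  vals[ex$target, asb] <- vals[ex$target, asb] + 0.8
  dimnames(vals) <- list(ex$exon_id, ann$sample_id)
  map <- data.frame(exon_id = ex$exon_id, gene_symbol = ex$gene,
                    asb_target = seq_len(m) %in% ex$target,
                    stringsAsFactors = FALSE)
  list(quant = vals, map = map)
}

simulate_drug_plate <- function(cfg, ann) {
  drugs <- c("fludarabine", "doxorubicin", "ibrutinib", "idelalisib", "venetoclax")
  dna_damage <- c("fludarabine", "doxorubicin")
  bcr_drugs <- c("ibrutinib", "idelalisib")
  conc_eff <- c(0.9, 0.7, 0.5)  # viability multiplier per concentration index
  rows <- list()
  for (s in seq_len(nrow(ann))) {
    g <- ann$true_group[s]
    base_alive <- 0.75
    well <- 0L
    # solvent controls
    for (w in 1:8) {
      well <- well + 1L
      ncell <- max(50L, round(rnorm(1, 500, 50)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ann$sample_id[s], drug = "DMSO", conc_index = 0L,
        well_id = sprintf("W%02d", well), n_cells = ncell,
        n_alive = rbinom(1, ncell, base_alive), is_solvent_control = 1L)
    }
    for (d in drugs) {
      for (ci in 1:3) {
        eff <- conc_eff[ci]
        if (g == "TP53" && d %in% dna_damage) eff <- sqrt(eff)  # resistance
        if (g == "ASB" && d %in% bcr_drugs) eff <- sqrt(eff)    # low BcR dependence
        for (rep_w in 1:2) {
          well <- well + 1L
          ncell <- max(50L, round(rnorm(1, 500, 50)))
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = ann$sample_id[s], drug = d, conc_index = ci,
            well_id = sprintf("W%02d", well), n_cells = ncell,
            n_alive = rbinom(1, ncell, base_alive * eff),
            is_solvent_control = 0L)
        }
      }
    }
  }
  do.call(rbind, rows)
}

simulate_lymph <- function(cfg, ann) {
  rates <- c(Tris12M = 0.001, Tris12U = 0.002, M = 0.001, U = 0.002,
             TP53 = 0.003, ASB = 0.004)
  rows <- list()
  for (s in seq_len(nrow(ann))) {
    np <- sample(3:8, 1)  # some samples fall below the 4-point minimum
    days <- seq(0, by = 90, length.out = np)
    l0 <- rnorm(1, 1.5, 0.2)
    counts <- 10^(l0 + rates[[ann$true_group[s]]] * days + rnorm(np, 0, 0.05))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = ann$sample_id[s], day = days, count = counts)
  }
  do.call(rbind, rows)
}
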