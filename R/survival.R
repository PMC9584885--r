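# Clinical endpoint construction, Kaplan-Meier / log-rank / Cox analyses,
# lymphocyte growth rates, and drug-screen viability normalization. The
# survival machinery is provided by the survival package behind this module
# surface.

#' Build a censored endpoint table from clinical date records
#'
#' Endpoint rules: TTNT runs from sample collection to treatment initiation;
#' TTFT from diagnosis to treatment initiation; OS from sample collection to
#' death. Patients without the terminal event during observation (including
#' those who died untreated, for TTNT/TTFT) are censored at the latest
#' follow-up contact. Records without any follow-up are excluded and
#' counted.
#'
#' @param records data.frame with columns `sample_id`, `date_collection`,
#'   `date_diagnosis`, `date_treatment`, `date_death`, `date_last_contact`
#'   (numeric days or Date; NA where not applicable).
#' @param type one of `"TTNT"`, `"TTFT"`, `"OS"`.
#' @return data.frame `sample_id, time_days, event, endpoint`; the number of
#'   excluded records is in attribute `n_excluded`.
#' @export
build_endpoint <- function(records, type = c("TTNT", "TTFT", "OS")) {
  type <- match.arg(type)
  origin <- switch(type, TTNT = records$date_collection,
                   TTFT = records$date_diagnosis,
                   OS = records$date_collection)
  terminal <- switch(type, TTNT = records$date_treatment,
                     TTFT = records$date_treatment,
                     OS = records$date_death)
  followup <- records$date_last_contact
  no_fu <- is.na(terminal) & is.na(followup)
  if (any(no_fu)) {
    message(sprintf("%d record(s) excluded: no clinical follow-up", sum(no_fu)))
  }
  keep <- !no_fu & !is.na(origin)
  origin <- as.numeric(origin[keep]); terminal <- as.numeric(terminal[keep])
  followup <- as.numeric(followup[keep])
  event <- as.integer(!is.na(terminal))
  time <- ifelse(event == 1, terminal - origin, followup - origin)
  bad <- which(time <= 0)
  if (length(bad)) {
    stopf("record-level error: non-positive %s time for sample %s",
          type, records$sample_id[keep][bad[1L]])
  }
  out <- data.frame(sample_id = records$sample_id[keep], time_days = time,
                    event = event, endpoint = type, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(no_fu)
  out
}

#' Extract an endpoint table from a cohort annotation
#' @param annotation a bundle annotation with `<endpoint>_days/_event` columns.
#' @param type `"TTNT"`, `"TTFT"` or `"OS"`.
#' @return data.frame `sample_id, time_days, event, endpoint`.
#' @export
endpoint_from_annotation <- function(annotation, type = c("TTNT", "TTFT", "OS")) {
  type <- match.arg(type)
  pre <- tolower(type)
  data.frame(sample_id = annotation$sample_id,
             time_days = annotation[[paste0(pre, "_days")]],
             event = annotation[[paste0(pre, "_event")]],
             endpoint = type, stringsAsFactors = FALSE)
}

#' Kaplan-Meier curve and median survival
#'
#' Product-limit estimate; the median is the earliest time at which the
#' survival function drops to 0.5 or below (NA if never reached).
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @return list with `time`, `surv` (step function values at event times),
#'   `n_risk`, `n_event`, and `median`.
#' @export
km_curve <- function(times, events) {
  if (any(times < 0)) stopf("negative times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1L]] else NA_real_
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med)
}

#' Log-rank test across groups
#'
#' @param times,events as in [km_curve()].
#' @param group group label per sample (>= 2 non-empty groups).
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank <- function(times, events, group) {
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2) {
    stopf("need at least 2 non-empty groups")
  }
  if (length(unique(group)) < 2) stopf("need at least 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(sd$n) - 1
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Wraps `survival::coxph` with the chosen ties correction; reports
#' coefficients, hazard ratios, 95% Wald intervals and p-values, and flags
#' monotone-likelihood (perfect separation) warnings.
#'
#' @param endpoint an endpoint table (`time_days`, `event`).
#' @param covariates data.frame of covariates aligned to the endpoint rows,
#'   or a one-sided formula string such as `"ASB * TP53"` evaluated in that
#'   data.frame.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_result` data.frame: `term, coef, hr, ci_lower, ci_upper,
#'   p`; log-likelihood, ties method and separation flag in attributes.
#' @export
cox_fit <- function(endpoint, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(endpoint$event) < 1) stopf("need at least one event")
  if (is.character(covariates)) stopf("pass covariates as a data.frame")
  constant <- vapply(covariates, function(v) length(unique(v)) < 2, logical(1))
  if (any(constant)) stopf("constant covariate: %s", names(covariates)[constant][1L])
  d <- cbind(endpoint[, c("time_days", "event")], covariates)
  f <- stats::as.formula(paste("survival::Surv(time_days, event) ~",
                               paste(names(covariates), collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(f, data = d, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation) warnf("monotone likelihood (possible separation); coefficients unstable")
  s <- summary(fit)
  co <- s$coefficients
  out <- data.frame(term = rownames(co), coef = co[, "coef"],
                    hr = exp(co[, "coef"]),
                    ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "loglik") <- fit$loglik[2L]
  attr(out, "ties") <- ties
  attr(out, "separation") <- separation
  attr(out, "score_test") <- unname(fit$score)
  out
}

#' In vivo lymphocyte growth rates
#'
#' Per-sample OLS slope of log10 lymphocyte counts versus time; samples with
#' fewer than four time points are excluded (reported in the `excluded`
#' component).
#'
#' @param series data.frame `sample_id, day, count` (counts > 0).
#' @return list with `rates` (data.frame `sample_id, slope, n_points`) and
#'   `excluded` (sample ids with reason).
#' @export
lymphocyte_growth <- function(series) {
  if (any(series$count <= 0)) stopf("non-positive lymphocyte count")
  out <- lapply(split(series, series$sample_id), function(d) {
    if (nrow(d) < 4) {
      return(data.frame(sample_id = d$sample_id[1L], slope = NA_real_,
                        n_points = nrow(d), stringsAsFactors = FALSE))
    }
    fit <- stats::lm.fit(cbind(1, d$day), log10(d$count))
    data.frame(sample_id = d$sample_id[1L], slope = fit$coefficients[2L],
               n_points = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  excluded <- out$sample_id[is.na(out$slope)]
  list(rates = out[!is.na(out$slope), ],
       excluded = data.frame(sample_id = excluded,
                             reason = rep("fewer than four time points",
                                          length(excluded)),
                             stringsAsFactors = FALSE))
}

#' Normalize drug-screen viability to solvent controls
#'
#' Per well, percent alive = `100 * n_alive / n_cells`; each treated well is
#' normalized by the mean percent alive across the sample's solvent (DMSO)
#' control wells: `100 * pct_alive / mean(pct_alive_solvent)`. Wells with
#' zero cells yield NA with a warning.
#'
#' @param plate data.frame with columns `sample_id, drug, conc_index,
#'   well_id, n_cells, n_alive, is_solvent_control`.
#' @return the plate with added `pct_alive` and `viability` (% of control).
#' @export
viability_normalize <- function(plate) {
  zero <- plate$n_cells == 0
  if (any(zero)) warnf("%d well(s) with zero cells; viability set to NA", sum(zero))
  pct <- ifelse(zero, NA_real_, 100 * plate$n_alive / plate$n_cells)
  plate$pct_alive <- pct
  ctrl <- tapply(pct[plate$is_solvent_control == 1],
                 plate$sample_id[plate$is_solvent_control == 1],
                 mean, na.rm = TRUE)
  missing_ctrl <- setdiff(unique(plate$sample_id), names(ctrl))
  if (length(missing_ctrl)) {
    stopf("no solvent-control wells for sample %s", missing_ctrl[1L])
  }
  plate$viability <- 100 * pct / ctrl[plate$sample_id]
  plate
}

#' Classify nuclei as alive by area threshold
#'
#' Alive = nuclear area strictly greater than the threshold (condensed,
#' i.e. small, nuclei are scored dead).
#'
#' @param areas per-cell nuclear areas in square micrometers (> 0).
#' @param threshold area threshold (default 23.8).
#' @return fraction of alive cells.
#' @export
classify_nuclei <- function(areas, threshold = 23.8) {
  if (!length(areas)) stopf("empty area list")
  if (any(areas <= 0)) stopf("areas must be positive")
  mean(areas > threshold)
}

#' Nonparametric group comparison
#'
#' Two-sided Wilcoxon rank-sum for two groups (exact when both groups have
#' at most 10 untied observations, normal approximation with tie correction
#' otherwise); Kruskal-Wallis for more than two groups.
#'
#' @param values numeric outcomes.
#' @param groups group labels (>= 2 non-empty groups).
#' @return list with `method`, `statistic`, `p`.
#' @export
group_rank_tests <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2) stopf("a group is empty")
  if (nlevels(groups) == 2) {
    a <- values[groups == levels(groups)[1L]]
    b <- values[groups == levels(groups)[2L]]
    exact <- max(length(a), length(b)) <= 10 && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
    list(method = "wilcoxon_rank_sum", statistic = unname(wt$statistic),
         p = wt$p.value)
  } else {
    kt <- stats::kruskal.test(values, groups)
    list(method = "kruskal_wallis", statistic = unname(kt$statistic),
         p = kt$p.value)
  }
}
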