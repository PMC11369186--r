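#' Aggregate read scores into a per-sample tumor-fraction score
#'
#' The sample score S is the estimated ratio of tumor-derived reads: the
#' fraction of scored reads whose classifier probability exceeds `tau`
#' (default), or the mean probability when `method = "mean"`. S is missing
#' when fewer than `min_reads_for_score` reads were scored.
#'
#' @param d Numeric vector of per-read probabilities in \[0,1\].
#' @param tau Read-level call threshold in (0,1).
#' @param min_reads_for_score Minimum scored reads for a defined S.
#' @param method `"fraction"` (#\{d > tau\}/n, the literal read ratio) or
#'   `"mean"` (mean d).
#' @return List: `S` (possibly `NA`), `n_reads_scored`, `tau`.
#' @export
sample_score <- function(d, tau = 0.5, min_reads_for_score = 30L,
                         method = c("fraction", "mean")) {
  method <- match.arg(method)
  if (!(tau > 0 && tau < 1)) param_error("tau must be in (0,1)")
  n <- length(d)
  S <- if (n < min_reads_for_score) NA_real_
       else if (method == "fraction") mean(d > tau)
       else mean(d)
  list(S = S, n_reads_scored = n, tau = tau)
}

#' Score a cohort of samples
#'
#' Runs [score_reads()] once over all reads and aggregates per sample with
#' [sample_score()]. Samples present in `sample_ids` but with no qualifying
#' reads get `S = NA` with zero reads scored.
#'
#' @param model A `read_model`.
#' @param reads A [methyl_reads()] table for all samples.
#' @param selected_regions Region set the model was trained on.
#' @param sample_ids Samples to report (default: all in `reads`).
#' @param min_cpgs,tau,min_reads_for_score,method See [sample_score()] and
#'   [score_reads()].
#' @return Data frame (sample_id, S, n_reads_scored).
#' @export
score_samples <- function(model, reads, selected_regions,
                          sample_ids = sort(unique(reads$sample_id)),
                          min_cpgs = 3L, tau = 0.5,
                          min_reads_for_score = 30L,
                          method = c("fraction", "mean")) {
  method <- match.arg(method)
  rs <- score_reads(model, reads, selected_regions, min_cpgs = min_cpgs)
  out <- lapply(sample_ids, function(s) {
    sc <- sample_score(rs$d[rs$sample_id == s], tau, min_reads_for_score,
                       method)
    data.frame(sample_id = s, S = sc$S, n_reads_scored = sc$n_reads_scored)
  })
  out <- do.call(rbind, out)
  attr(out, "read_scores") <- rs
  out
}

#' ROC curve, AUC, and Youden-index cutoff
#'
#' Thresholds are the sorted unique scores plus a low sentinel; a sample is
#' called positive when `score > threshold`. AUC is the trapezoid area,
#' which equals the Mann-Whitney statistic with ties counting 1/2. The
#' Youden cutoff maximizes J = sensitivity + specificity - 1; ties are
#' broken toward the lowest cutoff (maximizing sensitivity at equal J).
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels 0/1 (or logical) case labels.
#' @return List of class `roc_result`: thresholds, sensitivities,
#'   specificities, auc, youden_cutoff, J, confusion (tp/fp/tn/fn at the
#'   cutoff), accuracy.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2L)
    config_error("roc_curve needs both classes present")
  if (any(!is.finite(scores))) param_error("scores must be finite")
  thr <- c(min(scores) - 1, sort(unique(scores)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  sens <- vapply(thr, function(t) sum(scores > t & labels == 1L) / n1, 0)
  spec <- vapply(thr, function(t) sum(scores <= t & labels == 0L) / n0, 0)
  # trapezoid over (FPR, TPR); thresholds ascending -> FPR descending
  fpr <- 1 - spec
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (sens[-length(sens)] + sens[-1]) / 2)
  J <- sens + spec - 1
  # mathematically equal J can differ by float noise; treat as tied and
  # take the lowest cutoff (maximizes sensitivity at equal J)
  best <- which(J >= max(J) - 1e-9)
  best <- best[which.min(thr[best])]
  cut <- thr[best]
  pred <- scores > cut
  confusion <- c(tp = sum(pred & labels == 1L),
                 fp = sum(pred & labels == 0L),
                 tn = sum(!pred & labels == 0L),
                 fn = sum(!pred & labels == 1L))
  structure(list(
    thresholds = thr, sensitivities = sens, specificities = spec,
    auc = auc, youden_cutoff = cut, J = max(J), confusion = confusion,
    accuracy = (confusion["tp"] + confusion["tn"]) / length(scores),
    n_case = n1, n_control = n0
  ), class = "roc_result")
}

# sens/spec/accuracy of scores vs labels at a fixed (frozen) cutoff
classify_at <- function(scores, labels, cutoff) {
  labels <- as.integer(labels)
  pred <- scores > cutoff
  c(sensitivity = sum(pred & labels == 1L) / sum(labels == 1L),
    specificity = sum(!pred & labels == 0L) / sum(labels == 0L),
    accuracy = mean(pred == (labels == 1L)))
}

#' Evaluate sample scores across cohorts with a frozen training cutoff
#'
#' Computes the ROC per cohort; the Youden cutoff is chosen on the training
#' cohort and frozen, so validation sensitivity/specificity/accuracy are
#' leakage-free. AUC is computed per cohort independently. Samples with
#' missing S are excluded and listed.
#'
#' @param score_table Data frame (sample_id, S) covering all cohorts.
#' @param manifest Manifest with a label source column.
#' @param cohorts Named list: cohort name -> character vector of
#'   sample_ids; must include `"training"`.
#' @param case_groups Group (or grade) values treated as label 1.
#' @return List of class `cohort_eval`: per-cohort `roc` (training) /
#'   frozen-cutoff metrics, `cutoff`, `samples` table, `excluded`.
#' @export
evaluate_holdout <- function(score_table, manifest, cohorts, case_groups) {
  if (!"training" %in% names(cohorts))
    config_error("cohorts must include a 'training' cohort")
  lab_col <- if ("group" %in% names(manifest) &&
                 any(case_groups %in% manifest$group)) "group" else "grade"
  labels_all <- setNames(as.integer(manifest[[lab_col]] %in% case_groups),
                         manifest$sample_id)
  tab <- score_table
  tab$label <- labels_all[tab$sample_id]
  excluded <- tab$sample_id[is.na(tab$S)]
  res <- list()
  cutoff <- NULL
  for (nm in names(cohorts)) {
    sub <- tab[tab$sample_id %in% cohorts[[nm]] & !is.na(tab$S), ]
    if (length(unique(sub$label)) < 2L)
      config_error("cohort '%s' lacks class %s", nm,
                   setdiff(c(0, 1), unique(sub$label))[1])
    roc <- roc_curve(sub$S, sub$label)
    if (nm == "training") cutoff <- roc$youden_cutoff
    res[[nm]] <- list(roc = roc, n = nrow(sub))
  }
  for (nm in names(cohorts)) {
    sub <- tab[tab$sample_id %in% cohorts[[nm]] & !is.na(tab$S), ]
    res[[nm]]$at_training_cutoff <- classify_at(sub$S, sub$label, cutoff)
    sub$predicted <- as.integer(sub$S > cutoff)
    sub$cohort <- nm
    res[[nm]]$samples <- sub
  }
  structure(list(cohorts = res, cutoff = cutoff,
                 samples = do.call(rbind, lapply(res, `[[`, "samples")),
                 excluded = excluded), class = "cohort_eval")
}

#' Compare numeric biomarker columns by ROC
#'
#' One [roc_curve()] per column on the row-complete intersection of
#' samples. Inverse-direction biomarkers (lower value = more case-like,
#' e.g. a free-to-total ratio) are negated before the ROC so AUC stays
#' above 0.5 for an informative marker.
#'
#' @param manifest Manifest containing the biomarker columns.
#' @param columns Character vector of numeric column names.
#' @param labels 0/1 labels aligned with `manifest` rows.
#' @param directions Named vector over `columns`, `"higher"` (default) or
#'   `"lower"` = case-like direction.
#' @return Named list of `roc_result`.
#' @export
compare_biomarkers <- function(manifest, columns, labels,
                               directions = NULL) {
  for (col in columns) {
    if (!col %in% names(manifest))
      config_error("column '%s' not in manifest", col)
    if (!is.numeric(manifest[[col]]))
      config_error("column '%s' is not numeric", col)
  }
  complete <- complete.cases(manifest[, columns, drop = FALSE]) &
    !is.na(labels)
  out <- list()
  for (col in columns) {
    v <- manifest[[col]][complete]
    if (!is.null(directions) && identical(directions[[col]], "lower"))
      v <- -v
    out[[col]] <- roc_curve(v, labels[complete])
  }
  out
}

#' Sweep the marker-count threshold
#'
#' Re-runs the training/scoring pipeline at each candidate number of
#' selected regions and records accuracy and AUC, reproducing the
#' marker-count-vs-accuracy analysis. The heavy lifting is delegated to
#' `fit_fun(n, seed)`, which must return `list(accuracy =, auc =)`;
#' [run_pipeline()] supplies a suitable closure. Duplicate grid values are
#' computed once; values exceeding the available calls are evaluated at
#' the available count with a warning.
#'
#' @param n_grid Integer vector of candidate region counts.
#' @param n_available Number of selectable regions.
#' @param fit_fun Function `(n, seed) -> list(accuracy, auc)`.
#' @param seed Master seed; each grid point derives its own seed.
#' @return Data frame (n, n_used, accuracy, auc).
#' @export
threshold_sweep <- function(n_grid, n_available, fit_fun, seed = 1L) {
  if (any(n_grid < 1L)) param_error("grid values must be >= 1")
  n_grid <- sort(unique(as.integer(n_grid)))
  out <- lapply(n_grid, function(n) {
    n_used <- n
    if (n > n_available) {
      warning(sprintf("n = %d exceeds %d available calls; using %d",
                      n, n_available, n_available))
      n_used <- as.integer(n_available)
    }
    fit <- fit_fun(n_used, derive_seed(seed, paste0("sweep", n)))
    data.frame(n = n, n_used = n_used, accuracy = fit$accuracy,
               auc = fit$auc)
  })
  do.call(rbind, out)
}

#' Downsampling robustness of sample scores
#'
#' Subsamples each sample's scored reads without replacement at each
#' fraction, recomputes S, and reports the Pearson correlation between
#' every pair of fractions across samples (pairwise-complete). Because the
#' classifier scores each read deterministically, subsampling read scores
#' is identical to subsampling reads and rescoring.
#'
#' @param sample_read_scores Named list: sample_id -> numeric vector of
#'   per-read probabilities at full depth.
#' @param fractions Depth fractions in (0, 1\].
#' @param tau,min_reads_for_score,method See [sample_score()].
#' @param seed Seed for the subsampling.
#' @return List: `scores` (samples x fractions matrix of S, NA where below
#'   the read floor) and `correlations` (fractions x fractions Pearson
#'   matrix).
#' @export
downsample_robustness <- function(sample_read_scores, fractions,
                                  tau = 0.5, min_reads_for_score = 30L,
                                  method = "fraction", seed = 1L) {
  if (any(fractions <= 0 | fractions > 1))
    param_error("fractions must be in (0, 1]")
  fr_names <- as.character(fractions)
  S <- matrix(NA_real_, length(sample_read_scores), length(fractions),
              dimnames = list(names(sample_read_scores), fr_names))
  for (i in seq_along(sample_read_scores)) {
    d <- sample_read_scores[[i]]
    for (j in seq_along(fractions)) {
      set.seed(derive_seed(seed, paste0("ds", i, "f", j)))
      k <- floor(fractions[j] * length(d))
      dk <- if (fractions[j] == 1) d else sample(d, k)
      S[i, j] <- sample_score(dk, tau, min_reads_for_score, method)$S
    }
  }
  corr <- suppressWarnings(cor(S, use = "pairwise.complete.obs",
                               method = "pearson"))
  list(scores = S, correlations = corr)
}
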