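#' Per-read methylation level (alpha value)
#'
#' The alpha value of a read is the fraction of its covered CpGs that are
#' methylated. Reads with fewer than `min_cpgs` CpGs carry too little
#' pattern information and are excluded (not zero-filled).
#'
#' @param reads A [methyl_reads()] table.
#' @param min_cpgs Minimum CpGs a read must cover to be scored (default 3).
#' @return Data frame (read = row index into `reads`, alpha, n_cpgs);
#'   excluded reads are absent.
#' @export
compute_alpha <- function(reads, min_cpgs = 3L) {
  n_cpgs <- lengths(reads$cpg_states)
  keep <- which(n_cpgs >= min_cpgs)
  data.frame(
    read = keep,
    alpha = vapply(reads$cpg_states[keep], mean, 0),
    n_cpgs = n_cpgs[keep]
  )
}

#' Region summary statistics per sample
#'
#' For every (region, sample) pair computes the three statistics the DMR
#' calls are based on: `M`, the CpG-weighted mean methylation (total
#' methylated calls / total CpG calls over the region's reads); `P_hypo`,
#' the proportion of alpha-scored reads with alpha <= `alpha_lo`; and
#' `P_hyper`, the proportion with alpha >= `alpha_hi`. Pairs with fewer
#' than `min_reads` alpha-scored reads are flagged missing.
#'
#' @param reads A [methyl_reads()] table covering all samples.
#' @param regions Region data.frame (chrom, start, end, id).
#' @param alpha_lo,alpha_hi Read-level hypo/hyper cutoffs (defaults 0.2,
#'   0.8; must satisfy `0 <= alpha_lo < alpha_hi <= 1`).
#' @param min_cpgs Minimum CpGs per read (see [compute_alpha()]).
#' @param min_reads Minimum alpha-scored reads per (region, sample) before
#'   statistics are reported (default 5).
#' @param assignment Optional precomputed [assign_reads_to_regions()]
#'   result.
#' @return Long data.frame: region_id, sample_id, n_reads, M, P_hypo,
#'   P_hyper, missing. Statistics are `NA` where missing.
#' @export
region_statistics <- function(reads, regions, alpha_lo = 0.2,
                              alpha_hi = 0.8, min_cpgs = 3L,
                              min_reads = 5L, assignment = NULL) {
  if (!(alpha_lo >= 0 && alpha_lo < alpha_hi && alpha_hi <= 1))
    param_error("need 0 <= alpha_lo < alpha_hi <= 1")
  if (is.null(assignment))
    assignment <- assign_reads_to_regions(reads, regions)
  samples <- sort(unique(reads$sample_id))
  alpha_all <- rep(NA_real_, nrow(reads))
  a <- compute_alpha(reads, min_cpgs)
  alpha_all[a$read] <- a$alpha
  n_meth <- vapply(reads$cpg_states, sum, 0L)
  n_call <- lengths(reads$cpg_states)
  sample_f <- factor(reads$sample_id, levels = samples)

  n_r <- length(assignment)
  n_s <- length(samples)
  blank <- rep(NA_real_, n_r * n_s)
  res <- data.frame(
    region_id = rep(names(assignment), each = max(n_s, 1L)),
    sample_id = rep(samples, n_r),
    n_reads = rep(0L, n_r * n_s),
    M = blank, P_hypo = blank, P_hyper = blank,
    missing = rep(TRUE, n_r * n_s)
  )
  for (r in seq_len(n_r)) {
    idx <- assignment[[r]]
    idx <- idx[!is.na(alpha_all[idx])]
    if (length(idx) == 0L) next
    by_sample <- split(idx, sample_f[idx])
    for (s in seq_len(n_s)) {
      ri <- by_sample[[s]]
      n <- length(ri)
      if (n == 0L) next
      row <- (r - 1L) * n_s + s
      res$n_reads[row] <- n
      if (n < min_reads) next
      al <- alpha_all[ri]
      res$M[row] <- sum(n_meth[ri]) / sum(n_call[ri])
      res$P_hypo[row] <- mean(al <= alpha_lo)
      res$P_hyper[row] <- mean(al >= alpha_hi)
      res$missing[row] <- FALSE
    }
  }
  res
}

#' Pivot region statistics to a samples-by-regions matrix
#'
#' @param stats Output of [region_statistics()].
#' @param statistic `"M"`, `"P_hypo"` or `"P_hyper"`.
#' @return Numeric matrix, rows = samples, columns = regions.
#' @export
stats_matrix <- function(stats, statistic = c("P_hypo", "P_hyper", "M")) {
  statistic <- match.arg(statistic)
  samples <- sort(unique(stats$sample_id))
  regions <- unique(stats$region_id)
  m <- matrix(NA_real_, length(samples), length(regions),
              dimnames = list(samples, regions))
  m[cbind(match(stats$sample_id, samples),
          match(stats$region_id, regions))] <- stats[[statistic]]
  m
}

#' Call differentially methylated regions
#'
#' Per region, a two-sided Wilcoxon rank-sum test compares the chosen
#' statistic across case vs control samples; p-values are BH-corrected
#' across tested regions. A region is called when `q <= q_threshold` and
#' `|delta| >= min_abs_delta`, where `delta = mean(case) - mean(control)`.
#' Calling on `M` yields mDMRs (mean-methylation level); calling on
#' `P_hypo`/`P_hyper` yields pDMRs (read-proportion level, the
#' single-read-resolution feature). Samples with a missing statistic are
#' dropped from that region's test only.
#'
#' Direction describes the aberration in the case group: for `P_hypo`,
#' positive delta means case-enriched hypomethylated reads (direction
#' `hypo`); for `P_hyper` positive delta maps to `hyper`; for `M` positive
#' delta maps to `hyper`.
#'
#' @param stats Output of [region_statistics()].
#' @param manifest Manifest data.frame (sample_id, group and/or grade).
#' @param case_group,control_group Group labels to contrast. Values are
#'   matched against `group`, or against `grade` if not found there.
#' @param statistic `"M"` (mDMR) or `"P_hypo"`/`"P_hyper"` (pDMR).
#' @param min_abs_delta Effect-size gate (default 0.2).
#' @param q_threshold BH-adjusted significance gate (default 0.05).
#' @return Data frame with one row per testable region: region_id, kind,
#'   direction, delta, p_value, q_value, called.
#' @export
call_dmrs <- function(stats, manifest, case_group, control_group,
                      statistic = c("P_hypo", "P_hyper", "M"),
                      min_abs_delta = 0.2, q_threshold = 0.05) {
  statistic <- match.arg(statistic)
  case_ids <- samples_in_group(manifest, case_group)
  control_ids <- samples_in_group(manifest, control_group)
  vals <- stats[[statistic]]
  regions <- unique(stats$region_id)
  res <- lapply(regions, function(r) {
    sel <- stats$region_id == r & !is.na(vals)
    x <- vals[sel & stats$sample_id %in% case_ids]
    y <- vals[sel & stats$sample_id %in% control_ids]
    if (length(x) < 2L || length(y) < 2L)
      return(data.frame(region_id = r, delta = NA_real_,
                        p_value = NA_real_))
    p <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))$p.value
    data.frame(region_id = r, delta = mean(x) - mean(y), p_value = p)
  })
  res <- do.call(rbind, res)
  res$q_value <- NA_real_
  tested <- !is.na(res$p_value)
  res$q_value[tested] <- p.adjust(res$p_value[tested], method = "BH")
  res$kind <- if (statistic == "M") "mDMR" else "pDMR"
  res$statistic <- statistic
  pos_dir <- switch(statistic, P_hypo = "hypo", P_hyper = "hyper",
                    M = "hyper")
  neg_dir <- if (pos_dir == "hypo") "hyper" else "hypo"
  res$direction <- ifelse(is.na(res$delta), NA_character_,
                          ifelse(res$delta >= 0, pos_dir, neg_dir))
  res$called <- tested & res$q_value <= q_threshold &
    abs(res$delta) >= min_abs_delta
  rownames(res) <- NULL
  res[, c("region_id", "kind", "statistic", "direction", "delta",
          "p_value", "q_value", "called")]
}

samples_in_group <- function(manifest, group) {
  ids <- character(0)
  if ("group" %in% names(manifest))
    ids <- manifest$sample_id[manifest$group == group]
  if (length(ids) == 0L && "grade" %in% names(manifest))
    ids <- manifest$sample_id[manifest$grade == group]
  if (length(ids) == 0L)
    config_error("group '%s' not present in manifest", group)
  ids
}

#' Filter DMR calls for cancer specificity
#'
#' A region is *specific* iff it is called with the same direction in both
#' contrasts (case vs normal tissue AND case vs noncancer urine). Its delta
#' is recorded as the minimum-magnitude of the two (conservative).
#'
#' @param calls_vs_normal,calls_vs_noncancer [call_dmrs()] outputs computed
#'   on the same region universe.
#' @return The `calls_vs_normal` frame with columns `specific` and `delta`
#'   (min-magnitude) updated; q_value is the max of the two contrasts.
#' @export
filter_specific <- function(calls_vs_normal, calls_vs_noncancer) {
  if (!identical(sort(calls_vs_normal$region_id),
                 sort(calls_vs_noncancer$region_id)))
    param_error("the two call sets cover different region universes")
  b <- calls_vs_noncancer[match(calls_vs_normal$region_id,
                                calls_vs_noncancer$region_id), ]
  out <- calls_vs_normal
  out$specific <- out$called & b$called &
    !is.na(out$direction) & !is.na(b$direction) &
    out$direction == b$direction
  pick_b <- out$specific & abs(b$delta) < abs(out$delta)
  out$delta[pick_b] <- b$delta[pick_b]
  out$q_value <- pmax(out$q_value, b$q_value)
  out
}

#' Select the top-N DMRs by differential methylation value
#'
#' Filters calls to the requested direction and `specific == TRUE`, sorts by
#' `|delta|` descending with ties broken by (q ascending, chrom, start), and
#' returns the first `min(n, available)` regions. Warns when fewer than `n`
#' are available.
#'
#' @param calls Output of [filter_specific()] (needs a `specific` column;
#'   a plain [call_dmrs()] output is accepted and filtered on `called`).
#' @param regions Region data.frame (for coordinates in the tie-break).
#' @param direction `"hypo"` or `"hyper"`.
#' @param n Number of regions to keep.
#' @return Ordered region data.frame subset with a `delta` column.
#' @export
select_top_n <- function(calls, regions, direction = c("hypo", "hyper"),
                         n = 2000L) {
  direction <- match.arg(direction)
  if (!is_count(n) || n < 1L) param_error("n must be >= 1")
  pass <- if ("specific" %in% names(calls)) calls$specific else calls$called
  sub <- calls[pass & !is.na(calls$direction) &
                 calls$direction == direction, , drop = FALSE]
  coords <- regions[match(sub$region_id, regions$id), c("chrom", "start")]
  ord <- order(-abs(sub$delta), sub$q_value, coords$chrom, coords$start)
  sub <- sub[ord, , drop = FALSE]
  if (nrow(sub) < n)
    warning(sprintf("requested %d %s regions, only %d available",
                    n, direction, nrow(sub)))
  sub <- head(sub, n)
  out <- regions[match(sub$region_id, regions$id), , drop = FALSE]
  out$delta <- sub$delta
  out$direction <- direction
  rownames(out) <- NULL
  out
}

#' Per-region AUC of a statistic as a case/control classifier
#'
#' For each region, ranks case vs control samples by the statistic and
#' reports the Mann-Whitney AUC (ties count 1/2). Regions where either
#' group has zero non-missing samples get `NA`.
#'
#' @inheritParams call_dmrs
#' @return Data frame (region_id, auc, n_case, n_control).
#' @export
region_auc <- function(stats, manifest, case_group, control_group,
                       statistic = c("P_hypo", "P_hyper", "M")) {
  statistic <- match.arg(statistic)
  case_ids <- samples_in_group(manifest, case_group)
  control_ids <- samples_in_group(manifest, control_group)
  vals <- stats[[statistic]]
  regions <- unique(stats$region_id)
  res <- lapply(regions, function(r) {
    sel <- stats$region_id == r & !is.na(vals)
    x <- vals[sel & stats$sample_id %in% case_ids]
    y <- vals[sel & stats$sample_id %in% control_ids]
    auc <- if (length(x) == 0L || length(y) == 0L) NA_real_
           else mw_auc(x, y)
    data.frame(region_id = r, auc = auc,
               n_case = length(x), n_control = length(y))
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}

# Mann-Whitney AUC via midranks; ties contribute 1/2.
mw_auc <- function(case, control) {
  r <- rank(c(case, control))
  n1 <- length(case)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(control))
}

#' Hierarchically cluster samples on top differential regions
#'
#' Restricts the per-sample statistic matrix to the `top_fraction` of
#' regions by `|delta|`, imputes missing entries with the region mean, and
#' runs agglomerative clustering (Euclidean distance, Ward linkage). The
#' flat labels are the k = 2 cut.
#'
#' @param stat_mat Samples-by-regions matrix (see [stats_matrix()]).
#' @param calls [call_dmrs()] output giving each region's delta.
#' @param top_fraction Fraction of regions (by `|delta|`) to keep.
#' @return List: `hclust` (the tree), `labels` (named k = 2 memberships),
#'   `regions_used`.
#' @export
cluster_samples <- function(stat_mat, calls, top_fraction = 0.1) {
  if (nrow(stat_mat) < 2L) param_error("need at least 2 samples to cluster")
  # canonical sample order: ties in the distance matrix would otherwise
  # make the agglomeration depend on input row order
  stat_mat <- stat_mat[order(rownames(stat_mat)), , drop = FALSE]
  deltas <- calls$delta[match(colnames(stat_mat), calls$region_id)]
  keep_n <- max(1L, ceiling(top_fraction * sum(!is.na(deltas))))
  ord <- order(-abs(deltas))
  use <- ord[seq_len(min(keep_n, sum(!is.na(deltas))))]
  m <- stat_mat[, use, drop = FALSE]
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- mean(m[, j], na.rm = TRUE)
    if (anyNA(m[, j])) m[, j] <- 0
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "ward.D2")
  list(hclust = hc, labels = cutree(hc, k = 2L),
       regions_used = colnames(stat_mat)[use])
}

#' Write DMR calls as BED6+
#'
#' Columns: chrom, start, end, id, score (|delta| scaled to 0-1000),
#' strand ".", then kind, direction, delta, p, q, specific.
#'
#' @param calls [filter_specific()] (or [call_dmrs()]) output.
#' @param regions Region data.frame for coordinates.
#' @param path File path.
#' @export
write_dmr_bed <- function(calls, regions, path) {
  coords <- regions[match(calls$region_id, regions$id), ]
  out <- data.frame(
    chrom = coords$chrom, start = coords$start, end = coords$end,
    id = calls$region_id,
    score = ifelse(is.na(calls$delta), 0,
                   round(pmin(1, abs(calls$delta)) * 1000)),
    strand = ".",
    kind = calls$kind, direction = calls$direction, delta = calls$delta,
    p = calls$p_value, q = calls$q_value,
    specific = if ("specific" %in% names(calls)) calls$specific
               else calls$called
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
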