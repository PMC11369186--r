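# Shared fixtures and independent oracles, all built in code.

# A tiny hand-written read table with known alphas.
tiny_reads <- function() {
  methyl_reads(
    sample_id = c("s1", "s1", "s2"),
    chrom = "chr1",
    start = c(10L, 40L, 12L),
    strand = "+",
    sequence = c("ACGTTCGA", "TTCGACGT", "AACGTCGG"),
    cpg_offsets = list(c(1L, 5L), c(2L, 5L), c(2L, 5L)),
    cpg_states = list(c(1L, 0L), c(0L, 0L), c(1L, 1L)),
    origin_label = c("tumor", "normal", "unknown")
  )
}

# Independent oracle: per-read alpha by direct counting.
oracle_alpha <- function(reads, min_cpgs) {
  out <- data.frame(read = integer(0), alpha = numeric(0),
                    n_cpgs = integer(0))
  for (i in seq_len(nrow(reads))) {
    st <- reads$cpg_states[[i]]
    if (length(st) < min_cpgs) next
    out <- rbind(out, data.frame(read = i, alpha = sum(st) / length(st),
                                 n_cpgs = length(st)))
  }
  out
}

# Independent oracle: per-read interval scan assignment.
oracle_assign <- function(reads, regions) {
  out <- setNames(vector("list", nrow(regions)), regions$id)
  for (r in seq_len(nrow(regions))) {
    hits <- integer(0)
    for (i in seq_len(nrow(reads))) {
      pos <- reads$start[i] + reads$cpg_offsets[[i]]
      if (reads$chrom[i] == regions$chrom[r] &&
          any(pos >= regions$start[r] & pos < regions$end[r]))
        hits <- c(hits, i)
    }
    out[[r]] <- hits
  }
  out
}

# Independent oracle: region statistics by brute-force recount.
oracle_region_stats <- function(reads, regions, alpha_lo, alpha_hi,
                                min_cpgs, min_reads) {
  asg <- oracle_assign(reads, regions)
  samples <- sort(unique(reads$sample_id))
  rows <- list()
  for (r in names(asg)) {
    for (s in samples) {
      idx <- asg[[r]][reads$sample_id[asg[[r]]] == s]
      alphas <- c()
      meth <- 0; tot <- 0
      used <- c()
      for (i in idx) {
        st <- reads$cpg_states[[i]]
        if (length(st) < min_cpgs) next
        alphas <- c(alphas, mean(st))
        meth <- meth + sum(st); tot <- tot + length(st)
        used <- c(used, i)
      }
      n <- length(alphas)
      rows[[length(rows) + 1L]] <- if (n < min_reads)
        data.frame(region_id = r, sample_id = s, n_reads = n, M = NA_real_,
                   P_hypo = NA_real_, P_hyper = NA_real_, missing = TRUE)
      else
        data.frame(region_id = r, sample_id = s, n_reads = n,
                   M = meth / tot, P_hypo = mean(alphas <= alpha_lo),
                   P_hyper = mean(alphas >= alpha_hi), missing = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Independent oracle: AUC by exhaustive pair counting (ties = 1/2).
oracle_auc <- function(case, control) {
  tot <- 0
  for (x in case) for (y in control)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(case) * length(control))
}

# Independent oracle: Youden cutoff by brute-force threshold enumeration.
oracle_youden <- function(scores, labels) {
  thr <- c(min(scores) - 1, sort(unique(scores)))
  best_j <- -Inf; best_t <- NA
  for (t in thr) {
    sens <- sum(scores > t & labels == 1) / sum(labels == 1)
    spec <- sum(scores <= t & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  list(cutoff = best_t, J = best_j)
}

# Small planted-truth dataset: reads for two groups over regions where the
# first `n_planted` regions differ (tumor hypo) and the rest are null.
planted_dataset <- function(n_regions = 40, n_planted = 8,
                            n_per_group = 6, depth_X = 6, seed = 42,
                            p_tumor = 0.1, p_normal = 0.9) {
  cfg <- sim_config(n_regions = n_regions, p_meth_tumor = p_tumor,
                    p_meth_normal = p_normal,
                    frac_planted = n_planted / n_regions,
                    depth_X = depth_X, seed = seed)
  simulate_cohort(cfg, n_tumor_tissue = n_per_group,
                  n_normal_tissue = n_per_group,
                  n_pca_urine = 0, n_noncancer_urine = n_per_group,
                  sample_prefix = "fix")
}

# A quick trained model on strongly separable reads, shared across tests.
trained_toy <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_regions = 6, seed = 99, p_meth_tumor = 0.05,
                      p_meth_normal = 0.95, frac_planted = 1)
    ref <- simulate_reference(cfg)
    reads_t <- rbind_reads_public(lapply(seq_len(6), function(i)
      simulate_reads(ref$regions[i, ], 300, "tumor", seed = 100 + i,
                     sample_id = "t")))
    reads_n <- rbind_reads_public(lapply(seq_len(6), function(i)
      simulate_reads(ref$regions[i, ], 300, "normal", seed = 200 + i,
                     sample_id = "n")))
    keep_t <- lengths(reads_t$cpg_states) >= 3
    keep_n <- lengths(reads_n$cpg_states) >= 3
    x <- rbind(encode_reads_matrix_public(reads_t[keep_t, ], 66),
               encode_reads_matrix_public(reads_n[keep_n, ], 66))
    y <- c(rep(1L, sum(keep_t)), rep(0L, sum(keep_n)))
    spec <- model_spec(epochs = 8L, seed = 7L)
    model <- train_read_classifier(x, y, spec)
    cache <<- list(model = model, regions = ref$regions, cfg = cfg,
                   x = x, y = y)
    cache
  }
})

# internal helpers reached through the namespace (not exported API)
rbind_reads_public <- function(lst) readmeld:::rbind_reads(lst)
encode_reads_matrix_public <- function(reads, L)
  readmeld:::encode_reads_matrix(reads, L)
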