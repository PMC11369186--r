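test_that("alpha values are direct methylated-CpG fractions", {
  reads <- methyl_reads(
    "s1", "chr1", c(0L, 20L, 40L), "+",
    c("ACGACGACGACG", "ACGACGACG", "ACGACG"),
    list(c(1L, 4L, 7L, 10L), c(1L, 4L, 7L), c(1L, 4L)),
    list(c(1L, 0L, 1L, 1L), c(0L, 0L, 0L), c(1L, 1L))
  )
  a <- compute_alpha(reads, min_cpgs = 3)
  expect_identical(a$read, c(1L, 2L))        # 2-CpG read excluded
  expect_equal(a$alpha, c(0.75, 0))
  expect_identical(nrow(compute_alpha(reads, min_cpgs = 5)), 0L)
})

test_that("region statistics match the brute-force oracle on simulated data", {
  cfg <- sim_config(n_regions = 50, seed = 23)
  regions <- simulate_reference(cfg)$regions
  reads <- rbind_reads_public(lapply(1:4, function(k)
    simulate_urine_sample(regions, 0.4, 10, cfg, seed = 30 + k,
                          sample_id = paste0("s", k))$reads))
  expect_gte(nrow(reads), 5000)
  got <- region_statistics(reads, regions, alpha_lo = 0.2, alpha_hi = 0.8,
                           min_cpgs = 3, min_reads = 5)
  want <- oracle_region_stats(reads, regions, 0.2, 0.8, 3, 5)
  got <- got[order(got$region_id, got$sample_id), ]
  want <- want[order(want$region_id, want$sample_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("region statistics handle small and empty read sets", {
  regions <- data.frame(chrom = "chr1", start = 0L, end = 100L, id = "A")
  reads <- methyl_reads(
    rep("s1", 10), "chr1", seq(0L, 45L, by = 5L), "+",
    rep("ACGACGACG", 10),
    rep(list(c(1L, 4L, 7L)), 10),
    c(rep(list(c(0L, 0L, 0L)), 3), rep(list(c(1L, 1L, 1L)), 7))
  )
  st <- region_statistics(reads, regions, alpha_lo = 0.2, alpha_hi = 0.8,
                          min_cpgs = 3, min_reads = 5)
  expect_equal(st$P_hypo, 0.3)
  expect_equal(st$P_hyper, 0.7)
  expect_equal(st$M, 0.7)
  # all statistics missing below the read floor
  st2 <- region_statistics(reads[1:3, ], regions, min_reads = 5)
  expect_true(st2$missing)
  expect_true(is.na(st2$M) && is.na(st2$P_hypo))
  expect_error(region_statistics(reads, regions, alpha_lo = 0.9,
                                 alpha_hi = 0.8), "alpha_lo")
})

test_that("P_hypo is non-decreasing in alpha_lo", {
  cfg <- sim_config(n_regions = 10, seed = 41, concordance_kappa = 1)
  regions <- simulate_reference(cfg)$regions
  reads <- simulate_urine_sample(regions, 0.5, 10, cfg, seed = 42,
                                 sample_id = "s1")$reads
  cuts <- c(0.1, 0.2, 0.4, 0.6)
  mats <- lapply(cuts, function(lo)
    region_statistics(reads, regions, alpha_lo = lo, alpha_hi = 0.9)$P_hypo)
  for (k in seq_len(length(cuts) - 1)) {
    ok <- !is.na(mats[[k]]) & !is.na(mats[[k + 1]])
    expect_true(all(mats[[k + 1]][ok] >= mats[[k]][ok]))
  }
})

test_that("DMR calling recovers planted regions and honours stated handling", {
  ds <- planted_dataset(n_regions = 40, n_planted = 8, n_per_group = 6,
                        seed = 51)
  stats <- region_statistics(ds$reads, ds$regions)
  calls <- call_dmrs(stats, ds$manifest, "tumor_tissue", "normal_tissue",
                     statistic = "P_hypo")
  planted_ids <- ds$regions$id[ds$regions$planted]
  called_ids <- calls$region_id[calls$called]
  expect_setequal(intersect(called_ids, planted_ids), planted_ids)
  expect_true(all(calls$direction[calls$called] == "hypo"))
  # null regions: at most BH-level leakage
  expect_lte(length(setdiff(called_ids, planted_ids)), 2)

  # identical statistic vectors in both groups -> p = 1, never called
  st0 <- data.frame(region_id = "r1",
                    sample_id = paste0("s", 1:8),
                    n_reads = 10,
                    M = 0.5, P_hypo = rep(c(0.1, 0.2, 0.3, 0.4), 2),
                    P_hyper = 0.1, missing = FALSE)
  man0 <- data.frame(sample_id = paste0("s", 1:8),
                     group = rep(c("tumor_tissue", "normal_tissue"),
                                 each = 4))
  calls0 <- call_dmrs(st0, man0, "tumor_tissue", "normal_tissue", "P_hypo")
  expect_equal(calls0$p_value, 1)
  expect_false(any(calls0$called))

  # a missing statistic drops that sample from that region's test only
  st1 <- rbind(st0, st0)
  st1$region_id <- rep(c("r1", "r2"), each = 8)
  st1$P_hypo[1] <- NA
  st1$missing[1] <- TRUE
  calls1 <- call_dmrs(st1, man0, "tumor_tissue", "normal_tissue", "P_hypo")
  expect_identical(nrow(calls1), 2L)
  expect_false(any(is.na(calls1$p_value)))

  expect_error(call_dmrs(st0, man0, "plasma", "normal_tissue", "P_hypo"),
               "not present")
})

test_that("specificity requires the same direction in both contrasts", {
  mk_calls <- function(called, direction, delta) {
    data.frame(region_id = c("A", "B", "C"), kind = "pDMR",
               statistic = "P_hypo", direction = direction, delta = delta,
               p_value = 0.001, q_value = c(0.01, 0.01, 0.01),
               called = called)
  }
  vs_tissue <- mk_calls(c(TRUE, TRUE, TRUE), c("hypo", "hypo", "hypo"),
                        c(0.5, 0.6, 0.7))
  vs_urine <- mk_calls(c(TRUE, FALSE, TRUE), c("hypo", "hypo", "hyper"),
                       c(0.3, 0.6, -0.7))
  sp <- filter_specific(vs_tissue, vs_urine)
  expect_identical(sp$specific, c(TRUE, FALSE, FALSE))
  # conservative delta: minimum magnitude of the two contrasts
  expect_equal(sp$delta[1], 0.3)

  expect_error(filter_specific(vs_tissue, vs_urine[1:2, ]), "universe")
})

test_that("planted specificity filtering keeps only doubly-aberrant regions", {
  # tumor hypo in 16 planted regions, but noncancer urine is also aberrant
  # in 8 of them -> only the other 8 remain specific
  cfg <- sim_config(n_regions = 32, frac_planted = 0.5, seed = 61)
  regions <- simulate_reference(cfg)$regions
  shared_aberrant <- regions$id[1:8]          # urine matches tumor here
  mk_group <- function(origin_fun, prefix, n = 6) {
    rbind_reads_public(lapply(seq_len(n), function(k) {
      rbind_reads_public(lapply(seq_len(nrow(regions)), function(i) {
        simulate_reads(regions[i, ], 20, origin_fun(regions$id[i]),
                       seed = derive_seed(61 + k, paste0(prefix, i)),
                       sample_id = paste0(prefix, k))
      }))
    }))
  }
  reads <- rbind_reads_public(list(
    mk_group(function(id) "tumor", "tum"),
    mk_group(function(id) "normal", "nrm"),
    mk_group(function(id) if (id %in% shared_aberrant) "tumor" else "normal",
             "urn")
  ))
  man <- data.frame(
    sample_id = c(paste0("tum", 1:6), paste0("nrm", 1:6), paste0("urn", 1:6)),
    group = rep(c("tumor_tissue", "normal_tissue", "noncancer_urine"),
                each = 6)
  )
  stats <- region_statistics(reads, regions)
  c1 <- call_dmrs(stats, man, "tumor_tissue", "normal_tissue", "P_hypo")
  c2 <- call_dmrs(stats, man, "tumor_tissue", "noncancer_urine", "P_hypo")
  sp <- filter_specific(c1, c2)
  expect_setequal(sp$region_id[sp$specific], regions$id[9:16])
})

test_that("top-N selection ranks by |delta| with documented tie-breaks", {
  regions <- data.frame(chrom = "chr1", start = c(100L, 300L, 500L, 700L, 900L),
                        end = c(200L, 400L, 600L, 800L, 1000L),
                        id = paste0("r", 1:5))
  calls <- data.frame(
    region_id = paste0("r", 1:5), kind = "pDMR", statistic = "P_hypo",
    direction = c("hypo", "hypo", "hypo", "hyper", "hypo"),
    delta = c(0.5, 0.8, 0.5, 0.9, 0.3),
    p_value = 0.001, q_value = c(0.04, 0.01, 0.02, 0.01, 0.01),
    called = TRUE, specific = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  top <- select_top_n(calls, regions, "hypo", 3)
  # r2 first (largest delta), then r3 before r1 (equal delta, lower q)
  expect_identical(top$id, c("r2", "r3", "r1"))
  expect_warning(select_top_n(calls, regions, "hypo", 2000), "only 3")
  top_all <- suppressWarnings(select_top_n(calls, regions, "hypo", 2000))
  expect_identical(nrow(top_all), 3L)
})

test_that("per-region AUC equals exhaustive pair counting", {
  man <- data.frame(sample_id = paste0("s", 1:12),
                    group = rep(c("tumor_tissue", "normal_tissue"), 6))
  set.seed(71)
  for (rep_i in 1:25) {
    n <- sample(4:12, 1)
    ids <- paste0("s", 1:n)
    vals <- round(runif(n), 2)  # rounding forces ties
    st <- data.frame(region_id = "rX", sample_id = ids, n_reads = 10,
                     M = vals, P_hypo = vals, P_hyper = vals,
                     missing = FALSE)
    sub_man <- man[man$sample_id %in% ids, ]
    if (length(unique(sub_man$group)) < 2) next
    got <- region_auc(st, sub_man, "tumor_tissue", "normal_tissue",
                      "P_hypo")$auc
    case <- vals[sub_man$group == "tumor_tissue"]
    ctrl <- vals[sub_man$group == "normal_tissue"]
    expect_equal(got, oracle_auc(case, ctrl))
  }
  # degenerate cases
  st <- data.frame(region_id = "r", sample_id = paste0("s", 1:4),
                   n_reads = 10, M = c(1, 1, 0, 0), P_hypo = c(1, 1, 0, 0),
                   P_hyper = 0, missing = FALSE)
  man4 <- data.frame(sample_id = paste0("s", 1:4),
                     group = rep(c("tumor_tissue", "normal_tissue"), each = 2))
  expect_equal(region_auc(st, man4, "tumor_tissue", "normal_tissue",
                          "P_hypo")$auc, 1)
  st$P_hypo <- 0.5
  expect_equal(region_auc(st, man4, "tumor_tissue", "normal_tissue",
                          "P_hypo")$auc, 0.5)
  st$P_hypo <- c(NA, NA, 0.5, 0.5)
  expect_true(is.na(region_auc(st, man4, "tumor_tissue", "normal_tissue",
                               "P_hypo")$auc))
})

test_that("sample clustering recovers planted groups and is order-stable", {
  ds <- planted_dataset(n_regions = 30, n_planted = 10, n_per_group = 8,
                        seed = 81)
  stats <- region_statistics(ds$reads, ds$regions)
  tissue_ids <- ds$manifest$sample_id[ds$manifest$group %in%
                                        c("tumor_tissue", "normal_tissue")]
  stats <- stats[stats$sample_id %in% tissue_ids, ]
  calls <- call_dmrs(stats, ds$manifest, "tumor_tissue", "normal_tissue",
                     "P_hypo")
  m <- stats_matrix(stats, "P_hypo")
  cl <- cluster_samples(m, calls, top_fraction = 0.3)
  truth <- ds$manifest$group[match(rownames(m), ds$manifest$sample_id)]
  tab <- table(cl$labels, truth)
  # a perfect 2-cluster recovery: each cluster is pure
  expect_equal(max(tab[1, ]) + max(tab[2, ]), length(truth))

  # permuting sample order leaves the tree topology unchanged
  perm <- sample(nrow(m))
  cl2 <- cluster_samples(m[perm, ], calls, top_fraction = 0.3)
  co1 <- as.matrix(stats::cophenetic(cl$hclust))
  co2 <- as.matrix(stats::cophenetic(cl2$hclust))
  expect_equal(co1, co2[rownames(co1), colnames(co1)])

  # two identical samples merge first at height 0
  m2 <- m
  m2[2, ] <- m2[1, ]
  cl3 <- cluster_samples(m2, calls, top_fraction = 0.3)
  expect_equal(cl3$hclust$height[1], 0)
  expect_setequal(abs(cl3$hclust$merge[1, ]), c(1, 2))
  expect_error(cluster_samples(m[1, , drop = FALSE], calls), "2 samples")
})

test_that("planted-group P_hypo separation grows with the methylation gap", {
  gaps <- list(c(0.4, 0.6), c(0.25, 0.75), c(0.1, 0.9))
  seps <- vapply(seq_along(gaps), function(k) {
    ds <- planted_dataset(n_regions = 12, n_planted = 12, n_per_group = 4,
                          seed = 90 + k, p_tumor = gaps[[k]][1],
                          p_normal = gaps[[k]][2])
    stats <- region_statistics(ds$reads, ds$regions)
    grp <- ds$manifest$group[match(stats$sample_id,
                                   ds$manifest$sample_id)]
    mean(stats$P_hypo[grp == "tumor_tissue"], na.rm = TRUE) -
      mean(stats$P_hypo[grp == "normal_tissue"], na.rm = TRUE)
  }, 0)
  expect_true(all(seps > 0))
  expect_true(all(diff(seps) > 0))
})
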