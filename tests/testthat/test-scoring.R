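test_that("sample scores are thresholded read fractions with a floor", {
  expect_equal(sample_score(rep(0.9, 40), tau = 0.5)$S, 1)
  expect_equal(sample_score(c(0.1, 0.9, 0.9, 0.1), tau = 0.5,
                            min_reads_for_score = 1)$S, 0.5)
  # below the read floor the score is missing, not zero
  low <- sample_score(rep(0.9, 10), tau = 0.5, min_reads_for_score = 30)
  expect_true(is.na(low$S))
  expect_identical(low$n_reads_scored, 10L)
  # mean-probability alternative
  expect_equal(sample_score(c(0.2, 0.4), min_reads_for_score = 1,
                            method = "mean")$S, 0.3)
  expect_error(sample_score(0.5, tau = 0), "tau")
})

test_that("oracle classifier recovers theta within binomial error", {
  # a perfect read classifier: d = 1 for tumor-origin reads, 0 otherwise
  cfg <- sim_config(n_regions = 20, reads_per_region_per_X = 10, seed = 91)
  regions <- simulate_reference(cfg)$regions
  for (theta in c(0, 0.05, 0.1, 0.3)) {
    u <- simulate_urine_sample(regions, theta, 100, cfg,
                               seed = 92 + round(100 * theta))
    d <- as.numeric(u$reads$origin_label == "tumor")
    n <- length(d)
    expect_identical(n, 20000L)
    S <- sample_score(d, tau = 0.5, min_reads_for_score = 1)$S
    expect_lte(abs(S - theta), 3 * sqrt(theta * (1 - theta) / n) + 1e-12)
  }
})

test_that("roc_curve matches hand results and the pair-counting oracle", {
  r <- roc_curve(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$J, 1)
  expect_gt(r$youden_cutoff, 0.2 - 1e-12)
  expect_lt(r$youden_cutoff, 0.8)
  expect_equal(unname(r$accuracy), 1)

  # scores carrying no information: all equal -> AUC 0.5
  expect_equal(roc_curve(rep(0.4, 8), rep(c(0, 1), 4))$auc, 0.5)

  expect_error(roc_curve(c(0.1, 0.2), c(1, 1)), "both classes")

  # sensitivities are non-increasing in the threshold
  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 1)
    r <- roc_curve(scores, labels)
    expect_true(all(diff(r$sensitivities) <= 1e-12))
    expect_equal(r$auc, oracle_auc(scores[labels == 1], scores[labels == 0]))
  }
})

test_that("Youden cutoffs match brute-force enumeration with low-tie-break", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 1)
    r <- roc_curve(scores, labels)
    want <- oracle_youden(scores, labels)
    expect_equal(r$J, want$J)
    # equal-J ties resolve to the lowest cutoff
    J_all <- r$sensitivities + r$specificities - 1
    expect_equal(r$youden_cutoff,
                 min(r$thresholds[abs(J_all - r$J) < 1e-12]))
  }
})

test_that("cross-checked against pROC on a shared instance", {
  skip_if_not_installed("pROC")
  set.seed(303)
  scores <- runif(40)
  labels <- rbinom(40, 1, plogis(4 * scores - 2))
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  ours <- roc_curve(scores, labels)
  theirs <- suppressMessages(pROC::roc(labels, scores, direction = "<"))
  expect_equal(ours$auc, as.numeric(pROC::auc(theirs)))
})

test_that("holdout evaluation freezes the training cutoff", {
  scores <- data.frame(
    sample_id = sprintf("s%02d", 1:20),
    S = c(0.8, 0.7, 0.9, 0.6, 0.75, 0.1, 0.2, 0.15, 0.05, 0.3,
          0.65, 0.65, 0.85, 0.55, 0.95, 0.25, 0.1, 0.4, 0.2, 0.35)
  )
  man <- data.frame(sample_id = scores$sample_id,
                    group = rep(rep(c("pca_urine", "noncancer_urine"),
                                    each = 5), 2))
  cohorts <- list(training = scores$sample_id[1:10],
                  validation = scores$sample_id[11:20])
  ev <- evaluate_holdout(scores, man, cohorts, "pca_urine")
  expect_equal(ev$cutoff, ev$cohorts$training$roc$youden_cutoff)
  # validation metrics computed at the training cutoff, not its own
  v <- scores$S[11:20]
  vl <- rep(c(1, 0), each = 5)
  expect_equal(unname(ev$cohorts$validation$at_training_cutoff["sensitivity"]),
               sum(v > ev$cutoff & vl == 1) / 5)
  expect_equal(unname(ev$cohorts$validation$at_training_cutoff["specificity"]),
               sum(v <= ev$cutoff & vl == 0) / 5)

  # identical validation and training sets give identical RocResults
  cohorts2 <- list(training = scores$sample_id[1:10],
                   validation = scores$sample_id[1:10])
  ev2 <- evaluate_holdout(scores, man, cohorts2, "pca_urine")
  expect_equal(ev2$cohorts$validation$roc, ev2$cohorts$training$roc)

  # a cohort with one class empty names the problem
  man_bad <- man
  man_bad$group[11:20] <- "noncancer_urine"
  expect_error(evaluate_holdout(scores, man_bad, cohorts, "pca_urine"),
               "lacks class")

  # missing scores are excluded and reported
  scores$S[3] <- NA
  ev3 <- evaluate_holdout(scores, man, cohorts, "pca_urine")
  expect_identical(ev3$excluded, "s03")
  expect_equal(ev3$cohorts$training$n, 9L)
})

test_that("biomarker comparison handles direction flags and validation", {
  man <- data.frame(sample_id = paste0("s", 1:12),
                    tPSA = c(8, 9, 7, 6, 10, 12, 2, 3, 1, 4, 2, 5),
                    pfPSA = -c(8, 9, 7, 6, 10, 12, 2, 3, 1, 4, 2, 5),
                    note = letters[1:12])
  labels <- rep(c(1, 0), each = 6)
  rocs <- compare_biomarkers(man, c("tPSA", "pfPSA"), labels,
                             directions = c(tPSA = "higher",
                                            pfPSA = "lower"))
  # inverse-direction column with the flag set gives the same AUC
  expect_equal(rocs$pfPSA$auc, rocs$tPSA$auc)
  # a column equal to the labels is a perfect classifier
  man$perfect <- labels
  expect_equal(compare_biomarkers(man, "perfect", labels)$perfect$auc, 1)
  expect_error(compare_biomarkers(man, "note", labels), "not numeric")
  expect_error(compare_biomarkers(man, "absent", labels), "not in manifest")
})

test_that("threshold sweep dedupes, warns, and derives per-point seeds", {
  calls_seen <- list()
  fit_fun <- function(n, seed) {
    calls_seen[[length(calls_seen) + 1]] <<- c(n = n, seed = seed)
    list(accuracy = 0.5 + 0.01 * n, auc = 0.9)
  }
  expect_warning(
    threshold_sweep(50, n_available = 20,
                    function(n, seed) list(accuracy = 1, auc = 1)),
    "exceeds")
  sw <- suppressWarnings(
    threshold_sweep(c(5, 10, 10, 50), n_available = 20, fit_fun, seed = 3))
  expect_identical(sw$n, c(5L, 10L, 50L))
  expect_identical(sw$n_used, c(5L, 10L, 20L))
  expect_identical(length(calls_seen), 3L)
  seeds <- vapply(calls_seen, function(x) x[["seed"]], 0)
  expect_identical(anyDuplicated(seeds), 0L)
  expect_error(threshold_sweep(c(0, 5), 10, fit_fun), ">= 1")
})

test_that("downsampling keeps scores consistent across depths", {
  set.seed(404)
  # 30 samples with known tumor-read fractions and plenty of reads
  thetas <- rep(c(0, 0.05, 0.1, 0.2, 0.3, 0.15), 5)
  rs <- lapply(seq_along(thetas), function(i)
    as.numeric(runif(5000) < thetas[i]))
  names(rs) <- paste0("s", seq_along(thetas))
  ds <- downsample_robustness(rs, fractions = c(0.1, 0.5, 1),
                              min_reads_for_score = 30, seed = 6)
  expect_identical(dim(ds$scores), c(30L, 3L))
  expect_equal(unname(ds$correlations["1", "1"]), 1)
  expect_gte(ds$correlations["0.1", "1"], 0.9)

  # a fraction leaving too few reads yields missing cells, not a crash
  tiny <- lapply(1:4, function(i) runif(50))
  names(tiny) <- paste0("t", 1:4)
  ds2 <- downsample_robustness(tiny, fractions = c(0.01, 1),
                               min_reads_for_score = 30, seed = 7)
  expect_true(all(is.na(ds2$scores[, "0.01"])))
  expect_error(downsample_robustness(rs, fractions = c(0, 0.5)),
               "fractions")
})
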