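make_fastq <- function(path, reads) {
  writeLines(as.vector(rbind(paste0("@r", seq_along(reads)), reads, "+",
                             strrep("I", nchar(reads)))), path)
}

demo_design <- function() {
  barcodes <- c(AAAACCCCGGGG = "rep1_ind", TTTTGGGGCCCC = "rep2_ind")
  list(barcodes = barcodes,
       sample_condition = c(rep1_ind = "induced", rep2_ind = "induced"),
       sample_replicate = c(rep1_ind = 1L, rep2_ind = 2L),
       guide_flank5 = "ACGT")
}

test_that("demultiplex counts exact matches and discards the rest", {
  design <- demo_design()
  guides <- c(gA = "AAAAAAAAAAAAAAAAAAAA", gB = "CCCCCCCCCCCCCCCCCCCC")
  mk <- function(bc, gd) paste0("NNNN", bc, "ACGT", gd, "TTTTT")
  reads <- c(rep(mk("AAAACCCCGGGG", guides[1]), 25),
             rep(mk("AAAACCCCGGGG", guides[2]), 25),
             rep(mk("TTTTGGGGCCCC", guides[1]), 25),
             rep(mk("TTTTGGGGCCCC", guides[2]), 25))
  reads <- gsub("N", "G", reads)
  cm <- demultiplex(reads, design, guides)
  expect_true(all(cm$counts == 25))
  expect_equal(attr(cm, "discarded"), 0L)
  # single-nucleotide barcode error -> discarded
  bad <- gsub("N", "G", mk("AAAACCCCGGGT", guides[1]))
  cm2 <- demultiplex(c(reads, bad), design, guides)
  expect_equal(attr(cm2, "discarded"), 1L)
  expect_equal(cm2$counts, cm$counts)
  # order invariance
  cm3 <- demultiplex(rev(reads), design, guides)
  expect_equal(cm3$counts, cm$counts)
  # FASTQ file input path
  f <- withr::local_tempfile(fileext = ".fastq")
  make_fastq(f, reads)
  cm4 <- demultiplex(f, design, guides)
  expect_equal(cm4$counts, cm$counts)
  # duplicate barcodes rejected
  design$barcodes <- c(AAAACCCCGGGG = "a", AAAACCCCGGGG = "b")
  expect_error(demultiplex(reads, design, guides), "duplicate")
})

test_that("filter_low_counts uses the any-control-replicate rule strictly", {
  counts <- rbind(edge = c(20, 20, 100, 100), low = c(19, 500, 100, 100),
                  ok = c(50, 60, 1, 1))
  colnames(counts) <- c("d1", "d2", "i1", "i2")
  cm <- count_matrix(counts, condition = c("control_dead", "control_dead",
                                           "induced", "induced"),
                     replicate = c(1, 2, 1, 2))
  out <- filter_low_counts(cm, "control_dead", 20)
  expect_equal(rownames(out$counts), c("edge", "ok"))
  expect_equal(attr(out, "removed"), "low")
  # brute-force agreement on a random matrix
  withr::with_seed(9, {
    m <- matrix(rpois(600, 30), nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
  })
  cm2 <- count_matrix(m, condition = rep(c("control_dead", "induced"), 3),
                      replicate = rep(1:3, each = 2))
  out2 <- filter_low_counts(cm2, "control_dead", 20)
  brute <- sum(sapply(1:100, function(i) any(m[i, c(1, 3, 5)] < 20)))
  expect_equal(length(attr(out2, "removed")), brute)
})

test_that("clr_transform is exactly depth invariant", {
  x <- c(10, 200, 3, 57)
  expect_equal(clr_transform(1000 * x), clr_transform(x))
  m <- matrix(c(x, 2 * x), ncol = 2)
  sc <- m %*% diag(c(17, 0.003))
  expect_equal(clr_transform(sc), clr_transform(m))
  expect_equal(sum(clr_transform(x)), 0)
})

test_that("clr_mc_scores matches a high-instance rerun of the estimator", {
  cm <- count_matrix(rbind(g = c(100, 100, 900, 900),
                           h = c(900, 900, 100, 100)),
                     condition = rep(c("repressed", "induced"), each = 2),
                     replicate = c(1, 2, 1, 2))
  lo <- clr_mc_scores(cm, "repressed", "induced", n_instances = 128, seed = 1)
  hi <- clr_mc_scores(cm, "repressed", "induced", n_instances = 4096,
                      seed = 99)
  expect_lt(abs(lo$diff_btw[1] - hi$diff_btw[1]), 0.1)
  # two-guide CLR: diff for g is log2(900/100) relative to the geometric
  # centre; with a mirrored partner the expected diff is log2(9)
  expect_lt(abs(hi$diff_btw[1] - log2(9)), 0.1)
  expect_equal(lo$diff_btw[1], -lo$diff_btw[2], tolerance = 0.05)
  # determinism given seed
  again <- clr_mc_scores(cm, "repressed", "induced", n_instances = 128,
                         seed = 1)
  expect_identical(lo$diff_btw, again$diff_btw)
})

test_that("identical counts in every sample give null scores", {
  m <- matrix(rep(c(50, 500, 5000), 8), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  cm <- count_matrix(m, condition = rep(c("repressed", "induced"), each = 4),
                     replicate = rep(1:4, 2))
  sc <- clr_mc_scores(cm, "repressed", "induced", n_instances = 1024,
                      seed = 4)
  expect_true(all(abs(sc$diff_btw) < 0.05))
})

test_that("standardize_scores scales to unit variance and preserves ranks", {
  sc <- structure(data.frame(guide = c("a", "b", "c"),
                             diff_btw = c(-2, 0, 2), diff_win = 0,
                             rab_all = 0, effect = 0, q_value = 1),
                  class = c("score_table", "data.frame"))
  out <- standardize_scores(sc)
  expect_equal(out$std_score, c(-1, 0, 1))
  expect_equal(sd(out$std_score), 1)
  twice <- standardize_scores(out)
  expect_equal(twice$std_score, out$std_score)
  withr::with_seed(2, {
    sc$diff_btw <- rnorm(3) * 7
    cov <- rnorm(3)
  })
  out <- standardize_scores(sc)
  expect_equal(cor(out$std_score, cov, method = "spearman"),
               cor(sc$diff_btw, cov, method = "spearman"))
  sc$diff_btw <- rep(1, 3)
  expect_error(standardize_scores(sc), "zero variance")
})

test_that("depletion mode flips sign and recovers planted activity ranks", {
  pm <- make_planted_model(seed = 3)
  n <- 1000
  ctx <- random_contexts(n, seed = 14)
  act <- planted_activity(pm, ctx)
  withr::with_seed(15, {
    bias <- rlnorm(n, sdlog = 0.5)
    p_pool <- bias / sum(bias)
    p_end <- bias * exp(-0.3 * act)   # active guides deplete
    p_end <- p_end / sum(p_end)
    pool <- matrix(rmultinom(1, 2e6, p_pool), ncol = 1,
                   dimnames = list(sprintf("g%04d", 1:n), "pool"))
    endp <- cbind(rmultinom(1, 2e6, p_end), rmultinom(1, 2e6, p_end))
    rownames(endp) <- rownames(pool)
    colnames(endp) <- c("e1", "e2")
  })
  cm_end <- count_matrix(endp, condition = c("induced", "induced"),
                         replicate = 1:2)
  cm_pool <- count_matrix(pool, condition = "initial_pool", replicate = 1L)
  sc <- depletion_scores(cm_end, cm_pool, n_instances = 64, seed = 6)
  expect_true(attr(sc, "pool_replicated"))
  expect_gt(cor(sc$diff_btw, act, method = "spearman"), 0.8)
  raw <- depletion_scores(cm_end, cm_pool, n_instances = 64, seed = 6,
                          flip_sign = FALSE)
  expect_equal(raw$diff_btw, -sc$diff_btw)
  # strongest depleter: planted guide absent from endpoint
  hot <- rownames(pool)[which.max(act)]
  expect_gt(sc$diff_btw[sc$guide == hot], 1)
  # mismatched guide sets are rejected with offenders listed
  cm_bad <- count_matrix(pool[-1, , drop = FALSE], "initial_pool", 1L)
  expect_error(depletion_scores(cm_end, cm_bad, seed = 1), "g0001")
})

test_that("filter_high_variance is strict at the threshold", {
  sc <- structure(data.frame(guide = c("a", "b", "c"),
                             diff_btw = 1:3, diff_win = c(1.2, 1.0, 0.3),
                             rab_all = 0, effect = 0, q_value = 1),
                  class = c("score_table", "data.frame"))
  out <- filter_high_variance(sc, 1.0)
  expect_equal(out$guide, c("b", "c"))
  withr::with_seed(11, sc2 <- data.frame(guide = sprintf("g%02d", 1:50),
                                         diff_win = runif(50, 0, 2)))
  sc2$diff_btw <- 0; sc2$rab_all <- 0; sc2$effect <- 0; sc2$q_value <- 1
  out2 <- filter_high_variance(sc2, 1.0)
  expect_equal(nrow(out2), sum(!(sc2$diff_win > 1.0)))
})

test_that("significant_guides detects planted enrichment and is monotone", {
  cm <- planted_fold_counts(200, fold = 8, depth = 2e5, reps = 10, seed = 33)
  sc <- clr_mc_scores(cm, "repressed", "induced", n_instances = 64, seed = 7)
  hits <- significant_guides(sc, fdr = 0.01, direction = "positive")
  expect_true("g001" %in% hits)
  h05 <- significant_guides(sc, fdr = 0.05)
  expect_true(all(hits %in% h05))
  # all-identical counts: nothing significant
  m <- matrix(100, nrow = 20, ncol = 4,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  cmn <- count_matrix(m, condition = rep(c("repressed", "induced"), each = 2),
                      replicate = c(1, 2, 1, 2))
  scn <- clr_mc_scores(cmn, "repressed", "induced", n_instances = 64,
                       seed = 8)
  expect_length(significant_guides(scn, 0.01), 0)
})

test_that("diff_btw is insensitive to per-sample sequencing depth", {
  cm <- planted_fold_counts(100, fold = 4, depth = 1e5, reps = 3, seed = 44)
  sc1 <- clr_mc_scores(cm, "repressed", "induced", n_instances = 256,
                       seed = 5)
  scaled <- cm$counts
  scaled[, 1] <- scaled[, 1] * 7L
  cm2 <- count_matrix(scaled, cm$condition, cm$replicate)
  sc2 <- clr_mc_scores(cm2, "repressed", "induced", n_instances = 256,
                       seed = 5)
  expect_lt(max(abs(sc1$diff_btw - sc2$diff_btw)), 0.05)
})

test_that("growth classification separates the phenotype classes", {
  time <- seq(0, 1080, by = 10)
  # flat baseline in both conditions within a cohort of growers -> toxic
  grow <- 1 / (1 + ((1 - 0.02) / 0.02) * exp(-0.012 * time))
  oi <- rbind(flat = rep(0.02, length(time)),
              g1 = grow, g2 = grow, g3 = grow)
  or <- oi
  out <- classify_growth(oi, or, time)
  expect_equal(out$label[out$guide == "flat"], "toxic")
  # identical cohort: all normalized AUC exactly 1, all intermediate
  oi2 <- rbind(a = grow, b = grow, c = grow)
  out2 <- classify_growth(oi2, oi2, time)
  expect_equal(out2$auc_induced_norm, rep(1, 3))
  expect_equal(out2$label, rep("intermediate", 3))
  expect_error(classify_growth(oi2[, 1, drop = FALSE],
                               oi2[, 1, drop = FALSE], time[1]),
               "timepoints")
})

test_that("planted growth cohort recovers active and toxic extremes", {
  act <- c(rep(3, 20), rep(0, 33), rep(-3, 12), rep(0, 12))
  tox <- c(rep(0, 65), rep(1, 12))
  truth <- c(rep("active", 20), rep("intermediate", 33),
             rep("inactive", 12), rep("toxic", 12))
  sim <- simulate_growth(act, tox, seed = 10)
  out <- classify_growth(sim$od_induced, sim$od_repressed, sim$time)
  expect_equal(out$label[truth == "active"], rep("active", 20))
  expect_equal(out$label[truth == "toxic"], rep("toxic", 12))
  # no confusion between the extremes
  expect_false(any(out$label[truth == "active"] == "toxic"))
  expect_false(any(out$label[truth == "toxic"] == "active"))
})
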