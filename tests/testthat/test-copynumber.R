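test_that("modal depth matches uniform coverage on a plain genome", {
  g <- simulate_host_genome(1, 50000, seed = 121)
  reads <- simulate_reads(g, coverage = 30, error_rate = 0, seed = 122)
  idx <- build_index(list(g$records[[1]]))
  pa <- align_pairs(reads, idx)
  prof <- depth_profile(pa$alignments, g$records[[1]], window = 500)
  expect_lt(abs(prof$modal - 30) / 30, 0.05)
  expect_true(all(prof$windows$depth >= 0))
  # window larger than the reference: one window covering it
  small <- seq_record("tiny", random_dna_str(300, seed = 123), "host")
  p2 <- suppressWarnings(depth_profile(pa$alignments, small, window = 500))
  expect_equal(nrow(p2$windows), 1L)
  expect_equal(p2$windows$end, 300L)
  expect_warning(depth_profile(pa$alignments, small, window = 500), "zero")
  expect_error(depth_profile(pa$alignments, small, window = 50), ">= 100")
})

test_that("normalization puts copy count c at c/4", {
  g <- simulate_host_genome(1, 100000, seed = 124)
  id <- g$records[[1]]$id
  feats <- rbind(g$features,
                 data.frame(record_id = id, start = 20000L, end = 28000L,
                            label = "one_copy", copies = 1),
                 data.frame(record_id = id, start = 60000L, end = 68000L,
                            label = "four_copy", copies = 4),
                 data.frame(record_id = id, start = 83000L, end = 85000L,
                            label = "deleted", copies = 0))
  g <- genome_set(g$records, feats)
  reads <- simulate_reads(g, coverage = 30, error_rate = 0, seed = 125)
  idx <- build_index(list(g$records[[1]]))
  pa <- align_pairs(reads, idx)
  pset <- normalize_depth(depth_profiles(pa$alignments, list(g$records[[1]]),
                                         window = 500))
  iv <- function(lab) feats[feats$label == lab, c("record_id", "start", "end")]
  expect_lt(abs(normalized_mode(pset, iv("one_copy")) - 0.25), 0.02)
  expect_lt(abs(normalized_mode(pset, iv("four_copy")) - 1.00), 0.03)
  # two-copy background mode
  bg <- data.frame(record_id = id, start = 0L, end = 20000L)
  expect_lt(abs(normalized_mode(pset, bg) - 0.50), 0.02)
  # a fully deleted interior window sits at zero (read bleed-through only
  # at the margins)
  est0 <- estimate_feature_copies(pset, id, 83600, 84400, "deleted")
  expect_equal(est0$copies, 0L)
  expect_error(estimate_feature_copies(pset, id, -5, 100), "bounds")
  expect_error(estimate_feature_copies(pset, "nope", 0, 100), "not profiled")
})

test_that("normalized depth is scale-invariant in coverage", {
  g <- simulate_host_genome(1, 30000, seed = 126)
  id <- g$records[[1]]$id
  feats <- rbind(g$features,
                 data.frame(record_id = id, start = 10000L, end = 14000L,
                            label = "hemi", copies = 1))
  g <- genome_set(g$records, feats)
  est <- sapply(c(30, 60), function(cov) {
    reads <- simulate_reads(g, coverage = cov, error_rate = 0, seed = 127)
    pa <- align_pairs(reads, build_index(list(g$records[[1]])))
    pset <- normalize_depth(depth_profiles(pa$alignments,
                                           list(g$records[[1]]), 500))
    estimate_feature_copies(pset, id, 10000, 14000, "hemi")$mean_norm
  })
  expect_lt(abs(est[1] - est[2]), 0.05)
  expect_equal(round(4 * est), c(1, 1))
})

test_that("the default integrant's promoter and amplified region are recovered", {
  run <- default_run()
  cf <- run$scen$construct_features
  prom <- cf[cf$label == "promoter", ]
  expect_equal(estimate_feature_copies(run$pset, prom$record_id, prom$start,
                                       prom$end, "promoter")$copies, 3L)
  amp <- run$scen$truth$amplified_region
  expect_equal(estimate_feature_copies(run$pset, run$scen$plan$host_id,
                                       amp$start, amp$end, "amp")$copies, 8L)
})

test_that("delta-delta-Ct follows the closed form", {
  tab <- function(ts, rs, tc, rc) {
    data.frame(sample = rep(c("sample", "control"), each = 2),
               gene = rep(c("target", "reference"), 2),
               replicate = 1L, ct = c(ts, rs, tc, rc))
  }
  r <- ddct(tab(20, 20, 22, 20))
  expect_equal(r$ddct, -2)
  expect_equal(r$fold, 4)
  expect_equal(ddct(tab(25, 20, 25, 20))$fold, 1)
  expect_error(ddct(tab(20, 20, 22, 20)[-2, ]), "no Ct values")
  # noiseless simulation recovers the copy ratio exactly
  q <- simulate_qpcr(8, 2, replicates = 3, noise_sd = 0)
  expect_equal(ddct(q)$fold, 4)
})
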