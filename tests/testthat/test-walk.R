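test_that("greedy assembly reconstructs a uniquely tiled sequence", {
  truth <- random_dna_str(1000, seed = 101)
  starts <- seq(1, 851, by = 50)
  reads <- substring(truth, starts, starts + 149)
  # flip half the reads: orientation is canonicalized during assembly
  reads[seq(2, length(reads), 2)] <- revcomp(reads[seq(2, length(reads), 2)])
  contigs <- assemble_reads(reads, min_overlap = 40)
  expect_equal(length(contigs), 1L)
  got <- contigs[[1]]$seq
  expect_true(got == truth || got == revcomp(truth))
})

test_that("assembly respects overlap floors and containment", {
  a <- random_dna_str(150, seed = 103)
  b <- random_dna_str(150, seed = 104)
  expect_equal(length(assemble_reads(c(a, b), min_overlap = 40)), 2L)
  expect_equal(length(assemble_reads(c(a, revcomp(a)), min_overlap = 40)), 1L)
  expect_equal(length(assemble_reads(character(0))), 0L)
  expect_error(assemble_reads(c(a, b), min_overlap = 10), ">= 15")
})

test_that("end recruitment honours the window and rescues mates", {
  contig <- seq_record("c", random_dna_str(1000, seed = 105), "assembled")
  inside <- substr(contig$seq, 21, 170)     # overlaps [0, 200)
  outside <- substr(contig$seq, 501, 650)   # 500 bp from the end
  mate_of_inside <- random_dna_str(150, seed = 106)  # unmapped mate
  mate_of_outside <- random_dna_str(150, seed = 107)
  reads <- list(r1 = c(inside, outside), r2 = c(mate_of_inside, mate_of_outside),
                ids = c("in", "out"))
  got <- recruit_end_reads(contig, reads, window = 200,
                           direction = "upstream")
  expect_true(inside %in% got)
  expect_true(mate_of_inside %in% got)      # mate rescue
  expect_false(outside %in% got)
  expect_false(mate_of_outside %in% got)
  none <- recruit_end_reads(contig, list(r1 = random_dna_str(150, seed = 108),
                                         r2 = random_dna_str(150),
                                         ids = "x"), 200, "upstream")
  expect_equal(length(none), 0L)
})

test_that("a zero-cycle walk returns the seed unchanged", {
  seed <- seq_record("s", random_dna_str(500, seed = 109), "construct")
  wr <- walk(seed, list(r1 = character(), r2 = character(),
                        ids = character()),
             walk_config(n_cycles = 0))
  expect_identical(wr$final$seq, seed$seq)
  expect_equal(length(wr$extensions), 0L)
  expect_equal(wr$termination, "completed")
})

test_that("the upstream walk reconstructs true host sequence cycle by cycle", {
  ws <- walk_scenario(seed = 2, host_len = 8000, insertion = 5000)
  reads <- simulate_reads(ws$genome, coverage = 30, error_rate = 0, seed = 3)
  wr <- walk(ws$construct, reads, walk_config(direction = "upstream",
                                              n_cycles = 4))
  ext <- sum(wr$extensions)
  expect_equal(wr$termination, "completed")
  expect_equal(nchar(wr$final$seq) - wr$seed_len, ext)  # never shrinks
  # mate-rescue geometry: per-cycle extension within a loose insert band
  expect_gte(mean(wr$extensions), 500 - 2 * 150)
  expect_lte(mean(wr$extensions), 500 + 200)
  ext_seq <- substr(wr$final$seq, 1, ext)
  truth <- substr(ws$host_upstream, nchar(ws$host_upstream) - ext + 1,
                  nchar(ws$host_upstream))
  expect_gte(sitewalkr:::seq_identity(ext_seq, truth), 0.999)
  # determinism: same reads and config give the same contig
  wr2 <- walk(ws$construct, reads, walk_config(direction = "upstream",
                                               n_cycles = 4))
  expect_identical(wr$final$seq, wr2$final$seq)
})

test_that("a downstream walk runs into partial construct copies, not host", {
  run <- default_run()
  cons <- run$scen$construct
  L <- nchar(cons$seq)
  seed_rec <- seq_record(cons$id, substr(cons$seq, L - 999, L), "construct")
  wr <- walk(seed_rec, run$reads, walk_config(direction = "downstream",
                                              n_cycles = 12))
  ext <- sum(wr$extensions)
  expect_gt(ext, 0L)
  pl <- place_contig(wr$final, run$scen$references)
  # the extension (beyond the 1 kb seed) places on the construct itself
  ext_pl <- pl[pl$contig_start >= 1000, , drop = FALSE]
  expect_gt(nrow(ext_pl), 0L)
  expect_true(all(ext_pl$ref == cons$id))
})

test_that("contig placement reports exact coordinates and fusion splits", {
  h1 <- random_dna_str(3000, seed = 111)
  h2 <- random_dna_str(3000, seed = 112)
  refs <- list(seq_record("h1", h1, "host"), seq_record("h2", h2, "host"))
  sub <- seq_record("s", substr(h1, 1201, 2100), "assembled")
  pl <- place_contig(sub, refs)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$ref, "h1")
  expect_equal(c(pl$ref_start, pl$ref_end), c(1200L, 2100L))
  expect_equal(pl$identity, 1)
  fused <- seq_record("f", paste0(substr(h1, 1501, 2100),
                                  substr(h2, 501, 1100)), "assembled")
  plf <- place_contig(fused, refs)
  expect_equal(nrow(plf), 2L)
  expect_setequal(plf$ref, c("h1", "h2"))
  left <- plf[plf$ref == "h1", ]; right <- plf[plf$ref == "h2", ]
  expect_lte(abs(left$contig_end - 600L), 2L)
  expect_lte(abs(right$contig_start - 600L), 2L)
  expect_lte(abs(left$ref_end - 2100L), 2L)
  expect_lte(abs(right$ref_start - 500L), 2L)
})
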