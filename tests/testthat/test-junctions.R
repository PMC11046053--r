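test_that("soft-clip extraction uses exact anchor arithmetic", {
  aln <- data.frame(
    read_id = c("a", "b", "c"), mate = "R1", ref = "X",
    pos = c(100L, 100L, 100L), strand = "+",
    cigar = c("60M90S", "90S60M", "140M10S"),
    score = 0, nm = 0L, n_opt = 1L, ambiguous = FALSE,
    seq = c(random_dna_str(150, seed = 1), random_dna_str(150),
            random_dna_str(150)),
    primary = TRUE, stringsAsFactors = FALSE)
  fr <- extract_softclips(aln, min_clip = 20)
  expect_equal(nrow(fr), 2L)  # the 10 bp clip is below threshold
  right <- fr[fr$read_id == "a", ]
  expect_equal(right$side, "right")
  expect_equal(right$anchor_pos, 159L)      # p + 60 - 1, last matched base
  expect_equal(nchar(right$seq), 90L)
  expect_equal(right$seq, substr(aln$seq[1], 61, 150))
  left <- fr[fr$read_id == "b", ]
  expect_equal(left$side, "left")
  expect_equal(left$anchor_pos, 100L)       # first matched base
  expect_equal(left$seq, substr(aln$seq[2], 1, 90))
  expect_warning(extract_softclips(data.frame(
    read_id = "z", mate = "R1", ref = "X", pos = 0L, strand = "+",
    cigar = "150S", score = 0, nm = 0L, n_opt = 1L, ambiguous = FALSE,
    seq = random_dna_str(150), primary = TRUE, stringsAsFactors = FALSE)),
    "malformed")
})

test_that("clip re-alignment pairs anchors with entry points, both strands", {
  host <- random_dna_str(2000, seed = 7)
  refs <- list(seq_record("host", host, "host"))
  clips <- data.frame(
    read_id = c("fwd", "rev"), mate = "R1", anchor_ref = "X",
    anchor_pos = c(999L, 999L), side = "right", anchor_strand = "+",
    seq = c(substr(host, 501, 540), revcomp(substr(host, 601, 640))),
    stringsAsFactors = FALSE)
  cand <- realign_clips(clips, refs)
  fwd <- cand[cand$read_id == "fwd", ]
  expect_equal(fwd$orientation, "same")
  expect_setequal(c(fwd$pos_a, fwd$pos_b), c(999L, 500L))
  rev <- cand[cand$read_id == "rev", ]
  expect_equal(rev$orientation, "inverted")
  # inverted right-side clip enters at the far end of its hit interval
  expect_setequal(c(rev$pos_a, rev$pos_b), c(999L, 639L))
})

test_that("random clips produce no spurious candidates", {
  refs <- default_run()$scen$references
  set.seed(17)
  clips <- data.frame(
    read_id = sprintf("r%04d", 1:1000), mate = "R1", anchor_ref = "X",
    anchor_pos = 0L, side = "right", anchor_strand = "+",
    seq = vapply(1:1000, function(i) random_dna_str(30), character(1)),
    stringsAsFactors = FALSE)
  expect_equal(nrow(realign_clips(clips, refs)), 0L)
})

test_that("junction calling clusters, thresholds and filters self-noise", {
  cand <- function(id, pa, pb, ra = "A", rb = "B", or = "same") {
    data.frame(read_id = id, anchor_ref = ra, hit_ref = rb, ref_a = ra,
               pos_a = pa, ref_b = rb, pos_b = pb, orientation = or,
               stringsAsFactors = FALSE)
  }
  cands <- rbind(cand("r1", 100L, 200L), cand("r2", 100L, 200L),
                 cand("r3", 100L, 200L), cand("r4", 101L, 201L))
  calls <- call_junctions(cands, min_support = 3, position_tolerance = 2)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos_a, 100L)   # modal coordinate, not the outlier
  expect_equal(calls$pos_b, 200L)
  expect_equal(calls$support, 4L)
  # below the support floor: no call
  expect_equal(nrow(call_junctions(cands[1:2, ], min_support = 3)), 0L)
  # duplicate fragments from one read count once
  dup <- rbind(cand("r1", 50L, 300L), cand("r1", 50L, 300L),
               cand("r2", 50L, 300L))
  expect_equal(nrow(call_junctions(dup, min_support = 3)), 0L)
  # same-reference calls closer than a read length are suppressed
  near <- rbind(cand("r1", 100L, 180L, "A", "A"),
                cand("r2", 100L, 180L, "A", "A"),
                cand("r3", 100L, 180L, "A", "A"))
  expect_equal(nrow(call_junctions(near, min_support = 3,
                                   min_self_distance = 150)), 0L)
  far <- rbind(cand("r1", 100L, 500L, "A", "A"),
               cand("r2", 100L, 500L, "A", "A"),
               cand("r3", 100L, 500L, "A", "A"))
  expect_equal(nrow(call_junctions(far, min_support = 3,
                                   min_self_distance = 150)), 1L)
})

test_that("the default scenario's junctions are recovered exactly", {
  run <- default_run()
  m <- compare_to_truth(run$calls, run$scen$truth, tolerance = 0)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  # both construct<->host and host<->host calls are present
  host_ids <- vapply(run$scen$genome$records[1:2], `[[`, character(1), "id")
  cid <- run$scen$construct$id
  hh <- run$calls$ref_a %in% host_ids & run$calls$ref_b %in% host_ids
  ch <- xor(run$calls$ref_a == cid, run$calls$ref_b == cid)
  expect_gt(sum(hh), 0L)
  expect_gt(sum(ch), 0L)
})
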