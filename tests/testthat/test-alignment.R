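test_that("the index exposes every k-mer with its positions", {
  idx <- build_index(list(seq_record("r", "ACGTACGT", "host")), k = 11)
  expect_error(build_index(list(), 21), "nonempty")
  expect_error(build_index(list(seq_record("r", "ACGTACGT", "host")), 5),
               ">= 11")
  idx4 <- structure(list(ids = "r", seqs = "ACGTACGT", k = 4L),
                    class = "ref_index")
  expect_equal(index_kmer_count(idx4), 5L)  # L - k + 1
  hit <- index_lookup(idx4, "ACGT")         # duplicated k-mer: both positions
  expect_equal(sort(hit$pos), c(0L, 4L))
  expect_equal(nrow(index_lookup(idx4, "AAAA")), 0L)
})

test_that("exact reads align full-length at their source position", {
  ref <- seq_record("r", random_dna_str(5000, seed = 21), "host")
  idx <- build_index(list(ref))
  read <- substr(ref$seq, 1001, 1150)
  a <- align_read(read, idx)
  expect_equal(nrow(a), 1L)
  expect_equal(a$pos, 1000L)
  expect_equal(a$cigar, "150M")
  expect_equal(a$nm, 0L)
  expect_false(a$ambiguous)
  # reverse-complemented read maps to the same locus on the minus strand
  b <- align_read(revcomp(read), idx)
  expect_equal(b$pos, 1000L)
  expect_equal(b$strand, "-")
})

test_that("junction-spanning reads are soft-clipped at the fusion point", {
  a_part <- random_dna_str(300, seed = 31)
  b_part <- random_dna_str(300, seed = 32)
  idx <- build_index(list(seq_record("A", a_part, "host"),
                          seq_record("B", b_part, "host")))
  # read: last 60 bases of A followed by first 90 of B
  read <- paste0(substr(a_part, 241, 300), substr(b_part, 1, 90))
  a <- align_read(read, idx)
  a <- a[which.max(a$score), ]
  expect_equal(a$ref, "B")       # the longer matched part wins
  expect_equal(a$cigar, "60S90M")
  # and the complement fragment: clip length = 150 - matched prefix
  read2 <- paste0(substr(a_part, 211, 300), substr(b_part, 1, 60))
  a2 <- align_read(read2, idx)
  a2 <- a2[which.max(a2$score), ]
  expect_equal(a2$ref, "A")
  expect_equal(a2$cigar, "90M60S")
})

test_that("reads from sequence shared by two references are flagged ambiguous", {
  shared <- random_dna_str(400, seed = 41)
  r1 <- paste0(random_dna_str(500, seed = 42), shared, random_dna_str(500))
  r2 <- paste0(random_dna_str(500, seed = 43), shared, random_dna_str(500))
  idx <- build_index(list(seq_record("x", r1, "host"),
                          seq_record("y", r2, "construct")))
  a <- align_read(substr(shared, 101, 250), idx)
  expect_gte(nrow(a), 2L)
  expect_true(all(a$ambiguous))
  expect_setequal(unique(a$ref), c("x", "y"))
})

test_that("short reads warn and return unmapped", {
  idx <- build_index(list(seq_record("r", random_dna_str(100, seed = 3), "host")))
  expect_warning(a <- align_read("ACGTACGT", idx), "shorter")
  expect_equal(nrow(a), 0L)
})

test_that("pair alignment computes proper-pair geometry", {
  ref <- seq_record("r", random_dna_str(6000, seed = 51), "host")
  other <- seq_record("q", random_dna_str(3000, seed = 52), "host")
  idx <- build_index(list(ref, other))
  frag <- substr(ref$seq, 2001, 2500)
  reads <- list(r1 = c(substr(frag, 1, 150), substr(ref$seq, 1001, 1150),
                       strrep("N", 150)),
                r2 = c(revcomp(substr(frag, 351, 500)),
                       revcomp(substr(other$seq, 1001, 1150)),
                       revcomp(substr(ref$seq, 1201, 1350))),
                ids = c("proper", "split", "halfN"))
  pa <- align_pairs(reads, idx)
  expect_true(pa$pairs$proper[pa$pairs$read_id == "proper"])
  expect_false(pa$pairs$proper[pa$pairs$read_id == "split"])
  p <- pa$pairs[pa$pairs$read_id == "halfN", ]
  expect_false(p$r1_mapped)   # pure-N mate unmapped, pair retained
  expect_true(p$r2_mapped)
})

test_that("alignment recovery on error-free unique reads is essentially total", {
  g <- simulate_host_genome(1, 20000, seed = 61)
  reads <- simulate_reads(g, coverage = 10, error_rate = 0, seed = 62)
  idx <- build_index(list(g$records[[1]]))
  pa <- align_pairs(reads, idx)
  prim <- pa$alignments[pa$alignments$primary, ]
  full <- prim$cigar == "150M"
  expect_gte(mean(full), 0.999)
  # positions agree with simulation truth
  tr <- pa$reads$truth
  r1 <- prim[prim$mate == "R1", ]
  i <- match(r1$read_id, tr$id)
  ok <- ifelse(r1$strand == "+", r1$pos == tr$start[i],
               r1$pos == tr$end[i] - 150L)
  expect_gte(mean(ok), 0.999)
})

test_that("local alignment matches the spec'd worked example and edge cases", {
  r <- local_align("ACGTACGT", "ACGTACGT", 1, -1, -2)
  expect_equal(r$score, 8)
  expect_equal(r$query_range, c(0, 8))
  r2 <- local_align("ACGTACGT", "ACGAACGT", 1, -1, -2)
  expect_equal(r2$score, 6)
  expect_equal(r2$score, sw_oracle("ACGTACGT", "ACGAACGT", 1, -1, -2))
  expect_equal(local_align("A", "G", 1, -1, -2)$score, 0)
  expect_error(local_align("A", "A", -1, -1, -2), "match > 0")
})

test_that("SAM round-trips alignments and enforces CIGAR bookkeeping", {
  ref <- seq_record("r", random_dna_str(2000, seed = 71), "host")
  idx <- build_index(list(ref))
  reads <- list(r1 = substr(ref$seq, 501, 650),
                r2 = revcomp(substr(ref$seq, 851, 1000)), ids = "p1")
  pa <- align_pairs(reads, idx)
  sam <- tempfile(fileext = ".sam")
  write_sam(pa, sam)
  lines <- readLines(sam)
  expect_true(any(startsWith(lines, "@SQ")))
  back <- read_sam(sam)
  expect_equal(nrow(back), 2L)
  expect_equal(back$pos, c(500L, 850L))
  expect_equal(back$cigar, c("150M", "150M"))
  expect_setequal(back$strand, c("+", "-"))
  # corrupting the stored sequence violates the length invariant on write
  pa$alignments$seq[1] <- substr(pa$alignments$seq[1], 1, 100)
  expect_error(write_sam(pa, sam), "bookkeeping")
})
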