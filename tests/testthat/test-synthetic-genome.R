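test_that("host genome simulation honours lengths, seed and base model", {
  g <- simulate_host_genome(2, c(100000, 50000), seed = 7)
  expect_equal(unname(gs_lengths(g)), c(100000, 50000))
  g2 <- simulate_host_genome(2, c(100000, 50000), seed = 7)
  expect_identical(g$records[[1]]$seq, g2$records[[1]]$seq)
  expect_identical(g$records[[2]]$seq, g2$records[[2]]$seq)
  # uniform base model: GC fraction within the binomial band
  gc <- gc_scorer(g$records[[1]]$seq)
  expect_lt(abs(gc - 0.5), 0.01)  # 3 sigma for Binom(1e5, .5) is ~0.005
  expect_error(simulate_host_genome(1, 0), "positive")
  expect_true(all(g$features$copies == 2))
})

test_that("whole-construct insertion gives the arithmetic truth junctions", {
  g <- simulate_host_genome(1, 5000, seed = 3)
  host <- g$records[[1]]$id
  cons <- seq_record("vec", random_dna_str(1200, seed = 5), "construct")
  plan <- integration_plan(host, 2000,
                           data.frame(ref = "vec", start = 0L, end = 1200L,
                                      orient = "+", stringsAsFactors = FALSE))
  res <- apply_integration(g, cons, plan)
  mod <- res$genome$records[[res$truth$integrant_id]]
  expect_equal(nchar(mod$seq), 5000 + 1200)
  tj <- res$truth$junctions
  expect_equal(nrow(tj), 2L)
  # canonical endpoint pairs: (host 1999 | vec 0) and (vec 1199 | host 2000)
  expect_true(any(tj$ref_a == host & tj$pos_a == 1999 &
                    tj$ref_b == "vec" & tj$pos_b == 0))
  expect_true(any(tj$ref_a == host & tj$pos_a == 2000 &
                    tj$ref_b == "vec" & tj$pos_b == 1199))
})

test_that("reverse-complement segments appear verbatim in the output", {
  g <- simulate_host_genome(1, 3000, seed = 9)
  host <- g$records[[1]]$id
  cons <- seq_record("vec", random_dna_str(600, seed = 11), "construct")
  plan <- integration_plan(host, 1500,
                           data.frame(ref = "vec", start = 100L, end = 400L,
                                      orient = "-", stringsAsFactors = FALSE))
  res <- apply_integration(g, cons, plan)
  mod <- res$genome$records[[res$truth$integrant_id]]$seq
  expect_true(grepl(revcomp(substr(cons$seq, 101, 400)), mod, fixed = TRUE))
})

test_that("segment intervals out of bounds are rejected", {
  g <- simulate_host_genome(1, 1000, seed = 1)
  cons <- seq_record("vec", random_dna_str(100), "construct")
  plan <- integration_plan(g$records[[1]]$id, 500,
                           data.frame(ref = "vec", start = 0L, end = 500L,
                                      orient = "+", stringsAsFactors = FALSE))
  expect_error(apply_integration(g, cons, plan), "out of bounds")
})

test_that("the default scenario carries the expected truth structure", {
  scen <- default_scenario(1)
  tj <- scen$truth$junctions
  host1 <- scen$genome$records[[1]]$id
  host2 <- scen$genome$records[[2]]$id
  cid <- scen$construct$id
  refs_of <- paste(tj$ref_a, tj$ref_b)
  # host-fragment fusion (second contig), fragment-construct, and
  # construct-internal junctions all present
  expect_true(any(tj$ref_a == host1 & tj$ref_b == host2))
  expect_true(any(tj$ref_a == cid & tj$ref_b == host2 |
                    tj$ref_a == host2 & tj$ref_b == cid))
  expect_true(any(tj$ref_a == cid & tj$ref_b == cid))
  expect_true(any(tj$orientation == "inverted"))
  # cassette copy truth: four LC, one HC, one GS, three promoters
  expect_equal(unname(scen$truth$cassette_copies[c("LC", "HC", "GS", "promoter")]),
               c(4L, 1L, 1L, 3L))
  expect_equal(scen$truth$amplified_copies, 8L)
  expect_equal(scen$truth$amplified_fold, 4)
})

test_that("truth junctions are re-derivable by scanning the integrant sequence", {
  scen <- default_scenario(2)
  mod <- scen$genome$records[[scen$truth$integrant_id]]$seq
  seqs <- lapply(scen$references, `[[`, "seq")
  names(seqs) <- vapply(scen$references, `[[`, character(1), "id")
  pieces <- scen$truth$pieces
  # rebuilding the sample from the pieces reproduces the integrant exactly
  rebuilt <- paste(vapply(seq_len(nrow(pieces)), function(i) {
    p <- pieces[i, ]
    s <- substr(seqs[[p$ref]], p$start + 1, p$end)
    if (p$orient == "-") revcomp(s) else s
  }, character(1)), collapse = "")
  expect_identical(rebuilt, mod)
})

test_that("scenario builders remove junction-flanking micro-homology", {
  for (s in c(1, 5, 9)) {
    scen <- random_scenario(s)
    seqs <- lapply(scen$references, `[[`, "seq")
    names(seqs) <- vapply(scen$references, `[[`, character(1), "id")
    expect_equal(sitewalkr:::junction_homology(seqs, scen$truth$pieces), 0L)
  }
})
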