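# Crafted mini-references: a construct and a host contig sharing one
# cassette (the homologous case), plus a second unique host contig.
make_classify_fixture <- function() {
  cached("classify_fixture", {
    set.seed(81)
    shared <- random_dna_str(600)
    cons <- paste0(random_dna_str(1000), shared, random_dna_str(1000))
    host <- paste0(random_dna_str(3000), shared, random_dna_str(2000))
    host2 <- random_dna_str(3000)
    refs <- list(seq_record("host1", host, "host"),
                 seq_record("host2", host2, "host"),
                 seq_record("cons", cons, "construct"))
    list(refs = refs, idx = build_index(refs), cons = cons, host = host,
         host2 = host2, shared = shared)
  })
}

test_that("each informative class is assigned on its defining geometry", {
  fx <- make_classify_fixture()
  cons <- fx$cons; host <- fx$host; host2 <- fx$host2; shared <- fx$shared
  chim_read <- paste0(substr(host, 1001, 1070), substr(cons, 1, 80))
  reads <- list(
    r1 = c(substr(cons, 101, 250),          # isolateral
           substr(cons, 101, 250),          # flanking
           chim_read,                       # chimeric: 70M80S onto construct
           substr(shared, 101, 250),        # homologous (ambiguous origin)
           substr(host2, 101, 250)),        # non-informative
    r2 = c(revcomp(substr(cons, 501, 650)),
           revcomp(substr(host2, 1001, 1150)),
           revcomp(substr(host, 601, 750)),
           revcomp(substr(host, 1001, 1150)),
           revcomp(substr(host2, 501, 650))),
    ids = c("iso", "flank", "chim", "hom", "noninf"))
  pa <- align_pairs(reads, fx$idx)
  cl <- classify_pairs(pa, "cons")
  got <- setNames(cl$class, cl$read_id)
  expect_equal(unname(got[c("iso", "flank", "chim", "hom", "noninf")]),
               c("ISOLATERAL", "FLANKING", "CHIMERIC", "HOMOLOGOUS",
                 "NON_INFORMATIVE"))
  # the chimeric/flanking host contig is reported as support
  expect_equal(cl$host_ref[cl$read_id == "flank"], "host2")
  expect_equal(cl$host_ref[cl$read_id == "chim"], "host1")
})

test_that("classification partitions all pairs and empty input yields zeros", {
  run <- default_run()
  counts <- count_classes(run$classes)
  expect_equal(sum(counts$by_class), length(run$reads$ids))
  expect_true(all(run$classes$class %in% sitewalkr:::INFORMATIVE_CLASSES))
  # host-only dataset: only NON_INFORMATIVE nonzero
  g <- simulate_host_genome(1, 10000, seed = 91)
  reads <- simulate_reads(g, coverage = 5, error_rate = 0, seed = 92)
  idx <- build_index(c(g$records, list(seq_record("cons",
                                                  random_dna_str(2000, seed = 93),
                                                  "construct"))))
  pa <- align_pairs(reads, idx)
  cc <- count_classes(classify_pairs(pa, "cons"))
  expect_equal(sum(cc$by_class[setdiff(names(cc$by_class), "NON_INFORMATIVE")]),
               0L)
})

test_that("isolateral mate tallies are symmetric on the integrant dataset", {
  run <- default_run()
  counts <- count_classes(run$classes)
  iso <- counts$by_mate[counts$by_mate$class == "ISOLATERAL", ]
  expect_gt(iso$r1, 0L)
  expect_equal(iso$r1, iso$r2)
})

test_that("contig nomination ranks by junction-class support with a floor", {
  run <- default_run()
  counts <- count_classes(run$classes)
  truth_contigs <- c(run$scen$genome$records[[1]]$id,
                     run$scen$genome$records[[2]]$id)
  nom <- nominate_integration_contigs(counts, min_support = 3)
  expect_setequal(nom, truth_contigs)
  # no flanking/chimeric support points at uninvolved contigs
  expect_true(all(counts$by_ref$ref %in% truth_contigs))
  # floor excludes everything when support is insufficient
  expect_equal(length(nominate_integration_contigs(counts,
                                                   min_support = 10000)), 0L)
  expect_error(nominate_integration_contigs(counts, min_support = 0), ">= 1")
})
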