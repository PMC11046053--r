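# Scenario builders: synthetic integrant genomes with known truth.
#
# The default scenario reproduces the structure the pipeline is designed to
# resolve: one intact construct copy, two tandem truncated copies lacking the
# GS and HC cassettes, one inverted LC cassette, a short (~240 bp) flanking
# fragment from a second host contig in front of the construct copies, and a
# tandem-amplified upstream host region (8 total copies vs 2 in the
# unmodified control, i.e. 4-fold). The host carries a GS locus identical to
# the construct's GS cassette, which makes GS-derived reads ambiguous
# between references (the homologous class).

#' Build a synthetic expression construct
#'
#' Layout (0-based): vector backbone, promoter, LC cassette, spacer, HC
#' cassette, spacer, GS cassette, backbone. All sequence is drawn from the
#' current RNG stream (wrap in a seeded call for reproducibility).
#'
#' @param id Record id.
#' @return `list(record, features, layout)` where `features` marks the
#'   promoter/LC/HC/GS intervals and `layout` holds named coordinates.
#' @export
make_construct <- function(id = "construct") {
  sizes <- c(backbone5 = 600L, promoter = 800L, LC = 2400L, spacer1 = 400L,
             HC = 2400L, spacer2 = 400L, GS = 1500L, backbone3 = 800L)
  ends <- cumsum(sizes)
  starts <- ends - sizes
  seq <- random_dna(sum(sizes))
  layout <- list(starts = starts, ends = ends, length = sum(sizes),
                 trunc_start = starts[["promoter"]],
                 trunc_end = ends[["spacer1"]])
  keep <- c("promoter", "LC", "HC", "GS")
  features <- data.frame(record_id = id, start = unname(starts[keep]),
                         end = unname(ends[keep]), label = keep,
                         stringsAsFactors = FALSE)
  list(record = seq_record(id, seq, "construct"), features = features,
       layout = layout)
}

#' Build an integrant scenario with known truth
#'
#' Generates a two-contig host genome and a construct, plants a GS locus
#' identical to the construct's GS cassette in the host, assembles the
#' integration plan (amplified upstream region, flanking fragment from the
#' second contig, intact + truncated + inverted construct copies), removes
#' junction-flanking micro-homology so truth breakpoints are single-base
#' exact, and applies the plan.
#'
#' @param seed Integer seed; the whole scenario is a deterministic function
#'   of it.
#' @param host1_len,host2_len Host contig lengths (bp).
#' @param insertion 0-based insertion position on the first contig.
#' @param amp_len Length of the amplified upstream region (ends at the
#'   insertion point).
#' @param amp_factor Tandem copies of that region on the modified haplotype
#'   (total copies in the integrant = `amp_factor + 1`).
#' @param frag_start,frag_len Interval on the second contig inserted as the
#'   flanking fragment.
#' @param n_trunc Number of tandem truncated (promoter+LC) construct copies.
#' @param gs_host_pos Position of the host GS locus on the first contig.
#' @return `list(genome, construct, construct_features, plan, truth,
#'   references)`; `references` is the read-mapping reference set (original
#'   host contigs plus the construct).
#' @export
build_scenario <- function(seed = 1L, host1_len = 60000L, host2_len = 12000L,
                           insertion = 14000L, amp_len = 3000L,
                           amp_factor = 7L, frag_start = 4000L,
                           frag_len = 240L, n_trunc = 2L,
                           gs_host_pos = 6000L) {
  with_seed(seed, {
    genome <- simulate_host_genome(2L, c(host1_len, host2_len), seed = NULL)
    cons <- make_construct()
    lay <- cons$layout
    host1 <- genome$records[[1L]]$id
    host2 <- genome$records[[2L]]$id
    seqs <- lapply(genome$records, `[[`, "seq")
    # host GS locus identical to the construct GS cassette (homologous class)
    gs_seq <- substr(cons$record$seq, lay$starts[["GS"]] + 1L, lay$ends[["GS"]])
    substr(seqs[[host1]], gs_host_pos + 1L, gs_host_pos + nchar(gs_seq)) <- gs_seq

    segs <- rbind(
      data.frame(ref = host2, start = frag_start, end = frag_start + frag_len,
                 orient = "+", stringsAsFactors = FALSE),
      data.frame(ref = cons$record$id, start = 0L, end = lay$length,
                 orient = "+", stringsAsFactors = FALSE))
    for (i in seq_len(n_trunc)) {
      segs <- rbind(segs, data.frame(ref = cons$record$id,
                                     start = lay$trunc_start,
                                     end = lay$trunc_end, orient = "+",
                                     stringsAsFactors = FALSE))
    }
    segs <- rbind(segs, data.frame(ref = cons$record$id,
                                   start = lay$starts[["LC"]],
                                   end = lay$ends[["LC"]], orient = "-",
                                   stringsAsFactors = FALSE))
    amp <- if (amp_factor > 1)
      list(start = insertion - amp_len, end = insertion, factor = amp_factor)
    plan <- integration_plan(host1, insertion, segs, amp)

    # zero flanking homology at every planned junction
    seqs_all <- c(seqs, setNames(list(cons$record$seq), cons$record$id))
    tmp_genome <- genome_set(lapply(names(seqs), function(i)
      seq_record(i, seqs[[i]], "host")), genome$features)
    pieces <- plan_pieces(tmp_genome, seq_record(cons$record$id,
                                                 cons$record$seq, "construct"),
                          plan)
    seqs_all <- clean_junction_bases(seqs_all, pieces)

    genome <- genome_set(lapply(names(seqs), function(i)
      seq_record(i, seqs_all[[i]], "host")), genome$features)
    construct <- seq_record(cons$record$id, seqs_all[[cons$record$id]],
                            "construct")

    res <- apply_integration(genome, construct, plan,
                             cassette_features = cons$features)
    host_feats <- data.frame(record_id = host1, start = gs_host_pos,
                             end = gs_host_pos + nchar(gs_seq),
                             label = "GS_host", stringsAsFactors = FALSE)
    list(genome = res$genome, construct = construct,
         construct_features = cons$features, host_features = host_feats,
         plan = plan, truth = res$truth,
         references = c(lapply(names(seqs), function(i)
           seq_record(i, seqs_all[[i]], "host")), list(construct)))
  })
}

#' The default integrant scenario
#'
#' Fixed-size instance of [build_scenario()] shared by the documentation and
#' the acceptance checks: LC x4 (intact + two truncated + one inverted),
#' HC x1, GS x1, a 240 bp flanking fragment from the second contig, and an
#' 8-vs-2-copy amplified upstream region.
#'
#' @param seed Integer seed.
#' @return See [build_scenario()].
#' @export
default_scenario <- function(seed = 1L) build_scenario(seed = seed)

#' Compact randomized scenario for property sweeps
#'
#' Same structure as [default_scenario()] but smaller, with the insertion
#' point, fragment interval and host GS position drawn from the seed.
#'
#' @param seed Integer seed.
#' @return See [build_scenario()].
#' @export
random_scenario <- function(seed = 1L) {
  par <- with_seed(seed + 10000L, list(
    insertion = sample(9000:12000, 1L),
    frag_start = sample(1000:4000, 1L),
    gs_host_pos = sample(1500:4000, 1L)))
  build_scenario(seed = seed, host1_len = 16000L, host2_len = 6000L,
                 insertion = par$insertion, amp_len = 2000L, amp_factor = 3L,
                 frag_start = par$frag_start, frag_len = 240L, n_trunc = 1L,
                 gs_host_pos = par$gs_host_pos)
}

#' Plain-insertion scenario for the genome walk
#'
#' A single host contig with the full construct inserted so that a long
#' stretch of unique host sequence lies upstream; no amplification, no extra
#' copies. Both homologs carry the insertion (the walk does not depend on
#' zygosity).
#'
#' @param seed Integer seed.
#' @param host_len Host contig length (bp).
#' @param insertion 0-based insertion position (the upstream walk can extend
#'   at most this far).
#' @return `list(genome, construct, truth, host_upstream)` where
#'   `host_upstream` is the true host sequence 5' of the construct.
#' @export
walk_scenario <- function(seed = 1L, host_len = 20000L, insertion = 12000L) {
  with_seed(seed, {
    genome <- simulate_host_genome(1L, host_len, seed = NULL, prefix = "host")
    cons <- make_construct()
    host <- genome$records[[1L]]$id
    segs <- data.frame(ref = cons$record$id, start = 0L,
                       end = cons$layout$length, orient = "+",
                       stringsAsFactors = FALSE)
    plan <- integration_plan(host, insertion, segs)
    seqs_all <- c(lapply(genome$records, `[[`, "seq"),
                  setNames(list(cons$record$seq), cons$record$id))
    pieces <- plan_pieces(genome, cons$record, plan)
    seqs_all <- clean_junction_bases(seqs_all, pieces)
    genome <- genome_set(list(seq_record(host, seqs_all[[host]], "host")),
                         genome$features)
    construct <- seq_record(cons$record$id, seqs_all[[cons$record$id]],
                            "construct")
    res <- apply_integration(genome, construct, plan,
                             cassette_features = cons$features)
    # the sampled genome is the integrant haplotype at the two-copy background
    integrant <- res$genome$records[[res$truth$integrant_id]]
    sim_genome <- genome_set(list(integrant), data.frame(
      record_id = integrant$id, start = 0L, end = nchar(integrant$seq),
      label = "background", copies = 2, stringsAsFactors = FALSE))
    list(genome = sim_genome, construct = construct, truth = res$truth,
         host_record = genome$records[[host]],
         host_upstream = substr(seqs_all[[host]], 1L, insertion))
  })
}

#' Mostly-two-copy genome with known one-copy regions
#'
#' Depth-normalization scenario: a uniform host genome annotated with a set
#' of single-copy regions (emulating hemizygous loci) used to check that the
#' normalized-depth mode for one-copy sequence sits at 0.25.
#'
#' @param seed Integer seed.
#' @param genome_len Genome length (bp).
#' @param n_onecopy Number of one-copy regions.
#' @param region_len Length of each one-copy region (bp).
#' @return `list(genome, onecopy)`; `onecopy` is a data.frame of the
#'   one-copy intervals.
#' @export
depth_scenario <- function(seed = 1L, genome_len = 500000L, n_onecopy = 8L,
                           region_len = 5000L) {
  with_seed(seed, {
    genome <- simulate_host_genome(1L, genome_len, seed = NULL, prefix = "chr")
    id <- genome$records[[1L]]$id
    gap <- genome_len %/% (n_onecopy + 1L)
    starts <- gap * seq_len(n_onecopy)
    onecopy <- data.frame(record_id = id, start = starts,
                          end = starts + region_len, label = "one_copy",
                          copies = 1, stringsAsFactors = FALSE)
    feats <- rbind(genome$features, onecopy)
    list(genome = genome_set(genome$records, feats), onecopy = onecopy)
  })
}
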