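# Genome walking: serial de novo assembly and re-mapping. Each cycle maps
# all reads to the current contig, recruits the reads overlapping the
# terminal window on the growing end together with their mates (mate rescue
# pulls in sequence beyond the contig end, which is what extends the walk
# by roughly one insert length per cycle), assembles them, and splices the
# assembled contig onto the growing end by its exact overlap.

#' Walk configuration
#'
#' @param direction `"upstream"` (grow at the 5' end) or `"downstream"`.
#' @param n_cycles Number of assembly/re-mapping cycles.
#' @param end_window Recruitment window at the growing end (bp); applied at
#'   every cycle.
#' @param seed_window Window on the construct used to seed a downstream walk
#'   (bp).
#' @param min_overlap Minimum exact suffix-prefix overlap for the assembler
#'   and for splicing (bp).
#' @param min_reads Minimum recruited reads to attempt a cycle.
#' @param k Mapper seed length.
#' @return A `walk_config` list.
#' @export
walk_config <- function(direction = c("upstream", "downstream"),
                        n_cycles = 12L, end_window = 200L,
                        seed_window = 1000L, min_overlap = 40L,
                        min_reads = 3L, k = 21L) {
  direction <- match.arg(direction)
  if (end_window < 50L) stop("end_window must be >= 50")
  if (n_cycles < 0L) stop("n_cycles must be >= 0")
  if (min_overlap < 15L) stop("min_overlap must be >= 15")
  list(direction = direction, n_cycles = as.integer(n_cycles),
       end_window = as.integer(end_window),
       seed_window = as.integer(seed_window),
       min_overlap = as.integer(min_overlap),
       min_reads = as.integer(min_reads), k = as.integer(k))
}

#' Greedy overlap-layout-consensus assembly
#'
#' Repeatedly merges the pair of sequences with the longest exact
#' suffix-prefix overlap of at least `min_overlap`, trying both orientations
#' of the incoming sequence; contained sequences are absorbed. Tie-breaking
#' is a fixed total order, so assembly is deterministic.
#'
#' @param reads Character vector of read sequences.
#' @param min_overlap Minimum exact overlap (bp), >= 15.
#' @return List of [seq_record()] contigs (role `"assembled"`), longest
#'   first; empty input yields an empty list.
#' @export
assemble_reads <- function(reads, min_overlap = 40L) {
  if (min_overlap < 15L) stop("min_overlap must be >= 15")
  if (!length(reads)) return(list())
  contigs <- assemble_greedy_cpp(reads, min_overlap)
  lapply(seq_along(contigs), function(i) {
    seq_record(sprintf("asm%03d", i), contigs[i], "assembled")
  })
}

#' Recruit reads at the growing end of a contig
#'
#' Returns the reads whose alignment overlaps the terminal window on the
#' growing side, plus the mate sequence of every such read even when the
#' mate is unmapped (mate rescue).
#'
#' @param contig A [seq_record()].
#' @param reads Paired read set (`list(r1, r2, ids)`).
#' @param window Terminal window (bp).
#' @param direction `"upstream"` (window at the contig start) or
#'   `"downstream"`.
#' @param k Mapper seed length.
#' @return Character vector of recruited read/mate sequences (deduplicated).
#' @export
recruit_end_reads <- function(contig, reads, window, direction = "upstream",
                              k = 21L) {
  if (window > nchar(contig$seq)) window <- nchar(contig$seq)
  idx <- build_index(list(contig), k = k)
  all_seq <- c(reads$r1, reads$r2)
  hits <- map_batch(all_seq, idx, max_report = 1L)
  if (!nrow(hits)) return(character())
  span <- cigar_ref_span(hits$cigar)
  L <- nchar(contig$seq)
  in_window <- if (direction == "upstream") hits$pos < window else
    hits$pos + span > L - window
  sel <- unique(hits$read[in_window])
  if (!length(sel)) return(character())
  n <- length(reads$r1)
  mates <- ifelse(sel > n, sel - n, sel + n)
  unique(all_seq[unique(c(sel, mates))])
}

#' Iterative assembly-and-remapping genome walk
#'
#' Starting from a seed sequence (typically the construct, or its terminal
#' window for a downstream walk), each cycle maps all reads to the current
#' contig, recruits end-window reads with mate rescue, assembles them, and
#' splices the assembled contig onto the growing end via its exact overlap.
#' The walk stops after `n_cycles`, or earlier when no assembled contig
#' extends the end (`stalled`) or when the new extension mostly re-enters
#' sequence already assembled (`circular`, the signature of walking into
#' repeated construct copies).
#'
#' @param seed A [seq_record()] seeding the walk.
#' @param reads Paired read set (`list(r1, r2, ids)`).
#' @param config A [walk_config()].
#' @return `list(final, extensions, cycle_log, termination, seed_len)`;
#'   `final` is the assembled [seq_record()], `extensions` the per-cycle
#'   extension lengths (bp).
#' @export
walk <- function(seed, reads, config = walk_config()) {
  if (!nchar(seed$seq)) stop("seed must be nonempty")
  current <- seed$seq
  upstream <- config$direction == "upstream"
  extensions <- integer(0)
  log <- list()
  termination <- "completed"
  for (cycle in seq_len(config$n_cycles)) {
    contig <- seq_record("walk_current", current, "assembled")
    recruited <- recruit_end_reads(contig, reads, config$end_window,
                                   config$direction, k = config$k)
    if (length(recruited) < config$min_reads) { termination <- "stalled"; break }
    asm <- assemble_greedy_cpp(recruited, config$min_overlap)
    sp <- best_splice(current, asm, upstream, config$min_overlap)
    if (is.null(sp)) { termination <- "stalled"; break }
    if (is_circular_extension(sp$ext, current)) {
      termination <- "circular"; break
    }
    current <- if (upstream) paste0(sp$ext, current) else paste0(current, sp$ext)
    extensions <- c(extensions, nchar(sp$ext))
    log[[length(log) + 1L]] <- data.frame(
      cycle = cycle, reads_recruited = length(recruited),
      extension = nchar(sp$ext), contig_len = nchar(current))
    if (nchar(sp$ext) == 0L) { termination <- "stalled"; break }
  }
  list(final = seq_record(paste0(seed$id, "_walked"), current, "assembled"),
       extensions = extensions,
       cycle_log = if (length(log)) do.call(rbind, log) else
         data.frame(cycle = integer(), reads_recruited = integer(),
                    extension = integer(), contig_len = integer()),
       termination = termination,
       seed_len = nchar(seed$seq))
}

# Pick the assembled contig that best extends the growing end: largest
# extension whose exact-diagonal overlap with the current contig is at least
# min_overlap with >= 99% identity.
best_splice <- function(current, contigs, upstream, min_overlap) {
  best <- NULL
  for (cs in contigs) {
    for (orient in 1:2) {
      s <- if (orient == 1L) cs else revcomp_cpp(cs)
      h <- anchor_hits_cpp(s, current, 31L)
      h <- h[h$strand == 0L, , drop = FALSE]
      if (!nrow(h)) next
      diag <- h$rpos - h$qpos
      d <- as.integer(names(sort(table(diag), decreasing = TRUE))[1])
      ext_len <- if (upstream) -d else (d + nchar(s)) - nchar(current)
      if (ext_len <= 0L) next
      ov_start_q <- if (upstream) ext_len else 0L
      ov_len <- min(nchar(s) - ext_len, nchar(current) - max(0L, d))
      if (ov_len < min_overlap) next
      q_sub <- if (upstream) substr(s, ext_len + 1L, ext_len + ov_len) else
        substr(s, 1L, ov_len)
      r_sub <- if (upstream) substr(current, 1L, ov_len) else
        substr(current, d + 1L, d + ov_len)
      if (seq_identity(q_sub, r_sub) < 0.99) next
      ext <- if (upstream) substr(s, 1L, ext_len) else
        substr(s, nchar(s) - ext_len + 1L, nchar(s))
      if (is.null(best) || ext_len > best$ext_len)
        best <- list(ext = ext, ext_len = ext_len)
    }
  }
  best
}

seq_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0)
  mean(strsplit(substr(a, 1, n), "")[[1]] == strsplit(substr(b, 1, n), "")[[1]])
}

# An extension that mostly re-enters already-assembled sequence signals a
# repeat loop; >90% of its k-mers present in the current contig stops the
# walk with reason "circular".
is_circular_extension <- function(ext, current, k = 31L) {
  if (nchar(ext) < k) return(FALSE)
  h <- anchor_hits_cpp(ext, current, k)
  covered <- unique(h$qpos)
  length(covered) / (nchar(ext) - k + 1L) > 0.9
}

#' Place an assembled contig onto the reference set
#'
#' Exact-anchor placements: k-mer hits are clustered per (reference, strand,
#' diagonal), each cluster becomes a candidate placement, and placements
#' shorter than `min_placement_len` or below `min_identity` are dropped. A
#' contig spanning a fusion yields two placements partitioning it.
#'
#' @param contig A [seq_record()].
#' @param references A [genome_set()], list of [seq_record()]s, or
#'   `ref_index`.
#' @param min_placement_len Minimum placement length (bp).
#' @param min_identity Minimum identity of the placed interval.
#' @param k Anchor length.
#' @return `data.frame(contig_start, contig_end, ref, ref_start, ref_end,
#'   strand, identity)`, 0-based half-open, sorted along the contig.
#' @export
place_contig <- function(contig, references, min_placement_len = 200L,
                         min_identity = 0.95, k = 21L) {
  refs <- as_ref_index(references, k = k)
  h <- anchor_hits_cpp(contig$seq, refs$seqs, k)
  if (!nrow(h)) return(data.frame(contig_start = integer(),
                                  contig_end = integer(), ref = character(),
                                  ref_start = integer(), ref_end = integer(),
                                  strand = character(), identity = numeric(),
                                  stringsAsFactors = FALSE))
  L <- nchar(contig$seq)
  rc <- revcomp_cpp(contig$seq)
  h$diag <- h$rpos - h$qpos
  grp <- paste(h$ref, h$strand, h$diag)
  out <- list()
  for (g in unique(grp)) {
    hh <- h[grp == g, , drop = FALSE]
    qs <- min(hh$qpos); qe <- max(hh$qpos) + k
    rs <- min(hh$rpos); re <- max(hh$rpos) + k
    if (qe - qs < min_placement_len) next
    qseq <- if (hh$strand[1] == 0L) substr(contig$seq, qs + 1L, qe) else
      substr(rc, qs + 1L, qe)
    rseq <- substr(refs$seqs[hh$ref[1]], rs + 1L, re)
    ident <- seq_identity(qseq, rseq)
    if (ident < min_identity) next
    cs <- if (hh$strand[1] == 0L) qs else L - qe
    ce <- if (hh$strand[1] == 0L) qe else L - qs
    out[[length(out) + 1L]] <- data.frame(
      contig_start = cs, contig_end = ce, ref = refs$ids[hh$ref[1]],
      ref_start = rs, ref_end = re,
      strand = if (hh$strand[1] == 0L) "+" else "-", identity = ident,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig_start = integer(), contig_end = integer(),
               ref = character(), ref_start = integer(), ref_end = integer(),
               strand = character(), identity = numeric(),
               stringsAsFactors = FALSE)
  res <- res[order(res$contig_start, -((res$contig_end - res$contig_start))), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
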