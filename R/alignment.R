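# Built-in read mapper: k-mer seeds voted per (reference, strand, diagonal),
# gapless maximal-scoring-segment extension, terminal soft clips, all
# co-optimal placements reported. SAM interop lets an external mapper be
# substituted for any downstream stage.

#' Build a reference index handle
#'
#' The handle pins the reference set and seed length `k`; the k-mer hash is
#' built inside the batch mapping call (cheap relative to mapping, and the
#' reference set stays the single source of truth).
#'
#' @param references List of [seq_record()] objects.
#' @param k Seed k-mer length (>= 11).
#' @return An object of class `ref_index`.
#' @export
build_index <- function(references, k = 21L) {
  if (!length(references)) stop("reference set must be nonempty")
  if (k < 11L) stop("k must be >= 11")
  ids <- vapply(references, `[[`, character(1), "id")
  seqs <- vapply(references, `[[`, character(1), "seq")
  structure(list(ids = ids, seqs = unname(seqs), k = as.integer(k)),
            class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat(sprintf("<ref_index> %d references, k = %d\n", length(x$ids), x$k))
  invisible(x)
}

#' Number of indexed k-mer positions
#' @param index A [build_index()] handle.
#' @return Total count of length-k substrings over all references.
#' @export
index_kmer_count <- function(index) {
  sum(pmax(0L, nchar(index$seqs) - index$k + 1L))
}

#' Look up the reference positions of one k-mer
#' @param index A [build_index()] handle.
#' @param kmer A length-k nucleotide string.
#' @return `data.frame(ref, pos)` of 0-based forward-strand occurrences.
#' @export
index_lookup <- function(index, kmer) {
  if (nchar(kmer) != index$k) stop("query must have length k")
  h <- anchor_hits_cpp(kmer, index$seqs, index$k)
  h <- h[h$strand == 0L, , drop = FALSE]
  data.frame(ref = index$ids[h$ref], pos = h$rpos, stringsAsFactors = FALSE)
}

# Batch-map a character vector of reads; returns the co-optimal placement
# table. Scores: +1 per matching base, -8 per mismatch inside the aligned
# block; unalignable ends become soft clips. The heavy mismatch penalty
# keeps fusion-spanning reads from absorbing chance matches beyond the
# junction into the M block, so soft-clip boundaries are breakpoint-exact
# on error-free data.
map_batch <- function(reads, index, max_report = 8L) {
  df <- map_reads_cpp(reads, index$seqs, index$k, 1, 8, max_report)
  df$ref <- index$ids[df$ref]
  df$strand <- ifelse(df$strand == 0L, "+", "-")
  df
}

cigar_ops <- function(cigar) {
  m <- gregexpr("\\d+[MIDS]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDS]", cigar))[[1]]
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}

# reference span consumed by a CIGAR (M and D ops); fast path for the
# mapper's own xS yM zS shape, token parse for general SAM input
cigar_ref_span <- function(cigar) {
  simple <- grepl("^(\\d+S)?\\d+M(\\d+S)?$", cigar)
  span <- integer(length(cigar))
  if (any(simple))
    span[simple] <- as.integer(sub("^(\\d+S)?(\\d+)M(\\d+S)?$", "\\2",
                                   cigar[simple]))
  for (i in which(!simple)) {
    ops <- cigar_ops(cigar[i])
    span[i] <- sum(ops$len[ops$op %in% c("M", "D")])
  }
  span
}

#' Align a single read against an indexed reference set
#'
#' Seeded gapless extension on both strands; all co-optimal placements are
#' returned and flagged ambiguous when there are two or more (never broken
#' randomly -- downstream classification depends on seeing the ambiguity).
#'
#' @param read Nucleotide string.
#' @param index A [build_index()] handle.
#' @return `data.frame` with one row per co-optimal placement: `ref`, `pos`
#'   (0-based), `strand`, `cigar`, `score`, `nm`, `n_opt`, `ambiguous`,
#'   `seq` (stored in reference-forward orientation). Zero rows if unmapped;
#'   reads shorter than `k` warn and return zero rows.
#' @export
align_read <- function(read, index) {
  if (nchar(read) < index$k) {
    warning("read shorter than seed length k; unmapped")
    return(empty_alignment_df())
  }
  df <- map_batch(read, index)
  if (!nrow(df)) return(empty_alignment_df())
  data.frame(read_id = "read", mate = "R1", ref = df$ref, pos = df$pos,
             strand = df$strand, cigar = df$cigar, score = df$score,
             nm = df$nm, n_opt = df$n_opt, ambiguous = df$n_opt >= 2L,
             seq = ifelse(df$strand == "+", read, revcomp(read)),
             stringsAsFactors = FALSE)
}

empty_alignment_df <- function() {
  data.frame(read_id = character(), mate = character(), ref = character(),
             pos = integer(), strand = character(), cigar = character(),
             score = numeric(), nm = integer(), n_opt = integer(),
             ambiguous = logical(), seq = character(), stringsAsFactors = FALSE)
}

#' Align all read pairs against the joint reference set
#'
#' Each mate is aligned independently; the properly-paired flag requires the
#' primary placements on the same reference, opposite strands in FR
#' orientation, and an outer span within `insert_max`.
#'
#' @param reads Paired read set (`list(r1, r2, ids)`), e.g. from
#'   [simulate_reads()] or [read_fastq_pair()].
#' @param index A [build_index()] handle over host contigs plus construct.
#' @param insert_max Maximum proper-pair outer span (bp).
#' @return An object of class `pair_alignments`: `alignments` (co-optimal
#'   placement table; `primary` marks the deterministic first placement per
#'   read), `pairs` (per-pair mapping/proper flags), and the input reads.
#' @export
align_pairs <- function(reads, index, insert_max = 1000L) {
  n <- length(reads$ids)
  all_seq <- c(reads$r1, reads$r2)
  df <- map_batch(all_seq, index)
  mate_i <- ifelse(df$read > n, 2L, 1L)
  pair_i <- ifelse(df$read > n, df$read - n, df$read)
  aln <- data.frame(read_id = reads$ids[pair_i],
                    mate = c("R1", "R2")[mate_i],
                    ref = df$ref, pos = df$pos, strand = df$strand,
                    cigar = df$cigar, score = df$score, nm = df$nm,
                    n_opt = df$n_opt, ambiguous = df$n_opt >= 2L,
                    stringsAsFactors = FALSE)
  aln$seq <- all_seq[df$read]
  neg <- aln$strand == "-"
  if (any(neg))
    aln$seq[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(aln$seq[neg])))
  # deterministic primary: the C++ mapper emits co-optimal rows sorted by
  # (ref, pos, strand) within each read
  key <- paste(aln$read_id, aln$mate)
  aln$primary <- !duplicated(key)

  prim <- aln[aln$primary, , drop = FALSE]
  span <- cigar_ref_span(prim$cigar)
  p1 <- prim[prim$mate == "R1", , drop = FALSE]
  p2 <- prim[prim$mate == "R2", , drop = FALSE]
  i1 <- match(reads$ids, p1$read_id)
  i2 <- match(reads$ids, p2$read_id)
  end1 <- p1$pos[i1] + cigar_ref_span(p1$cigar)[i1]
  end2 <- p2$pos[i2] + cigar_ref_span(p2$cigar)[i2]
  same_ref <- !is.na(i1) & !is.na(i2) & p1$ref[i1] == p2$ref[i2]
  opp <- same_ref & p1$strand[i1] != p2$strand[i2]
  lo <- pmin(p1$pos[i1], p2$pos[i2])
  hi <- pmax(end1, end2)
  fwd_first <- ifelse(p1$pos[i1] <= p2$pos[i2], p1$strand[i1], p2$strand[i2])
  proper <- opp & fwd_first == "+" & (hi - lo) <= insert_max
  proper[is.na(proper)] <- FALSE
  pairs <- data.frame(read_id = reads$ids,
                      r1_mapped = !is.na(i1), r2_mapped = !is.na(i2),
                      proper = proper, stringsAsFactors = FALSE)
  structure(list(alignments = aln, pairs = pairs, reads = reads,
                 index = index),
            class = "pair_alignments")
}

#' @export
print.pair_alignments <- function(x, ...) {
  cat(sprintf("<pair_alignments> %d pairs, %d placements, %.1f%% proper\n",
              nrow(x$pairs), nrow(x$alignments),
              100 * mean(x$pairs$proper)))
  invisible(x)
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under linear gap penalty, with full traceback.
#'
#' @param query,target Nucleotide strings.
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap Gap score per base (< 0).
#' @return `list(score, query_range, target_range, cigar)`; ranges are
#'   0-based half-open `c(start, end)`, the empty alignment has score 0.
#' @export
local_align <- function(query, target, match = 1, mismatch = -1, gap = -2) {
  if (match <= 0 || mismatch >= 0 || gap >= 0)
    stop("require match > 0, mismatch < 0, gap < 0")
  r <- sw_align_cpp(query, target, match, mismatch, gap)
  list(score = r$score,
       query_range = c(r$qstart, r$qend),
       target_range = c(r$tstart, r$tend),
       cigar = r$cigar)
}

# ---- SAM interop ------------------------------------------------------------

#' Write alignments as SAM
#'
#' Mandatory fields with 1-based POS, CIGAR including soft clips, SEQ in
#' reference-forward orientation; secondary co-optimal placements carry flag
#' 0x100. The CIGAR read-length bookkeeping invariant is asserted on write.
#'
#' @param pa A `pair_alignments` object (or a bare alignment table).
#' @param path Output SAM path.
#' @export
write_sam <- function(pa, path) {
  aln <- if (inherits(pa, "pair_alignments")) pa$alignments else pa
  index <- if (inherits(pa, "pair_alignments")) pa$index else NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  if (!is.null(index))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", index$ids, nchar(index$seqs)), con)
  read_len_ok <- vapply(seq_len(nrow(aln)), function(i) {
    ops <- cigar_ops(aln$cigar[i])
    sum(ops$len[ops$op %in% c("M", "I", "S")]) == nchar(aln$seq[i])
  }, logical(1))
  if (!all(read_len_ok)) stop("CIGAR length bookkeeping violated")
  flag <- 1L + ifelse(aln$mate == "R1", 64L, 128L) +
    ifelse(aln$strand == "-", 16L, 0L) + ifelse(aln$primary, 0L, 256L)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                     aln$read_id, flag, aln$ref, aln$pos + 1L,
                     ifelse(aln$ambiguous, 0L, 60L), aln$cigar, aln$seq,
                     aln$nm), con)
  invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Minimal reader for mapper substitution: mandatory fields, soft-clip-aware
#' CIGARs, NM tag when present.
#'
#' @param path SAM file.
#' @return Alignment `data.frame` in the package's internal layout.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(empty_alignment_df())
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  keep <- bitwAnd(flag, 4L) == 0L
  data.frame(
    read_id = vapply(f, `[`, character(1), 1)[keep],
    mate = ifelse(bitwAnd(flag, 128L) > 0L, "R2", "R1")[keep],
    ref = vapply(f, `[`, character(1), 3)[keep],
    pos = vapply(f, function(x) as.integer(x[4]), integer(1))[keep] - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")[keep],
    cigar = vapply(f, `[`, character(1), 6)[keep],
    score = NA_real_, nm = nm[keep], n_opt = 1L,
    ambiguous = (vapply(f, function(x) as.integer(x[5]), integer(1)) == 0L)[keep],
    seq = vapply(f, `[`, character(1), 10)[keep],
    primary = (bitwAnd(flag, 256L) == 0L)[keep],
    stringsAsFactors = FALSE)
}
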