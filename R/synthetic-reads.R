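#' Simulate paired-end reads from a genome set
#'
#' Fragments are drawn along each contig proportional to the local planned
#' copy count (features with a `copies` column; uncovered sequence counts as
#' the two-copy background), so `coverage` is the expected depth over
#' two-copy sequence. Mates are the two fragment ends with the inner mate
#' reverse-complemented (FR orientation); which physical end becomes R1 is
#' randomized per pair. Substitution errors are i.i.d. per base; no indels.
#'
#' The pair count is `round(coverage * sum(length_i * copies_i / 2) /
#' (2 * read_len))`, which reduces to `coverage * L / (2 * read_len)` on an
#' all-two-copy genome.
#'
#' @param genome A [genome_set()].
#' @param coverage Expected fold-coverage over two-copy background.
#' @param read_len Read length (bp).
#' @param insert_mean,insert_sd Fragment-length distribution (bp).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return `list(r1, r2, ids, truth)`; `truth` records the source record,
#'   fragment interval and mate orientation of every pair.
#' @export
simulate_reads <- function(genome, coverage, read_len = 150L,
                           insert_mean = 500L, insert_sd = 50L,
                           error_rate = 0.001, seed = 1L) {
  if (coverage <= 0) stop("coverage must be positive")
  if (read_len > insert_mean) stop("read_len must not exceed insert_mean")
  recs <- genome$records
  feats <- genome$features
  # piecewise copy profile per record -> sampling weights
  pieces <- do.call(rbind, lapply(names(recs), function(id) {
    L <- nchar(recs[[id]]$seq)
    f <- feats[feats$record_id == id & !is.na(feats$copies), , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    cuts <- sort(unique(c(0L, L, f$start, f$end)))
    starts <- cuts[-length(cuts)]; ends <- cuts[-1L]
    copies <- vapply(seq_along(starts), function(i) {
      hit <- f$start <= starts[i] & f$end >= ends[i]
      if (any(hit)) f$copies[which(hit)[length(which(hit))]] else 2
    }, numeric(1))
    data.frame(record_id = id, start = starts, end = ends, copies = copies,
               stringsAsFactors = FALSE)
  }))
  pieces$weight <- (pieces$end - pieces$start) * pieces$copies / 2
  eff_len <- sum(pieces$weight)
  n_pairs <- round(coverage * eff_len / (2 * read_len))

  with_seed(seed, {
    pi <- sample.int(nrow(pieces), n_pairs, replace = TRUE,
                     prob = pieces$weight)
    flen <- round(rnorm(n_pairs, insert_mean, insert_sd))
    # bounded resampling of fragments shorter than the read
    for (tries in 1:10) {
      bad <- which(flen < read_len)
      if (!length(bad)) break
      flen[bad] <- round(rnorm(length(bad), insert_mean, insert_sd))
    }
    flen[flen < read_len] <- read_len
    rec_len <- gs_lengths(genome)[pieces$record_id[pi]]
    flen <- pmin(flen, rec_len)
    start <- pieces$start[pi] +
      floor(runif(n_pairs) * (pieces$end[pi] - pieces$start[pi]))
    start <- pmin(start, rec_len - flen)
    start <- pmax(start, 0L)

    rid <- pieces$record_id[pi]
    fwd <- character(n_pairs); rev <- character(n_pairs)
    for (id in unique(rid)) {
      w <- which(rid == id)
      s <- recs[[id]]$seq
      fwd[w] <- substring(s, start[w] + 1L, start[w] + read_len)
      rev[w] <- substring(s, start[w] + flen[w] - read_len + 1L,
                          start[w] + flen[w])
    }
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(rev)))
    flip <- runif(n_pairs) < 0.5
    r1 <- ifelse(flip, rev, fwd)
    r2 <- ifelse(flip, fwd, rev)
    if (error_rate > 0) {
      r1 <- add_substitutions(r1, error_rate)
      r2 <- add_substitutions(r2, error_rate)
    }
    ids <- sprintf("pair%07d", seq_len(n_pairs))
    list(r1 = r1, r2 = r2, ids = ids,
         truth = data.frame(id = ids, record_id = rid, start = start,
                            end = start + flen, flipped = flip,
                            stringsAsFactors = FALSE))
  })
}

add_substitutions <- function(reads, rate) {
  n_err <- rbinom(length(reads), nchar(reads), rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  reads
}
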