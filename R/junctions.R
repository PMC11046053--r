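# Junction resolution: terminal soft-clip fragments from chimeric
# alignments are re-aligned to the full reference set; each successful
# re-alignment pairs the clip's anchor coordinate with the re-alignment's
# entry point, and candidates are clustered into single-base fusion calls.

#' Extract terminal soft-clip fragments from alignments
#'
#' One fragment per terminal `S` block of length at least `min_clip`. The
#' anchor is the reference coordinate immediately adjacent to the clip: the
#' first matched base for a left-side clip, the last matched base for a
#' right-side clip. Stored sequences are in reference-forward orientation,
#' so clip coordinates need no strand correction downstream.
#'
#' @param alignments Alignment `data.frame` (e.g. `pa$alignments` or
#'   [read_sam()] output); rows lacking a parseable CIGAR are skipped with a
#'   warning.
#' @param min_clip Minimum clip length (bp).
#' @return `data.frame(read_id, mate, anchor_ref, anchor_pos, side,
#'   anchor_strand, seq)`.
#' @export
extract_softclips <- function(alignments, min_clip = 20L) {
  if (min_clip < 1L) stop("min_clip must be >= 1")
  out <- list()
  candidates <- grep("S", alignments$cigar, fixed = TRUE)
  for (i in candidates) {
    cg <- alignments$cigar[i]
    ops <- tryCatch(cigar_ops(cg), error = function(e) NULL)
    if (is.null(ops) || !nrow(ops) ||
        !all(ops$op %in% c("M", "I", "D", "S")) ||
        sum(ops$len[ops$op == "M"]) == 0L) {
      warning("skipping record with malformed CIGAR: ", cg)
      next
    }
    refspan <- sum(ops$len[ops$op %in% c("M", "D")])
    seq <- alignments$seq[i]
    pos <- alignments$pos[i]
    n_ops <- nrow(ops)
    if (ops$op[1] == "S" && ops$len[1] >= min_clip) {
      out[[length(out) + 1L]] <- data.frame(
        read_id = alignments$read_id[i], mate = alignments$mate[i],
        anchor_ref = alignments$ref[i], anchor_pos = pos, side = "left",
        anchor_strand = alignments$strand[i],
        seq = substr(seq, 1L, ops$len[1]), stringsAsFactors = FALSE)
    }
    if (ops$op[n_ops] == "S" && ops$len[n_ops] >= min_clip) {
      out[[length(out) + 1L]] <- data.frame(
        read_id = alignments$read_id[i], mate = alignments$mate[i],
        anchor_ref = alignments$ref[i], anchor_pos = pos + refspan - 1L,
        side = "right", anchor_strand = alignments$strand[i],
        seq = substr(seq, nchar(seq) - ops$len[n_ops] + 1L, nchar(seq)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(read_id = character(), mate = character(),
                      anchor_ref = character(), anchor_pos = integer(),
                      side = character(), anchor_strand = character(),
                      seq = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Re-align clip fragments and form junction candidates
#'
#' Each clipped sequence is aligned against all references on both strands
#' (seeded gapless alignment with a short seed so the shortest admissible
#' clips are recoverable). A candidate is emitted when the clip aligns with
#' identity at least `min_identity` over at least `min_clip` bases and the
#' placement is unambiguous; clips with co-optimal placements are discarded
#' (ambiguity-safe, mirroring the exclusion of homologous evidence). The
#' candidate pairs the clip's anchor with the reference position of the
#' anchor-adjacent clip base; reverse-strand hits are marked inverted.
#'
#' @param clips Output of [extract_softclips()].
#' @param references A `ref_index`, a list of [seq_record()]s, or a
#'   [genome_set()].
#' @param min_clip Minimum aligned length (bp).
#' @param min_identity Minimum matched fraction of the clip.
#' @param k_clip Seed length for clip re-alignment.
#' @return Candidate `data.frame(read_id, anchor_ref, hit_ref, ref_a, pos_a,
#'   ref_b, pos_b, orientation)` with canonicalized endpoint order.
#' @export
realign_clips <- function(clips, references, min_clip = 20L,
                          min_identity = 0.95, k_clip = 15L) {
  refs <- as_ref_index(references, k = k_clip)
  if (!nrow(clips)) return(empty_candidate_df())
  hits <- map_batch(clips$seq, refs, max_report = 2L)
  if (!nrow(hits)) return(empty_candidate_df())
  hits <- hits[hits$n_opt == 1L, , drop = FALSE]
  if (!nrow(hits)) return(empty_candidate_df())
  ci <- hits$read
  clip_len <- nchar(clips$seq[ci])
  ops <- lapply(hits$cigar, cigar_ops)
  mlen <- vapply(ops, function(o) sum(o$len[o$op == "M"]), integer(1))
  lclip <- vapply(ops, function(o)
    if (o$op[1] == "S") o$len[1] else 0L, integer(1))
  ident <- (mlen - hits$nm) / clip_len
  keep <- ident >= min_identity & mlen >= min_clip
  if (!any(keep)) return(empty_candidate_df())
  hits <- hits[keep, , drop = FALSE]
  ci <- ci[keep]; clip_len <- clip_len[keep]; lclip <- lclip[keep]

  side <- clips$side[ci]
  # reference position of the anchor-adjacent clip base, extrapolated along
  # the gapless diagonal (exact when the clip aligns from its first base)
  b <- ifelse(side == "right", 0L, clip_len - 1L)
  entry <- ifelse(hits$strand == "+",
                  hits$pos + (b - lclip),
                  hits$pos + (clip_len - 1L - lclip - b))
  reflen <- setNames(nchar(refs$seqs), refs$ids)
  entry <- pmin(pmax(entry, 0L), reflen[hits$ref] - 1L)
  orientation <- ifelse(hits$strand == "+", "same", "inverted")

  cand <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    j <- canonical_junction(clips$anchor_ref[ci[i]], clips$anchor_pos[ci[i]],
                            hits$ref[i], entry[i], orientation[i])
    cbind(data.frame(read_id = clips$read_id[ci[i]],
                     anchor_ref = clips$anchor_ref[ci[i]],
                     hit_ref = hits$ref[i], stringsAsFactors = FALSE), j)
  }))
  rownames(cand) <- NULL
  cand
}

empty_candidate_df <- function() {
  data.frame(read_id = character(), anchor_ref = character(),
             hit_ref = character(), ref_a = character(), pos_a = integer(),
             ref_b = character(), pos_b = integer(),
             orientation = character(), stringsAsFactors = FALSE)
}

as_ref_index <- function(references, k = 21L) {
  if (inherits(references, "ref_index")) return(references)
  if (inherits(references, "genome_set")) references <- references$records
  if (inherits(references, "seq_record")) references <- list(references)
  build_index(references, k = k)
}

#' Call fusion junctions from clustered candidates
#'
#' Candidates sharing a reference pair and orientation are clustered when
#' both breakpoints lie within `position_tolerance`; the cluster breakpoint
#' is the modal coordinate pair (ties broken toward the smaller
#' coordinates), support counts distinct read ids, and clusters below
#' `min_support` are discarded. Junctions between a reference and itself at
#' a distance below `min_self_distance` are suppressed (internal soft-clip
#' noise cannot span less than a read length).
#'
#' @param candidates Output of [realign_clips()].
#' @param min_support Minimum distinct-read support.
#' @param position_tolerance Clustering tolerance (bp); 0 demands exact
#'   agreement.
#' @param min_self_distance Minimum same-reference breakpoint separation (bp).
#' @return `data.frame(ref_a, pos_a, ref_b, pos_b, orientation, support)` of
#'   class `junction_calls`.
#' @export
call_junctions <- function(candidates, min_support = 3L,
                           position_tolerance = 2L,
                           min_self_distance = 150L) {
  if (min_support < 1L) stop("min_support must be >= 1")
  out <- list()
  if (nrow(candidates)) {
    grp <- paste(candidates$ref_a, candidates$ref_b, candidates$orientation,
                 sep = "\r")
    for (g in unique(grp)) {
      cc <- candidates[grp == g, , drop = FALSE]
      cc <- cc[order(cc$pos_a, cc$pos_b), , drop = FALSE]
      cluster <- integer(nrow(cc))
      cur <- 1L; ra <- cc$pos_a[1]; rb <- cc$pos_b[1]
      for (i in seq_len(nrow(cc))) {
        if (abs(cc$pos_a[i] - ra) > position_tolerance ||
            abs(cc$pos_b[i] - rb) > position_tolerance) {
          cur <- cur + 1L; ra <- cc$pos_a[i]; rb <- cc$pos_b[i]
        }
        cluster[i] <- cur
      }
      for (cl in unique(cluster)) {
        m <- cc[cluster == cl, , drop = FALSE]
        support <- length(unique(m$read_id))
        if (support < min_support) next
        keypos <- paste(m$pos_a, m$pos_b)
        tab <- sort(table(keypos), decreasing = TRUE)
        best <- names(tab)[tab == tab[1]]
        modal <- sort(best)[1]
        pp <- as.integer(strsplit(modal, " ", fixed = TRUE)[[1]])
        if (m$ref_a[1] == m$ref_b[1] &&
            abs(pp[1] - pp[2]) < min_self_distance) next
        out[[length(out) + 1L]] <- data.frame(
          ref_a = m$ref_a[1], pos_a = pp[1], ref_b = m$ref_b[1],
          pos_b = pp[2], orientation = m$orientation[1], support = support,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    cbind(empty_junction_df(), data.frame(support = integer()))
  res <- res[order(res$ref_a, res$pos_a, res$ref_b, res$pos_b), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("junction_calls", "data.frame"))
}

#' Write junction calls as BEDPE-style TSV
#' @param calls Output of [call_junctions()].
#' @param path Output TSV.
#' @export
write_junctions <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
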