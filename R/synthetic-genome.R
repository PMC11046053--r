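#' Simulate a multi-contig host genome
#'
#' Contigs are i.i.d. uniform over A/C/G/T and annotated as a two-copy
#' (diploid-like) background. Repeatable under a fixed seed.
#'
#' @param n_contigs Number of contigs.
#' @param lengths Integer vector of contig lengths (bp), recycled to
#'   `n_contigs`.
#' @param seed Integer seed.
#' @param prefix Contig id prefix.
#' @return A [genome_set()] with one `background` feature per contig at
#'   copy count 2.
#' @export
simulate_host_genome <- function(n_contigs, lengths, seed = 1L, prefix = "contig") {
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  lengths <- rep_len(as.integer(lengths), n_contigs)
  with_seed(seed, {
    recs <- lapply(seq_len(n_contigs), function(i) {
      seq_record(sprintf("%s%02d", prefix, i), random_dna(lengths[i]), "host")
    })
    feats <- data.frame(
      record_id = vapply(recs, `[[`, character(1), "id"),
      start = 0L, end = lengths, label = "background", copies = 2,
      stringsAsFactors = FALSE)
    genome_set(recs, feats)
  })
}

#' Describe how a construct integrates into a host contig
#'
#' An integration plan specifies, for one host contig, the insertion point,
#' the ordered segments placed there (intervals on the construct or on other
#' host contigs, each forward or reverse-complemented), and an optional
#' tandem amplification of a flanking host region.
#'
#' @param host_id Host contig receiving the insertion.
#' @param position 0-based insertion position (segments inserted before this
#'   base).
#' @param segments `data.frame` with columns `ref`, `start`, `end` (0-based
#'   half-open) and `orient` (`"+"` forward, `"-"` reverse-complement).
#' @param amplified Optional `list(start, end, factor)`: the host interval
#'   `[start, end)` (which must end at or before `position`) is present in
#'   `factor` tandem copies on the modified haplotype. `factor >= 1`;
#'   1 means no amplification.
#' @return An object of class `integration_plan`.
#' @export
integration_plan <- function(host_id, position, segments, amplified = NULL) {
  stopifnot(is.data.frame(segments),
            all(c("ref", "start", "end", "orient") %in% names(segments)))
  if (any(segments$start < 0 | segments$start >= segments$end))
    stop("invalid segment intervals")
  if (!all(segments$orient %in% c("+", "-"))) stop("orient must be '+' or '-'")
  if (!is.null(amplified)) {
    stopifnot(all(c("start", "end", "factor") %in% names(amplified)))
    if (amplified$factor < 1) stop("amplification factor must be >= 1")
    if (amplified$end > position) stop("amplified region must end at or before the insertion position")
    if (amplified$start >= amplified$end) stop("invalid amplified interval")
  }
  structure(list(host_id = host_id, position = as.integer(position),
                 segments = segments, amplified = amplified),
            class = "integration_plan")
}

# Ordered piece list (ref, start, end, orient) making up the modified contig.
plan_pieces <- function(genome, construct, plan) {
  L <- nchar(gs_seq(genome, plan$host_id))
  p <- plan$position
  if (p < 0 || p > L) stop("insertion position out of bounds")
  pieces <- list()
  add <- function(ref, start, end, orient = "+") {
    if (end > start)
      pieces[[length(pieces) + 1L]] <<- data.frame(
        ref = ref, start = as.integer(start), end = as.integer(end),
        orient = orient, stringsAsFactors = FALSE)
  }
  amp <- plan$amplified
  if (!is.null(amp) && amp$factor > 1) {
    add(plan$host_id, 0L, amp$end)
    for (i in seq_len(amp$factor - 1L)) add(plan$host_id, amp$start, amp$end)
    add(plan$host_id, amp$end, p)
  } else {
    add(plan$host_id, 0L, p)
  }
  for (i in seq_len(nrow(plan$segments))) {
    s <- plan$segments[i, ]
    add(s$ref, s$start, s$end, s$orient)
  }
  add(plan$host_id, p, L)
  do.call(rbind, pieces)
}

piece_seq <- function(seqs, piece) {
  s <- substr(seqs[[piece$ref]], piece$start + 1L, piece$end)
  if (piece$orient == "-") s <- revcomp(s) else s
}

# Derive truth junctions from adjacent pieces that are not
# reference-contiguous. A junction is the last base of the left piece and the
# first base of the right piece, in reference coordinates; the endpoint pair
# is canonicalized by (ref, pos) order so calls and truth compare directly.
pieces_junctions <- function(pieces) {
  out <- list()
  for (i in seq_len(nrow(pieces) - 1L)) {
    p <- pieces[i, ]; q <- pieces[i + 1L, ]
    contiguous <- p$ref == q$ref && p$orient == q$orient &&
      ((p$orient == "+" && p$end == q$start) ||
       (p$orient == "-" && q$end == p$start))
    if (contiguous) next
    pa <- if (p$orient == "+") p$end - 1L else p$start
    pb <- if (q$orient == "+") q$start else q$end - 1L
    orient <- if (p$orient == q$orient) "same" else "inverted"
    out[[length(out) + 1L]] <- canonical_junction(p$ref, pa, q$ref, pb, orient)
  }
  if (!length(out)) return(empty_junction_df())
  unique(do.call(rbind, out))
}

canonical_junction <- function(ref_a, pos_a, ref_b, pos_b, orientation) {
  if (ref_b < ref_a || (ref_b == ref_a && pos_b < pos_a)) {
    tmp <- ref_a; ref_a <- ref_b; ref_b <- tmp
    tmp <- pos_a; pos_a <- pos_b; pos_b <- tmp
  }
  data.frame(ref_a = ref_a, pos_a = as.integer(pos_a),
             ref_b = ref_b, pos_b = as.integer(pos_b),
             orientation = orientation, stringsAsFactors = FALSE)
}

empty_junction_df <- function() {
  data.frame(ref_a = character(), pos_a = integer(), ref_b = character(),
             pos_b = integer(), orientation = character(),
             stringsAsFactors = FALSE)
}

# Breakpoints are single-base identifiable only when the joined references do
# not share the bases flanking the fusion (zero micro-homology). Scenario
# builders call this to mutate the reference base next to each planned
# junction so that every truth breakpoint is exact. Constraints on a shared
# flanking base are gathered as a union before assigning, and the pass is
# iterated to a fixpoint because assigned bases can themselves be referenced
# by other junctions' constraints.
clean_junction_bases <- function(seqs, pieces) {
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  getb <- function(ref, pos) substr(seqs[[ref]], pos + 1L, pos + 1L)
  adjacent_noncontiguous <- function() {
    out <- list()
    for (i in seq_len(nrow(pieces) - 1L)) {
      p <- pieces[i, ]; q <- pieces[i + 1L, ]
      contiguous <- p$ref == q$ref && p$orient == q$orient &&
        ((p$orient == "+" && p$end == q$start) ||
         (p$orient == "-" && q$end == p$start))
      if (!contiguous) out[[length(out) + 1L]] <- list(p = p, q = q)
    }
    out
  }
  pairs <- adjacent_noncontiguous()
  for (pass in 1:20) {
    # gather forbidden-value sets per mutable flanking base
    forb <- list()
    forbid <- function(ref, pos, value) {
      key <- paste0(ref, "@", pos)
      forb[[key]] <<- unique(c(forb[[key]], value, recursive = TRUE))
      attr(forb[[key]], "where") <<- c(ref, pos)
      forb[[key]]
    }
    for (pr in pairs) {
      p <- pr$p; q <- pr$q
      qfirst <- if (q$orient == "+") getb(q$ref, q$start) else comp1(getb(q$ref, q$end - 1L))
      plast <- if (p$orient == "+") getb(p$ref, p$end - 1L) else comp1(getb(p$ref, p$start))
      if (p$orient == "+" && p$end < nchar(seqs[[p$ref]])) {
        forbid(p$ref, p$end, qfirst)
      } else if (p$orient == "-" && p$start > 0) {
        forbid(p$ref, p$start - 1L, comp1(qfirst))
      }
      if (q$orient == "+" && q$start > 0) {
        forbid(q$ref, q$start - 1L, plast)
      } else if (q$orient == "-" && q$end < nchar(seqs[[q$ref]])) {
        forbid(q$ref, q$end, comp1(plast))
      }
    }
    changed <- FALSE
    for (key in names(forb)) {
      loc <- strsplit(key, "@", fixed = TRUE)[[1L]]
      ref <- loc[1L]; pos <- as.integer(loc[2L])
      cur <- getb(ref, pos)
      bad <- as.character(forb[[key]])
      if (cur %in% bad) {
        choice <- setdiff(c("A", "C", "G", "T"), bad)[1L]
        substr(seqs[[ref]], pos + 1L, pos + 1L) <- choice
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  seqs
}

# Max flanking micro-homology over all planned junctions (0 = every
# breakpoint single-base identifiable). Used by tests and scenario builders.
junction_homology <- function(seqs, pieces) {
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  getb <- function(ref, pos) substr(seqs[[ref]], pos + 1L, pos + 1L)
  worst <- 0L
  for (i in seq_len(nrow(pieces) - 1L)) {
    p <- pieces[i, ]; q <- pieces[i + 1L, ]
    contiguous <- p$ref == q$ref && p$orient == q$orient &&
      ((p$orient == "+" && p$end == q$start) ||
       (p$orient == "-" && q$end == p$start))
    if (contiguous) next
    qfirst <- if (q$orient == "+") getb(q$ref, q$start) else comp1(getb(q$ref, q$end - 1L))
    plast <- if (p$orient == "+") getb(p$ref, p$end - 1L) else comp1(getb(p$ref, p$start))
    cont <- if (p$orient == "+") {
      if (p$end < nchar(seqs[[p$ref]])) getb(p$ref, p$end) else NA
    } else {
      if (p$start > 0) comp1(getb(p$ref, p$start - 1L)) else NA
    }
    prev <- if (q$orient == "+") {
      if (q$start > 0) getb(q$ref, q$start - 1L) else NA
    } else {
      if (q$end < nchar(seqs[[q$ref]])) comp1(getb(q$ref, q$end)) else NA
    }
    if (!is.na(cont) && cont == qfirst) worst <- max(worst, 1L)
    if (!is.na(prev) && prev == plast) worst <- max(worst, 1L)
  }
  worst
}

#' Apply an integration plan to a host genome
#'
#' Builds the integrant genome: the target contig is replaced by one
#' unmodified homolog (copy count 1) and one modified haplotype (copy count 1)
#' containing the planned segments; all other contigs keep the two-copy
#' background. Returns the genome together with a deterministic truth set:
#' every adjacent-segment fusion junction at single-base resolution, cassette
#' copy counts, and the amplified-region fold.
#'
#' @param genome A [genome_set()] from [simulate_host_genome()].
#' @param construct A [seq_record()] with role `"construct"`.
#' @param plan An [integration_plan()].
#' @param cassette_features Optional `data.frame` (`record_id`, `start`,
#'   `end`, `label`) of cassette intervals on the construct whose copy counts
#'   are tallied in the truth set.
#' @return `list(genome, truth)` where `truth` has `junctions` (canonical
#'   endpoint pairs), `cassette_copies`, `amplified_fold`, `amplified_copies`
#'   and `amplified_region`.
#' @export
apply_integration <- function(genome, construct, plan, cassette_features = NULL) {
  stopifnot(inherits(plan, "integration_plan"))
  seqs <- lapply(genome$records, `[[`, "seq")
  seqs[[construct$id]] <- construct$seq
  # validate segment sources
  for (i in seq_len(nrow(plan$segments))) {
    s <- plan$segments[i, ]
    if (is.null(seqs[[s$ref]])) stop("unknown segment source '", s$ref, "'")
    if (s$end > nchar(seqs[[s$ref]])) stop("segment interval out of bounds on '", s$ref, "'")
  }
  pieces <- plan_pieces(genome, construct, plan)
  sample_seq <- paste(vapply(seq_len(nrow(pieces)), function(i)
    piece_seq(seqs, pieces[i, ]), character(1)), collapse = "")

  junctions <- pieces_junctions(pieces)

  # cassette copy counts: pieces fully covering the cassette interval
  cassette_copies <- integer(0)
  if (!is.null(cassette_features) && nrow(cassette_features)) {
    cassette_copies <- vapply(seq_len(nrow(cassette_features)), function(i) {
      f <- cassette_features[i, ]
      sum(pieces$ref == f$record_id & pieces$start <= f$start & pieces$end >= f$end)
    }, integer(1))
    names(cassette_copies) <- cassette_features$label
  }

  amp <- plan$amplified
  amp_copies <- if (is.null(amp)) 2L else as.integer(amp$factor + 1L)
  amp_fold <- amp_copies / 2

  mod_id <- paste0(plan$host_id, "_integrant")
  recs <- genome$records
  recs[[mod_id]] <- seq_record(mod_id, sample_seq, "host")
  feats <- genome$features
  feats$copies[feats$record_id == plan$host_id & feats$label == "background"] <- 1
  feats <- rbind(feats, data.frame(
    record_id = mod_id, start = 0L, end = nchar(sample_seq),
    label = "background", copies = 1, stringsAsFactors = FALSE))

  truth <- list(junctions = junctions,
                cassette_copies = cassette_copies,
                amplified_fold = amp_fold,
                amplified_copies = amp_copies,
                amplified_region = amp,
                integrant_id = mod_id,
                pieces = pieces)
  list(genome = genome_set(recs, feats), truth = truth)
}

#' Write truth junctions and features as BED-like TSV
#'
#' @param truth A truth set from [apply_integration()].
#' @param path Output TSV.
#' @export
write_truth <- function(truth, path) {
  write.table(truth$junctions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
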