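# Read-depth copy number. Depth is summarized in tiling windows; the
# genome-wide modal window depth anchors the normalization: dividing by
# twice the mode puts the two-copy background at 0.5, so a region at copy
# count c sits at c/4 (one-copy 0.25, three-copy 0.75, four-copy 1.0 --
# the printed peak positions this convention is inferred from).

#' Per-window read-depth profile of one reference
#'
#' Per-base coverage from the M/D blocks of primary, unambiguous
#' alignments, averaged in tiling windows.
#'
#' @param alignments Alignment table (e.g. `pa$alignments`).
#' @param reference A [seq_record()].
#' @param window Window size (bp), >= 100.
#' @return `list(ref, window, windows, coverage, modal)` of class
#'   `depth_profile`; `windows` has 0-based `start`, `end`, `depth`;
#'   `modal` is the modal window depth of this reference.
#' @export
depth_profile <- function(alignments, reference, window = 500L) {
  if (window < 100L) stop("window must be >= 100")
  L <- nchar(reference$seq)
  aln <- alignments[alignments$ref == reference$id &
                      alignments$primary & !alignments$ambiguous, ,
                    drop = FALSE]
  cov <- if (nrow(aln)) {
    span <- cigar_ref_span(aln$cigar)
    IRanges::coverage(IRanges::IRanges(start = aln$pos + 1L, width = span),
                      width = L)
  } else {
    warning("no alignments on ", reference$id, "; zero-depth profile")
    S4Vectors::Rle(0L, L)
  }
  starts <- seq.int(0L, max(0L, L - 1L), by = window)
  ends <- pmin(starts + window, L)
  depth <- IRanges::viewMeans(IRanges::Views(cov, start = starts + 1L,
                                             end = ends))
  win <- data.frame(start = starts, end = ends, depth = as.numeric(depth))
  structure(list(ref = reference$id, window = as.integer(window),
                 windows = win, coverage = cov,
                 modal = modal_depth(win$depth)),
            class = "depth_profile")
}

#' Depth profiles over a reference set with a genome-wide mode
#'
#' @param alignments Alignment table.
#' @param references List of [seq_record()]s (or a [genome_set()]).
#' @param window Window size (bp).
#' @return `list(profiles, modal, window)` of class `depth_profile_set`;
#'   `modal` is the modal window depth across all references.
#' @export
depth_profiles <- function(alignments, references, window = 500L) {
  if (inherits(references, "genome_set")) references <- references$records
  profs <- lapply(references, function(r)
    suppressWarnings(depth_profile(alignments, r, window)))
  names(profs) <- vapply(references, `[[`, character(1), "id")
  all_depth <- unlist(lapply(profs, function(p) p$windows$depth))
  structure(list(profiles = profs, modal = modal_depth(all_depth),
                 window = as.integer(window)),
            class = "depth_profile_set")
}

# Modal window depth: kernel-density peak of the central depth mass
# (windows within [0.5, 1.6]x the median), Silverman reference bandwidth
# floored at pilot/50. Restricting to the central mass makes the estimate
# of the dominant (two-copy background) peak insensitive to the deleted,
# hemizygous and amplified minority far from it; a fixed-bin histogram mode
# would be biased by up to half a bin and flip between adjacent bins under
# resampling.
modal_depth <- function(depths, bins_per_mode = 50L) {
  d <- depths[is.finite(depths) & depths > 0]
  if (!length(d)) return(0)
  if (length(d) == 1L) return(d)
  pilot <- median(d)
  core <- d[d > 0.5 * pilot & d < 1.6 * pilot]
  if (length(core) < 2L) core <- d
  bw <- max(stats::bw.nrd0(core), pilot / bins_per_mode)
  dens <- stats::density(core, bw = bw)
  dens$x[which.max(dens$y)]
}

#' Normalize a depth profile set to the two-copy background
#'
#' Each window depth is divided by twice the genome-wide modal depth, so
#' two-copy background windows sit at 0.5 and a copy-count-c region at c/4.
#'
#' @param pset A `depth_profile_set`.
#' @return The set with a `norm` column added to every window table and a
#'   `norm_factor` field.
#' @export
normalize_depth <- function(pset) {
  stopifnot(inherits(pset, "depth_profile_set"))
  if (pset$modal <= 0) stop("modal depth is zero; cannot normalize")
  nf <- 2 * pset$modal
  pset$profiles <- lapply(pset$profiles, function(p) {
    p$windows$norm <- p$windows$depth / nf
    p
  })
  pset$norm_factor <- nf
  pset
}

#' Histogram mode of normalized window depths over selected intervals
#'
#' @param pset A normalized `depth_profile_set`.
#' @param intervals Optional `data.frame(record_id, start, end)`; windows
#'   fully inside these intervals are used (all windows when NULL).
#' @return The modal normalized depth (kernel-density-peak mode).
#' @export
normalized_mode <- function(pset, intervals = NULL) {
  stopifnot(!is.null(pset$norm_factor))
  vals <- unlist(lapply(names(pset$profiles), function(id) {
    w <- pset$profiles[[id]]$windows
    if (is.null(intervals)) return(w$norm)
    iv <- intervals[intervals$record_id == id, , drop = FALSE]
    if (!nrow(iv)) return(numeric(0))
    keep <- vapply(seq_len(nrow(w)), function(i)
      any(w$start[i] >= iv$start & w$end[i] <= iv$end), logical(1))
    w$norm[keep]
  }))
  if (!length(vals)) stop("no windows inside the given intervals")
  if (length(vals) == 1L) return(vals)
  # density-peak mode; bandwidth floored at the sample SD so that a
  # unimodal peak over a modest number of windows is located stably
  bw <- max(stats::bw.nrd0(vals), stats::sd(vals), 0.01)
  dens <- stats::density(vals, bw = bw)
  dens$x[which.max(dens$y)]
}

#' Integer copy-number estimate for a feature interval
#'
#' The feature mean is taken from per-base coverage over the exact interval
#' (window averaging would dilute short cassettes with flanking sequence at
#' a different copy count), divided by the same normalization constant;
#' copies = round(4 x mean normalized depth).
#'
#' @param pset A normalized `depth_profile_set`.
#' @param record_id Reference carrying the feature.
#' @param start,end Feature interval (0-based, half-open).
#' @param label Feature label carried into the output.
#' @return `list(label, mean_norm, copies, norm_factor)` of class
#'   `copy_number_estimate`.
#' @export
estimate_feature_copies <- function(pset, record_id, start, end,
                                    label = NA_character_) {
  stopifnot(!is.null(pset$norm_factor))
  p <- pset$profiles[[record_id]]
  if (is.null(p)) stop("feature reference '", record_id, "' not profiled")
  L <- length(p$coverage)
  if (start < 0 || end > L || start >= end)
    stop("feature interval out of bounds")
  m <- mean(as.numeric(IRanges::viewMeans(
    IRanges::Views(p$coverage, start = start + 1L, end = end))))
  mn <- m / pset$norm_factor
  structure(list(label = label, mean_norm = mn,
                 copies = as.integer(round(4 * mn)),
                 norm_factor = pset$norm_factor),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("<copy_number_estimate> %s: %.3f normalized -> %d copies\n",
              x$label, x$mean_norm, x$copies))
  invisible(x)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per sample, delta-Ct = mean Ct(target) - mean Ct(reference gene);
#' delta-delta-Ct = delta-Ct(sample) - delta-Ct(control); the fold change is
#' `2^-ddCt` (100% amplification efficiency).
#'
#' @param ct A `ct_table` (columns `sample`, `gene`, `ct`), e.g. from
#'   [simulate_qpcr()] or read from TSV.
#' @param sample_id,control_id Sample identifiers.
#' @param target_gene,reference_gene Gene identifiers.
#' @return `list(fold, ddct, dct_sample, dct_control)`.
#' @export
ddct <- function(ct, sample_id = "sample", control_id = "control",
                 target_gene = "target", reference_gene = "reference") {
  mean_ct <- function(s, g) {
    v <- ct$ct[ct$sample == s & ct$gene == g]
    if (!length(v)) stop("no Ct values for sample '", s, "', gene '", g, "'")
    mean(v)
  }
  dct_s <- mean_ct(sample_id, target_gene) - mean_ct(sample_id, reference_gene)
  dct_c <- mean_ct(control_id, target_gene) - mean_ct(control_id, reference_gene)
  dd <- dct_s - dct_c
  list(fold = 2^(-dd), ddct = dd, dct_sample = dct_s, dct_control = dct_c)
}
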