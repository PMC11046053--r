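# Sliding-window scoring with per-base aggregation. A window's score is
# assigned to every base it covers; for each base the mean, minimum and
# maximum over all covering windows are reported (edge bases keep their
# partial coverage). The scorer is pluggable: any function mapping a
# character vector of window sequences to numeric scores can stand behind
# the track, e.g. an external enhancer-activity model; the package ships a
# GC-content toy scorer.

#' Sliding window intervals
#'
#' @param length Sequence length (bp).
#' @param window Window size (bp), default 249.
#' @param stride Stride (bp), default 1.
#' @return `data.frame(start, end)` of 0-based half-open windows wholly
#'   inside the sequence; empty (with a warning) when `length < window`.
#' @export
make_windows <- function(length, window = 249L, stride = 1L) {
  if (window < 1L || stride < 1L) stop("window and stride must be >= 1")
  if (length < window) {
    warning("sequence shorter than window; no windows")
    return(data.frame(start = integer(), end = integer()))
  }
  starts <- seq.int(0L, length - window, by = stride)
  data.frame(start = starts, end = starts + window)
}

#' Aggregate window scores to per-base mean/min/max
#'
#' @param intervals `data.frame(start, end)` from [make_windows()].
#' @param scores One score per interval.
#' @param length Sequence length (bp).
#' @return `list(length, n_windows, mean, min, max, covered)` of class
#'   `window_score_track`; per-base vectors are NA where no window covers.
#' @export
aggregate_per_base <- function(intervals, scores, length) {
  if (nrow(intervals) != length(scores))
    stop("need exactly one score per interval")
  L <- as.integer(length)
  mean_v <- rep(NA_real_, L); min_v <- rep(NA_real_, L); max_v <- rep(NA_real_, L)
  if (nrow(intervals)) {
    w <- intervals$end - intervals$start
    stride1 <- nrow(intervals) > 1L &&
      all(diff(intervals$start) == 1L) && length(unique(w)) == 1L
    # coverage count and score sum by difference arrays (O(L))
    d_cnt <- numeric(L + 1L); d_sum <- numeric(L + 1L)
    i1 <- intervals$start + 1L; i2 <- intervals$end + 1L
    for (i in seq_len(nrow(intervals))) {
      d_cnt[i1[i]] <- d_cnt[i1[i]] + 1
      d_cnt[i2[i]] <- d_cnt[i2[i]] - 1
      d_sum[i1[i]] <- d_sum[i1[i]] + scores[i]
      d_sum[i2[i]] <- d_sum[i2[i]] - scores[i]
    }
    cnt <- cumsum(d_cnt)[seq_len(L)]
    covered <- cnt > 0
    mean_v[covered] <- cumsum(d_sum)[seq_len(L)][covered] / cnt[covered]
    if (stride1) {
      # base i is covered by windows start in [i-w+1, i] (clamped): a
      # sliding range over the score vector -> rolling min/max
      ww <- w[1]; nwin <- nrow(intervals)
      eff <- min(ww, nwin)
      roll_max <- zoo::rollmax(scores, eff, fill = NA, align = "right")
      roll_min <- -zoo::rollmax(-scores, eff, fill = NA, align = "right")
      for (b in seq_len(L)) {
        lo <- max(1L, b - ww + 1L)
        hi <- min(b, nwin)
        if (lo > hi) next
        if (hi - lo + 1L == eff) {
          max_v[b] <- roll_max[hi]; min_v[b] <- roll_min[hi]
        } else {
          max_v[b] <- max(scores[lo:hi]); min_v[b] <- min(scores[lo:hi])
        }
      }
    } else {
      min_v[covered] <- Inf; max_v[covered] <- -Inf
      for (i in seq_len(nrow(intervals))) {
        span <- (intervals$start[i] + 1L):intervals$end[i]
        min_v[span] <- pmin(min_v[span], scores[i])
        max_v[span] <- pmax(max_v[span], scores[i])
      }
    }
  } else {
    covered <- logical(L)
  }
  structure(list(length = L, n_windows = nrow(intervals), mean = mean_v,
                 min = min_v, max = max_v, covered = covered),
            class = "window_score_track")
}

#' Score a sequence with a pluggable window scorer
#'
#' Composition of [make_windows()], the scorer and [aggregate_per_base()].
#' The scorer receives the character vector of window sequences and must
#' return one finite numeric score per window (adapter contract for
#' external models; one-hot encoding or any featurization happens inside
#' the scorer).
#'
#' @param sequence Nucleotide string or [seq_record()].
#' @param scorer `function(character) -> numeric`.
#' @param window,stride Window geometry (bp).
#' @return A `window_score_track`.
#' @export
score_track <- function(sequence, scorer, window = 249L, stride = 1L) {
  if (inherits(sequence, "seq_record")) sequence <- sequence$seq
  L <- nchar(sequence)
  iv <- make_windows(L, window, stride)
  if (!nrow(iv)) return(aggregate_per_base(iv, numeric(0), L))
  seqs <- substring(sequence, iv$start + 1L, iv$end)
  scores <- tryCatch(scorer(seqs), error = function(e)
    stop("scorer failed on window starting at ", iv$start[1], ": ",
         conditionMessage(e)))
  if (length(scores) != nrow(iv) || !all(is.finite(scores))) {
    bad <- if (length(scores) == nrow(iv)) iv$start[!is.finite(scores)][1] else iv$start[1]
    stop("scorer returned invalid scores (window starting at ", bad, ")")
  }
  aggregate_per_base(iv, as.numeric(scores), L)
}

#' GC-content window scorer
#'
#' Toy scorer: the GC fraction of each window. Stands in for an external
#' enhancer-activity model behind the same adapter contract.
#'
#' @param seqs Character vector of window sequences.
#' @return Numeric GC fractions.
#' @export
gc_scorer <- function(seqs) {
  (nchar(seqs) - nchar(gsub("[GCgc]", "", seqs))) / nchar(seqs)
}

#' Write a per-base track as bedGraph
#'
#' @param track A `window_score_track`.
#' @param ref_id Sequence name for the first column.
#' @param path Output file.
#' @param stat One of `"mean"`, `"min"`, `"max"`.
#' @export
write_bedgraph <- function(track, ref_id, path, stat = c("mean", "min", "max")) {
  stat <- match.arg(stat)
  v <- track[[stat]]
  keep <- !is.na(v)
  df <- data.frame(ref = ref_id, start = which(keep) - 1L,
                   end = which(keep), value = v[keep])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
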