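# Shared fixtures, built once per test run and memoized; all synthetic,
# generated in code under fixed seeds.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# full discovery chain on the default integrant scenario, error-free 30x
default_run <- function() cached("default_run", {
  scen <- default_scenario(1)
  reads <- simulate_reads(scen$genome, coverage = 30, error_rate = 0, seed = 2)
  idx <- build_index(scen$references)
  pa <- align_pairs(reads, idx)
  classes <- classify_pairs(pa, scen$construct$id)
  clips <- extract_softclips(pa$alignments[pa$alignments$primary, ],
                             min_clip = 20)
  cands <- realign_clips(clips, idx)
  calls <- call_junctions(cands, min_support = 3, position_tolerance = 0)
  pset <- normalize_depth(depth_profiles(pa$alignments, scen$references, 500))
  list(scen = scen, reads = reads, idx = idx, pa = pa, classes = classes,
       cands = cands, calls = calls, pset = pset)
})

random_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent Smith-Waterman oracle: plain R dynamic program over the full
# score matrix, score only
sw_oracle <- function(query, target, match, mismatch, gap) {
  n <- nchar(query); m <- nchar(target)
  if (n == 0 || m == 0) return(0)
  q <- strsplit(query, "")[[1]]; t <- strsplit(target, "")[[1]]
  H <- matrix(0, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + ifelse(q[i - 1] == t[j - 1], match, mismatch),
                     H[i - 1, j] + gap,
                     H[i, j - 1] + gap)
    }
  }
  max(H)
}

# brute-force per-base window aggregation oracle
aggregate_oracle <- function(intervals, scores, length) {
  mean_v <- rep(NA_real_, length); min_v <- rep(NA_real_, length)
  max_v <- rep(NA_real_, length)
  for (b in seq_len(length)) {
    cover <- which(intervals$start < b & intervals$end >= b)
    if (!length(cover)) next
    mean_v[b] <- mean(scores[cover])
    min_v[b] <- min(scores[cover])
    max_v[b] <- max(scores[cover])
  }
  list(mean = mean_v, min = min_v, max = max_v)
}
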