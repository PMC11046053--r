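# End-to-end orchestration: simulate (or load) -> align -> classify ->
# junctions -> copy number -> optional genome walk -> report, deterministic
# under the config seeds. Every intermediate is written to the output
# directory in plain-text formats so a run can be resumed or any stage
# substituted (e.g. an external mapper via SAM).

default_config <- function() {
  list(
    seed = 1L,
    scenario = list(preset = "default"),
    reads = list(coverage = 30, read_len = 150L, insert_mean = 500L,
                 insert_sd = 50L, error_rate = 0),
    align = list(k = 21L, insert_max = 1000L),
    classify = list(min_clip = 20L, min_support = 5L),
    junctions = list(min_clip = 20L, min_identity = 0.95, min_support = 3L,
                     position_tolerance = 2L, min_self_distance = 150L),
    copy_number = list(window = 500L),
    walk = list(enabled = FALSE, direction = "upstream", n_cycles = 12L,
                end_window = 200L, seed_window = 1000L, min_overlap = 40L),
    truth_tolerance = 0L,
    outdir = NULL)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration
#'
#' @param config A YAML file path or a named list of overrides; missing
#'   entries fall back to package defaults.
#' @return The merged configuration list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  merge_config(default_config(), config)
}

#' Run the discovery pipeline end to end
#'
#' Builds (or loads) the inputs, aligns all pairs against the joint
#' host+construct reference set, classifies them, nominates integration
#' contigs, calls fusion junctions from soft clips, estimates cassette copy
#' numbers from normalized depth, optionally runs the genome walk, and --
#' when the scenario carries a truth set -- scores junction calls and copy
#' calls against it.
#'
#' @param config A YAML path or list (see [load_config()]). With the
#'   default scenario presets everything is simulated from `seed`;
#'   alternatively `reads$fastq1`/`reads$fastq2` and `scenario$fasta` load
#'   external inputs (no truth comparison then).
#' @return A `run_report` list.
#' @export
run_discovery <- function(config = list()) {
  cfg <- load_config(config)
  t0 <- Sys.time()
  note <- function(...) message(sprintf(...))

  # ---- inputs ----
  truth <- NULL; scen <- NULL
  if (!is.null(cfg$scenario$fasta)) {
    if (!file.exists(cfg$scenario$fasta))
      stop("reference FASTA not found: ", cfg$scenario$fasta)
    references <- read_fasta(cfg$scenario$fasta)
    construct_id <- cfg$scenario$construct_id
    if (is.null(construct_id)) stop("scenario$construct_id required with scenario$fasta")
  } else {
    scen <- switch(cfg$scenario$preset,
                   default = default_scenario(cfg$seed),
                   random = random_scenario(cfg$seed),
                   stop("unknown scenario preset: ", cfg$scenario$preset))
    references <- scen$references
    construct_id <- scen$construct$id
    truth <- scen$truth
  }
  if (!is.null(cfg$reads$fastq1)) {
    if (!file.exists(cfg$reads$fastq1) || !file.exists(cfg$reads$fastq2))
      stop("FASTQ input not found: ", cfg$reads$fastq1)
    reads <- read_fastq_pair(cfg$reads$fastq1, cfg$reads$fastq2)
  } else {
    reads <- simulate_reads(scen$genome, coverage = cfg$reads$coverage,
                            read_len = cfg$reads$read_len,
                            insert_mean = cfg$reads$insert_mean,
                            insert_sd = cfg$reads$insert_sd,
                            error_rate = cfg$reads$error_rate,
                            seed = cfg$seed)
  }
  note("inputs: %d references, %d read pairs", length(references),
       length(reads$ids))

  # ---- align ----
  index <- build_index(references, k = cfg$align$k)
  pa <- align_pairs(reads, index, insert_max = cfg$align$insert_max)
  note("aligned: %d placements, %.1f%% proper pairs", nrow(pa$alignments),
       100 * mean(pa$pairs$proper))

  # ---- classify ----
  classes <- classify_pairs(pa, construct_id,
                            min_clip = cfg$classify$min_clip)
  counts <- count_classes(classes)
  nominated <- nominate_integration_contigs(counts,
                                            min_support = cfg$classify$min_support)
  note("classes: %s",
       paste(names(counts$by_class), as.integer(counts$by_class),
             sep = "=", collapse = " "))

  # ---- junctions ----
  clips <- extract_softclips(pa$alignments[pa$alignments$primary, ],
                             min_clip = cfg$junctions$min_clip)
  cands <- realign_clips(clips, index, min_clip = cfg$junctions$min_clip,
                         min_identity = cfg$junctions$min_identity)
  calls <- call_junctions(cands, min_support = cfg$junctions$min_support,
                          position_tolerance = cfg$junctions$position_tolerance,
                          min_self_distance = cfg$junctions$min_self_distance)
  note("junctions: %d calls from %d clip candidates", nrow(calls), nrow(cands))

  # ---- copy number ----
  pset <- normalize_depth(depth_profiles(pa$alignments, references,
                                         window = cfg$copy_number$window))
  copy_tab <- NULL
  if (!is.null(scen) && !is.null(scen$construct_features)) {
    cf <- scen$construct_features
    est <- lapply(seq_len(nrow(cf)), function(i)
      estimate_feature_copies(pset, cf$record_id[i], cf$start[i], cf$end[i],
                              cf$label[i]))
    copy_tab <- data.frame(label = cf$label,
                           mean_norm = vapply(est, `[[`, numeric(1), "mean_norm"),
                           copies = vapply(est, `[[`, integer(1), "copies"))
  }

  # ---- walk (optional) ----
  walk_res <- NULL
  if (isTRUE(cfg$walk$enabled)) {
    cons <- references[[which(vapply(references, `[[`, character(1), "id") ==
                                construct_id)]]
    seed_rec <- if (cfg$walk$direction == "downstream") {
      L <- nchar(cons$seq)
      seq_record(cons$id, substr(cons$seq, max(1L, L - cfg$walk$seed_window + 1L), L),
                 "construct")
    } else cons
    wc <- walk_config(direction = cfg$walk$direction,
                      n_cycles = cfg$walk$n_cycles,
                      end_window = cfg$walk$end_window,
                      seed_window = cfg$walk$seed_window,
                      min_overlap = cfg$walk$min_overlap)
    walk_res <- walk(seed_rec, reads, wc)
    note("walk: %d cycles, %d bp extension, %s",
         length(walk_res$extensions), sum(walk_res$extensions),
         walk_res$termination)
  }

  # ---- truth comparison ----
  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- compare_to_truth(calls, truth, tolerance = cfg$truth_tolerance,
                                copy_estimates = copy_tab)
    note("truth: junction precision %.3f recall %.3f", metrics$precision,
         metrics$recall)
  }

  report <- structure(list(
    config = cfg, n_pairs = length(reads$ids),
    class_counts = as.list(counts$by_class), by_mate = counts$by_mate,
    by_ref = counts$by_ref, nominated = nominated, junctions = calls,
    copy_estimates = copy_tab, modal_depth = pset$modal,
    walk = if (!is.null(walk_res))
      list(cycles = length(walk_res$extensions),
           extension = sum(walk_res$extensions),
           termination = walk_res$termination),
    truth_metrics = metrics,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")

  if (!is.null(cfg$outdir)) write_report(report, pa, scen, reads, cfg$outdir)
  report
}

#' Compare junction calls (and copy calls) to a truth set
#'
#' A call matches a truth junction when reference pair and orientation
#' agree and both breakpoints are within `tolerance`.
#'
#' @param calls A `junction_calls` table.
#' @param truth A truth set from [apply_integration()] (needs a nonempty
#'   `junctions` table).
#' @param tolerance Positional tolerance (bp).
#' @param copy_estimates Optional `data.frame(label, copies)` to score
#'   against the truth cassette copies.
#' @return `list(precision, recall, n_calls, n_truth, copy_accuracy)`.
#' @export
compare_to_truth <- function(calls, truth, tolerance = 0L,
                             copy_estimates = NULL) {
  tj <- truth$junctions
  if (!nrow(tj)) stop("truth junction list is empty")
  match_one <- function(ra, pa_, rb, pb, or) {
    any(tj$ref_a == ra & tj$ref_b == rb & tj$orientation == or &
          abs(tj$pos_a - pa_) <= tolerance & abs(tj$pos_b - pb) <= tolerance)
  }
  matched_call <- if (nrow(calls)) vapply(seq_len(nrow(calls)), function(i)
    match_one(calls$ref_a[i], calls$pos_a[i], calls$ref_b[i], calls$pos_b[i],
              calls$orientation[i]), logical(1)) else logical(0)
  matched_truth <- vapply(seq_len(nrow(tj)), function(i) {
    if (!nrow(calls)) return(FALSE)
    any(calls$ref_a == tj$ref_a[i] & calls$ref_b == tj$ref_b[i] &
          calls$orientation == tj$orientation[i] &
          abs(calls$pos_a - tj$pos_a[i]) <= tolerance &
          abs(calls$pos_b - tj$pos_b[i]) <= tolerance)
  }, logical(1))
  copy_acc <- NULL
  if (!is.null(copy_estimates) && length(truth$cassette_copies)) {
    i <- match(names(truth$cassette_copies), copy_estimates$label)
    ok <- !is.na(i)
    copy_acc <- mean(copy_estimates$copies[i[ok]] ==
                       unname(truth$cassette_copies[ok]))
  }
  list(precision = if (nrow(calls)) mean(matched_call) else NA_real_,
       recall = mean(matched_truth),
       n_calls = nrow(calls), n_truth = nrow(tj),
       copy_accuracy = copy_acc)
}

write_report <- function(report, pa, scen, reads, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(scen)) {
    write_fasta(scen$references, file.path(outdir, "references.fasta"))
    write_fasta(scen$genome, file.path(outdir, "sample_genome.fasta"))
    write_truth(scen$truth, file.path(outdir, "truth_junctions.tsv"))
  }
  write_fastq(reads, file.path(outdir, "reads"))
  write_sam(pa, file.path(outdir, "alignments.sam"))
  write.table(report$by_ref, file.path(outdir, "contig_support.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_junctions(report$junctions, file.path(outdir, "junctions.tsv"))
  if (!is.null(report$copy_estimates))
    write.table(report$copy_estimates, file.path(outdir, "copy_estimates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  json <- report
  json$config <- NULL
  json$junctions <- as.data.frame(report$junctions)
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  pairs:", x$n_pairs, "\n")
  cat("  classes:", paste(names(x$class_counts), unlist(x$class_counts),
                          sep = "=", collapse = " "), "\n")
  cat("  nominated contigs:", paste(x$nominated, collapse = ", "), "\n")
  cat("  junctions:", nrow(x$junctions), "\n")
  if (!is.null(x$truth_metrics))
    cat(sprintf("  truth: precision %.3f recall %.3f\n",
                x$truth_metrics$precision, x$truth_metrics$recall))
  invisible(x)
}
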