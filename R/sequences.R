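#' Named nucleotide sequence with a role
#'
#' The basic sequence container used throughout the package: a host contig,
#' the expression construct, or an assembled contig produced by the genome
#' walk.
#'
#' @param id Unique sequence identifier.
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param role One of `"host"`, `"construct"`, `"assembled"`.
#' @return An object of class `seq_record` with fields `id`, `seq`, `role`.
#' @export
seq_record <- function(id, sequence, role = c("host", "construct", "assembled")) {
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("sequence must be nonempty")
  if (grepl("[^ACGTN]", sequence)) stop("sequence alphabet restricted to A,C,G,T,N")
  structure(list(id = id, seq = sequence, role = role), class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s [%s], %d bp\n", x$id, x$role, nchar(x$seq)))
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$seq)

#' A set of sequence records with interval features
#'
#' @param records List of [seq_record()] objects with unique ids.
#' @param features `data.frame` with columns `record_id`, `start`, `end`
#'   (0-based, half-open), `label`, `copies` (planned copy count of the
#'   interval in the sampled genome; the diploid-like background is 2).
#' @return An object of class `genome_set`.
#' @export
genome_set <- function(records, features = NULL) {
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("record ids must be unique")
  names(records) <- ids
  if (is.null(features)) {
    features <- data.frame(record_id = character(), start = integer(),
                           end = integer(), label = character(),
                           copies = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("record_id", "start", "end", "label", "copies") %in% names(features)))
  if (nrow(features)) {
    len <- vapply(features$record_id, function(i) nchar(records[[i]]$seq), numeric(1))
    if (any(features$start < 0 | features$end > len | features$start >= features$end))
      stop("feature intervals must lie within record bounds with start < end")
  }
  structure(list(records = records, features = features), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("<genome_set> %d records, %d features\n",
              length(x$records), nrow(x$features)))
  invisible(x)
}

gs_seq <- function(genome, id) {
  r <- genome$records[[id]]
  if (is.null(r)) stop("no record '", id, "' in genome set")
  r$seq
}

gs_lengths <- function(genome) {
  vapply(genome$records, function(r) nchar(r$seq), numeric(1))
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) vapply(x, revcomp_cpp, character(1), USE.NAMES = FALSE)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- FASTA / FASTQ interop (Biostrings) -------------------------------------

#' Write sequence records to FASTA
#'
#' @param records List of [seq_record()] objects or a [genome_set()].
#' @param path Output file.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "genome_set")) records <- records$records
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- Biostrings::DNAStringSet(vapply(records, function(r) r$seq, character(1)))
  names(seqs) <- vapply(records, function(r) r$id, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file into sequence records
#'
#' @param path FASTA file.
#' @param role Role assigned to every record read.
#' @return List of [seq_record()] objects.
#' @export
read_fasta <- function(path, role = "host") {
  seqs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    seq_record(names(seqs)[i], as.character(seqs[[i]]), role)
  })
}

#' Write a paired read set to FASTQ files
#'
#' Mates are written to `<prefix>_1.fastq` and `<prefix>_2.fastq` with `/1`
#' and `/2` id suffixes and uniform quality.
#'
#' @param reads A paired read set from [simulate_reads()].
#' @param prefix Output path prefix.
#' @export
write_fastq <- function(reads, prefix) {
  for (mate in 1:2) {
    s <- Biostrings::DNAStringSet(if (mate == 1) reads$r1 else reads$r2)
    names(s) <- paste0(reads$ids, "/", mate)
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(s)))
    Biostrings::writeQualityScaledXStringSet(
      Biostrings::QualityScaledDNAStringSet(s, Biostrings::PhredQuality(q)),
      sprintf("%s_%d.fastq", prefix, mate))
  }
  invisible(prefix)
}

#' Read paired FASTQ files
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return A paired read set (list with `r1`, `r2`, `ids`).
#' @export
read_fastq_pair <- function(path1, path2) {
  s1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(s1) != length(s2)) stop("mate files differ in read count")
  ids <- sub("/[12]$", "", names(s1))
  list(r1 = unname(as.character(s1)), r2 = unname(as.character(s2)),
       ids = ids)
}
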