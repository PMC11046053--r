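# Informative-read classification: every aligned pair is assigned exactly
# one class. Isolateral pairs sit wholly on the construct; flanking pairs
# split their mates between construct and a host contig; chimeric reads
# carry a soft clip that re-aligns to a different reference (base-resolution
# junction evidence); homologous pairs are ambiguous between construct and
# host because of shared sequence (e.g. the GS selection marker). Precedence
# when several criteria fire: CHIMERIC > FLANKING > HOMOLOGOUS > ISOLATERAL
# > NON_INFORMATIVE, so junction-resolving evidence is never absorbed by a
# coarser class.

INFORMATIVE_CLASSES <- c("CHIMERIC", "FLANKING", "HOMOLOGOUS", "ISOLATERAL",
                         "NON_INFORMATIVE")

#' Classify aligned read pairs into informative categories
#'
#' @param pa A `pair_alignments` object from [align_pairs()] (both mates
#'   aligned against the joint host+construct reference set).
#' @param construct_id Reference id of the construct.
#' @param min_clip Minimum soft-clip length for the chimeric criterion (bp).
#' @return `data.frame(read_id, class, host_ref)` of class
#'   `informative_classes`; `host_ref` names the host contig supporting a
#'   FLANKING or CHIMERIC call (NA otherwise).
#' @export
classify_pairs <- function(pa, construct_id, min_clip = 20L) {
  stopifnot(inherits(pa, "pair_alignments"))
  aln <- pa$alignments
  ids <- pa$pairs$read_id
  if (!nrow(aln)) {
    return(structure(data.frame(read_id = ids, class = "NON_INFORMATIVE",
                                host_ref = NA_character_,
                                stringsAsFactors = FALSE),
                     class = c("informative_classes", "data.frame")))
  }
  key <- paste(aln$read_id, aln$mate)
  is_c <- aln$ref == construct_id
  has_c <- rowsum(as.integer(is_c), key) > 0L
  has_h <- rowsum(as.integer(!is_c), key) > 0L
  prim <- aln[aln$primary, , drop = FALSE]
  pkey <- paste(prim$read_id, prim$mate)

  info <- function(mate) {
    k <- paste(ids, mate)
    i <- match(k, pkey)
    mapped <- !is.na(i)
    n_opt <- ifelse(mapped, prim$n_opt[i], 0L)
    list(mapped = mapped,
         ref = ifelse(mapped, prim$ref[i], NA_character_),
         uniq = mapped & n_opt == 1L,
         construct_only = mapped & !has_h[match(k, rownames(has_h))],
         mixed_amb = mapped & n_opt >= 2L &
           has_c[match(k, rownames(has_c))] & has_h[match(k, rownames(has_h))])
  }
  m1 <- info("R1"); m2 <- info("R2")

  # chimeric: a terminal soft clip whose re-alignment lands on a different
  # reference than the matched block
  clips <- extract_softclips(prim, min_clip = min_clip)
  chim_host <- rep(NA_character_, length(ids))
  chim <- rep(FALSE, length(ids))
  if (nrow(clips)) {
    cand <- realign_clips(clips, pa$index, min_clip = min_clip)
    if (nrow(cand)) {
      cross <- cand[cand$anchor_ref != cand$hit_ref, , drop = FALSE]
      if (nrow(cross)) {
        i <- match(ids, cross$read_id)
        chim <- !is.na(i)
        hr <- ifelse(cross$anchor_ref != construct_id, cross$anchor_ref,
                     cross$hit_ref)
        chim_host <- ifelse(chim, ifelse(hr[i] == construct_id,
                                         NA_character_, hr[i]),
                            NA_character_)
      }
    }
  }

  flank_c1 <- m1$uniq & m1$ref == construct_id & m2$uniq & m2$ref != construct_id
  flank_c2 <- m2$uniq & m2$ref == construct_id & m1$uniq & m1$ref != construct_id
  flanking <- (flank_c1 | flank_c2) %in% TRUE
  flank_host <- ifelse(flank_c1 %in% TRUE, m2$ref,
                       ifelse(flank_c2 %in% TRUE, m1$ref, NA_character_))
  homologous <- (m1$mixed_amb | m2$mixed_amb) %in% TRUE
  isolateral <- (m1$construct_only & m2$construct_only) %in% TRUE

  cls <- rep("NON_INFORMATIVE", length(ids))
  cls[isolateral] <- "ISOLATERAL"
  cls[homologous] <- "HOMOLOGOUS"
  cls[flanking] <- "FLANKING"
  cls[chim] <- "CHIMERIC"
  host_ref <- rep(NA_character_, length(ids))
  host_ref[cls == "FLANKING"] <- flank_host[cls == "FLANKING"]
  host_ref[cls == "CHIMERIC"] <- chim_host[cls == "CHIMERIC"]

  out <- data.frame(read_id = ids, class = cls, host_ref = host_ref,
                    r1_mapped = m1$mapped, r2_mapped = m2$mapped,
                    stringsAsFactors = FALSE)
  structure(out, class = c("informative_classes", "data.frame"))
}

#' Tally informative-read classes
#'
#' Exhaustive, mutually exclusive tally of classified pairs, with per-mate
#' counts (so the isolateral R1 = R2 symmetry can be checked) and
#' per-host-contig support for the junction-bearing classes.
#'
#' @param classes Output of [classify_pairs()].
#' @return `list(by_class, by_mate, by_ref, total)`.
#' @export
count_classes <- function(classes) {
  by_class <- table(factor(classes$class, levels = INFORMATIVE_CLASSES))
  by_mate <- do.call(rbind, lapply(INFORMATIVE_CLASSES, function(cl) {
    w <- classes$class == cl
    data.frame(class = cl, r1 = sum(classes$r1_mapped[w]),
               r2 = sum(classes$r2_mapped[w]), stringsAsFactors = FALSE)
  }))
  w <- classes$class %in% c("FLANKING", "CHIMERIC") & !is.na(classes$host_ref)
  by_ref <- if (any(w)) {
    tab <- table(classes$host_ref[w],
                 factor(classes$class[w], levels = c("FLANKING", "CHIMERIC")))
    df <- data.frame(ref = rownames(tab),
                     flanking = as.integer(tab[, "FLANKING"]),
                     chimeric = as.integer(tab[, "CHIMERIC"]),
                     stringsAsFactors = FALSE)
    df$support <- df$flanking + df$chimeric
    df[order(-df$support, df$ref), , drop = FALSE]
  } else {
    data.frame(ref = character(), flanking = integer(), chimeric = integer(),
               support = integer(), stringsAsFactors = FALSE)
  }
  list(by_class = by_class, by_mate = by_mate, by_ref = by_ref,
       total = nrow(classes))
}

#' Nominate candidate integration contigs
#'
#' Host contigs ranked by combined flanking + chimeric pair support.
#'
#' @param counts Output of [count_classes()].
#' @param min_support Minimum pair support to nominate.
#' @return Character vector of host contig ids, best-supported first.
#' @export
nominate_integration_contigs <- function(counts, min_support = 5L) {
  if (min_support < 1L) stop("min_support must be >= 1")
  tab <- counts$by_ref
  tab$ref[tab$support >= min_support]
}
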