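#' Curation configuration
#'
#' Defaults mirror the study conditions: positives require at least 100
#' supporting alignments, chromosomes 1 and 9 are held out for testing,
#' negatives are downsampled to three per positive, and pseudo-junctions draw
#' their initial intron length uniformly from \[200, 20000\] with 20
#' generation attempts per gene locus.
#'
#' @param min_support Minimum alignment support for positives (inclusive).
#' @param held_out_contigs Contigs reserved for the test partition.
#' @param negative_to_positive_ratio Negatives sampled per positive for
#'   training.
#' @param pseudo_intron_length_range Inclusive range of the random initial
#'   intron length for pseudo-junction generation.
#' @param attempts_per_locus Pseudo-junction attempts per gene locus.
#' @param seed RNG seed for all sampling in curation.
#' @return An object of class `curation_config`.
#' @export
curation_config <- function(min_support = 100L,
                            held_out_contigs = c("chr1", "chr9"),
                            negative_to_positive_ratio = 3L,
                            pseudo_intron_length_range = c(200L, 20000L),
                            attempts_per_locus = 20L,
                            seed = 1L) {
  stopifnot(negative_to_positive_ratio >= 1,
            pseudo_intron_length_range[1] >= 1,
            diff(pseudo_intron_length_range) >= 0)
  structure(list(min_support = as.integer(min_support),
                 held_out_contigs = held_out_contigs,
                 negative_to_positive_ratio = as.integer(negative_to_positive_ratio),
                 pseudo_intron_length_range = as.integer(pseudo_intron_length_range),
                 attempts_per_locus = as.integer(attempts_per_locus),
                 seed = seed),
            class = "curation_config")
}

#' Build the two positive junction classes
#'
#' Positive-main junctions are supported junctions present in the main
#' (single-canonical-isoform) annotation; positive-alt junctions are
#' supported junctions present only in the alternative annotation.  Both may
#' additionally be restricted to junctions overlapping protein-coding loci.
#'
#' @param supported Support-filtered alignment junctions
#'   ([filter_by_support()]).
#' @param main_annotation,alt_annotation Junction frames of annotated introns.
#' @param coding_loci Optional [gene_loci()] frame; when given, positives must
#'   overlap a locus.
#' @return List with elements `positive_main` and `positive_alt`
#'   (disjoint [junction_frame()]s with labels set).
#' @export
build_positive_sets <- function(supported, main_annotation, alt_annotation,
                                coding_loci = NULL) {
  sk <- junction_key(supported)
  if (!is.null(coding_loci) && nrow(supported)) {
    ov <- overlaps_locus(supported, coding_loci)
    supported <- supported[ov, , drop = FALSE]
    sk <- sk[ov]
  }
  mk <- junction_key(main_annotation)
  ak <- junction_key(alt_annotation)
  pm <- supported[sk %in% mk, , drop = FALSE]
  pa <- supported[sk %in% setdiff(ak, mk), , drop = FALSE]
  if (nrow(pm)) pm$label <- "positive-main"
  if (nrow(pa)) pa$label <- "positive-alt"
  list(positive_main = pm, positive_alt = pa)
}

# junctions overlapping >= 1 locus (any strand)
overlaps_locus <- function(junctions, loci) {
  if (!nrow(junctions)) return(logical(0))
  jr <- GenomicRanges::GRanges(junctions$contig,
                               IRanges::IRanges(junctions$start + 1L,
                                                junctions$end))
  lr <- GenomicRanges::GRanges(loci$contig,
                               IRanges::IRanges(loci$start + 1L, loci$end))
  IRanges::overlapsAny(jr, lr)
}

# for each junction, strands of all overlapping loci
locus_strands <- function(junctions, loci) {
  jr <- GenomicRanges::GRanges(junctions$contig,
                               IRanges::IRanges(junctions$start + 1L,
                                                junctions$end))
  lr <- GenomicRanges::GRanges(loci$contig,
                               IRanges::IRanges(loci$start + 1L, loci$end))
  hits <- GenomicRanges::findOverlaps(jr, lr)
  split(loci$strand[S4Vectors::subjectHits(hits)],
        factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(junctions))))
}

#' Build the Negative-1 class
#'
#' Junctions supported by exactly one alignment whose strand is opposite to
#' every overlapping protein-coding locus.  Such junctions resemble splicing
#' noise: they have (minimal) alignment evidence but lie antisense to a known
#' gene.
#'
#' @param all_alignment_junctions Junction frame with support counts (not
#'   support-filtered).
#' @param coding_loci A stranded [gene_loci()] frame.
#' @return A [junction_frame()] labelled `"negative-1"`.
#' @export
build_negative_one <- function(all_alignment_junctions, coding_loci) {
  j <- all_alignment_junctions
  j <- j[j$support == 1L & j$strand %in% c("+", "-"), , drop = FALSE]
  if (!nrow(j)) { j$label <- character(0); return(j) }
  st <- locus_strands(j, coding_loci)
  opp <- vapply(seq_len(nrow(j)), function(i) {
    s <- st[[i]]
    length(s) > 0 && all(s != j$strand[i])
  }, logical(1))
  out <- j[opp, , drop = FALSE]
  if (nrow(out)) out$label <- "negative-1"
  rownames(out) <- NULL
  out
}

# positions (0-based) of a 2-mer on a contig, cached per call environment
dinuc_positions <- function(genome, contig, motif, cache) {
  key <- paste(contig, motif)
  if (!is.null(cache[[key]])) return(cache[[key]])
  hits <- gregexpr(motif, genome$seqs[[contig]], fixed = TRUE)[[1]]
  pos <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
  cache[[key]] <- pos
  pos
}

#' Generate pseudo-junctions on the strand opposite to gene loci
#'
#' Implements the four-step per-attempt procedure: pick the strand opposite
#' the locus; draw a random start inside the locus; scan forward on the
#' genome for the donor-side dinucleotide (`GT` for a `+` target,
#' `CT` for `-`); draw a random intron length from
#' `config$pseudo_intron_length_range` and jump forward by that amount; scan
#' forward for the acceptor-side dinucleotide (`AG` / `AC`).  A failed scan
#' aborts the attempt.  At most `config$attempts_per_locus` attempts are made
#' per locus.  Deterministic under `config$seed`.
#'
#' @param genome A [genome_handle()].
#' @param coding_loci A stranded [gene_loci()] frame.
#' @param config A [curation_config()].
#' @return A deduplicated [junction_frame()] labelled `"negative-random"`,
#'   with attribute `"attempts"` = c(total, failed).
#' @export
generate_pseudo_junctions <- function(genome, coding_loci,
                                      config = curation_config()) {
  genome <- genome_handle(genome)
  cache <- new.env(parent = emptyenv())
  lo <- config$pseudo_intron_length_range[1]
  hi <- config$pseudo_intron_length_range[2]
  res <- list(); total <- 0L; failed <- 0L
  with_seed(config$seed, {
    for (i in seq_len(nrow(coding_loci))) {
      contig <- coding_loci$contig[i]
      if (!contig %in% names(genome$seqs)) next
      target <- if (coding_loci$strand[i] == "+") "-" else "+"
      don_motif <- if (target == "+") "GT" else "CT"
      acc_motif <- if (target == "+") "AG" else "AC"
      dpos <- dinuc_positions(genome, contig, don_motif, cache)
      apos <- dinuc_positions(genome, contig, acc_motif, cache)
      ls <- coding_loci$start[i]; le <- coding_loci$end[i]
      for (a in seq_len(config$attempts_per_locus)) {
        total <- total + 1L
        p0 <- ls + sample.int(max(le - ls, 1L), 1L) - 1L
        di <- findInterval(p0 - 1L, dpos) + 1L   # first donor pos >= p0
        if (di > length(dpos)) { failed <- failed + 1L; next }
        d <- dpos[di]
        len <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        ai <- findInterval(d + len - 1L, apos) + 1L  # first acceptor pos >= d+len
        if (ai > length(apos)) { failed <- failed + 1L; next }
        aend <- apos[ai] + 2L                     # junction end past the 2-mer
        res[[length(res) + 1L]] <-
          data.frame(contig = contig, start = d, end = aend, strand = target,
                     stringsAsFactors = FALSE)
      }
    }
  })
  df <- do.call(rbind, res)
  if (is.null(df) || !nrow(df)) {
    out <- junction_frame()
  } else {
    df <- df[!duplicated(paste(df$contig, df$start, df$end, df$strand)), ,
             drop = FALSE]
    df <- df[order(df$contig, df$start, df$end), , drop = FALSE]
    out <- junction_frame(contig = df$contig, start = df$start, end = df$end,
                          strand = df$strand, support = 0L,
                          source = "generated", label = "negative-random")
  }
  attr(out, "attempts") <- c(total = total, failed = failed)
  out
}

#' Build the Negative-Random class
#'
#' Random canonical GT-AG pairs antisense to protein-coding loci that do not
#' coincide with any known junction.  Uses the pseudo-junction generator and
#' removes generated junctions matching `known` keys.
#'
#' @inheritParams generate_pseudo_junctions
#' @param known Optional [junction_frame()] of known junctions to exclude.
#' @return A [junction_frame()] labelled `"negative-random"`.
#' @export
build_negative_random <- function(genome, coding_loci,
                                  config = curation_config(), known = NULL) {
  out <- generate_pseudo_junctions(genome, coding_loci, config)
  if (!is.null(known) && nrow(out)) {
    keep <- !junction_key(out, stranded = FALSE) %in%
      junction_key(known, stranded = FALSE)
    att <- attr(out, "attempts")
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "attempts") <- att
  }
  out
}

#' Chromosome-held-out split with negative downsampling
#'
#' Junctions on the held-out contigs form the test partition (minus any
#' caller-supplied exclusion list, e.g. externally detected paralogs); the
#' remainder is the training partition, in which negatives are downsampled to
#' `negative_to_positive_ratio` per positive with the seeded RNG.
#'
#' @param positive_main,positive_alt,negative_one,negative_random The four
#'   labelled junction classes.
#' @param config A [curation_config()].
#' @param exclude Optional [junction_frame()] whose keys are removed from the
#'   test partition.
#' @return An object of class `labeled_junctions`: list with `train`, `test`
#'   and `counts`.
#' @export
split_and_sample <- function(positive_main, positive_alt, negative_one,
                             negative_random, config = curation_config(),
                             exclude = NULL) {
  all <- rbind(positive_main, positive_alt, negative_one, negative_random)
  if (anyDuplicated(junction_key(all)))
    warning("class lists are not disjoint on (contig,start,end,strand)")
  is_test <- all$contig %in% config$held_out_contigs
  test <- all[is_test, , drop = FALSE]
  train <- all[!is_test, , drop = FALSE]
  if (!is.null(exclude) && nrow(test))
    test <- test[!junction_key(test) %in% junction_key(exclude), , drop = FALSE]
  pos <- startsWith(train$label, "positive")
  n_pos <- sum(pos)
  n_neg_want <- config$negative_to_positive_ratio * n_pos
  neg_idx <- which(!pos)
  if (length(neg_idx) > n_neg_want) {
    keep <- with_seed(config$seed, sort(sample(neg_idx, n_neg_want)))
    train <- train[sort(c(which(pos), keep)), , drop = FALSE]
  } else if (length(neg_idx) < n_neg_want) {
    warning(sprintf(
      "only %d negatives available for %d positives (wanted ratio %d); using all",
      length(neg_idx), n_pos, config$negative_to_positive_ratio))
  }
  rownames(train) <- rownames(test) <- NULL
  structure(list(train = train, test = test,
                 counts = rbind(train = table(factor(train$label, levels = label_levels())),
                                test = table(factor(test$label, levels = label_levels())))),
            class = "labeled_junctions")
}

label_levels <- function() c("positive-main", "positive-alt", "negative-1",
                             "negative-random", "unlabeled")

#' @export
print.labeled_junctions <- function(x, ...) {
  cat("labeled_junctions\n")
  print(x$counts)
  invisible(x)
}

#' Tally donor/acceptor dinucleotides
#'
#' Counts the (first two intronic, last two intronic) base pairs of each
#' junction in its own transcription sense, and the fraction of canonical
#' GT-AG junctions.
#'
#' @param junctions A [junction_frame()].
#' @param genome A [genome_handle()].
#' @return List with `tally` (data frame: `donor`, `acceptor`, `count`,
#'   sorted by decreasing count) and `canonical_fraction`.
#' @export
dinucleotide_tally <- function(junctions, genome) {
  genome <- genome_handle(genome)
  if (!nrow(junctions))
    return(list(tally = data.frame(donor = character(), acceptor = character(),
                                   count = integer(), stringsAsFactors = FALSE),
                canonical_fraction = NA_real_))
  donor <- character(nrow(junctions))
  acceptor <- character(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    if (junctions$strand[i] == "-") {
      donor[i] <- fetch_window(genome, junctions$contig[i],
                               junctions$end[i] - 2L, junctions$end[i], "-")
      acceptor[i] <- fetch_window(genome, junctions$contig[i],
                                  junctions$start[i], junctions$start[i] + 2L,
                                  "-")
    } else {
      donor[i] <- fetch_window(genome, junctions$contig[i],
                               junctions$start[i], junctions$start[i] + 2L)
      acceptor[i] <- fetch_window(genome, junctions$contig[i],
                                  junctions$end[i] - 2L, junctions$end[i])
    }
  }
  tab <- as.data.frame(table(donor = donor, acceptor = acceptor),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3] <- "count"
  tab <- tab[order(-tab$count), , drop = FALSE]
  rownames(tab) <- NULL
  list(tally = tab,
       canonical_fraction = sum(donor == "GT" & acceptor == "AG") /
         nrow(junctions))
}
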