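#' Identify spurious junction keys
#'
#' Junction keys (contig:start:end, strand-free, since an alignment's N
#' operation may carry no strand tag) whose junction score falls below the
#' threshold.
#'
#' @param scored Result of [score_junctions()].
#' @param threshold Score cutoff; junctions with score `< threshold` are
#'   spurious.  The default 0.1 matches the cutoff used in the alignment
#'   filtering analyses.
#' @return Character vector of keys.
#' @export
spurious_set <- function(scored, threshold = 0.1) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  keys <- junction_key(scored, stranded = FALSE)
  keys[!is.na(scored$junction_score) & scored$junction_score < threshold]
}

#' Remove alignments containing spurious junctions
#'
#' Any alignment containing any spurious splice junction (exact
#' contig:start:end match on its CIGAR N operations) is removed.  If the
#' removed alignment was paired, its retained mate is unpaired: flag bits
#' 0x1, 0x2, 0x8, 0x20, 0x40, 0x80 are cleared and the mate
#' reference/position/template-length fields reset.  If the removed
#' alignment's read is multi-mapped, the NH tag of its surviving alignments
#' is decremented by the number of that read's removed alignments.  The kept
#' output is coordinate-sorted.
#'
#' @param alignments Alignment data frame from [read_alignments()], or a
#'   SAM/BAM path.
#' @param spurious Character keys from [spurious_set()] (or a junction
#'   frame).
#' @param kept_path,discarded_path Optional output paths (`.sam` or `.bam`).
#' @return An object of class `clean_report`: list with `scanned`, `kept`,
#'   `removed`, `mates_unpaired`, `nh_updated`, `n_spurious`, and the
#'   modified `kept` / `discarded` record tables.
#' @export
clean_alignments <- function(alignments, spurious, kept_path = NULL,
                             discarded_path = NULL) {
  rec <- if (is.character(alignments)) read_alignments(alignments) else alignments
  hdr <- attr(rec, "header")
  if (is.data.frame(spurious))
    spurious <- junction_key(spurious, stranded = FALSE)
  spurious <- unique(spurious)
  n <- nrow(rec)
  removed <- logical(n)
  if (n && length(spurious)) {
    cand <- which(grepl("N", rec$cigar, fixed = TRUE) &
                    !has_flag(rec$flag, FLAG_UNMAPPED))
    for (i in cand) {
      iv <- cigar_introns(rec$pos[i], rec$cigar[i])
      if (!is.null(iv) &&
          any(paste(rec$rname[i], iv$start, iv$end, sep = ":") %in% spurious))
        removed[i] <- TRUE
    }
  }

  # NH repair: one read end = (qname, first/second-in-pair bit)
  end_bit <- bitwAnd(rec$flag, bitwOr(FLAG_FIRST, FLAG_SECOND))
  rkey <- paste(rec$qname, end_bit)
  nh_updated <- 0L
  if (any(removed)) {
    rem_per_read <- table(rkey[removed])
    surv <- which(!removed & rkey %in% names(rem_per_read) & !is.na(rec$nh))
    if (length(surv)) {
      dec <- as.integer(rem_per_read[rkey[surv]])
      rec$nh[surv] <- pmax(rec$nh[surv] - dec, 1L)
      nh_updated <- length(surv)
    }
  }

  # mate unpairing: clear pairing-related bits on surviving mates of removed
  # paired alignments
  mates_unpaired <- 0L
  if (any(removed)) {
    rem_paired <- which(removed & has_flag(rec$flag, FLAG_PAIRED))
    if (length(rem_paired)) {
      # the mate of record i is the alignment of the other read end located
      # where i points (rnext/pnext)
      mate_rname <- ifelse(rec$rnext[rem_paired] == "=",
                           rec$rname[rem_paired], rec$rnext[rem_paired])
      mate_bit <- ifelse(end_bit[rem_paired] == FLAG_FIRST, FLAG_SECOND,
                         ifelse(end_bit[rem_paired] == FLAG_SECOND,
                                FLAG_FIRST, 0L))
      want <- paste(rec$qname[rem_paired], mate_bit, mate_rname,
                    rec$pnext[rem_paired])
      have <- paste(rec$qname, end_bit, rec$rname, rec$pos)
      hit <- which(!removed & have %in% want)
      if (length(hit)) {
        unpair_mask <- bitwNot(bitwOr(bitwOr(bitwOr(FLAG_PAIRED, FLAG_PROPER),
                                             bitwOr(FLAG_MATE_UNMAPPED,
                                                    FLAG_MATE_REVERSE)),
                                      bitwOr(FLAG_FIRST, FLAG_SECOND)))
        rec$flag[hit] <- bitwAnd(rec$flag[hit], unpair_mask)
        rec$rnext[hit] <- "*"
        rec$pnext[hit] <- -1L
        rec$tlen[hit] <- 0L
        mates_unpaired <- length(hit)
      }
    }
  }

  kept <- rec[!removed, , drop = FALSE]
  discarded <- rec[removed, , drop = FALSE]
  if (nrow(kept))
    kept <- kept[order(kept$rname, kept$pos), , drop = FALSE]
  rownames(kept) <- rownames(discarded) <- NULL
  attr(kept, "header") <- hdr
  attr(discarded, "header") <- hdr
  if (!is.null(kept_path)) write_alignments(kept, kept_path, hdr)
  if (!is.null(discarded_path)) write_alignments(discarded, discarded_path, hdr)
  structure(list(scanned = n, kept = nrow(kept), removed = nrow(discarded),
                 mates_unpaired = mates_unpaired, nh_updated = nh_updated,
                 n_spurious = length(spurious),
                 kept_records = kept, discarded_records = discarded),
            class = "clean_report")
}

#' @export
print.clean_report <- function(x, ...) {
  cat(sprintf("clean_report: scanned %d, kept %d, removed %d\n",
              x$scanned, x$kept, x$removed))
  cat(sprintf("  mates unpaired %d, NH tags updated %d, spurious keys %d\n",
              x$mates_unpaired, x$nh_updated, x$n_spurious))
  invisible(x)
}

#' Extract, score and clean in one call
#'
#' The three-step alignment-cleaning workflow: extract junctions from the
#' alignments, score them with the model, and remove every alignment
#' containing a junction scoring below the threshold.
#'
#' @param alignments SAM/BAM path or record table.
#' @param genome A [genome_handle()] or FASTA path.
#' @param model A trained `splice_net` or checkpoint path.
#' @param threshold Junction-score cutoff (default 0.1).
#' @param out_dir When given, writes `cleaned.sam`/`discarded.sam` (or
#'   `.bam` when the input was BAM), the junction BED and the report JSON
#'   there.
#' @return A `clean_report` (see [clean_alignments()]) with the scored
#'   junction table attached as `scores`.
#' @export
clean_bam <- function(alignments, genome, model, threshold = 0.1,
                      out_dir = NULL) {
  rec <- if (is.character(alignments)) read_alignments(alignments) else alignments
  genome <- genome_handle(genome)
  junc <- junctions_from_alignments(rec, genome)
  scored <- score_junctions(junc, genome, model)
  bad <- spurious_set(scored, threshold)
  ext <- if (is.character(alignments) &&
             grepl("\\.bam$", alignments, ignore.case = TRUE)) ".bam" else ".sam"
  kp <- dp <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_junction_bed(junc, file.path(out_dir, "junction.bed"))
    write_scored_bed(scored, file.path(out_dir, "junction.scored.bed"))
    kp <- file.path(out_dir, paste0("cleaned", ext))
    dp <- file.path(out_dir, paste0("discarded", ext))
  }
  rep <- clean_alignments(rec, bad, kp, dp)
  rep$scores <- scored
  rep$threshold <- threshold
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(scanned = rep$scanned, kept = rep$kept, removed = rep$removed,
           mates_unpaired = rep$mates_unpaired, nh_updated = rep$nh_updated,
           n_spurious = rep$n_spurious, threshold = threshold),
      file.path(out_dir, "clean_report.json"), auto_unbox = TRUE)
  }
  rep
}

#' Intron-level precision and recall
#'
#' Exact set comparison of unique (contig, start, end, strand) introns:
#' TP = introns present in both the alignments and the annotation,
#' FP = alignment introns absent from the annotation, FN = annotation
#' introns absent from the alignments; precision = TP / (TP + FP),
#' recall = TP / (TP + FN).
#'
#' @param alignment_junctions Junction frame derived from alignments.
#' @param annotation_introns Junction frame of annotated introns.
#' @return List with `TP`, `FP`, `FN`, `precision`, `recall`.
#' @export
intron_compare <- function(alignment_junctions, annotation_introns) {
  ak <- unique(junction_key(alignment_junctions))
  nk <- unique(junction_key(annotation_introns))
  tp <- length(intersect(ak, nk))
  fp <- length(setdiff(ak, nk))
  fn <- length(setdiff(nk, ak))
  list(TP = tp, FP = fp, FN = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}
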