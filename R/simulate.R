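#' Synthetic fixture specification
#'
#' Parameters of the seeded toy-genome generator.  Contigs are i.i.d.
#' uniform ACGT background into which multi-exon genes are planted on both
#' strands.  Every planted intron is canonical: it starts with a GT donor
#' whose consensus extends to `donor_consensus`, ends with AG preceded by a
#' polypyrimidine tract, and carries a branch-point motif whose adenosine
#' lies 35-40nt upstream of the acceptor site, matching the sequence
#' determinants the splicing machinery reads.  Decoy junctions are canonical
#' GT-AG pairs found on the antisense strand of gene loci, with no planted
#' signal beyond the terminal dinucleotides.  Intron lengths are drawn from
#' a mixture covering the sub-200, 200-400 and >400 regimes so that all
#' window-edge rules are exercised.
#'
#' @param n_contigs,contig_length Number and length (bp) of contigs.
#' @param genes_per_contig Genes planted per contig.
#' @param exons_per_gene Exons per gene.
#' @param exon_length_range Uniform range of exon lengths.
#' @param intron_length_ranges,intron_length_weights Mixture of uniform
#'   ranges for intron lengths and their weights.
#' @param alt_isoform_fraction Fraction of genes that also get an
#'   exon-skipping isoform (its skip intron is an alternative junction).
#' @param donor_consensus,donor_sub_rate Donor-site consensus (starting GT)
#'   and per-position substitution rate beyond the invariant GT.
#' @param ppt_length_range,ppt_pyrimidine Polypyrimidine-tract length range
#'   and per-base pyrimidine probability.
#' @param branchpoint_consensus,branchpoint_offset_range Branch-point motif
#'   (its adenosine is the 4th base) and the distance of that adenosine
#'   upstream of the intron end.
#' @param decoy_attempts_per_locus Antisense decoy generation attempts per
#'   gene locus.
#' @param noise_rate Fraction of simulated spliced reads that carry a noise
#'   junction (antisense decoy or shifted-boundary) with support 1.
#' @param read_length,coverage Simulated read length and spliced-read count
#'   per true junction.
#' @param paired_fraction,multimap_fraction Fractions of junction reads that
#'   are paired / multi-mapped (NH = 2).
#' @param seed Seed making all generation deterministic.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_contigs = 4L, contig_length = 1000000L,
                         genes_per_contig = 250L, exons_per_gene = 3L,
                         exon_length_range = c(100L, 300L),
                         intron_length_ranges = list(c(80L, 199L),
                                                     c(200L, 400L),
                                                     c(401L, 2500L)),
                         intron_length_weights = c(0.1, 0.2, 0.7),
                         alt_isoform_fraction = 0.2,
                         donor_consensus = "GTAAGT", donor_sub_rate = 0.15,
                         ppt_length_range = c(15L, 25L),
                         ppt_pyrimidine = 0.85,
                         branchpoint_consensus = "CTAAC",
                         branchpoint_offset_range = c(35L, 40L),
                         decoy_attempts_per_locus = 20L,
                         noise_rate = 0.05, read_length = 100L,
                         coverage = 10L, paired_fraction = 0.5,
                         multimap_fraction = 0.05, seed = 1L) {
  rates <- c(donor_sub_rate, ppt_pyrimidine, noise_rate, paired_fraction,
             multimap_fraction, alt_isoform_fraction)
  stopifnot(all(rates >= 0 & rates <= 1),
            abs(sum(intron_length_weights) - 1) < 1e-8,
            min(vapply(intron_length_ranges, min, numeric(1))) >=
              nchar(donor_consensus) + branchpoint_offset_range[2] + 10L)
  structure(as.list(environment())[c(
    "n_contigs", "contig_length", "genes_per_contig", "exons_per_gene",
    "exon_length_range", "intron_length_ranges", "intron_length_weights",
    "alt_isoform_fraction", "donor_consensus", "donor_sub_rate",
    "ppt_length_range", "ppt_pyrimidine", "branchpoint_consensus",
    "branchpoint_offset_range", "decoy_attempts_per_locus", "noise_rate",
    "read_length", "coverage", "paired_fraction", "multimap_fraction",
    "seed")], class = "fixture_spec")
}

BASES <- c("A", "C", "G", "T")

mutate_motif <- function(motif, rate, keep = integer(0)) {
  v <- strsplit(motif, "")[[1]]
  hit <- runif(length(v)) < rate
  hit[keep] <- FALSE
  v[hit] <- sample(BASES, sum(hit), replace = TRUE)
  v
}

# sense-strand intron sequence of length L with planted signals
build_intron <- function(L, spec) {
  v <- sample(BASES, L, replace = TRUE)
  dc <- mutate_motif(spec$donor_consensus, spec$donor_sub_rate, keep = 1:2)
  v[seq_along(dc)] <- dc
  v[c(L - 1L, L)] <- c("A", "G")
  p <- sample(spec$ppt_length_range[1]:spec$ppt_length_range[2], 1L)
  ppt_pos <- (L - 2L - p + 1L):(L - 2L)
  py <- runif(p) < spec$ppt_pyrimidine
  v[ppt_pos] <- ifelse(py, sample(c("C", "T"), p, replace = TRUE),
                       sample(BASES, p, replace = TRUE))
  d <- sample(spec$branchpoint_offset_range[1]:spec$branchpoint_offset_range[2],
              1L)
  bp <- mutate_motif(spec$branchpoint_consensus, 0.1, keep = 4L)
  a_pos <- L - d                      # branch adenosine position (1-based)
  bp_pos <- (a_pos - 3L):(a_pos + length(bp) - 4L)
  v[bp_pos] <- bp
  v
}

#' Generate a toy genome with planted introns
#'
#' Builds the seeded fixture genome: FASTA, a GFF3 annotation (one primary
#' isoform per gene plus exon-skipping isoforms for a fraction of genes), a
#' truth BED of every planted junction, and antisense decoy GT-AG junctions
#' found with the pseudo-junction generator (excluding all truth keys).
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created); defaults to a fresh temporary
#'   directory.
#' @return An object of class `splice_fixture`: list with `genome`
#'   ([genome_handle()]), `truth` (labelled [junction_frame()]), `decoys`,
#'   `loci`, `spec`, `dir` and file `paths`.
#' @export
generate_genome <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- sprintf("ctg%d", seq_len(spec$n_contigs))
  seqs <- setNames(character(spec$n_contigs), contigs)
  truth <- list(); loci <- list(); gff <- c("##gff-version 3")
  gid <- 0L
  with_seed(spec$seed, {
    for (ci in seq_len(spec$n_contigs)) {
      bg <- sample(BASES, spec$contig_length, replace = TRUE)
      pos <- 0L
      for (gi in seq_len(spec$genes_per_contig)) {
        gid <- gid + 1L
        pos <- pos + sample(200:800, 1L)
        ne <- spec$exons_per_gene
        ex_len <- sample(spec$exon_length_range[1]:spec$exon_length_range[2],
                         ne, replace = TRUE)
        comp <- sample(seq_along(spec$intron_length_ranges), ne - 1L,
                       replace = TRUE, prob = spec$intron_length_weights)
        in_len <- vapply(comp, function(k) {
          r <- spec$intron_length_ranges[[k]]
          sample(r[1]:r[2], 1L)
        }, integer(1))
        glen <- sum(ex_len) + sum(in_len)
        if (pos + glen > spec$contig_length)
          stop("fixture spec infeasible: gene does not fit on contig")
        strand <- sample(c("+", "-"), 1L)
        # sense-local exon/intron intervals
        b <- cumsum(c(0L, as.vector(rbind(ex_len, c(in_len, 0L))))[
          seq_len(2L * ne)])
        ex_s <- b[seq(1L, 2L * ne - 1L, by = 2L)]
        ex_e <- ex_s + ex_len
        in_s <- ex_e[-ne]; in_e <- ex_s[-1L]
        tosense <- function(a, b2) {   # local sense -> genomic 0-based
          if (strand == "+") c(pos + a, pos + b2)
          else c(pos + glen - b2, pos + glen - a)
        }
        for (k in seq_len(ne - 1L)) {
          iv <- build_intron(in_e[k] - in_s[k], spec)
          g <- tosense(in_s[k], in_e[k])
          if (strand == "-") iv <- rev(chartr("ACGT", "TGCA", iv))
          bg[(g[1] + 1L):g[2]] <- iv
          truth[[length(truth) + 1L]] <- data.frame(
            contig = contigs[ci], start = g[1], end = g[2], strand = strand,
            label = "positive-main", gene = sprintf("gene%04d", gid),
            intron_num = k, stringsAsFactors = FALSE)
        }
        has_alt <- ne >= 3L && runif(1) < spec$alt_isoform_fraction
        if (has_alt) {
          g <- tosense(in_s[1], in_e[2])   # skip exon 2
          truth[[length(truth) + 1L]] <- data.frame(
            contig = contigs[ci], start = g[1], end = g[2], strand = strand,
            label = "positive-alt", gene = sprintf("gene%04d", gid),
            intron_num = 1L, stringsAsFactors = FALSE)
        }
        loci[[length(loci) + 1L]] <- data.frame(
          gene = sprintf("gene%04d", gid), contig = contigs[ci],
          start = pos, end = pos + glen, strand = strand,
          stringsAsFactors = FALSE)
        # GFF3 (1-based inclusive)
        gname <- sprintf("gene%04d", gid)
        attr_bt <- "gene_biotype=protein_coding"
        gff <- c(gff, sprintf("%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\tID=%s;%s",
                              contigs[ci], pos + 1L, pos + glen, strand,
                              gname, attr_bt))
        emit_tx <- function(tx, keep_exons) {
          lines <- sprintf("%s\tfixture\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;%s",
                           contigs[ci], pos + 1L, pos + glen, strand, tx,
                           gname, attr_bt)
          for (k in keep_exons) {
            g <- tosense(ex_s[k], ex_e[k])
            lines <- c(lines,
                       sprintf("%s\tfixture\texon\t%d\t%d\t.\t%s\t.\tParent=%s;%s",
                               contigs[ci], g[1] + 1L, g[2], strand, tx,
                               attr_bt))
          }
          lines
        }
        gff <- c(gff, emit_tx(paste0(gname, ".1"), seq_len(ne)))
        if (has_alt)
          gff <- c(gff, emit_tx(paste0(gname, ".2"), setdiff(seq_len(ne), 2L)))
        pos <- pos + glen
      }
      seqs[ci] <- paste(bg, collapse = "")
    }
  })
  genome <- genome_handle(seqs)
  truth <- do.call(rbind, truth)
  tj <- junction_frame(contig = truth$contig, start = truth$start,
                       end = truth$end, strand = truth$strand,
                       support = 0L, source = "annotation",
                       label = truth$label)
  tj$gene <- truth$gene
  tj$intron_num <- truth$intron_num
  loci <- do.call(rbind, loci)
  decoys <- build_negative_random(
    genome, loci,
    curation_config(seed = spec$seed + 1L,
                    attempts_per_locus = spec$decoy_attempts_per_locus),
    known = tj)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gff = file.path(dir, "annotation.gff3"),
                truth = file.path(dir, "truth.bed"),
                decoys = file.path(dir, "decoys.bed"),
                manifest = file.path(dir, "manifest.json"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), paths$fasta)
  writeLines(gff, paths$gff)
  write_junction_bed(tj, paths$truth)
  write_junction_bed(decoys, paths$decoys)
  jsonlite::write_json(
    list(spec = spec[setdiff(names(spec), c("intron_length_ranges"))],
         n_truth = nrow(tj), n_decoys = nrow(decoys),
         fasta_md5 = unname(tools::md5sum(paths$fasta))),
    paths$manifest, auto_unbox = TRUE)
  structure(list(genome = genome, truth = tj, decoys = decoys, loci = loci,
                 spec = spec, dir = dir, paths = paths),
            class = "splice_fixture")
}

#' @export
print.splice_fixture <- function(x, ...) {
  cat(sprintf("splice_fixture: %d contig(s), %d true junction(s), %d decoy(s)\n",
              length(contig_names(x$genome)), nrow(x$truth), nrow(x$decoys)))
  invisible(x)
}

#' Simulate spliced alignments over a fixture genome
#'
#' Writes `coverage` spliced reads (CIGAR `M N M`) across every true
#' junction, with a fraction of reads paired (reciprocal mate pointers,
#' proper-pair flags) and a fraction multi-mapped (a secondary alignment
#' elsewhere, NH = 2 on both).  A further `noise_rate` fraction of reads
#' carry noise junctions - antisense decoys or shifted-boundary variants of
#' true junctions - each supported by exactly one alignment.
#'
#' @param fixture A [generate_genome()] result.
#' @param path Output SAM path (default `sim.sam` inside the fixture
#'   directory).
#' @param spec Overrides the fixture's [fixture_spec()].
#' @return List of class `sim_alignments`: `records`, `path`,
#'   `truth_support` (expected support per true junction), `noise`
#'   (junction frame of planted noise junctions, support 1).
#' @export
simulate_spliced_alignments <- function(fixture, path = NULL,
                                        spec = fixture$spec) {
  genome <- fixture$genome
  truth <- fixture$truth
  rl <- spec$read_length
  path <- path %||% file.path(fixture$dir, "sim.sam")
  recs <- list(); noise <- list()
  rid <- 0L
  with_seed(spec$seed + 2L, {
    spliced_read <- function(contig, s, e, strand, flag = 0L, nh = 1L,
                             qname = NULL) {
      a <- sample(20:(rl - 20L), 1L)
      p0 <- s - a
      if (p0 < 0L) { a <- a + p0; p0 <- 0L }
      sq <- paste0(fetch_plus(genome, contig, p0, s),
                   fetch_plus(genome, contig, e, e + rl - a))
      rid <<- rid + 1L
      data.frame(qname = qname %||% sprintf("r%06d", rid), flag = flag,
                 rname = contig, pos = p0, mapq = 60L,
                 cigar = sprintf("%dM%dN%dM", a, e - s, rl - a),
                 rnext = "*", pnext = -1L, tlen = 0L, seq = sq,
                 qual = strrep("I", rl), nh = nh, xs = strand, tags = "",
                 stringsAsFactors = FALSE)
    }
    # decorate a spliced read: paired with an unspliced downstream mate, or
    # multi-mapped with a secondary alignment, or plain single-end
    emit <- function(r, contig, jend) {
      paired <- runif(1) < spec$paired_fraction
      clen <- contig_lengths(genome)[[contig]]
      m_pos <- jend + sample(0:150, 1L)
      if (paired && m_pos + rl <= clen) {
        r$flag <- bitwOr(r$flag,
                         FLAG_PAIRED + FLAG_PROPER + FLAG_FIRST +
                           FLAG_MATE_REVERSE)
        mate <- data.frame(qname = r$qname,
                           flag = FLAG_PAIRED + FLAG_PROPER + FLAG_SECOND +
                             FLAG_REVERSE,
                           rname = r$rname, pos = m_pos, mapq = 60L,
                           cigar = paste0(rl, "M"), rnext = "=",
                           pnext = r$pos, tlen = -(m_pos + rl - r$pos),
                           seq = fetch_plus(genome, contig, m_pos, m_pos + rl),
                           qual = strrep("I", rl), nh = 1L,
                           xs = NA_character_, tags = "",
                           stringsAsFactors = FALSE)
        r$rnext <- "="; r$pnext <- m_pos; r$tlen <- m_pos + rl - r$pos
        recs[[length(recs) + 1L]] <<- r
        recs[[length(recs) + 1L]] <<- mate
      } else if (runif(1) < spec$multimap_fraction) {
        r$nh <- 2L
        others <- setdiff(contig_names(genome), r$rname)
        other <- if (length(others)) sample(others, 1L) else r$rname
        alt_pos <- sample.int(contig_lengths(genome)[[other]] - rl, 1L) - 1L
        sec <- r
        sec$flag <- bitwOr(r$flag, FLAG_SECONDARY)
        sec$rname <- other; sec$pos <- alt_pos
        sec$cigar <- paste0(rl, "M")
        sec$xs <- NA_character_
        recs[[length(recs) + 1L]] <<- r
        recs[[length(recs) + 1L]] <<- sec
      } else {
        recs[[length(recs) + 1L]] <<- r
      }
    }
    for (i in seq_len(nrow(truth))) {
      for (k in seq_len(spec$coverage)) {
        r <- spliced_read(truth$contig[i], truth$start[i], truth$end[i],
                          truth$strand[i])
        emit(r, truth$contig[i], truth$end[i])
      }
    }
    n_noise <- round(spec$noise_rate * nrow(truth) * spec$coverage)
    truth_keys <- junction_key(truth, stranded = FALSE)
    used <- character(0)
    tries <- 0L
    while (length(noise) < n_noise && tries < 10L * n_noise) {
      tries <- tries + 1L
      if (runif(1) < 0.5 && nrow(fixture$decoys)) {
        j <- fixture$decoys[sample.int(nrow(fixture$decoys), 1L), ]
      } else {
        t0 <- truth[sample.int(nrow(truth), 1L), ]
        sh <- sample(c(-10:-3, 3:10), 1L)
        j <- data.frame(contig = t0$contig, start = t0$start + sh,
                        end = t0$end + sh, strand = t0$strand,
                        stringsAsFactors = FALSE)
      }
      key <- paste(j$contig, j$start, j$end, sep = ":")
      if (key %in% truth_keys || key %in% used) next
      used <- c(used, key)
      emit(spliced_read(j$contig, j$start, j$end, j$strand), j$contig, j$end)
      noise[[length(noise) + 1L]] <-
        data.frame(contig = j$contig, start = j$start, end = j$end,
                   strand = j$strand, stringsAsFactors = FALSE)
    }
  })
  records <- do.call(rbind, recs)
  records <- records[order(records$rname, records$pos), , drop = FALSE]
  rownames(records) <- NULL
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", contig_names(genome),
                   contig_lengths(genome)))
  attr(records, "header") <- hdr
  write_alignments(records, path, hdr)
  nj <- do.call(rbind, noise)
  noise_jf <- if (is.null(nj)) junction_frame() else
    junction_frame(contig = nj$contig, start = nj$start, end = nj$end,
                   strand = nj$strand, support = 1L, source = "generated")
  ts <- fixture$truth
  ts$support <- spec$coverage
  structure(list(records = records, path = path, truth_support = ts,
                 noise = noise_jf),
            class = "sim_alignments")
}

#' Build the desk-scale training fixture
#'
#' Windows for training and evaluating the network without any external
#' data: planted true junctions are positives; negatives are antisense decoy
#' GT-AG junctions plus a small share of shifted-boundary noise junctions,
#' at `ratio` negatives per positive (the 1:3 class balance used for model
#' training).  The split holds out the last contig.
#'
#' @param spec A [fixture_spec()].
#' @param n_positive Positives drawn from the planted junctions.
#' @param ratio Negatives per positive.
#' @param shifted_fraction Share of negatives that are shifted-boundary
#'   noise rather than decoys.
#' @param held_out Contigs held out as the test partition; defaults to the
#'   last two contigs, mirroring the two held-out chromosomes of the
#'   chromosome-held-out split.
#' @return List of class `training_fixture`: `train` and `test` (each with
#'   `windows`, `positive`, `junctions`), plus `genome` and `fixture`.
#' @export
build_training_fixture <- function(spec = fixture_spec(), n_positive = 2000L,
                                   ratio = 3L, shifted_fraction = 0.08,
                                   held_out = NULL) {
  fixture <- generate_genome(spec)
  truth <- fixture$truth
  decoys <- fixture$decoys
  held_out <- held_out %||%
    sprintf("ctg%d", unique(pmax(1L, spec$n_contigs - 0:1)))
  n_neg <- ratio * n_positive
  n_shift <- round(shifted_fraction * n_neg)
  with_seed(spec$seed + 3L, {
    if (nrow(truth) > n_positive)
      truth <- truth[sort(sample.int(nrow(truth), n_positive)), , drop = FALSE]
    # oversample shifted-boundary candidates, then keep exactly n_shift
    # distinct ones that do not collide with a true junction
    src <- truth[sample.int(nrow(truth), 3L * n_shift, replace = TRUE), ,
                 drop = FALSE]
    sh <- sample(c(-10:-3, 3:10), 3L * n_shift, replace = TRUE)
    shifted <- junction_frame(contig = src$contig, start = src$start + sh,
                              end = src$end + sh, strand = src$strand,
                              support = 1L, source = "generated",
                              label = "negative-1")
    shifted <- shifted[!junction_key(shifted) %in% junction_key(truth), ,
                       drop = FALSE]
    shifted <- shifted[!duplicated(junction_key(shifted)), , drop = FALSE]
    shifted <- head(shifted, n_shift)
    n_decoy <- n_neg - nrow(shifted)
    if (nrow(decoys) > n_decoy)
      decoys <- decoys[sort(sample.int(nrow(decoys), n_decoy)), , drop = FALSE]
    else warning("fewer decoys than requested; using all")
    all <- rbind(truth[, names(junction_frame()), drop = FALSE],
                 decoys[, names(junction_frame()), drop = FALSE],
                 shifted[, names(junction_frame()), drop = FALSE])
  })
  all$positive <- startsWith(all$label, "positive")
  windows <- extract_pair_window(fixture$genome, all)
  is_test <- all$contig %in% held_out
  mk <- function(sel) list(windows = windows[sel], positive = all$positive[sel],
                           junctions = all[sel, , drop = FALSE])
  structure(list(train = mk(!is_test), test = mk(is_test),
                 genome = fixture$genome, fixture = fixture,
                 held_out = held_out),
            class = "training_fixture")
}

#' @export
print.training_fixture <- function(x, ...) {
  cat(sprintf(
    "training_fixture: %d train (%d pos), %d test (%d pos), held out: %s\n",
    length(x$train$windows), sum(x$train$positive),
    length(x$test$windows), sum(x$test$positive),
    paste(x$held_out, collapse = ",")))
  invisible(x)
}
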