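# reference scores for the simulated alignments: the fixture defines which
# junctions are real, so true junctions get high scores and planted noise
# junctions low ones; cleaning semantics are then checked exactly
fixture_scores <- function(sim, fixture) {
  truth <- fixture$truth
  truth$junction_score <- 0.95
  noise <- sim$noise
  if (nrow(noise)) noise$junction_score <- 0.01
  rbind(truth[, c("contig", "start", "end", "strand", "junction_score")],
        noise[, c("contig", "start", "end", "strand", "junction_score")])
}

test_that("spurious keys are the junctions scoring below threshold", {
  sc <- data.frame(contig = "c", start = c(0L, 10L, 20L),
                   end = c(5L, 15L, 25L), strand = "+",
                   junction_score = c(0.05, 0.5, NA))
  expect_equal(spurious_set(sc, 0.1), "c:0:5")
  expect_equal(length(spurious_set(sc, 0)), 0L)
  expect_equal(length(spurious_set(sc, 1)), 2L)
  expect_error(spurious_set(sc, 2), "0, 1")
})

test_that("cleaning removes exactly the alignments carrying spurious junctions", {
  fixture <- get_fixture()
  sim <- get_sim()
  scores <- fixture_scores(sim, fixture)
  bad <- spurious_set(scores, 0.1)
  expect_equal(length(bad), nrow(sim$noise))
  rep <- clean_alignments(sim$records, bad)

  # independent oracle: walk every CIGAR ourselves
  removed_oracle <- vapply(seq_len(nrow(sim$records)), function(i) {
    r <- sim$records[i, ]
    if (!grepl("N", r$cigar, fixed = TRUE)) return(FALSE)
    iv <- spliceguard:::cigar_introns(r$pos, r$cigar)
    any(paste(r$rname, iv$start, iv$end, sep = ":") %in% bad)
  }, logical(1))
  expect_equal(rep$removed, sum(removed_oracle))
  expect_equal(rep$kept + rep$removed, rep$scanned)
  expect_equal(rep$scanned, nrow(sim$records))

  # junctions re-extracted from the kept records exclude all spurious keys
  jk <- junctions_from_alignments(rep$kept_records)
  expect_false(any(junction_key(jk, stranded = FALSE) %in% bad))

  # idempotence
  rep2 <- clean_alignments(rep$kept_records, bad)
  expect_equal(rep2$removed, 0L)
  expect_equal(rep2$kept, rep$kept)

  # intron-level precision improves; recall is untouched because only noise
  # junctions score below threshold
  before <- intron_compare(junctions_from_alignments(sim$records),
                           fixture$truth)
  after <- intron_compare(jk, fixture$truth)
  expect_gt(after$precision, before$precision)
  expect_equal(after$recall, before$recall)
  expect_equal(after$precision, 1)
})

test_that("mates of removed paired reads are unpaired with cleared flag bits", {
  hdr <- c("@HD\tVN:1.6", "@SQ\tSN:c1\tLN:10000")
  rec <- data.frame(
    qname = c("p1", "p1"), flag = c(99L, 147L), rname = "c1",
    pos = c(100L, 400L), mapq = 60L,
    cigar = c("20M100N30M", "50M"), rnext = "=",
    pnext = c(400L, 100L), tlen = c(350L, -350L),
    seq = strrep("A", 50), qual = strrep("I", 50),
    nh = NA_integer_, xs = NA_character_, tags = "",
    stringsAsFactors = FALSE)
  attr(rec, "header") <- hdr
  rep <- clean_alignments(rec, "c1:120:220")
  expect_equal(rep$removed, 1L)
  expect_equal(rep$mates_unpaired, 1L)
  mate <- rep$kept_records
  # bits 0x1, 0x2, 0x8, 0x20, 0x40, 0x80 cleared; reverse bit 0x10 kept
  expect_equal(mate$flag, 16L)
  expect_equal(mate$rnext, "*")
  expect_equal(mate$pnext, -1L)
  expect_equal(mate$tlen, 0L)
})

test_that("NH tags are decremented on surviving alignments of removed reads", {
  hdr <- c("@HD\tVN:1.6", "@SQ\tSN:c1\tLN:10000", "@SQ\tSN:c2\tLN:10000")
  mk <- function(qname, flag, rname, pos, cigar, nh)
    data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
               mapq = 0L, cigar = cigar, rnext = "*", pnext = -1L, tlen = 0L,
               seq = strrep("A", 50), qual = strrep("I", 50), nh = nh,
               xs = NA_character_, tags = "", stringsAsFactors = FALSE)
  rec <- rbind(mk("m1", 0L, "c1", 100L, "20M100N30M", 3L),
               mk("m1", 256L, "c1", 5000L, "50M", 3L),
               mk("m1", 256L, "c2", 700L, "50M", 3L),
               mk("other", 0L, "c2", 900L, "50M", 1L))
  attr(rec, "header") <- hdr
  rep <- clean_alignments(rec, "c1:120:220")
  expect_equal(rep$removed, 1L)
  expect_equal(rep$nh_updated, 2L)
  kept <- rep$kept_records
  expect_equal(kept$nh[kept$qname == "m1"], c(2L, 2L))
  expect_equal(kept$nh[kept$qname == "other"], 1L)
  # kept output is coordinate-sorted
  expect_false(is.unsorted(order(kept$rname, kept$pos)))
})

test_that("intron comparison implements the exact set formulas", {
  aln <- junction_frame(contig = "c", start = (1:5) * 100L,
                        end = (1:5) * 100L + 50L, strand = "+")
  ann <- junction_frame(contig = "c", start = c(1:3, 9) * 100L,
                        end = c(1:3, 9) * 100L + 50L, strand = "+")
  r <- intron_compare(aln, ann)
  expect_equal(r$TP, 3L); expect_equal(r$FP, 2L); expect_equal(r$FN, 1L)
  expect_equal(r$precision, 0.6)
  expect_equal(r$recall, 0.75)
  same <- intron_compare(aln, aln)
  expect_equal(same$precision, 1); expect_equal(same$recall, 1)
  disjoint <- intron_compare(aln, junction_frame(contig = "z", start = 1L,
                                                 end = 100L, strand = "+"))
  expect_equal(disjoint$precision, 0); expect_equal(disjoint$recall, 0)
})

test_that("cleaned SAM files are written with headers and parse back", {
  fixture <- get_fixture()
  sim <- get_sim()
  bad <- spurious_set(fixture_scores(sim, fixture), 0.1)
  kp <- tempfile(fileext = ".sam"); dp <- tempfile(fileext = ".sam")
  rep <- clean_alignments(sim$records, bad, kept_path = kp,
                          discarded_path = dp)
  kept <- read_alignments(kp)
  expect_equal(nrow(kept), rep$kept)
  expect_equal(nrow(read_alignments(dp)), rep$removed)
  expect_true(any(startsWith(attr(kept, "header"), "@SQ")))
})
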