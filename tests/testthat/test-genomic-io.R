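test_that("fetch_window slices, pads and reverse-complements correctly", {
  g <- genome_handle(c(chr = "ACGTAAAACCCC"))
  expect_equal(fetch_window(g, "chr", 0, 4, "+"), "ACGT")
  # ACGT is its own reverse complement
  expect_equal(fetch_window(g, "chr", 0, 4, "-"), "ACGT")
  expect_equal(fetch_window(g, "chr", -3, 2), "NNNAC")
  expect_equal(fetch_window(g, "chr", 10, 15), "CCNNN")
  expect_equal(nchar(fetch_window(g, "chr", -5, 20)), 25L)
  expect_error(fetch_window(g, "nope", 0, 4), "contig")
  expect_error(fetch_window(g, "chr", 4, 4), "start < end")
})

test_that("minus-strand fetch equals reverse complement of plus strand", {
  set.seed(11)
  g <- genome_handle(c(c1 = rand_dna(500)))
  for (i in 1:25) {
    s <- sample(0:450, 1); e <- s + sample(1:50, 1)
    expect_identical(fetch_window(g, "c1", s, e, "-"),
                     revcomp(fetch_window(g, "c1", s, e, "+")))
  }
})

test_that("genome_handle uppercases and maps ambiguity codes to N", {
  g <- genome_handle(c(x = "acgtRYswn"))
  expect_equal(fetch_window(g, "x", 0, 9), "ACGTNNNNN")
})

test_that("annotation parsing builds transcript models and drops overlapping exons", {
  m <- parse_annotation(tiny_gff())
  expect_equal(nrow(m$transcripts), 1L)
  expect_equal(nrow(m$exons), 3L)
  expect_equal(m$n_excluded, 0L)
  # 0-based half-open conversion
  expect_equal(m$exons$start, c(0L, 200L, 400L))
  expect_equal(m$exons$end, c(100L, 300L, 500L))

  bad <- tiny_gff(extra = c(
    "chrA\ttest\tmRNA\t1\t500\t.\t+\t.\tID=t2;Parent=g1",
    "chrA\ttest\texon\t1\t250\t.\t+\t.\tParent=t2",
    "chrA\ttest\texon\t200\t300\t.\t+\t.\tParent=t2"))
  expect_message(m2 <- parse_annotation(bad), "overlapping")
  expect_equal(m2$n_excluded, 1L)
  expect_false("t2" %in% m2$transcripts$tx)
})

test_that("malformed annotation lines are rejected with the line number", {
  p <- write_tmp(c("##gff-version 3", "chrA\ttest\tgene\t1\t10"), ".gff3")
  expect_error(parse_annotation(p), "line 2")
})

test_that("empty annotation yields empty models", {
  p <- write_tmp("##gff-version 3", ".gff3")
  m <- parse_annotation(p)
  expect_equal(nrow(m$transcripts), 0L)
  expect_equal(nrow(introns_from_annotation(m)), 0L)
})

test_that("introns are derived per adjacent exon pair and deduplicated", {
  m <- parse_annotation(tiny_gff())
  j <- introns_from_annotation(m)
  expect_equal(j$start, c(100L, 300L))
  expect_equal(j$end, c(200L, 400L))
  expect_equal(j$strand, c("+", "+"))
  expect_equal(j$intron_num, c(1L, 2L))

  # second isoform sharing intron 1 -> still two unique junctions
  iso <- tiny_gff(extra = c(
    "chrA\ttest\tmRNA\t1\t300\t.\t+\t.\tID=t2;Parent=g1",
    "chrA\ttest\texon\t1\t100\t.\t+\t.\tParent=t2",
    "chrA\ttest\texon\t201\t300\t.\t+\t.\tParent=t2"))
  j2 <- introns_from_annotation(parse_annotation(iso))
  expect_equal(nrow(j2), 2L)
  expect_true(any(grepl("t1", j2$parents) & grepl("t2", j2$parents)))
})

test_that("minus-strand transcripts give the same intron intervals", {
  p <- write_tmp(c(
    "##gff-version 3",
    "chrA\ttest\tgene\t1\t500\t.\t-\t.\tID=g1",
    "chrA\ttest\tmRNA\t1\t500\t.\t-\t.\tID=t1;Parent=g1",
    "chrA\ttest\texon\t1\t100\t.\t-\t.\tParent=t1",
    "chrA\ttest\texon\t201\t300\t.\t-\t.\tParent=t1",
    "chrA\ttest\texon\t401\t500\t.\t-\t.\tParent=t1"), ".gff3")
  j <- introns_from_annotation(parse_annotation(p))
  expect_equal(j$start, c(100L, 300L))
  expect_equal(j$end, c(200L, 400L))
  expect_equal(j$strand, c("-", "-"))
})

test_that("junction BED writing is six-column, sorted, and round-trips", {
  j <- junction_frame(contig = c("chr2", "chr1"), start = c(500L, 100L),
                      end = c(700L, 250L), strand = c("-", "+"),
                      support = c(7L, 1L), name = c("J2", "J0"))
  j$intron_num <- c(2L, 1L)
  p <- tempfile(fileext = ".bed")
  write_junction_bed(j, p, fifth = "intron_num")
  lines <- readLines(p)
  expect_equal(lines[1], "chr1\t100\t250\tJ0\t1\t+")
  expect_equal(lines[2], "chr2\t500\t700\tJ2\t2\t-")

  write_junction_bed(j, p, fifth = "support")
  back <- read_junction_bed(p)
  expect_equal(back[, c("contig", "start", "end", "strand")],
               j[order(j$contig), c("contig", "start", "end", "strand")],
               ignore_attr = TRUE)
  expect_equal(back$support, c(1L, 7L))

  write_junction_bed(junction_frame(), p)
  expect_equal(file.size(p), 0)
  expect_equal(nrow(read_junction_bed(p)), 0L)
})
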