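test_that("positive sets split by annotation membership after support filtering", {
  sup <- junction_frame(contig = "c1", start = c(100L, 300L, 500L),
                        end = c(200L, 400L, 600L), strand = "+",
                        support = c(150L, 150L, 120L))
  main <- junction_frame(contig = "c1", start = 100L, end = 200L, strand = "+")
  alt <- junction_frame(contig = "c1", start = c(100L, 300L),
                        end = c(200L, 400L), strand = "+")
  ps <- build_positive_sets(sup, main, alt)
  expect_equal(ps$positive_main$start, 100L)
  expect_equal(ps$positive_alt$start, 300L)   # in alt only
  expect_equal(unique(ps$positive_main$label), "positive-main")
  # junction with low support never reaches this step: caller filters first
  low <- filter_by_support(junction_frame(contig = "c1", start = 300L,
                                          end = 400L, strand = "+",
                                          support = 3L), 100)
  expect_equal(nrow(low), 0L)
})

test_that("negative-1 requires support 1 and opposition to every overlapping locus", {
  loci <- data.frame(gene = "g", contig = "c1", start = 0L, end = 1000L,
                     strand = "+")
  j <- junction_frame(contig = "c1", start = c(100L, 300L, 500L, 2000L),
                      end = c(200L, 400L, 600L, 2100L),
                      strand = c("-", "-", "+", "-"),
                      support = c(1L, 2L, 1L, 1L))
  out <- build_negative_one(j, loci)
  # kept: support 1, '-' inside '+' gene; dropped: support 2, same strand,
  # and the junction outside any locus
  expect_equal(out$start, 100L)
  expect_equal(out$label, "negative-1")
})

test_that("pseudo-junction generation follows the scan procedure and is seeded", {
  # a locus of all A: no GT anywhere -> all attempts fail
  g <- genome_handle(c(cA = strrep("A", 5000)))
  loci <- data.frame(gene = "g1", contig = "cA", start = 0L, end = 4000L,
                     strand = "+")
  cfg <- curation_config(seed = 5, pseudo_intron_length_range = c(200L, 2000L))
  out <- generate_pseudo_junctions(g, loci, cfg)
  expect_equal(nrow(out), 0L)
  expect_equal(unname(attr(out, "attempts")["failed"]), 20L)

  # a real random locus: junctions are canonical in their own sense and at
  # least the drawn length long
  set.seed(2)
  g2 <- genome_handle(c(cB = rand_dna(30000)))
  loci2 <- data.frame(gene = "g2", contig = "cB", start = 0L, end = 25000L,
                      strand = "+")
  out2 <- generate_pseudo_junctions(g2, loci2, cfg)
  expect_gt(nrow(out2), 0L)
  expect_true(all(out2$strand == "-"))
  expect_true(all(out2$end - out2$start >= 200L))
  tal <- dinucleotide_tally(out2, g2)
  expect_equal(tal$canonical_fraction, 1)

  # byte-identical output under the same seed
  p1 <- tempfile(); p2 <- tempfile()
  write_junction_bed(generate_pseudo_junctions(g2, loci2, cfg), p1)
  write_junction_bed(generate_pseudo_junctions(g2, loci2, cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("negative-random excludes known junctions", {
  set.seed(2)
  g <- genome_handle(c(cB = rand_dna(30000)))
  loci <- data.frame(gene = "g", contig = "cB", start = 0L, end = 25000L,
                     strand = "+")
  cfg <- curation_config(seed = 5, pseudo_intron_length_range = c(200L, 2000L))
  all <- generate_pseudo_junctions(g, loci, cfg)
  known <- all[1:2, , drop = FALSE]
  out <- build_negative_random(g, loci, cfg, known = known)
  expect_false(any(junction_key(known, stranded = FALSE) %in%
                     junction_key(out, stranded = FALSE)))
})

test_that("split holds out configured contigs and downsamples negatives 3:1", {
  mk <- function(contig, n, label, offset = 0) {
    junction_frame(contig = contig, start = offset + (1:n) * 100L,
                   end = offset + (1:n) * 100L + 50L, strand = "+",
                   support = 200L, label = label)
  }
  pm <- mk("chr2", 8, "positive-main")
  pa <- mk("chr2", 2, "positive-alt", offset = 5000L)
  n1 <- mk("chr2", 60, "negative-1", offset = 20000L)
  nr <- mk("chr2", 40, "negative-random", offset = 50000L)
  test_j <- mk("chr9", 5, "positive-main", offset = 90000L)
  cfg <- curation_config(seed = 4)
  ds <- split_and_sample(rbind(pm, test_j), pa, n1, nr, cfg)
  expect_s3_class(ds, "labeled_junctions")
  expect_true(all(ds$test$contig == "chr9"))
  expect_equal(sum(startsWith(ds$train$label, "positive")), 10L)
  expect_equal(sum(!startsWith(ds$train$label, "positive")), 30L)
  # exclusion list removes from the test partition
  ds2 <- split_and_sample(rbind(pm, test_j), pa, n1, nr, cfg,
                          exclude = test_j[1, , drop = FALSE])
  expect_equal(nrow(ds2$test), 4L)
  # sampling reproducible under the seed
  ds3 <- split_and_sample(rbind(pm, test_j), pa, n1, nr, cfg)
  expect_identical(ds$train, ds3$train)
})

test_that("dinucleotide tally counts donor/acceptor pairs in sense orientation", {
  # contig: junction A [10,20) '+' with GT..AG; junction B [30,40) '+' GC..AG
  s <- strrep("A", 60)
  substr(s, 11, 12) <- "GT"; substr(s, 19, 20) <- "AG"
  substr(s, 31, 32) <- "GC"; substr(s, 39, 40) <- "AG"
  g <- genome_handle(c(c1 = s))
  j <- junction_frame(contig = "c1", start = c(10L, 10L, 10L, 30L),
                      end = c(20L, 20L, 20L, 40L), strand = "+",
                      name = paste0("j", 1:4))
  tal <- dinucleotide_tally(j, g)
  expect_equal(tal$canonical_fraction, 0.75)
  expect_equal(tal$tally$count[tal$tally$donor == "GT"], 3L)
  empty <- dinucleotide_tally(junction_frame(), g)
  expect_equal(nrow(empty$tally), 0L)
})

test_that("fixture classes are pairwise disjoint and decoys avoid positives", {
  f <- get_fixture()
  expect_equal(anyDuplicated(junction_key(rbind(
    f$truth[, names(junction_frame())], f$decoys))), 0L)
  expect_false(any(junction_key(f$decoys, stranded = FALSE) %in%
                     junction_key(f$truth, stranded = FALSE)))
})
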