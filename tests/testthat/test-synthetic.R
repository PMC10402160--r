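test_that("genome generation is byte-identical under a fixed seed", {
  s <- small_spec(seed = 77)
  f1 <- generate_genome(s, dir = tempfile())
  f2 <- generate_genome(s, dir = tempfile())
  expect_identical(unname(tools::md5sum(f1$paths$fasta)),
                   unname(tools::md5sum(f2$paths$fasta)))
  expect_identical(readLines(f1$paths$truth), readLines(f2$paths$truth))
})

test_that("planted junctions are canonical with the promised signals", {
  f <- get_fixture()
  expect_equal(dinucleotide_tally(f$truth, f$genome)$canonical_fraction, 1)
  w <- extract_pair_window(f$genome, f$truth)
  L <- f$truth$end - f$truth$start
  expect_true(all(substr(w[L >= 400], 201, 202) == "GT"))
  # polypyrimidine enrichment upstream of the acceptor versus decoys
  py_frac <- function(wins) {
    tract <- substr(wins, 571, 598)   # 28nt immediately before the AG
    mean(vapply(strsplit(tract, ""), function(v)
      mean(v %in% c("C", "T")), numeric(1)))
  }
  wd <- extract_pair_window(f$genome, f$decoys)
  expect_gt(py_frac(w[L >= 400]), py_frac(wd) + 0.2)
})

test_that("annotation and truth agree through the package's own parser", {
  f <- get_fixture()
  models <- parse_annotation(f$paths$gff)
  ann <- introns_from_annotation(models)
  expect_setequal(junction_key(ann), junction_key(f$truth))
  loci <- gene_loci(models, biotype = "protein_coding")
  expect_equal(nrow(loci), nrow(f$loci))
})

test_that("noise-free simulation reproduces exactly the truth set", {
  spec <- small_spec(seed = 31, noise_rate = 0, multimap_fraction = 0,
                     paired_fraction = 0)
  f <- generate_genome(spec)
  sim <- simulate_spliced_alignments(f)
  j <- junctions_from_alignments(sim$records, f$genome)
  expect_setequal(junction_key(j), junction_key(f$truth))
  expect_true(all(j$support == spec$coverage))
})

test_that("paired simulation emits reciprocal mates and valid multi-mappers", {
  sim <- get_sim()
  rec <- sim$records
  paired <- rec[spliceguard:::has_flag(rec$flag, 0x1L), , drop = FALSE]
  expect_gt(nrow(paired), 0L)
  key <- paste(paired$qname, paired$rname, paired$pos)
  mate_key <- paste(paired$qname,
                    ifelse(paired$rnext == "=", paired$rname, paired$rnext),
                    paired$pnext)
  expect_true(all(mate_key %in% key))
  mm <- rec[!is.na(rec$nh) & rec$nh == 2L, , drop = FALSE]
  if (nrow(mm)) {
    counts <- table(mm$qname)
    expect_true(all(counts == 2L))
    expect_true(all(tapply(spliceguard:::has_flag(mm$flag, 0x100L),
                           mm$qname, sum) == 1L))
  }
  # noise junctions have support exactly 1
  j <- junctions_from_alignments(rec, get_fixture()$genome)
  nk <- junction_key(sim$noise, stranded = FALSE)
  jk <- junction_key(j, stranded = FALSE)
  expect_true(all(j$support[jk %in% nk] == 1L))
})

test_that("curation applied to simulated alignments recovers the generated classes", {
  fixture <- get_fixture()
  sim <- get_sim()
  models <- parse_annotation(fixture$paths$gff)
  loci <- gene_loci(models)
  j <- junctions_from_alignments(sim$records, fixture$genome)
  # support filtering at the fixture's coverage floor recovers the truth set
  sup <- filter_by_support(j, min_support = 5L)
  expect_setequal(junction_key(sup), junction_key(fixture$truth))
  # antisense support-1 noise junctions are classified negative-1
  neg1 <- build_negative_one(j, loci)
  expect_true(all(junction_key(neg1, stranded = FALSE) %in%
                    junction_key(sim$noise, stranded = FALSE)))
  # none of the recovered negatives is a true junction
  expect_false(any(junction_key(neg1, stranded = FALSE) %in%
                     junction_key(fixture$truth, stranded = FALSE)))
})

test_that("the training fixture honours the 1:3 class balance and the held-out split", {
  fx <- get_training_fixture()
  n_pos <- sum(fx$train$positive) + sum(fx$test$positive)
  n_neg <- sum(!fx$train$positive) + sum(!fx$test$positive)
  expect_equal(n_neg, 3L * n_pos)
  expect_equal(n_pos, 2000L)
  expect_true(all(fx$test$junctions$contig %in% fx$held_out))
  expect_false(any(fx$train$junctions$contig %in% fx$held_out))
  # no true junction appears among the negatives
  truth_keys <- junction_key(fx$fixture$truth)
  neg <- rbind(fx$train$junctions[!fx$train$positive, ],
               fx$test$junctions[!fx$test$positive, ])
  expect_false(any(junction_key(neg) %in% truth_keys))
  expect_true(all(nchar(fx$train$windows) == 800L))
})
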