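test_that("confusion metrics match the worked example", {
  scores <- c(0.9, 0.3, 0.1, 0.05)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  r <- classify_at_threshold(scores, labels, 0.8)
  expect_equal(r$TP, 1L); expect_equal(r$FN, 1L)
  expect_equal(r$TN, 2L); expect_equal(r$FP, 0L)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 0.5)
  expect_equal(r$accuracy, 0.75)
  expect_equal(classify_at_threshold(scores, labels, 0)$recall, 1)
  expect_warning(deg <- classify_at_threshold(scores, labels, 0.95),
                 "precision")
  expect_equal(deg$precision, 0)
  expect_true(deg$degenerate_precision)
  expect_error(classify_at_threshold(scores, labels, 1.2), "0, 1")
})

test_that("confusion metrics reproduce a brute-force oracle on random inputs", {
  set.seed(50)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    scores <- runif(n)
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    t <- runif(1)
    r <- suppressWarnings(classify_at_threshold(scores, labels, t))
    o <- brute_confusion(scores, labels, t)
    expect_equal(c(r$TP, r$FP, r$FN, r$TN), unname(o[c("TP", "FP", "FN", "TN")]))
    expect_equal(r$precision, if (o["TP"] + o["FP"] == 0) 0 else
      unname(o["TP"] / (o["TP"] + o["FP"])))
    expect_equal(r$recall, unname(o["TP"] / (o["TP"] + o["FN"])))
  }
})

test_that("the min rule makes junction classification equal both-sites classification", {
  set.seed(51)
  for (i in 1:10) {
    don <- runif(40); acc <- runif(40)
    labels <- runif(40) < 0.5
    js <- pmin(don, acc)
    for (t in seq(0, 1, by = 0.1)) {
      a <- js >= t
      b <- don >= t & acc >= t
      expect_identical(a, b)
    }
    expect_true(all(js <= don & js <= acc))
  }
})

test_that("threshold sweep finds the F1-optimal threshold on separable scores", {
  scores <- c(0.95, 0.9, 0.85, 0.1, 0.05, 0.02)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  sw <- threshold_sweep(scores, labels)
  expect_equal(max(sw$f1), 1)
  # smallest threshold on the F1 = 1 plateau
  expect_equal(attr(sw, "best_threshold"), min(sw$threshold[sw$f1 == 1]))
  sw2 <- threshold_sweep(scores, labels, grid = c(0, 1))
  expect_equal(nrow(sw2), 2L)
  # every row agrees with direct recomputation
  for (k in seq_len(nrow(sw))) {
    r <- suppressWarnings(classify_at_threshold(scores, labels,
                                                sw$threshold[k]))
    expect_equal(sw$precision[k], r$precision)
    expect_equal(sw$recall[k], r$recall)
  }
})

test_that("AUC-ROC equals pairwise concordance and handles perfect scores", {
  expect_equal(curves_and_auc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))$auc_roc, 1)
  set.seed(52)
  for (i in 1:10) {
    n <- sample(10:100, 1)
    scores <- round(runif(n), 2)   # induce ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    r <- curves_and_auc(scores, labels)
    expect_equal(r$auc_roc, brute_auc(scores, labels), tolerance = 1e-12)
  }
  expect_error(curves_and_auc(runif(5), rep(TRUE, 5)), "both classes")
})

test_that("AUC-ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  scores <- runif(200)
  labels <- runif(200) < 0.5
  ours <- curves_and_auc(scores, labels)$auc_roc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("random scores give chance-level AUC", {
  set.seed(54)
  scores <- runif(4000)
  labels <- rep(c(TRUE, FALSE), 2000)
  expect_equal(curves_and_auc(scores, labels)$auc_roc, 0.5, tolerance = 0.05)
})

test_that("score differences and the filtered view behave as documented", {
  sc <- data.frame(donor_score = c(0.5, 0.9, 0.6, 0.9),
                   acceptor_score = c(0.5, 0.2, 0.5, 0.7))
  d <- score_difference_distribution(sc)
  expect_equal(d$differences, c(0, 0.7, 0.1, 0.2))
  expect_equal(d$filtered, c(0.7, 0.2))   # drops |0.1| < 0.15, keeps 0.2
  same <- score_difference_distribution(
    data.frame(donor_score = rep(0.4, 3), acceptor_score = rep(0.4, 3)))
  expect_true(all(same$differences == 0))
})

test_that("junctions are scored in order with min-rule scores and error records", {
  m <- splice_model(seed = 8)
  g <- genome_handle(c(cc = rand_dna(5000, seed = 55)))
  j <- junction_frame(contig = c("cc", "missing", "cc"),
                      start = c(1000L, 10L, 2000L),
                      end = c(1500L, 50L, 2300L), strand = "+")
  expect_warning(s <- score_junctions(j, g, m), "absent")
  expect_equal(s$ok, c(TRUE, FALSE, TRUE))
  expect_true(is.na(s$junction_score[2]))
  expect_equal(s$junction_score[c(1, 3)],
               pmin(s$donor_score, s$acceptor_score)[c(1, 3)])
  # an all-N window still scores without crashing
  gn <- genome_handle(c(nn = strrep("N", 2000)))
  jn <- junction_frame(contig = "nn", start = 800L, end = 1200L, strand = "+")
  sn <- score_junctions(jn, gn, m)
  expect_true(sn$donor_score >= 0 && sn$donor_score <= 1)
})

test_that("test-set composition honours the requested ratios", {
  mk <- function(n, label) junction_frame(contig = "c", start = (1:n) * 1000L,
                                          end = (1:n) * 1000L + 100L,
                                          strand = "+", label = label)
  j <- rbind(mk(400, "positive-main"), mk(400, "positive-alt"),
             mk(500, "negative-1"), mk(500, "negative-random"))
  j$start <- seq_len(nrow(j)) * 1000L; j$end <- j$start + 100L
  ts <- compose_test_set(j, n_per_negative_class = 100L, ratio = "1:1",
                         seed = 3)
  expect_equal(sum(ts$is_positive), 200L)
  expect_equal(sum(!ts$is_positive), 200L)
  ts10 <- compose_test_set(j, n_per_negative_class = 100L, ratio = "1:10",
                           seed = 3)
  expect_equal(sum(ts10$is_positive), 20L)
  expect_equal(sum(!ts10$is_positive), 200L)
  ts2 <- compose_test_set(j, n_per_negative_class = 100L, ratio = "1:1",
                          seed = 3)
  expect_identical(ts, ts2)
})
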