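#' Score junctions from a BED file or junction table
#'
#' Encodes each junction's 800nt pair window and runs the network in
#' evaluation mode.  The donor score is the donor-channel output at window
#' position 200 and the acceptor score the acceptor-channel output at 600;
#' the junction score is the minimum of the two, reflecting that a junction
#' is only as believable as its weaker site.  Results are order-preserving
#' and independent of the batch size.
#'
#' @param junctions A [junction_frame()] or a BED6 path.
#' @param genome A [genome_handle()] or FASTA path.
#' @param model A trained `splice_net` or a checkpoint path.
#' @param batch_size Windows per forward pass.
#' @return The junction table with `donor_score`, `acceptor_score`,
#'   `junction_score` and `ok` (FALSE for junctions on unknown contigs,
#'   which are reported rather than silently dropped) columns appended.
#' @export
score_junctions <- function(junctions, genome, model, batch_size = 64L) {
  if (is.character(junctions)) junctions <- read_junction_bed(junctions)
  genome <- genome_handle(genome)
  if (is.character(model)) model <- load_splice_model(model)
  out <- junctions
  out$donor_score <- NA_real_
  out$acceptor_score <- NA_real_
  out$junction_score <- NA_real_
  out$ok <- out$contig %in% contig_names(genome)
  if (any(out$ok)) {
    idx <- which(out$ok)
    win <- extract_pair_window(genome, out[idx, , drop = FALSE])
    s <- predict(model, win, type = "sites", batch_size = batch_size)
    out$donor_score[idx] <- s$donor_score
    out$acceptor_score[idx] <- s$acceptor_score
    out$junction_score[idx] <- pmin(s$donor_score, s$acceptor_score)
  }
  if (any(!out$ok))
    warning(sprintf("%d junction(s) on contigs absent from the genome",
                    sum(!out$ok)))
  out
}

#' Write scored junctions as augmented BED
#'
#' BED6 columns followed by donor, acceptor and junction score.
#'
#' @param scored Result of [score_junctions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scored_bed <- function(scored, path) {
  ord <- order(scored$contig, scored$start, scored$end, scored$strand)
  s <- scored[ord, , drop = FALSE]
  writeLines(paste(s$contig, s$start, s$end, s$name, s$support, s$strand,
                   sprintf("%.6f", s$donor_score),
                   sprintf("%.6f", s$acceptor_score),
                   sprintf("%.6f", s$junction_score), sep = "\t"), path)
  invisible(path)
}

#' Confusion-matrix report at a score threshold
#'
#' A junction is predicted positive iff its score is `>= threshold` (with
#' the min-rule junction score this equals requiring both sites to clear the
#' threshold).  Accuracy is the proportion of correct predictions among all
#' predictions, precision the proportion of predicted positives that are
#' true, and recall the proportion of true junctions predicted positive.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels Logical (or 0/1) true-class labels.
#' @param threshold Decision threshold in \[0, 1\].
#' @return An object of class `classification_report`: a list of counts and
#'   metrics.  When nothing is predicted positive, precision is reported as
#'   0 with `degenerate_precision = TRUE`.
#' @export
classify_at_threshold <- function(scores, labels, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  labels <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  degenerate <- (tp + fp) == 0L
  if (degenerate && (tp + fn) > 0L)
    warning("no predicted positives at this threshold; precision reported as 0")
  precision <- if (degenerate) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (!is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(threshold = threshold, TP = tp, FP = fp, FN = fn, TN = tn,
                 accuracy = (tp + tn) / length(scores),
                 precision = precision, recall = recall, f1 = f1,
                 degenerate_precision = degenerate),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("threshold %.3f: TP %d FP %d FN %d TN %d\n", x$threshold,
              x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("  accuracy %.4f precision %.4f recall %.4f F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Discrimination-threshold sweep
#'
#' Precision, recall and F1 over a grid of thresholds, and the threshold
#' maximizing F1 (ties resolved to the smallest threshold).
#'
#' @inheritParams classify_at_threshold
#' @param grid Thresholds to evaluate.
#' @return Data frame `threshold`, `precision`, `recall`, `f1` with
#'   attribute `"best_threshold"`.
#' @export
threshold_sweep <- function(scores, labels, grid = seq(0, 1, by = 0.01)) {
  if (any(grid < 0 | grid > 1)) stop("grid must lie in [0, 1]")
  rows <- lapply(grid, function(t) {
    r <- suppressWarnings(classify_at_threshold(scores, labels, t))
    data.frame(threshold = t, precision = r$precision, recall = r$recall,
               f1 = r$f1)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_threshold") <- out$threshold[which.max(out$f1)]
  out
}

#' ROC and precision-recall curves with AUCs
#'
#' Standard rank-based curves; both areas are computed by the trapezoid
#' rule.  Ties in scores are handled by grouping (one curve point per
#' distinct score).
#'
#' @inheritParams classify_at_threshold
#' @return List with `roc` (data frame `fpr`, `tpr`, `threshold`),
#'   `pr` (`recall`, `precision`, `threshold`), `auc_roc`, `auc_pr`.
#' @export
curves_and_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L)
    stop("both classes must be present to compute curves")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- !duplicated(s, fromLast = TRUE)   # last index of each tie group
  ctp <- cumsum(y)[grp]; cfp <- cumsum(!y)[grp]; thr <- s[grp]
  tpr <- c(0, ctp / P); fpr <- c(0, cfp / N)
  prec <- c(1, ctp / (ctp + cfp)); rec <- c(0, ctp / P)
  auc_roc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  auc_pr <- sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = c(Inf, thr)),
       pr = data.frame(recall = rec, precision = prec,
                       threshold = c(Inf, thr)),
       auc_roc = auc_roc, auc_pr = auc_pr)
}

#' Donor-acceptor score differences
#'
#' Per-junction `donor_score - acceptor_score`, optionally excluding small
#' differences (|difference| < 0.15 by default) to focus on junctions whose
#' two sites disagree.
#'
#' @param scored Result of [score_junctions()] (or a data frame with
#'   `donor_score`/`acceptor_score`).
#' @param filter Drop differences with absolute value below `min_abs`.
#' @param min_abs Exclusion half-width for the filtered view.
#' @return List with `differences`, the `filtered` view, and a `summary`.
#' @export
score_difference_distribution <- function(scored, filter = FALSE,
                                          min_abs = 0.15) {
  d <- scored$donor_score - scored$acceptor_score
  filtered <- d[abs(d) >= min_abs]
  list(differences = d,
       filtered = if (filter) filtered else d[abs(d) >= min_abs],
       summary = c(mean = mean(d), sd = stats::sd(d),
                   frac_large = if (length(d)) length(filtered) / length(d)
                                else NA_real_))
}

#' Assemble a test set with a chosen positive:negative ratio
#'
#' Seeded sampler reproducing the test-set recipes used for evaluation:
#' equal numbers from the two positive classes and the two negative classes,
#' at an overall positive-to-negative ratio of 1:1 or 1:10.
#'
#' @param labeled A `labeled_junctions` object (its `test` partition is
#'   sampled) or a junction frame with `label`.
#' @param n_per_negative_class Junctions drawn from each negative class.
#' @param ratio `"1:1"` or `"1:10"` positive:negative.
#' @param classes Positive classes to include.
#' @param seed RNG seed.
#' @return A [junction_frame()] with a logical `is_positive` column.
#' @export
compose_test_set <- function(labeled, n_per_negative_class = 10000L,
                             ratio = c("1:1", "1:10"),
                             classes = c("positive-main", "positive-alt"),
                             seed = 1L) {
  ratio <- match.arg(ratio)
  j <- if (inherits(labeled, "labeled_junctions")) labeled$test else labeled
  neg_classes <- c("negative-1", "negative-random")
  per_pos <- if (ratio == "1:1")
    n_per_negative_class * length(neg_classes) / length(classes)
  else n_per_negative_class * length(neg_classes) / 10L / length(classes)
  take <- function(df, n) {
    if (nrow(df) <= n) df else df[sort(sample.int(nrow(df), n)), , drop = FALSE]
  }
  with_seed(seed, {
    parts <- c(
      lapply(classes, function(cl)
        take(j[j$label == cl, , drop = FALSE], round(per_pos))),
      lapply(neg_classes, function(cl)
        take(j[j$label == cl, , drop = FALSE], n_per_negative_class)))
    out <- do.call(rbind, parts)
    out$is_positive <- startsWith(out$label, "positive")
    rownames(out) <- NULL
    out
  })
}
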