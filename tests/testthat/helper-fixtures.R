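# shared fixtures, memoised so expensive generation happens once per run

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small two-contig fixture for fast pipeline tests
small_spec <- function(seed = 9, ...) {
  fixture_spec(n_contigs = 2L, contig_length = 120000L,
               genes_per_contig = 15L, coverage = 10L, seed = seed, ...)
}

get_fixture <- function() memo("fixture", generate_genome(small_spec()))

get_sim <- function() memo("sim", simulate_spliced_alignments(get_fixture()))

# the desk-scale training fixture and the model trained on it (shared by the
# acceptance checks and the training-behaviour tests)
get_training_fixture <- function() memo("trainfix", build_training_fixture())

# desk-scale recipe: one epoch, small batches and a cooler learning rate so
# the optimizer takes a few hundred stable steps on a few thousand windows
# (the published full-scale recipe in train_config() assumes ~10^5 steps)
desk_train_config <- function() {
  train_config(epochs = 1L, batch_size = 16L, lr = 1e-3, warmup_steps = 25L,
               seed = 1L)
}

get_trained_model <- function() {
  memo("trained", {
    fx <- get_training_fixture()
    model <- splice_model(seed = 1)
    train_splice(model, fx$train$windows, fx$train$positive,
                 desk_train_config())
  })
}

# independent confusion-matrix oracle
brute_confusion <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  c(TP = sum(pred & labels), FP = sum(pred & !labels),
    FN = sum(!pred & labels), TN = sum(!pred & !labels))
}

# AUC-ROC as pairwise concordance (ties count 1/2)
brute_auc <- function(scores, labels) {
  p <- scores[labels]; n <- scores[!labels]
  cmp <- outer(p, n, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# brute-force dilated grouped convolution straight from the definition:
# out(n, oc) = sum over s + D*t = n of in(s, ic) * K(t)
brute_gconv <- function(x, w, b, G, W, D) {
  L <- nrow(x); Cin <- ncol(x); Cout <- ncol(w); cpg <- Cin / G
  pad <- D * (W - 1) / 2
  out <- matrix(0, L, Cout)
  for (oc in seq_len(Cout)) {
    g <- (oc - 1) %/% (Cout / G)
    for (n in seq_len(L)) {
      acc <- b[oc]
      for (ic in seq_len(cpg)) for (t in seq_len(W)) {
        s <- n + (t - 1) * D - pad
        if (s >= 1 && s <= L)
          acc <- acc + x[s, g * cpg + ic] * w[(ic - 1) * W + t, oc]
      }
      out[n, oc] <- acc
    }
  }
  out
}

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal GFF3 with one 3-exon transcript plus optional extras
tiny_gff <- function(extra = character(0)) {
  write_tmp(c(
    "##gff-version 3",
    "chrA\ttest\tgene\t1\t500\t.\t+\t.\tID=g1;gene_biotype=protein_coding",
    "chrA\ttest\tmRNA\t1\t500\t.\t+\t.\tID=t1;Parent=g1",
    "chrA\ttest\texon\t1\t100\t.\t+\t.\tParent=t1",
    "chrA\ttest\texon\t201\t300\t.\t+\t.\tParent=t1",
    "chrA\ttest\texon\t401\t500\t.\t+\t.\tParent=t1",
    extra), ".gff3")
}
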