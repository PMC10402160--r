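#' Network architecture configuration
#'
#' The reference architecture: 20 residual units in 5 groups of 4, all with
#' F = 64 filters, grouped (G = 4) dilated 1-D convolutions with per-group
#' window sizes `c(11, 11, 11, 21, 21)` and dilation rates
#' `c(1, 5, 10, 15, 20)`, pre-activation ordering (batch norm, leaky ReLU
#' with slope 0.1, convolution) inside each unit, an identity shortcut per
#' unit, a 1x1 stem convolution, a 1x1 skip projection of the stem plus one
#' per residual group accumulated into a skip sum, one further 1x1
#' convolution on the skip sum, and a 3-channel 1x1 output convolution with a
#' per-position softmax.
#'
#' @param filters Channels in every convolutional layer (F).
#' @param window_sizes Kernel width per residual group (W, must be odd).
#' @param dilations Dilation rate per residual group (D).
#' @param groups Channel groups in residual-unit convolutions (G).
#' @param units_per_group Residual units per group.
#' @param input_length Window length the model scores (800).
#' @param lrelu_slope Negative slope of the leaky ReLU.
#' @param bn_momentum,bn_eps Batch-norm running-average momentum and variance
#'   epsilon.
#' @return An object of class `splice_config`.
#' @export
splice_config <- function(filters = 64L,
                          window_sizes = c(11L, 11L, 11L, 21L, 21L),
                          dilations = c(1L, 5L, 10L, 15L, 20L),
                          groups = 4L,
                          units_per_group = 4L,
                          input_length = 800L,
                          lrelu_slope = 0.1,
                          bn_momentum = 0.1,
                          bn_eps = 1e-5) {
  if (length(window_sizes) != length(dilations))
    stop("window_sizes and dilations must have equal length")
  if (any(window_sizes %% 2 == 0))
    stop("window sizes must be odd (symmetric padding)")
  if (filters %% groups != 0)
    stop("filters must be divisible by groups")
  structure(list(filters = as.integer(filters),
                 window_sizes = as.integer(window_sizes),
                 dilations = as.integer(dilations),
                 groups = as.integer(groups),
                 units_per_group = as.integer(units_per_group),
                 n_groups = length(window_sizes),
                 input_length = as.integer(input_length),
                 in_channels = 4L,
                 out_channels = 3L,
                 lrelu_slope = lrelu_slope,
                 bn_momentum = bn_momentum,
                 bn_eps = bn_eps),
            class = "splice_config")
}

#' Receptive span of the residual stack
#'
#' Each dilated convolution widens the neighbourhood feeding one output
#' position by `D * (W - 1)` per layer; over the two convolutions of each of
#' the residual units, the total span is `S = sum over units of 2 * D * (W - 1)`.
#'
#' @param config A [splice_config()].
#' @return The span S in positions (6880 for the reference configuration).
#' @export
receptive_span <- function(config = splice_config()) {
  sum(config$units_per_group * 2L * config$dilations *
        (config$window_sizes - 1L))
}

# per-block parameter layout, mirrored exactly by the C++ engine
param_layout <- function(config) {
  F <- config$filters; cpg <- F %/% config$groups
  blocks <- list(c("stem_w", config$in_channels * F), c("stem_b", F),
                 c("skip0_w", F * F), c("skip0_b", F))
  for (g in seq_len(config$n_groups)) {
    wsz <- cpg * config$window_sizes[g] * F
    for (u in seq_len(config$units_per_group)) {
      p <- sprintf("g%du%d_", g, u)
      blocks <- c(blocks, list(
        c(paste0(p, "bn1_gamma"), F), c(paste0(p, "bn1_beta"), F),
        c(paste0(p, "conv1_w"), wsz), c(paste0(p, "conv1_b"), F),
        c(paste0(p, "bn2_gamma"), F), c(paste0(p, "bn2_beta"), F),
        c(paste0(p, "conv2_w"), wsz), c(paste0(p, "conv2_b"), F)))
    }
    blocks <- c(blocks, list(c(sprintf("g%d_out_w", g), F * F),
                             c(sprintf("g%d_out_b", g), F)))
  }
  blocks <- c(blocks, list(c("penult_w", F * F), c("penult_b", F),
                           c("out_w", F * config$out_channels),
                           c("out_b", config$out_channels)))
  sizes <- vapply(blocks, function(b) as.integer(b[2]), integer(1))
  names(sizes) <- vapply(blocks, `[`, character(1), 1)
  offsets <- cumsum(c(0L, sizes))[seq_along(sizes)]
  names(offsets) <- names(sizes)
  list(sizes = sizes, offsets = offsets, total = sum(sizes))
}

# engine-facing config list
engine_cfg <- function(config) {
  list(filters = config$filters, groups = config$groups,
       units_per_group = config$units_per_group, n_groups = config$n_groups,
       in_channels = config$in_channels, out_channels = config$out_channels,
       window_sizes = config$window_sizes, dilations = config$dilations,
       lrelu_slope = config$lrelu_slope, bn_eps = config$bn_eps,
       bn_momentum = config$bn_momentum)
}

# uniform(-k, k) with k = 1/sqrt(fan_in) for each conv; batch-norm gamma 1,
# beta 0; running stats (mean 0, var 1) kept separately.  The output head
# uses prior-probability initialisation: small weights and logit biases such
# that donor/acceptor start near probability 0.01 - the standard remedy for
# focal-loss training on extremely label-sparse outputs, preventing the
# early collapse into the all-"neither" solution.
init_parameters <- function(config, seed = NULL, rare_prior = 0.01) {
  lay <- param_layout(config)
  par <- numeric(lay$total)
  cpg <- config$filters %/% config$groups
  with_seed(seed, {
    for (nm in names(lay$sizes)) {
      i0 <- lay$offsets[[nm]]; n <- lay$sizes[[nm]]
      idx <- (i0 + 1L):(i0 + n)
      if (grepl("bn._gamma$", nm)) par[idx] <- 1
      else if (grepl("bn._beta$", nm)) par[idx] <- 0
      else if (nm == "out_w") par[idx] <- rnorm(n, 0, 0.01)
      else if (nm == "out_b") {
        b <- rep(-log((1 - rare_prior) / rare_prior), config$out_channels)
        b[channel_index("neither")] <- 0
        par[idx] <- b
      } else {
        fan_in <- if (nm == "stem_w" || nm == "stem_b") config$in_channels
        else if (grepl("conv._[wb]$", nm)) {
          g <- as.integer(sub("^g(\\d+).*", "\\1", nm))
          cpg * config$window_sizes[g]
        } else config$filters
        k <- 1 / sqrt(fan_in)
        par[idx] <- runif(n, -k, k)
      }
    }
  })
  par
}

#' Build the splice-junction recognition network
#'
#' Constructs an untrained model of class `splice_net` with randomly
#' initialised parameters.  Train it with [train_splice()] and apply it with
#' [predict()] or [score_junctions()].
#'
#' @param config A [splice_config()].
#' @param seed RNG seed for parameter initialisation (uses the session RNG
#'   when `NULL`).
#' @return An object of class `splice_net`.
#' @export
splice_model <- function(config = splice_config(), seed = NULL) {
  par <- init_parameters(config, seed)
  # running stats per unit: mean1 = 0, var1 = 1, mean2 = 0, var2 = 1
  bnstats <- rep(rep(c(0, 1, 0, 1), each = config$filters),
                 times = config$n_groups * config$units_per_group)
  stopifnot(length(par) == cpp_param_count(engine_cfg(config)))
  structure(list(config = config, par = par, bnstats = bnstats,
                 trained = FALSE, history = NULL),
            class = "splice_net")
}

#' Count trainable parameters
#'
#' Sums every trainable scalar: convolution weights and biases plus the
#' batch-norm scale/shift pairs.  Batch-norm running statistics are not
#' parameters and are excluded.  The reference configuration yields 651,715.
#'
#' @param model A `splice_net` (or a [splice_config()]).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  config <- if (inherits(model, "splice_config")) model else model$config
  param_layout(config)$total
}

#' @export
print.splice_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("splice_net: %s residual units (%d groups x %d), F=%d, G=%d\n",
              cfg$n_groups * cfg$units_per_group, cfg$n_groups,
              cfg$units_per_group, cfg$filters, cfg$groups))
  cat(sprintf("  W = [%s], D = [%s]\n",
              paste(cfg$window_sizes, collapse = ", "),
              paste(cfg$dilations, collapse = ", ")))
  cat(sprintf("  parameters: %s; receptive span: %s nt\n",
              format(count_parameters(x), big.mark = ","),
              format(receptive_span(cfg), big.mark = ",")))
  cat(sprintf("  trained: %s\n", if (x$trained) "yes" else "no"))
  invisible(x)
}

#' @export
summary.splice_net <- function(object, ...) {
  print(object)
  lay <- param_layout(object$config)
  cat("parameter blocks:\n")
  grp <- sub("^g(\\d+)u\\d+_.*", "residual group \\1", names(lay$sizes))
  grp[!startsWith(names(lay$sizes), "g") |
        grepl("_out_[wb]$", names(lay$sizes))] <-
    names(lay$sizes)[!startsWith(names(lay$sizes), "g") |
                       grepl("_out_[wb]$", names(lay$sizes))]
  tab <- tapply(lay$sizes, grp, sum)
  for (nm in names(tab))
    cat(sprintf("  %-20s %s\n", nm, format(tab[[nm]], big.mark = ",")))
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("training: %d steps, final loss %.5f\n",
                nrow(h), h$loss[nrow(h)]))
  }
  invisible(object)
}

#' Score windows with the network
#'
#' @param object A trained `splice_net`.
#' @param windows Character vector of input windows (length
#'   `config$input_length`), e.g. from [extract_pair_window()].
#' @param type `"sites"` for a data frame of donor/acceptor probabilities at
#'   the label positions, `"matrix"` for the full per-position score array.
#' @param batch_size Windows per forward pass.
#' @param ... Unused.
#' @return For `"sites"`, a data frame with `donor_score` and
#'   `acceptor_score`; for `"matrix"`, a `3 x L x n` array (channels
#'   `neither`, `acceptor`, `donor`).
#' @export
predict.splice_net <- function(object, windows, type = c("sites", "matrix"),
                               batch_size = 64L, ...) {
  type <- match.arg(type)
  L <- object$config$input_length
  n <- length(windows)
  if (!n) {
    if (type == "sites")
      return(data.frame(donor_score = numeric(0), acceptor_score = numeric(0)))
    return(array(numeric(0), dim = c(3, L, 0)))
  }
  if (any(nchar(windows) != L))
    stop("all windows must have length ", L)
  cfg <- engine_cfg(object$config)
  res <- if (type == "sites") {
    data.frame(donor_score = numeric(n), acceptor_score = numeric(n))
  } else array(0, dim = c(3, L, n),
               dimnames = list(channel_names(), NULL, NULL))
  for (b0 in seq(1L, n, by = batch_size)) {
    b1 <- min(b0 + batch_size - 1L, n)
    codes <- encode_codes(windows[b0:b1])
    P <- cpp_net_forward(object$par, object$bnstats, codes, cfg, FALSE)
    nb <- b1 - b0 + 1L
    if (type == "sites") {
      don <- P[(seq_len(nb) - 1L) * L + DONOR_INDEX + 1L,
               channel_index("donor")]
      acc <- P[(seq_len(nb) - 1L) * L + ACCEPTOR_INDEX + 1L,
               channel_index("acceptor")]
      res$donor_score[b0:b1] <- don
      res$acceptor_score[b0:b1] <- acc
    } else {
      for (j in seq_len(nb))
        res[, , b0 + j - 1L] <- t(P[((j - 1L) * L + 1L):(j * L), ])
    }
  }
  res
}

#' Plot training history
#'
#' @param x A trained `splice_net`.
#' @param ... Passed to [plot()].
#' @export
plot.splice_net <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(h$step, h$loss, type = "l", xlab = "step", ylab = "focal loss",
       main = "training loss", ...)
  plot(h$step, h$lr, type = "l", xlab = "step", ylab = "learning rate",
       main = "schedule", ...)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with a versioned header carrying the architecture
#' configuration, the flat parameter vector, batch-norm running statistics
#' and the training history.
#'
#' @param model A `splice_net`.
#' @param path Checkpoint path.
#' @return `save_splice_model` returns `path` invisibly; `load_splice_model`
#'   returns the restored `splice_net`.
#' @export
save_splice_model <- function(model, path) {
  stopifnot(inherits(model, "splice_net"))
  obj <- list(format = "spliceguard-checkpoint", version = 1L,
              config = model$config, par = model$par,
              bnstats = model$bnstats, trained = model$trained,
              history = model$history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_splice_model
#' @export
load_splice_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "spliceguard-checkpoint"))
    stop("not a spliceguard checkpoint: ", path)
  structure(list(config = obj$config, par = obj$par, bnstats = obj$bnstats,
                 trained = obj$trained, history = obj$history),
            class = "splice_net")
}
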