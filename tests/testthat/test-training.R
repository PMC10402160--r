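test_that("cross-entropy matches hand values and is non-negative", {
  I <- diag(3)
  expect_equal(cross_entropy(I, diag(3) * 0.999998 + 1e-6), 0,
               tolerance = 1e-5)
  # single position, true donor with probability one half
  expect_equal(cross_entropy(c(0, 0, 1), c(0.25, 0.25, 0.5)), log(2))
  set.seed(40)
  for (i in 1:20) {
    P <- matrix(runif(30), 3); P <- sweep(P, 2, colSums(P), "/")
    I <- matrix(0, 3, 10); I[cbind(sample(3, 10, TRUE), 1:10)] <- 1
    expect_gte(cross_entropy(I, P), 0)
  }
})

test_that("focal loss reduces to cross-entropy at gamma 0 and matches hand value", {
  set.seed(41)
  P <- matrix(runif(30), 3); P <- sweep(P, 2, colSums(P), "/")
  I <- matrix(0, 3, 10); I[cbind(sample(3, 10, TRUE), 1:10)] <- 1
  expect_equal(focal_loss(I, P, gamma = 0), cross_entropy(I, P),
               tolerance = 1e-10)
  # true donor at P = 0.5, gamma = 2: (1-0.5)^2 * ln 2
  expect_equal(focal_loss(c(0, 0, 1), c(0.25, 0.25, 0.5), gamma = 2),
               0.25 * log(2))
  expect_equal(round(focal_loss(c(0, 0, 1), c(0.25, 0.25, 0.5), 2), 4), 0.1733)
  # the modulating factor only ever shrinks the loss
  for (g in c(0.5, 1, 2, 5))
    expect_lte(focal_loss(I, P, g), cross_entropy(I, P))
})

test_that("focal-loss gradient matches a numerical derivative", {
  set.seed(42)
  P <- matrix(runif(15, 0.05, 0.95), 3, 5)
  I <- matrix(0, 3, 5); I[cbind(sample(3, 5, TRUE), 1:5)] <- 1
  g <- 2
  # analytic dL/dP at true-class entries
  analytic <- -I * (-g * (1 - P)^(g - 1) * log(P) + (1 - P)^g / P)
  h <- 1e-6
  for (k in which(I == 1)) {
    P1 <- P; P1[k] <- P1[k] + h
    P2 <- P; P2[k] <- P2[k] - h
    num <- (focal_loss(I, P1, g) - focal_loss(I, P2, g)) / (2 * h)
    expect_equal(num, analytic[k], tolerance = 1e-4)
  }
})

test_that("the engine's batch loss equals the weighted focal-loss oracle", {
  m <- splice_model(seed = 6)
  set.seed(43)
  wins <- replicate(4, rand_dna(800))
  pos <- c(TRUE, FALSE, TRUE, FALSE)
  cfg <- spliceguard:::engine_cfg(m$config)
  codes <- spliceguard:::encode_codes(wins)
  res <- spliceguard:::cpp_net_train_batch(m$par, m$bnstats, codes, pos,
                                           2, 3, cfg)
  # oracle: per-position focal loss from the train-mode probabilities,
  # positive windows weighted x3, mean over batch x positions
  P <- spliceguard:::cpp_net_forward(m$par, m$bnstats, codes, cfg, TRUE)
  total <- 0
  for (i in seq_along(wins)) {
    rows <- (i - 1) * 800 + 1:800
    Pi <- t(P[rows, ])
    I <- make_label(wins[i], positive = pos[i])[c(1, 2, 3), ]
    total <- total + (if (pos[i]) 3 else 1) * focal_loss(I, Pi, 2)
  }
  expect_equal(res$loss, total / (4 * 800), tolerance = 1e-5)
})

test_that("network gradients agree with finite differences", {
  m <- splice_model(seed = 3)
  set.seed(44)
  codes <- spliceguard:::encode_codes(replicate(2, rand_dna(800)))
  pos <- c(TRUE, FALSE)
  cfg <- spliceguard:::engine_cfg(m$config)
  g <- spliceguard:::cpp_net_train_batch(m$par, m$bnstats, codes, pos,
                                         2, 3, cfg)$grad
  idx <- order(-abs(g))[c(1, 3, 7, 15)]
  h <- 2e-3
  for (i in idx) {
    p1 <- m$par; p1[i] <- p1[i] + h
    p2 <- m$par; p2[i] <- p2[i] - h
    num <- (spliceguard:::cpp_net_loss(p1, codes, pos, 2, 3, cfg) -
              spliceguard:::cpp_net_loss(p2, codes, pos, 2, 3, cfg)) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-3)
  }
})

test_that("the learning-rate schedule ramps linearly then decays by cosine", {
  cfg <- train_config(lr = 0.03, warmup_steps = 1000L)
  expect_equal(lr_at_step(0, 10000, cfg), 0)
  expect_equal(lr_at_step(500, 10000, cfg), 0.015)
  expect_equal(lr_at_step(1000, 10000, cfg), 0.03)
  expect_equal(lr_at_step(5500, 10000, cfg), 0.015)   # decay midpoint
  expect_equal(lr_at_step(10000, 10000, cfg), 0)
  expect_error(lr_at_step(10, 500, cfg), "warmup")
  none <- train_config(lr = 0.03, warmup_steps = 0L)
  expect_equal(lr_at_step(0, 100, none), 0.03)
})

test_that("training records one optimizer step per mini-batch and is seeded", {
  set.seed(45)
  wins <- replicate(10, rand_dna(800))
  pos <- rep(c(TRUE, FALSE), 5)
  cfg <- train_config(epochs = 1L, batch_size = 100L, warmup_steps = 1L,
                      seed = 7L)
  m1 <- train_splice(splice_model(seed = 5), wins, pos, cfg)
  expect_equal(nrow(m1$history), 1L)   # ceil(10/100) = 1 step
  expect_true(m1$trained)
  m2 <- train_splice(splice_model(seed = 5), wins, pos, cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$par, m2$par)
  expect_error(train_splice(splice_model(seed = 5), character(0), logical(0),
                            cfg), "empty")
})

test_that("training configurations round-trip through key=value text", {
  cfg <- train_config(batch_size = 16L, lr = 1e-3, warmup_steps = 25L,
                      seed = 3L)
  p <- tempfile(fileext = ".cfg")
  write_train_config(cfg, p)
  back <- read_train_config(p)
  expect_equal(back$lr, cfg$lr)
  expect_equal(back$batch_size, cfg$batch_size)
  expect_equal(back$gamma, cfg$gamma)
  expect_equal(back$weight_decay, cfg$weight_decay)
})

test_that("desk-scale training reduces the focal loss over the run", {
  m <- get_trained_model()
  h <- m$history
  first <- mean(head(h$loss, 5))
  last <- mean(tail(h$loss, 5))
  expect_lt(last, first)
})
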