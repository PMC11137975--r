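test_that("config validation enforces positive sizes", {
  expect_error(extractor_config(seq_length = 0), "positive")
  expect_error(extractor_config(hidden_units = -2), "positive")
  cfg <- extractor_config(seq_length = 40, embedding_dim = 5,
                          hidden_units = 10)
  expect_s3_class(cfg, "ncp_extractor_config")
})

test_that("two builds with the same seed share identical parameters", {
  cfg <- tiny_config()
  m1 <- build_extractor(cfg)
  m2 <- build_extractor(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_extractor(tiny_config(seed = 8))
  expect_false(identical(m1$params, m3$params))
})

test_that("a hand-set single-unit cell reproduces the gate equations", {
  # 1 hidden unit, 1-dim embedding, scalar weights: evaluate the update
  # gate, reset gate, candidate and convex-combination state by hand over
  # two steps and compare with the compiled cell.
  cfg <- extractor_config(seq_length = 2, embedding_dim = 1,
                          hidden_units = 1, batch_size = 1, seed = 1)
  m <- build_extractor(cfg)
  p <- m$params
  p$E <- matrix(c(0, 0.5, -0.25, 0.8, -0.6, 0.1), nrow = 1)  # tokens 0..5
  p$Wu_h <- matrix(0.3); p$Wu_x <- matrix(-0.7); p$bu <- 0.1
  p$Wr_h <- matrix(-0.2); p$Wr_x <- matrix(0.4); p$br <- -0.3
  p$Wc_h <- matrix(0.6); p$Wc_x <- matrix(0.9); p$bc <- 0.05
  p$head_w <- c(1, 1); p$head_b <- 0

  sig <- function(x) 1 / (1 + exp(-x))
  h <- 0
  expected <- numeric(2)
  tokens <- c(1L, 3L)  # A then G
  for (t in 1:2) {
    x <- p$E[1, tokens[t] + 1]
    u <- sig(0.3 * h - 0.7 * x + 0.1)
    r <- sig(-0.2 * h + 0.4 * x - 0.3)
    hc <- tanh(0.6 * (r * h) + 0.9 * x + 0.05)
    h <- u * hc + (1 - u) * h
    expected[t] <- h  # max over one unit is the unit itself
  }
  got <- ncpred:::gru_batch_cpp(p, matrix(tokens, ncol = 1), numeric(0), FALSE, FALSE)
  expect_equal(as.numeric(got$features), expected, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  for (bi in c(FALSE, TRUE)) {
    cfg <- extractor_config(seq_length = 7, embedding_dim = 3,
                            hidden_units = 4, bidirectional = bi,
                            batch_size = 2, seed = 3)
    m <- build_extractor(cfg)
    set.seed(9)
    X <- matrix(sample(0:5, 14, replace = TRUE), nrow = 7)
    y <- c(0, 1)
    res <- ncpred:::gru_batch_cpp(m$params, X, y, bi, TRUE)
    loss_at <- function(params) ncpred:::gru_batch_cpp(params, X, y, bi, FALSE)$loss
    for (nm in names(res$grads)) {
      g <- res$grads[[nm]]
      idx <- seq_len(min(length(g), 4))
      for (i in idx) {
        eps <- 1e-6
        p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
        expect_equal(g[i], num, tolerance = 1e-3,
                     info = paste(nm, i, "bidirectional:", bi))
      }
    }
  }
})

test_that("feature dimension is input-independent and finite", {
  for (bi in c(FALSE, TRUE)) {
    m <- build_extractor(tiny_config(bidirectional = bi))
    set.seed(31)
    for (i in 1:10) {
      s <- random_seq(sample(3:120, 1), p_n = 0.1)
      v <- extract_deep_features(m, encode_indices(s, 60))
      expect_length(v, 60)
      expect_true(all(is.finite(v)))
    }
    # all-padding input stays finite
    v0 <- extract_deep_features(m, integer(60))
    expect_true(all(is.finite(v0)))
    expect_error(extract_deep_features(m, integer(10)), "expects 60")
  }
})

test_that("batch extraction equals per-input extraction in row order", {
  m <- build_extractor(tiny_config())
  d <- toy_dataset(4, seed = 12)
  enc <- encode_dataset(d, 60)
  batch <- extract_deep_features_batch(m, enc)
  expect_equal(dim(batch), c(8L, 60L))
  for (i in c(1, 5, 8)) {
    single <- extract_deep_features(m, enc[, i])
    expect_equal(unname(unlist(batch[i, ])), as.numeric(single))
  }
  empty <- extract_deep_features_batch(m, enc[, 0, drop = FALSE])
  expect_equal(nrow(empty), 0L)
})

test_that("training reduces loss on motif-separable data and is deterministic", {
  # positives carry an ATGATGATG prefix; the rest is random
  set.seed(41)
  n <- 100
  pos <- replicate(n / 2, paste0("ATGATGATG", random_seq(40)))
  neg <- replicate(n / 2, random_seq(49))
  d <- tibble::tibble(id = paste0("s", 1:n), seq = c(pos, neg),
                      label = factor(rep(c("ncRNA", "mRNA"), each = n / 2),
                                     levels = c("mRNA", "ncRNA")),
                      length = 49L)
  enc <- encode_dataset(d, 60)
  m1 <- train_extractor(build_extractor(tiny_config(epochs = 6)), enc, d$label)
  h <- tidy(m1)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])

  m2 <- train_extractor(build_extractor(tiny_config(epochs = 6)), enc, d$label)
  expect_identical(m1$params, m2$params)
  expect_equal(tidy(m2), h)

  expect_error(train_extractor(build_extractor(tiny_config()), enc,
                               rep("ncRNA", n)), "both classes")
})

test_that("a linear probe on extracted features separates motif classes", {
  set.seed(42)
  n <- 120
  pos <- replicate(n / 2, paste0("ATGATGATGATG", random_seq(30)))
  neg <- replicate(n / 2, random_seq(42))
  d <- tibble::tibble(id = paste0("s", 1:n), seq = c(pos, neg),
                      label = factor(rep(c("ncRNA", "mRNA"), each = n / 2),
                                     levels = c("mRNA", "ncRNA")),
                      length = 42L)
  sp <- split_dataset(d, 0.7, seed = 2)
  all_d <- dplyr::bind_rows(sp$train, sp$validation)
  tm <- seq_len(nrow(all_d)) <= nrow(sp$train)
  enc <- encode_dataset(all_d, 60)
  m <- train_extractor(build_extractor(tiny_config(epochs = 10)),
                       enc[, tm], all_d$label[tm])
  deep <- extract_deep_features_batch(m, enc)
  fused <- fuse_features(deep, deep[, 0], train = tm)
  probe <- train_classifier(fused, all_d$label, "rfc", seed = 1)
  acc <- evaluate_classifier(probe, fused$values[!tm, , drop = FALSE],
                             all_d$label[!tm])$metrics$acc
  expect_gte(acc, 0.9)
})

test_that("checkpoints round-trip and refuse tampered configs", {
  m <- build_extractor(tiny_config())
  f <- tempfile(fileext = ".rds")
  save_extractor(m, f)
  back <- load_extractor(f)
  expect_identical(back$params, m$params)
  tampered <- m
  tampered$config$seq_length <- 99L
  save_extractor(tampered, f)
  expect_error(load_extractor(f), "fingerprint")
})
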