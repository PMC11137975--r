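test_that("fusion concatenates blocks and standardizes on training rows", {
  set.seed(16)
  hand <- tibble::as_tibble(matrix(stats::rnorm(40 * 5), 40,
                                   dimnames = list(NULL, paste0("h", 1:5))))
  deep <- tibble::as_tibble(matrix(stats::rnorm(40 * 7), 40,
                                   dimnames = list(NULL, paste0("d", 1:7))))
  train <- rep(c(TRUE, FALSE), c(28, 12))
  fused <- fuse_features(hand, deep, train = train)
  expect_equal(fused$column_names, c(paste0("h", 1:5), paste0("d", 1:7)))
  expect_equal(ncol(fused$values), 12)
  tr_means <- colMeans(fused$values[train, ])
  tr_sds <- apply(fused$values[train, ], 2, stats::sd)
  expect_true(all(abs(tr_means) < 1e-9))
  expect_equal(unname(tr_sds), rep(1, 12))

  # degenerate deep block: identity on the handcrafted block
  only_hand <- fuse_features(hand, deep[, 0], train = train)
  expect_equal(only_hand$column_names, paste0("h", 1:5))

  expect_error(fuse_features(hand, deep[1:10, ]), "row mismatch")
})

test_that("validation rows never influence the fusion scaler", {
  set.seed(17)
  hand <- tibble::as_tibble(matrix(stats::rnorm(30 * 3), 30,
                                   dimnames = list(NULL, paste0("h", 1:3))))
  train <- rep(c(TRUE, FALSE), c(20, 10))
  f_train_only <- fuse_features(hand, hand[, 0], train = train)
  shifted <- hand
  shifted[!train, ] <- shifted[!train, ] + 100  # move validation rows far away
  f_shifted <- fuse_features(shifted, shifted[, 0], train = train)
  expect_equal(f_shifted$center, f_train_only$center)
  expect_equal(f_shifted$scale, f_train_only$scale)
  # whereas fitting on all rows would differ
  f_leaky <- fuse_features(shifted, shifted[, 0])
  expect_false(isTRUE(all.equal(f_leaky$center, f_train_only$center)))
})

test_that("classifiers fit separable toy data and respect the threshold", {
  set.seed(18)
  lab <- rep(c("ncRNA", "mRNA"), each = 20)
  tab <- tibble::tibble(sig = as.numeric(lab == "ncRNA"),
                        noise = stats::rnorm(40))
  for (kind in c("rfc", "svm", "nb")) {
    bundle <- train_classifier(tab, lab, kind, seed = 4)
    pred <- predict(bundle, tab)
    expect_true(all(pred$prob_ncRNA >= 0 & pred$prob_ncRNA <= 1))
    if (kind == "rfc") {
      expect_equal(as.character(pred$label), lab)
    }
  }
  expect_error(train_classifier(tab, rep("ncRNA", 40), "rfc"), "both classes")
  expect_error(train_classifier(tab, lab, "gbm"), "arg")

  # threshold rule: prob >= threshold => ncRNA
  bundle <- train_classifier(tab, lab, "rfc", seed = 4)
  pred <- predict(bundle, tab)
  expect_equal(pred$label, factor(ifelse(pred$prob_ncRNA >= 0.5,
                                         "ncRNA", "mRNA"),
                                  levels = c("mRNA", "ncRNA")))
})

test_that("prediction is deterministic, schema-checked and row-stable", {
  set.seed(19)
  lab <- rep(c("ncRNA", "mRNA"), each = 25)
  tab <- tibble::as_tibble(matrix(stats::rnorm(50 * 4), 50,
                                  dimnames = list(NULL, paste0("f", 1:4))))
  tab$f1 <- tab$f1 + as.numeric(lab == "ncRNA")
  b1 <- train_classifier(tab, lab, "rfc", seed = 5)
  b2 <- train_classifier(tab, lab, "rfc", seed = 5)
  probe <- as.matrix(tab)[1:10, ]
  expect_equal(predict(b1, probe), predict(b2, probe))

  # permuting rows permutes outputs identically
  perm <- sample(nrow(tab))
  p_all <- predict(b1, as.matrix(tab))
  p_perm <- predict(b1, as.matrix(tab)[perm, ])
  expect_equal(p_perm$prob_ncRNA, p_all$prob_ncRNA[perm])

  expect_error(predict(b1, probe[, 1:3]), "schema mismatch")
  empty <- predict(b1, as.matrix(tab)[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("the pipeline runs end to end and is reproducible", {
  d <- generate_dataset(generator_params(n_per_class = 40, seed = 7))
  cfg <- extractor_config(seq_length = 300, embedding_dim = 12,
                          hidden_units = 8, batch_size = 8, epochs = 4,
                          patience = Inf, seed = 11)
  p1 <- run_training_pipeline(d, extractor = cfg, seed = 11, verbose = FALSE)
  expect_s3_class(p1, "ncp_pipeline")
  expect_equal(length(p1$classifier$schema), 91 + 300)
  expect_gte(p1$report$metrics$acc, 0.8)

  p2 <- run_training_pipeline(d, extractor = cfg, seed = 11, verbose = FALSE)
  expect_equal(p2$report$cm, p1$report$cm)
  expect_equal(glance(p1), glance(p2))

  unlabeled <- d
  unlabeled$label <- NA
  expect_error(run_training_pipeline(unlabeled, extractor = cfg, seed = 1),
               "labels")
})

test_that("a fitted selection restricts the pipeline's handcrafted block", {
  d <- generate_dataset(generator_params(n_per_class = 40, seed = 8))
  cfg <- extractor_config(seq_length = 200, embedding_dim = 8,
                          hidden_units = 6, batch_size = 8, epochs = 2,
                          patience = Inf, seed = 3)
  p <- run_training_pipeline(d, extractor = cfg, seed = 3,
                             selection = pinc10_preset(), verbose = FALSE)
  expect_equal(length(p$classifier$schema), 10 + 200)
})
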