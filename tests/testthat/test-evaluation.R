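test_that("confusion counts with ncRNA as the positive class", {
  cm <- confusion(c("ncRNA", "ncRNA", "mRNA", "mRNA"),
                  c("ncRNA", "mRNA", "mRNA", "ncRNA"))
  expect_equal(cm$TP, 1); expect_equal(cm$FN, 1)
  expect_equal(cm$TN, 1); expect_equal(cm$FP, 1)

  perfect <- confusion(rep(c("ncRNA", "mRNA"), 3), rep(c("ncRNA", "mRNA"), 3))
  expect_equal(perfect$FP + perfect$FN, 0)
  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion(c("ncRNA", "mRNA"), "ncRNA"), "lengths differ")
})

test_that("compute_metrics matches hand-computed values", {
  perfect <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(perfect$acc, 1); expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)

  m <- compute_metrics(list(TP = 2, FP = 1, FN = 1, TN = 2))
  expect_equal(m$f1, 4 / 6)
  expect_equal(m$acc, 4 / 6)
  expect_equal(m$se, 2 / 3)
  expect_equal(m$spc, 2 / 3)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$npv, 2 / 3)
  expect_equal(m$mcc, (2 * 2 - 1 * 1) / sqrt(3 * 3 * 3 * 3))

  wrong <- compute_metrics(list(TP = 0, TN = 0, FP = 5, FN = 5))
  expect_equal(wrong$mcc, -1)
  expect_equal(wrong$acc, 0)

  # 0/0 cells are undefined, not zero
  no_pos <- compute_metrics(list(TP = 0, TN = 4, FP = 0, FN = 0))
  expect_true(is.na(no_pos$se))
  expect_true(is.na(no_pos$ppv))
  expect_equal(no_pos$acc, 1)
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "all-zero")
})

test_that("metric ranges hold over random confusion matrices", {
  set.seed(13)
  for (i in 1:1000) {
    cm <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                  c("TP", "TN", "FP", "FN")))
    if (sum(unlist(cm)) == 0) next
    m <- compute_metrics(cm)
    expect_true(m$acc >= 0 && m$acc <= 1)
    expect_true(is.na(m$mcc) || (m$mcc >= -1 && m$mcc <= 1))
    for (col in c("se", "spc", "ppv", "npv", "f1")) {
      expect_true(is.na(m[[col]]) || (m[[col]] >= 0 && m[[col]] <= 1))
    }
  }
})

test_that("roc_auc covers perfect, reversed and uninformative rankings", {
  truth <- rep(c("ncRNA", "mRNA"), each = 4)
  expect_equal(roc_auc(truth, c(5:8, 1:4))$auc, 1)
  expect_equal(roc_auc(truth, c(1:4, 5:8))$auc, 0)
  expect_equal(roc_auc(truth, rep(1, 8))$auc, 0.5)
  expect_error(roc_auc(rep("ncRNA", 4), 1:4), "both classes")
  # curve endpoints
  pts <- roc_auc(truth, stats::rnorm(8))$points
  expect_equal(pts$tpr[1], 0); expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1); expect_equal(pts$fpr[nrow(pts)], 1)
})

test_that("AUC equals the pairwise Mann-Whitney oracle", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    truth <- sample(c("ncRNA", "mRNA"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("ncRNA", "mRNA")
    scores <- sample(stats::rnorm(5), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(truth, scores)$auc, oracle_auc(truth, scores),
                 tolerance = 1e-12)
  }
})

test_that("paired z-test matches the discordant-count formula", {
  truth <- rep("ncRNA", 15)
  a <- rep(c("ncRNA", "mRNA"), c(10, 5))
  b <- rep(c("mRNA", "ncRNA"), c(10, 5))
  cmp <- paired_z_test(truth, a, b)
  expect_equal(cmp$f12, 10); expect_equal(cmp$f21, 5)
  expect_equal(cmp$z, 5 / sqrt(15), tolerance = 1e-12)
  expect_equal(cmp$p, 1 - stats::pnorm(5 / sqrt(15)))

  # antisymmetry
  rev <- paired_z_test(truth, b, a)
  expect_equal(rev$z, -cmp$z)

  # equal discordance centers at zero
  tie <- paired_z_test(rep("ncRNA", 14),
                       rep(c("ncRNA", "mRNA"), 7),
                       rep(c("mRNA", "ncRNA"), 7))
  expect_equal(tie$z, 0); expect_equal(tie$p, 0.5)

  # no discordance: defined as z = 0, p = 0.5
  none <- paired_z_test(truth, a, a)
  expect_equal(none$f12 + none$f21, 0)
  expect_equal(none$z, 0); expect_equal(none$p, 0.5)
})

test_that("only ncRNA-truth instances enter the discordant counts", {
  truth <- c("ncRNA", "mRNA", "mRNA")
  a <- c("ncRNA", "mRNA", "ncRNA")   # a right on the mRNA pair or not
  b <- c("mRNA", "ncRNA", "mRNA")
  cmp <- paired_z_test(truth, a, b)
  expect_equal(cmp$f12, 1)  # the single ncRNA instance
  expect_equal(cmp$f21, 0)
  expect_equal(tidy(cmp)$z, cmp$z)
})

test_that("evaluate_classifier assembles metrics, confusion and ROC", {
  set.seed(15)
  tab <- tibble::tibble(x = c(stats::rnorm(20, 2), stats::rnorm(20)))
  lab <- rep(c("ncRNA", "mRNA"), each = 20)
  fused <- fuse_features(tab, tab[, 0])
  bundle <- train_classifier(fused, lab, "rfc", seed = 3)
  ev <- evaluate_classifier(bundle, fused$values, lab)
  expect_s3_class(ev, "ncp_eval")
  expect_equal(glance(ev)$TP + glance(ev)$FN, 20)
  expect_equal(nrow(tidy(ev)), 8)  # 7 metrics + auc
  expect_s3_class(autoplot(ev$roc), "ggplot")
  # report files
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".txt")
  write_report(ev, jf, tf)
  expect_equal(jsonlite::read_json(jf)$acc, ev$metrics$acc)
  expect_length(readLines(tf), 2)
})
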