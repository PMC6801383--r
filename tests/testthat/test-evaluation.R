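test_that("median aggregation follows the even-count rule and is invariant", {
  p <- fixture_predictions(c(0.2, 0.8, 0.5), ids = rep("m1", 3))
  expect_equal(aggregate_median(p)$score, 0.5)
  p2 <- fixture_predictions(c(0.2, 0.4), ids = rep("m1", 2))
  expect_equal(aggregate_median(p2)$score, 0.3)
  # permutation invariance and n_images bookkeeping
  probs <- c(0.1, 0.9, 0.4, 0.6, 0.5)
  ids <- c("a", "a", "b", "b", "b")
  base <- aggregate_median(fixture_predictions(probs, ids))
  set.seed(1)
  for (r in 1:5) {
    o <- sample(5)
    again <- aggregate_median(fixture_predictions(probs[o], ids[o]))
    expect_equal(again[order(again$mol_id), ], base[order(base$mol_id), ],
                 ignore_attr = TRUE)
  }
  expect_equal(base$n_images[base$mol_id == "b"], 3L)
  expect_error(aggregate_median(fixture_predictions(1.2)), "\\[0, 1\\]")
})

test_that("rank AUC equals the all-pairs oracle and the trapezoid curve", {
  # closed-form cases
  expect_equal(roc_auc(c(0.9, 0.9, 0.1, 0.1),
                       c("active", "active", "inactive", "inactive"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6),
                       rep(c("active", "inactive"), 3))$auc, 0.5)
  # one inversion in six scores
  s <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.1)
  l <- c("active", "active", "active", "inactive", "inactive", "inactive")
  expect_equal(roc_auc(s, l)$auc, oracle_auc(s, l))
  # random instances: rank statistic == all-pairs count == trapezoid area
  set.seed(7)
  for (r in 1:50) {
    n <- sample(4:50, 1)
    sc <- round(stats::runif(n), sample(c(1, 2, 7), 1))  # induce ties
    lb <- ifelse(stats::runif(n) < 0.4, "active", "inactive")
    if (length(unique(lb)) < 2) next
    got <- roc_auc(sc, lb)
    expect_equal(got$auc, oracle_auc(sc, lb), tolerance = 1e-12)
    trap <- sum(diff(got$curve$fpr) *
                  (utils::head(got$curve$tpr, -1) +
                     utils::tail(got$curve$tpr, -1)) / 2)
    expect_equal(got$auc, trap, tolerance = 1e-12)
  }
  expect_error(roc_auc(c(0.1, 0.9), c("active", "active")), "both classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (r in 1:10) {
    n <- sample(10:40, 1)
    sc <- round(stats::runif(n), 2)
    lb <- ifelse(stats::runif(n) < 0.5, "active", "inactive")
    if (length(unique(lb)) < 2) next
    ours <- roc_auc(sc, lb)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = lb, predictor = sc, levels = c("inactive", "active"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("Youden cutoff equals exhaustive threshold search", {
  # perfectly separated: chosen threshold classifies all correctly
  s <- c(0.9, 0.8, 0.2, 0.1)
  l <- c("active", "active", "inactive", "inactive")
  thr <- select_cutoff(s, l)
  m <- confusion_metrics(s, l, thr)
  expect_equal(m$sensitivity + m$specificity - 1, 1)
  # all ties: J = 0 everywhere, deterministic result
  expect_equal(select_cutoff(rep(0.5, 4), l), select_cutoff(rep(0.5, 4), l))
  # random sets vs brute force over a fine threshold grid
  set.seed(3)
  for (r in 1:20) {
    n <- sample(4:12, 1)
    sc <- round(stats::runif(n), 2)
    lb <- ifelse(stats::runif(n) < 0.5, "active", "inactive")
    if (length(unique(lb)) < 2) next
    thr <- select_cutoff(sc, lb)
    j_at <- function(t) {
      act <- lb == "active"
      sum(sc >= t & act) / sum(act) + sum(sc < t & !act) / sum(!act) - 1
    }
    grid <- seq(-0.05, 1.05, by = 0.005)
    expect_equal(j_at(thr), max(vapply(grid, j_at, numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("metric formulas equal brute-force evaluation on random matrices", {
  # the pinned worked example: tp 3, fp 1, tn 4, fn 2 -> MCC = 10/sqrt(600)
  fx <- scores_for_counts(3, 1, 4, 2)
  m <- confusion_metrics(fx$scores, fx$labels, 0.5)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(3, 1, 4, 2))
  expect_equal(m$mcc, 10 / sqrt(600), tolerance = 1e-12)
  expect_equal(m$bac, (3 / 5 + 4 / 5) / 2, tolerance = 1e-12)
  # random confusion matrices vs the oracle formulas
  set.seed(5)
  for (r in 1:200) {
    cnt <- stats::rpois(4, 5) + 1
    fx <- scores_for_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    m <- confusion_metrics(fx$scores, fx$labels, 0.5)
    o <- oracle_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    for (nm in names(o)) expect_equal(m[[nm]], o[[nm]], tolerance = 1e-12)
  }
})

test_that("degenerate confusion cases return flagged defined values", {
  # no called positives: precision 0, flagged
  fx <- scores_for_counts(0, 0, 4, 2)
  m <- confusion_metrics(fx$scores, fx$labels, 0.5)
  expect_equal(m$precision, 0)
  expect_equal(m$mcc, 0)
  expect_true(m$degenerate)
  # sensitivity 1, specificity 0 -> BAC 0.5
  fx2 <- scores_for_counts(3, 2, 0, 0)
  m2 <- confusion_metrics(fx2$scores, fx2$labels, 0.5)
  expect_equal(m2$bac, 0.5)
  # precision == recall implies F == precision
  fx3 <- scores_for_counts(3, 1, 5, 1)
  m3 <- confusion_metrics(fx3$scores, fx3$labels, 0.5)
  expect_equal(m3$f_value, m3$precision, tolerance = 1e-12)
})

test_that("metrics are invariant under molecule relabeling and reordering", {
  set.seed(21)
  sc <- stats::runif(12)
  lb <- rep(c("active", "inactive"), 6)
  base <- confusion_metrics(sc, lb, 0.5)
  o <- sample(12)
  again <- confusion_metrics(sc[o], lb[o], 0.5)
  for (nm in c("bac", "accuracy", "f_value", "mcc", "auc"))
    expect_equal(again[[nm]], base[[nm]])
})

test_that("adding a correctly-classified molecule never lowers accuracy", {
  set.seed(31)
  for (r in 1:20) {
    n <- sample(4:20, 1)
    sc <- stats::runif(n)
    lb <- ifelse(stats::runif(n) < 0.5, "active", "inactive")
    base <- confusion_metrics(sc, lb, 0.5)$accuracy
    grown <- confusion_metrics(c(sc, 0.9), c(lb, "active"), 0.5)$accuracy
    expect_gte(grown, base - 1e-12)
  }
})

test_that("evaluate_predictions freezes the validation cutoff on test data", {
  labels <- c(a = "active", b = "active", c = "inactive", d = "inactive")
  val <- fixture_predictions(c(0.8, 0.7, 0.3, 0.2), c("a", "b", "c", "d"))
  test <- fixture_predictions(c(0.9, 0.4, 0.35, 0.1), c("a", "b", "c", "d"))
  m <- evaluate_predictions(test, labels, val_predictions = val)
  expect_equal(m$threshold, select_cutoff(c(0.8, 0.7, 0.3, 0.2),
                                          c("active", "active",
                                            "inactive", "inactive")))
  expect_equal(m$tp + m$fp + m$tn + m$fn, 4L)
})
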