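test_that("confusion metrics reproduce the printed-definition arithmetic", {
  # constructed pool with TP=3, FP=1, TN=5, FN=1
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.2, 0.1, 0.1)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- confusion_metrics(scores, labels, threshold = 0.5)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(3, 1, 5, 1))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 5 / 6)
  expect_equal(m$f1, 0.75)
  # F1 is the harmonic mean of PPV and sensitivity whenever both defined
  expect_equal(m$f1, 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity))
  # separable pool: everything is 1
  p <- confusion_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(c(p$auroc, p$f1, p$sensitivity, p$specificity, p$ppv, p$npv),
               rep(1, 6))
  # degenerate pool: no positives -> sensitivity absent, specificity defined
  d <- confusion_metrics(c(0.2, 0.3), c(0, 0), 0.5)
  expect_true(is.na(d$sensitivity))
  expect_equal(d$specificity, 1)
  expect_error(confusion_metrics(c(0.5), c(2)), "binary")
})

test_that("AUROC equals exhaustive pair counting with the tie convention", {
  pair_count_auroc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    tot / (length(pos) * length(neg))
  }
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.4, 8), rep(c(0, 1), 4)), 0.5)
  set.seed(51)
  for (rep in 1:5) {
    s <- round(runif(12), 1)          # rounded to force ties
    y <- rep(c(1, 0), each = 6)
    expect_equal(auroc(s, y), pair_count_auroc(s, y))
  }
  # invariant under strictly increasing transforms
  s <- runif(20); y <- rbinom(20, 1, 0.5)
  if (length(unique(y)) == 2)
    expect_equal(auroc(exp(3 * s), y), auroc(s, y))
  # independent cross-check against pROC
  skip_if_not_installed("pROC")
  s <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.2, 0.7, 0.6)
  y <- c(0, 0, 1, 1, 0, 0, 1, 1)
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("operating-point selection matches an exhaustive sweep", {
  set.seed(52)
  s <- c(runif(40, 0.4, 1), runif(60, 0, 0.6))
  y <- rep(c(1, 0), c(40, 60))
  op <- select_operating_point(s, y, "balanced")
  # oracle: sweep every candidate threshold and take the best F1
  grid <- sort(unique(c(0, 1, s)))
  f1s <- vapply(grid, function(t) {
    m <- confusion_metrics(s, y, t); if (is.na(m$f1)) -Inf else m$f1
  }, numeric(1))
  expect_equal(op$metrics$f1, max(f1s))
  expect_equal(op$threshold, max(grid[f1s == max(f1s)]))
  # balanced F1 dominates every other threshold on the grid
  expect_true(all(op$metrics$f1 >= f1s))
  # degenerate single-valued scores: the same threshold in every mode
  clin <- tibble::tibble(sensitivity = c(0.8, 0.7), specificity = c(0.9, 0.95))
  sd1 <- rep(0.5, 10); yd <- rep(c(0, 1), 5)
  for (mode in c("balanced", "high_sensitivity", "high_specificity")) {
    opd <- select_operating_point(sd1, yd, mode, clin)
    expect_true(opd$threshold %in% c(0, 0.5, 1))
  }
  expect_error(select_operating_point(s, y, "high_sensitivity"),
               "clinician_stats")
})

test_that("threshold ordering across modes on a separable pool", {
  set.seed(53)
  s <- c(rnorm(300, 0.7, 0.08), rnorm(700, 0.3, 0.08))
  s <- pmin(pmax(s, 0), 1)
  y <- rep(c(1, 0), c(300, 700))
  clin <- tibble::tibble(sensitivity = c(0.95, 0.9), specificity = c(0.8, 0.85))
  t_sens <- select_operating_point(s, y, "high_sensitivity", clin)$threshold
  t_bal <- select_operating_point(s, y, "balanced")$threshold
  t_spec <- select_operating_point(s, y, "high_specificity", clin)$threshold
  expect_lte(t_sens, t_bal)
  expect_lte(t_bal, t_spec)
})

test_that("clinician scoring against the majority reference", {
  set.seed(54)
  ref <- rbinom(200, 1, 0.3)
  votes <- rbind(ref, 1 - ref, ref)
  rownames(votes) <- c("same", "complement", "again")
  cp <- clinician_performance(votes, ref)
  expect_equal(cp$sensitivity[cp$annotator == "same"], 1)
  expect_equal(cp$f1[cp$annotator == "same"], 1)
  expect_equal(cp$sensitivity[cp$annotator == "complement"], 0)
  expect_error(clinician_performance(votes, ref[-1]), "disagree")
})

test_that("per-tooth-type pooling matches the loop oracle and partitions", {
  set.seed(55)
  scores <- matrix(runif(2 * 32), 2, 32)
  labels <- matrix(rbinom(2 * 32, 1, 0.4), 2, 32)
  rep_tbl <- per_tooth_type_report(scores, labels, threshold = 0.5)
  ch <- fdi_chart()
  for (type in c("incisor", "canine", "premolar", "molar")) {
    cols <- ch$index[ch$type == type] + 1
    want <- confusion_metrics(scores[, cols], labels[, cols], 0.5)
    got <- rep_tbl[rep_tbl$tooth_type == type, ]
    expect_equal(got$tp, want$tp)
    expect_equal(got$f1, want$f1)
    expect_equal(got$n_teeth, length(cols))
  }
  # "all" equals the pool of the four subsets
  all_row <- rep_tbl[rep_tbl$tooth_type == "all", ]
  expect_equal(all_row$tp + all_row$fp + all_row$tn + all_row$fn, 64)
  expect_equal(all_row$tp, sum(rep_tbl$tp[rep_tbl$tooth_type != "all"]))
  # a subset without positives reports sensitivity as absent
  lab0 <- labels; lab0[, tooth_type_indices("canine") + 1] <- 0
  r0 <- per_tooth_type_report(scores, lab0, 0.5)
  expect_true(is.na(r0$sensitivity[r0$tooth_type == "canine"]))
})
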