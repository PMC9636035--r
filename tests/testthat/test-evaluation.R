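test_that("AUC equals the pair-counting value on stated and random instances", {
  r <- roc_auc(c(0.8, 0.6, 0.7, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(F, F, T, T))$auc, 1)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(1)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    s <- round(runif(n), sample(1:3, 1))
    y <- runif(n) < 0.5
    if (!any(y) || all(y)) next
    expect_equal(roc_auc(s, y)$auc, auc_pairs_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("the ROC curve's trapezoidal area matches the pair statistic", {
  set.seed(2)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    s <- round(runif(n), sample(c(1, 2, 8), 1))
    y <- runif(n) < 0.4
    if (!any(y) || all(y)) next
    r <- roc_auc(s, y)
    trap <- sum(diff(r$fpr) * (head(r$sensitivity, -1) + tail(r$sensitivity, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-9)
  }
})

test_that("shuffled labels give chance-level AUC on average", {
  set.seed(3)
  s <- runif(100)
  y <- rep(c(TRUE, FALSE), 50)
  aucs <- replicate(1000, roc_auc(s, sample(y))$auc)
  expect_gte(mean(aucs), 0.48)
  expect_lte(mean(aucs), 0.52)
})

test_that("bootstrap percentile intervals are seeded order statistics", {
  b <- bootstrap_ci(rep(3.5, 10), mean, n_replicates = 200, seed = 4)
  expect_equal(c(b$lower, b$upper), c(3.5, 3.5))

  x <- rnorm(30)
  b1 <- bootstrap_ci(x, mean, n_replicates = 500, seed = 5)
  b2 <- bootstrap_ci(x, mean, n_replicates = 500, seed = 5)
  expect_identical(b1[c("lower", "upper")], b2[c("lower", "upper")])
  # endpoints are order statistics at the nearest-rank indices
  sorted <- sort(b1$replicates)
  expect_identical(b1$lower, sorted[ceiling(0.025 * 500)])
  expect_identical(b1$upper, sorted[ceiling(0.975 * 500)])

  # failing resamples are redrawn and counted
  set.seed(6)
  d <- data.frame(s = runif(8), y = c(rep(TRUE, 2), rep(FALSE, 6)))
  b3 <- bootstrap_ci(d, function(dd) roc_auc(dd$s, dd$y)$auc,
                     n_replicates = 100, seed = 7)
  expect_gt(b3$n_redrawn, 0)
  expect_true(is.finite(b3$lower) && is.finite(b3$upper))
})

test_that("Spearman rho is mid-rank Pearson", {
  expect_equal(spearman_rho(1:10, exp(1:10)), 1)
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  x <- c(1, 2, 2, 4); y <- c(3, 1, 4, 4)
  expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:50) {
    a <- sample(1:6, 10, TRUE); b <- sample(1:6, 10, TRUE)
    if (var(a) == 0 || var(b) == 0) next
    expect_equal(spearman_rho(a, b), spearman_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("Kaplan-Meier matches hand product-limit results and survfit", {
  km <- km_estimate(c(2, 4, 6), c(1, 0, 1))
  expect_equal(km$surv, c(2 / 3, 2 / 3, 0))

  km2 <- km_estimate(c(5, 8, 11), c(0, 0, 0))
  expect_true(all(km2$surv == 1))

  km3 <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km3$surv, c(3 / 4, 2 / 4, 1 / 4, 0))

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")

  set.seed(9)
  tm <- ceiling(rexp(40, 1 / 20)); ev <- rbinom(40, 1, 0.7)
  ours <- km_estimate(tm, ev)
  sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  expect_equal(ours$surv[ours$n_event > 0],
               summary(sf)$surv, tolerance = 1e-12)
})

test_that("log-rank matches the hand O-E computation and survdiff", {
  tm <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 1); gr <- c("A", "A", "B", "B")
  lr <- logrank_test(tm, ev, gr)
  # hand tabulation: risk sets 4,3,2,1 with d=1 each; group A is at risk
  # with 2,1,0,0 members, so E_A = 2/4 + 1/3 and the hypergeometric
  # variance terms are (2/4)(2/4) and (1/3)(2/3) (the (n-d)/(n-1) factor
  # is 1 with a single event per time)
  EA <- 2 / 4 + 1 / 3
  VA <- (2 / 4) * (1 - 2 / 4) + (1 / 3) * (1 - 1 / 3)
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, EA, tolerance = 1e-9)
  expect_equal(lr$chi2, (2 - EA)^2 / VA, tolerance = 1e-9)

  # identical groups: statistic 0, p = 1
  lr0 <- logrank_test(c(3, 5, 3, 5), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # label swap invariance
  lr_sw <- logrank_test(tm, ev, c("B", "B", "A", "A"))
  expect_equal(lr_sw$chi2, lr$chi2, tolerance = 1e-12)

  set.seed(10)
  tm2 <- ceiling(rexp(60, 1 / 15)); ev2 <- rbinom(60, 1, 0.8)
  gr2 <- rep(c("x", "y"), 30)
  ours <- logrank_test(tm2, ev2, gr2)
  sd <- survival::survdiff(survival::Surv(tm2, ev2) ~ gr2)
  expect_equal(ours$chi2, sd$chisq, tolerance = 1e-9)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("heatmap grids bin patch predictions with missing cells marked", {
  preds <- data.frame(x = 0, y = 0, p_tmb_high = 0.9)
  g <- render_heatmap(preds, c(1024, 1024), 512)
  expect_equal(dim(g), c(2L, 2L))
  expect_equal(g[1, 1], 0.9)
  expect_equal(sum(is.na(g)), 3L)

  expect_equal(dim(render_heatmap(data.frame(x = 0, y = 0, p_tmb_high = 1),
                                  c(1000, 700), 512)),
               c(ceiling(700 / 512), ceiling(1000 / 512)))

  # round-trip through the CSV
  set.seed(11)
  preds2 <- data.frame(x = c(0, 512, 512), y = c(0, 0, 512),
                       p_tmb_high = runif(3))
  csv <- tempfile(fileext = ".csv"); png_f <- tempfile(fileext = ".png")
  g2 <- render_heatmap(preds2, c(1024, 1024), 512, out_png = png_f,
                       out_csv = csv)
  df <- read.csv(csv)
  for (i in seq_len(nrow(df)))
    expect_equal(g2[df$row[i] + 1, df$col[i] + 1], df$value[i])
  expect_true(file.exists(png_f))

  expect_warning(render_heatmap(data.frame(x = c(0, 10), y = c(0, 0),
                                           p_tmb_high = c(0.2, 0.6)),
                                c(1024, 1024), 512),
                 "overlapping")
  expect_error(render_heatmap(data.frame(x = -1, y = 0, p_tmb_high = 1),
                              c(512, 512), 512), "bounds")
})

test_that("cohort evaluation bundles rank-invariant statistics and survival", {
  set.seed(12)
  n <- 30
  manifest <- data.frame(
    patient_id = sprintf("P%02d", 1:n), slide_id = sprintf("P%02d_S1", 1:n),
    cohort = "t", split = "val",
    tmb_value = c(runif(15, 20, 205), runif(15, 206, 900)),
    tmb_class = rep(c("low", "high"), each = 15),
    surv_time_days = ceiling(rexp(n, 1 / 300)), surv_event = rbinom(n, 1, 0.8))
  scores <- data.frame(patient_id = manifest$patient_id,
                       piter_score = plogis(scale(manifest$tmb_value) +
                                              rnorm(n, 0, 0.8)))
  rep1 <- evaluate_cohort(scores, manifest, n_boot = 200, seed = 1)
  expect_gt(rep1$auc, 0.5)
  expect_true(rep1$auc_ci_low <= rep1$auc && rep1$auc <= rep1$auc_ci_high)
  expect_true(!is.null(rep1$logrank_p))

  # rank invariance: replacing scores by their ranks changes nothing
  scores2 <- scores; scores2$piter_score <- rank(scores$piter_score)
  rep2 <- evaluate_cohort(scores2, manifest, n_boot = 200, seed = 1)
  expect_equal(rep2$auc, rep1$auc, tolerance = 1e-12)
  expect_equal(rep2$rho, rep1$rho, tolerance = 1e-12)

  # boundary cutoff: everyone called high
  rep3 <- evaluate_cohort(scores, manifest, cutoff = -Inf, n_boot = 50, seed = 1)
  expect_equal(rep3$sensitivity, 1)
  expect_equal(rep3$specificity, 0)

  expect_error(evaluate_cohort(scores, manifest[, 1:2]), "missing columns")

  d <- tempfile()
  json <- write_report(rep1, d)
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$auc, rep1$auc, tolerance = 1e-9)
  unlink(d, recursive = TRUE)
})
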