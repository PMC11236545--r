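test_that("undersample balances 108/22 to 22/22 keeping every minority window", {
  d <- toy_dataset(n_pain = 22, n_nopain = 108, n_subjects = 10)
  b <- undersample(d, seed = 3)
  expect_equal(as.vector(table(b$label)[c("no_pain", "pain")]), c(22, 22))
  expect_true(all(d$t_center[d$label == "pain"] %in% b$t_center))

  # already balanced: unchanged up to ordering
  d2 <- toy_dataset(n_pain = 15, n_nopain = 15)
  b2 <- undersample(d2, seed = 1)
  expect_setequal(b2$t_center, d2$t_center)

  # determinism contract
  expect_identical(undersample(d, seed = 7), undersample(d, seed = 7))
  expect_false(identical(undersample(d, seed = 7)$t_center,
                         undersample(d, seed = 8)$t_center))

  d3 <- d[d$label == "pain", ]
  expect_error(undersample(d3), "both classes")
})

test_that("knn scores match their degenerate closed forms", {
  d <- toy_dataset(n_pain = 8, n_nopain = 8, effect = 2, seed = 2)
  # k = 1, query equal to a training point -> that point's label
  fit <- pain_knn(d, config = knn_config(k = 1))
  s <- predict(fit, d)
  expect_equal(s, as.numeric(d$label == "pain"))
  # k = n, uniform weights -> global pain fraction for any query
  fit <- pain_knn(d, config = knn_config(k = nrow(d)))
  expect_equal(predict(fit, d[3, ]), mean(d$label == "pain"))
  expect_error(pain_knn(d, config = knn_config(k = nrow(d) + 1)), "exceeds")
})

test_that("knn agrees with an exhaustive-sort neighbour oracle", {
  set.seed(17)
  for (metric in c("euclidean", "manhattan")) {
    for (k in c(1, 3, 7)) {
      d <- toy_dataset(n_pain = 12, n_nopain = 18, effect = 1, seed = k)
      q <- toy_dataset(n_pain = 3, n_nopain = 3, effect = 1, seed = 99 + k)
      cfg <- knn_config(k = k, metric = metric, standardize = FALSE)
      fit <- pain_knn(d, config = cfg)
      got <- predict(fit, q)
      x <- as.matrix(d[, c("AU4s1_area_around_mean", "AU4s2_area_around_mean")])
      qx <- as.matrix(q[, c("AU4s1_area_around_mean", "AU4s2_area_around_mean")])
      want <- vapply(seq_len(nrow(qx)), function(i) {
        dist <- if (metric == "euclidean") {
          sqrt(rowSums((x - matrix(qx[i, ], nrow(x), 2, byrow = TRUE))^2))
        } else {
          rowSums(abs(x - matrix(qx[i, ], nrow(x), 2, byrow = TRUE)))
        }
        nn <- order(dist)[1:k]             # same stable tie-break
        mean(d$label[nn] == "pain")
      }, numeric(1))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("distance weighting weights votes by inverse distance", {
  d <- toy_dataset(n_pain = 5, n_nopain = 5, effect = 4, seed = 6)
  cfg <- knn_config(k = 3, weighting = "distance", standardize = FALSE)
  fit <- pain_knn(d, config = cfg)
  q <- d[1, ]
  q$AU4s1_area_around_mean <- q$AU4s1_area_around_mean + 0.01
  x <- fit$x; y <- fit$y
  qx <- c(q$AU4s1_area_around_mean, q$AU4s2_area_around_mean)
  dist <- sqrt(colSums((t(x) - qx)^2))
  nn <- order(dist)[1:3]
  w <- 1 / dist[nn]
  expect_equal(predict(fit, q), sum(w * y[nn]) / sum(w), tolerance = 1e-12)
  # an exact training match dominates entirely
  expect_equal(predict(fit, d[1, ]), as.numeric(d$label[1] == "pain"))
})

test_that("LOSO pools every window once, trained without its subject", {
  d <- toy_dataset(n_pain = 12, n_nopain = 24, n_subjects = 3, seed = 8)
  p <- loso_cv(d, knn_config(k = 3, seed = 5))
  expect_equal(nrow(p), nrow(d))
  expect_equal(sort(unique(p$fold)), 1:3)
  # each window appears exactly once
  expect_equal(sort(paste(p$subject_id, p$t_center)),
               sort(paste(d$subject_id, d$t_center)))
  # fold f holds exactly subject f's windows
  subjects <- sort(unique(d$subject_id))
  for (f in 1:3) {
    expect_equal(unique(p$subject_id[p$fold == f]), subjects[f])
  }
  expect_error(loso_cv(d[d$subject_id == "S01", ]), "2 subjects")

  # a subject with only no-pain windows still gets a valid fold
  d2 <- d
  d2$label[d2$subject_id == "S01"] <- "no_pain"
  d2$facial_score[d2$subject_id == "S01"] <- 1L
  expect_silent(p2 <- loso_cv(d2, knn_config(k = 3)))
  expect_equal(nrow(p2), nrow(d2))
})

test_that("LOSO evaluation is a pure function of (dataset, config, seed)", {
  d <- toy_dataset(n_pain = 10, n_nopain = 20, n_subjects = 4, effect = 1.2,
                   seed = 3)
  e1 <- loso_evaluate(d, knn_config(k = 5), replicates = 200, seed = 42)
  e2 <- loso_evaluate(d, knn_config(k = 5), replicates = 200, seed = 42)
  expect_identical(e1$predictions, e2$predictions)
  expect_identical(e1$auc, e2$auc)
  expect_identical(e1$auc_ci, e2$auc_ci)
})

test_that("tuning maximises pooled-LOSO F1 with deterministic tie-breaks", {
  # single-candidate grid returns that candidate
  d <- toy_dataset(n_pain = 10, n_nopain = 20, n_subjects = 4, effect = 4,
                   seed = 12)
  one <- data.frame(k = 3, weighting = "distance", metric = "manhattan")
  tr <- tune_hyperparameters(d, one, seed = 1)
  expect_equal(tr$config$k, 3L)
  expect_equal(tr$config$metric, "manhattan")

  # cleanly separable data reaches F1 = 1
  tr <- tune_hyperparameters(d, default_grid(), seed = 1)
  expect_equal(tr$f1, 1.0)

  # on ties the smaller k wins: separable data ties many configs at 1
  expect_equal(tr$config$k, min(tr$results$k[tr$results$f1 == 1]))
})

test_that("roc_auc equals the pairwise Mann-Whitney oracle and its closed forms", {
  # perfect separation
  truth <- rep(c("pain", "no_pain"), each = 5)
  expect_equal(roc_auc(truth, c(6:10, 1:5))$auc, 1.0)

  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    truth <- sample(c("pain", "no_pain"), n, replace = TRUE,
                    prob = c(0.4, 0.6))
    if (length(unique(truth)) < 2) next
    score <- round(runif(n), 2)  # rounded scores force ties
    expect_equal(roc_auc(truth, score)$auc, auc_oracle(truth, score),
                 tolerance = 1e-12)
  }

  # invariance under strictly monotone transforms
  truth <- sample(c("pain", "no_pain"), 50, replace = TRUE)
  truth[1:2] <- c("pain", "no_pain")
  score <- rnorm(50)
  a0 <- roc_auc(truth, score)$auc
  expect_equal(roc_auc(truth, exp(score))$auc, a0)
  expect_equal(roc_auc(truth, rank(score))$auc, a0)
})

test_that("labels independent of scores give AUC near one half", {
  set.seed(99)
  n <- 4000
  truth <- ifelse(rbinom(n, 1, 0.5) == 1, "pain", "no_pain")
  score <- runif(n)
  auc <- roc_auc(truth, score)$auc
  # 3 sigma of the Mann-Whitney null for this n
  sigma <- sqrt((n + 1) / (12 * sum(truth == "pain") * sum(truth == "no_pain")))
  expect_lt(abs(auc - 0.5), 3 * sigma)
})

test_that("stratified bootstrap CI is deterministic and degenerate when perfect", {
  truth <- rep(c("pain", "no_pain"), each = 10)
  score <- c(rnorm(10, 5), rnorm(10, 0))
  ci1 <- bootstrap_auc_ci(truth, score, replicates = 300, seed = 4)
  ci2 <- bootstrap_auc_ci(truth, score, replicates = 300, seed = 4)
  expect_identical(ci1[c("lo", "hi")], ci2[c("lo", "hi")])
  expect_equal(c(ci1$lo, ci1$hi), c(1, 1))  # separation survives resampling
})

test_that("operating points follow their policies and hand-counted confusion", {
  # constructed 10-prediction set, threshold fixed at 0.5:
  # pain scores .9 .8 .6 .4 (3 TP, 1 FN); no-pain .7 .3 .2 .1 .05 .45 (1 FP)
  truth <- c(rep("pain", 4), rep("no_pain", 6))
  score <- c(0.9, 0.8, 0.6, 0.4, 0.7, 0.3, 0.2, 0.1, 0.05, 0.45)
  op <- operating_point(truth, score, policy = "fixed", threshold = 0.5)
  expect_equal(op$sensitivity, 3 / 4)
  expect_equal(op$specificity, 5 / 6)
  expect_equal(op$confusion["pain", "pred_pain"], 3 / 4)
  expect_equal(op$confusion["no_pain", "pred_no_pain"], 5 / 6)
  expect_equal(rowSums(op$confusion), c(no_pain = 1, pain = 1))

  # perfect classifier: sens = spec = 1 at an interior threshold
  op <- operating_point(rep(c("pain", "no_pain"), each = 5),
                        c(6:10, 1:5) / 10, policy = "youden")
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)

  # all scores equal: one of the trivial operating points
  op <- operating_point(truth, rep(0.5, 10), policy = "youden")
  expect_true((op$sensitivity == 1 && op$specificity == 0) ||
                (op$sensitivity == 0 && op$specificity == 1))

  # sensitivity floor policy
  op <- operating_point(truth, score, policy = "sens_floor",
                        min_sensitivity = 1)
  expect_gte(op$sensitivity, 1)
})

test_that("loso_evaluate separates a strong toy effect end to end", {
  d <- toy_dataset(n_pain = 15, n_nopain = 30, n_subjects = 5, effect = 5,
                   noise = 0.5, seed = 10)
  ev <- loso_evaluate(d, tune = TRUE, replicates = 200, seed = 2)
  expect_gt(ev$auc, 0.95)
  expect_s3_class(ev, "pain_eval")
  expect_output(print(ev), "AUC")
  expect_lte(ev$auc_ci[["lo"]], ev$auc_ci[["hi"]])
})
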