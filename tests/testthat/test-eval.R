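P3 <- matrix(c(0.5, 0.3, 0.2,
               0.2, 0.7, 0.1,
               0.1, 0.2, 0.7), 3, 3, byrow = TRUE)

test_that("accuracy counts argmax agreement exactly", {
  onehot <- diag(3)
  expect_equal(accuracy(onehot, c("positive", "uncertain", "negative")), 1)
  expect_equal(accuracy(onehot, c("negative", "positive", "uncertain")), 0)
  expect_equal(accuracy(P3, c("positive", "negative", "negative")), 2 / 3,
               tolerance = 1e-9)
  expect_error(accuracy(P3, c("positive", "negative")), "mismatch")
})

test_that("argmax ties break toward the lower class index and are counted", {
  P <- matrix(c(0.4, 0.4, 0.2), 1, 3)
  expect_message(pred <- predicted_classes(P), "tie")
  expect_identical(pred[1], "positive")
  expect_equal(attr(pred, "n_ties"), 1)
})

test_that("NLPP uses the natural log, the floor, and the mean", {
  expect_equal(nlpp(diag(3), c("positive", "uncertain", "negative")), 0)
  U <- matrix(1 / 3, 4, 3)
  expect_equal(nlpp(U, rep("uncertain", 4)), log(3), tolerance = 1e-9)
  P <- matrix(c(0.5, 0.25, 0.25,
                0.25, 0.5, 0.25), 2, 3, byrow = TRUE)
  expect_equal(nlpp(P, c("positive", "positive")),
               (-log(0.5) - log(0.25)) / 2, tolerance = 1e-9)
  ## degenerate zero probability stays finite through the 1e-12 floor
  Z <- matrix(c(1, 0, 0), 1, 3)
  expect_message(v <- nlpp(Z, "negative"), "floor")
  expect_equal(v, -log(1e-12))
})

test_that("MMPCL is the mean of per-row maxima, bounded in [1/3, 1]", {
  expect_equal(mmpcl(diag(3)), 1)
  expect_equal(mmpcl(matrix(1 / 3, 5, 3)), 1 / 3, tolerance = 1e-12)
  expect_equal(mmpcl(P3[1:2, ]), 0.6, tolerance = 1e-9)
  expect_true(is.na(mmpcl(matrix(numeric(0), 0, 3))))
})

test_that("MMPCL bounds hold on random simplex rows; 1 only for one-hot", {
  withr::with_seed(14, {
    for (i in 1:25) {
      a <- matrix(rgamma(30, runif(1, 0.2, 3)), 10, 3)
      P <- a / rowSums(a)
      v <- mmpcl(P)
      expect_gte(v, 1 / 3)
      expect_lte(v, 1)
      expect_lt(v, 1)  # random draws are almost surely not one-hot
    }
  })
})

test_that("group-wise MMPCL splits FN and TP with explicit empty markers", {
  P <- matrix(c(0.6, 0.3, 0.1,    # truth positive, predicted positive (TP)
                0.2, 0.6, 0.2,    # truth positive, predicted uncertain (FN)
                0.8, 0.1, 0.1,    # truth positive, predicted positive (TP)
                0.1, 0.2, 0.7),   # truth negative (ignored for class positive)
              4, 3, byrow = TRUE)
  truth <- c("positive", "positive", "positive", "negative")
  g <- groupwise_mmpcl(P, truth, class_c = "positive")
  expect_equal(g$mmpcl[g$group == "FN"], 0.6, tolerance = 1e-9)
  expect_equal(g$n[g$group == "FN"], 1)
  expect_equal(g$mmpcl[g$group == "TP"], (0.6 + 0.8) / 2, tolerance = 1e-9)
  expect_equal(g$n[g$group == "TP"], 2)
  ## perfect classifier: FN empty
  g2 <- groupwise_mmpcl(diag(3), c("positive", "uncertain", "negative"),
                        class_c = "positive")
  expect_true(is.na(g2$mmpcl[g2$group == "FN"]))
  expect_equal(g2$n[g2$group == "FN"], 0)
  ## always-wrong classifier: TP empty, FN count = class count
  g3 <- groupwise_mmpcl(matrix(c(0, 0, 1), 3, 3, byrow = TRUE),
                        rep("positive", 3), class_c = "positive")
  expect_true(is.na(g3$mmpcl[g3$group == "TP"]))
  expect_equal(g3$n[g3$group == "FN"], 3)
  expect_error(groupwise_mmpcl(P, truth, class_c = "negative"))
})

test_that("FN and TP counts partition the class rows", {
  withr::with_seed(23, {
    for (i in 1:10) {
      n <- 40
      a <- matrix(rgamma(n * 3, 1), n, 3)
      P <- a / rowSums(a)
      truth <- sample(c("positive", "uncertain", "negative"), n, replace = TRUE)
      for (cl in c("positive", "uncertain")) {
        g <- groupwise_mmpcl(P, truth, class_c = cl)
        expect_equal(sum(g$n), sum(truth == cl))
      }
    }
  })
})

test_that("reliability analysis reproduces hand-binned ECE", {
  P <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(reliability_analysis(P, c("positive", "uncertain", "negative",
                                         "positive"), n_bins = 2)$ece, 0)
  ## 10-row hand fixture, 2 bins on [0,1]: bin (0.5,1] holds rows with
  ## confidence 0.9 (6 rows, 4 correct), bin [0,0.5] rows with 0.4 (4 rows,
  ## 2 correct); ECE = 0.6*|4/6-0.9| + 0.4*|0.5-0.4|
  conf_hi <- matrix(c(0.9, 0.05, 0.05), 6, 3, byrow = TRUE)
  conf_lo <- matrix(c(0.4, 0.3, 0.3), 4, 3, byrow = TRUE)
  P10 <- rbind(conf_hi, conf_lo)
  truth <- c(rep("positive", 4), "uncertain", "negative",
             rep("positive", 2), "uncertain", "negative")
  ra <- reliability_analysis(P10, truth, n_bins = 2)
  expect_equal(ra$ece, 0.6 * abs(4 / 6 - 0.9) + 0.4 * abs(0.5 - 0.4),
               tolerance = 1e-9)
  expect_equal(ra$table$n, c(4L, 6L))
  ## all-uniform rows with balanced truth: confidence 1/3, accuracy ~ 1/3
  U <- matrix(1 / 3, 9, 3)
  tu <- rep(c("positive", "uncertain", "negative"), 3)
  ra2 <- suppressMessages(reliability_analysis(U, tu, n_bins = 3))
  expect_equal(ra2$ece, 0, tolerance = 1e-9)
})

test_that("evaluate_run averages repeats and retains raw values", {
  mk <- function(p_truth) {
    P <- cbind(p_truth, (1 - p_truth) / 2, (1 - p_truth) / 2)
    list(probs = P, truth = rep("positive", length(p_truth)))
  }
  runs <- list(
    list(CONSTest = mk(rep(exp(-1.0), 4))),   # NLPP exactly 1.0
    list(CONSTest = mk(rep(exp(-1.2), 4)))    # NLPP exactly 1.2
  )
  rep_ <- evaluate_run(runs)
  expect_equal(rep_$summary$nlpp[rep_$summary$variant == "CONSTest"], 1.1,
               tolerance = 1e-9)
  expect_equal(rep_$per_repeat$metrics$nlpp, c(1.0, 1.2), tolerance = 1e-9)
  ## identical repeats reproduce the per-repeat values
  rep2 <- evaluate_run(list(runs[[1]], runs[[1]]))
  expect_equal(rep2$summary$nlpp[1], 1.0, tolerance = 1e-9)
  expect_error(evaluate_run(list(runs[[1]], list(Other = mk(0.5)))), "CONSTest")
})

test_that("a 12-row two-repeat fixture reproduces the hand-computed report", {
  ## repeat 1: CONS 4 rows, INCONS 2 rows; repeat 2 differs
  cons1 <- list(probs = matrix(c(0.7, 0.2, 0.1,
                                 0.1, 0.8, 0.1,
                                 0.2, 0.3, 0.5,
                                 0.6, 0.2, 0.2), 4, 3, byrow = TRUE),
                truth = c("positive", "uncertain", "negative", "uncertain"))
  inc1 <- list(probs = matrix(c(0.5, 0.4, 0.1,
                                0.3, 0.3, 0.4), 2, 3, byrow = TRUE),
               truth = c("negative", "positive"))
  cons2 <- list(probs = matrix(c(0.9, 0.05, 0.05,
                                 0.3, 0.4, 0.3,
                                 0.1, 0.1, 0.8,
                                 0.25, 0.5, 0.25), 4, 3, byrow = TRUE),
                truth = c("positive", "positive", "negative", "uncertain"))
  inc2 <- list(probs = matrix(c(0.2, 0.5, 0.3,
                                0.4, 0.2, 0.4), 2, 3, byrow = TRUE),
               truth = c("uncertain", "positive"))
  rep_ <- evaluate_run(list(list(CONSTest = cons1, INCONS = inc1),
                            list(CONSTest = cons2, INCONS = inc2)))
  s <- rep_$summary
  ## accuracy: repeat 1 CONS 3/4 (row 4 predicted positive); repeat 2 CONS
  ## 3/4 (row 2 FN to uncertain); INCONS 0/2, then 2/2 in repeat 2 (row 2
  ## ties positive/negative and breaks toward positive, which is the truth)
  expect_equal(s$accuracy[s$variant == "CONSTest"], (3 / 4 + 3 / 4) / 2,
               tolerance = 1e-9)
  expect_equal(s$accuracy[s$variant == "INCONS"], (0 + 1) / 2,
               tolerance = 1e-9)
  expect_equal(s$nlpp[s$variant == "CONSTest"],
               (mean(-log(c(0.7, 0.8, 0.5, 0.2))) +
                  mean(-log(c(0.9, 0.3, 0.8, 0.5)))) / 2, tolerance = 1e-9)
  expect_equal(s$mmpcl[s$variant == "CONSTest"],
               (mean(c(0.7, 0.8, 0.5, 0.6)) + mean(c(0.9, 0.4, 0.8, 0.5))) / 2,
               tolerance = 1e-9)
  ## group-wise, positive class, CONS: r1 TP {0.7}, FN none; r2 TP {0.9},
  ## FN {0.4}; mean TP = 0.8 over both repeats, FN = 0.4 from repeat 2 only
  g <- rep_$groupwise
  gpos <- g[g$variant == "CONSTest" & g$class == "positive", ]
  expect_equal(gpos$mmpcl[gpos$group == "TP"], (0.7 + 0.9) / 2, tolerance = 1e-9)
  expect_equal(gpos$mmpcl[gpos$group == "FN"], 0.4, tolerance = 1e-9)
  expect_equal(gpos$n[gpos$group == "TP"], 2)
  expect_equal(gpos$n[gpos$group == "FN"], 1)
})

test_that("NLPP via evaluate_run equals an independent per-row computation", {
  withr::with_seed(17, {
    a <- matrix(rgamma(60, 1), 20, 3)
    P <- a / rowSums(a)
    truth <- sample(c("positive", "uncertain", "negative"), 20, replace = TRUE)
    rep_ <- evaluate_run(list(list(S = list(probs = P, truth = truth))))
    idx <- match(truth, c("positive", "uncertain", "negative"))
    oracle <- mean(-log(P[cbind(1:20, idx)]))
    expect_equal(rep_$summary$nlpp, oracle, tolerance = 1e-12)
  })
})

test_that("evaluation reports round-trip through JSON", {
  withr::with_seed(19, {
    a <- matrix(rgamma(30, 1), 10, 3)
    P <- a / rowSums(a)
    truth <- sample(c("positive", "uncertain", "negative"), 10, replace = TRUE)
    rep_ <- evaluate_run(list(list(S = list(probs = P, truth = truth))))
    f <- tempfile(fileext = ".json")
    write_report(rep_, f)
    back <- read_report(f)
    expect_equal(back$summary$nlpp, rep_$summary$nlpp, tolerance = 1e-12)
    expect_equal(back$summary$variant, rep_$summary$variant)
  })
})
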