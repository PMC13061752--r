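sc1 <- scale_calibration(1) # 1 px = 1 mm keeps coordinates readable

test_that("matching equals exhaustive assignment on random small instances", {
  set.seed(61)
  for (rep in 1:40) {
    nt <- sample(0:6, 1); np <- sample(0:6, 1)
    true <- data.frame(x = runif(nt, 0, 12), y = runif(nt, 0, 12))
    pred <- data.frame(x = runif(np, 0, 12), y = runif(np, 0, 12))
    mr <- match_centers(pred, true, radius_mm = 2, scale = sc1)
    or <- oracle_match(pred, true, 2, sc1)
    expect_equal(nrow(mr$tp_pairs), or$tp)
    if (or$tp > 0) expect_equal(sum(mr$tp_pairs$dist_mm), or$dist, tolerance = 1e-9)
    # partition invariants
    expect_equal(nrow(mr$tp_pairs) + length(mr$fn), nt)
    expect_equal(nrow(mr$tp_pairs) + length(mr$fp), np)
    expect_true(all(mr$tp_pairs$dist_mm <= 2))
    expect_false(any(duplicated(mr$tp_pairs$pred_idx)))
    expect_false(any(duplicated(mr$tp_pairs$true_idx)))
  }
})

test_that("matching handles identity, the worked example, and radius growth", {
  pts <- data.frame(x = runif(5, 0, 10), y = runif(5, 0, 10))
  mr <- match_centers(pts, pts, 2, sc1)
  expect_equal(nrow(mr$tp_pairs), 5L)
  expect_length(mr$fp, 0)
  expect_length(mr$fn, 0)

  true <- data.frame(x = c(0, 5), y = c(0, 0))
  pred <- data.frame(x = c(0.5, 20), y = c(0, 0))
  mr2 <- match_centers(pred, true, 2, sc1)
  expect_equal(nrow(mr2$tp_pairs), 1L)
  expect_length(mr2$fp, 1)
  expect_length(mr2$fn, 1)

  # TP count is non-decreasing in the radius
  set.seed(62)
  t3 <- data.frame(x = runif(6, 0, 10), y = runif(6, 0, 10))
  p3 <- data.frame(x = runif(6, 0, 10), y = runif(6, 0, 10))
  tps <- vapply(c(0.5, 1, 2, 4, 8),
                function(r) nrow(match_centers(p3, t3, r, sc1)$tp_pairs),
                numeric(1))
  expect_true(all(diff(tps) >= 0))
})

test_that("swapping pred and true swaps FP with FN and P with R", {
  set.seed(63)
  true <- data.frame(x = runif(5, 0, 8), y = runif(5, 0, 8))
  pred <- data.frame(x = runif(3, 0, 8), y = runif(3, 0, 8))
  a <- detection_metrics(match_centers(pred, true, 2, sc1))
  b <- detection_metrics(match_centers(true, pred, 2, sc1))
  expect_equal(a$tp, b$tp)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
  expect_equal(a$precision, b$recall)
  expect_equal(a$recall, b$precision)
  expect_equal(a$f1, b$f1)
})

test_that("greedy matching agrees with assignment on easy instances", {
  pts <- data.frame(x = c(1, 5, 9), y = c(1, 1, 1))
  mr <- match_centers(pts, pts, 2, sc1, method = "greedy")
  expect_equal(nrow(mr$tp_pairs), 3L)
})

test_that("detection metrics follow the formula and its conventions", {
  m <- detection_metrics(list(tp = 1L, fp = 1L, fn = 1L))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  perfect <- detection_metrics(list(tp = 7L, fp = 0L, fn = 0L))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
  degenerate <- detection_metrics(list(tp = 0L, fp = 3L, fn = 2L))
  expect_equal(c(degenerate$precision, degenerate$recall, degenerate$f1), c(0, 0, 0))
  nothing <- detection_metrics(list(tp = 0L, fp = 0L, fn = 0L))
  expect_equal(c(nothing$precision, nothing$recall), c(1, 1))
})

test_that("counting errors follow MAE / MAPE with the t = 0 convention", {
  m <- count_error_metrics(data.frame(t = c(10, 20), p = c(9, 22)))
  expect_equal(m$mae, 1.5)
  expect_equal(m$mape, 10)
  expect_equal(m$n, 2L)

  ident <- count_error_metrics(data.frame(t = c(4, 9), p = c(4, 9)))
  expect_equal(ident$mae, 0)
  expect_equal(ident$mape, 0)

  single <- count_error_metrics(data.frame(t = 4, p = 6))
  expect_equal(single$mae, 2)
  expect_equal(single$mape, 50)

  expect_warning(z <- count_error_metrics(data.frame(t = c(0, 10), p = c(1, 10))),
                 "excluded from MAPE")
  expect_equal(z$mae, 0.5)
  expect_equal(z$mape, 0) # only the t = 10 image enters
  expect_equal(z$n, 2L)

  expect_error(count_error_metrics(data.frame(t = numeric(0), p = numeric(0))),
               "at least one")
  expect_error(count_error_metrics(data.frame(t = -1, p = 0)), ">= 0")
})

test_that("run evaluation pools TP/FP/FN across images (micro-averaging)", {
  # image A: 2 true, 2 predicted, all matched; image B: 3 true, 1 far
  # prediction -> pooled counts TP=2+0? construct explicitly
  annA <- make_ann(data.frame(x = c(2, 8), y = c(2, 2)), 20L, 20L, 1)
  annB <- make_ann(data.frame(x = c(2, 8, 14), y = c(10, 10, 10)), 20L, 20L, 1)
  preds <- list(A = data.frame(x = c(2.2, 8.1), y = c(2, 2)),
                B = data.frame(x = c(2.5, 18), y = c(10, 18)))
  rep <- evaluate_run(preds, list(A = annA, B = annB), radius_mm = 2)
  # pooled: TP = 3, FP = 1, FN = 2
  expect_equal(rep$detection$tp, 3L)
  expect_equal(rep$detection$fp, 1L)
  expect_equal(rep$detection$fn, 2L)
  expect_equal(rep$detection$precision, 3 / 4)
  expect_equal(rep$detection$recall, 3 / 5)
  expect_equal(rep$detection$f1, 2 * 0.75 * 0.6 / 1.35)
  # micro is the pooled number, not the mean of per-image F1
  expect_equal(rep$macro_f1, mean(c(1, 0.4)))
  expect_false(isTRUE(all.equal(rep$detection$f1, rep$macro_f1)))
  expect_equal(rep$counts$mae, mean(c(0, 1))) # |2-2| and |3-2|

  # perfect predictions give F1 = 1 and MAE = 0
  perfect <- evaluate_run(list(A = annA$points), list(A = annA))
  expect_equal(perfect$detection$f1, 1)
  expect_equal(perfect$counts$mae, 0)

  expect_error(evaluate_run(list(A = annA$points, C = annA$points),
                            list(A = annA, B = annB)),
               "C")
})

test_that("evaluation reports serialize to JSON with aggregate block", {
  ann <- make_ann(data.frame(x = c(2, 8), y = c(2, 2)), 20L, 20L, 1)
  rep <- evaluate_run(list(A = ann$points), list(A = ann))
  f <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_evaluation_report(rep, f, fc)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(parsed$aggregate$f1, 1)
  expect_equal(parsed$aggregate$mae, 0)
  expect_equal(nrow(utils::read.csv(fc)), 1L)
})
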