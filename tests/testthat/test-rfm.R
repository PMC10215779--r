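# Brute-force oracle for the Gini-gap rule: enumerate every cut point of the
# importance-sorted vector, take the largest gap (earliest on ties), extend
# to the second-largest when the cut keeps a single predictor, fall back to
# the top predictor when no usable second gap exists.
select_oracle <- function(imp, canonical = predictor_ids()) {
  canon <- match(names(imp), canonical)
  canon[is.na(canon)] <- length(canonical) + seq_len(sum(is.na(canon)))
  ord <- order(-imp, canon)
  v <- as.numeric(imp[ord])
  best <- 0; best_gap <- -Inf
  second <- 0; second_gap <- -Inf
  for (cut in seq_len(length(v) - 1)) {
    gap <- v[cut] - v[cut + 1]
    if (gap > best_gap) {
      second <- best; second_gap <- best_gap
      best <- cut; best_gap <- gap
    } else if (gap > second_gap) {
      second <- cut; second_gap <- gap
    }
  }
  cut <- best
  if (cut == 1) {
    all_tied <- length(unique(v[-length(v)] - v[-1])) == 1
    cut <- if (length(v) == 2 || all_tied) 1 else second
  }
  names(imp)[ord][seq_len(cut)]
}

test_that("presence labels derive from counts and conserve occurrences", {
  fr <- synthetic_frame(100, seed = 8)
  lt <- build_labels(fr)
  expect_identical(dim(lt$labels), c(100L, 3L))
  expect_identical(unname(colSums(lt$labels)),
                   vapply(attr(fr, "genera"), function(g) sum(fr[[g]] > 0),
                          double(1), USE.NAMES = FALSE))
  # single-genus row labels that genus 1 and the rest 0
  i <- which(fr$Alpha > 0 & fr$Beta == 0 & fr$Gamma == 0)[1]
  expect_identical(unname(lt$labels[i, ]), c(1L, 0L, 0L))
  expect_true(all(rowSums(lt$labels) >= 1))
})

test_that("the 80/20 split is seeded, disjoint, and exhaustive", {
  lt <- build_labels(synthetic_frame(100, seed = 8))
  s1 <- split_80_20(lt, seed = 4)
  s2 <- split_80_20(lt, seed = 4)
  expect_identical(s1$train_idx, s2$train_idx)
  expect_identical(nrow(s1$train$features), 80L)
  expect_identical(nrow(s1$test$features), 20L)
  expect_identical(sort(c(s1$train_idx, setdiff(1:100, s1$train_idx))), 1:100)

  tiny <- build_labels(synthetic_frame(20, seed = 8))
  tiny$features <- tiny$features[1:4, ]; tiny$labels <- tiny$labels[1:4, ]
  expect_error(split_80_20(tiny), "at least 5 rows")
})

test_that("a perfectly separating feature dominates importance and accuracy", {
  withr::with_seed(15, {
    n <- 200
    X <- as.data.frame(matrix(rnorm(n * 6), n,
                              dimnames = list(NULL, paste0("p", 1:6))))
    y <- as.integer(X$p3 > 0)
    X$p3 <- X$p3 + ifelse(y == 1, 2, -2)   # widen the margin
  })
  rf <- train_rf(X[1:160, ], y[1:160], n_trees = 200, seed = 5)
  expect_identical(names(which.max(rf$importance)), "p3")
  expect_true(all(rf$importance >= 0) && any(rf$importance > 0))
  ev <- evaluate_rf(rf, X[161:200, ], y[161:200])
  expect_identical(ev$accuracy, 100)
  expect_identical(ev$specificity, 100)

  expect_error(train_rf(X, rep(1L, n)), "degenerate labels")
})

test_that("confusion-matrix arithmetic matches hand evaluation", {
  withr::with_seed(16, {
    x1 <- rep(c(0, 1), each = 60) + rnorm(120, sd = 0.05)
    train <- data.frame(x1 = x1, x2 = rnorm(120))
  })
  rf <- train_rf(train, rep(c(0L, 1L), each = 60), n_trees = 100, seed = 1)
  # 9 rows the model will call negative, 11 it will call positive
  test_x <- data.frame(x1 = c(rep(0, 9), rep(1, 11)), x2 = 0)
  test_y <- c(rep(0L, 8), 1L,                # among predicted-0: 8 TN, 1 FN
              rep(1L, 9), 0L, 0L)            # among predicted-1: 9 TP, 2 FP
  ev <- evaluate_rf(rf, test_x, test_y)
  expect_identical(ev$confusion, c(TN = 8L, FP = 2L, FN = 1L, TP = 9L))
  expect_equal(ev$accuracy, 85)
  expect_equal(ev$specificity, 80)

  # no actual negatives: specificity undefined but accuracy still computed
  ev2 <- evaluate_rf(rf, test_x[10:20, ], rep(1L, 11))
  expect_true(is.na(ev2$specificity))
  expect_equal(ev2$accuracy, 100)
})

test_that("Gini-gap selection matches its stated examples", {
  imp <- c(a = 10, b = 9, c = 4, d = 3, e = 2)
  expect_identical(select_predictors(imp), c("a", "b"))        # gap 5 after b
  imp2 <- c(a = 10, b = 4, c = 3, d = 1)
  expect_identical(select_predictors(imp2), c("a", "b", "c"))  # extension rule
  imp3 <- c(temperature_0m = 5, salinity_0m = 5)
  expect_identical(select_predictors(imp3), "temperature_0m")  # fallback
  expect_error(select_predictors(c(a = 1)), "at least 2")
})

test_that("selection agrees with brute-force cut-point enumeration", {
  withr::with_seed(23, {
    for (i in 1:300) {
      k <- sample(2:12, 1)
      v <- if (i %% 3 == 0) sample(0:5, k, replace = TRUE) else round(runif(k, 0, 10), 2)
      imp <- stats::setNames(as.numeric(v), sample(predictor_ids(), k))
      got <- select_predictors(imp)
      want <- select_oracle(imp)
      expect_identical(got, want)
      # selected is a prefix of the importance ordering
      canon <- match(names(imp), predictor_ids())
      ord <- names(imp)[order(-imp, canon)]
      expect_identical(got, ord[seq_along(got)])
    }
  })
})

test_that("rfm_all shares one split and reports per-genus selections", {
  fr <- synthetic_frame(150, seed = 10)
  lt <- build_labels(fr)
  res <- rfm_all(lt, split_seed = 1, rf_seed = 2, n_trees = 100)
  expect_identical(res$summary$genus, attr(fr, "genera"))
  expect_true(all(res$summary$accuracy >= 0 & res$summary$accuracy <= 100,
                  na.rm = TRUE))
  expect_true(all(vapply(res$selected, length, integer(1)) >= 1))
  for (g in names(res$selected)) {
    imp <- res$importance$importance[res$importance$genus == g]
    names(imp) <- res$importance$predictor[res$importance$genus == g]
    expect_identical(res$selected[[g]], select_oracle(imp))
  }
})
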