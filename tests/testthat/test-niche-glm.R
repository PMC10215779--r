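test_that("negative-binomial fit recovers closed-form and simulated parameters", {
  # intercept-only on constant counts: intercept = log(c)
  fit <- fit_nb_glm(rep(5L, 40))
  expect_equal(unname(fit$coefficients[1]), log(5), tolerance = 1e-6)

  # parameter recovery on simulated overdispersed counts
  withr::with_seed(12, {
    x <- rnorm(2000)
    y <- MASS::rnegbin(2000, mu = exp(1 + 0.5 * x), theta = 2)
  })
  fit <- fit_nb_glm(y, data.frame(x = x))
  expect_equal(unname(fit$coefficients["x"]), 0.5, tolerance = 0.1)
  expect_identical(fit$family, "negative_binomial")

  expect_error(fit_nb_glm(c(-1L, 2L)), "non-negative")
  degen <- fit_nb_glm(rep(0L, 10))
  expect_true(degen$degenerate)
})

test_that("multivariate statistic is zero for constant counts and order-invariant", {
  fr <- synthetic_frame(60, seed = 3)
  flat <- fr
  for (g in attr(fr, "genera")) flat[[g]] <- 2L
  attr(flat, "genera") <- attr(fr, "genera")
  mv0 <- manyglm_test(flat, n_resamples = 19, seed = 1)
  expect_equal(mv0$statistic, 0, tolerance = 1e-6)
  expect_length(mv0$warnings, 1)     # n_resamples below 99 is flagged

  mv_a <- manyglm_test(fr, genera = c("Alpha", "Beta", "Gamma"),
                       n_resamples = 99, seed = 5)
  mv_b <- manyglm_test(fr, genera = c("Gamma", "Alpha", "Beta"),
                       n_resamples = 99, seed = 5)
  expect_equal(mv_a$statistic, mv_b$statistic, tolerance = 1e-8)
  expect_identical(mv_a$p_value, mv_b$p_value)
})

test_that("counts deterministically driven by a predictor reach maximal significance", {
  fr <- synthetic_frame(80, seed = 4)
  x <- fr$temperature_0m
  fr$Alpha <- as.integer(round(pmax(0, 4 + 3 * x)))
  fr$Beta <- as.integer(round(pmax(0, 4 - 3 * x)))
  mv <- manyglm_test(fr, genera = c("Alpha", "Beta"), n_resamples = 99, seed = 2)
  expect_identical(mv$p_value, 1 / 100)
})

test_that("niche biplot is deterministic, order-invariant, and distance-monotone", {
  withr::with_seed(6, {
    M <- matrix(rnorm(5 * 8), 5, 8,
                dimnames = list(paste0("g", 1:5), paste0("p", 1:8)))
  })
  M[2, ] <- M[1, ]                   # two identical genera
  bp <- niche_biplot(M)
  expect_equal(bp$scores[1, ], bp$scores[2, ], tolerance = 1e-10)
  expect_true(all(diff(bp$var_explained) <= 1e-12))

  perm <- withr::with_seed(7, sample(ncol(M)))
  bp2 <- niche_biplot(M[, perm])
  expect_equal(abs(bp$scores), abs(bp2$scores), tolerance = 1e-8)

  # growing perturbation of a duplicated genus moves it monotonically away
  dists <- vapply(c(0.1, 0.3, 0.6, 1.0, 2.0), function(eps) {
    Mp <- rbind(M, perturbed = M[1, ] + eps * seq_len(ncol(M)) / ncol(M))
    s <- niche_biplot(Mp)$scores
    sqrt(sum((s["perturbed", ] - s["g1", ])^2))
  }, double(1))
  expect_true(all(diff(dists) > 0))

  expect_error(niche_biplot(M[1:2, ]), "3 genera")
})

test_that("identical groups share a letter; separated groups do not", {
  vals <- c(1:50, 1:50)
  grp <- rep(c("A", "B"), each = 50)
  r <- kruskal_dunn_letters(vals, grp)
  expect_identical(unname(r$letters["A"]), unname(r$letters["B"]))

  sep <- kruskal_dunn_letters(c(1:50, 101:150), rep(c("A", "B"), each = 50))
  expect_false(sep$letters["A"] == sep$letters["B"])
  # direct z computation for the separated pair (no ties)
  N <- 100; rbar <- c(mean(1:50), mean(51:100))
  z <- (rbar[1] - rbar[2]) / sqrt(N * (N + 1) / 12 * (2 / 50))
  expect_equal(sep$dunn$z, z, tolerance = 1e-10)
  expect_lt(sep$dunn$p, 0.05)
  expect_equal(sep$chisq, unname(kruskal.test(c(1:50, 101:150),
                                              factor(rep(1:2, each = 50)))$statistic))

  expect_error(kruskal_dunn_letters(1:10, rep("A", 10)), "2 groups")
})

test_that("overlap chains produce shared middle letters mirroring non-significance", {
  vals <- c(1:30, 1:30 + 5, 1:30 + 10)
  grp <- rep(c("A", "B", "C"), each = 30)
  r <- kruskal_dunn_letters(vals, grp)
  expect_identical(unname(r$letters), c("a", "ab", "b"))

  # property: sharing a letter <=> pairwise non-significance, on random data
  withr::with_seed(9, {
    for (rep_i in 1:5) {
      g <- rep(letters[1:4], each = 25)
      v <- rnorm(100, mean = rep(runif(4, 0, 2), each = 25))
      res <- kruskal_dunn_letters(v, g)
      for (k in seq_len(nrow(res$dunn))) {
        shares <- any(strsplit(res$letters[res$dunn$group1[k]], "")[[1]] %in%
                        strsplit(res$letters[res$dunn$group2[k]], "")[[1]])
        expect_identical(shares, res$dunn$p_adjusted[k] >= res$alpha)
      }
    }
  })
})
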