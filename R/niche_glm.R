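# Multivariate abundance GLM niche test, coefficient biplot, and
# Kruskal-Wallis / Dunn distribution grouping. Counts are modelled per genus
# with a negative-binomial log link (overdispersed, low-mean abundance
# counts); the multivariate statistic is the sum of per-genus
# null-vs-full likelihood-ratio statistics, with significance from
# unrestricted row-permutation resampling of the predictor rows.

#' Fit a negative-binomial GLM to one genus' counts
#'
#' Log-link negative binomial via maximum likelihood ([MASS::glm.nb()]);
#' when the NB fit degenerates (no overdispersion, e.g. constant counts) the
#' fit falls back to Poisson and is flagged via `family`.
#'
#' @param counts Non-negative integer response vector.
#' @param predictors Numeric matrix/data frame of covariates, or `NULL` for
#'   an intercept-only model. No missing values (impute first).
#' @return An `nb_fit`: list with `coefficients`, `deviance`,
#'   `null_deviance`, `theta` (`Inf` under the Poisson fallback), `family`,
#'   `converged`, `degenerate`, and the underlying `model`.
#' @export
fit_nb_glm <- function(counts, predictors = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != floor(counts))) stop("counts must be integers")
  if (all(counts == 0)) {
    return(structure(list(coefficients = NULL, deviance = NA_real_,
                          null_deviance = NA_real_, theta = NA_real_,
                          family = "degenerate", converged = FALSE,
                          degenerate = TRUE, model = NULL),
                     class = "nb_fit"))
  }
  df <- if (is.null(predictors)) {
    data.frame(y = counts)
  } else {
    cbind(data.frame(y = counts), as.data.frame(predictors))
  }
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ ., data = df)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || !is.finite(fit$theta)) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ ., data = df, family = poisson())),
      error = function(e) stats::glm(y ~ 1, data = df, family = poisson())
    )
    family <- "poisson"
    theta <- Inf
  } else {
    family <- "negative_binomial"
    theta <- fit$theta
  }
  structure(list(coefficients = coef(fit), deviance = fit$deviance,
                 null_deviance = fit$null.deviance, theta = theta,
                 family = family, converged = fit$converged,
                 degenerate = FALSE, model = fit),
            class = "nb_fit")
}

# Deviance of a fixed-family GLM fit without formula overhead. Divergent
# iterations (possible for sparse overdispersed counts) fall back to a
# null start; an unfittable model contributes its null deviance, i.e. a
# zero likelihood-ratio statistic.
glm_deviance <- function(X, y, fam) {
  dev <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = fam,
                             control = stats::glm.control(maxit = 100))$deviance),
    error = function(e) NA_real_
  )
  if (is.na(dev)) {
    start <- c(log(mean(y) + 0.1), rep(0, ncol(X) - 1))
    dev <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = fam, start = start,
                               control = stats::glm.control(maxit = 100))$deviance),
      error = function(e) NA_real_
    )
  }
  if (is.na(dev)) {
    dev <- suppressWarnings(glm.fit(matrix(1, length(y), 1), y, family = fam)$deviance)
  }
  dev
}

#' Multivariate GLM permutation test of environmental niche structure
#'
#' Fits one negative-binomial GLM per genus (counts ~ standardized
#' predictors), sums the per-genus null-vs-full likelihood-ratio statistics
#' into a multivariate statistic, and computes its p-value by unrestricted
#' row-permutation of the predictor matrix (the dispersion of each genus is
#' held at its observed estimate across permutations).
#'
#' @param frame An imputed `curated_frame` (or any data frame with genus
#'   count columns and predictor columns).
#' @param predictors Character vector of predictor columns (default: all
#'   canonical predictor ids present in `frame`).
#' @param genera Character vector of genus count columns (default: attribute
#'   `genera` of the frame). At least 2 required.
#' @param n_resamples Number of permutations (a value below 99 is recorded
#'   as a warning in the result).
#' @param seed Integer seed for the permutations.
#' @return An `mv_glm_result`: `statistic`, `p_value`, `per_genus` tibble
#'   (statistic, theta, family per genus), `coefficients` (genus x term
#'   matrix), `n_resamples`, `seed`, `warnings`.
#' @export
manyglm_test <- function(frame, predictors = NULL, genera = NULL,
                         n_resamples = 999, seed = 1) {
  genera <- genera %||% attr(frame, "genera")
  if (is.null(genera)) stop("genera not given and frame carries no 'genera' attribute")
  genera <- intersect(genera, names(frame))
  if (length(genera) < 2) stop("need at least 2 genera")
  predictors <- predictors %||% intersect(predictor_ids(), names(frame))
  X <- as.matrix(frame[, predictors, drop = FALSE])
  if (anyNA(X)) stop("predictors contain missing values; impute first")
  sds <- apply(X, 2, sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  n <- nrow(X)
  # The 28 predictors are strongly collinear across depths; the LR
  # statistics depend only on the design's column space, so fit against an
  # orthonormal basis of it for numerical stability.
  qrX <- qr(X)
  Xo <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE] * sqrt(n)
  Xfull <- cbind(`(Intercept)` = 1, Xo)
  Xnull <- matrix(1, n, 1)

  warnings <- character(0)
  if (n_resamples < 99) {
    warnings <- c(warnings, sprintf("n_resamples = %d is below 99; p-value resolution is poor", n_resamples))
  }

  fams <- list(); stats_g <- numeric(length(genera)); coefs <- list()
  per <- vector("list", length(genera))
  for (k in seq_along(genera)) {
    y <- frame[[genera[k]]]
    fit <- fit_nb_glm(y, X)
    fam <- if (is.finite(fit$theta)) MASS::negative.binomial(fit$theta) else poisson()
    # refit both models under the fixed family so LR statistics are comparable
    dev_full <- glm_deviance(Xfull, y, fam)
    dev_null <- glm_deviance(Xnull, y, fam)
    stats_g[k] <- max(dev_null - dev_full, 0)
    fams[[k]] <- fam
    co <- fit$coefficients
    co[is.na(co)] <- 0            # aliased (collinear) terms
    coefs[[k]] <- stats::setNames(as.numeric(co), names(co))
    per[[k]] <- tibble::tibble(genus = genera[k], statistic = stats_g[k],
                               theta = fit$theta, family = fit$family)
  }
  observed <- sum(stats_g)

  perm_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_resamples), function(r) {
      pidx <- sample.int(n)
      Xp <- Xfull
      Xp[, -1] <- Xfull[pidx, -1, drop = FALSE]
      s <- 0
      for (k in seq_along(genera)) {
        y <- frame[[genera[k]]]
        dev_full <- glm_deviance(Xp, y, fams[[k]])
        dev_null <- glm_deviance(Xnull, y, fams[[k]])
        s <- s + max(dev_null - dev_full, 0)
      }
      s
    }, double(1))
  })
  p <- (1 + sum(perm_stats >= observed - 1e-8)) / (1 + n_resamples)

  terms <- c("(Intercept)", colnames(X))
  coef_mat <- matrix(0, length(genera), length(terms),
                     dimnames = list(genera, terms))
  for (k in seq_along(genera)) {
    # backtick-wrapping by the formula interface is stripped on match
    nm <- gsub("^`|`$", "", names(coefs[[k]]))
    hit <- match(nm, terms)
    coef_mat[k, hit[!is.na(hit)]] <- coefs[[k]][!is.na(hit)]
  }
  structure(list(statistic = observed, p_value = p,
                 per_genus = dplyr::bind_rows(per),
                 coefficients = coef_mat,
                 n_resamples = n_resamples, seed = seed,
                 warnings = warnings),
            class = "mv_glm_result")
}

#' @export
print.mv_glm_result <- function(x, ...) {
  cat(sprintf("<mv_glm_result> statistic = %.2f, p = %.4g (%d permutations, %d genera)\n",
              x$statistic, x$p_value, x$n_resamples, nrow(x$coefficients)))
  invisible(x)
}

#' Project genera into a 2D niche biplot
#'
#' Principal-component projection of the standardized genus x predictor
#' coefficient matrix onto two axes. Sign convention: each axis is oriented
#' so its largest-magnitude loading is positive, making the configuration
#' deterministic and invariant to predictor column order.
#'
#' @param x An `mv_glm_result` or a genus x predictor coefficient matrix
#'   (an `(Intercept)` column is dropped).
#' @return List with `scores` (genus x 2), `loadings`, `var_explained`
#'   (non-increasing proportion per axis).
#' @export
niche_biplot <- function(x) {
  M <- if (inherits(x, "mv_glm_result")) x$coefficients else as.matrix(x)
  M <- M[, setdiff(colnames(M), "(Intercept)"), drop = FALSE]
  if (nrow(M) < 3) stop("biplot undefined for fewer than 3 genera")
  sds <- apply(M, 2, sd)
  M <- M[, sds > 0, drop = FALSE]
  if (ncol(M) < 1) stop("no predictor with variation across genera")
  Z <- scale(M)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loads <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loads[, j]))
    if (loads[top, j] < 0) {
      loads[, j] <- -loads[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loads, var_explained = ve[seq_len(k)])
}

#' Kruskal-Wallis test with Dunn post-hoc compact letter display
#'
#' Tie-corrected Kruskal-Wallis chi-squared across groups, pairwise Dunn
#' z-tests on mean ranks, and a compact letter display in which two groups
#' share a letter exactly when their pairwise comparison is non-significant
#' at `alpha`. Letters are the maximal cliques of the non-significance
#' graph, so the sharing relation mirrors the test results by construction.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length as `values`; at least 2 groups.
#' @param alpha Significance level for the pairwise tests.
#' @param p_adjust Multiple-comparison adjustment for the Dunn p-values
#'   (any [stats::p.adjust()] method; default `"none"`).
#' @return List with `chisq`, `df`, `p_value` (Kruskal-Wallis), `dunn`
#'   (tibble of pairwise z and p), `letters` (named character), `alpha`.
#' @export
kruskal_dunn_letters <- function(values, groups, alpha = 0.05, p_adjust = "none") {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 1)) stop("every group needs at least one value")
  kw <- kruskal.test(values, groups)

  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- as.vector(table(groups))
  ties <- table(values)
  C <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pair <- utils::combn(seq_along(lev), 2)
  z <- p <- numeric(ncol(pair))
  for (k in seq_len(ncol(pair))) {
    i <- pair[1, k]; j <- pair[2, k]
    se <- sqrt((N * (N + 1) / 12 - C) * (1 / ni[i] + 1 / ni[j]))
    z[k] <- (rbar[i] - rbar[j]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  p_adj <- p.adjust(p, method = p_adjust)
  dunn <- tibble::tibble(group1 = lev[pair[1, ]], group2 = lev[pair[2, ]],
                         z = z, p = p, p_adjusted = p_adj)

  nonsig <- p_adj >= alpha
  g <- igraph::make_empty_graph(n = length(lev), directed = FALSE)
  if (any(nonsig)) {
    g <- igraph::add_edges(g, as.vector(pair[, nonsig, drop = FALSE]))
  }
  cliques <- igraph::max_cliques(g)
  cliques <- cliques[order(vapply(cliques, min, double(1)))]
  letters_vec <- stats::setNames(rep("", length(lev)), lev)
  for (ci in seq_along(cliques)) {
    members <- as.integer(cliques[[ci]])
    letters_vec[members] <- paste0(letters_vec[members], letters[ci])
  }
  list(chisq = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, dunn = dunn, letters = letters_vec,
       alpha = alpha)
}
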