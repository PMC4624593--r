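# Elastic-net association: penalized fit, CV penalty selection,
# rank-proportional feature scoring, and bootstrap rank aggregation.

# Align a feature x sample matrix (or integrated_matrix) with an outcome
# vector; returns list(x = n x p model matrix, y, tags, entity, platform).
align_xy <- function(X, y) {
  if (inherits(y, "outcome_vector")) y <- y$values
  if (is.null(names(y))) stop("y must be named by sample id")
  if (inherits(X, "integrated_matrix")) {
    vals <- X$values
    entity <- X$entity
    platform <- X$platform
  } else {
    stopifnot(is.matrix(X))
    vals <- X
    entity <- rownames(X)
    platform <- rep(NA_character_, nrow(X))
  }
  missing <- setdiff(names(y), colnames(vals))
  if (length(missing))
    stop("X columns must cover y's encoded samples; missing: ",
         paste(head(missing, 5), collapse = ", "))
  vals <- vals[, names(y), drop = FALSE]
  list(x = t(vals), y = as.numeric(y), tags = rownames(vals),
       entity = entity, platform = platform)
}

#' Smallest penalty with an all-zero solution
#'
#' From the optimality conditions of the elastic-net objective, the
#' coefficient vector is exactly zero whenever
#' `lambda >= max_j |x_j' (y - ybar)| / (n * alpha)`. For `alpha` below
#' 0.001 the bound is computed at 0.001 (the all-zero penalty diverges as
#' the penalty becomes pure ridge).
#'
#' @param X integrated matrix or feature-by-sample matrix.
#' @param y outcome vector (named numeric or [encode_outcome()] result).
#' @param alpha elastic-net mixing weight.
#' @return the penalty bound `lambda_max`.
#' @export
lambda_max <- function(X, y, alpha = 0.5) {
  a <- align_xy(X, y)
  n <- length(a$y)
  yc <- a$y - mean(a$y)
  max(abs(crossprod(a$x, yc))) / (n * max(alpha, 0.001))
}

#' Default penalty grid
#'
#' 100 log-spaced values decreasing from `lambda_max` down to
#' `min_ratio * lambda_max`.
#'
#' @param lmax the largest penalty (see [lambda_max()]).
#' @param nlambda grid length.
#' @param min_ratio ratio of the smallest to the largest penalty.
#' @return strictly decreasing numeric vector.
#' @export
lambda_grid <- function(lmax, nlambda = 100, min_ratio = 1e-3) {
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' Fit an elastic-net regression
#'
#' Minimizes
#' \deqn{\frac{1}{2n}\sum_j (y_j - \beta_0 - x_j^T\beta)^2 +
#'       \lambda\left(\alpha\|\beta\|_1 +
#'       \frac{1-\alpha}{2}\|\beta\|_2^2\right)}
#' by cyclic coordinate descent with soft-thresholding; unselected
#' features have exactly zero coefficients. Convergence is declared when
#' the largest coefficient change in a full sweep drops below `tol`.
#'
#' @param X an [integrate_platforms()] result, or a numeric matrix with
#'   features as rows and samples as columns. Columns must cover the
#'   samples named in `y`.
#' @param y an [encode_outcome()] result or named numeric vector.
#' @param alpha mixing weight in `[0,1]` (1 = lasso, 0 = ridge).
#' @param lambda penalty value(s); a decreasing vector is fitted as a
#'   warm-started path and the last value returned (pass via
#'   [cv_select_lambda()] for data-driven selection).
#' @param tol convergence tolerance on the coefficient change.
#' @param maxit maximum number of coordinate sweeps.
#' @param record_objective record the objective value after every sweep
#'   (available as `fit$objective`).
#' @return an `enet_fit`: list with `alpha`, `lambda`, `beta0`, `beta`
#'   (named by `"<feature>|<platform>"` tags), `features` annotation,
#'   `converged`, `niter`, `n`, and optionally `objective`.
#' @export
fit_elastic_net <- function(X, y, alpha = 0.5, lambda, tol = 1e-7,
                            maxit = 100000L, record_objective = FALSE) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]")
  if (any(lambda < 0)) stop("lambda must be >= 0")
  a <- align_xy(X, y)
  n <- length(a$y)
  if (n < 2) stop("at least 2 samples required")
  xm <- colMeans(a$x)
  xc <- sweep(a$x, 2, xm)
  ym <- mean(a$y)
  yc <- a$y - ym
  res <- enet_cd_path(crossprod(xc) / n, drop(crossprod(xc, yc)) / n,
                      sum(yc^2) / n, alpha, as.numeric(lambda), tol,
                      as.integer(maxit), record_objective)
  l <- length(lambda)
  beta <- res$beta[, l]
  names(beta) <- a$tags
  structure(list(alpha = alpha, lambda = lambda[l],
                 beta0 = ym - sum(xm * beta), beta = beta,
                 features = data.frame(tag = a$tags, entity = a$entity,
                                       platform = a$platform,
                                       stringsAsFactors = FALSE),
                 converged = as.logical(res$converged[l]),
                 niter = res$niter[l], n = n,
                 objective = if (record_objective) res$objective[[l]] else NULL),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf("<enet_fit alpha=%.3g lambda=%.4g: %d/%d features selected>\n",
              x$alpha, x$lambda, sum(x$beta != 0), length(x$beta)))
  invisible(x)
}

#' Select the penalty by k-fold cross-validation
#'
#' Samples are assigned to `k` folds by a seeded random permutation; the
#' full penalty path is fitted on each training split and the mean
#' held-out squared error computed per penalty. The selected penalty
#' minimizes the average mean-squared error over the testing folds (ties
#' resolve to the largest, i.e. most parsimonious, penalty), and the
#' final model is refitted on all samples at that penalty.
#'
#' @inheritParams fit_elastic_net
#' @param k number of folds (default 10).
#' @param grid strictly decreasing penalty grid; defaults to
#'   [lambda_grid()] at this data's [lambda_max()].
#' @param seed RNG seed for the fold assignment.
#' @param fold_tol convergence tolerance for the per-fold path fits; the
#'   held-out error curve does not require the final fit's precision, so
#'   a looser default is used. The full-data refit runs at `tol`.
#' @return list with `lambda` (the selected penalty), `fit` (the
#'   full-data `enet_fit` at that penalty), `cv_curve` (data frame
#'   `lambda`, `mse`), and `folds`.
#' @export
cv_select_lambda <- function(X, y, alpha = 0.5, k = 10, grid = NULL,
                             seed = 1L, tol = 1e-7, fold_tol = 1e-4,
                             maxit = 100000L) {
  a <- align_xy(X, y)
  core <- cv_core(a$x, a$y, alpha = alpha, k = k, grid = grid, seed = seed,
                  tol = tol, fold_tol = fold_tol, maxit = maxit)
  beta <- core$beta
  names(beta) <- a$tags
  fit <- structure(list(alpha = alpha, lambda = core$lambda,
                        beta0 = core$beta0, beta = beta,
                        features = data.frame(tag = a$tags, entity = a$entity,
                                              platform = a$platform,
                                              stringsAsFactors = FALSE),
                        converged = core$converged, niter = core$niter,
                        n = length(a$y), objective = NULL),
                   class = "enet_fit")
  list(lambda = core$lambda, fit = fit,
       cv_curve = data.frame(lambda = core$grid, mse = core$cvm),
       folds = core$folds)
}

# Cross-validation engine on a plain n x p model matrix. Fold Gram
# matrices are obtained by downdating the full Gram matrix with each
# held-out block, so the dominant O(n p^2) product is computed once.
# Fold fits run at `fold_tol` (the CV curve does not need the final
# fit's precision); the full-data refit at the selected penalty runs at
# `tol`.
cv_core <- function(x, yv, alpha, k, grid, seed, tol, fold_tol, maxit) {
  if (k < 2) stop("k must be >= 2")
  n <- nrow(x)
  if (n < k) stop("fewer samples than folds")
  if (is.null(grid)) {
    lmax <- max(abs(crossprod(x, yv - mean(yv)))) / (n * max(alpha, 0.001))
    grid <- lambda_grid(lmax)
  }
  if (length(grid) > 1 && any(diff(grid) >= 0))
    stop("grid must be strictly decreasing")

  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  G <- crossprod(x)
  Xy <- drop(crossprod(x, yv))
  cs <- colSums(x)
  sy <- sum(yv)
  syy <- sum(yv^2)
  mse <- matrix(NA_real_, k, length(grid))
  for (f in seq_len(k)) {
    te <- which(folds == f)
    xte <- x[te, , drop = FALSE]
    yte <- yv[te]
    ntr <- n - length(te)
    xm <- (cs - colSums(xte)) / ntr
    ym <- (sy - sum(yte)) / ntr
    H <- (G - crossprod(xte)) / ntr - tcrossprod(xm)
    cvec <- (Xy - drop(crossprod(xte, yte))) / ntr - xm * ym
    yy <- (syy - sum(yte^2)) / ntr - ym^2
    res <- enet_cd_path(H, cvec, yy, alpha, as.numeric(grid), fold_tol,
                        as.integer(maxit), FALSE)
    pred <- sweep(xte, 2, xm) %*% res$beta + ym
    mse[f, ] <- colMeans((yte - pred)^2)
  }
  cvm <- colMeans(mse)
  best <- which.min(cvm)

  xm <- cs / n
  ym <- sy / n
  H <- G / n - tcrossprod(xm)
  cvec <- Xy / n - xm * ym
  yy <- syy / n - ym^2
  res <- enet_cd_path(H, cvec, yy, alpha, as.numeric(grid[seq_len(best)]),
                      tol, as.integer(maxit), FALSE)
  beta <- res$beta[, best]
  list(lambda = grid[best], beta = beta, beta0 = ym - sum(xm * beta),
       converged = as.logical(res$converged[best]), niter = res$niter[best],
       grid = grid, cvm = cvm, folds = folds)
}

#' Rank-proportional feature scores from a fit
#'
#' The `m` features with nonzero coefficients are ranked `1..m` by
#' decreasing absolute coefficient (ties broken lexicographically by
#' feature tag); the feature at rank `r` scores `(m - r + 1)/m`, so the
#' top feature scores 1 and the weakest selected feature `1/m`. The
#' alternative inverse-rank scheme scores `1/r`. Unselected features
#' receive no score. The direction is the coefficient sign: positive =
#' direct association (the outcome increases as the predictor increases),
#' negative = inverse association.
#'
#' @param fit an [fit_elastic_net()] result (must have converged).
#' @param method `"linear"` (default) or `"inverse"`.
#' @return data frame `tag`, `entity`, `platform`, `coefficient`, `rank`,
#'   `score`, `direction` — one row per selected feature, best rank first.
#' @export
score_features <- function(fit, method = c("linear", "inverse")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "enet_fit"))
  if (!fit$converged) stop("fit did not converge")
  nz <- which(fit$beta != 0)
  ann <- fit$features[nz, , drop = FALSE]
  co <- fit$beta[nz]
  if (!length(nz)) {
    return(data.frame(tag = character(0), entity = character(0),
                      platform = character(0), coefficient = numeric(0),
                      rank = integer(0), score = numeric(0),
                      direction = numeric(0), stringsAsFactors = FALSE))
  }
  ord <- order(-abs(co), ann$tag)
  m <- length(ord)
  r <- seq_len(m)
  score <- if (method == "linear") (m - r + 1) / m else 1 / r
  data.frame(tag = ann$tag[ord], entity = ann$entity[ord],
             platform = ann$platform[ord],
             coefficient = unname(co[ord]), rank = r, score = score,
             direction = sign(unname(co[ord])), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Aggregate feature scores per entity
#'
#' The score of a gene (or miR/protein) is the sum of the scores of all
#' its selected features across platforms; entities with no scored
#' feature are absent. Per-platform direction signs are carried along.
#'
#' @param scores a [score_features()] result.
#' @return data frame `entity`, `score` (descending; ties broken by
#'   entity id) with attribute `features` holding the input rows.
#' @export
aggregate_genes <- function(scores) {
  if (!nrow(scores)) {
    out <- data.frame(entity = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "features") <- scores
    return(out)
  }
  agg <- tapply(scores$score, scores$entity, sum)
  out <- data.frame(entity = names(agg), score = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$entity), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "features") <- scores
  out
}

#' Rank entities from a single cross-validated fit
#'
#' Convenience wrapper: [cv_select_lambda()] then [score_features()] then
#' [aggregate_genes()], returned in the same shape as [bootstrap_rank()]
#' with `B = 1`.
#'
#' @inheritParams cv_select_lambda
#' @param score_method passed to [score_features()].
#' @return a `gene_ranking` data frame (see [bootstrap_rank()]).
#' @export
rank_candidates <- function(X, y, alpha = 0.5, k = 10, seed = 1L,
                            score_method = "linear") {
  cv <- cv_select_lambda(X, y, alpha = alpha, k = k, seed = seed)
  sc <- score_features(cv$fit, method = score_method)
  agg <- aggregate_genes(sc)
  ranking <- data.frame(entity = agg$entity, score = agg$score,
                        selection_frequency = rep(1, nrow(agg)),
                        score_variance = rep(0, nrow(agg)),
                        stringsAsFactors = FALSE)
  feats <- sc
  if (nrow(feats)) {
    feats <- data.frame(tag = feats$tag, entity = feats$entity,
                        platform = feats$platform, mean_score = feats$score,
                        selection_frequency = 1, direction = feats$direction,
                        stringsAsFactors = FALSE)
  } else {
    feats <- empty_feature_summary()
  }
  new_gene_ranking(ranking, feats, B = 1L, lambda = cv$lambda)
}

empty_feature_summary <- function() {
  data.frame(tag = character(0), entity = character(0),
             platform = character(0), mean_score = numeric(0),
             selection_frequency = numeric(0), direction = numeric(0),
             stringsAsFactors = FALSE)
}

new_gene_ranking <- function(ranking, features, B, lambda = NA_real_) {
  ranking$rank <- seq_len(nrow(ranking))
  attr(ranking, "features") <- features
  attr(ranking, "B") <- B
  attr(ranking, "lambda") <- lambda
  class(ranking) <- c("gene_ranking", "data.frame")
  ranking
}

#' Bootstrap rank aggregation
#'
#' The complete data set is resampled with replacement `B` times (n of
#' n); on each resample the penalty is re-selected by k-fold CV, the
#' selected features are rank-scored, and the scores summed per entity.
#' The ranking reports, per entity, the mean score over all `B` resamples
#' (resamples where the entity was not selected contribute 0), the
#' selection frequency (fraction of resamples with a positive score), and
#' the score variance. Entities consistently selected across resamples
#' have high mean rank score and low variance. Order: mean score
#' descending, ties broken by higher selection frequency, then entity id.
#'
#' @inheritParams cv_select_lambda
#' @param B number of bootstrap resamples (>= 1).
#' @param score_method passed to [score_features()].
#' @return a `gene_ranking` data frame with columns `entity`, `score`,
#'   `selection_frequency`, `score_variance`, `rank`; attributes
#'   `features` (per-feature mean score, selection frequency, and modal
#'   direction sign) and `B`.
#' @export
bootstrap_rank <- function(X, y, alpha = 0.5, B = 100L, seed = 1L, k = 10,
                           score_method = "linear") {
  if (B < 1) stop("B must be >= 1")
  a <- align_xy(X, y)
  n <- length(a$y)
  ent_scores <- list()
  feat_score <- feat_sel <- feat_dir <- numeric(0)

  ann <- data.frame(tag = a$tags, entity = a$entity, platform = a$platform,
                    stringsAsFactors = FALSE)
  for (b in seq_len(B)) {
    idx <- with_seed(child_seed(seed, b), sample.int(n, n, replace = TRUE))
    core <- cv_core(a$x[idx, , drop = FALSE], a$y[idx], alpha = alpha, k = k,
                    grid = NULL, seed = child_seed(seed, 100000L + b),
                    tol = 1e-7, fold_tol = 1e-4, maxit = 100000L)
    beta <- core$beta
    names(beta) <- a$tags
    fit <- structure(list(alpha = alpha, lambda = core$lambda,
                          beta0 = core$beta0, beta = beta, features = ann,
                          converged = core$converged, niter = core$niter,
                          n = n, objective = NULL),
                     class = "enet_fit")
    sc <- score_features(fit, method = score_method)
    agg <- aggregate_genes(sc)
    v <- agg$score
    names(v) <- agg$entity
    ent_scores[[b]] <- v
    if (nrow(sc)) {
      add <- function(acc, key, val) {
        cur <- acc[key]
        cur[is.na(cur)] <- 0
        acc[key] <- cur + val
        acc
      }
      feat_score <- add(feat_score, sc$tag, sc$score)
      feat_sel <- add(feat_sel, sc$tag, 1)
      feat_dir <- add(feat_dir, sc$tag, sc$direction)
    }
  }

  entities <- sort(unique(a$entity))
  smat <- matrix(0, length(entities), B, dimnames = list(entities, NULL))
  for (b in seq_len(B)) {
    v <- ent_scores[[b]]
    if (length(v)) smat[names(v), b] <- v
  }
  mean_score <- rowMeans(smat)
  sel_freq <- rowMeans(smat > 0)
  score_var <- if (B > 1) apply(smat, 1, stats::var) else rep(0, length(entities))

  keep <- mean_score > 0
  ranking <- data.frame(entity = entities[keep],
                        score = mean_score[keep],
                        selection_frequency = sel_freq[keep],
                        score_variance = score_var[keep],
                        stringsAsFactors = FALSE)
  ord <- order(-ranking$score, -ranking$selection_frequency, ranking$entity)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL

  if (length(feat_score)) {
    tags <- names(feat_score)
    at <- match(tags, a$tags)
    feats <- data.frame(tag = tags, entity = a$entity[at],
                        platform = a$platform[at],
                        mean_score = unname(feat_score) / B,
                        selection_frequency = unname(feat_sel) / B,
                        direction = sign(unname(feat_dir)),
                        stringsAsFactors = FALSE)
    feats <- feats[order(-feats$mean_score, feats$tag), , drop = FALSE]
    rownames(feats) <- NULL
  } else {
    feats <- empty_feature_summary()
  }
  new_gene_ranking(ranking, feats, B = as.integer(B))
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("<gene_ranking: %d entities, B=%d resamples>\n",
              nrow(x), attr(x, "B")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}
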