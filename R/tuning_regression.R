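#' Pairwise activity correlations during a BCI session
#'
#' Pearson correlation matrix of the ΔF/F traces. Constant traces get NA
#' rows/columns with a warning.
#'
#' @param session A [session_record()].
#' @return Symmetric neurons x neurons correlation matrix with unit diagonal.
#' @export
pairwise_correlations <- function(session) {
  h <- session$dff
  if (nrow(h) < 2L) stop("need at least 2 neurons")
  sds <- apply(h, 1L, stats::sd)
  C <- suppressWarnings(stats::cor(t(h)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant trace(s): correlation undefined")
    C[sds == 0, ] <- NA_real_
    C[, sds == 0] <- NA_real_
  }
  diag(C)[sds > 0] <- 1
  C
}

## Sum over the defined target responses of group g of x_j * w[j, g].
## Row-less helper shared by the regressor builders.
target_weighted_sum <- function(x, w, target_mask, g) {
  j <- which(target_mask[, g])
  wj <- w[j, g]
  ok <- is.finite(wj)
  if (!any(ok)) return(0)
  xv <- x[j[ok]]
  if (anyNA(xv)) return(NA_real_)
  sum(xv * wj[ok])
}

#' Correlation regressor
#'
#' For each non-target neuron i and group g, the PS-response-weighted sum of
#' the Pearson correlations between i and the target neurons of g:
#' `A_rho[i, g] = sum_j C[i, j] * W[j, g]` over targets j with a defined PS
#' response. Targets without a defined response are excluded (weighting by
#' response already removes non-responding targets).
#'
#' @param C Pairwise correlation matrix.
#' @param ps A [ps_response()].
#' @param masks A [classify_neurons()] result.
#' @return Neurons x groups matrix, defined on non-target entries.
#' @export
correlation_regressor <- function(C, ps, masks) {
  n <- nrow(C); G <- ncol(masks$target)
  out <- matrix(NA_real_, n, G)
  for (g in seq_len(G)) {
    i_idx <- which(masks$nontarget[, g])
    for (i in i_idx)
      out[i, g] <- target_weighted_sum(C[i, ], ps$w_ps, masks$target, g)
  }
  out
}

#' Change-in-correlation regressor
#'
#' Across-day difference of the correlation regressor,
#' `sum_j (C_b[i, j] W_b[j, g] - C_a[i, j] W_a[j, g])` over the targets of
#' each group, defined for non-target neurons.
#'
#' @param C_a,C_b Correlation matrices for the two sessions.
#' @param ps_a,ps_b [ps_response()] objects for the two sessions.
#' @param masks Cross-day [classify_neurons()] masks.
#' @return Neurons x groups matrix.
#' @export
delta_correlation_regressor <- function(C_a, C_b, ps_a, ps_b, masks) {
  correlation_regressor(C_b, ps_b, masks) -
    correlation_regressor(C_a, ps_a, masks)
}

tuning_components <- function(mode) {
  base <- c("pre", "early", "late", "rew")
  switch(mode, base4 = base, full8 = c(base, paste0("d_", base)),
         stop("mode must be 'base4' or 'full8'"))
}

#' Build the task-tuning regressor table
#'
#' Constructs one row per defined (non-target neuron i, group g) pair and one
#' column per tuning regressor `Y_i * X_g`, where `Y_i` ranges over 1 and the
#' components of i's task-tuning vector, `X_g = sum_j X_j W[j, g]` over the
#' targets of g weighted by their PS responses, and `X` ranges over 1 and the
#' tuning components. The (Y=1, X=1) combination is the summed target
#' response itself and is appended as the `control` column rather than a
#' tuning column, giving 24 tuning columns in `base4` mode (4 + 4 + 16) and
#' 80 in `full8` mode (8 + 8 + 64). Rows whose neuron lacks a needed tuning
#' component are dropped (count reported via message).
#'
#' @param tuning A `task_tuning` table ([tuning_and_delta()]).
#' @param ps A [ps_response()] supplying the target weights.
#' @param masks A [classify_neurons()] result.
#' @param mode `"base4"` (mean tuning only) or `"full8"` (tuning plus
#'   learning slopes).
#' @param weight_matrix Optional neurons x groups matrix overriding
#'   `ps$w_ps` as the target weighting (e.g. uniform weights for model
#'   networks).
#' @param control Optional per-group control column overriding the summed
#'   target response (e.g. the across-day change in target response for
#'   ΔW fits).
#' @return A data.frame of class `regressor_table` with columns `i`, `g`,
#'   the tuning columns, and `control`; attribute `tuning_cols` names the
#'   tuning columns.
#' @export
build_tuning_regressors <- function(tuning, ps, masks,
                                    mode = c("base4", "full8"),
                                    weight_matrix = NULL, control = NULL) {
  mode <- match.arg(mode)
  w <- if (is.null(weight_matrix)) ps$w_ps else weight_matrix
  build_regressors_generic(tuning, tuning_components(mode), w, masks,
                           control, mode)
}

## Core regressor construction over an arbitrary component set; shared by
## the data pipeline (4/8-dim tuning) and the circuit models (2-epoch
## tuning).
build_regressors_generic <- function(tuning, comps, w, masks,
                                     control = NULL, mode = "custom",
                                     include_control = TRUE) {
  G <- ncol(masks$target)
  tun <- as.data.frame(tuning)

  # PS-response-weighted group tuning X_g for X = 1 and each component
  xg <- matrix(NA_real_, G, length(comps) + 1L,
               dimnames = list(NULL, c("1", comps)))
  for (g in seq_len(G)) {
    xg[g, "1"] <- target_weighted_sum(rep(1, nrow(tun)), w, masks$target, g)
    for (x in comps)
      xg[g, x] <- target_weighted_sum(tun[[x]], w, masks$target, g)
  }

  idx <- which(masks$nontarget, arr.ind = TRUE)
  i <- idx[, 1]; g <- idx[, 2]
  y_mat <- cbind(`1` = rep(1, length(i)),
                 as.matrix(tun[i, comps, drop = FALSE]))
  combos <- expand.grid(y = c("1", comps), x = c("1", comps),
                        stringsAsFactors = FALSE)
  combos <- combos[!(combos$y == "1" & combos$x == "1"), , drop = FALSE]
  cols <- lapply(seq_len(nrow(combos)), function(k)
    y_mat[, combos$y[k]] * xg[g, combos$x[k]])
  names(cols) <- sprintf("nt_%s.tg_%s", combos$y, combos$x)
  tab <- data.frame(i = i, g = g, cols, check.names = FALSE)
  if (include_control)
    tab$control <- if (is.null(control)) xg[g, "1"] else control[g]

  keep <- stats::complete.cases(tab)
  if (any(!keep))
    message(sum(!keep), " row(s) dropped for missing tuning or weights")
  tab <- tab[keep, , drop = FALSE]
  attr(tab, "tuning_cols") <- names(cols)
  attr(tab, "mode") <- mode
  class(tab) <- c("regressor_table", "data.frame")
  tab
}

#' Write a regressor table to long-form CSV
#' @param table A `regressor_table`.
#' @param path Output path.
#' @export
write_regressors_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Cross-validated lasso fit of connectivity on tuning regressors
#'
#' Fits a lasso multivariate linear regression of a causal-connectivity (or
#' Δcausal-connectivity) response on the regressor columns, with the L1
#' penalty selected by 10-fold cross-validation: the penalty grid is 50
#' log-spaced values spanning `[1e-4 * lambda_max, lambda_max]` (with
#' `lambda_max` the smallest penalty that zeroes all slopes), and the chosen
#' penalty minimizes the mean out-of-fold squared error. Predictors are
#' z-scored before fitting; coefficients are reported in
#' standardized-predictor units (see [coef.mlr_fit()] for the raw scale).
#' Held-out prediction quality is the Pearson correlation between the
#' out-of-fold predictions and the response.
#'
#' @param y Response vector (e.g. W or ΔW values of the retained rows).
#' @param X Numeric matrix or `regressor_table` of predictors (the `i`/`g`
#'   key columns of a regressor table are ignored).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param fold_by Optional grouping vector (e.g. session id per row); rows
#'   sharing a group are assigned to the same fold to avoid leakage.
#' @param n_lambda Grid size (default 50).
#' @param lambda Optional fixed penalty: skips cross-validation and fits at
#'   this value (out-of-fold quantities are then NA).
#' @return An object of class `mlr_fit`.
#' @export
fit_lasso_cv <- function(y, X, folds = 10, seed = 1, fold_by = NULL,
                         n_lambda = 50, lambda = NULL) {
  if (inherits(X, "regressor_table") || is.data.frame(X)) {
    X <- as.matrix(as.data.frame(X)[setdiff(colnames(X), c("i", "g"))])
  }
  storage.mode(X) <- "double"
  n <- length(y)
  if (nrow(X) != n) stop("X and y sizes differ")
  if (n < folds) stop("fewer rows than folds")
  if (n < 10 * ncol(X))
    warning("fewer than 10 rows per column; fit may be unstable")
  mu <- colMeans(X); sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) stop("zero-variance predictor column(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sds, "/")

  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
  if (lambda_max == 0) {
    # response carries no linear signal (e.g. constant y): null model
    beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    return(structure(list(coefficients = beta, intercept = mean(y),
                          lambda = 0, lambda_grid = 0, cvm = NA,
                          foldid = NULL, oof_pred = NULL,
                          holdout_cor = NA_real_,
                          scaling = list(mu = mu, sd = sds), y = y,
                          seed = seed), class = "mlr_fit"))
  }

  if (!is.null(lambda)) {
    # fixed penalty: no cross-validation
    if (lambda >= lambda_max) {
      beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
      return(structure(list(coefficients = beta, intercept = mean(y),
                            lambda = lambda, lambda_grid = lambda, cvm = NA,
                            foldid = NULL, oof_pred = NULL,
                            holdout_cor = NA_real_,
                            scaling = list(mu = mu, sd = sds), y = y,
                            seed = seed), class = "mlr_fit"))
    }
    grid <- exp(seq(log(lambda_max), log(lambda), length.out = n_lambda))
    fit <- glmnet::glmnet(Xs, y, alpha = 1, lambda = grid,
                          standardize = FALSE, thresh = 1e-12)
    beta <- as.numeric(fit$beta[, n_lambda])
    names(beta) <- colnames(X)
    return(structure(list(coefficients = beta,
                          intercept = fit$a0[[n_lambda]], lambda = lambda,
                          lambda_grid = grid, cvm = NA, foldid = NULL,
                          oof_pred = NULL, holdout_cor = NA_real_,
                          scaling = list(mu = mu, sd = sds), y = y,
                          seed = seed), class = "mlr_fit"))
  }

  grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4),
                  length.out = n_lambda))

  set.seed(seed)
  if (is.null(fold_by)) {
    foldid <- sample(rep_len(seq_len(folds), n))
  } else {
    groups <- unique(fold_by)
    gf <- sample(rep_len(seq_len(folds), length(groups)))
    foldid <- gf[match(fold_by, groups)]
  }

  oof <- matrix(NA_real_, n, n_lambda)
  for (f in seq_len(folds)) {
    hold <- foldid == f
    if (!any(hold) || all(hold)) next
    fit_f <- glmnet::glmnet(Xs[!hold, , drop = FALSE], y[!hold],
                            alpha = 1, lambda = grid, standardize = FALSE)
    oof[hold, ] <- stats::predict(fit_f, Xs[hold, , drop = FALSE], s = grid)
  }
  cvm <- colMeans((oof - y)^2, na.rm = TRUE)
  k <- which.min(cvm)
  fit <- glmnet::glmnet(Xs, y, alpha = 1, lambda = grid, standardize = FALSE)
  beta <- as.numeric(fit$beta[, k])
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, intercept = fit$a0[[k]],
                 lambda = grid[k], lambda_grid = grid, cvm = cvm,
                 foldid = foldid, oof_pred = oof[, k],
                 holdout_cor = suppressWarnings(stats::cor(oof[, k], y)),
                 scaling = list(mu = mu, sd = sds), y = y, seed = seed),
            class = "mlr_fit")
}

#' @export
print.mlr_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(
    "Lasso MLR fit: %d rows, %d predictors (%d nonzero at lambda = %.3g)\n",
    length(x$y), length(x$coefficients), nz, x$lambda))
  cat(sprintf("Held-out prediction correlation: %.3f\n", x$holdout_cor))
  invisible(x)
}

#' Coefficients of a lasso MLR fit
#'
#' @param object An `mlr_fit`.
#' @param scale `"standardized"` (default; per-SD units) or `"raw"`
#'   (back-transformed to the original predictor units).
#' @param ... Unused.
#' @export
coef.mlr_fit <- function(object, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  b <- object$coefficients
  if (scale == "raw") b <- b / object$scaling$sd
  b
}

#' @export
predict.mlr_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "regressor_table") || is.data.frame(newdata))
    newdata <- as.matrix(as.data.frame(newdata)[names(object$coefficients)])
  Xs <- sweep(sweep(newdata, 2L, object$scaling$mu, "-"), 2L,
              object$scaling$sd, "/")
  as.numeric(object$intercept + Xs %*% object$coefficients)
}

#' @export
summary.mlr_fit <- function(object, ...) {
  b <- object$coefficients
  out <- data.frame(term = names(b), coefficient = unname(b))
  out <- out[order(-abs(out$coefficient)), ]
  structure(list(table = out[out$coefficient != 0, , drop = FALSE],
                 lambda = object$lambda, holdout_cor = object$holdout_cor),
            class = "summary.mlr_fit")
}

#' @export
print.summary.mlr_fit <- function(x, ...) {
  cat(sprintf("Selected penalty: %.4g; held-out correlation: %.3f\n",
              x$lambda, x$holdout_cor))
  cat("Nonzero coefficients (standardized units):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' One-sided Wald test for a positive slope after regressing out controls
#'
#' Ordinary least squares of the response on an intercept, the control
#' column(s) and the focal regressor; the Wald statistic is the focal slope
#' divided by its standard error, with a one-sided p-value for slope > 0.
#' Used to ask whether a regressor carries signal beyond the summed target
#' response control.
#'
#' @param y Response vector.
#' @param focal Focal regressor vector.
#' @param controls Optional vector/matrix of control regressors.
#' @return List with `slope`, `se`, `statistic`, `p_value` (one-sided,
#'   positive alternative) and `n`.
#' @export
wald_positive_test <- function(y, focal, controls = NULL) {
  X <- cbind(1, controls, focal)
  ok <- stats::complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    d <- svd(X, nu = 0, nv = 0)$d
    stop("focal and control regressors are collinear (condition number ",
         format(max(d) / max(min(d), .Machine$double.eps), digits = 3), ")")
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtx_inv[ncol(X), ncol(X)])
  slope <- fit$coefficients[ncol(X)]
  tval <- slope / se
  list(slope = unname(slope), se = se, statistic = unname(tval),
       p_value = stats::pt(tval, df, lower.tail = FALSE), n = length(y))
}

#' Per-column Wald scan of a regressor table
#'
#' Fits, for each tuning column in turn, an OLS model containing the
#' intercept, the control column and that single regressor, and reports the
#' slope and one-sided positive Wald p-value. Mirrors single-regressor fits
#' used to assess raw associations.
#'
#' @param y Response vector aligned with the table rows.
#' @param table A `regressor_table`.
#' @return Data.frame with columns `term`, `slope`, `p_value`, in table
#'   column order.
#' @export
single_regressor_scan <- function(y, table) {
  cols <- attr(table, "tuning_cols")
  ctrl <- table$control
  out <- lapply(cols, function(cl) {
    w <- wald_positive_test(y, table[[cl]], ctrl)
    data.frame(term = cl, slope = w$slope, p_value = w$p_value)
  })
  do.call(rbind, out)
}
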