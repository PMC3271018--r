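#' Sparse (lasso) regression of behavior on causal connection strengths
#'
#' L1-penalized linear regression of a behavioral measure on per-subject
#' directed connection strengths, with the penalty chosen by k-fold
#' cross-validation (minimum CV error rule, seeded fold assignment).
#' Predictors are standardized internally; coefficients of connections that
#' do not contribute are exactly zero, and the selected set is reported in
#' decreasing order of standardized coefficient magnitude.
#'
#' Additional covariates (e.g. participant age, to check that connectivity
#' outcompetes demographics) enter simply as extra columns of `X`; they
#' compete for selection on the same footing as the connections.
#'
#' @param X numeric matrix, subjects x connections (columns named by edge)
#' @param y behavioral vector (reaction time or accuracy)
#' @param folds number of CV folds (default 5); must not exceed n
#' @param seed seed for the fold assignment
#' @param alpha elastic-net mixing parameter; 1 (default) = pure lasso
#' @param lambda optional fixed penalty; skips cross-validation
#' @return a `sparse_fit`: list with `coefficients` (named, zeros kept),
#'   `intercept`, `selected_edges` (ordered by importance), `lambda`,
#'   `r_squared` (in-sample), `r_squared_cv`, `mse` (in-sample,
#'   standardized-y scale), `mse_cv`, `folds`, `seed`
#' @export
sparse_regression <- function(X, y, folds = 5, seed = 1, alpha = 1,
                              lambda = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stopf("length(y) must equal nrow(X)")
  if (!all(is.finite(y)) || !all(is.finite(X))) {
    stopf("X and y must be finite")
  }
  if (sd(y) < 1e-12) stopf("constant response: regression undefined")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (n < ncol(X)) {
    warnf("fewer subjects (%d) than predictors (%d)", n, ncol(X))
  }
  # standardized response so that MSE is on the standardized scale
  ys <- (y - mean(y)) / sd(y)
  if (is.null(lambda)) {
    if (n < folds) stopf("need at least as many subjects as folds")
    foldid <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
    cv <- glmnet::cv.glmnet(X, ys, alpha = alpha, foldid = foldid,
                            standardize = TRUE)
    lambda <- cv$lambda.min
    mse_cv <- min(cv$cvm)
  } else {
    mse_cv <- NA_real_
    folds <- NA_integer_
  }
  fit <- glmnet::glmnet(X, ys, alpha = alpha, lambda = lambda,
                        standardize = TRUE, thresh = 1e-12)
  beta <- as.numeric(coef(fit))[-1]
  names(beta) <- colnames(X)
  intercept <- as.numeric(coef(fit))[1]
  pred <- intercept + drop(X %*% beta)
  mse <- mean((ys - pred)^2)
  r2 <- max(0, 1 - mse / mean((ys - mean(ys))^2))
  r2_cv <- if (is.na(mse_cv)) NA_real_ else max(0, 1 - mse_cv / var(ys))
  sds <- apply(X, 2, sd)
  importance <- abs(beta) * sds
  sel <- names(beta)[beta != 0]
  sel <- sel[order(importance[sel], decreasing = TRUE)]
  structure(list(coefficients = beta, intercept = intercept,
                 selected_edges = sel, lambda = lambda,
                 r_squared = r2, r_squared_cv = r2_cv, mse = mse,
                 mse_cv = mse_cv, folds = folds,
                 seed = seed, alpha = alpha,
                 y_center = mean(y), y_scale = sd(y),
                 edge_names = colnames(X)),
            class = "sparse_fit")
}

#' @export
print.sparse_fit <- function(x, ...) {
  cat(sprintf("<sparse_fit> lambda = %.4g, R^2 = %.3f, MSE = %.3f\n",
              x$lambda, x$r_squared, x$mse))
  if (length(x$selected_edges) > 0) {
    cat("selected (by importance):",
        paste(x$selected_edges, collapse = ", "), "\n")
  } else {
    cat("no connections selected\n")
  }
  invisible(x)
}

#' Predict behavior from a sparse fit
#'
#' Linear prediction with the stored coefficients; the internal response
#' standardization is undone so predictions are on the original behavioral
#' scale.
#'
#' @param object a `sparse_fit`
#' @param X_new matrix with the training connection columns (matched by
#'   name)
#' @param ... unused
#' @return numeric prediction vector
#' @export
predict.sparse_fit <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new))) colnames(X_new) <- object$edge_names
  if (!identical(colnames(X_new), object$edge_names)) {
    if (!all(object$edge_names %in% colnames(X_new))) {
      stopf("X_new is missing training connection columns")
    }
    X_new <- X_new[, object$edge_names, drop = FALSE]
  }
  std <- object$intercept + drop(X_new %*% object$coefficients)
  object$y_center + object$y_scale * std
}

#' @rdname predict.sparse_fit
#' @export
predict_behavior <- function(object, X_new, ...) {
  predict.sparse_fit(object, X_new, ...)
}

#' Side-by-side report of sparse-fit quality for two groups
#'
#' @param fitA,fitB `sparse_fit`s on disjoint groups over the same edge set
#' @param labels group labels for the report
#' @return data.frame: group, r_squared, r_squared_cv, mse, mse_cv,
#'   n_selected, selected; attribute `better_predicted` names the group
#'   with the higher in-sample R^2
#' @export
compare_model_fit <- function(fitA, fitB, labels = c("A", "B")) {
  stopifnot(inherits(fitA, "sparse_fit"), inherits(fitB, "sparse_fit"))
  if (!identical(fitA$edge_names, fitB$edge_names)) {
    stopf("fits use different edge sets")
  }
  out <- data.frame(
    group = labels,
    r_squared = c(fitA$r_squared, fitB$r_squared),
    r_squared_cv = c(fitA$r_squared_cv, fitB$r_squared_cv),
    mse = c(fitA$mse, fitB$mse),
    mse_cv = c(fitA$mse_cv, fitB$mse_cv),
    n_selected = c(length(fitA$selected_edges), length(fitB$selected_edges)),
    selected = c(paste(fitA$selected_edges, collapse = ","),
                 paste(fitB$selected_edges, collapse = ",")))
  attr(out, "better_predicted") <- labels[which.max(out$r_squared)]
  out
}
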