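# Partial least squares (PLS1, NIPALS with X-deflation) and the validation
# statistics of the modelling workflow: calibration R2/RMSEc, leave-one-out
# Q2cv/RMSEcv, external Q2ext/RMSEp (Q2F1 convention), per-LV explained
# variance, and loading/score exports for mechanistic interpretation.

# Internal NIPALS PLS1 on matrices that are ALREADY centered and scaled.
# Returns weights W, X-loadings P, y-loadings q, scores T, projection
# weights Wstar = W (P'W)^-1 (built incrementally), and the p x A matrix B
# whose column a holds the regression vector using the first a LVs.
.nipals_pls1 <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite values in X or y")
  if (A < 1L || A > min(n - 1L, p)) stop("n_lv out of range for this data")
  W <- P <- Wstar <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  B <- matrix(0, p, A)
  b <- numeric(p)
  Xa <- X
  ya <- y
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("n_lv exceeds the rank of X (degenerate component ", a, ")")
    w <- w / nw
    tt <- Xa %*% w
    tsq <- sum(tt^2)
    pp <- crossprod(Xa, tt) / tsq
    qq <- sum(ya * tt) / tsq
    Xa <- Xa - tcrossprod(tt, pp)
    ya <- ya - qq * tt
    W[, a] <- w
    P[, a] <- pp
    q[a] <- qq
    Tm[, a] <- tt
    ws <- w
    if (a > 1L) {
      for (j in seq_len(a - 1L)) ws <- ws - sum(P[, j] * w) * Wstar[, j]
    }
    Wstar[, a] <- ws
    b <- b + qq * ws
    B[, a] <- b
  }
  list(W = W, P = P, q = q, scores = Tm, Wstar = Wstar, B = B)
}

#' Fit a PLS1 regression model
#'
#' NIPALS partial least squares with a single response and X-deflation.
#' Input descriptors and response are autoscaled internally (mean 0, sd 1,
#' n-1 denominator); the stored scaling makes predictions reproducible from
#' the coefficient vector alone, on the original response scale.
#'
#' @param X Numeric matrix or data frame of descriptors (rows = compounds).
#' @param y Numeric response (here: adsorption energies, kcal/mol).
#' @param n_lv Number of latent vectors A (1 <= A <= min(n - 1, p)).
#' @return Object of class `pls_model`: scaling parameters, weights `W`,
#'   loadings `P`, y-loadings `q`, training scores, projection weights,
#'   `coefficients` (autoscaled space, for `n_lv` LVs), original-scale
#'   `coefficients_original` and `intercept`, per-LV explained X/y variance
#'   (percent), fitted values, residuals, `r2` and `rmse_c`.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' y <- X %*% c(1, -1, 0.5, 0) + 2
#' m <- fit_pls(X, y, n_lv = 4)
#' m$r2  # 1 within numerical error
#' @export
fit_pls <- function(X, y, n_lv) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in X or y")
  }
  sx <- autoscale(X)
  ym <- mean(y)
  ysd <- sqrt(sum((y - ym)^2) / (length(y) - 1L))
  if (ysd == 0) stop("response has zero variance")
  ys <- (y - ym) / ysd
  fit <- .nipals_pls1(sx$x, ys, n_lv)
  ssx <- sum(sx$x^2)
  ssy <- sum(ys^2)
  ev_x <- 100 * colSums(fit$P^2) * colSums(fit$scores^2) / ssx
  ev_y <- 100 * fit$q^2 * colSums(fit$scores^2) / ssy
  coef_sc <- fit$B[, n_lv]
  coef_orig <- coef_sc * ysd / sx$scale
  intercept <- ym - sum(coef_orig * sx$center)
  fitted <- ym + ysd * as.vector(sx$x %*% coef_sc)
  resid <- y - fitted
  press <- sum(resid^2)
  tss <- sum((y - ym)^2)
  model <- list(
    n_lv = n_lv,
    selected_descriptors = colnames(X),
    x_center = sx$center, x_scale = sx$scale,
    y_center = ym, y_scale = ysd,
    W = fit$W, P = fit$P, q = fit$q,
    scores = fit$scores, Wstar = fit$Wstar,
    coefficients = coef_sc,
    coefficients_original = coef_orig,
    intercept = intercept,
    explained_x_variance = ev_x,
    explained_y_variance = ev_y,
    fitted = fitted, residuals = resid,
    r2 = 1 - press / tss,
    rmse_c = sqrt(press / length(y))
  )
  class(model) <- "pls_model"
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS1 model:", length(x$selected_descriptors), "descriptors (",
      paste(x$selected_descriptors, collapse = ", "), "),",
      x$n_lv, "latent vectors\n")
  cat(sprintf("  R2 = %.4f, RMSEc = %.4f\n", x$r2, x$rmse_c))
  cat("  explained X variance (%):",
      paste(sprintf("%.2f", x$explained_x_variance), collapse = " + "), "\n")
  cat("  explained y variance (%):",
      paste(sprintf("%.2f", x$explained_y_variance), collapse = " + "), "\n")
  invisible(x)
}

#' Predict adsorption energies for new compounds
#'
#' Applies the stored autoscaling and regression vector; returns predictions
#' on the original response scale (kcal/mol).
#'
#' @param object A `pls_model`.
#' @param newdata Matrix or data frame containing (at least) the model's
#'   descriptor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  nd <- if (is.null(dim(newdata))) {
    matrix(newdata, 1L, dimnames = list(NULL, object$selected_descriptors))
  } else as.matrix(newdata)
  if (!is.null(colnames(nd))) {
    miss <- setdiff(object$selected_descriptors, colnames(nd))
    if (length(miss)) {
      stop("newdata is missing descriptor column(s): ",
           paste(miss, collapse = ", "))
    }
    nd <- nd[, object$selected_descriptors, drop = FALSE]
  } else if (ncol(nd) != length(object$selected_descriptors)) {
    stop("newdata has ", ncol(nd), " columns; model expects ",
         length(object$selected_descriptors))
  }
  xs <- apply_scaling(nd, object$x_center, object$x_scale)
  object$y_center + object$y_scale * as.vector(xs %*% object$coefficients)
}

#' Project new compounds onto the model's latent vectors
#'
#' Scores for compounds not used in fitting, computed by projection with the
#' stored weights (never by refitting).
#'
#' @param model A `pls_model`.
#' @param newdata Matrix/data frame with the model's descriptor columns.
#' @return n x n_lv score matrix.
#' @export
project_scores <- function(model, newdata) {
  nd <- as.matrix(newdata)
  if (!is.null(colnames(nd))) {
    nd <- nd[, model$selected_descriptors, drop = FALSE]
  }
  xs <- apply_scaling(nd, model$x_center, model$x_scale)
  xs %*% model$Wstar
}

# Internal: PRESS for every LV count 1..A_max by the leave-one-out loop,
# rescaling inside each fold.  Returns a matrix of held-out predictions
# (n x A_max) on the original y scale.  The fold scaling is inlined (same
# elementwise arithmetic as autoscale(), so results are identical to a
# naive per-fold refit) to keep the GA fitness loop fast.
.loo_predictions <- function(X, y, A_max) {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- n - 1L
  pred <- matrix(NA_real_, n, A_max)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    ctr <- colMeans(Xi)
    xc <- Xi - rep(ctr, each = m)
    sds <- sqrt(colSums(xc^2) / (m - 1L))
    if (any(sds == 0)) {
      stop("LOO fold ", i, ": zero-variance column(s): ",
           paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
    }
    yi <- y[-i]
    ym <- mean(yi)
    ysd <- sqrt(sum((yi - ym)^2) / (m - 1L))
    fit <- .nipals_pls1(xc / rep(sds, each = m), (yi - ym) / ysd, A_max)
    xq <- matrix((X[i, ] - ctr) / sds, 1L)
    for (a in seq_len(A_max)) {  # per-column products match predict() exactly
      pred[i, a] <- ym + ysd * as.vector(xq %*% fit$B[, a])
    }
  }
  pred
}

#' Leave-one-out cross-validation of a PLS fit
#'
#' Refits the model n times, each time excluding one compound (autoscaling
#' statistics are recomputed inside every fold), and predicts the excluded
#' compound.  `q2_cv = 1 - PRESS / TSS` with TSS about the full-training
#' mean; `rmse_cv = sqrt(PRESS / n)`.
#'
#' @inheritParams fit_pls
#' @return List with `q2_cv`, `rmse_cv`, `press` and the held-out
#'   `predictions`.
#' @export
loo_cv <- function(X, y, n_lv) {
  y <- as.numeric(y)
  if (length(y) < 3L) stop("leave-one-out needs at least 3 compounds")
  pred <- .loo_predictions(X, y, n_lv)[, n_lv]
  press <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  list(q2_cv = 1 - press / tss,
       rmse_cv = sqrt(press / length(y)),
       press = press,
       predictions = pred)
}

#' Choose the number of latent vectors by cross-validation
#'
#' Returns the LV count in `1..max_lv` minimizing the leave-one-out RMSEcv;
#' ties go to the smaller count.
#'
#' @inheritParams fit_pls
#' @param max_lv Largest LV count to consider (<= min(n - 2, p)).
#' @return Integer LV count.
#' @export
select_n_lvs <- function(X, y, max_lv) {
  y <- as.numeric(y)
  pred <- .loo_predictions(X, y, max_lv)
  press <- colSums((y - pred)^2)
  which.min(press)  # first minimum = fewest LVs
}

#' External validation of a fitted model
#'
#' Predicts an independent validation set and reports the external
#' predictive coefficient `q2_ext` (Q2F1 convention: the denominator is the
#' sum of squares of the validation responses about the TRAINING mean) and
#' the root-mean-square error of prediction `rmse_p`.
#'
#' @param model A `pls_model`.
#' @param X_val,y_val Validation descriptors and observed energies.
#' @return List with `q2_ext`, `rmse_p` and the `predictions`.
#' @export
external_validation <- function(model, X_val, y_val) {
  y_val <- as.numeric(y_val)
  if (!length(y_val)) stop("empty validation set")
  pred <- predict(model, X_val)
  press <- sum((y_val - pred)^2)
  denom <- sum((y_val - model$y_center)^2)
  list(q2_ext = 1 - press / denom,
       rmse_p = sqrt(press / length(y_val)),
       predictions = pred)
}

#' Per-LV explained variance of a fitted model
#'
#' Percentage of the autoscaled X (resp. y) sum of squares captured by each
#' latent vector's rank-one reconstruction.  Stored at fit time; this
#' accessor returns both blocks side by side.
#'
#' @param model A `pls_model`.
#' @return `data.frame` with columns `lv`, `x_pct`, `y_pct`.
#' @export
explained_variance <- function(model) {
  data.frame(lv = seq_len(model$n_lv),
             x_pct = model$explained_x_variance,
             y_pct = model$explained_y_variance)
}

#' Assemble the model's validation report
#'
#' Bundles the calibration, cross-validation and external-validation
#' statistics the OECD-style validation of the model reports.
#'
#' @param model A fitted `pls_model`.
#' @param X,y Training descriptors and energies (for the LOO pass).
#' @param X_val,y_val External validation set.
#' @return Object of class `validation_report` with fields `r2`, `q2_cv`,
#'   `q2_ext`, `rmse_c`, `rmse_cv`, `rmse_p`.
#' @export
validation_report <- function(model, X, y, X_val, y_val) {
  cv <- loo_cv(X, y, model$n_lv)
  ext <- external_validation(model, X_val, y_val)
  rep <- list(r2 = model$r2, q2_cv = cv$q2_cv, q2_ext = ext$q2_ext,
              rmse_c = model$rmse_c, rmse_cv = cv$rmse_cv,
              rmse_p = ext$rmse_p)
  if (rep$q2_cv > rep$r2) {
    warning("q2_cv exceeds r2; the fit may be ill-posed")
  }
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("R2     = %.4f   RMSEc  = %.4f\n", x$r2, x$rmse_c))
  cat(sprintf("Q2cv   = %.4f   RMSEcv = %.4f\n", x$q2_cv, x$rmse_cv))
  cat(sprintf("Q2ext  = %.4f   RMSEp  = %.4f\n", x$q2_ext, x$rmse_p))
  invisible(x)
}

#' Loading and score tables for mechanistic interpretation
#'
#' Exports per-LV loading values of each selected descriptor and per-compound
#' scores.  Validation-set scores are obtained by projection onto the fitted
#' latent vectors, never by refitting.
#'
#' @param model A `pls_model`.
#' @param X_val Optional validation descriptors to project.
#' @return List of two data frames: `loadings` (descriptor x LV) and
#'   `scores` (compound x LV with a `set` column).
#' @export
export_interpretation <- function(model, X_val = NULL) {
  A <- model$n_lv
  load_df <- data.frame(descriptor = model$selected_descriptors,
                        model$P[, seq_len(A), drop = FALSE])
  colnames(load_df)[-1L] <- paste0("LV", seq_len(A))
  sc <- model$scores
  sets <- rep("training", nrow(sc))
  if (!is.null(X_val)) {
    sv <- project_scores(model, X_val)
    sc <- rbind(sc, sv)
    sets <- c(sets, rep("validation", nrow(sv)))
  }
  score_df <- data.frame(set = sets, sc)
  colnames(score_df)[-1L] <- paste0("LV", seq_len(A))
  list(loadings = load_df, scores = score_df)
}

#' Serialize a PLS model to JSON
#'
#' Writes scaling parameters, the coefficient vector in model-equation form
#' (intercept plus one term per descriptor, original scale), loadings, LV
#' count and explained variances.
#'
#' @param model A `pls_model`.
#' @param path Output path.
#' @param seed Optional seed(s) to record alongside the model.
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path, seed = NULL) {
  out <- list(
    n_lv = model$n_lv,
    selected_descriptors = model$selected_descriptors,
    scaling = list(x_center = as.list(model$x_center),
                   x_scale = as.list(model$x_scale),
                   y_center = model$y_center, y_scale = model$y_scale),
    equation = c(list(intercept = model$intercept),
                 as.list(stats::setNames(model$coefficients_original,
                                         model$selected_descriptors))),
    coefficients_autoscaled = as.list(stats::setNames(
      model$coefficients, model$selected_descriptors)),
    loadings = as.data.frame(model$P),
    explained_x_variance = model$explained_x_variance,
    explained_y_variance = model$explained_y_variance,
    seed = seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
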