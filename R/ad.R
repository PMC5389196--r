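# Leverage-based applicability domain.  Leverage is computed in the
# autoscaled space of the model's selected descriptors (query rows scaled
# with the TRAINING statistics, no intercept column), so the critical value
# 3(p + 1)/n with p = 4 descriptors and n = 24 training compounds equals the
# conventional 0.625.

#' Critical leverage
#'
#' `h* = 3 (p + 1) / n`, the conventional warning leverage with `p`
#' descriptors and `n` training compounds.  With 4 descriptors and 24
#' training compounds, `h* = 0.625`.
#'
#' @param p Number of model descriptors (>= 1).
#' @param n Number of training compounds (> p).
#' @return The critical leverage.
#' @examples
#' critical_leverage(4, 24)  # 0.625
#' @export
critical_leverage <- function(p, n) {
  if (p < 1L) stop("p must be >= 1")
  if (n <= p) stop("n must exceed p")
  3 * (p + 1) / n
}

#' Leverage of query compounds
#'
#' `h = x' (X'X)^-1 x` for each query row, computed with a numerically
#' stable solve of the cross-product system (no explicit inverse).  `X` is
#' the autoscaled training matrix; query rows must be scaled with the same
#' (training) statistics.
#'
#' @param X_train Autoscaled training descriptor matrix (n x p).
#' @param X_query Scaled query rows (m x p, or a single vector).
#' @return Numeric vector of leverages (length m).
#' @export
leverage <- function(X_train, X_query) {
  X_train <- as.matrix(X_train)
  Xq <- if (is.null(dim(X_query))) matrix(X_query, 1L) else as.matrix(X_query)
  xtx <- crossprod(X_train)
  sol <- tryCatch(solve(xtx, t(Xq)),
                  error = function(e) {
                    stop("X'X is singular; the selected descriptors are ",
                         "collinear on the training set", call. = FALSE)
                  })
  rowSums(Xq * t(sol))
}

#' Insubria (leverage vs prediction) table and AD summary
#'
#' For every congener: its leverage relative to the training set in the
#' model's autoscaled descriptor space, its predicted adsorption energy, its
#' set membership, and an in/out-of-domain flag against the critical
#' leverage `h* = 3(p + 1)/n`.  The table is the data behind an Insubria
#' plot (x = leverage, y = predicted energy, vertical line at h*), used to
#' judge whether predictions for compounds without reference energies are
#' interpolations.
#'
#' @param model A fitted `pls_model`.
#' @param split A `ks_split` with `training`, `validation` and `prediction`
#'   index sets.
#' @param table The full descriptor table (one row per congener).
#' @return List with `results` (data frame: `congener_index`, `name`,
#'   `set_label`, `leverage`, `predicted_E_ads`, `in_domain`) and `summary`
#'   (class `ad_summary`: `h_star`, `n_out_of_domain`, `pct_out_of_domain`,
#'   `n_total`).
#' @export
insubria_table <- function(model, split, table) {
  desc <- model$selected_descriptors
  X_all <- as.matrix(table[, desc, drop = FALSE])
  Xs <- apply_scaling(X_all, model$x_center, model$x_scale)
  Xtr <- Xs[split$training, , drop = FALSE]
  h <- leverage(Xtr, Xs)
  pred <- predict(model, X_all)
  h_star <- critical_leverage(length(desc), length(split$training))
  set_label <- rep("prediction", nrow(table))
  set_label[split$training] <- "training"
  set_label[split$validation] <- "validation"
  res <- data.frame(congener_index = table$index,
                    name = table$name,
                    set_label = set_label,
                    leverage = h,
                    predicted_E_ads = pred,
                    in_domain = h <= h_star,
                    stringsAsFactors = FALSE)
  list(results = res,
       summary = ad_summary(sum(!res$in_domain), nrow(res), h_star))
}

#' Applicability-domain summary
#'
#' @param n_out Number of out-of-domain congeners.
#' @param n_total Total number of congeners assessed.
#' @param h_star The critical leverage used.
#' @return Object of class `ad_summary` with the out-of-domain percentage
#'   `pct_out_of_domain = 100 * n_out / n_total`.
#' @export
ad_summary <- function(n_out, n_total, h_star) {
  structure(list(h_star = h_star,
                 n_out_of_domain = as.integer(n_out),
                 n_total = as.integer(n_total),
                 pct_out_of_domain = 100 * n_out / n_total),
            class = "ad_summary")
}

#' @export
print.ad_summary <- function(x, ...) {
  cat(sprintf("AD summary: h* = %.4g; %d of %d congeners (%.2f%%) out of domain\n",
              x$h_star, x$n_out_of_domain, x$n_total, x$pct_out_of_domain))
  invisible(x)
}
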