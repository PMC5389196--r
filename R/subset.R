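# Representative-subset selection: autoscaling, the Kennard-Stone maximin
# sampler, and the deterministic training/validation split of the selection.

#' Autoscale a numeric matrix
#'
#' Column-wise centering and scaling to unit standard deviation (the standard
#' chemometric preprocessing).  The standard-deviation denominator is n - 1
#' by default (`ddof = 1`).
#'
#' @param x Numeric matrix (>= 2 rows).
#' @param ddof Delta degrees of freedom of the sd denominator (0 or 1).
#' @return List with elements `x` (the scaled matrix), `center` (column
#'   means), `scale` (column sds).
#' @examples
#' autoscale(cbind(a = c(1, 2, 3)))$x  # (-1, 0, 1)
#' @export
autoscale <- function(x, ddof = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("autoscaling needs at least 2 rows")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  denom <- nrow(x) - ddof
  sds <- sqrt(colSums(xc^2) / denom)
  bad <- which(sds == 0)
  if (length(bad)) {
    nms <- colnames(x)[bad]
    if (is.null(nms)) nms <- as.character(bad)
    stop("zero-variance column(s): ", paste(nms, collapse = ", "))
  }
  list(x = sweep(xc, 2L, sds, "/"), center = ctr, scale = sds)
}

#' Apply stored scaling parameters to new rows
#'
#' @param x Numeric matrix or vector (one row).
#' @param center,scale Column means and sds from [autoscale()].
#' @return Scaled matrix.
#' @export
apply_scaling <- function(x, center, scale) {
  x <- if (is.null(dim(x))) matrix(x, 1L) else as.matrix(x)
  sweep(sweep(x, 2L, center), 2L, scale, "/")
}

#' Kennard-Stone maximin selection
#'
#' Selects `k` well-spread rows of `x`: the first two picks are the pair at
#' maximal Euclidean distance, and each subsequent pick maximizes its minimal
#' distance to the rows already selected.  All ties are broken toward the
#' lowest row index, making the selection deterministic.
#'
#' @param x Numeric matrix (typically autoscaled descriptor space).
#' @param k Number of rows to select (2 <= k <= nrow(x)).
#' @return Integer vector of row indices, in selection order.
#' @examples
#' kennard_stone(cbind(c(0, 1, 10)), 2)  # rows 1 and 3
#' @export
kennard_stone <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= nrow(x)")
  d <- as.matrix(stats::dist(x))
  # farthest pair, lowest (i, j) on ties; scan column-major upper triangle
  best <- c(1L, 2L)
  bestd <- -Inf
  for (j in 2:n) {
    i <- which.max(d[1:(j - 1L), j])
    if (d[i, j] > bestd) {
      bestd <- d[i, j]
      best <- c(i, j)
    }
  }
  sel <- best
  mind <- pmin(d[, best[1L]], d[, best[2L]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)  # lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
  }
  as.integer(unname(sel))
}

#' Split a Kennard-Stone selection into training and validation sets
#'
#' Deterministic rule: every `step`-th compound of the selection order
#' (ranks `offset + 1, offset + 1 + step, ...`) goes to validation, the rest
#' to training.  With the defaults (32 selected, 8 validation, step 4,
#' offset 3) validation takes selection ranks 4, 8, ..., 32.
#'
#' @param selected Integer vector of selected indices in selection order.
#' @param n_val Number of validation compounds (< length(selected)).
#' @param step Spacing in selection rank; default `ceiling(length(selected) /
#'   n_val)`.
#' @param offset Rank offset of the first validation pick (default
#'   `step - 1`).
#' @return List with integer vectors `training` and `validation` (original
#'   indices, in selection order).
#' @export
split_train_validation <- function(selected, n_val,
                                   step = if (n_val > 0)
                                     ceiling(length(selected) / n_val) else 0L,
                                   offset = step - 1L) {
  n <- length(selected)
  if (n_val >= n) stop("n_val must be smaller than the number selected")
  if (n_val == 0L) {
    return(list(training = selected, validation = integer(0)))
  }
  ranks <- offset + 1L + step * (seq_len(n_val) - 1L)
  if (any(ranks > n)) stop("validation ranks exceed the selection size")
  list(training = selected[-ranks], validation = selected[ranks])
}

#' Select the calibration subset of a descriptor table
#'
#' End-to-end subset selection as used in the pipeline: autoscale the full
#' descriptor space (all descriptors, since selection precedes descriptor
#' selection in the workflow), run Kennard-Stone for `k` compounds, and split
#' them into training and validation sets; everything unselected becomes the
#' prediction set.
#'
#' @param table Descriptor table ([generate_descriptor_table()] or
#'   [read_descriptor_table()]).
#' @param k Total calibration compounds to select (default 32, i.e. about 2%
#'   of the 1,701 congeners).
#' @param n_val Of these, how many go to validation (default 8).
#' @param descriptors Character vector of descriptor columns defining the
#'   selection space (default: all descriptor columns).
#' @return Object of class `ks_split`: list with `training`, `validation`,
#'   `prediction` (row indices of `table`), `selection_order`, and `scaling`
#'   (`center`/`scale` of the selection space).
#' @export
select_subset <- function(table, k = 32L, n_val = 8L,
                          descriptors = descriptor_names(table)) {
  if (k < n_val + 2L) stop("k must be at least n_val + 2")
  X <- as.matrix(table[, descriptors, drop = FALSE])
  sc <- autoscale(X)
  sel <- kennard_stone(sc$x, k)
  sp <- split_train_validation(sel, n_val)
  structure(list(training = sp$training,
                 validation = sp$validation,
                 prediction = setdiff(seq_len(nrow(table)), sel),
                 selection_order = sel,
                 scaling = list(center = sc$center, scale = sc$scale)),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat("Kennard-Stone split:",
      length(x$training), "training /",
      length(x$validation), "validation /",
      length(x$prediction), "prediction\n")
  invisible(x)
}

#' Serialize a split to JSON
#'
#' @param split A `ks_split` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
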