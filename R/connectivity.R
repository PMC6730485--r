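# Functional-connectivity estimation and thresholding.

new_fc <- function(values, kind, segment = NA_character_, threshold = NULL) {
  structure(values, kind = kind, segment = segment, threshold = threshold,
            class = c("fnirs_fc", "matrix", "array"))
}

#' Pearson functional-connectivity matrix
#'
#' Pairwise Pearson correlation of the channel dHbO series over a recording
#' segment: the resting state, the task session (all trials including
#' inter-trial rests), or a custom sample window. A zero-variance channel
#' gets a zero row/column (with a warning) rather than NA.
#'
#' @param hemo an `fnirs_hemo`, or a plain numeric matrix (time x channels)
#'   when `segment` is `NULL` or an index vector.
#' @param segment `"resting"`, `"task"`, `NULL` (all samples) or an integer
#'   vector of sample indices.
#' @return A symmetric `fnirs_fc` matrix of kind `"r"` with unit diagonal.
#' @export
fc_matrix <- function(hemo, segment = c("task", "resting")) {
  if (inherits(hemo, "fnirs_hemo")) {
    x <- hemo$hbo
    if (is.character(segment)) {
      segment <- match.arg(segment)
      sch <- hemo$schedule
      idx <- switch(segment,
                    resting = which(hemo$time < attr(sch, "rest_end")),
                    task = which(hemo$time >= attr(sch, "task_start") &
                                   hemo$time < attr(sch, "task_end")))
    } else if (is.null(segment)) {
      idx <- seq_len(nrow(x)); segment <- "all"
    } else {
      idx <- segment; segment <- "custom"
    }
  } else {
    x <- as.matrix(hemo)
    idx <- if (is.null(segment) || is.character(segment)) seq_len(nrow(x)) else segment
    segment <- if (is.character(segment)) "all" else "custom"
  }
  if (length(idx) < 30L) {
    stop("segment must contain at least 30 samples", call. = FALSE)
  }
  if (ncol(x) < 2L) stop("at least 2 channels required", call. = FALSE)
  seg <- x[idx, , drop = FALSE]
  sds <- apply(seg, 2, sd)
  zero <- sds == 0
  r <- matrix(0, ncol(x), ncol(x))
  if (any(!zero)) {
    r[!zero, !zero] <- cor(seg[, !zero, drop = FALSE])
  }
  if (any(zero)) {
    warning(sprintf("zero-variance channel(s) %s: row/column set to 0",
                    paste(which(zero), collapse = ", ")))
  }
  diag(r) <- 1
  dimnames(r) <- list(channel_labels(ncol(x)), channel_labels(ncol(x)))
  new_fc(r, kind = "r", segment = segment)
}

#' Fisher r-to-z transformation of a connectivity matrix
#'
#' Applies `z = atanh(r)` element-wise to the off-diagonal entries (r is
#' clipped to +/-(1 - 1e-7) first); the diagonal is set to zero. Correlation
#' values are not additive, so group averaging is done on this scale.
#'
#' @param m an `fnirs_fc` of kind `"r"`.
#' @return An `fnirs_fc` of kind `"z"`.
#' @export
fisher_z <- function(m) {
  check_kind(m, "r")
  r <- pmin(pmax(unclass(m), -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  new_fc(z, kind = "z", segment = attr(m, "segment"))
}

check_kind <- function(m, kind) {
  if (!inherits(m, "fnirs_fc") || !identical(attr(m, "kind"), kind)) {
    stop(sprintf("input must be an fnirs_fc matrix of kind \"%s\"", kind),
         call. = FALSE)
  }
  invisible(m)
}

#' Binarize a connectivity matrix at a fixed correlation threshold
#'
#' Edge (i, j) is present iff `r(i, j) > threshold` (signed r, i != j). The
#' study's displayed binary matrices use threshold 0.8.
#'
#' @param m an `fnirs_fc` of kind `"r"`.
#' @param threshold correlation cutoff in (-1, 1).
#' @return An `fnirs_fc` of kind `"binary"` with zero diagonal; the threshold
#'   provenance is kept in the `threshold` attribute.
#' @export
binarize_fixed <- function(m, threshold = 0.8) {
  check_kind(m, "r")
  if (threshold <= -1 || threshold >= 1) {
    stop("`threshold` must lie in (-1, 1)", call. = FALSE)
  }
  a <- (unclass(m) > threshold) * 1
  diag(a) <- 0
  a <- pmax(a, t(a)) # symmetry guard (input is symmetric already)
  new_fc(a, kind = "binary", segment = attr(m, "segment"),
         threshold = list(mode = "fixed", value = threshold))
}

#' Binarize a connectivity matrix at a proportional sparsity level
#'
#' Retains the `round(s * N(N-1)/2)` strongest off-diagonal entries by
#' signed r value as edges. Ties are broken deterministically by channel
#' index order (row, then column, of the upper triangle).
#'
#' @param m an `fnirs_fc` of kind `"r"`.
#' @param sparsity fraction of possible edges to retain, in (0, 1\].
#' @return An `fnirs_fc` of kind `"binary"`.
#' @export
binarize_sparsity <- function(m, sparsity) {
  check_kind(m, "r")
  if (!(sparsity > 0 && sparsity <= 1)) {
    stop("`sparsity` must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  vals <- unclass(m)[ut]
  k <- round(sparsity * n * (n - 1) / 2)
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  a <- matrix(0, n, n, dimnames = dimnames(m))
  a[ut[keep, , drop = FALSE]] <- 1
  a <- a + t(a)
  new_fc(a, kind = "binary", segment = attr(m, "segment"),
         threshold = list(mode = "sparsity", value = sparsity, n_edges = k))
}

#' Group-average connectivity matrix
#'
#' Averages subject-level r matrices on the Fisher-z scale
#' (`tanh(mean(atanh(r)))`), since correlations are not additive, and
#' returns an r-kind matrix.
#'
#' @param matrices list of `fnirs_fc` matrices of kind `"r"`, all of the
#'   same dimension.
#' @return An `fnirs_fc` of kind `"r"`.
#' @export
fc_group_average <- function(matrices) {
  if (length(matrices) == 0L) stop("empty matrix collection", call. = FALSE)
  dims <- vapply(matrices, nrow, 1L)
  if (any(dims != dims[1])) stop("matrices differ in dimension", call. = FALSE)
  zs <- lapply(matrices, function(m) unclass(fisher_z(m)))
  zbar <- Reduce(`+`, zs) / length(zs)
  r <- tanh(zbar)
  diag(r) <- 1
  dimnames(r) <- dimnames(matrices[[1]])
  new_fc(r, kind = "r", segment = attr(matrices[[1]], "segment"))
}

#' Mean off-diagonal Fisher z of a connectivity matrix
#'
#' The scalar connectivity-strength summary used for subject-level group
#' comparisons: the mean of `atanh(r)` over the upper triangle.
#'
#' @param m an `fnirs_fc` of kind `"r"`.
#' @return A single number.
#' @export
mean_fisher_z <- function(m) {
  mean(upper_tri_values(unclass(fisher_z(m))))
}

#' @export
print.fnirs_fc <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("fNIRS connectivity matrix (%d x %d, kind = %s, segment = %s%s)\n",
              nrow(x), ncol(x), attr(x, "kind"), attr(x, "segment"),
              if (is.null(thr)) "" else
                sprintf(", %s threshold %g", thr$mode, thr$value)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))],
        digits = 3)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
plot.fnirs_fc <- function(x, ...) {
  n <- nrow(x)
  pal <- if (identical(attr(x, "kind"), "binary")) c("white", "black") else
    colorRampPalette(c("navy", "white", "firebrick"))(64)
  zlim <- if (identical(attr(x, "kind"), "binary")) c(0, 1) else
    c(-1, 1) * max(abs(unclass(x)))
  image(seq_len(n), seq_len(n), t(unclass(x))[, n:1], col = pal, zlim = zlim,
        xlab = "channel", ylab = "channel", axes = FALSE,
        main = sprintf("connectivity (%s)", attr(x, "kind")), ...)
  axis(1, at = seq_len(n), cex.axis = 0.6)
  axis(2, at = seq_len(n), labels = n:1, cex.axis = 0.6)
  invisible(x)
}
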