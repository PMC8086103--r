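# The CpG-by-sample methylation matrix container with a declared value scale.
# The scale (beta or m) is always declared explicitly, never inferred.

#' Construct a methylation matrix
#'
#' A CpG-by-sample grid of finite values with a declared scale. Rows are CpG
#' sites, columns are samples (the processed-matrix convention of public
#' array repositories).
#'
#' @param values Numeric matrix, CpG rows by sample columns, all finite.
#' @param scale `"beta"` (values in `[0, 1]`) or `"m"` (unbounded).
#' @param cpg_ids,sample_ids Unique identifiers; default to dimnames.
#' @return A `methylation_matrix`: the matrix with row/column names and a
#'   `scale` attribute.
#' @export
methylation_matrix <- function(values, scale = c("beta", "m"),
                               cpg_ids = rownames(values),
                               sample_ids = colnames(values)) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` contains missing or non-finite entries; complete ",
         "matrices are required", call. = FALSE)
  }
  if (is.null(cpg_ids)) cpg_ids <- sprintf("cpg_%04d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(ncol(values)))
  cpg_ids <- as.character(cpg_ids)
  sample_ids <- as.character(sample_ids)
  if (length(cpg_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match the matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(cpg_ids)) {
    stop("duplicate CpG identifiers: ",
         paste(unique(cpg_ids[duplicated(cpg_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (scale == "beta" && (any(values < 0) || any(values > 1))) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "scale is 'beta' but value %.6g at CpG '%s', sample '%s' is outside [0, 1]",
      values[bad[1], bad[2]], cpg_ids[bad[1]], sample_ids[bad[2]]),
      call. = FALSE)
  }
  dimnames(values) <- list(cpg_ids, sample_ids)
  structure(values, scale = scale, class = c("methylation_matrix", "matrix"))
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d CpG x %d samples, scale = %s\n",
              nrow(x), ncol(x), meth_scale(x)))
  utils::str(unclass(x)[seq_len(min(3, nrow(x))), seq_len(min(4, ncol(x))),
                        drop = FALSE])
  invisible(x)
}

#' Declared value scale of a methylation matrix
#' @param x A `methylation_matrix`.
#' @return `"beta"` or `"m"`.
#' @export
meth_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("not a methylation_matrix: no declared scale",
                       call. = FALSE)
  s
}

#' Convert a methylation matrix between the Beta and M scales
#'
#' @param x A `methylation_matrix`.
#' @param to Target scale, `"beta"` or `"m"`.
#' @param clamp_eps Clamp half-width used by [beta_to_m()] when going to the
#'   M scale.
#' @return A `methylation_matrix` on the requested scale (the identity
#'   conversion returns `x` unchanged).
#' @export
convert_scale <- function(x, to = c("beta", "m"), clamp_eps = 1e-6) {
  to <- match.arg(to)
  from <- meth_scale(x)
  if (from == to) return(x)
  v <- unclass(x)
  attr(v, "scale") <- NULL
  out <- if (to == "m") beta_to_m(v, clamp_eps = clamp_eps) else m_to_beta(v)
  methylation_matrix(out, scale = to, cpg_ids = rownames(x),
                     sample_ids = colnames(x))
}

.assert_scale <- function(x, scale, fn) {
  if (meth_scale(x) != scale) {
    stop(sprintf("%s() requires a matrix on the '%s' scale (got '%s'); ",
                 fn, scale, meth_scale(x)),
         "use convert_scale() first", call. = FALSE)
  }
  invisible(x)
}
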