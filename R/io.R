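# Delimited-text I/O for methylation matrices and sample metadata. Matrices
# follow the processed-file layout of public array repositories: header row
# of sample ids, first column the CpG identifier, tab- or comma-separated.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("file '", path, "' is empty", call. = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a CpG-by-sample methylation matrix from delimited text
#'
#' The delimiter (tab or comma) is auto-detected from the header line. The
#' first column holds CpG identifiers; the remaining columns are samples.
#' The value scale is never inferred from the data and must be declared.
#' Rows containing non-numeric or missing cells are rejected with the
#' offending CpG identifiers named; Beta-scale values are range-checked.
#'
#' @param path Path to a delimited text file.
#' @param scale Declared scale of the stored values, `"beta"` or `"m"`.
#' @return A [methylation_matrix()].
#' @export
read_matrix <- function(path, scale = c("beta", "m")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) {
    stop("malformed header in '", path,
         "': need a CpG id column plus at least one sample column",
         call. = FALSE)
  }
  cpg_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  bad_rows <- which(apply(is.na(vals), 1L, any))
  if (length(bad_rows) > 0L) {
    shown <- utils::head(cpg_ids[bad_rows], 5L)
    stop("non-numeric or missing cells in ", length(bad_rows),
         " row(s), e.g. CpG id(s): ", paste(shown, collapse = ", "),
         call. = FALSE)
  }
  methylation_matrix(vals, scale = scale, cpg_ids = cpg_ids,
                     sample_ids = sample_ids)
}

#' Write a methylation matrix as delimited text
#'
#' Values are written with 15 significant digits so a write/read round trip
#' is lossless well beyond 12 significant digits.
#'
#' @param x A [methylation_matrix()].
#' @param path Output path.
#' @param sep Field separator; defaults to tab (`.csv` paths get a comma).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, sep = NULL) {
  meth_scale(x)  # validates class
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("cpg_id", colnames(x)), collapse = sep), con)
  body <- apply(unclass(x), 1L, function(r)
    paste(sprintf("%.15g", r), collapse = sep))
  writeLines(paste(rownames(x), body, sep = sep), con)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Expects a CSV with columns `sample_id`, `group`, `age`, `sex`. The group
#' column must have exactly two levels; `sex` may be a 0/1 indicator or a
#' two-level label (mapped to 0/1 in sorted order). When a companion matrix
#' is supplied, sample ids must match it exactly.
#'
#' @param path Path to a CSV file.
#' @param matrix Optional companion [methylation_matrix()] to validate
#'   sample ids against.
#' @return A data frame with columns `sample_id`, `group` (factor, two
#'   levels), `age` (numeric), `sex` (0/1 numeric).
#' @export
read_metadata <- function(path, matrix = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "group", "age", "sex")
  missing_cols <- setdiff(needed, colnames(df))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  lev <- sort(unique(as.character(df$group)))
  if (length(lev) != 2L) {
    stop("`group` must have exactly two levels, found ", length(lev), ": ",
         paste(lev, collapse = ", "), call. = FALSE)
  }
  ref <- if ("Placebo" %in% lev) "Placebo" else lev[1L]
  df$group <- factor(df$group, levels = c(ref, setdiff(lev, ref)))
  df$age <- as.numeric(df$age)
  if (anyNA(df$age)) stop("`age` contains non-numeric values", call. = FALSE)
  if (is.character(df$sex) || is.factor(df$sex)) {
    sl <- sort(unique(as.character(df$sex)))
    if (length(sl) > 2L) {
      stop("`sex` must be binary, found levels: ",
           paste(sl, collapse = ", "), call. = FALSE)
    }
    df$sex <- as.numeric(factor(df$sex, levels = sl)) - 1
  }
  df$sex <- as.numeric(df$sex)
  if (anyNA(df$sex) || !all(df$sex %in% c(0, 1))) {
    stop("`sex` must be a 0/1 indicator or a two-level label", call. = FALSE)
  }
  if (!is.null(matrix)) {
    ids_m <- colnames(matrix)
    extra <- setdiff(df$sample_id, ids_m)
    miss <- setdiff(ids_m, df$sample_id)
    if (length(extra) || length(miss)) {
      stop("metadata/matrix sample-id mismatch; ",
           if (length(miss)) paste0("missing from metadata: ",
                                    paste(utils::head(miss, 5), collapse = ", "),
                                    "; ") else "",
           if (length(extra)) paste0("not in matrix: ",
                                     paste(utils::head(extra, 5), collapse = ", "))
           else "",
           call. = FALSE)
    }
    df <- df[match(ids_m, df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a sample-metadata table
#' @param metadata Data frame as returned by [read_metadata()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
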