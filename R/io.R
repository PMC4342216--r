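# Readers/writers for the tabular formats the pipeline touches, housekeeping
# normalization, heatmap row standardization.
#
# TSV dialect: tab-separated, UTF-8, '.' decimal separator, 'NA' missing
# token. Expression tables carry a header row and a leading probe-id column.

#' Read an expression matrix from TSV
#'
#' Validates shape strictly: rows must be rectangular, cells numeric (or
#' `NA`), identifiers unique. Errors name the offending line.
#'
#' @param path TSV file: header row of sample ids, first column probe ids.
#' @param orientation `"probes_by_samples"` (default) or
#'   `"samples_by_probes"` (the table is transposed after reading).
#' @return Numeric matrix, probes in rows, samples in columns.
#' @export
read_expression <- function(path,
                            orientation = c("probes_by_samples",
                                            "samples_by_probes")) {
  orientation <- match.arg(orientation)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop("ragged table: line ", which(nf != nf[1])[1],
         " has ", nf[nf != nf[1]][1], " fields, expected ", nf[1])
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = "NA")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated identifier '", ids[duplicated(ids)][1], "' at line ",
         which(duplicated(ids))[1] + 1L)
  vals <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1L,
                                      dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric cell '", as.matrix(vals)[bad[1, 1], bad[1, 2]],
         "' at line ", bad[1, 1] + 1L, ", column ",
         colnames(vals)[bad[1, 2]])
  m <- num
  rownames(m) <- ids
  if (orientation == "samples_by_probes") m <- t(m)
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: finite values round-trip losslessly (full
#' double precision).
#'
#' @param x Numeric matrix, probes in rows.
#' @param path Output file path.
#' @param id_column Header of the identifier column, default `"probe_id"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "probe_id") {
  x <- .as_expr_matrix(x)
  df <- data.frame(id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' CSV with columns `sample_id`, `grade` (1/2/3/unknown), optional `er`
#' (pos/neg/unknown) and optional survival columns `time`, `event` (exported
#' unchanged for external survival tools). Grade and ER codings are validated
#' at parse time.
#'
#' @param path CSV file path.
#' @return Data frame with character `sample_id`, `grade`, `er`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "grade") %in% names(df)))
    stop("labels file needs columns 'sample_id' and 'grade'")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  df$grade <- as.character(df$grade)
  df$grade[is.na(df$grade)] <- "unknown"
  bad <- setdiff(unique(df$grade), c("1", "2", "3", "unknown"))
  if (length(bad)) stop("invalid grade value(s): ", paste(bad, collapse = ", "))
  if ("er" %in% names(df)) {
    df$er <- as.character(df$er)
    df$er[is.na(df$er)] <- "unknown"
    bad <- setdiff(unique(df$er), c("pos", "neg", "unknown"))
    if (length(bad)) stop("invalid er value(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' Housekeeping normalization
#'
#' Subtracts, per sample, the mean log-scale value of the reference
#' (housekeeping) probes from every probe. After normalization the reference
#' probes average exactly zero in every sample.
#'
#' @param x Log-scale expression matrix (probes x samples).
#' @param reference_probe_ids Probe ids of the reference set; all must be
#'   present in `x`.
#' @return Normalized matrix, same shape as `x`.
#' @export
housekeeping_normalize <- function(x, reference_probe_ids) {
  x <- .as_expr_matrix(x)
  miss <- setdiff(reference_probe_ids, rownames(x))
  if (length(miss))
    stop("reference probe(s) absent: ", paste(miss, collapse = ", "))
  ref_mean <- colMeans(x[reference_probe_ids, , drop = FALSE], na.rm = TRUE)
  sweep(x, 2L, ref_mean, "-")
}

#' Select stable reference probes
#'
#' Ranks candidate housekeeping probes by expression stability — the
#' across-sample variance of their sample-centered values (per-sample column
#' means removed first, so that global per-sample shifts do not affect the
#' ranking) — and keeps the `k` most stable.
#'
#' @param x Expression matrix (probes x samples).
#' @param candidate_ids Candidate probe ids, all present in `x`.
#' @param k Number of references to keep, `k <= length(candidate_ids)`.
#' @return Character vector of `k` probe ids, most stable first.
#' @export
select_reference_probes <- function(x, candidate_ids, k) {
  x <- .as_expr_matrix(x)
  miss <- setdiff(candidate_ids, rownames(x))
  if (length(miss))
    stop("candidate probe(s) absent: ", paste(miss, collapse = ", "))
  if (k > length(candidate_ids))
    stop("k (", k, ") exceeds the number of candidates (",
         length(candidate_ids), ")")
  centered <- sweep(x, 2L, colMeans(x, na.rm = TRUE), "-")
  v <- apply(centered[candidate_ids, , drop = FALSE], 1L, stats::var,
             na.rm = TRUE)
  ord <- order(v, candidate_ids, method = "radix")
  candidate_ids[ord][seq_len(k)]
}

#' Row-standardize a matrix for heatmap display
#'
#' Centers every probe at mean 0 and scales it to standard deviation 1
#' (population SD, divisor n, so the displayed row has SD exactly 1).
#'
#' @param x Numeric matrix (probes x samples), every row with >= 2 distinct
#'   values.
#' @return Matrix of per-row z-scores.
#' @export
rowstandardize_for_heatmap <- function(x) {
  x <- .as_expr_matrix(x)
  mu <- rowMeans(x, na.rm = TRUE)
  cnt <- rowSums(!is.na(x))
  sdp <- sqrt(rowSums((x - mu)^2, na.rm = TRUE) / cnt)
  if (any(sdp == 0))
    stop("constant row(s): ",
         paste(utils::head(rownames(x)[sdp == 0], 5L), collapse = ", "))
  (x - mu) / sdp
}
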