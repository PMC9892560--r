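#' @importFrom stats median optim optimize pnorm p.adjust rnbinom rbinom rpois
#'   runif rnorm model.matrix setNames lm coef cor sd
#'   fisher.test var aggregate
#' @importFrom utils read.delim write.table head
NULL

FORMAT_HEADER <- "# nichefx format v1"

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

.write_tsv <- function(df, path, header = FORMAT_HEADER, col.names = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  invisible(path)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' The expected layout is one header row of sample ids, a first column
#' `gene_id`, and non-negative integer counts. Malformed cells are rejected
#' with row/column context rather than coerced.
#'
#' @param path Path to a tab-separated count file.
#' @return Integer matrix, genes as rows (rownames = gene ids), samples as
#'   columns.
#' @export
read_counts <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("count file needs a gene_id column plus >=1 sample")
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("NA count at gene ", gene_ids[idx[1]], ", sample ",
         colnames(m)[idx[2]])
  }
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative or non-integer count at gene ", gene_ids[bad[1, 1]],
         ", sample ", colnames(m)[bad[1, 2]])
  }
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  m
}

#' Write a count matrix to TSV
#'
#' Gene rows are sorted stably by gene id so output is reproducible
#' regardless of input order.
#'
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  counts <- counts[order(rownames(counts)), , drop = FALSE]
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  .write_tsv(df, path)
}

#' Read a sample-design table and align it to a count matrix
#'
#' The design must provide columns `sample_id`, `age` (young/aged), `time`
#' (T0/T21) and `batch`. Rows are reordered to match the columns of
#' `counts`; unknown factor levels or missing samples are errors.
#'
#' @param path Path to the design TSV.
#' @param counts Count matrix whose columns define the sample order
#'   (optional; when NULL the file order is kept).
#' @return Data frame with factor columns `age`, `time`, `batch`, one row
#'   per sample.
#' @export
read_design <- function(path, counts = NULL) {
  df <- .read_tsv(path)
  need <- c("sample_id", "age", "time", "batch")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("design missing columns: ", paste(miss, collapse = ", "))
  validate_design(df, counts)
}

#' Validate and align a sample design
#'
#' @param df Data frame with sample_id, age, time, batch.
#' @param counts Optional count matrix for column alignment.
#' @return The validated design, factors releveled (young/T0 reference).
#' @export
validate_design <- function(df, counts = NULL) {
  bad_age <- setdiff(unique(as.character(df$age)), c("young", "aged"))
  if (length(bad_age)) stop("unknown age level(s): ", paste(bad_age, collapse = ", "))
  bad_time <- setdiff(unique(as.character(df$time)), c("T0", "T21"))
  if (length(bad_time)) stop("unknown time level(s): ", paste(bad_time, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in design")
  df$age <- factor(df$age, levels = c("young", "aged"))
  df$time <- factor(df$time, levels = c("T0", "T21"))
  df$batch <- factor(df$batch)
  if (!is.null(counts)) {
    miss <- setdiff(colnames(counts), df$sample_id)
    if (length(miss)) stop("design missing sample(s): ", paste(miss, collapse = ", "))
    df <- df[match(colnames(counts), df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a sample design table
#' @param design Design data frame.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  .write_tsv(design, path)
}

#' Read a BED file of genomic intervals
#'
#' Coordinates are 0-based half-open as in the BED standard and are kept
#' that way internally. Columns beyond the sixth are retained under their
#' positional names (`V7`, ...); column 7 conventionally carries the
#' absolute summit position for peak files.
#'
#' @param path Path to a BED3/BED6(+) file.
#' @return Data frame with columns chrom, start, end and, when present,
#'   name, score, strand and extra columns.
#' @export
read_bed <- function(path) {
  df <- .read_tsv(path, header = FALSE)
  if (ncol(df) < 3) stop("BED needs >= 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad)) stop("invalid interval (start >= end) at line ", bad[1])
  if ("strand" %in% names(df)) {
    bads <- setdiff(unique(df$strand), c("+", "-", "."))
    if (length(bads)) stop("invalid strand value(s): ", paste(bads, collapse = ", "))
  }
  df
}

#' Write intervals as BED
#' @param intervals Data frame with chrom/start/end and optional
#'   name/score/strand plus extra columns.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  std <- c("chrom", "start", "end", "name", "score", "strand")
  keep <- c(intersect(std, names(intervals)),
            setdiff(names(intervals), std))
  .write_tsv(intervals[, keep, drop = FALSE], path, col.names = FALSE)
}

#' Read a per-CpG methylation table
#'
#' Input columns: chrom, pos (1-based), strand, context, count_methylated,
#' count_total — the coverage-file dialect emitted by bisulfite callers.
#' Positions are converted to 0-based on load (conversion noted once per
#' session).
#'
#' @param path Path to the methylation TSV.
#' @return Data frame with chrom, pos0 (0-based), strand, context,
#'   count_methylated, count_total.
#' @export
read_methylation <- function(path) {
  df <- .read_tsv(path)
  need <- c("chrom", "pos", "strand", "context", "count_methylated", "count_total")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("methylation table missing: ", paste(miss, collapse = ", "))
  bad <- which(df$count_methylated > df$count_total | df$count_methylated < 0)
  if (length(bad)) stop("count_methylated > count_total at line ", bad[1])
  if (any(df$pos < 1)) stop("methylation positions must be 1-based (>= 1)")
  if (!isTRUE(getOption("nichefx.meth_conversion_noted"))) {
    message("methylation positions converted 1-based -> 0-based on load")
    options(nichefx.meth_conversion_noted = TRUE)
  }
  data.frame(chrom = df$chrom, pos0 = as.integer(df$pos) - 1L,
             strand = df$strand, context = df$context,
             count_methylated = as.integer(df$count_methylated),
             count_total = as.integer(df$count_total),
             stringsAsFactors = FALSE)
}

#' Write a methylation track (0-based internal -> 1-based on disk)
#' @param track Data frame as returned by [read_methylation()].
#' @param path Output path.
#' @export
write_methylation <- function(track, path) {
  df <- data.frame(chrom = track$chrom, pos = track$pos0 + 1L,
                   strand = track$strand, context = track$context,
                   count_methylated = track$count_methylated,
                   count_total = track$count_total)
  .write_tsv(df, path)
}

#' Read a bedGraph coverage file
#' @param path Path to a bedGraph (chrom, start, end, value).
#' @return Data frame chrom/start/end/value, 0-based half-open.
#' @export
read_bedgraph <- function(path) {
  df <- .read_tsv(path, header = FALSE)
  if (ncol(df) != 4) stop("bedGraph needs exactly 4 columns")
  names(df) <- c("chrom", "start", "end", "value")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start >= df$end)) stop("invalid bedGraph interval (start >= end)")
  df
}

#' Read a MatrixMarket count matrix (interoperability)
#'
#' @param mtx_path Path to the .mtx file.
#' @param genes_path Path to a one-column file of gene ids (rows).
#' @param samples_path Path to a one-column file of sample ids (columns).
#' @return Integer matrix as from [read_counts()].
#' @export
read_counts_mtx <- function(mtx_path, genes_path, samples_path) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the Matrix package is required for MTX input")
  }
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(genes_path)
  colnames(m) <- readLines(samples_path)
  if (any(m < 0 | m != round(m))) stop("negative or non-integer values in MTX")
  storage.mode(m) <- "integer"
  m
}
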