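#' Construct a gain/normal/loss (GNL) copy-number table
#'
#' Discretized copy-number state per sample, in one of two modes:
#' segment mode (`sample, chrom, start, end, gnl`) as produced downstream of
#' SNP-array segmentation, or gene mode (gene x sample integer matrix) as
#' distributed for public cohorts. The 5-symbol alphabet is
#' -2 homozygous deletion, -1 loss, 0 neutral, +1 gain, +2 amplification.
#' Coordinates are 1-based inclusive throughout.
#'
#' @param segments data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `gnl` (segment mode), or `NULL`.
#' @param genes Integer matrix genes x samples (gene mode), or `NULL`.
#'   Exactly one of `segments`/`genes` must be given.
#' @return Object of class `gnl_table` with fields `mode` (`"segment"` or
#'   `"gene"`), `segments`, `genes`, `samples`.
#' @export
gnl_table <- function(segments = NULL, genes = NULL) {
  if (is.null(segments) == is.null(genes))
    stop("gnl_table: supply exactly one of 'segments' or 'genes'")
  if (!is.null(segments)) {
    segments <- as.data.frame(segments)
    need <- c("sample", "chrom", "start", "end", "gnl")
    if (!all(need %in% colnames(segments)))
      stop("gnl_table: segment table needs columns ", paste(need, collapse = ", "))
    segments$chrom <- as.character(segments$chrom)
    if (!all(segments$gnl %in% -2:2))
      stop("gnl_table: gnl values must be integers in -2..2")
    if (any(segments$end < segments$start))
      stop("gnl_table: segment end < start")
    # overlap check within each sample x chromosome
    spl <- split(segments, list(segments$sample, segments$chrom), drop = TRUE)
    for (s in spl) {
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stop(sprintf("gnl_table: overlapping segments for sample '%s' chrom %s",
                     s$sample[1], s$chrom[1]))
    }
    samples <- unique(segments$sample)
    return(structure(list(mode = "segment", segments = segments, genes = NULL,
                          samples = samples), class = "gnl_table"))
  }
  genes <- as.matrix(genes)
  if (is.null(rownames(genes)) || is.null(colnames(genes)))
    stop("gnl_table: gene matrix needs gene rownames and sample colnames")
  if (!all(genes[!is.na(genes)] %in% -2:2))
    stop("gnl_table: gnl values must be integers in -2..2")
  structure(list(mode = "gene", segments = NULL, genes = genes,
                 samples = colnames(genes)), class = "gnl_table")
}

#' @export
print.gnl_table <- function(x, ...) {
  if (x$mode == "segment")
    cat(sprintf("gnl_table [segment]: %d segments, %d samples\n",
                nrow(x$segments), length(x$samples)))
  else
    cat(sprintf("gnl_table [gene]: %d genes, %d samples\n",
                nrow(x$genes), length(x$samples)))
  invisible(x)
}

#' Read a GNL table from TSV
#'
#' Auto-detects the mode: a file whose header contains
#' `sample, chrom, start, end, gnl` is read as segments; otherwise it is
#' read as a gene x sample integer matrix (first column gene ids).
#'
#' @param path TSV path.
#' @return A [gnl_table()].
#' @export
read_gnl <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (all(c("sample", "chrom", "start", "end", "gnl") %in% header)) {
    seg <- utils::read.delim(path, na.strings = c("NA", ""))
    return(gnl_table(segments = seg))
  }
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  gnl_table(genes = m)
}

#' Write a GNL table to TSV
#' @param x A [gnl_table()].
#' @param path Output path.
#' @export
write_gnl <- function(x, path) {
  if (x$mode == "segment") {
    utils::write.table(x$segments[, c("sample", "chrom", "start", "end", "gnl")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  } else {
    df <- data.frame(gene = rownames(x$genes), x$genes, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }
  invisible(path)
}
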