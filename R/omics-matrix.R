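#' Construct an omics matrix
#'
#' The shared container for the three continuous data types handled by the
#' pipeline: log-scale expression intensities, normalized miRNA abundances
#' and DNA-methylation beta values. Features are rows, samples are columns.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique row and column names. Missing entries are explicit `NA`.
#' @param omic_kind One of `"mrna"`, `"mirna"`, `"methylation"`. Methylation
#'   values must lie in `[0, 1]`.
#' @param feature_annot Optional data.frame of per-feature annotation, one row
#'   per feature in the same order as `values`. Recognised columns:
#'   `chrom`, `start`, `end`, `arm` (labels such as `"1p"`, `"19q"`), and
#'   `cpg_island` (logical).
#'
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `omic_kind` and `feature_annot`.
#' @export
omics_matrix <- function(values, omic_kind = c("mrna", "mirna", "methylation"),
                         feature_annot = NULL) {
  omic_kind <- match.arg(omic_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("omics_matrix: 'values' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("omics_matrix: duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))])[1:3], collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("omics_matrix: duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))])[1:3], collapse = ", "))
  if (omic_kind == "methylation") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("omics_matrix: methylation beta outside [0,1] at feature '%s', sample '%s' (value %g)",
                   rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                   values[bad[1, 1], bad[1, 2]]))
  }
  if (!is.null(feature_annot)) {
    feature_annot <- as.data.frame(feature_annot)
    if (nrow(feature_annot) != nrow(values))
      stop("omics_matrix: feature_annot must have one row per feature")
    if (!is.null(feature_annot$arm)) {
      known <- arm_vocabulary()
      bad <- setdiff(unique(stats::na.omit(feature_annot$arm)), known)
      if (length(bad) > 0)
        stop("omics_matrix: unknown arm label(s): ", paste(bad, collapse = ", "))
    }
    rownames(feature_annot) <- rownames(values)
  }
  structure(list(values = values, omic_kind = omic_kind,
                 feature_annot = feature_annot),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples (%.1f%% NA)\n",
              x$omic_kind, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  if (!is.null(x$feature_annot))
    cat("  feature annotation columns:",
        paste(colnames(x$feature_annot), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

# Chromosome-arm label vocabulary: 39 autosomal arms (acrocentric p arms of
# 13/14/15/21/22 excluded from the autosomal 39 count convention but accepted
# here since the boundary table ships them) plus the X arms.
arm_vocabulary <- function() {
  ab <- arm_boundaries()
  ab$arm
}

#' Chromosome-arm boundary table (hg19)
#'
#' Arm start/end coordinates derived from the GRCh37 centromere gaps,
#' 1-based inclusive. Shipped as plain text with the package.
#'
#' @return data.frame with columns `chrom`, `arm`, `start`, `end`.
#' @export
arm_boundaries <- function() {
  path <- system.file("extdata", "arm_boundaries_hg19.tsv", package = "otsubtypes")
  if (path == "")  # during development before installation
    path <- file.path("inst", "extdata", "arm_boundaries_hg19.tsv")
  utils::read.delim(path, colClasses = c("character", "character", "numeric", "numeric"))
}

#' Read a feature-by-sample matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' `"NA"` and empty cells become `NA`. An optional sidecar annotation TSV
#' (same feature order or matched by a `feature_id` column) supplies
#' coordinates, arm labels and CpG-island flags.
#'
#' @param path Path to the matrix TSV.
#' @param omic_kind One of `"mrna"`, `"mirna"`, `"methylation"`.
#' @param annot_path Optional sidecar annotation TSV.
#' @return An [omics_matrix()].
#' @export
read_matrix <- function(path, omic_kind = c("mrna", "mirna", "methylation"),
                        annot_path = NULL) {
  omic_kind <- match.arg(omic_kind)
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                          colClasses = NA)
  if (ncol(df) < 2) stop("read_matrix: need a feature-id column plus >= 1 sample column")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("read_matrix: duplicate feature ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m) && !anyNA(df[, -1]))
      stop("read_matrix: non-numeric cells in ", path)
  }
  rownames(m) <- ids
  annot <- NULL
  if (!is.null(annot_path)) {
    annot <- utils::read.delim(annot_path, na.strings = c("NA", ""))
    if ("feature_id" %in% colnames(annot)) {
      rownames(annot) <- annot$feature_id
      annot <- annot[ids, setdiff(colnames(annot), "feature_id"), drop = FALSE]
    }
  }
  omics_matrix(m, omic_kind, feature_annot = annot)
}

#' Write an omics matrix to TSV
#'
#' Inverse of [read_matrix()]: first column `feature_id`, then one column per
#' sample; `NA` written as the literal token `NA`.
#'
#' @param x An [omics_matrix()] or a plain named matrix.
#' @param path Output path.
#' @export
write_matrix <- function(x, path) {
  m <- if (inherits(x, "omics_matrix")) x$values else x
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct a class partition
#'
#' Per-sample class labels, the unit exchanged between the per-omic
#' clustering stage and the integration stage. `NA` means the sample was not
#' classified at that molecular level.
#'
#' @param labels Named vector (sample id -> label); labels may be integer or
#'   character, `NA` allowed.
#' @return Named character vector of class `class_partition`.
#' @export
class_partition <- function(labels) {
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop("class_partition: labels must be named by sample id")
  if (anyDuplicated(names(labels)))
    stop("class_partition: duplicate sample ids")
  out <- as.character(labels)
  names(out) <- names(labels)
  class(out) <- "class_partition"
  out
}

#' @export
print.class_partition <- function(x, ...) {
  cat(sprintf("class_partition: %d samples, %d classes\n",
              length(x), length(setdiff(unique(unclass(x)), NA))))
  print(table(unclass(x), useNA = "ifany"))
  invisible(x)
}
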