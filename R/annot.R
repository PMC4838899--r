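#' Validate a sample annotation table
#'
#' Checks the clinical/technical annotation used downstream: overall survival
#' time in months (`os_time >= 0`), event indicator (`os_event` in 0/1), and
#' the flags consumed by contamination filtering and the radiotherapy
#' analysis. Missing optional columns are tolerated.
#'
#' @param annot data.frame with at least a `sample` column; recognised
#'   columns: `cohort`, `grade`, `histology`, `idh_status`, `codel_status`,
#'   `age`, `os_time`, `os_event`, `initial_radiotherapy`,
#'   `is_normal_control`.
#' @return The validated data.frame (invisibly classed `sample_annot`).
#' @export
sample_annot <- function(annot) {
  annot <- as.data.frame(annot)
  if (!"sample" %in% colnames(annot))
    stop("sample_annot: need a 'sample' column")
  if (anyDuplicated(annot$sample))
    stop("sample_annot: duplicate sample ids")
  if (!is.null(annot$os_time) && any(annot$os_time < 0, na.rm = TRUE))
    stop("sample_annot: os_time must be >= 0")
  if (!is.null(annot$os_event) &&
      !all(annot$os_event %in% c(0, 1, NA)))
    stop("sample_annot: os_event must be 0/1")
  if (is.null(annot$is_normal_control)) annot$is_normal_control <- FALSE
  class(annot) <- c("sample_annot", "data.frame")
  annot
}

#' Construct a gene set
#'
#' @param name Set name.
#' @param members Character vector of gene ids; duplicates removed.
#' @param source Free-text provenance tag.
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(name, members, source = "") {
  structure(list(name = name, members = unique(as.character(members)),
                 source = source), class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path GMT path.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("read_gmt: malformed line: ", substr(l, 1, 40))
    gene_set(f[1], f[-(1:2)], source = f[2])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used throughout to quantify recovery of planted subtype structure.
#' Samples with `NA` in either partition are dropped.
#'
#' @param a,b Label vectors (named vectors are matched by name; unnamed
#'   vectors are matched by position).
#' @return ARI in `[-1, 1]`; 1 means identical partitions up to relabelling.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b)) stop("adjusted_rand_index: length mismatch")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
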