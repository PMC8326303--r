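# Normalization for nearest-centroid classification: log2 transform and
# per-gene median centering with explicit reference construction. The
# reference-construction choice (a single pooled median versus per-cohort
# medians) is a first-class option because subtype calling is sensitive
# to the composition of the cohort used to build the reference.

#' Log2-transform an expression matrix
#'
#' Applies `log2(v + offset)` to every value and flags the matrix as
#' log2-scaled. A matrix already flagged log2 is returned unchanged with
#' a warning (idempotence guard).
#'
#' @param x an `expr_matrix`.
#' @param offset nonnegative pseudocount added before the log.
#' @return log2-scaled `expr_matrix`.
#' @export
log2_transform <- function(x, offset = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (offset < 0) stop("offset must be nonnegative")
  if (x$units == "log2") {
    warning("matrix already log2-scaled; returned unchanged")
    return(x)
  }
  v <- x$values
  if (any(v < 0, na.rm = TRUE)) stop("negative values cannot be log-transformed")
  if (any(v + offset <= 0, na.rm = TRUE))
    stop("log of zero: value + offset must be > 0")
  x$values <- log2(v + offset)
  x$units <- "log2"
  x
}

#' Median-center an expression matrix
#'
#' Subtracts from each gene the median of that gene over a reference
#' group of samples. With `reference_mode = "single"` the reference is
#' the pooled set of all samples (one median per gene); with
#' `"per_cohort"` each cohort is centered to its own per-gene medians.
#' Missing cells are excluded from median computation and preserved.
#'
#' @param x an `expr_matrix`.
#' @param reference_mode `"single"` (default) or `"per_cohort"`.
#' @param cohort optional per-sample cohort labels; defaults to
#'   `x$cohort`. Required for `per_cohort` mode.
#' @return centered `expr_matrix`.
#' @export
median_center <- function(x, reference_mode = c("single", "per_cohort"),
                          cohort = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  reference_mode <- match.arg(reference_mode)
  v <- x$values
  if (reference_mode == "single") {
    med <- apply(v, 1L, median, na.rm = TRUE)
    if (any(!is.finite(med))) {
      bad <- rownames(v)[!is.finite(med)]
      stop("gene(s) with all-missing values in reference group: ",
           paste(bad, collapse = ", "))
    }
    v <- sweep(v, 1L, med, "-")
  } else {
    if (is.null(cohort)) cohort <- x$cohort
    if (is.null(cohort) || length(cohort) != ncol(v) || anyNA(cohort))
      stop("per_cohort centering requires a cohort label for every sample")
    for (co in unique(cohort)) {
      idx <- which(cohort == co)
      med <- apply(v[, idx, drop = FALSE], 1L, median, na.rm = TRUE)
      if (any(!is.finite(med))) {
        bad <- rownames(v)[!is.finite(med)]
        stop("gene(s) with all-missing values in cohort '", co, "': ",
             paste(bad, collapse = ", "))
      }
      v[, idx] <- sweep(v[, idx, drop = FALSE], 1L, med, "-")
    }
  }
  x$values <- v
  x
}

#' Restrict an expression matrix to a signature's genes
#'
#' Matches gene symbols case-insensitively after trimming. Errors if the
#' fraction of signature genes found falls below `min_coverage`.
#'
#' @param x an `expr_matrix`.
#' @param signature a `gene_signature` or character vector of symbols.
#' @param min_coverage minimum fraction of signature genes that must be
#'   present (default 0.8).
#' @return `expr_matrix` restricted to the signature genes found (in
#'   signature order); attribute `"coverage_report"` lists `coverage`,
#'   `n_found`, `n_signature` and `missing_genes`.
#' @export
subset_to_signature <- function(x, signature, min_coverage = 0.8) {
  stopifnot(inherits(x, "expr_matrix"))
  if (min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must be in (0, 1]")
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else as.character(signature)
  key <- .norm_symbol(rownames(x$values))
  pos <- match(.norm_symbol(genes), key)
  found <- !is.na(pos)
  coverage <- mean(found)
  missing <- genes[!found]
  if (coverage < min_coverage)
    stop(sprintf("signature coverage %.2f below threshold %.2f; missing: %s",
                 coverage, min_coverage, paste(missing, collapse = ", ")))
  x$values <- x$values[pos[found], , drop = FALSE]
  attr(x, "coverage_report") <- list(coverage = coverage,
                                     n_found = sum(found),
                                     n_signature = length(genes),
                                     missing_genes = missing)
  x
}
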