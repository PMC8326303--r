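# Cross-scheme agreement: contingency of joint subtype calls with
# per-cell hypergeometric enrichment, and Euclidean distances between
# subtype centroids of both schemes in a shared z-scored gene space.

#' Cross-tabulate two subtype assignments
#'
#' @param assign_a,assign_b `subtype_assignment` data.frames (or any
#'   data.frames with `sample_id` and `class` columns) over the same
#'   samples; samples missing from either assignment are excluded and
#'   counted.
#' @param classes_a,classes_b optional class orderings for rows/columns
#'   (default: sorted observed classes).
#' @return object of class `contingency_result`: list with `counts`
#'   (matrix, scheme A rows x scheme B columns), `n` (jointly assigned
#'   samples) and `n_excluded`.
#' @export
cross_tabulate <- function(assign_a, assign_b,
                           classes_a = NULL, classes_b = NULL) {
  common <- intersect(assign_a$sample_id, assign_b$sample_id)
  if (length(common) == 0L) stop("assignments share no samples")
  n_excl <- length(unique(c(assign_a$sample_id, assign_b$sample_id))) -
    length(common)
  la <- assign_a$class[match(common, assign_a$sample_id)]
  lb <- assign_b$class[match(common, assign_b$sample_id)]
  if (is.null(classes_a)) classes_a <- sort(unique(la))
  if (is.null(classes_b)) classes_b <- sort(unique(lb))
  counts <- table(factor(la, levels = classes_a),
                  factor(lb, levels = classes_b))
  counts <- unclass(counts)
  dimnames(counts) <- list(classes_a, classes_b)
  structure(list(counts = counts, n = length(common), n_excluded = n_excl),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("Cross-scheme contingency (n = ", x$n, "):\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Per-cell enrichment of a contingency table
#'
#' For every (row class, column class) cell, tests whether the overlap is
#' larger than expected under independence given the margins: one-sided
#' hypergeometric upper-tail p for overlap at least as large as observed,
#' an odds ratio from the 2x2 collapse of the table (Haldane 0.5
#' correction when any collapsed cell is zero), and Benjamini-Hochberg
#' q-values across all cells.
#'
#' @param x a `contingency_result` or a plain count matrix.
#' @return data.frame with `class_a`, `class_b`, `count`, `expected`,
#'   `odds_ratio`, `p_hyper`, `q_bh`.
#' @export
pair_enrichment <- function(x) {
  counts <- if (inherits(x, "contingency_result")) x$counts else as.matrix(x)
  n <- sum(counts)
  if (n < 1) stop("contingency grand total must be >= 1")
  rs <- rowSums(counts); cs <- colSums(counts)
  out <- expand.grid(class_a = rownames(counts), class_b = colnames(counts),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$class_a, rownames(counts)),
                   match(out$class_b, colnames(counts))), ]
  rownames(out) <- NULL
  stat <- t(vapply(seq_len(nrow(out)), function(k) {
    a <- out$class_a[k]; b <- out$class_b[k]
    x11 <- counts[a, b]
    m <- rs[a]; kk <- cs[b]
    # P(X >= x11), X ~ Hypergeom(white = kk, black = n - kk, drawn = m)
    p <- phyper(x11 - 1, kk, n - kk, m, lower.tail = FALSE)
    x12 <- m - x11; x21 <- kk - x11; x22 <- n - m - kk + x11
    cells <- c(x11, x12, x21, x22)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    c(count = x11, expected = m * kk / n, odds_ratio = or, p_hyper = p)
  }, numeric(4)))
  out <- cbind(out, as.data.frame(stat))
  out$q_bh <- p.adjust(out$p_hyper, method = "BH")
  out
}

#' Pairwise distances between subtype centroids of two schemes
#'
#' Computes per-class centroids (per-gene mean over the class's samples)
#' in gene-wise z-scored space and the Euclidean distances between all
#' centroids of both schemes, plus, for each scheme-A class, the nearest
#' scheme-B class.
#'
#' @param x an `expr_matrix` providing the gene space (typically already
#'   subset to the union of the two signatures).
#' @param assign_a,assign_b `subtype_assignment` data.frames.
#' @param genes optional character vector restricting the gene space.
#' @return object of class `centroid_distances`: list with `distances`
#'   (symmetric matrix over all classes of both schemes), `nearest`
#'   (data.frame `class_a`, `nearest_b`, `distance`), `genes` used and
#'   `metric`.
#' @export
centroid_distance_matrix <- function(x, assign_a, assign_b, genes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(genes)) {
    pos <- match(.norm_symbol(genes), .norm_symbol(rownames(v)))
    pos <- pos[!is.na(pos)]
    if (length(pos) < 2L) stop("fewer than 2 gene-space genes found")
    v <- v[pos, , drop = FALSE]
  }
  common <- intersect(intersect(assign_a$sample_id, assign_b$sample_id),
                      colnames(v))
  if (length(common) == 0L) stop("no samples shared by matrix and assignments")
  v <- .zscore_rows(v[, common, drop = FALSE])
  la <- assign_a$class[match(common, assign_a$sample_id)]
  lb <- assign_b$class[match(common, assign_b$sample_id)]
  cls_a <- sort(unique(la)); cls_b <- sort(unique(lb))
  cent_of <- function(lab, cls) vapply(cls, function(cl) {
    idx <- lab == cl
    if (!any(idx)) stop("empty class: ", cl)
    rowMeans(v[, idx, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(v)))
  cents <- cbind(cent_of(la, cls_a), cent_of(lb, cls_b))
  colnames(cents) <- c(cls_a, cls_b)
  d <- as.matrix(dist(t(cents), method = "euclidean"))
  cross <- d[cls_a, cls_b, drop = FALSE]
  nearest <- data.frame(
    class_a = cls_a,
    nearest_b = cls_b[apply(cross, 1L, which.min)],
    distance = apply(cross, 1L, min),
    stringsAsFactors = FALSE)
  structure(list(distances = d, nearest = nearest,
                 genes = rownames(v), metric = "euclidean"),
            class = "centroid_distances")
}

#' @export
print.centroid_distances <- function(x, ...) {
  cat("Centroid distance matrix (", x$metric, ", ", length(x$genes),
      " genes):\n", sep = "")
  print(round(x$distances, 3))
  cat("Nearest cross-scheme classes:\n")
  print(x$nearest)
  invisible(x)
}
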