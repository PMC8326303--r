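# Nearest-centroid subtype assignment, used identically for both
# subtyping schemes: per-class reference profiles are trained from a
# labeled cohort, and each sample is assigned to the class whose centroid
# its signature-gene profile correlates with most strongly.

#' Train per-class centroids from a labeled cohort
#'
#' @param x an `expr_matrix`, already preprocessed and subset to the
#'   signature genes.
#' @param labels per-sample class labels (character/factor, length =
#'   number of samples, or named by sample id).
#' @param signature the `gene_signature` the centroids belong to; every
#'   signature class must appear in `labels` with at least 2 samples.
#' @param summary `"mean"` (default) or `"median"` per-gene summary.
#' @return object of class `centroid_model`: list with `signature`,
#'   `centroids` (genes x classes matrix), `summary`, `n_train`
#'   (samples per class).
#' @export
train_centroids <- function(x, labels, signature,
                            summary = c("mean", "median")) {
  stopifnot(inherits(x, "expr_matrix"), inherits(signature, "gene_signature"))
  summary <- match.arg(summary)
  labels <- .align_labels(labels, colnames(x$values))
  classes <- signature$classes
  missing_cls <- setdiff(classes, unique(labels))
  if (length(missing_cls))
    stop("class absent from labels: ", paste(missing_cls, collapse = ", "))
  n_train <- table(factor(labels, levels = classes))
  if (any(n_train < 2L))
    stop("every class needs at least 2 labeled samples")
  fun <- if (summary == "mean") function(m) rowMeans(m, na.rm = TRUE)
         else function(m) apply(m, 1L, median, na.rm = TRUE)
  cent <- vapply(classes, function(cl) {
    fun(x$values[, labels == cl, drop = FALSE])
  }, numeric(nrow(x$values)))
  rownames(cent) <- rownames(x$values)
  structure(list(signature = signature, centroids = cent,
                 summary = summary, n_train = as.integer(n_train)),
            class = "centroid_model")
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("Centroid model (", x$signature$name, "): ", nrow(x$centroids),
      " genes x ", ncol(x$centroids), " classes (", x$summary, ")\n", sep = "")
  invisible(x)
}

.align_labels <- function(labels, sample_ids) {
  labels <- if (is.factor(labels)) as.character(labels) else labels
  if (!is.null(names(labels))) {
    miss <- setdiff(sample_ids, names(labels))
    if (length(miss)) stop("labels missing for samples: ",
                           paste(head(miss, 5), collapse = ", "))
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("labels length does not match number of samples")
  }
  as.character(labels)
}

#' Assign samples to subtypes by nearest centroid
#'
#' Each sample's similarity to every class centroid is the correlation of
#' its signature-gene profile with the centroid over pairwise-complete
#' genes (Spearman by default, the rank-based convention of PAM50-style
#' classifiers). The assigned class is the argmax; ties are broken by the
#' signature's class-priority order (most aggressive class first), so
#' every sample receives a class.
#'
#' @param x an `expr_matrix` preprocessed identically to the centroid
#'   training matrix and covering (a subset of) the model's genes.
#' @param model a `centroid_model`.
#' @param similarity `"spearman"` (default) or `"pearson"`.
#' @return data.frame of class `subtype_assignment`: `sample_id`,
#'   `scheme`, `class` (assigned), one `score_<class>` column per class,
#'   and `confidence` (top score minus runner-up).
#' @export
assign_subtypes <- function(x, model, similarity = c("spearman", "pearson")) {
  stopifnot(inherits(x, "expr_matrix"), inherits(model, "centroid_model"))
  similarity <- match.arg(similarity)
  cent <- model$centroids
  pos <- match(.norm_symbol(rownames(cent)), .norm_symbol(rownames(x$values)))
  if (all(is.na(pos))) stop("no signature genes found in matrix")
  v <- x$values[pos[!is.na(pos)], , drop = FALSE]
  cent <- cent[!is.na(pos), , drop = FALSE]
  classes <- colnames(cent)
  scores <- matrix(NA_real_, ncol(v), length(classes),
                   dimnames = list(colnames(v), classes))
  for (i in seq_len(ncol(v))) {
    ok <- !is.na(v[, i])
    if (sum(ok) < 3L)
      stop("fewer than 3 shared signature genes for sample '",
           colnames(v)[i], "'")
    scores[i, ] <- suppressWarnings(
      cor(v[ok, i], cent[ok, , drop = FALSE], method = similarity))
  }
  if (anyNA(scores))
    stop("undefined similarity (constant profile) for sample(s): ",
         paste(rownames(scores)[apply(is.na(scores), 1L, any)], collapse = ", "))
  # priority order = signature class order; argmax with that tie-break
  prio <- match(classes, model$signature$classes)
  pick <- apply(scores, 1L, function(s) {
    top <- which(s == max(s))
    top[which.min(prio[top])]
  })
  sorted <- apply(scores, 1L, function(s) sort(s, decreasing = TRUE)[1:2])
  out <- data.frame(sample_id = colnames(v),
                    scheme = model$signature$name,
                    class = classes[pick],
                    stringsAsFactors = FALSE)
  for (cl in classes) out[[paste0("score_", cl)]] <- scores[, cl]
  out$confidence <- sorted[1L, ] - sorted[2L, ]
  class(out) <- c("subtype_assignment", "data.frame")
  out
}

#' Collapse externally produced 5-class PAM50 calls to the 3 retained classes
#'
#' The prostate adaptation of PAM50 retains only LumA, LumB and Basal.
#' When classification is done inside this package the HER2 and
#' Normal-like centroids are simply never used (3-centroid argmax); this
#' helper exists for importing externally produced 5-class calls. Labels
#' already in the retained set pass through; HER2/Normal-like calls are
#' remapped to the best retained class by their stored per-class scores.
#'
#' @param labels character vector of 5-class calls (`LumA`, `LumB`,
#'   `Basal`, `HER2`, `Normal-like`).
#' @param scores optional numeric matrix (samples x classes) of per-class
#'   similarity scores; required if any label must be remapped.
#' @return character vector of 3-class labels.
#' @export
collapse_pam50 <- function(labels, scores = NULL) {
  retained <- c("LumB", "LumA", "Basal")
  allowed <- c(retained, "HER2", "Normal-like")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), allowed)
  if (length(bad)) stop("unknown PAM50 label(s): ", paste(bad, collapse = ", "))
  need <- !(labels %in% retained)
  if (!any(need)) return(labels)
  if (is.null(scores) || !all(retained %in% colnames(scores)))
    stop("HER2/Normal-like labels require per-class scores over ",
         "LumA/LumB/Basal to collapse")
  for (i in which(need)) {
    s <- scores[i, retained]
    labels[i] <- retained[which.max(s)]
  }
  labels
}
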