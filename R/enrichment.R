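# Gene set enrichment: class-vs-rest gene ranking, the weighted
# running-sum enrichment score, a phenotype-permutation null with NES and
# BH FDR, and the luminal/basal marker separation index.

# Vectorized per-row mean and sample sd with NA handling (the ranking is
# recomputed for every phenotype permutation, so this is the hot path).
.row_mean_sd <- function(v) {
  n <- rowSums(!is.na(v))
  s <- rowSums(v, na.rm = TRUE)
  ss <- rowSums(v * v, na.rm = TRUE)
  mu <- s / n
  var <- pmax(ss - n * mu^2, 0) / pmax(n - 1, 1)
  list(mean = mu, sd = sqrt(var))
}

#' Rank genes for a class-vs-rest comparison
#'
#' Default metric is the signal-to-noise ratio
#' `(mu_target - mu_rest) / (sd_target + sd_rest)` with each class
#' standard deviation floored at `max(sd, 0.2 * |mu|, 1e-8)` (the GSEA
#' desktop convention, protecting near-constant genes); `"tstat"` is a
#' Welch t statistic. Genes are sorted by descending metric, ties broken
#' by gene symbol.
#'
#' @param x an `expr_matrix`.
#' @param labels per-sample class labels.
#' @param target_class the class ranked against the rest; both sides
#'   must have at least 3 samples.
#' @param metric `"snr"` (default) or `"tstat"`.
#' @return data.frame of class `ranked_genes` with columns `gene`,
#'   `metric`, ordered descending.
#' @export
rank_genes <- function(x, labels, target_class, metric = c("snr", "tstat")) {
  stopifnot(inherits(x, "expr_matrix"))
  metric <- match.arg(metric)
  labels <- .align_labels(labels, colnames(x$values))
  in_t <- labels == target_class
  if (sum(in_t) < 3L || sum(!in_t) < 3L)
    stop("target class and rest each need at least 3 samples")
  v <- x$values
  st1 <- .row_mean_sd(v[, in_t, drop = FALSE])
  st0 <- .row_mean_sd(v[, !in_t, drop = FALSE])
  m1 <- st1$mean; s1 <- st1$sd
  m0 <- st0$mean; s0 <- st0$sd
  if (metric == "snr") {
    s1 <- pmax(s1, 0.2 * abs(m1), 1e-8)
    s0 <- pmax(s0, 0.2 * abs(m0), 1e-8)
    met <- (m1 - m0) / (s1 + s0)
  } else {
    n1 <- sum(in_t); n0 <- sum(!in_t)
    se <- sqrt(pmax(s1, 1e-8)^2 / n1 + pmax(s0, 1e-8)^2 / n0)
    met <- (m1 - m0) / se
  }
  ord <- order(-met, rownames(v))
  out <- data.frame(gene = rownames(v)[ord], metric = met[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ranked_genes", "data.frame")
  out
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; genes in the set increment the running sum by
#' `|metric|^p` normalized over in-set hits, genes outside decrement by
#' `1/(N - N_hit)`. The enrichment score is the signed maximum deviation
#' from zero; the leading edge is the in-set genes at or before the
#' extremum (at or after it, for a negative score).
#'
#' @param ranked a `ranked_genes` data.frame (descending metric order).
#' @param gene_set character vector of member symbols.
#' @param weight_p exponent on `|metric|` for hit increments: 1 (GSEA
#'   standard, default) or 0 (unweighted Kolmogorov-Smirnov-like form).
#' @return list with `es`, `running_sum` (length N), `leading_edge`,
#'   `n_hits`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  genes <- ranked$gene
  n <- length(genes)
  hit <- .norm_symbol(genes) %in% .norm_symbol(gene_set)
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set has no genes in the ranked list")
  if (n_hit == n) stop("gene set covers every ranked gene")
  w <- abs(ranked$metric)^weight_p
  w[!hit] <- 0
  nr <- sum(w)
  if (nr == 0) {            # all in-set metrics zero: fall back to uniform
    w[hit] <- 1
    nr <- n_hit
  }
  # P_hit and P_miss accumulated separately (the textbook definition);
  # their difference is the running sum
  p_hit <- cumsum(ifelse(hit, w / nr, 0))
  p_miss <- cumsum(ifelse(hit, 0, 1 / (n - n_hit)))
  rs <- p_hit - p_miss
  # signed maximum deviation; exact ties in |deviation| (possible with
  # rational unweighted increments) resolve to the positive extremum
  mx <- max(rs)
  mn <- min(rs)
  if (mx >= -mn - 1e-12) {
    es <- mx
    i_max <- which.max(rs)
  } else {
    es <- mn
    i_max <- which.min(rs)
  }
  leading <- if (es >= 0) genes[hit & seq_len(n) <= i_max]
             else genes[hit & seq_len(n) >= i_max]
  list(es = es, running_sum = rs, leading_edge = leading, n_hits = n_hit)
}

#' GSEA with phenotype permutation
#'
#' For each gene set: observed enrichment score from the class-vs-rest
#' ranking; a null distribution of scores from `n_perm` label
#' permutations (the ranking is recomputed for every permutation); a
#' normalized score NES = ES / mean(|null ES| of matching sign); a
#' permutation p-value `(1 + #{null at least as extreme, same sign}) /
#' (1 + #{null of same sign})`; and BH q-values across sets. Sets failing
#' the [enrichment_score()] preconditions are reported as skipped.
#'
#' @param x an `expr_matrix`.
#' @param labels per-sample class labels.
#' @param target_class class whose enrichment is scored (vs rest).
#' @param gene_sets named list of gene symbol vectors (e.g. from
#'   [read_gmt()]).
#' @param n_perm number of label permutations (>= 100; default 999).
#' @param weight_p running-sum weight exponent (default 1).
#' @param metric ranking metric, see [rank_genes()].
#' @param seed integer seed (required: results are permutation-based).
#' @return data.frame of class `enrichment_result`: `subtype`, `gene_set`,
#'   `size`, `es`, `nes`, `p_perm`, `q_bh`, `leading_edge`
#'   (comma-collapsed), `skipped`.
#' @export
gsea <- function(x, labels, target_class, gene_sets, n_perm = 999,
                 weight_p = 1, metric = "snr", seed) {
  if (missing(seed)) stop("a seed is required for permutation GSEA")
  if (n_perm < 100) stop("n_perm must be >= 100")
  labels <- .align_labels(labels, colnames(x$values))
  set.seed(as.integer(seed))
  ranked <- rank_genes(x, labels, target_class, metric = metric)
  obs <- lapply(gene_sets, function(gs)
    tryCatch(enrichment_score(ranked, gs, weight_p), error = function(e) e))
  ok <- !vapply(obs, inherits, logical(1), "error")
  null_es <- matrix(NA_real_, n_perm, length(gene_sets))
  for (b in seq_len(n_perm)) {
    pl <- sample(labels)
    rb <- rank_genes(x, pl, target_class, metric = metric)
    for (j in which(ok))
      null_es[b, j] <- enrichment_score(rb, gene_sets[[j]], weight_p)$es
  }
  out <- data.frame(subtype = target_class, gene_set = names(gene_sets),
                    size = vapply(gene_sets, length, integer(1)),
                    es = NA_real_, nes = NA_real_, p_perm = NA_real_,
                    q_bh = NA_real_, leading_edge = NA_character_,
                    skipped = !ok, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  for (j in which(ok)) {
    es <- obs[[j]]$es
    nul <- null_es[, j]
    same <- if (es >= 0) nul[nul >= 0] else nul[nul < 0]
    out$es[j] <- es
    out$nes[j] <- if (length(same) && mean(abs(same)) > 0)
      es / mean(abs(same)) else NA_real_
    out$p_perm[j] <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    out$leading_edge[j] <- paste(obs[[j]]$leading_edge, collapse = ",")
  }
  out$q_bh[ok] <- p.adjust(out$p_perm[ok], method = "BH")
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Luminal/basal marker separation by subtype
#'
#' Scores each sample by its mean z-scored luminal-marker expression `L`
#' and basal-marker expression `B`, and their contrast `delta = L - B`;
#' summarizes mean `delta` per subtype; and reports a scheme-level
#' separation index: the standardized difference of `delta` between the
#' scheme's luminal-labeled and basal-labeled subtypes (difference of
#' class means divided by the pooled within-class standard deviation).
#' Larger values indicate cleaner luminal/basal separation.
#'
#' @param x an `expr_matrix` containing (some of) the marker genes.
#' @param assignments a `subtype_assignment` data.frame.
#' @param luminal_markers,basal_markers marker gene symbol vectors.
#' @param luminal_classes,basal_classes which subtype labels count as
#'   luminal/basal for the scheme-level index (defaults cover the PCS and
#'   collapsed PAM50 schemes).
#' @return list with `per_sample` (sample_id, class, L, B, delta),
#'   `per_subtype` (class, mean_delta, n), `separation_index`.
#' @export
marker_separation <- function(x, assignments, luminal_markers,
                              basal_markers,
                              luminal_classes = c("PCS1", "PCS2",
                                                  "LumA", "LumB"),
                              basal_classes = c("PCS3", "Basal")) {
  stopifnot(inherits(x, "expr_matrix"))
  key <- .norm_symbol(rownames(x$values))
  lum <- which(key %in% .norm_symbol(luminal_markers))
  bas <- which(key %in% .norm_symbol(basal_markers))
  if (length(lum) == 0L || length(bas) == 0L)
    stop("no luminal or no basal marker genes present in the matrix")
  common <- intersect(colnames(x$values), assignments$sample_id)
  if (length(common) == 0L) stop("no samples shared with assignments")
  z <- .zscore_rows(x$values[, common, drop = FALSE])
  L <- colMeans(z[lum, , drop = FALSE], na.rm = TRUE)
  B <- colMeans(z[bas, , drop = FALSE], na.rm = TRUE)
  per_sample <- data.frame(
    sample_id = common,
    class = assignments$class[match(common, assignments$sample_id)],
    L = L, B = B, delta = L - B, stringsAsFactors = FALSE)
  rownames(per_sample) <- NULL
  agg <- aggregate(delta ~ class, per_sample, mean)
  names(agg)[2] <- "mean_delta"
  agg$n <- as.integer(table(per_sample$class)[agg$class])
  g_lum <- per_sample$delta[per_sample$class %in% luminal_classes]
  g_bas <- per_sample$delta[per_sample$class %in% basal_classes]
  idx <- NA_real_
  if (length(g_lum) >= 2L && length(g_bas) >= 2L) {
    sp <- sqrt(((length(g_lum) - 1) * var(g_lum) +
                (length(g_bas) - 1) * var(g_bas)) /
               (length(g_lum) + length(g_bas) - 2))
    idx <- (mean(g_lum) - mean(g_bas)) / max(sp, 1e-12)
  }
  list(per_sample = per_sample, per_subtype = agg, separation_index = idx)
}
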