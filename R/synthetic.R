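# Synthetic cohort generator. Emulates the statistical structure the
# comparison pipeline assumes: three latent subtypes with class-specific
# expression blocks on both signatures' genes, partially concordant
# labels across the two schemes, luminal/basal marker architecture,
# subtype-dependent exponential survival hazards with uniform-horizon
# censoring, Gleason grade associated with subtype, and optional cohort
# batch shifts.

#' Specify a synthetic cohort
#'
#' Defaults describe the reference simulation conditions used throughout
#' the package's tests and documentation: three subtypes with a 1.0
#' log2-unit shift on each class's block of signature genes, Gaussian
#' noise sd 0.5, 10% cross-scheme label corruption, subtype-dependent
#' hazards with the aggressive class at 3x the others, 20% censoring and
#' a moderate Gleason-subtype association.
#'
#' @param n_per_class integer(3): samples per scheme-A class
#'   (PCS1/PCS2/PCS3).
#' @param shift per-subtype mean shift (log2 units) applied to the
#'   subtype's specific gene block.
#' @param noise_sd Gaussian noise standard deviation.
#' @param corruption fraction of samples whose scheme-B label is
#'   resampled uniformly from the other classes.
#' @param marker_shift shift applied to lineage marker genes (luminal
#'   classes up on luminal markers, basal class up on basal markers).
#' @param mixed_class optional scheme-B class receiving half `marker_shift`
#'   on both marker panels (a composite luminal/basal phenotype), e.g.
#'   `"LumA"`; `NULL` disables.
#' @param hazards named list per endpoint of numeric(3) event rates per
#'   month for (aggressive, intermediate, indolent) scheme-A classes.
#' @param censoring target censoring fraction in \[0, 1).
#' @param gleason_assoc strength in \[0, 1\] of the Gleason-subtype
#'   association (0 = independent).
#' @param n_background extra unstructured noise genes.
#' @param batch_delta log2 shift added to a second cohort by
#'   [generate_batch_shifted()].
#' @return object of class `cohort_spec` (validated list).
#' @export
cohort_spec <- function(n_per_class = c(100, 100, 100),
                        shift = 1.0,
                        noise_sd = 0.5,
                        corruption = 0.10,
                        marker_shift = 1.0,
                        mixed_class = NULL,
                        hazards = list(BCR = c(0.030, 0.010, 0.010),
                                       Met = c(0.015, 0.005, 0.005),
                                       PCSM = c(0.009, 0.003, 0.003)),
                        censoring = 0.20,
                        gleason_assoc = 0.5,
                        n_background = 200,
                        batch_delta = 0) {
  spec <- list(n_per_class = as.integer(n_per_class), shift = shift,
               noise_sd = noise_sd, corruption = corruption,
               marker_shift = marker_shift, mixed_class = mixed_class,
               hazards = hazards, censoring = censoring,
               gleason_assoc = gleason_assoc,
               n_background = as.integer(n_background),
               batch_delta = batch_delta)
  if (length(spec$n_per_class) != 3L || any(spec$n_per_class < 0))
    stop("n_per_class must be 3 nonnegative integers")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$corruption < 0 || spec$corruption > 1)
    stop("corruption must be in [0, 1]")
  if (any(unlist(spec$hazards) <= 0)) stop("hazards must be > 0")
  if (spec$censoring < 0 || spec$censoring >= 1)
    stop("censoring must be in [0, 1)")
  if (spec$gleason_assoc < 0 || spec$gleason_assoc > 1)
    stop("gleason_assoc must be in [0, 1]")
  structure(spec, class = "cohort_spec")
}

# The planted cross-scheme pairing: each scheme-A class's concordant
# scheme-B partner (aggressive-luminal, luminal, basal).
.PLANTED_PAIRING <- c(PCS1 = "LumB", PCS2 = "LumA", PCS3 = "Basal")

# Gleason category probabilities per scheme-A class at full association.
.GLEASON_BY_CLASS <- rbind(PCS1 = c(0.10, 0.30, 0.60),
                           PCS2 = c(0.45, 0.40, 0.15),
                           PCS3 = c(0.40, 0.40, 0.20))

# Uniform censoring horizon H with P(censor) = target for exponential
# event times: P(U(0,H) < Exp(lambda)) = (1 - exp(-lambda*H))/(lambda*H),
# averaged over class weights; solved by bisection.
.censor_horizon <- function(lambdas, weights, target) {
  pc <- function(H) sum(weights * (1 - exp(-lambdas * H)) / (lambdas * H))
  lo <- 1e-6; hi <- 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (pc(mid) > target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Generate a synthetic cohort
#'
#' Expression is Gaussian background noise plus each subtype's mean shift
#' on its specific gene block: scheme-A blocks are the PCS37 class
#' blocks, scheme-B blocks are the PAM50 class blocks (driven by the
#' sample's scheme-B label), and lineage marker genes follow the marker
#' architecture. Scheme-B true labels equal the planted scheme-A partner
#' class except for a corrupted fraction. Survival times are exponential
#' with per-subtype rates and censored by an independent uniform horizon
#' calibrated to the target censoring fraction; Gleason category is drawn
#' with the specified subtype association.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (required).
#' @param sample_prefix prefix for generated sample ids.
#' @return list of class `synthetic_cohort`: `expression`
#'   (`expr_matrix`, log2 units), `labels_a`, `labels_b` (named character
#'   vectors of true labels), `clinical` (`clinical_table`), `manifest`
#'   (realized parameters incl. seed).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed,
                            sample_prefix = "S") {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed)) stop("a seed is required")
  n <- sum(spec$n_per_class)
  if (n < 6L) stop("total n must be >= 6")
  set.seed(as.integer(seed))
  reg <- builtin_signatures()
  classes_a <- reg$PCS37$classes
  classes_b <- reg$PAM50$classes
  labels_a <- rep(classes_a, spec$n_per_class)
  sample_ids <- sprintf("%s%04d", sample_prefix, seq_len(n))

  # scheme-B labels: planted partner, then uniform corruption
  labels_b <- unname(.PLANTED_PAIRING[labels_a])
  flip <- runif(n) < spec$corruption
  for (i in which(flip))
    labels_b[i] <- sample(setdiff(classes_b, labels_b[i]), 1L)

  genes <- unique(c(reg$PCS37$genes, reg$PAM50$genes,
                    reg$luminal_markers, reg$basal_markers))
  bg <- if (spec$n_background > 0)
    sprintf("BG%04d", seq_len(spec$n_background)) else character(0)
  all_genes <- c(genes, bg)
  expr <- matrix(rnorm(length(all_genes) * n, 0, spec$noise_sd),
                 length(all_genes), n,
                 dimnames = list(all_genes, sample_ids))

  add_block <- function(block_genes, sample_idx, amount) {
    rows <- match(block_genes, all_genes)
    rows <- rows[!is.na(rows)]
    expr[rows, sample_idx] <<- expr[rows, sample_idx] + amount
  }
  ann_a <- reg$PCS37$gene_class
  for (cl in classes_a)
    add_block(names(ann_a)[ann_a == cl], labels_a == cl, spec$shift)
  ann_b <- reg$PAM50$gene_class
  for (cl in classes_b)
    add_block(names(ann_b)[ann_b == cl], labels_b == cl, spec$shift)
  # marker architecture follows the scheme-A lineage (PCS1/PCS2 luminal,
  # PCS3 basal); samples of the optional mixed scheme-B class instead get
  # a composite half-shift on both panels
  lineage_lum <- labels_a %in% c("PCS1", "PCS2")
  mixed <- if (!is.null(spec$mixed_class)) labels_b == spec$mixed_class
           else rep(FALSE, n)
  add_block(reg$luminal_markers, lineage_lum & !mixed, spec$marker_shift)
  add_block(reg$basal_markers, !lineage_lum & !mixed, spec$marker_shift)
  add_block(reg$luminal_markers, mixed, spec$marker_shift / 2)
  add_block(reg$basal_markers, mixed, spec$marker_shift / 2)

  # survival endpoints: exponential event times, uniform-horizon censoring
  weights <- spec$n_per_class / n
  clin <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  horizons <- list()
  for (ep in names(spec$hazards)) {
    lam <- spec$hazards[[ep]][match(labels_a, classes_a)]
    t_ev <- rexp(n, rate = lam)
    if (spec$censoring > 0) {
      H <- .censor_horizon(spec$hazards[[ep]], weights, spec$censoring)
      t_c <- runif(n, 0, H)
    } else {
      H <- Inf
      t_c <- rep(Inf, n)
    }
    horizons[[ep]] <- H
    clin[[paste0(ep, "_time")]] <- pmax(pmin(t_ev, t_c), 1e-6)
    clin[[paste0(ep, "_event")]] <- as.integer(t_ev <= t_c)
    clin[[paste0(ep, "_missing")]] <- FALSE
  }
  # Gleason: mixture of uniform and class-specific distribution
  gl <- character(n)
  for (i in seq_len(n)) {
    p <- (1 - spec$gleason_assoc) * rep(1 / 3, 3) +
      spec$gleason_assoc * .GLEASON_BY_CLASS[labels_a[i], ]
    gl[i] <- sample(.GLEASON_LEVELS, 1L, prob = p)
  }
  clin$gleason_category <- bin_gleason(gl)
  attr(clin, "endpoints") <- names(spec$hazards)
  class(clin) <- c("clinical_table", "data.frame")

  manifest <- list(seed = as.integer(seed), n = n,
                   n_per_class = spec$n_per_class,
                   shift = spec$shift, noise_sd = spec$noise_sd,
                   corruption = spec$corruption,
                   marker_shift = spec$marker_shift,
                   mixed_class = spec$mixed_class,
                   hazards = spec$hazards, censoring = spec$censoring,
                   censor_horizons = horizons,
                   gleason_assoc = spec$gleason_assoc,
                   n_background = spec$n_background,
                   batch_delta = spec$batch_delta,
                   pairing = as.list(.PLANTED_PAIRING))
  structure(list(
    expression = expression_matrix(expr, units = "log2"),
    labels_a = setNames(labels_a, sample_ids),
    labels_b = setNames(labels_b, sample_ids),
    clinical = clin,
    manifest = manifest), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: n =", x$manifest$n, "(",
      paste(x$manifest$n_per_class, collapse = "/"), "per class ),",
      length(rownames(x$expression$values)), "genes\n")
  invisible(x)
}

#' Generate two cohorts with a batch shift
#'
#' Cohort 1 is a draw from `spec`; cohort 2 is an independent draw from
#' `spec2` (default: same spec) with `delta` log2 units added to every
#' expression value. The merged dataset carries per-sample cohort labels,
#' so the effect of reference construction (single pooled median versus
#' per-cohort medians) on downstream subtype calling can be measured.
#'
#' @param spec a [cohort_spec()] for cohort 1.
#' @param delta log2 batch shift added to cohort 2.
#' @param seed integer seed.
#' @param spec2 optional different spec for cohort 2 (e.g. skewed class
#'   composition).
#' @return list of class `batch_cohorts`: `expression` (merged
#'   `expr_matrix` with cohort labels), `labels_a`, `labels_b`,
#'   `clinical`, `cohort` (named vector "C1"/"C2"), `manifest`.
#' @export
generate_batch_shifted <- function(spec = cohort_spec(), delta, seed,
                                   spec2 = spec) {
  if (missing(seed)) stop("a seed is required")
  c1 <- generate_cohort(spec, seed = seed, sample_prefix = "A")
  c2 <- generate_cohort(spec2, seed = seed + 1L, sample_prefix = "B")
  v2 <- c2$expression$values + delta
  stopifnot(identical(rownames(c1$expression$values), rownames(v2)))
  merged <- cbind(c1$expression$values, v2)
  cohort <- setNames(rep(c("C1", "C2"),
                         c(ncol(c1$expression$values), ncol(v2))),
                     colnames(merged))
  clin <- rbind(as.data.frame(c1$clinical), as.data.frame(c2$clinical))
  class(clin) <- c("clinical_table", "data.frame")
  structure(list(
    expression = expression_matrix(merged, units = "log2", cohort = cohort),
    labels_a = c(c1$labels_a, c2$labels_a),
    labels_b = c(c1$labels_b, c2$labels_b),
    clinical = clin,
    cohort = cohort,
    manifest = list(seed = as.integer(seed), delta = delta,
                    cohort1 = c1$manifest, cohort2 = c2$manifest)),
    class = "batch_cohorts")
}
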