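# End-to-end orchestration: classify both schemes, cross-scheme
# concordance, per-subtype GSEA, marker separation, survival comparison,
# with a reproducibility manifest. Stages whose inputs are absent are
# skipped with a logged reason, never silently.

#' Default pipeline configuration
#'
#' Returns the fully populated default configuration as a named list;
#' write it to YAML as a starting template with `yaml::write_yaml()`.
#' Fields: `seed` (mandatory for any run), `simulate` (a [cohort_spec()]
#' argument list, used when no `expression` file is given), `expression`
#' / `clinical` / `gmt` (input file paths), `clinical_schema` (column
#' mapping for [read_clinical()]), `preprocess` (`log2`, `offset`,
#' `reference_mode`, `min_signature_coverage`), `similarity`,
#' `n_perm`, `adjust_gleason`.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(seed = NULL,
       simulate = list(),       # cohort_spec() arguments
       expression = NULL, clinical = NULL, gmt = NULL,
       clinical_schema = NULL,
       train_labels = NULL,     # path to TSV sample_id/label_a/label_b
       preprocess = list(log2 = FALSE, offset = 1,
                         reference_mode = "single",
                         min_signature_coverage = 0.8),
       similarity = "spearman",
       n_perm = 199,
       adjust_gleason = TRUE)
}

.log_stage <- function(log, msg) {
  message("[pcsubtype] ", msg)
  c(log, msg)
}

#' Run the full two-scheme comparison
#'
#' Executes the pipeline stages in order: obtain expression (load files
#' or generate a synthetic cohort), preprocess (optional log2, median
#' centering with the configured reference construction), train centroids
#' and assign subtypes under both schemes, cross-scheme concordance
#' (contingency, per-cell enrichment, centroid distances), GSEA per
#' subtype (if gene sets available), marker separation per scheme, and
#' survival comparison per endpoint (if clinical data available). All
#' tables are written under `out_dir` together with `manifest.json`
#' recording the seed, config hash and package version. Deterministic
#' given config + seed.
#'
#' @param config named list (see [default_config()]) or path to a
#'   YAML/JSON config file.
#' @param out_dir output directory (created if needed).
#' @return invisible list with all in-memory results (`assignments_a`,
#'   `assignments_b`, `contingency`, `enrichment`, `distances`, `gsea`,
#'   `markers`, `survival`, `manifest`).
#' @export
run_comparison <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config)
              else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$seed)) stop("config error: a seed is mandatory")
  if (!is.null(cfg$clinical) && is.null(cfg$clinical_schema))
    stop("config error: clinical file given without clinical_schema")
  if (!is.null(cfg$expression) && is.null(cfg$train_labels))
    stop("config error: external expression requires train_labels ",
         "(centroid training labels for both schemes)")
  seed <- as.integer(cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- .config_hash(cfg)
  log <- character(0)
  wrt <- function(df, name) write_result_table(
    df, file.path(out_dir, name), seed = seed, config_hash = chash)
  reg <- builtin_signatures()

  # --- stage: input -------------------------------------------------------
  if (!is.null(cfg$expression)) {
    log <- .log_stage(log, paste("loading expression from", cfg$expression))
    expr <- read_expression(cfg$expression)
    labels_a <- labels_b <- NULL
    if (!is.null(cfg$train_labels)) {
      lt <- read.delim(cfg$train_labels, stringsAsFactors = FALSE)
      labels_a <- setNames(lt$label_a, lt$sample_id)
      if ("label_b" %in% names(lt))
        labels_b <- setNames(lt$label_b, lt$sample_id)
    }
    clinical <- NULL
    if (!is.null(cfg$clinical)) {
      if (is.null(cfg$clinical_schema))
        stop("config error: clinical file given without clinical_schema")
      clinical <- read_clinical(cfg$clinical, cfg$clinical_schema)
    }
  } else {
    log <- .log_stage(log, "no expression input; generating synthetic cohort")
    spec <- do.call(cohort_spec, cfg$simulate)
    cohort <- generate_cohort(spec, seed = seed)
    expr <- cohort$expression
    labels_a <- cohort$labels_a
    labels_b <- cohort$labels_b
    clinical <- cohort$clinical
  }
  if (is.null(labels_a))
    stop("stage classify: centroid training labels are required ",
         "(train_labels) when loading external expression")

  # --- stage: preprocess --------------------------------------------------
  if (isTRUE(cfg$preprocess$log2))
    expr <- log2_transform(expr, offset = cfg$preprocess$offset)
  expr <- median_center(expr, reference_mode = cfg$preprocess$reference_mode)
  log <- .log_stage(log, paste("median-centered,",
                               cfg$preprocess$reference_mode, "reference"))

  # --- stage: classify both schemes --------------------------------------
  mincov <- cfg$preprocess$min_signature_coverage
  sub_a <- subset_to_signature(expr, reg$PCS37, min_coverage = mincov)
  sub_b <- subset_to_signature(expr, reg$PAM50, min_coverage = mincov)
  model_a <- train_centroids(sub_a, labels_a, reg$PCS37)
  assign_a <- assign_subtypes(sub_a, model_a, similarity = cfg$similarity)
  if (is.null(labels_b))
    stop("stage classify: scheme-B training labels required")
  model_b <- train_centroids(sub_b, labels_b, reg$PAM50)
  assign_b <- assign_subtypes(sub_b, model_b, similarity = cfg$similarity)
  wrt(as.data.frame(assign_a), "calls_PCS.tsv")
  wrt(as.data.frame(assign_b), "calls_PAM50.tsv")
  log <- .log_stage(log, "assigned subtypes under both schemes")

  # --- stage: concordance -------------------------------------------------
  ct <- cross_tabulate(assign_a, assign_b,
                       classes_a = reg$PCS37$classes,
                       classes_b = reg$PAM50$classes)
  enr <- pair_enrichment(ct)
  union_genes <- unique(c(reg$PCS37$genes, reg$PAM50$genes))
  cd <- centroid_distance_matrix(expr, assign_a, assign_b,
                                 genes = union_genes)
  wrt(data.frame(class_a = rownames(ct$counts), ct$counts,
                 check.names = FALSE), "contingency.tsv")
  wrt(enr, "enrichment.tsv")
  wrt(data.frame(label = rownames(cd$distances), cd$distances,
                 check.names = FALSE), "centroid_distances.tsv")
  wrt(cd$nearest, "nearest_pairs.tsv")
  log <- .log_stage(log, "computed cross-scheme concordance")

  # --- stage: GSEA --------------------------------------------------------
  gsea_tabs <- NULL
  gene_sets <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL
  if (is.null(gene_sets)) {
    log <- .log_stage(log, "GSEA skipped: no gene sets configured")
  } else {
    gsea_tabs <- list()
    both <- list(PCS = assign_a, PAM50 = assign_b)
    for (scheme in names(both)) {
      asn <- both[[scheme]]
      lab <- setNames(asn$class, asn$sample_id)
      for (cl in unique(asn$class)) {
        tab <- gsea(expr, lab, cl, gene_sets, n_perm = cfg$n_perm,
                    seed = seed + match(cl, sort(unique(asn$class))))
        gsea_tabs[[paste(scheme, cl, sep = "_")]] <- tab
      }
    }
    wrt(do.call(rbind, gsea_tabs), "gsea.tsv")
    log <- .log_stage(log, "computed per-subtype GSEA")
  }

  # --- stage: marker separation ------------------------------------------
  markers <- list(
    PCS = marker_separation(expr, assign_a, reg$luminal_markers,
                            reg$basal_markers),
    PAM50 = marker_separation(expr, assign_b, reg$luminal_markers,
                              reg$basal_markers))
  wrt(data.frame(scheme = names(markers),
                 separation_index = vapply(markers, `[[`, numeric(1),
                                           "separation_index")),
      "marker_separation.tsv")
  log <- .log_stage(log, "computed marker separation")

  # --- stage: survival ----------------------------------------------------
  surv <- NULL
  if (is.null(clinical)) {
    log <- .log_stage(log, "survival skipped: no clinical table")
  } else {
    surv <- list(
      PCS = subtype_outcome_report(assign_a, clinical,
                                   class_order = reg$PCS37$classes,
                                   adjust_gleason = cfg$adjust_gleason),
      PAM50 = subtype_outcome_report(assign_b, clinical,
                                     class_order = reg$PAM50$classes,
                                     adjust_gleason = cfg$adjust_gleason))
    for (scheme in names(surv)) {
      for (ep in names(surv[[scheme]])) {
        res <- surv[[scheme]][[ep]]
        km_tab <- do.call(rbind, lapply(names(res$km), function(k)
          data.frame(group = k, res$km[[k]])))
        wrt(km_tab, sprintf("km_%s_%s.tsv", scheme, ep))
        wrt(res$pairwise, sprintf("hr_%s_%s.tsv", scheme, ep))
      }
    }
    cindex <- do.call(rbind, lapply(names(surv), function(scheme)
      do.call(rbind, lapply(names(surv[[scheme]]), function(ep)
        data.frame(scheme = scheme, endpoint = ep,
                   c_index = surv[[scheme]][[ep]]$c_index,
                   c_index_adjusted = surv[[scheme]][[ep]]$c_index_adjusted)))))
    wrt(cindex, "cindex.tsv")
    log <- .log_stage(log, "computed survival comparison")
  }

  manifest <- list(package = "pcsubtype",
                   version = as.character(packageVersion("pcsubtype")),
                   seed = seed, config_hash = chash, log = log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(assignments_a = assign_a, assignments_b = assign_b,
                 contingency = ct, enrichment = enr, distances = cd,
                 gsea = gsea_tabs, markers = markers, survival = surv,
                 manifest = manifest))
}
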