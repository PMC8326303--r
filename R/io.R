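# Readers/writers for the formats the pipeline touches: expression
# matrices (TSV/CSV, genes in rows by default), GMT gene-set collections
# and clinical endpoint tables.

#' Construct an expression matrix object
#'
#' Container for a genes x samples numeric matrix with an expression-units
#' flag and optional per-sample cohort labels.
#'
#' @param values numeric matrix with unique rownames (gene symbols) and
#'   unique colnames (sample ids).
#' @param units `"log2"` or `"raw"`.
#' @param cohort optional character vector of per-sample cohort labels
#'   (length = number of samples).
#' @return object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, units = c("log2", "raw"),
                              cohort = NULL) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (any(is.infinite(values)))
    stop("expression values must be finite or NA")
  if (!is.null(cohort)) {
    if (length(cohort) != ncol(values))
      stop("cohort labels must cover every sample")
    cohort <- setNames(as.character(cohort), colnames(values))
  }
  structure(list(values = values, units = units, cohort = cohort),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", x$units, ")",
      if (!is.null(x$cohort))
        paste0(", ", length(unique(x$cohort)), " cohort(s)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty table: ", path)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a gene expression table
#'
#' Reads a delimited text table with one header row and one id column into
#' an [expression_matrix()]. Duplicate gene ids are collapsed by keeping
#' the row with the highest variance across samples (first occurrence on
#' ties), the standard practice for signature scoring. Gene symbols are
#' trimmed; matching downstream is case-insensitive but the original
#' casing is preserved.
#'
#' @param path file path (TSV or CSV; delimiter auto-detected, tab first).
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param units expression units flag, `"log2"` or `"raw"`.
#' @param sep optional delimiter override.
#' @return an `expr_matrix`; its `"load_report"` attribute is a list with
#'   `n_genes`, `n_samples`, `n_duplicates_collapsed`, `n_missing_cells`.
#' @export
read_expression <- function(path, orientation = c("genes_in_rows",
                                                  "samples_in_rows"),
                            units = c("log2", "raw"), sep = NULL) {
  orientation <- match.arg(orientation)
  units <- match.arg(units)
  if (is.null(sep)) sep <- .detect_sep(path)
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) stop("empty table: ", path)
  ids <- trimws(as.character(tab[[1L]]))
  hdr <- names(tab)[-1L]   # before subsetting: `[.data.frame` dedups names
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad))
        stop("non-numeric cell in column '", names(vals)[j],
             "' (e.g. row ", bad[1L], ": '", v[bad[1L]], "')")
      v <- num
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(ids, hdr)
  if (orientation == "samples_in_rows") m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  n_dup <- 0L
  if (anyDuplicated(rownames(m))) {
    key <- .norm_symbol(rownames(m))
    n_dup <- sum(duplicated(key))
    rv <- apply(m, 1L, var, na.rm = TRUE)
    rv[!is.finite(rv)] <- -Inf
    ord <- order(key, -rv, seq_len(nrow(m)))  # highest variance, then first
    keep <- ord[!duplicated(key[ord])]
    m <- m[sort(keep), , drop = FALSE]
  }
  out <- expression_matrix(m, units = units)
  attr(out, "load_report") <- list(
    n_genes = nrow(m), n_samples = ncol(m),
    n_duplicates_collapsed = n_dup,
    n_missing_cells = sum(is.na(m)))
  out
}

#' Write an expression matrix as TSV (genes in rows)
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then one or more member gene
#' symbols, tab-separated. Members are deduplicated; set names must be
#' unique.
#'
#' @param path GMT file path.
#' @return named list of class `gene_set_collection`; each element is a
#'   character vector of member symbols with a `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    nm <- trimws(f[1L])
    if (nm %in% names(sets))
      stop("duplicate gene set name '", nm, "' at line ", i)
    members <- unique(trimws(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop("GMT line ", i, ": set '", nm, "' has no members")
    attr(members, "description") <- f[2L]
    sets[[nm]] <- members
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors (optionally with a
#'   `"description"` attribute per set).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.GLEASON_LEVELS <- c("lt7", "eq7", "gt7")

#' Bin raw Gleason sum scores into the three-level grade category
#'
#' Scores below 7 map to `lt7`, exactly 7 to `eq7`, above 7 to `gt7`.
#'
#' @param score numeric vector of Gleason sum scores (2-10) or character
#'   vector already using the category labels.
#' @return factor with levels `lt7 < eq7 < gt7` (NA preserved).
#' @export
bin_gleason <- function(score) {
  if (is.character(score) || is.factor(score)) {
    score <- as.character(score)
    bad <- !is.na(score) & !(score %in% .GLEASON_LEVELS)
    if (any(bad))
      stop("unknown Gleason category: ", paste(unique(score[bad]), collapse = ", "))
    return(factor(score, levels = .GLEASON_LEVELS, ordered = TRUE))
  }
  cat <- ifelse(is.na(score), NA_character_,
                ifelse(score < 7, "lt7", ifelse(score == 7, "eq7", "gt7")))
  factor(cat, levels = .GLEASON_LEVELS, ordered = TRUE)
}

#' Read a clinical endpoint table
#'
#' Parses a per-sample table with survival endpoints (time in months and
#' 0/1 event indicator per endpoint) and Gleason grade, given a schema
#' mapping from logical fields to column names. Raw Gleason sums are
#' binned to the three-level category (`lt7`/`eq7`/`gt7`). Rows with
#' missing endpoint fields are retained and flagged per endpoint.
#'
#' @param path file path (TSV or CSV; delimiter auto-detected).
#' @param schema named list mapping fields to column names:
#'   `sample_id`, `gleason` (raw sum or pre-binned category), optionally
#'   `cohort`, and per endpoint `<ep>_time`, `<ep>_event`.
#' @param endpoints character vector of endpoint names (default
#'   `c("BCR","Met","PCSM")`); endpoints absent from `schema` are skipped.
#' @param sep optional delimiter override.
#' @return a `clinical_table` data.frame with columns `sample_id`,
#'   `gleason_category`, optional `cohort`, and per endpoint
#'   `<ep>_time`, `<ep>_event`, `<ep>_missing`.
#' @export
read_clinical <- function(path, schema, endpoints = c("BCR", "Met", "PCSM"),
                          sep = NULL) {
  if (is.null(sep)) sep <- .detect_sep(path)
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty clinical table: ", path)
  need <- function(col) {
    if (!col %in% names(tab)) stop("clinical table lacks column '", col, "'")
    tab[[col]]
  }
  out <- data.frame(sample_id = as.character(need(schema$sample_id)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) stop("duplicate sample ids in clinical table")
  if (!is.null(schema$gleason))
    out$gleason_category <- bin_gleason(need(schema$gleason))
  if (!is.null(schema$cohort))
    out$cohort <- as.character(need(schema$cohort))
  kept <- character(0)
  for (ep in endpoints) {
    tcol <- schema[[paste0(ep, "_time")]]
    ecol <- schema[[paste0(ep, "_event")]]
    if (is.null(tcol) || is.null(ecol)) next
    tt <- as.numeric(need(tcol))
    ev <- as.numeric(need(ecol))
    bad_t <- which(!is.na(tt) & tt <= 0)
    if (length(bad_t))
      stop(ep, " time must be > 0 (row ", bad_t[1L], ")")
    bad_e <- which(!is.na(ev) & !(ev %in% c(0, 1)))
    if (length(bad_e))
      stop(ep, " event must be 0/1 (row ", bad_e[1L], ")")
    out[[paste0(ep, "_time")]] <- tt
    out[[paste0(ep, "_event")]] <- as.integer(ev)
    out[[paste0(ep, "_missing")]] <- is.na(tt) | is.na(ev)
    kept <- c(kept, ep)
  }
  attr(out, "endpoints") <- kept
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Write a clinical table as CSV
#'
#' @param x a `clinical_table` (or plain data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[, !grepl("_missing$", names(df)), drop = FALSE]
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
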