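#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median sd var phyper p.adjust setNames aggregate
#'   rnorm rexp runif pchisq pnorm coef dist
#' @importFrom utils read.delim write.table packageVersion head tail
#'   combn modifyList
NULL

# z used for 95% Wald intervals; stated explicitly so tests are not
# sensitive to 1.96 rounding drift.
.Z95 <- 1.959964

.norm_symbol <- function(x) toupper(trimws(x))

#' Gene-wise z-scoring of an expression matrix
#'
#' Centers each gene to zero mean and scales to unit standard deviation
#' across all samples. Genes with zero variance are centered but left
#' unscaled (divisor 1) to avoid NaNs.
#'
#' @param x numeric matrix, genes in rows.
#' @return matrix of the same shape.
#' @keywords internal
.zscore_rows <- function(x) {
  mu <- rowMeans(x, na.rm = TRUE)
  sdev <- apply(x, 1L, sd, na.rm = TRUE)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  sweep(sweep(x, 1L, mu, "-"), 1L, sdev, "/")
}

#' Write a result table as TSV with a provenance comment header
#'
#' All pipeline result tables share this format: a single `#`-prefixed
#' comment line recording the package version, the seed and a config hash,
#' followed by an ordinary tab-separated table with a header row.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param seed integer seed recorded in the header (or NA).
#' @param config_hash short string identifying the run configuration.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, seed = NA, config_hash = "") {
  hdr <- sprintf("# pcsubtype %s | seed=%s | config=%s",
                 as.character(packageVersion("pcsubtype")),
                 as.character(seed), config_hash)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path file path.
#' @return data.frame (comment lines dropped).
#' @export
read_result_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

# Small deterministic string hash (djb2) for config provenance headers.
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}
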