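#' Read a beta-value matrix from delimited text
#'
#' Reads a loci x samples matrix of beta values. The first column holds
#' locus ids, the header holds sample ids; comma or tab delimiters are
#' auto-detected from the first line. Missing values are allowed and kept
#' as `NA`; values outside `[0, 1]` raise an error naming the offending
#' cell.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` (default) auto-detects.
#' @return Numeric matrix with locus rownames and sample colnames.
#' @export
fmc_read_beta <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m)))
    stop("duplicate locus ids in ", path, call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids in ", path, call. = FALSE)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("beta value out of [0, 1] at locus '", rownames(m)[bad[1, 1]],
         "', sample '", colnames(m)[bad[1, 2]], "' (",
         m[bad[1, , drop = FALSE]], ")", call. = FALSE)
  }
  m
}

#' Write a beta-value matrix as delimited text
#'
#' @param beta matrix with locus rownames and sample colnames.
#' @param path output path.
#' @param sep delimiter (default comma).
#' @return `path`, invisibly.
#' @export
fmc_write_beta <- function(beta, path, sep = ",") {
  df <- data.frame(locus = rownames(beta), beta, check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write inference results to a directory
#'
#' Writes a schema-versioned JSON summary (`summary.json`: `P(S | beta)`
#' table, posterior means and 95% equal-tailed intervals, seed, package
#' version), the model-averaged posterior sample table
#' (`posterior_samples.tsv`) and a posterior predictive density table
#' (`predictive_density.tsv`).
#'
#' @param fit an [fmc_fit()] result.
#' @param dir output directory (created if needed).
#' @param rhat optional named R-hat vector from [fmc_convergence()].
#' @return `dir`, invisibly.
#' @export
fmc_write_results <- function(fit, dir, rhat = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- summary(fit)
  summary_obj <- list(
    schema_version = "1.0",
    package_version = as.character(packageVersion("fmclock")),
    seed = fit$seed,
    n_loci = length(fit$beta),
    age = fit$age,
    evidence = fit$evidence,
    posterior = as.data.frame(cbind(parameter = rownames(sm$params),
                                    as.data.frame(sm$params))),
    rhat = as.list(rhat))
  jsonlite::write_json(summary_obj, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(as.data.frame(fit$posterior),
              file.path(dir, "posterior_samples.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(predict(fit), file.path(dir, "predictive_density.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
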