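pkg_version <- function() {
  as.character(utils::packageVersion("stpscore"))
}

# Comment header written at the top of every TSV the package emits;
# readers skip "#" lines.
tsv_header <- function(what, seed = NULL) {
  h <- sprintf("# stpscore %s | %s", pkg_version(), what)
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %d", seed))
  h
}

#' Write a data.frame as a commented TSV
#'
#' Tab-separated, UTF-8, `"."` decimal, `#` comment header recording the
#' tool version (and seed when given).  The workhorse behind every table
#' writer in the package.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @param what One-line description placed in the header.
#' @param seed Optional integer seed to record.
#' @export
write_tsv <- function(df, path, what = "table", seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header(what, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commented TSV into a data.frame
#'
#' @param path Path to a TSV with optional `#` comment lines.
#' @return Data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Tabulate reference thresholds
#'
#' @param thresholds Named list of `reference_threshold`s.
#' @return Data.frame with columns `pathway`, `mean`, `sd`, `upper`,
#'   `n_ref`.
#' @export
thresholds_table <- function(thresholds) {
  do.call(rbind, lapply(names(thresholds), function(p) {
    t <- thresholds[[p]]
    data.frame(pathway = p, mean = t$ref_mean, sd = t$ref_sd,
               upper = t$upper, n_ref = t$n_ref, stringsAsFactors = FALSE)
  }))
}

#' Read reference thresholds from a TSV written via [thresholds_table()]
#'
#' @param path TSV path.
#' @return Named list of `reference_threshold`s.
#' @export
read_thresholds_tsv <- function(path) {
  df <- read_tsv(path)
  out <- lapply(seq_len(nrow(df)), function(i)
    structure(list(pathway_name = df$pathway[i], ref_mean = df$mean[i],
                   ref_sd = df$sd[i], upper = df$upper[i],
                   n_ref = df$n_ref[i]),
              class = "reference_threshold"))
  names(out) <- df$pathway
  out
}

#' Tabulate comparison results
#'
#' One row per named comparison; a Bonferroni-adjusted p column is emitted
#' for transparency but plays no role in any verdict (the analysis applies
#' no multiple-testing correction).
#'
#' @param comparisons Named list of `comparison_result`s.
#' @return Data.frame.
#' @export
comparisons_table <- function(comparisons) {
  df <- do.call(rbind, lapply(names(comparisons), function(nm) {
    x <- comparisons[[nm]]
    data.frame(comparison = nm, method = x$method,
               statistic = x$statistic, p_value = x$p_value,
               alternative = x$alternative, n1 = x$n1, n2 = x$n2,
               ties_present = x$ties_present, stringsAsFactors = FALSE)
  }))
  df$p_bonferroni <- pmin(1, df$p_value * nrow(df))
  df
}

#' Tabulate QC reports
#'
#' @param reports Named list of `qc_report`s.
#' @return Data.frame with `sample_id`, `pass`, semicolon-joined
#'   `failure_reasons`.
#' @export
qc_report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(sample_id = r$sample_id, pass = r$pass,
               failure_reasons = paste(r$failure_reasons, collapse = ";"),
               stringsAsFactors = FALSE)))
}

#' Tabulate profile matches
#'
#' @param matches List of `profile_match`es.
#' @return Data.frame with `sample_id`, `best_label`, `similarity`.
#' @export
profile_match_table <- function(matches) {
  do.call(rbind, lapply(matches, function(m)
    data.frame(sample_id = m$sample_id, best_label = m$best_label,
               similarity = m$similarity, stringsAsFactors = FALSE)))
}
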