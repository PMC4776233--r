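# Substrate calling by the dual-threshold criteria: a protein is called a
# substrate when at least `min_peptides` distinct peptide sequences pass the
# log2 ratio cutoff. Calls supported by >= 5 peptides are "hot", by 2-4
# "warm".

#' Convert a fold change to a log2 ratio
#'
#' @param fold Positive fold change(s).
#' @return `log2(fold)`.
#' @examples
#' fold_to_log2(5.85)   # passes the 1.8 cutoff
#' @export
fold_to_log2 <- function(fold) {
  if (!is.numeric(fold) || any(is.na(fold)) || any(fold <= 0)) {
    stop("`fold` must be positive", call. = FALSE)
  }
  log2(fold)
}

#' Fraction of up-regulated peptides
#'
#' The conventional up-regulation standard counts peptides with log2(H/L)
#' strictly greater than the cutoff (default 1).
#'
#' @param table A [quant_table()].
#' @param log2_cutoff Strict lower bound on the log2 ratio.
#' @return Fraction in `[0, 1]`.
#' @export
upregulated_fraction <- function(table, log2_cutoff = 1) {
  if (nrow(table) == 0L) stop("empty quant table", call. = FALSE)
  mean(table$log2_ratio > log2_cutoff)
}

#' Call substrates with the dual-threshold criteria
#'
#' Per protein, the number of distinct peptide sequences with
#' `log2_ratio >= log2_cutoff` is counted (charge/modification variants and
#' repeated locations of the same sequence collapse); a substrate call is
#' emitted when that count reaches `min_peptides`. Calls supported by at
#' least 5 peptides are tiered `hot`, by 2-4 `warm`.
#'
#' @param table A [quant_table()].
#' @param log2_cutoff Inclusive log2 ratio cutoff (default 1.8).
#' @param min_peptides Minimum distinct passing peptides (default 2; must be
#'   at least 2).
#' @param known Optional character vector of known-substrate accessions used
#'   to flag calls.
#' @return A `substrate_calls` data frame with columns `accession`,
#'   `n_up_peptides`, `tier`, `is_known`, ordered by accession, with the
#'   supporting peptide rows in the `peptides` attribute (a named list).
#' @export
call_substrates <- function(table, log2_cutoff = 1.8, min_peptides = 2L,
                            known = NULL) {
  min_peptides <- as.integer(min_peptides)
  if (min_peptides < 2L) {
    stop("`min_peptides` must be at least 2: single-peptide calls are not substrates",
         call. = FALSE)
  }
  pass <- table[table$log2_ratio >= log2_cutoff, , drop = FALSE]
  counts <- passing_peptide_counts(pass)
  hit <- counts[counts >= min_peptides]
  acc <- sort(names(hit))
  n_up <- as.integer(hit[acc])
  calls <- data.frame(accession = acc,
                      n_up_peptides = n_up,
                      tier = ifelse(n_up >= 5L, "hot", "warm"),
                      is_known = if (is.null(known)) NA else acc %in% known,
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  support <- lapply(acc, function(a) {
    p <- pass[pass$accession == a, , drop = FALSE]
    p[!duplicated(p$sequence), , drop = FALSE]
  })
  names(support) <- acc
  structure(calls, peptides = support,
            log2_cutoff = log2_cutoff, min_peptides = min_peptides,
            class = c("substrate_calls", "data.frame"))
}

# distinct passing peptide sequences per accession
passing_peptide_counts <- function(pass) {
  if (nrow(pass) == 0L) return(integer())
  uniq <- unique(pass[, c("accession", "sequence")])
  table(uniq$accession)
}

#' @export
print.substrate_calls <- function(x, ...) {
  cat(sprintf("Substrate calls: %d (log2 >= %.2f, >= %d peptides)\n",
              nrow(x), attr(x, "log2_cutoff"), attr(x, "min_peptides")))
  cat(sprintf("  hot: %d, warm: %d\n", sum(x$tier == "hot"),
              sum(x$tier == "warm")))
  if (nrow(x) && !anyNA(x$is_known)) {
    cat(sprintf("  known substrates: %d (%.1f%%)\n", sum(x$is_known),
                100 * mean(x$is_known)))
  }
  invisible(x)
}

#' @export
summary.substrate_calls <- function(object, ...) {
  print(object)
  if (nrow(object)) {
    cat("  supporting peptides per call:\n")
    print(summary(object$n_up_peptides))
  }
  invisible(object)
}

#' Precision and recall of substrate calls against ground truth
#'
#' @param calls A [call_substrates()] result.
#' @param truth A [ground_truth()].
#' @return List with `precision`, `recall`, `n_calls`, `n_true`.
#' @export
call_performance <- function(calls, truth) {
  tp <- sum(calls$accession %in% truth$substrates)
  list(precision = if (nrow(calls)) tp / nrow(calls) else NA_real_,
       recall = if (length(truth$substrates)) tp / length(truth$substrates)
                else NA_real_,
       n_calls = nrow(calls), n_true = length(truth$substrates))
}

new_cutoff_curve <- function(threshold, num, den, denominator_kind) {
  pct <- ifelse(den > 0, 100 * num / den, NA_real_)
  if (anyNA(pct)) {
    message(sum(is.na(pct)),
            " threshold(s) with empty denominator: percentage undefined (NA)")
  }
  structure(data.frame(threshold = threshold, percent_known = pct,
                       n_numerator = num, n_denominator = den),
            denominator_kind = denominator_kind,
            class = c("cutoff_curve", "data.frame"))
}

#' @export
print.cutoff_curve <- function(x, ...) {
  cat(sprintf("Cutoff curve (%% known, denominator = %s)\n",
              attr(x, "denominator_kind")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Percentage of known-substrate peptides by ratio cutoff
#'
#' For each cutoff `c`, among peptides with `log2_ratio >= c`, the
#' percentage whose accession belongs to the known-substrate reference set.
#' Used to optimize the ratio cutoff against a curated database of
#' substrates.
#'
#' @param table A [quant_table()].
#' @param known Character vector of known-substrate accessions.
#' @param cutoffs Numeric vector of log2 ratio cutoffs.
#' @return A `cutoff_curve` data frame (`threshold`, `percent_known`,
#'   `n_numerator`, `n_denominator`); an empty denominator yields `NA`.
#' @export
known_percentage_by_ratio_cutoff <- function(table, known, cutoffs) {
  stopifnot(length(cutoffs) > 0)
  num <- den <- integer(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    sel <- table$log2_ratio >= cutoffs[i]
    den[i] <- sum(sel)
    num[i] <- sum(sel & table$accession %in% known)
  }
  new_cutoff_curve(cutoffs, num, den, "peptides")
}

#' Percentage of known substrates by supporting-peptide minimum
#'
#' At a fixed ratio cutoff, for each peptide-count minimum `m`, among
#' proteins with at least `m` distinct passing peptides, the percentage in
#' the known-substrate reference set. Used to optimize the peptide-count
#' criterion.
#'
#' @param table A [quant_table()].
#' @param known Character vector of known-substrate accessions.
#' @param log2_cutoff Inclusive log2 ratio cutoff (default 1.8).
#' @param count_minima Integer vector of peptide-count minima.
#' @return A `cutoff_curve` data frame with protein denominators.
#' @export
known_percentage_by_count <- function(table, known, log2_cutoff = 1.8,
                                      count_minima = 1:10) {
  stopifnot(length(count_minima) > 0)
  counts <- passing_peptide_counts(
    table[table$log2_ratio >= log2_cutoff, , drop = FALSE])
  num <- den <- integer(length(count_minima))
  for (i in seq_along(count_minima)) {
    acc <- names(counts)[counts >= count_minima[i]]
    den[i] <- length(acc)
    num[i] <- sum(acc %in% known)
  }
  new_cutoff_curve(as.integer(count_minima), num, den, "proteins")
}

#' Write a substrate-call table or cutoff curve as TSV
#'
#' @param x A `substrate_calls` or `cutoff_curve` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
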