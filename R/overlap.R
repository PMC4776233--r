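# Set-overlap arithmetic between substrate calls and reference datasets
# (known-substrate databases, in vivo degradome lists).

new_overlap_result <- function(size_a, size_b, intersection) {
  un <- size_a + size_b - intersection
  structure(list(size_a = size_a, size_b = size_b,
                 intersection = intersection, union = un,
                 pct_of_a = if (size_a > 0) 100 * intersection / size_a
                            else NA_real_,
                 pct_of_b = if (size_b > 0) 100 * intersection / size_b
                            else NA_real_,
                 jaccard_pct = if (un > 0) 100 * intersection / un
                               else NA_real_),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap: |A| = %d, |B| = %d, |A ∩ B| = %d\n",
              x$size_a, x$size_b, x$intersection))
  cat(sprintf("  %.1f%% of A, %.1f%% of B, Jaccard %.1f%%\n",
              x$pct_of_a, x$pct_of_b, x$jaccard_pct))
  invisible(x)
}

#' Overlap between two accession sets
#'
#' Exact set arithmetic; percentages are kept as raw doubles and rounded to
#' one decimal only when printed.
#'
#' @param set_a,set_b Character vectors of accessions (deduplicated
#'   internally after whitespace stripping; no identifier mapping is
#'   attempted).
#' @return An `overlap_result`: `size_a`, `size_b`, `intersection`, `union`,
#'   `pct_of_a`, `pct_of_b`, `jaccard_pct`.
#' @export
overlap <- function(set_a, set_b) {
  a <- unique(trimws(as.character(set_a)))
  b <- unique(trimws(as.character(set_b)))
  new_overlap_result(length(a), length(b), length(intersect(a, b)))
}

#' Overlap reconstructed from printed counts
#'
#' When only the set sizes and the union size are reported, the
#' intersection follows from inclusion-exclusion.
#'
#' @param size_a,size_b Set sizes.
#' @param union_size Size of the union; must satisfy
#'   `max(size_a, size_b) <= union_size <= size_a + size_b`.
#' @return An `overlap_result`.
#' @examples
#' overlap_from_counts(762, 517, 1064)  # two in vivo degradome studies
#' @export
overlap_from_counts <- function(size_a, size_b, union_size) {
  if (union_size > size_a + size_b || union_size < max(size_a, size_b)) {
    stop("inconsistent counts: union must lie in [max(|A|,|B|), |A|+|B|]",
         call. = FALSE)
  }
  new_overlap_result(size_a, size_b, size_a + size_b - union_size)
}

#' Per-tier overlap of substrate calls with an in vivo reference
#'
#' Computes, separately for hot and warm calls and combined, the share of
#' called substrates present in the reference set (e.g. proteins observed
#' to be degraded during apoptosis).
#'
#' @param calls A [call_substrates()] result.
#' @param invivo Character vector of reference accessions.
#' @return List of `overlap_result`s named `hot`, `warm`, `combined`; a tier
#'   with no members is `NULL` (with a message).
#' @export
stratified_overlap <- function(calls, invivo) {
  one <- function(acc, label) {
    if (!length(acc)) {
      message("tier '", label, "' has no members: overlap undefined")
      return(NULL)
    }
    overlap(acc, invivo)
  }
  list(hot = one(calls$accession[calls$tier == "hot"], "hot"),
       warm = one(calls$accession[calls$tier == "warm"], "warm"),
       combined = one(calls$accession, "combined"))
}
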