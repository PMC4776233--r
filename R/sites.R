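# Cleavage-site analysis. Every non-terminal peptide boundary reads out one
# cleavage site: the N-side site sits at start-1 (its P1 is the preceding
# residue), the C-side site at end (P1 is the peptide's last residue).
# Cleavage occurs between P1 and P1'. Sites with P1 in {K, R} and a
# non-proline successor are attributed to trypsin; P1 = D sites to the
# caspase; the remainder to other/background proteolysis.

#' Classify the enzyme generating a cleavage site
#'
#' @param p1 P1 residue(s) (the residue N-terminal of the scissile bond).
#' @param following P1' residue(s) (the residue C-terminal of the bond).
#' @return `"tryptic"` when P1 is K or R and P1' is not P; else
#'   `"aspartate"` when P1 is D; else `"other"`.
#' @examples
#' classify_site("R", "S")  # tryptic
#' classify_site("D", "A")  # aspartate
#' classify_site("K", "P")  # other: proline blocks trypsin
#' @export
classify_site <- function(p1, following) {
  ifelse(p1 %in% c("K", "R") & following != "P", "tryptic",
         ifelse(p1 == "D", "aspartate", "other"))
}

#' Sequence context of a cleavage site
#'
#' The field's dot notation: the 5 residues ending at P1, a `.`, and the 5
#' residues from P1' on, padded with `-` where the window runs past a
#' protein end (e.g. `PPEKD.GFPSG`).
#'
#' @param protein_sequence Protein string.
#' @param position 1-based P1 position, in `[1, length - 1]`.
#' @return An 11-character context string.
#' @export
site_context <- function(protein_sequence, position) {
  L <- nchar(protein_sequence)
  if (any(position < 1L | position >= L)) {
    stop("`position` must lie in [1, protein length - 1]", call. = FALSE)
  }
  vapply(position, function(p) {
    left <- substring(protein_sequence, max(1L, p - 4L), p)
    right <- substring(protein_sequence, p + 1L, min(L, p + 5L))
    paste0(strrep("-", 5L - nchar(left)), left, ".",
           right, strrep("-", 5L - nchar(right)))
  }, character(1))
}

#' Caspase DXXD motif family of an aspartate site
#'
#' Examines P4-P1, the four residues ending at the cleavage position: the
#' site carries a DXXD motif when both P4 and P1 are aspartate. Sub-families
#' are fixed by P3 (DEXD, DLXD, DDXD) and are mutually exclusive; a DXXD
#' with any other P3 is reported as plain `"DXXD"`. Sites whose P4 falls
#' outside the protein are `"none"`.
#'
#' @param protein_sequence Protein string.
#' @param position 1-based P1 position of an aspartate site.
#' @return One of `"DEXD"`, `"DLXD"`, `"DDXD"`, `"DXXD"`, `"none"`.
#' @export
motif_class <- function(protein_sequence, position) {
  vapply(position, function(p) {
    if (p < 4L) return("none")
    w <- substring(protein_sequence, p - 3L, p)
    if (substring(w, 1L, 1L) != "D" || substring(w, 4L, 4L) != "D") {
      return("none")
    }
    switch(substring(w, 2L, 2L),
           E = "DEXD", L = "DLXD", D = "DDXD", "DXXD")
  }, character(1))
}

#' Extract unique cleavage sites from up-regulated peptides
#'
#' Each peptide reads out up to two sites: the N-side site at `start - 1`
#' (skipped for protein N-terminal peptides) and the C-side site at `end`
#' (skipped for protein C-terminal peptides) — terminal peptide boundaries
#' are flush with the protein and carry no cleavage information. Sites are
#' deduplicated on (accession, position); a boundary read from both sides
#' keeps the `n_side` record.
#'
#' @param table A [quant_table()]; typically already filtered to
#'   up-regulated peptides, otherwise pass `log2_cutoff`.
#' @param proteome A [proteome()].
#' @param log2_cutoff Optional inclusive log2 ratio filter applied before
#'   extraction (`NULL` keeps all rows).
#' @return A `cleavage_sites` data frame with columns `accession`,
#'   `position`, `p1`, `enzyme_class`, `context`, `motif_family`,
#'   `source_terminus`, ordered by accession and position.
#' @export
extract_sites <- function(table, proteome, log2_cutoff = NULL) {
  if (!is.null(log2_cutoff)) {
    table <- table[table$log2_ratio >= log2_cutoff, , drop = FALSE]
  }
  seqs <- proteome_lookup(proteome, table$accession)
  if (nrow(table) &&
      any(substring(seqs, table$start, table$end) != table$sequence)) {
    stop("peptide rows violate the substring invariant against the proteome",
         call. = FALSE)
  }
  lens <- nchar(seqs)
  n_ok <- table$start > 1L
  c_ok <- table$end < lens
  sites <- data.frame(
    accession = c(table$accession[n_ok], table$accession[c_ok]),
    position = c(table$start[n_ok] - 1L, table$end[c_ok]),
    source_terminus = rep(c("n_side", "c_side"), c(sum(n_ok), sum(c_ok))),
    stringsAsFactors = FALSE)
  # value-based preference makes the result order-invariant
  sites <- sites[order(sites$accession, sites$position,
                       match(sites$source_terminus, c("n_side", "c_side"))), ,
                 drop = FALSE]
  sites <- sites[!duplicated(sites[, c("accession", "position")]), ,
                 drop = FALSE]
  pseq <- proteome_lookup(proteome, sites$accession)
  sites$p1 <- substring(pseq, sites$position, sites$position)
  sites$enzyme_class <- classify_site(
    sites$p1, substring(pseq, sites$position + 1L, sites$position + 1L))
  sites$context <- if (nrow(sites)) {
    mapply(site_context, pseq, sites$position, USE.NAMES = FALSE)
  } else character()
  sites$motif_family <- if (nrow(sites)) {
    ifelse(sites$enzyme_class == "aspartate",
           mapply(motif_class, pseq, sites$position, USE.NAMES = FALSE),
           "none")
  } else character()
  sites <- sites[, c("accession", "position", "p1", "enzyme_class",
                     "context", "motif_family", "source_terminus")]
  rownames(sites) <- NULL
  structure(sites, class = c("cleavage_sites", "data.frame"))
}

#' Position frequency matrix over cleavage-site contexts
#'
#' Builds the per-position residue frequencies across site context windows
#' (P5..P1, P1'..P5'); the end-padding sentinel `-` is counted as its own
#' category, so every column sums to 1. The matrix is what a sequence-logo
#' renderer consumes.
#'
#' @param sites A [extract_sites()] result (at least one site).
#' @return A 21 x 10 matrix (20 residues + `-`), columns `P5`..`P1`,
#'   `P1'`..`P5'`, class `bbc_pfm`.
#' @export
build_pfm <- function(sites) {
  if (nrow(sites) == 0L) stop("no sites: cannot build a PFM", call. = FALSE)
  win <- paste0(substr(sites$context, 1L, 5L),
                substr(sites$context, 7L, 11L))
  mat <- matrix(unlist(strsplit(win, "")), ncol = 10L, byrow = TRUE)
  lev <- c(AA20, "-")
  pfm <- apply(mat, 2L, function(col) {
    as.vector(table(factor(col, levels = lev))) / length(col)
  })
  dimnames(pfm) <- list(residue = lev,
                        position = c(paste0("P", 5:1),
                                     paste0("P", 1:5, "'")))
  structure(pfm, class = c("bbc_pfm", class(pfm)))
}

#' Write a position frequency matrix as TSV
#'
#' Residues as rows, positions P5..P5' as columns; consumable by logo
#' renderers.
#'
#' @param pfm A [build_pfm()] matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(residue = rownames(pfm), unclass(pfm),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize extracted cleavage sites
#'
#' @param sites A [extract_sites()] result.
#' @param substrates Optional accessions of called substrates used as the
#'   denominator of the "substrates with at least one D site" fraction;
#'   defaults to the accessions present in `sites`.
#' @return A `site_summary` list: per-enzyme-class counts and fractions,
#'   unique aspartate-site count, DXXD family counts, and the count and
#'   fraction of substrates carrying at least one aspartate site.
#' @export
summarize_sites <- function(sites, substrates = NULL) {
  if (is.null(substrates)) substrates <- unique(sites$accession)
  cls <- factor(sites$enzyme_class,
                levels = c("tryptic", "aspartate", "other"))
  n_class <- c(table(cls))
  asp <- sites[sites$enzyme_class == "aspartate", , drop = FALSE]
  fam <- c(table(factor(asp$motif_family,
                        levels = c("DEXD", "DLXD", "DDXD", "DXXD", "none"))))
  n_dxxd <- sum(fam[c("DEXD", "DLXD", "DDXD", "DXXD")])
  with_d <- intersect(substrates, unique(asp$accession))
  structure(list(
    n_sites = nrow(sites),
    class_counts = n_class,
    class_fractions = if (nrow(sites)) n_class / nrow(sites) else n_class,
    n_aspartate = nrow(asp),
    dxxd_counts = fam[c("DEXD", "DLXD", "DDXD", "DXXD")],
    dxxd_fraction = if (nrow(asp)) n_dxxd / nrow(asp) else NA_real_,
    n_substrates = length(substrates),
    n_substrates_with_d_site = length(with_d),
    frac_substrates_with_d_site =
      if (length(substrates)) length(with_d) / length(substrates)
      else NA_real_
  ), class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat(sprintf("Cleavage sites: %d unique\n", x$n_sites))
  f <- 100 * x$class_fractions
  cat(sprintf("  tryptic %d (%.1f%%), aspartate %d (%.1f%%), other %d (%.1f%%)\n",
              x$class_counts["tryptic"], f["tryptic"],
              x$class_counts["aspartate"], f["aspartate"],
              x$class_counts["other"], f["other"]))
  cat(sprintf("  DXXD motifs among D sites: %.1f%% (DEXD %d, DLXD %d, DDXD %d, other DXXD %d)\n",
              100 * x$dxxd_fraction, x$dxxd_counts["DEXD"],
              x$dxxd_counts["DLXD"], x$dxxd_counts["DDXD"],
              x$dxxd_counts["DXXD"]))
  cat(sprintf("  substrates with >= 1 D site: %d of %d (%.1f%%)\n",
              x$n_substrates_with_d_site, x$n_substrates,
              100 * x$frac_substrates_with_d_site))
  invisible(x)
}

#' Precision of recovered aspartate sites against planted truth
#'
#' @param sites A [extract_sites()] result.
#' @param truth A [ground_truth()].
#' @return List with `precision`, `recall`, `n_recovered`, `n_true` for the
#'   aspartate-class sites.
#' @export
site_recovery <- function(sites, truth) {
  asp <- sites[sites$enzyme_class == "aspartate", , drop = FALSE]
  key <- function(a, p) paste(a, p)
  rec <- key(asp$accession, asp$position)
  tru <- key(truth$sites$accession, truth$sites$position)
  tp <- sum(rec %in% tru)
  list(precision = if (length(rec)) tp / length(rec) else NA_real_,
       recall = if (length(tru)) tp / length(tru) else NA_real_,
       n_recovered = length(rec), n_true = length(tru))
}
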