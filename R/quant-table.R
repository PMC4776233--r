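# Quantified-peptide table: the atom of the screen. One row per quantified
# peptide with its heavy/light ratio (H/L = protease treated / untreated),
# its location in the parent protein, and the flanking residues.

#' Construct a quantified-peptide table
#'
#' @param rows Data frame with columns `sequence`, `accession`, `start`,
#'   `end`, `ratio_hl`, `log2_ratio`, `preceding`, `following` (extra
#'   columns are kept).
#' @param provenance Free-text origin of the table.
#' @return A `quant_table` (a data frame with a `provenance` attribute).
#' @export
quant_table <- function(rows, provenance = "") {
  needed <- c("sequence", "accession", "start", "end", "ratio_hl",
              "log2_ratio", "preceding", "following")
  miss <- setdiff(needed, names(rows))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rows[, c("sequence", "accession", "start")])) {
    stop("duplicate (sequence, accession, start) rows", call. = FALSE)
  }
  if (nrow(rows)) {
    stopifnot(all(rows$ratio_hl > 0),
              all(abs(rows$log2_ratio - log2(rows$ratio_hl)) < 1e-9),
              all(rows$start >= 1L), all(rows$end >= rows$start),
              all(nchar(rows$preceding) == 1L),
              all(nchar(rows$following) == 1L))
  }
  structure(as.data.frame(rows), provenance = provenance,
            class = c("quant_table", "data.frame"))
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("Quantified peptide table: %d peptides, %d proteins\n",
              nrow(x), length(unique(x$accession))))
  if (nrow(x)) {
    cat(sprintf("  log2(H/L): median %.2f, %.1f%% above 1\n",
                stats::median(x$log2_ratio),
                100 * mean(x$log2_ratio > 1)))
  }
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("  provenance:", prov, "\n")
  invisible(x)
}

#' Locate a peptide within one protein
#'
#' @param sequence Peptide string (non-empty).
#' @param protein_sequence Protein string (non-empty).
#' @return Integer vector of all 1-based exact-match start positions, in
#'   increasing order; overlapping matches are all reported. Empty if no
#'   match.
#' @examples
#' map_peptide("AA", "AAAA")  # 1 2 3
#' @export
map_peptide <- function(sequence, protein_sequence) {
  stopifnot(nzchar(sequence), nzchar(protein_sequence))
  n <- nchar(sequence)
  L <- nchar(protein_sequence)
  if (n > L) return(integer())
  starts <- seq_len(L - n + 1L)
  starts[substring(protein_sequence, starts, starts + n - 1L) == sequence]
}

flank_before <- function(seq, start) {
  ifelse(start == 1L, "-", substring(seq, start - 1L, start - 1L))
}

flank_after <- function(seq, end) {
  L <- nchar(seq)
  ifelse(end == L, "-", substring(seq, end + 1L, end + 1L))
}

#' Read a quantified-peptide table
#'
#' Reads a tab-separated table with mandatory columns `sequence`,
#' `accession`, `ratio_hl` and optional `start`, and annotates each row
#' against the protein library: `end`, `log2_ratio` and the flanking
#' residues are (re)computed. Rows with unknown accessions, non-positive
#' ratios, or peptides that cannot be located in their protein are dropped
#' with a message; when `start` is absent a peptide matching at several
#' positions takes the smallest (with a warning).
#'
#' @param path Path to the TSV file.
#' @param proteome A [proteome()] the peptides are mapped against.
#' @param invert_ratio Set `TRUE` for tables whose ratio is oriented
#'   untreated/treated; ratios are reciprocated on input.
#' @return A [quant_table()].
#' @export
read_quant_table <- function(path, proteome, invert_ratio = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  needed <- c("sequence", "accession", "ratio_hl")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) {
    stop("quant table ", path, " lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n0 <- nrow(raw)
  raw$ratio_hl <- as.numeric(raw$ratio_hl)
  if (invert_ratio) raw$ratio_hl <- 1 / raw$ratio_hl
  keep <- !is.na(raw$ratio_hl) & raw$ratio_hl > 0
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped: non-positive or missing ratio")
  }
  raw <- raw[keep, , drop = FALSE]

  known <- raw$accession %in% proteome$accession
  if (any(!known)) {
    message(sum(!known), " row(s) dropped: accession not in proteome")
  }
  raw <- raw[known, , drop = FALSE]
  seqs <- proteome_lookup(proteome, raw$accession)

  if (!"start" %in% names(raw)) raw$start <- NA_integer_
  raw$start <- as.integer(raw$start)
  multi <- 0L
  for (i in which(is.na(raw$start))) {
    hits <- map_peptide(raw$sequence[i], seqs[i])
    if (length(hits) > 1L) multi <- multi + 1L
    raw$start[i] <- if (length(hits)) hits[1L] else NA_integer_
  }
  if (multi) {
    warning(multi, " peptide(s) matched at multiple positions; ",
            "smallest start used", call. = FALSE)
  }
  raw$end <- raw$start + nchar(raw$sequence) - 1L
  located <- !is.na(raw$start) & raw$start >= 1L &
    raw$end <= nchar(seqs) &
    substring(seqs, raw$start, raw$end) == raw$sequence
  if (any(!located)) {
    message(sum(!located), " row(s) dropped: peptide not located in protein")
  }
  raw <- raw[located, , drop = FALSE]
  seqs <- seqs[located]

  raw$log2_ratio <- log2(raw$ratio_hl)
  raw$preceding <- flank_before(seqs, raw$start)
  raw$following <- flank_after(seqs, raw$end)
  rownames(raw) <- NULL
  quant_table(raw, provenance = sprintf("%s (%d of %d rows kept)",
                                        path, nrow(raw), n0))
}

#' Write a quantified-peptide table
#'
#' Writes the core tab-separated schema (`sequence`, `accession`, `start`,
#' `ratio_hl`); the remaining fields are recomputed on read against the
#' protein library.
#'
#' @param table A [quant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path) {
  utils::write.table(table[, c("sequence", "accession", "start", "ratio_hl")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference accession list
#'
#' One accession per line; blank lines and `#` comments are ignored;
#' duplicates collapse. Used for known-substrate databases (CASBAH-style)
#' and in vivo degradome lists.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of unique accessions.
#' @export
read_accession_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}
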