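# Protein library container and FASTA I/O.

#' Construct a protein library
#'
#' A proteome is the screening library of the bead-based cleavage (BBC)
#' experiment: a set of protein records, each an accession plus an
#' amino-acid sequence over the 20 canonical residues.
#'
#' @param accession Character vector of unique identifiers.
#' @param sequence Character vector of uppercase amino-acid sequences
#'   (canonical residues only), same length as `accession`.
#' @return A `bbc_proteome`: a data frame with columns `accession` and
#'   `sequence`.
#' @examples
#' proteome(c("P1", "P2"), c("MKAD", "MDEVDGK"))
#' @export
proteome <- function(accession, sequence) {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  if (length(accession) != length(sequence)) {
    stop("`accession` and `sequence` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(accession)) {
    stop("duplicate accessions: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(sequence) && any(!nzchar(sequence))) {
    stop("empty sequence for accession ",
         paste(accession[!nzchar(sequence)], collapse = ", "), call. = FALSE)
  }
  bad <- !is_canonical_sequence(sequence)
  if (length(sequence) && any(bad)) {
    stop("non-canonical residues in sequence of ",
         paste(accession[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    data.frame(accession = accession, sequence = sequence,
               stringsAsFactors = FALSE),
    class = c("bbc_proteome", "data.frame")
  )
}

#' @export
print.bbc_proteome <- function(x, ...) {
  cat(sprintf("Protein library: %d sequences", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", lengths %d-%d (median %d)",
                min(nchar(x$sequence)), max(nchar(x$sequence)),
                as.integer(stats::median(nchar(x$sequence)))))
  }
  cat("\n")
  invisible(x)
}

proteome_lookup <- function(proteome, accession) {
  idx <- match(accession, proteome$accession)
  if (anyNA(idx)) {
    stop("accession(s) not in proteome: ",
         paste(unique(accession[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  proteome$sequence[idx]
}

#' Read a protein library from a FASTA file
#'
#' The accession is the first whitespace-delimited token of each header.
#' Sequences are uppercased and validated against the canonical 20-letter
#' alphabet; duplicate accessions and illegal residues are rejected with the
#' offending line number.
#'
#' @param path Path to a FASTA file.
#' @return A [proteome()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) return(proteome(character(), character()))
  acc <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  seqs <- toupper(as.character(set))
  if (anyDuplicated(acc) || any(!is_canonical_sequence(seqs)) ||
      any(!nzchar(acc))) {
    fasta_validation_error(path)          # re-scan to name the line
  }
  proteome(acc, seqs)
}

# Scan the raw file to attribute a validation failure to a line number.
fasta_validation_error <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seen <- character()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      acc <- strsplit(sub("^>", "", ln), "[ \t]+")[[1]][1]
      if (is.na(acc) || !nzchar(acc)) {
        stop(sprintf("%s:%d: FASTA header with empty accession", path, i),
             call. = FALSE)
      }
      if (acc %in% seen) {
        stop(sprintf("%s:%d: duplicate accession '%s'", path, i, acc),
             call. = FALSE)
      }
      seen <- c(seen, acc)
    } else if (nzchar(ln) && !is_canonical_sequence(toupper(gsub("\\s", "", ln)))) {
      stop(sprintf("%s:%d: illegal residue in sequence line", path, i),
           call. = FALSE)
    }
  }
  stop("invalid FASTA: ", path, call. = FALSE)
}

#' Write a protein library as FASTA
#'
#' @param proteome A [proteome()].
#' @param path Output path; sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  set <- Biostrings::BStringSet(stats::setNames(proteome$sequence,
                                                proteome$accession))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
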