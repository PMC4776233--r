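# Independent oracles kept deliberately naive.

# Brute-force tryptic digestion: enumerate every substring and keep those
# whose termini and interior satisfy the KR/P rule with <= max_missed
# internal missed cleavages.
brute_force_digest <- function(fragment, max_missed) {
  n <- nchar(fragment)
  ch <- strsplit(fragment, "")[[1]]
  is_cut <- function(i) i >= 1 && i < n && ch[i] %in% c("K", "R") &&
    ch[i + 1] != "P"
  out <- character()
  for (s in 1:n) {
    for (e in s:n) {
      if ((s == 1 || is_cut(s - 1)) && (e == n || is_cut(e))) {
        internal <- if (e > s) sum(vapply(s:(e - 1), is_cut, logical(1)))
                    else 0L
        if (internal <= max_missed) {
          out <- c(out, substring(fragment, s, e))
        }
      }
    }
  }
  sort(out)
}

# Brute-force release: partition at cuts, test attachment membership.
brute_force_release <- function(L, cuts, attachments) {
  cuts <- sort(unique(cuts))
  bounds <- c(0, cuts, L)
  frags <- list()
  for (i in seq_len(length(bounds) - 1)) {
    s <- bounds[i] + 1
    e <- bounds[i + 1]
    if (!any(attachments %in% s:e)) frags[[length(frags) + 1]] <- c(s, e)
  }
  frags
}

random_sequence <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

# Minimal in-memory quant table from parallel vectors, against a proteome.
toy_quant_table <- function(lib, sequence, accession, start, ratio) {
  seqs <- lib$sequence[match(accession, lib$accession)]
  end <- start + nchar(sequence) - 1L
  stopifnot(substring(seqs, start, end) == sequence)
  quant_table(data.frame(
    sequence = sequence, accession = accession, start = start, end = end,
    ratio_hl = ratio, log2_ratio = log2(ratio),
    preceding = ifelse(start == 1L, "-",
                       substring(seqs, start - 1L, start - 1L)),
    following = ifelse(end == nchar(seqs), "-",
                       substring(seqs, end + 1L, end + 1L)),
    stringsAsFactors = FALSE))
}

# Random table of passing/failing peptides over fake proteins; used by the
# monotonicity properties. Peptides are synthetic labels on a synthetic
# library where sequence content does not matter for counting.
random_quant_table <- function(n_proteins = 20, n_peptides = 200) {
  lib <- proteome(sprintf("RP%03d", seq_len(n_proteins)),
                  vapply(rep(60, n_proteins),
                         function(L) random_sequence(L), ""))
  acc <- sample(lib$accession, n_peptides, replace = TRUE)
  seqs <- lib$sequence[match(acc, lib$accession)]
  start <- sample(1:50, n_peptides, replace = TRUE)
  len <- sample(7:10, n_peptides, replace = TRUE)
  pep <- substring(seqs, start, start + len - 1L)
  ratio <- 2^rnorm(n_peptides, 1.5, 1.5)
  df <- data.frame(sequence = pep, accession = acc, start = start,
                   ratio_hl = ratio, stringsAsFactors = FALSE)
  df <- df[!duplicated(df[, c("sequence", "accession", "start")]), ]
  df$end <- df$start + nchar(df$sequence) - 1L
  df$log2_ratio <- log2(df$ratio_hl)
  seqs <- lib$sequence[match(df$accession, lib$accession)]
  df$preceding <- ifelse(df$start == 1L, "-",
                         substring(seqs, df$start - 1L, df$start - 1L))
  df$following <- ifelse(df$end == nchar(seqs), "-",
                         substring(seqs, df$end + 1L, df$end + 1L))
  quant_table(df)
}
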