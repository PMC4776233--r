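#' Worked example: canonical caspase-3 cleavage contexts
#'
#' Three well-characterized caspase-3 cleavage events — PAK2 D148
#' (`PPEKD.GFPSGTPALNAK.GTEAP`), PAK2 D212
#' (`SIYTR.SVIDPVPAPVGDSHVD.GAAKS`) and BCAS2 D14
#' (`EVVVD.ALPYFDQGYEAPGVR.EAAAA`) — embedded at their native residue
#' numbering in synthetic carrier sequences (the flanking regions outside
#' the published context windows are filler, not the real proteins), plus
#' the reported fold changes of the three semi-tryptic peptides (5.85,
#' 35.85 and 10.18). Useful as a hand-checkable demonstration of site
#' extraction, enzyme classification and the dual-threshold criteria.
#'
#' @return List with `proteome` (a [proteome()] of two synthetic carriers,
#'   `PAK2_SYN` and `BCAS2_SYN`) and `table` (a [quant_table()] with the
#'   three peptides).
#' @examples
#' ex <- caspase_context_examples()
#' extract_sites(ex$table, ex$proteome, log2_cutoff = 1.8)
#' @export
caspase_context_examples <- function() {
  place <- function(base, at, what) {
    substr(base, at, at + nchar(what) - 1L) <- what
    base
  }
  pak2 <- strrep("A", 230L)
  pak2 <- place(pak2, 144L, "PPEKDGFPSGTPALNAKGTEAP")
  pak2 <- place(pak2, 192L, "SIYTRSVIDPVPAPVGDSHVDGAAKS")
  bcas2 <- place(strrep("G", 40L), 10L, "EVVVDALPYFDQGYEAPGVREAAAA")
  substr(bcas2, 1L, 1L) <- "M"
  lib <- proteome(c("PAK2_SYN", "BCAS2_SYN"), c(pak2, bcas2))

  pep <- data.frame(
    sequence = c("GFPSGTPALNAK", "SVIDPVPAPVGDSHVD", "ALPYFDQGYEAPGVR"),
    accession = c("PAK2_SYN", "PAK2_SYN", "BCAS2_SYN"),
    start = c(149L, 197L, 15L),
    ratio_hl = c(5.85, 35.85, 10.18),
    stringsAsFactors = FALSE)
  pep$end <- pep$start + nchar(pep$sequence) - 1L
  pep$log2_ratio <- log2(pep$ratio_hl)
  seqs <- proteome_lookup(lib, pep$accession)
  pep$preceding <- flank_before(seqs, pep$start)
  pep$following <- flank_after(seqs, pep$end)
  list(proteome = lib,
       table = quant_table(pep, provenance = "caspase_context_examples()"))
}
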