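# Canonical amino-acid alphabet and background composition used by the
# simulator (Swiss-Prot average residue frequencies, renormalized).

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_BACKGROUND_FREQ <- local({
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.46, C = 1.38, Q = 3.93,
         E = 6.72, G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80,
         M = 2.41, F = 3.86, P = 4.74, S = 6.65, T = 5.36, W = 1.10,
         Y = 2.92, V = 6.86)
  f <- f[AA20]
  f / sum(f)
})

#' Background amino-acid frequencies used by the proteome simulator
#'
#' Average residue composition (Swiss-Prot style) from which random protein
#' sequences, and the `X` positions of planted cleavage motifs, are drawn.
#'
#' @return Named numeric vector over the 20 canonical residues, summing to 1.
#' @export
aa_background <- function() AA_BACKGROUND_FREQ

is_canonical_sequence <- function(x) {
  grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), x)
}
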