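#' Parameters of the simulated bead-based cleavage experiment
#'
#' Bundles every knob of the synthetic degradome generator: the size and
#' composition of the protein library, how many proteins are true protease
#' substrates and how many sites each carries, the P4-P1 motifs planted at
#' those sites, the bead-coupling chemistry, background (endogenous)
#' proteolysis shared by the treated and control arms, the tryptic digestion
#' window, and the heavy/light ratio noise model.
#'
#' @param n_proteins Number of proteins in the library.
#' @param length_mean,length_sd Normal distribution of protein lengths in
#'   residues; draws are truncated below at 50.
#' @param substrate_fraction Probability that a protein is a true substrate.
#' @param sites_per_substrate_mean Expected planted cleavage sites per
#'   substrate; counts follow a shifted Poisson (always at least 1).
#' @param motif_weights Named probability vector over planted P4-P1 motifs.
#'   Motif strings are 4 characters over the amino-acid alphabet plus `X`
#'   (an `X` is drawn from [aa_background()]); the last character must be
#'   `D` so every planted P1 is an aspartate.
#' @param coupling_prob Per-primary-amine probability of covalent bead
#'   attachment (protein N-terminus and every lysine, independently).
#' @param background_rate Per-peptide-bond probability of endogenous
#'   (non-specific) cleavage, applied identically to both arms.
#' @param cleavage_efficiency Probability that a planted site is actually
#'   cut in the protease-treated arm.
#' @param log2_bg_sd Standard deviation of log2 ratios for peptides present
#'   in both arms (background population, centered at 0).
#' @param log2_sub_mean,log2_sub_sd Location and scale of log2 ratios for
#'   peptides detected only in the treated arm (substrate population).
#' @param max_missed_cleavages Maximum missed tryptic cleavages per peptide.
#' @param min_pep_len,max_pep_len Detectability window in residues.
#' @param seed Integer seed; identical parameters give byte-identical output.
#' @return A validated `sim_params` list.
#' @seealso [simulate_experiment()]
#' @export
sim_params <- function(n_proteins = 300L,
                       length_mean = 400,
                       length_sd = 120,
                       substrate_fraction = 0.15,
                       sites_per_substrate_mean = 4,
                       motif_weights = c(DEVD = 0.4, DELD = 0.2,
                                         DDXD = 0.2, DQXD = 0.2),
                       coupling_prob = 0.2,
                       background_rate = 0.001,
                       cleavage_efficiency = 0.9,
                       log2_bg_sd = 0.4,
                       log2_sub_mean = 3.0,
                       log2_sub_sd = 0.8,
                       max_missed_cleavages = 2L,
                       min_pep_len = 7L,
                       max_pep_len = 35L,
                       seed = 42L) {
  p <- list(n_proteins = as.integer(n_proteins),
            length_mean = length_mean, length_sd = length_sd,
            substrate_fraction = substrate_fraction,
            sites_per_substrate_mean = sites_per_substrate_mean,
            motif_weights = motif_weights,
            coupling_prob = coupling_prob,
            background_rate = background_rate,
            cleavage_efficiency = cleavage_efficiency,
            log2_bg_sd = log2_bg_sd,
            log2_sub_mean = log2_sub_mean, log2_sub_sd = log2_sub_sd,
            max_missed_cleavages = as.integer(max_missed_cleavages),
            min_pep_len = as.integer(min_pep_len),
            max_pep_len = as.integer(max_pep_len),
            seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  probs <- c("substrate_fraction", "coupling_prob", "background_rate",
             "cleavage_efficiency")
  for (nm in probs) {
    chk(is.numeric(p[[nm]]) && length(p[[nm]]) == 1 &&
          p[[nm]] >= 0 && p[[nm]] <= 1,
        sprintf("`%s` must be a probability in [0, 1]", nm))
  }
  chk(p$n_proteins >= 0, "`n_proteins` must be non-negative")
  chk(p$length_mean > 0 && p$length_sd >= 0,
      "`length_mean` must be positive and `length_sd` non-negative")
  chk(p$sites_per_substrate_mean >= 1,
      "`sites_per_substrate_mean` must be at least 1")
  chk(p$log2_bg_sd >= 0 && p$log2_sub_sd >= 0,
      "noise standard deviations must be non-negative")
  chk(p$max_missed_cleavages >= 0, "`max_missed_cleavages` must be >= 0")
  chk(p$min_pep_len >= 1 && p$max_pep_len >= p$min_pep_len,
      "peptide length window invalid")
  w <- p$motif_weights
  chk(is.numeric(w) && !is.null(names(w)) && all(w >= 0) && sum(w) > 0,
      "`motif_weights` must be a named non-negative vector with positive sum")
  chk(all(grepl(paste0("^[", paste(AA20, collapse = ""), "X]{3}D$"),
                names(w))),
      "motif names must be 4-mers over the amino-acid alphabet plus X, ending in D")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("BBC simulation parameters\n")
  cat(sprintf("  library: %d proteins, lengths ~ N(%g, %g) truncated at 50\n",
              x$n_proteins, x$length_mean, x$length_sd))
  cat(sprintf("  substrates: fraction %.2f, mean %.1f planted sites, motifs %s\n",
              x$substrate_fraction, x$sites_per_substrate_mean,
              paste(names(x$motif_weights), collapse = "/")))
  cat(sprintf("  chemistry: coupling %.2f per amine, background %.4g per bond, efficiency %.2f\n",
              x$coupling_prob, x$background_rate, x$cleavage_efficiency))
  cat(sprintf("  ratios: background sd %.2f, substrate N(%.1f, %.2f); seed %d\n",
              x$log2_bg_sd, x$log2_sub_mean, x$log2_sub_sd, x$seed))
  invisible(x)
}
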