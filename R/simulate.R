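# Synthetic degradome generator: emulates the wet-lab arms of the BBC
# experiment (immobilization, protease incubation, release, tryptic
# digestion, heavy/light quantification) on a random protein library with
# planted caspase substrates, and keeps the ground truth for
# parameter-recovery testing.

#' Generate a random protein library
#'
#' Lengths are drawn from a normal distribution truncated below at 50
#' residues; residues are drawn independently from [aa_background()].
#'
#' @param params A [sim_params()] object; uses `n_proteins`, `length_mean`,
#'   `length_sd` and `seed`.
#' @return A [proteome()] with accessions `SYN0001`, `SYN0002`, ...
#' @export
generate_proteome <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  n <- params$n_proteins
  if (n == 0L) return(proteome(character(), character()))
  lens <- pmax(50L, as.integer(round(stats::rnorm(n, params$length_mean,
                                                  params$length_sd))))
  seqs <- vapply(lens, function(L) {
    paste(sample(AA20, L, replace = TRUE, prob = AA_BACKGROUND_FREQ),
          collapse = "")
  }, character(1))
  proteome(sprintf("SYN%04d", seq_len(n)), seqs)
}

#' Ground truth of a simulated screen
#'
#' @param substrates Accessions of planted substrates.
#' @param sites Data frame with columns `accession` and `position` (1-based
#'   P1 residue of each planted cleavage site).
#' @param background_degraded Accessions that shed at least one
#'   background-released fragment.
#' @return A `bbc_truth` list.
#' @export
ground_truth <- function(substrates = character(),
                         sites = data.frame(accession = character(),
                                            position = integer()),
                         background_degraded = character()) {
  stopifnot(all(c("accession", "position") %in% names(sites)))
  if (!all(sites$accession %in% substrates)) {
    stop("every true site must belong to a planted substrate", call. = FALSE)
  }
  structure(list(substrates = sort(unique(substrates)),
                 sites = sites[order(sites$accession, sites$position), ,
                               drop = FALSE],
                 background_degraded = sort(unique(background_degraded))),
            class = "bbc_truth")
}

#' @export
print.bbc_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d substrates, %d planted sites, %d background-degraded proteins\n",
              length(x$substrates), nrow(x$sites),
              length(x$background_degraded)))
  invisible(x)
}

#' Plant caspase cleavage sites into a protein library
#'
#' A Bernoulli(`substrate_fraction`) subset of proteins becomes true
#' substrates. Each substrate receives at least one planted site (count is
#' a shifted Poisson with mean `sites_per_substrate_mean`) at uniformly
#' chosen internal positions; the four residues ending at the P1 position
#' are overwritten with a motif drawn from `motif_weights` (any `X` drawn
#' from the background composition), so every planted P1 is an aspartate.
#' Motif windows never overlap; placement of a site is retried a bounded
#' number of times and a protein with no placeable site is dropped from the
#' substrate set.
#'
#' Uses the current RNG state; [simulate_experiment()] seeds it.
#'
#' @param proteins A [proteome()].
#' @param params A [sim_params()].
#' @return List with elements `proteome` (edited sequences) and `truth`
#'   (a [ground_truth()] whose `background_degraded` is empty).
#' @export
plant_substrates <- function(proteins, params) {
  validate_sim_params(params)
  n <- nrow(proteins)
  seqs <- proteins$sequence
  is_sub <- stats::runif(n) < params$substrate_fraction
  acc_sub <- character()
  site_acc <- character()
  site_pos <- integer()
  w <- params$motif_weights / sum(params$motif_weights)
  for (i in which(is_sub)) {
    L <- nchar(seqs[i])
    n_sites <- 1L + stats::rpois(1L, params$sites_per_substrate_mean - 1)
    placed <- integer()
    for (s in seq_len(n_sites)) {
      for (try in seq_len(20L)) {
        # P1 position: motif occupies [p-3, p], cleavage between p and p+1
        p <- sample(4:(L - 1L), 1L)
        if (!any(abs(placed - p) < 4L)) { placed <- c(placed, p); break }
      }
    }
    if (!length(placed)) next
    motifs <- sample(names(w), length(placed), replace = TRUE, prob = w)
    for (k in seq_along(placed)) {
      m <- strsplit(motifs[k], "")[[1]]
      xs <- m == "X"
      if (any(xs)) {
        m[xs] <- sample(AA20, sum(xs), replace = TRUE,
                        prob = AA_BACKGROUND_FREQ)
      }
      substr(seqs[i], placed[k] - 3L, placed[k]) <- paste(m, collapse = "")
    }
    acc_sub <- c(acc_sub, proteins$accession[i])
    site_acc <- c(site_acc, rep(proteins$accession[i], length(placed)))
    site_pos <- c(site_pos, sort(placed))
  }
  list(proteome = proteome(proteins$accession, seqs),
       truth = ground_truth(acc_sub,
                            data.frame(accession = site_acc,
                                       position = site_pos,
                                       stringsAsFactors = FALSE)))
}

#' Fragments released from a bead-immobilized protein
#'
#' The protein is partitioned at all cut positions (cleavage occurs after
#' the P1 residue); a fragment is released into solution if and only if it
#' contains no bead-attachment residue.
#'
#' @param sequence_length Protein length in residues (or a single protein
#'   sequence, from which the length is taken).
#' @param cut_positions Integer vector of P1 positions (1 to length − 1).
#' @param attachment_positions Integer vector of covalently coupled residue
#'   indices (typically the N-terminal residue and a subset of lysines).
#' @return Data frame with columns `start` and `end` (1-based inclusive),
#'   one row per released fragment, in N-to-C order.
#' @export
simulate_release <- function(sequence_length, cut_positions,
                             attachment_positions = integer()) {
  L <- if (is.character(sequence_length)) nchar(sequence_length)
       else as.integer(sequence_length)
  cuts <- sort(unique(as.integer(cut_positions)))
  if (length(cuts) && (min(cuts) < 1L || max(cuts) >= L)) {
    stop("cut positions must lie in [1, length - 1]", call. = FALSE)
  }
  att <- as.integer(attachment_positions)
  bounds <- c(0L, cuts, L)
  start <- bounds[-length(bounds)] + 1L
  end <- bounds[-1L]
  keep <- vapply(seq_along(start), function(i) {
    !any(att >= start[i] & att <= end[i])
  }, logical(1))
  data.frame(start = start[keep], end = end[keep])
}

#' In-silico tryptic digestion of a fragment
#'
#' Cleaves after K or R except when the next residue is P (the trypsin
#' "KR/P" rule) and emits every peptide with at most `max_missed` internal
#' missed cleavages. The returned edge flags record whether a peptide
#' terminus coincides with a fragment edge, which is what makes
#' protease-generated (semi-tryptic) termini traceable downstream.
#'
#' @param fragment Amino-acid string (non-empty).
#' @param max_missed Maximum internal missed cleavages.
#' @return Data frame with columns `peptide`, `start_offset` (1-based within
#'   the fragment), `nterm_edge`, `cterm_edge`.
#' @examples
#' digest_tryptic("AAKAA", max_missed = 0)
#' digest_tryptic("AAKPAA", max_missed = 0)  # proline blocks the cut
#' @export
digest_tryptic <- function(fragment, max_missed = 2L) {
  if (!is.character(fragment) || length(fragment) != 1L || !nzchar(fragment)) {
    stop("`fragment` must be a single non-empty string", call. = FALSE)
  }
  n <- nchar(fragment)
  ch <- strsplit(fragment, "")[[1]]
  cuts <- if (n > 1L) {
    which(ch[-n] %in% c("K", "R") & ch[-1L] != "P")
  } else integer()
  bounds <- c(0L, cuts, n)
  nseg <- length(bounds) - 1L
  i <- rep(seq_len(nseg), times = pmin(nseg, seq_len(nseg) + max_missed) -
             seq_len(nseg) + 1L)
  j <- unlist(lapply(seq_len(nseg),
                     function(a) a:min(nseg, a + max_missed)))
  start <- bounds[i] + 1L
  end <- bounds[j + 1L]
  data.frame(peptide = substring(fragment, start, end),
             start_offset = start,
             nterm_edge = start == 1L,
             cterm_edge = end == n,
             stringsAsFactors = FALSE)
}

#' Simulate a full bead-based cleavage screen
#'
#' Orchestrates the whole in-silico experiment: random library generation,
#' substrate planting, per-amine bead attachment, a protease-treated arm
#' (planted sites cut with probability `cleavage_efficiency` plus uniform
#' background cuts) and a control arm (the same background cuts only),
#' fragment release, tryptic digestion within the detectability window, and
#' a per-peptide heavy/light ratio: peptides present in both arms take
#' ratio = treated/control occurrences with multiplicative log-normal noise
#' (`log2_bg_sd`); peptides detected only in the treated arm draw their
#' log2 ratio from N(`log2_sub_mean`, `log2_sub_sd`) capped at 10;
#' control-only peptides get the mirrored treatment floored at −10.
#'
#' @param params A [sim_params()].
#' @return List with elements `table` (a [quant_table()] carrying extra
#'   provenance columns: per-arm occurrence counts `n_ctrl`/`n_trt` and the
#'   logical `caspase_released` flag), `proteome` (the edited library) and
#'   `truth` (a [ground_truth()]).
#' @export
simulate_experiment <- function(params) {
  validate_sim_params(params)
  lib <- generate_proteome(params)   # seeds the RNG with params$seed
  planted <- plant_substrates(lib, params)
  lib <- planted$proteome
  truth <- planted$truth
  bg_degraded <- character()

  rows <- vector("list", nrow(lib))
  for (i in seq_len(nrow(lib))) {
    acc <- lib$accession[i]
    seq <- lib$sequence[i]
    L <- nchar(seq)
    ch <- strsplit(seq, "")[[1]]
    amines <- c(1L, which(ch == "K"))
    attach <- amines[stats::runif(length(amines)) < params$coupling_prob]
    bg_cuts <- which(stats::runif(L - 1L) < params$background_rate)
    site_p1 <- truth$sites$position[truth$sites$accession == acc]
    applied <- site_p1[stats::runif(length(site_p1)) <
                         params$cleavage_efficiency]
    treated_cuts <- sort(unique(c(bg_cuts, applied)))

    ctrl_frags <- simulate_release(L, bg_cuts, attach)
    trt_frags <- simulate_release(L, treated_cuts, attach)
    if (nrow(ctrl_frags) && length(bg_cuts)) {
      bg_degraded <- c(bg_degraded, acc)
    }

    ctrl <- digest_fragments(seq, ctrl_frags, params)
    trt <- digest_fragments(seq, trt_frags, params)
    if (nrow(trt)) {
      frag_caspase <- (trt_frags$start - 1L) %in% applied |
        trt_frags$end %in% applied
      trt$caspase <- frag_caspase[trt$frag_id]
    }
    rows[[i]] <- merge_arm_counts(acc, ctrl, trt)
  }
  tab <- do.call(rbind, rows[lengths(rows) > 0 & vapply(rows, NROW, 0L) > 0])
  truth$background_degraded <- sort(unique(bg_degraded))

  if (is.null(tab) || nrow(tab) == 0L) {
    qt <- quant_table(data.frame(sequence = character(),
                                 accession = character(),
                                 start = integer(), end = integer(),
                                 ratio_hl = numeric(),
                                 log2_ratio = numeric(),
                                 preceding = character(),
                                 following = character(),
                                 n_ctrl = integer(), n_trt = integer(),
                                 caspase_released = logical(),
                                 stringsAsFactors = FALSE),
                      provenance = "simulate_experiment (empty)")
    return(list(table = qt, proteome = lib, truth = truth))
  }

  # deterministic row order before drawing per-peptide noise
  tab <- tab[order(tab$accession, tab$start, tab$sequence), , drop = FALSE]
  both <- tab$n_ctrl > 0L & tab$n_trt > 0L
  trt_only <- tab$n_ctrl == 0L & tab$n_trt > 0L
  ctrl_only <- tab$n_trt == 0L & tab$n_ctrl > 0L
  log2r <- numeric(nrow(tab))
  log2r[both] <- log2(tab$n_trt[both] / tab$n_ctrl[both]) +
    stats::rnorm(sum(both), 0, params$log2_bg_sd)
  log2r[trt_only] <- pmin(10, stats::rnorm(sum(trt_only),
                                           params$log2_sub_mean,
                                           params$log2_sub_sd))
  log2r[ctrl_only] <- pmax(-10, -stats::rnorm(sum(ctrl_only),
                                              params$log2_sub_mean,
                                              params$log2_sub_sd))

  seqs <- proteome_lookup(lib, tab$accession)
  lens <- nchar(seqs)
  df <- data.frame(sequence = tab$sequence,
                   accession = tab$accession,
                   start = tab$start,
                   end = tab$end,
                   ratio_hl = 2^log2r,
                   log2_ratio = log2r,
                   preceding = ifelse(tab$start == 1L, "-",
                                      substring(seqs, tab$start - 1L,
                                                tab$start - 1L)),
                   following = ifelse(tab$end == lens, "-",
                                      substring(seqs, tab$end + 1L,
                                                tab$end + 1L)),
                   n_ctrl = tab$n_ctrl,
                   n_trt = tab$n_trt,
                   caspase_released = tab$caspase,
                   stringsAsFactors = FALSE)
  qt <- quant_table(df, provenance = sprintf(
    "simulate_experiment(n_proteins=%d, seed=%d)", params$n_proteins,
    params$seed))
  list(table = qt, proteome = lib, truth = truth)
}

# Digest every released fragment of one protein; absolute coordinates.
digest_fragments <- function(seq, frags, params) {
  out <- vector("list", nrow(frags))
  for (k in seq_len(nrow(frags))) {
    d <- digest_tryptic(substring(seq, frags$start[k], frags$end[k]),
                        params$max_missed_cleavages)
    len <- nchar(d$peptide)
    d <- d[len >= params$min_pep_len & len <= params$max_pep_len, ,
           drop = FALSE]
    if (!nrow(d)) next
    out[[k]] <- data.frame(sequence = d$peptide,
                           start = frags$start[k] + d$start_offset - 1L,
                           frag_id = k,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(sequence = character(), start = integer(),
                      frag_id = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Tally control/treated occurrences of each (start, sequence) peptide.
merge_arm_counts <- function(acc, ctrl, trt) {
  key_c <- paste(ctrl$start, ctrl$sequence)
  key_t <- paste(trt$start, trt$sequence)
  keys <- sort(unique(c(key_c, key_t)))
  if (!length(keys)) return(NULL)
  n_ctrl <- as.integer(table(factor(key_c, levels = keys)))
  n_trt <- as.integer(table(factor(key_t, levels = keys)))
  caspase <- logical(length(keys))
  if (nrow(trt)) {
    casp_keys <- unique(key_t[trt$caspase])
    caspase <- keys %in% casp_keys
  }
  first <- match(keys, c(key_c, key_t))
  allpep <- rbind(ctrl[, c("sequence", "start")],
                  trt[, c("sequence", "start")])
  data.frame(accession = acc,
             sequence = allpep$sequence[first],
             start = allpep$start[first],
             end = allpep$start[first] + nchar(allpep$sequence[first]) - 1L,
             n_ctrl = n_ctrl, n_trt = n_trt, caspase = caspase,
             stringsAsFactors = FALSE)
}

#' Write and read ground truth as plain text
#'
#' `write_ground_truth()` writes two files into `dir`: `substrates.txt`
#' (one accession per line) and `sites.tsv` (accession, tab, P1 position).
#'
#' @param truth A [ground_truth()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(truth$substrates, file.path(dir, "substrates.txt"))
  utils::write.table(truth$sites, file.path(dir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  sites <- utils::read.delim(file.path(dir, "sites.tsv"),
                             stringsAsFactors = FALSE)
  ground_truth(readLines(file.path(dir, "substrates.txt")), sites)
}
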