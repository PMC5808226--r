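#' Generate a synthetic oocyte swelling experiment
#'
#' Draws a per-oocyte water permeability for an expressing group and a
#' water-injected control group from lognormal distributions (permeability
#' is positive and right-skewed across oocytes) and simulates each swelling
#' trace at the standard 15 s / 5 min recording design. Defaults mirror the
#' characteristic contrast between channel-expressing oocytes and controls:
#' expressing mean 7.7e-3 cm/s, control mean 7.0e-4 cm/s (an 11-fold
#' difference), 10 oocytes per group, 1% multiplicative area noise.
#'
#' @param n_expressing,n_control Number of oocytes per group (>= 1).
#' @param pf_expressing,pf_control Group mean Pf, cm/s.
#' @param pf_cv Between-oocyte coefficient of variation of Pf (lognormal
#'   sdlog; default 0.1).
#' @param noise_sd Relative area noise per frame (default 0.01).
#' @param constants [assay_constants()] bundle.
#' @param dt,duration Sampling interval and recording length, s.
#' @param seed Integer seed; the same (parameters, seed) pair regenerates
#'   the identical experiment.
#' @return A list with `traces` (a `swelling_trace` tibble for all oocytes)
#'   and `truth` (scenario label, per-oocyte true Pf, parameters, seed).
#' @examples
#' exp1 <- gen_swelling_experiment(n_expressing = 3, n_control = 3, seed = 42)
#' dplyr::count(exp1$traces, group)
#' @export
gen_swelling_experiment <- function(n_expressing = 10, n_control = 10,
                                    pf_expressing = 7.7e-3,
                                    pf_control = 7.0e-4, pf_cv = 0.1,
                                    noise_sd = 0.01,
                                    constants = assay_constants(),
                                    dt = 15, duration = 300, seed = 1L) {
  stopifnot(n_expressing >= 1, n_control >= 1,
            pf_expressing >= 0, pf_control >= 0, pf_cv >= 0)
  withr::with_seed(seed, {
    pf_e <- stats::rlnorm(n_expressing, log(pf_expressing), pf_cv)
    pf_c <- stats::rlnorm(n_control, log(pf_control), pf_cv)
    if (pf_cv == 0) { pf_e <- rep(pf_expressing, n_expressing)
                      pf_c <- rep(pf_control, n_control) }
    ids <- c(sprintf("exp_%02d", seq_len(n_expressing)),
             sprintf("ctl_%02d", seq_len(n_control)))
    groups <- rep(c("expressing", "control"), c(n_expressing, n_control))
    pfs <- c(pf_e, pf_c)
    sub_seeds <- sample.int(.Machine$integer.max, length(ids))
    traces <- purrr::pmap_dfr(
      list(pfs, ids, groups, sub_seeds),
      function(pf, id, grp, sd_seed) {
        simulate_swelling(pf, constants = constants, dt = dt,
                          duration = duration, noise_sd = noise_sd,
                          seed = sd_seed, oocyte_id = id, group = grp,
                          condition = "water")
      }
    )
    list(
      traces = new_swelling_trace(traces),
      truth = list(scenario = "swelling", seed = seed,
                   pf = stats::setNames(pfs, ids),
                   group = stats::setNames(groups, ids),
                   noise_sd = noise_sd, dt = dt, duration = duration)
    )
  })
}

#' Generate a synthetic isotonic solute-uptake experiment
#'
#' As [gen_swelling_experiment()] but with the linear solute-uptake model.
#' Defaults sit at the magnitude typical of a water-selective channel in a
#' 140 mM solute bath (apparent permeability around 5e-6 cm/s in both
#' groups, i.e. no real uptake difference), with 9 oocytes per group.
#'
#' @param n_a,n_b Oocytes per group.
#' @param psol_a,psol_b Group mean apparent solute permeability, cm/s.
#' @param psol_cv Between-oocyte lognormal coefficient of variation.
#' @param condition Solute label (e.g. "glycerol", "trehalose", "urea").
#' @inheritParams gen_swelling_experiment
#' @return A list with `traces` and `truth` (per-oocyte true Psol).
#' @examples
#' gen_solute_experiment(n_a = 2, n_b = 2, seed = 3)$truth$psol
#' @export
gen_solute_experiment <- function(n_a = 9, n_b = 9, psol_a = 5.0e-6,
                                  psol_b = 5.0e-6, psol_cv = 0.1,
                                  noise_sd = 0.01, condition = "glycerol",
                                  constants = assay_constants(),
                                  dt = 15, duration = 300, seed = 1L) {
  stopifnot(n_a >= 1, n_b >= 1, psol_a >= 0, psol_b >= 0)
  withr::with_seed(seed, {
    ps_a <- stats::rlnorm(n_a, log(psol_a), psol_cv)
    ps_b <- stats::rlnorm(n_b, log(psol_b), psol_cv)
    if (psol_cv == 0) { ps_a <- rep(psol_a, n_a); ps_b <- rep(psol_b, n_b) }
    if (psol_a == 0) ps_a <- rep(0, n_a)
    if (psol_b == 0) ps_b <- rep(0, n_b)
    ids <- c(sprintf("a_%02d", seq_len(n_a)), sprintf("b_%02d", seq_len(n_b)))
    groups <- rep(c("expressing", "control"), c(n_a, n_b))
    pss <- c(ps_a, ps_b)
    sub_seeds <- sample.int(.Machine$integer.max, length(ids))
    traces <- purrr::pmap_dfr(
      list(pss, ids, groups, sub_seeds),
      function(ps, id, grp, sd_seed) {
        simulate_solute_uptake(ps, constants = constants, dt = dt,
                               duration = duration, noise_sd = noise_sd,
                               seed = sd_seed, oocyte_id = id, group = grp,
                               condition = condition)
      }
    )
    list(
      traces = new_swelling_trace(traces),
      truth = list(scenario = "solute", seed = seed,
                   psol = stats::setNames(pss, ids),
                   group = stats::setNames(groups, ids),
                   condition = condition, noise_sd = noise_sd,
                   dt = dt, duration = duration)
    )
  })
}

.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  # codons vector above is ordered base1-major; rebuild in standard order
  codons <- character(64); k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1; codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

.codons_for <- function(aa) names(.codon_table)[.codon_table == aa]

#' Generate a synthetic aquaporin-like cDNA with planted hallmarks
#'
#' Builds a transcript of random codons flanked by untranslated regions,
#' with NPA boxes planted at requested residue positions, a requested
#' C-terminal motif, and a degenerate primer pair whose product has a
#' requested length. The 5' UTR is kept free of ATG and in-ORF internal
#' starts/stops cannot truncate the planted ORF, and a verifier re-scans
#' the finished sequence (regenerating with a bumped seed, bounded retries)
#' to guarantee the planted ORF is the longest in the transcript. This is a
#' synthetic stand-in for a deposited mRNA record, with every feature known
#' by construction.
#'
#' @param orf_aa Protein length in residues, excluding the stop (>= 10).
#' @param npa_at 1-based residue positions where "NPA" is planted (each in
#'   `[1, orf_aa - 2]`).
#' @param cterm Terminal motif planted at the protein's C-terminus.
#' @param utr5,utr3 UTR lengths in nt.
#' @param product_bp Length of the planted degenerate-primer product
#'   (>= 2 * primer_len; `NULL` to skip planting primers).
#' @param primer_len Primer footprint length (default 20).
#' @param degeneracy Number of primer positions replaced by an IUPAC
#'   ambiguity code containing the true base (default 3 per primer).
#' @param seed Integer seed.
#' @param max_tries Verifier retry bound.
#' @return A list with `sequence` (the transcript string), `id`, and
#'   `truth`: ORF coordinates, protein, planted NPA positions, cterm,
#'   primer pair (`fwd`, `rev`) and expected product length, seed.
#' @examples
#' tx <- gen_aqp_transcript(orf_aa = 60, npa_at = 10, seed = 7)
#' substr(tx$sequence, tx$truth$orf_start, tx$truth$orf_start + 2) # "ATG"
#' @export
gen_aqp_transcript <- function(orf_aa = 258, npa_at = c(89, 206),
                               cterm = "SYDF", utr5 = 120, utr3 = 180,
                               product_bp = 431, primer_len = 20,
                               degeneracy = 3, seed = 1L, max_tries = 25) {
  stopifnot(orf_aa >= 10, utr5 >= 0, utr3 >= 0)
  if (any(npa_at < 2 | npa_at > orf_aa - 2)) {
    stop("NPA positions must lie in [2, orf_aa - 2] (position 1 is the ",
         "initiator methionine)", call. = FALSE)
  }
  if (length(npa_at) > 0 && nchar(cterm) > 0 &&
      any(npa_at + 2 >= orf_aa - nchar(cterm) + 1)) {
    stop("an NPA position overlaps the planted C-terminal motif",
         call. = FALSE)
  }
  if (nchar(cterm) > orf_aa) stop("cterm longer than the ORF", call. = FALSE)
  for (try in seq_len(max_tries)) {
    out <- withr::with_seed(seed + try - 1L,
                            .build_transcript(orf_aa, npa_at, cterm, utr5,
                                              utr3, product_bp, primer_len,
                                              degeneracy))
    found <- find_longest_orf(out$sequence)
    if (nrow(found) == 1 && found$orf_start == out$truth$orf_start &&
        found$orf_end == out$truth$orf_end) {
      out$truth$seed <- seed
      return(out)
    }
  }
  stop("could not generate a transcript whose planted ORF is the longest ",
       "within ", max_tries, " tries", call. = FALSE)
}

.build_transcript <- function(orf_aa, npa_at, cterm, utr5, utr3,
                              product_bp, primer_len, degeneracy) {
  # protein: random residues, then plant motifs
  aa_pool <- setdiff(unique(.codon_table), "*")
  protein <- sample(aa_pool, orf_aa, replace = TRUE)
  protein[1] <- "M"
  if (nchar(cterm) > 0) {
    protein[(orf_aa - nchar(cterm) + 1):orf_aa] <- strsplit(cterm, "")[[1]]
  }
  for (p in npa_at) protein[p:(p + 2)] <- c("N", "P", "A")
  # scrub spurious NPA occurrences so the planted positions are exhaustive
  repeat {
    hits <- scan_motif(paste(protein, collapse = ""), "NPA")
    spurious <- setdiff(hits, npa_at)
    if (length(spurious) == 0) break
    protein[spurious] <- "L" # removing the Asn kills the motif
  }
  # codons: avoid creating spurious NPA by construction order (protein is
  # fixed first, so the residue string is exact)
  codons <- vapply(protein, function(a) {
    cs <- .codons_for(a)
    cs[sample.int(length(cs), 1)]
  }, character(1))
  codons[1] <- "ATG"
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
  cds <- paste0(paste(codons, collapse = ""), stop_codon)
  # UTRs: A/C/T only upstream (no ATG possible without G... ATG needs G;
  # excluding G prevents both ATG and TGA/TAG stops from aligning new ORFs)
  u5 <- paste(sample(c("A", "C", "T"), utr5, replace = TRUE), collapse = "")
  u3 <- paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE),
              collapse = "")
  seq <- paste0(u5, cds, u3)
  truth <- list(orf_start = utr5 + 1, orf_end = utr5 + nchar(cds),
                protein = paste(protein, collapse = ""),
                npa_at = sort(npa_at), cterm = cterm)
  if (!is.null(product_bp)) {
    if (product_bp < 2 * primer_len || product_bp > nchar(seq)) {
      stop("product_bp incompatible with primer and transcript lengths",
           call. = FALSE)
    }
    f_start <- sample.int(nchar(seq) - product_bp + 1, 1)
    r_end <- f_start + product_bp - 1
    fwd_site <- substr(seq, f_start, f_start + primer_len - 1)
    rev_site <- substr(seq, r_end - primer_len + 1, r_end)
    fwd <- .degenerate(fwd_site, degeneracy)
    rev <- .degenerate(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rev_site))), degeneracy)
    truth$fwd <- fwd
    truth$rev <- rev
    truth$product_bp <- product_bp
    truth$forward_start <- f_start
    truth$reverse_end <- r_end
  }
  list(sequence = seq, id = "synthetic_aqp_transcript", truth = truth)
}

# replace `n` positions with the smallest IUPAC ambiguity code containing
# the true base plus one alternative
.degenerate <- function(primer, n) {
  if (n == 0) return(primer)
  amb <- list(A = c(G = "R", C = "M", T = "W"),
              G = c(A = "R", C = "S", T = "K"),
              C = c(A = "M", G = "S", T = "Y"),
              T = c(A = "W", G = "K", C = "Y"))
  chars <- strsplit(primer, "")[[1]]
  pos <- sample(seq_along(chars), min(n, length(chars)))
  for (p in pos) {
    alts <- amb[[chars[p]]]
    chars[p] <- alts[sample.int(length(alts), 1)]
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Builds a tidy Ct table for one target and one reference gene across
#' conditions with planted true fold changes relative to the first
#' condition supplied. Reference Cts are Gaussian around a common baseline;
#' target Cts equal a target baseline minus log2(fold), plus noise. The
#' default design is 4 biological replicates, each run in technical
#' triplicate.
#'
#' @param conditions Character vector of condition labels.
#' @param true_folds Named numeric vector of true folds (> 0), one per
#'   condition, relative to the condition whose fold is 1 (the natural
#'   calibrator).
#' @param reference_gene,target_gene Gene labels in the output.
#' @param ct_noise_sd Gaussian Ct noise per technical well, cycles
#'   (default 0.2).
#' @param n_bio,n_tech Biological / technical replicates (defaults 4 and 3).
#' @param base_ct_reference,base_ct_target Baseline Ct values.
#' @param seed Integer seed.
#' @return A list-free tibble of rows (`sample_id`, `condition`, `gene`,
#'   `bio_rep`, `tech_rep`, `ct`) with the ground truth attached as
#'   attribute `truth` (folds, design, seed).
#' @examples
#' tab <- gen_ct_table(conditions = c("fg", "hg"),
#'                     true_folds = c(fg = 1, hg = 19.23), ct_noise_sd = 0)
#' relative_quantity(tab, calibrator = "fg")
#' @export
gen_ct_table <- function(conditions, true_folds,
                         reference_gene = "reference",
                         target_gene = "target", ct_noise_sd = 0.2,
                         n_bio = 4, n_tech = 3, base_ct_reference = 20,
                         base_ct_target = 24, seed = 1L) {
  stopifnot(length(conditions) >= 1, n_bio >= 1, n_tech >= 1,
            ct_noise_sd >= 0)
  if (is.null(names(true_folds))) names(true_folds) <- conditions
  if (!all(conditions %in% names(true_folds)) || any(true_folds <= 0)) {
    stop("`true_folds` must name every condition with a positive fold",
         call. = FALSE)
  }
  design <- tidyr::expand_grid(
    condition = conditions, gene = c(target_gene, reference_gene),
    bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech)
  )
  withr::with_seed(seed, {
    mu <- ifelse(design$gene == reference_gene, base_ct_reference,
                 base_ct_target - log2(true_folds[design$condition]))
    design$ct <- mu + stats::rnorm(nrow(design), 0, ct_noise_sd)
  })
  out <- design |>
    dplyr::mutate(sample_id = paste(.data$condition, .data$bio_rep,
                                    sep = "_"), .before = 1)
  attr(out, "truth") <- list(scenario = "qpcr", seed = seed,
                             folds = true_folds[conditions],
                             n_bio = n_bio, n_tech = n_tech,
                             ct_noise_sd = ct_noise_sd)
  out
}
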