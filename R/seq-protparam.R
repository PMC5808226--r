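# Average residue masses (Da) and pKa values following the ExPASy
# ProtParam conventions (Bjellqvist pKa set). Only amino-acid composition
# enters either quantity, so both are permutation-invariant.

.aa_avg_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_avg_mass <- 18.01524

# side-chain pKa (negative groups deprotonate acid -> -1; positive carry +1)
.pka_neg <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00, Cterm = 3.55)
.pka_pos <- c(H = 5.98, K = 10.00, R = 12.00)
# N-terminal pKa depends on the first residue
.pka_nterm <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
                E = 7.70, G = 7.50)
.pka_nterm_default <- 7.50

.aa_counts <- function(protein) {
  protein <- toupper(protein)
  if (!nzchar(protein)) stop("empty protein sequence", call. = FALSE)
  chars <- strsplit(protein, "")[[1]]
  unknown <- setdiff(unique(chars), names(.aa_avg_mass))
  if (length(unknown) > 0) {
    stop("invalid residue(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  table(factor(chars, levels = names(.aa_avg_mass)))
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.015 Da), using the
#' ExPASy/ProtParam average-mass table, reported in kDa.
#'
#' @param protein Character string over the standard 20-letter alphabet.
#' @return Molecular weight in kDa.
#' @examples
#' protein_mw("GG") * 1000 # 132.12 Da
#' @export
protein_mw <- function(protein) {
  counts <- .aa_counts(protein)
  (sum(counts * .aa_avg_mass) + .water_avg_mass) / 1000
}

#' Theoretical isoelectric point of a protein
#'
#' Net charge as a function of pH by Henderson-Hasselbalch over the ionizable
#' side chains (D, E, C, Y negative; H, K, R positive) plus the free termini,
#' with the Bjellqvist pKa set used by ExPASy's Compute pI/MW; the pI is
#' located by bisection until the net charge is below `tol` in magnitude.
#'
#' @param protein Character string over the standard 20-letter alphabet.
#' @param tol Convergence tolerance on the net charge (default 1e-4).
#' @return The isoelectric point in pH units.
#' @examples
#' protein_pi("GG") # ~5.5
#' @export
protein_pi <- function(protein, tol = 1e-4) {
  counts <- .aa_counts(protein)
  first <- substr(toupper(protein), 1, 1)
  nterm_pka <- if (first %in% names(.pka_nterm)) .pka_nterm[[first]] else
    .pka_nterm_default
  charge_at <- function(ph) {
    pos <- sum(counts[names(.pka_pos)] / (1 + 10^(ph - .pka_pos))) +
      1 / (1 + 10^(ph - nterm_pka))
    neg_names <- setdiff(names(.pka_neg), "Cterm")
    neg <- sum(counts[neg_names] / (1 + 10^(.pka_neg[neg_names] - ph))) +
      1 / (1 + 10^(.pka_neg[["Cterm"]] - ph))
    pos - neg
  }
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    ch <- charge_at(mid)
    if (abs(ch) < tol) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  mid
}
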