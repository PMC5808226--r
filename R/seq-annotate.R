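#' Annotate aquaporin hallmark features on a cDNA sequence
#'
#' One-stop annotation of a candidate water-channel transcript: finds the
#' longest forward-strand ORF and its translation, computes molecular weight
#' and isoelectric point, scans for NPA boxes, records the C-terminal 4-mer,
#' calls hydrophobic segments from the Kyte-Doolittle profile, and (when a
#' reference protein is supplied) maps the aromatic/arginine selectivity-
#' filter positions onto the query. All coordinates are 1-based inclusive.
#'
#' @param seq cDNA sequence (character string or `DNAString`).
#' @param id Label for the record.
#' @param template Optional reference protein for selectivity-filter
#'   mapping (e.g. a structurally characterized water channel).
#' @param template_positions 1-based filter positions on the template
#'   (default `c(58, 182, 191, 197)`).
#' @param hydropathy_window,hydropathy_threshold Passed to
#'   [hydropathy_profile()].
#' @return An object of class `aqp_annotation`: a list with elements `id`,
#'   `orf` (tibble), `protein`, `length_aa`, `mw_kda`, `pi`, `npa_starts`,
#'   `cterm_motif`, `tm_segments` (tibble), `hydropathy` (tibble), and
#'   `selectivity_filter` (tibble or NULL).
#' @examples
#' tx <- gen_aqp_transcript(orf_aa = 60, npa_at = 10, seed = 7)
#' annotate_aquaporin(tx$sequence)
#' @export
annotate_aquaporin <- function(seq, id = "query", template = NULL,
                               template_positions = c(58, 182, 191, 197),
                               hydropathy_window = 19,
                               hydropathy_threshold = 1.6) {
  orf <- find_longest_orf(seq)
  if (nrow(orf) == 0) {
    stop("no open reading frame found in ", id, call. = FALSE)
  }
  protein <- orf$protein[1]
  hyd <- hydropathy_profile(protein, window = hydropathy_window,
                            threshold = hydropathy_threshold)
  filt <- if (!is.null(template)) {
    map_selectivity_filter(protein, template,
                           template_positions = template_positions)
  }
  structure(list(
    id = id,
    orf = orf[, c("orf_start", "orf_end")],
    protein = protein,
    length_aa = orf$length_aa[1],
    mw_kda = protein_mw(protein),
    pi = protein_pi(protein),
    npa_starts = scan_motif(protein, "NPA"),
    cterm_motif = cterm_motif(protein, 4),
    tm_segments = hyd$segments,
    hydropathy = hyd$profile,
    selectivity_filter = filt
  ), class = "aqp_annotation")
}

#' @export
print.aqp_annotation <- function(x, ...) {
  cat("Aquaporin hallmark annotation:", x$id, "\n")
  cat(sprintf("  ORF           %d..%d (1-based, stop included)\n",
              x$orf$orf_start, x$orf$orf_end))
  cat(sprintf("  Protein       %d aa, %.1f kDa, pI %.1f\n",
              x$length_aa, x$mw_kda, round(x$pi, 2)))
  cat("  NPA boxes     ",
      if (length(x$npa_starts)) paste(x$npa_starts, collapse = ", ")
      else "none", "\n")
  cat("  C-terminus    ", x$cterm_motif, "\n")
  cat(sprintf("  Hydrophobic segments: %d\n", nrow(x$tm_segments)))
  if (!is.null(x$selectivity_filter)) {
    sf <- x$selectivity_filter
    cat("  ar/R filter   ",
        paste0(sf$query_residue, ifelse(is.na(sf$query_pos), "(gap)",
                                        sf$query_pos), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy feature table of an annotation
#'
#' One row per annotated feature with 1-based inclusive coordinates:
#' the ORF (nucleotide coordinates), each NPA box, the C-terminal motif and
#' each hydrophobic segment (residue coordinates).
#'
#' @param x An `aqp_annotation` object.
#' @param ... Unused.
#' @return A tibble with columns `id`, `feature`, `coordinate_system`,
#'   `start`, `end`, `detail`.
#' @export
tidy.aqp_annotation <- function(x, ...) {
  rows <- list(
    tibble::tibble(feature = "orf", coordinate_system = "nucleotide",
                   start = x$orf$orf_start, end = x$orf$orf_end,
                   detail = sprintf("%d aa", x$length_aa))
  )
  if (length(x$npa_starts) > 0) {
    rows <- c(rows, list(tibble::tibble(
      feature = "npa_box", coordinate_system = "residue",
      start = x$npa_starts, end = x$npa_starts + 2, detail = "NPA"
    )))
  }
  n <- x$length_aa
  rows <- c(rows, list(tibble::tibble(
    feature = "cterm_motif", coordinate_system = "residue",
    start = n - nchar(x$cterm_motif) + 1, end = n, detail = x$cterm_motif
  )))
  if (nrow(x$tm_segments) > 0) {
    rows <- c(rows, list(tibble::tibble(
      feature = "hydrophobic_segment", coordinate_system = "residue",
      start = x$tm_segments$start, end = x$tm_segments$end,
      detail = "Kyte-Doolittle"
    )))
  }
  if (!is.null(x$selectivity_filter)) {
    sf <- x$selectivity_filter
    rows <- c(rows, list(tibble::tibble(
      feature = "arR_filter", coordinate_system = "residue",
      start = sf$query_pos, end = sf$query_pos,
      detail = sprintf("%s (template %s%d)", sf$query_residue,
                       sf$template_residue, sf$template_pos)
    )))
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(id = x$id, .before = 1)
}

#' @export
glance.aqp_annotation <- function(x, ...) {
  tibble::tibble(
    id = x$id, length_aa = x$length_aa, mw_kda = x$mw_kda, pi = x$pi,
    n_npa = length(x$npa_starts), cterm = x$cterm_motif,
    n_hydrophobic_segments = nrow(x$tm_segments)
  )
}
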