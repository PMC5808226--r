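#' Global pairwise protein alignment with percent identity
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (BLOSUM62, gap open 10, gap extend 0.5 by default) via
#' `Biostrings::pairwiseAlignment()`. Percent identity is computed as
#' matches / alignment columns x 100 (PID1), i.e. gap columns count in the
#' denominator.
#'
#' @param a,b Protein sequences (character strings or `AAString`).
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (default "BLOSUM62").
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @return A list with `aligned_a`, `aligned_b` (gapped strings of equal
#'   length), `score`, and `identity` (percent).
#' @examples
#' global_align("ACDE", "ACDD")$identity # 75
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_opening = 10, gap_extension = 0.5) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  cols_a <- strsplit(ga, "")[[1]]
  cols_b <- strsplit(gb, "")[[1]]
  identity <- 100 * sum(cols_a == cols_b & cols_a != "-") / length(cols_a)
  list(aligned_a = ga, aligned_b = gb,
       score = Biostrings::score(aln), identity = identity)
}

#' Map selectivity-filter positions from a template onto a query
#'
#' Globally aligns the query against a reference protein (e.g. an aquaporin
#' of known structure) and reports, for each stated template position, the
#' aligned query residue and its 1-based position in the query. Template
#' positions falling opposite an alignment gap are reported with residue
#' `"-"` and `NA` position. This is how the four aromatic/arginine (ar/R)
#' constriction residues of a reference water channel are located on a new
#' sequence.
#'
#' @param query,template Protein sequences.
#' @param template_positions Integer vector of 1-based template residue
#'   positions (default `c(58, 182, 191, 197)`, the ar/R constriction of
#'   bovine AQP1).
#' @param ... Passed to [global_align()].
#' @return A tibble with `template_pos`, `template_residue`, `query_pos`
#'   (NA at gaps), `query_residue` ("-" at gaps).
#' @examples
#' map_selectivity_filter("MKFV", "MKFV", template_positions = c(2, 4))
#' @export
map_selectivity_filter <- function(query, template,
                                   template_positions = c(58, 182, 191, 197),
                                   ...) {
  template <- toupper(as.character(template))
  if (any(template_positions < 1 | template_positions > nchar(template))) {
    stop("template position outside the template sequence", call. = FALSE)
  }
  aln <- global_align(query, template, ...)
  qa <- strsplit(aln$aligned_a, "")[[1]]
  ta <- strsplit(aln$aligned_b, "")[[1]]
  q_pos <- cumsum(qa != "-")
  t_pos <- cumsum(ta != "-")
  purrr::map_dfr(template_positions, function(p) {
    col <- match(p, t_pos) # first column where template position p appears
    stopifnot(!is.na(col), ta[col] != "-")
    gap <- qa[col] == "-"
    tibble::tibble(
      template_pos = p,
      template_residue = ta[col],
      query_pos = if (gap) NA_integer_ else q_pos[col],
      query_residue = qa[col]
    )
  })
}
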