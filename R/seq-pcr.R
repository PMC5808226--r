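#' In-silico PCR with IUPAC-degenerate primers
#'
#' Matches the forward primer against the forward strand and the reverse
#' primer, as its reverse complement, against the forward strand. IUPAC
#' degeneracy codes are honored on the primer side only; ambiguity codes in
#' the template (e.g. N) match nothing. Matching is exact (no mismatches).
#' Every forward site is paired with every non-conflicting downstream
#' reverse site; the product length includes both primer footprints and
#' products are returned sorted by length.
#'
#' @param template DNA template, character string or `DNAString`.
#' @param fwd,rev Primer sequences 5'->3', length >= 10, IUPAC codes allowed.
#' @param max_products Cap on the number of products returned (default 100).
#' @return A tibble with columns `forward_start`, `reverse_end` (1-based
#'   inclusive template coordinates), `length_bp`, `fwd_primer`,
#'   `rev_primer`; zero rows when there is no product.
#' @examples
#' in_silico_pcr("AAACATCAGTTTGGGCCCAAA", "CAYCARTTTG", "AAAGGGCCCA")
#' @export
in_silico_pcr <- function(template, fwd, rev, max_products = 100) {
  template <- toupper(as.character(template))
  fwd <- toupper(as.character(fwd)); rev <- toupper(as.character(rev))
  if (nchar(fwd) < 10 || nchar(rev) < 10) {
    stop("primers must be at least 10 nt long", call. = FALSE)
  }
  subj <- Biostrings::DNAString(template)
  fwd_hits <- Biostrings::matchPattern(Biostrings::DNAString(fwd), subj,
                                       fixed = "subject")
  rev_rc <- Biostrings::reverseComplement(Biostrings::DNAString(rev))
  rev_hits <- Biostrings::matchPattern(rev_rc, subj, fixed = "subject")
  fs <- Biostrings::start(fwd_hits)
  re_start <- Biostrings::start(rev_hits)
  re_end <- Biostrings::end(rev_hits)
  if (length(fs) == 0 || length(re_end) == 0) {
    return(.empty_pcr())
  }
  out <- purrr::map_dfr(fs, function(f) {
    # reverse footprint downstream of the forward one (footprints may abut
    # or even overlap, but the product must contain both in order)
    ok <- re_start >= f & re_end >= f + nchar(fwd) - 1
    tibble::tibble(forward_start = f, reverse_end = re_end[ok])
  })
  if (nrow(out) == 0) return(.empty_pcr())
  out |>
    dplyr::mutate(length_bp = .data$reverse_end - .data$forward_start + 1,
                  fwd_primer = fwd, rev_primer = rev) |>
    dplyr::arrange(.data$length_bp, .data$forward_start) |>
    utils::head(max_products)
}

.empty_pcr <- function() {
  tibble::tibble(forward_start = integer(), reverse_end = integer(),
                 length_bp = integer(), fwd_primer = character(),
                 rev_primer = character())
}
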