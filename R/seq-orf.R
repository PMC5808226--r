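#' Find the longest open reading frame on the forward strand
#'
#' Scans the three forward reading frames for spans that begin with ATG and
#' end with an in-frame stop codon (standard genetic code) and returns the
#' longest; ties are broken in favour of the smaller start coordinate.
#' Forward-strand-only with ATG starts is appropriate for oriented mRNA /
#' RACE products. Coordinates are 1-based and inclusive and include the stop
#' codon; the translation excludes the stop.
#'
#' @param seq A DNA sequence: a single character string (IUPAC codes
#'   permitted but ambiguous codons never form ATG/stop) or a
#'   `Biostrings::DNAString`.
#' @return A one-row tibble with `orf_start`, `orf_end`, `length_aa`,
#'   `protein`; zero rows when no ORF exists.
#' @examples
#' find_longest_orf("ATGAAATAA") # 1..9, protein "MK"
#' @export
find_longest_orf <- function(seq) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 6) stop("sequence shorter than 6 nt", call. = FALSE)
  n <- nchar(s)
  best <- NULL
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq.int(1 + frame, n - 2, by = 3)
    codons <- substring(s, starts, starts + 2)
    open_at <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_at) && codons[i] == "ATG") open_at <- i
      if (!is.na(open_at) && codons[i] %in% stops) {
        span <- (i - open_at + 1) * 3
        cand <- c(start = starts[open_at], end = starts[i] + 2, span = span)
        if (is.null(best) || span > best["span"] ||
            (span == best["span"] && cand["start"] < best["start"])) {
          best <- cand
        }
        open_at <- NA_integer_
      }
    }
  }
  if (is.null(best)) {
    return(tibble::tibble(orf_start = integer(), orf_end = integer(),
                          length_aa = integer(), protein = character()))
  }
  cds <- substr(s, best["start"], best["end"] - 3)
  protein <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  tibble::tibble(orf_start = unname(best["start"]),
                 orf_end = unname(best["end"]),
                 length_aa = nchar(protein), protein = protein)
}

#' Length difference between two transcript variants
#'
#' Absolute difference in nucleotide length between two sequences, e.g. two
#' RACE-derived transcript variants sharing one ORF but differing in their
#' UTRs.
#'
#' @param a,b Character strings or `Biostrings::DNAString` objects.
#' @return Length difference in bp (non-negative integer).
#' @examples
#' variant_length_diff(strrep("A", 10), strrep("A", 17)) # 7
#' @export
variant_length_diff <- function(a, b) {
  abs(nchar(as.character(b)) - nchar(as.character(a)))
}
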