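#' Find all occurrences of a protein motif
#'
#' Exact (non-degenerate) scan for a short motif such as the aquaporin
#' "NPA" box; overlapping hits are reported. Positions are 1-based.
#'
#' @param protein Protein sequence, character string.
#' @param motif Non-empty motif string.
#' @return Sorted integer vector of 1-based start positions (possibly empty).
#' @examples
#' scan_motif("NPAXXXNPA", "NPA") # 1, 7
#' @export
scan_motif <- function(protein, motif) {
  if (!nzchar(motif)) stop("motif must be non-empty", call. = FALSE)
  protein <- toupper(protein); motif <- toupper(motif)
  hits <- integer()
  from <- 1
  repeat {
    p <- regexpr(motif, substr(protein, from, nchar(protein)), fixed = TRUE)
    if (p < 0) break
    hits <- c(hits, from + p - 1)
    from <- from + p # advance one position: overlaps allowed
  }
  hits
}

#' Terminal k-mer of a protein
#'
#' The last `k` residues, e.g. the "SYDF" C-terminal signature of insect
#' water-selective aquaporins.
#'
#' @param protein Protein sequence, length >= `k`.
#' @param k Motif length (default 4).
#' @return Character string of length `k`.
#' @examples
#' cterm_motif("AAASYDF") # "SYDF"
#' @export
cterm_motif <- function(protein, k = 4) {
  n <- nchar(protein)
  if (n < k) stop("protein shorter than k = ", k, call. = FALSE)
  substr(protein, n - k + 1, n)
}

# Kyte-Doolittle hydropathy index
.kd_scale <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

#' Sliding-window hydropathy profile and hydrophobic segment calls
#'
#' Kyte-Doolittle hydropathy values averaged over a centered window of odd
#' length; the mean is defined only where the full window fits. Putative
#' membrane-spanning segments are maximal runs of window centers above
#' `threshold`, merged when separated by gaps of at most `merge_gap`
#' centers, and reported when at least `min_len` centers long. This is a
#' hydropathy heuristic, not a topology predictor: segment boundaries are
#' window centers, and the default parameters make hydrophobic cores
#' visible rather than reproducing any dedicated transmembrane predictor.
#'
#' @param protein Protein sequence, character string.
#' @param window Odd window length, `<= nchar(protein)` (default 19, the
#'   conventional span of a membrane-crossing helix).
#' @param threshold Mean hydropathy above which a center is hydrophobic
#'   (default 1.6).
#' @param merge_gap Merge segments separated by at most this many
#'   sub-threshold centers (default 3).
#' @param min_len Minimum segment length in centers (default 1).
#' @return A list with `profile` (tibble: `center`, `hydropathy`) and
#'   `segments` (tibble: `start`, `end`, 1-based inclusive residue
#'   positions of window centers).
#' @examples
#' hydropathy_profile(strrep("A", 19), window = 19)$profile
#' @export
hydropathy_profile <- function(protein, window = 19, threshold = 1.6,
                               merge_gap = 3, min_len = 1) {
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  protein <- toupper(protein)
  n <- nchar(protein)
  if (window > n) stop("window longer than the protein", call. = FALSE)
  chars <- strsplit(protein, "")[[1]]
  vals <- .kd_scale[chars]
  if (anyNA(vals)) {
    stop("invalid residue(s): ",
         paste(unique(chars[is.na(vals)]), collapse = ", "), call. = FALSE)
  }
  half <- (window - 1) / 2
  csum <- c(0, cumsum(vals))
  centers <- (half + 1):(n - half)
  prof <- (csum[centers + half + 1] - csum[centers - half]) / window
  profile <- tibble::tibble(center = centers, hydropathy = unname(prof))

  above <- profile$hydropathy > threshold
  segs <- .runs_true(above)
  if (nrow(segs) > 1) {
    merged <- segs[1, , drop = FALSE]
    for (i in 2:nrow(segs)) {
      if (segs$start[i] - merged$end[nrow(merged)] - 1 <= merge_gap) {
        merged$end[nrow(merged)] <- segs$end[i]
      } else {
        merged <- rbind(merged, segs[i, ])
      }
    }
    segs <- merged
  }
  segs <- segs[segs$end - segs$start + 1 >= min_len, , drop = FALSE]
  segments <- tibble::tibble(start = centers[segs$start], end = centers[segs$end])
  list(profile = profile, segments = segments)
}

.runs_true <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}
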