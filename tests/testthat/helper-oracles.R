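# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain string/arithmetic implementations.

# --- exhaustive forward-frame ORF scan -------------------------------------
oracle_longest_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 0:2) {
    starts <- seq.int(1 + frame, n - 2, by = 3)
    codons <- substring(s, starts, starts + 2)
    atg_idx <- which(codons == "ATG")
    stop_idx <- which(codons %in% stops)
    for (a in atg_idx) {
      downstream <- stop_idx[stop_idx >= a]
      if (length(downstream) == 0) next
      e <- downstream[1]
      cand <- c(start = starts[a], end = starts[e] + 2,
                span = (e - a + 1) * 3)
      if (is.null(best) || cand["span"] > best["span"] ||
          (cand["span"] == best["span"] && cand["start"] < best["start"])) {
        best <- cand
      }
    }
  }
  best
}

# --- IUPAC degeneracy expansion --------------------------------------------
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

expand_degenerate <- function(primer) {
  chars <- strsplit(toupper(primer), "")[[1]]
  opts <- lapply(chars, function(ch) iupac_sets[[ch]])
  grid <- do.call(expand.grid, c(opts, stringsAsFactors = FALSE))
  apply(grid, 1, paste, collapse = "")
}

oracle_match_starts <- function(primer, template) {
  template <- toupper(template)
  k <- nchar(primer)
  hits <- integer()
  for (ex in expand_degenerate(primer)) {
    for (i in seq_len(nchar(template) - k + 1)) {
      if (substr(template, i, i + k - 1) == ex) hits <- c(hits, i)
    }
  }
  sort(unique(hits))
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

oracle_pcr_lengths <- function(template, fwd, rev) {
  fs <- oracle_match_starts(fwd, template)
  rs <- oracle_match_starts(revcomp_chr(rev), template)
  out <- integer()
  for (f in fs) {
    for (r in rs) {
      r_end <- r + nchar(rev) - 1
      if (r >= f && r_end >= f + nchar(fwd) - 1) {
        out <- c(out, r_end - f + 1)
      }
    }
  }
  sort(out)
}

# --- brute-force global alignment (affine gaps) for tiny sequences --------
# enumerates every alignment of a vs b; returns identities (percent,
# matches / columns) of all maximum-score alignments
oracle_align_identities <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  results <- list()
  rec <- function(i, j, cols_a, cols_b, score, last) {
    if (i > length(a) && j > length(b)) {
      results[[length(results) + 1]] <<- list(score = score,
                                              ca = cols_a, cb = cols_b)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      rec(i + 1, j + 1, c(cols_a, a[i]), c(cols_b, b[j]),
          score + sub[a[i], b[j]], "d")
    }
    if (i <= length(a)) {
      pen <- if (last == "u") gap_ext else gap_open + gap_ext
      rec(i + 1, j, c(cols_a, a[i]), c(cols_b, "-"), score - pen, "u")
    }
    if (j <= length(b)) {
      pen <- if (last == "l") gap_ext else gap_open + gap_ext
      rec(i, j + 1, c(cols_a, "-"), c(cols_b, b[j]), score - pen, "l")
    }
  }
  rec(1, 1, character(0), character(0), 0, "start")
  scores <- vapply(results, `[[`, numeric(1), "score")
  best <- results[abs(scores - max(scores)) < 1e-9]
  vapply(best, function(r) {
    100 * sum(r$ca == r$cb & r$ca != "-") / length(r$ca)
  }, numeric(1))
}

# random DNA / protein helpers
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
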