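#' Read and write swelling-trace tables
#'
#' Traces travel as tidy CSV with columns `oocyte_id`, `group`,
#' `condition`, `time_s`, `rel_area` (UTF-8, '.' decimal separator); the
#' relative volume is re-derived on read so the file stays minimal.
#'
#' @param path File path.
#' @return `read_traces()` returns a `swelling_trace` tibble;
#'   `write_traces()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_traces(simulate_swelling(7.77e-3, noise_sd = 0), f)
#' read_traces(f)
#' @export
read_traces <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("oocyte_id", "group", "condition", "time_s", "rel_area")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("trace CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df |>
    dplyr::mutate(rel_volume = relative_volume(.data$rel_area)) |>
    new_swelling_trace()
}

#' @param traces A `swelling_trace` tibble.
#' @rdname read_traces
#' @export
write_traces <- function(traces, path) {
  .validate_trace(traces)
  traces |>
    dplyr::select("oocyte_id", "group", "condition", "time_s", "rel_area") |>
    readr::write_csv(path)
  invisible(path)
}

#' Write permeability estimates as CSV
#'
#' @param estimates A `permeability_estimates` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  readr::write_csv(tibble::as_tibble(unclass(estimates)), path)
  invisible(path)
}

#' Read permeability estimates from CSV
#'
#' @param path File path.
#' @return A `permeability_estimates` tibble.
#' @export
read_estimates <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- unique(c("permeability_estimates", class(out)))
  out
}

#' Write a group comparison as JSON
#'
#' @param comparison One-row tibble from [compare_groups()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  jsonlite::write_json(as.list(comparison), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A named character vector of upper-case sequences, keyed by the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  set <- if (alphabet == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path; lines are wrapped at 60 columns.
#' @param alphabet `"dna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  set <- if (alphabet == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}
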