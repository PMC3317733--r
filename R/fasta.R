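#' Read protein sequences from a FASTA file
#'
#' Reads every record of a FASTA file into a data frame of identifiers and
#' upper-cased residue strings, preserving file order. The identifier is the
#' header up to the first whitespace. Residues outside the 20-letter alphabet
#' (e.g. X, B, Z, U) are retained.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with character columns `id` and `residues`, one row
#'   per record, in file order.
#' @seealso [write_fasta()], [filter_by_length()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no sequences found in FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("FASTA record with empty identifier in: ", path, call. = FALSE)
  }
  data.frame(id = ids,
             residues = toupper(as.character(set)),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' Writes one `>id` header and one single-line sequence per record, so the
#' output is byte-stable for fixture generation and round-trips exactly
#' through [read_fasta()].
#'
#' @param sequences Data frame with columns `id` and `residues`, as returned
#'   by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.data.frame(sequences),
            all(c("id", "residues") %in% names(sequences)))
  lines <- as.vector(rbind(paste0(">", sequences$id),
                           toupper(sequences$residues)))
  writeLines(lines, path)
  invisible(path)
}

#' Drop sequences shorter than a minimum length
#'
#' Screens out protein sequences below a length threshold, the standard
#' dataset-construction filter for profile-based classifiers (short chains
#' yield unstable PSSMs and admit only small auto-covariance lags). Order is
#' preserved and the number of removed records is reported via `message()`.
#'
#' @param sequences Data frame with columns `id` and `residues`.
#' @param min_length Minimum sequence length kept (default 50).
#' @return The subset of `sequences` with `nchar(residues) >= min_length`.
#' @export
filter_by_length <- function(sequences, min_length = 50L) {
  stopifnot(is.data.frame(sequences), "residues" %in% names(sequences))
  if (!is.numeric(min_length) || length(min_length) != 1L || min_length < 1) {
    stop("'min_length' must be a single integer >= 1", call. = FALSE)
  }
  keep <- nchar(sequences$residues) >= min_length
  removed <- sum(!keep)
  if (removed > 0L) {
    message(removed, " sequence(s) shorter than ", min_length,
            " residues removed")
  }
  sequences[keep, , drop = FALSE]
}
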