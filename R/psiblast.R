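#' PSI-BLAST invocation settings
#'
#' Configuration for generating a PSSM with an external PSI-BLAST binary:
#' three search iterations and an inclusion e-value threshold of 1e-4 by
#' default, against a formatted protein database (typically non-redundant
#' Swiss-Prot).
#'
#' @param database_path Path to the formatted BLAST protein database.
#' @param iterations Number of PSI-BLAST iterations (default 3).
#' @param evalue_threshold Inclusion e-value threshold (default 1e-4).
#' @return Object of class `psiblast_config`.
#' @export
psiblast_config <- function(database_path, iterations = 3L,
                            evalue_threshold = 1e-4) {
  stopifnot(is.character(database_path), length(database_path) == 1L,
            iterations >= 1, evalue_threshold > 0)
  structure(list(database_path = database_path,
                 iterations = as.integer(iterations),
                 evalue_threshold = evalue_threshold),
            class = "psiblast_config")
}

# Argument vector for the NCBI BLAST+ psiblast front end; split out so the
# constructed command line is testable without running the binary.
psiblast_args <- function(query_path, config, pssm_path) {
  c("-query", query_path,
    "-db", config$database_path,
    "-num_iterations", format(config$iterations),
    "-inclusion_ethresh", format(config$evalue_threshold, scientific = FALSE),
    "-out_ascii_pssm", pssm_path,
    "-out", nullfile())
}

#' Generate a PSSM profile with an external PSI-BLAST binary
#'
#' Writes the query sequence to a temporary FASTA file, runs the binary
#' requesting an ASCII PSSM, and parses the result with [parse_pssm()].
#' This wrapper is optional plumbing: every other part of the toolkit works
#' from PSSM files (or the synthetic generator) and does not need the
#' binary.
#'
#' @param sequence One-row data frame with `id` and `residues` (as returned
#'   by [read_fasta()]), or a [pssm_profile()]-style list with those
#'   fields.
#' @param config A [psiblast_config()].
#' @param binary Name or path of the PSI-BLAST executable (default
#'   `"psiblast"`).
#' @return A [pssm_profile()] for the query sequence.
#' @export
run_psiblast <- function(sequence, config, binary = "psiblast") {
  stopifnot(inherits(config, "psiblast_config"))
  if (is.data.frame(sequence)) sequence <- as.list(sequence[1L, ])
  stopifnot(is.character(sequence$id), is.character(sequence$residues))
  exe <- Sys.which(binary)
  if (!nzchar(exe)) {
    stop("PSI-BLAST executable '", binary, "' not found on PATH; ",
         "profile generation is unavailable (all other functionality ",
         "works from existing PSSM files)", call. = FALSE)
  }
  query <- tempfile(fileext = ".fasta")
  pssm_out <- tempfile(fileext = ".pssm")
  on.exit(unlink(c(query, pssm_out)), add = TRUE)
  write_fasta(data.frame(id = sequence$id, residues = sequence$residues,
                         stringsAsFactors = FALSE), query)
  out <- suppressWarnings(
    system2(exe, psiblast_args(query, config, pssm_out),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L || !file.exists(pssm_out)) {
    stop("psiblast exited with status ", status, ":\n",
         paste(out, collapse = "\n"), call. = FALSE)
  }
  profile <- parse_pssm(pssm_out, id = sequence$id)
  if (profile$n != nchar(sequence$residues)) {
    stop("PSSM length ", profile$n, " does not match query length ",
         nchar(sequence$residues), call. = FALSE)
  }
  profile
}
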