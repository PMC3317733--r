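#' Construct a PSSM profile object
#'
#' Binds an L x 20 position-specific scoring matrix to the residue sequence
#' it was computed for. Columns are labelled with, and assumed to follow,
#' the canonical amino-acid order [AA_ORDER]; [parse_pssm()] reorders file
#' columns to that order before construction, so every downstream encoder
#' sees identical column semantics.
#'
#' @param id Sequence identifier (non-empty string).
#' @param residues Residue string; upper-cased on ingest. Letters outside
#'   the 20-letter alphabet are allowed.
#' @param scores Numeric matrix with `nchar(residues)` rows and 20 columns
#'   (row i = position i, column j = amino-acid type `AA_ORDER[j]`).
#' @return An object of class `pssm_profile`: a list with elements `id`,
#'   `residues`, `scores` and `n` (profile length).
#' @export
pssm_profile <- function(id, residues, scores) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("'id' must be a non-empty string", call. = FALSE)
  }
  if (!is.character(residues) || length(residues) != 1L || nchar(residues) < 1L) {
    stop("'residues' must be a non-empty string", call. = FALSE)
  }
  residues <- toupper(residues)
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (ncol(scores) != 20L) {
    stop("'scores' must have exactly 20 columns, got ", ncol(scores),
         call. = FALSE)
  }
  if (nrow(scores) != nchar(residues)) {
    stop("profile has ", nrow(scores), " score rows but ", nchar(residues),
         " residues", call. = FALSE)
  }
  if (!all(is.finite(scores))) {
    stop("'scores' contains non-finite values", call. = FALSE)
  }
  dimnames(scores) <- list(NULL, AA_ORDER)
  structure(list(id = id, residues = residues, scores = scores,
                 n = nrow(scores)),
            class = "pssm_profile")
}

#' @export
#' @method print pssm_profile
print.pssm_profile <- function(x, ...) {
  cat("PSSM profile '", x$id, "': ", x$n, " positions x 20 amino-acid columns\n",
      sep = "")
  preview <- substr(x$residues, 1L, 60L)
  if (nchar(x$residues) > 60L) preview <- paste0(preview, "...")
  cat("  sequence: ", preview, "\n", sep = "")
  cat("  score range: [", min(x$scores), ", ", max(x$scores), "]\n", sep = "")
  invisible(x)
}

#' @export
#' @method all.equal pssm_profile
all.equal.pssm_profile <- function(target, current, ...) {
  all.equal(unclass(target), unclass(current), ...)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-Q`/`-out_ascii_pssm` text dialect: free-form header lines, a
#' column-header line naming the amino acids, then one row per residue with
#' a position index, the residue letter and 20 integer log-odds scores
#' (rows carrying the additional 20-column weighted-percentage block and
#' trailing statistics are accepted; only the first 20 scores are used).
#' Columns are mapped from the header's amino-acid order onto [AA_ORDER].
#'
#' @param path Path to the PSSM file.
#' @param id Identifier for the resulting profile; defaults to the file name
#'   without extension.
#' @return A [pssm_profile()].
#' @export
parse_pssm <- function(path, id = NULL) {
  if (!file.exists(path)) {
    stop("PSSM file not found: ", path, call. = FALSE)
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)

  # column header: the first line whose tokens are 20 (or 40) amino-acid
  # letters; the first 20 give the file's column order
  header_cols <- NULL
  header_at <- 0L
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[k]]), "\\s+")[[1]]
    if (length(tok) %in% c(20L, 40L) && all(tok %in% AA_ORDER)) {
      cols <- tok[1:20]
      if (!anyDuplicated(cols)) {
        header_cols <- cols
        header_at <- k
        break
      }
    }
  }
  if (is.null(header_cols)) {
    stop("no amino-acid column header found in PSSM file: ", path,
         call. = FALSE)
  }

  residues <- character(0)
  rows <- list()
  expect_idx <- 1L
  for (k in seq(header_at + 1L, length.out = max(0L, length(lines) - header_at))) {
    line <- lines[[k]]
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    # data rows start "<index> <residue-letter> ..."; anything else ends the block
    if (length(tok) < 2L || !grepl("^[0-9]+$", tok[[1]]) ||
        !grepl("^[A-Za-z]$", tok[[2]])) {
      if (length(rows) > 0L) break else next
    }
    fields <- tok[-(1:2)]
    if (!(length(fields) %in% c(20L, 40L, 42L))) {
      stop("PSSM row at line ", k, " has ", length(fields),
           " score fields (expected 20, or 40/42 with the percentage block): ",
           path, call. = FALSE)
    }
    scores <- suppressWarnings(as.numeric(fields[1:20]))
    if (any(is.na(scores))) {
      stop("non-numeric score in PSSM row at line ", k, ": ", path,
           call. = FALSE)
    }
    residues[expect_idx] <- toupper(tok[[2]])
    rows[[expect_idx]] <- scores
    expect_idx <- expect_idx + 1L
  }
  if (length(rows) == 0L) {
    stop("no PSSM data rows found in: ", path, call. = FALSE)
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- header_cols
  mat <- mat[, AA_ORDER, drop = FALSE]
  pssm_profile(id = id, residues = paste(residues, collapse = ""),
               scores = mat)
}

#' Write a PSSM profile as a PSI-BLAST-style ASCII file
#'
#' Emits the same dialect [parse_pssm()] reads, with fixed column widths and
#' a fixed header, so generated fixtures are byte-stable and
#' `parse_pssm(write_pssm(p))` reproduces `p` exactly. Scores must be
#' integer-valued, matching the log-odds convention of the format.
#'
#' @param profile A [pssm_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  sc <- profile$scores
  if (max(abs(sc - round(sc))) > 1e-8) {
    stop("the ASCII PSSM dialect stores integer log-odds scores; ",
         "got non-integer values", call. = FALSE)
  }
  sc <- round(sc)
  res <- strsplit(profile$residues, "")[[1]]
  header <- c("",
              "Last position-specific scoring matrix computed",
              paste0("          ", paste(sprintf("%4s", AA_ORDER), collapse = "")))
  body <- vapply(seq_len(profile$n), function(i) {
    paste0(sprintf("%5d %s   ", i, res[[i]]),
           paste(sprintf("%4d", sc[i, ]), collapse = ""))
  }, character(1))
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    stop("cannot open PSSM output path: ", path, " (", conditionMessage(e), ")",
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(c(header, body, ""), con)
  invisible(path)
}
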