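#' Auto-covariance (PSSM-AC) encoding of a profile
#'
#' Transforms an L x 20 PSSM into a fixed-length vector of per-column
#' auto-covariances. For profile column j and lag d (d = 1..lg),
#' \deqn{AC(d, j) = \frac{1}{n-d} \sum_{i=1}^{n-d}
#'   (P_{i,j} - \bar P_j)(P_{i+d,j} - \bar P_j)}
#' where \eqn{\bar P_j} is the full-length mean of column j. The descriptor
#' captures local sequence-order correlation that composition-style
#' encodings discard, and its dimension is `lg * 20` regardless of sequence
#' length. Output order is column-major: all lags for the first amino-acid
#' column, then the second, and so on; element names are `AC_<aa>_lag<d>`.
#'
#' @param profile A [pssm_profile()] with more than `lg` rows.
#' @param lg Maximum lag (positive integer); every lag 1..`lg` must leave at
#'   least one product term, so `profile$n > lg` is required.
#' @param normalization `"raw"` (default) uses the scores as stored;
#'   `"sigmoid"` squashes each score through the logistic function first
#'   (see [apply_normalization()]).
#' @return Named numeric vector of length `lg * 20` with attributes
#'   `encoder_digest` and `source_id`.
#' @seealso [encode_pssm_400()], [encode_dataset()]
#' @export
encode_pssm_ac <- function(profile, lg, normalization = c("raw", "sigmoid")) {
  stopifnot(inherits(profile, "pssm_profile"))
  normalization <- match.arg(normalization)
  if (!is.numeric(lg) || length(lg) != 1L || lg < 1 || lg != round(lg)) {
    stop("'lg' must be a single positive integer", call. = FALSE)
  }
  lg <- as.integer(lg)
  n <- profile$n
  if (n <= lg) {
    stop("sequence '", profile$id, "' too short for auto-covariance: n = ",
         n, " must exceed lg = ", lg, call. = FALSE)
  }
  sc <- apply_normalization(profile, normalization)$scores
  centered <- sweep(sc, 2L, colMeans(sc))
  ac <- matrix(0, nrow = lg, ncol = 20L)
  for (d in seq_len(lg)) {
    ac[d, ] <- colSums(centered[seq_len(n - d), , drop = FALSE] *
                       centered[seq_len(n - d) + d, , drop = FALSE]) / (n - d)
  }
  out <- as.vector(ac)  # column-major: lag fastest within each aa column
  names(out) <- paste0("AC_", rep(AA_ORDER, each = lg), "_lag",
                       rep(seq_len(lg), times = 20L))
  structure(out,
            encoder_digest = encoder_digest("pssm-ac", lg = lg,
                                            normalization = normalization),
            source_id = profile$id)
}

#' Composition (PSSM-400) encoding of a profile
#'
#' Order-free 400-dimensional descriptor: for each of the 20 residue types,
#' the PSSM rows at positions where the sequence shows that residue are
#' aggregated into one 20-vector, and the 20 blocks are concatenated in
#' canonical order. Residue types absent from the sequence contribute an
#' all-zero block; residues outside the 20-letter alphabet contribute to no
#' block. The default aggregation is the mean over occurrences, which keeps
#' the descriptor independent of sequence length; `aggregate = "sum"` gives
#' the summed variant. Element names are `P400_<residue>_<column>`.
#'
#' @param profile A [pssm_profile()].
#' @param aggregate `"mean"` (default) or `"sum"` over the occurrences of
#'   each residue type.
#' @param normalization As in [encode_pssm_ac()].
#' @return Named numeric vector of length 400 with attributes
#'   `encoder_digest` and `source_id`.
#' @export
encode_pssm_400 <- function(profile, aggregate = c("mean", "sum"),
                            normalization = c("raw", "sigmoid")) {
  stopifnot(inherits(profile, "pssm_profile"))
  aggregate <- match.arg(aggregate)
  normalization <- match.arg(normalization)
  sc <- apply_normalization(profile, normalization)$scores
  res <- strsplit(profile$residues, "")[[1]]
  blocks <- lapply(AA_ORDER, function(a) {
    idx <- which(res == a)
    if (length(idx) == 0L) return(numeric(20L))
    agg <- colSums(sc[idx, , drop = FALSE])
    if (aggregate == "mean") agg <- agg / length(idx)
    agg
  })
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- paste0("P400_", rep(AA_ORDER, each = 20L), "_",
                       rep(AA_ORDER, times = 20L))
  structure(out,
            encoder_digest = encoder_digest("pssm-400", aggregate = aggregate,
                                            normalization = normalization),
            source_id = profile$id)
}

#' Optional score rescaling before encoding
#'
#' `"raw"` returns the profile unchanged; `"sigmoid"` replaces each score x
#' by the logistic transform 1/(1 + exp(-x)), a rescaling some profile-based
#' encoders apply to map integer log-odds into (0, 1). The sequence and
#' length are untouched.
#'
#' @param profile A [pssm_profile()].
#' @param mode `"raw"` or `"sigmoid"`.
#' @return A [pssm_profile()] with transformed scores.
#' @export
apply_normalization <- function(profile, mode = c("raw", "sigmoid")) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (is.character(mode) && length(mode) == 1L &&
      !mode %in% c("raw", "sigmoid")) {
    stop("unknown normalization mode: '", mode, "'", call. = FALSE)
  }
  mode <- match.arg(mode)
  if (mode == "raw") return(profile)
  out <- profile
  out$scores <- 1 / (1 + exp(-profile$scores))
  out
}

#' Encode a set of profiles into a feature matrix
#'
#' Applies one encoder configuration to every profile and stacks the
#' resulting vectors into a matrix (rows = sequences, in input order,
#' rownames = profile ids). The matrix carries the configuration digest so
#' that models trained on it can detect encoding mismatches at prediction
#' time.
#'
#' @param profiles List of [pssm_profile()] objects.
#' @param encoder `"pssm-ac"` or `"pssm-400"`.
#' @param lg Maximum lag for `"pssm-ac"` (default 30, ignored otherwise).
#' @param normalization,aggregate Passed to the encoder.
#' @return Numeric matrix with attribute `encoder_digest`.
#' @export
encode_dataset <- function(profiles, encoder = c("pssm-ac", "pssm-400"),
                           lg = 30L, normalization = c("raw", "sigmoid"),
                           aggregate = c("mean", "sum")) {
  encoder <- match.arg(encoder)
  normalization <- match.arg(normalization)
  aggregate <- match.arg(aggregate)
  stopifnot(is.list(profiles), length(profiles) > 0L)
  vecs <- lapply(profiles, function(p) {
    if (encoder == "pssm-ac") {
      encode_pssm_ac(p, lg = lg, normalization = normalization)
    } else {
      encode_pssm_400(p, aggregate = aggregate, normalization = normalization)
    }
  })
  mat <- do.call(rbind, vecs)
  rownames(mat) <- vapply(profiles, `[[`, character(1), "id")
  attr(mat, "encoder_digest") <- attr(vecs[[1L]], "encoder_digest")
  mat
}

#' Write / read a feature matrix as delimited text
#'
#' One row per sequence; the first column holds the sequence identifier and
#' the header names each feature. The encoder digest is stored in a leading
#' comment line so it survives the round trip.
#'
#' @param features Matrix from [encode_dataset()].
#' @param path Output (or input) path.
#' @param sep Field separator, tab by default.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the matrix with its `encoder_digest` attribute restored.
#' @export
write_features <- function(features, path, sep = "\t") {
  stopifnot(is.matrix(features))
  digest <- attr(features, "encoder_digest")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(digest)) writeLines(paste0("# encoder_digest: ", digest), con)
  writeLines(paste(c("id", colnames(features)), collapse = sep), con)
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(features)))
  utils::write.table(data.frame(id = ids, features, check.names = FALSE),
                     con, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path, sep = "\t") {
  lines <- readLines(path, n = 1L)
  digest <- NULL
  skip <- 0L
  if (length(lines) == 1L && startsWith(lines, "# encoder_digest: ")) {
    digest <- sub("^# encoder_digest: ", "", lines)
    skip <- 1L
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  attr(mat, "encoder_digest") <- digest
  mat
}

# Canonical, human-readable fingerprint of an encoder configuration; stored
# with feature matrices and trained models to catch encoding mismatches.
encoder_digest <- function(encoder, ...) {
  opts <- list(...)
  paste(c(encoder, paste(names(opts), unlist(opts), sep = "=")),
        collapse = "|")
}
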