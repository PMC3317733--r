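#' Specification of a synthetic labelled profile corpus
#'
#' Describes a two-class corpus of artificial PSSM profiles in which the
#' class signal lives purely in local sequence-order correlation: each of
#' the 20 profile columns of a sequence is an independent stationary AR(1)
#' series whose lag-1 coefficient is `rho_pos` for positives and `rho_neg`
#' for negatives. The marginal standard deviation is held at `noise_sd`
#' for both classes (innovation variance is `noise_sd^2 * (1 - rho^2)`), so
#' per-column means and variances match across classes and order-free
#' descriptors such as PSSM-400 carry essentially no class information,
#' while the auto-covariance descriptor does. Scores are scaled by
#' `score_scale`, rounded to integers and clamped to \[-10, 10\] to mimic
#' the PSI-BLAST log-odds dialect.
#'
#' @param n_pos,n_neg Number of positive / negative sequences.
#' @param length_range Inclusive (min, max) of uniformly drawn sequence
#'   lengths.
#' @param rho_pos,rho_neg AR(1) coefficients in (-1, 1) for the two classes.
#' @param noise_sd Marginal standard deviation of each column (> 0).
#' @param score_scale Multiplier mapping the latent series to the integer
#'   log-odds range (> 0).
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the spec.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_pos = 100L, n_neg = 100L,
                       length_range = c(60L, 100L),
                       rho_pos = 0.7, rho_neg = 0.0,
                       noise_sd = 1, score_scale = 3, seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1,
            length(length_range) == 2L, length_range[1] >= 2,
            length_range[1] <= length_range[2],
            abs(rho_pos) < 1, abs(rho_neg) < 1,
            noise_sd > 0, score_scale > 0)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 rho_pos = rho_pos, rho_neg = rho_neg,
                 noise_sd = noise_sd, score_scale = score_scale,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' @export
#' @method print synth_spec
print.synth_spec <- function(x, ...) {
  cat(sprintf(paste0("Synthetic corpus spec: %d positive (rho = %g) + ",
                     "%d negative (rho = %g) profiles,\n  lengths %d-%d, ",
                     "marginal sd %g, score scale %g, seed %d\n"),
              x$n_pos, x$rho_pos, x$n_neg, x$rho_neg,
              x$length_range[1], x$length_range[2],
              x$noise_sd, x$score_scale, x$seed))
  invisible(x)
}

# Stationary AR(1) series with lag-1 coefficient rho and unit marginal
# variance: x_1 ~ N(0, 1), x_i = rho * x_{i-1} + sqrt(1 - rho^2) * e_i.
ar1_series <- function(n, rho) {
  innov <- stats::rnorm(n)
  x <- numeric(n)
  x[1L] <- innov[1L]
  s <- sqrt(1 - rho^2)
  for (i in seq_len(n - 1L) + 1L) {
    x[i] <- rho * x[i - 1L] + s * innov[i]
  }
  x
}

#' Generate one synthetic PSSM profile
#'
#' Draws a random residue string (uniform over the 20-letter alphabet) and
#' an L x 20 score matrix whose columns are independent stationary AR(1)
#' series with the requested lag-1 autocorrelation and marginal standard
#' deviation `noise_sd`. With `quantize = TRUE` (the default) scores are
#' scaled by `score_scale`, rounded and clamped to \[-10, 10\], matching the
#' integer log-odds range of real profiles; `quantize = FALSE` keeps the
#' continuous series (times `score_scale`), which is convenient for
#' checking the generator against AR(1) theory.
#'
#' @param length Sequence length L.
#' @param rho AR(1) coefficient in (-1, 1).
#' @param noise_sd Marginal standard deviation.
#' @param score_scale Scale applied before rounding.
#' @param id Profile identifier.
#' @param quantize Round and clamp scores to the integer dialect?
#' @param seed Optional integer seed for a self-contained reproducible
#'   draw; when `NULL` the current RNG stream is used (as
#'   [generate_profiles()] does under its own seed).
#' @return A [pssm_profile()].
#' @export
generate_profile <- function(length, rho, noise_sd = 1, score_scale = 3,
                             id = "synth", quantize = TRUE, seed = NULL) {
  stopifnot(length >= 2, abs(rho) < 1, noise_sd > 0, score_scale > 0)
  draw <- function() {
    scores <- vapply(seq_len(20L),
                     function(j) ar1_series(length, rho) * noise_sd,
                     numeric(length))
    scores <- scores * score_scale
    if (quantize) scores <- pmin(pmax(round(scores), -10), 10)
    residues <- paste(sample(AA_ORDER, length, replace = TRUE),
                      collapse = "")
    pssm_profile(id = id, residues = residues, scores = scores)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate an in-memory labelled corpus
#'
#' Draws the full corpus described by a [synth_spec()]: positives first
#' (`pos_001`, ...), then negatives (`neg_001`, ...). Deterministic given
#' the spec's seed.
#'
#' @param spec A [synth_spec()].
#' @return List with `profiles` (list of [pssm_profile()]), `labels`
#'   (+1/-1 vector) and `ids`.
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    ids <- c(sprintf("pos_%03d", seq_len(spec$n_pos)),
             sprintf("neg_%03d", seq_len(spec$n_neg)))
    rhos <- c(rep(spec$rho_pos, spec$n_pos), rep(spec$rho_neg, spec$n_neg))
    lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                   spec$n_pos + spec$n_neg, replace = TRUE)
    profiles <- lapply(seq_along(ids), function(i) {
      generate_profile(lens[i], rhos[i], noise_sd = spec$noise_sd,
                       score_scale = spec$score_scale, id = ids[i])
    })
    list(profiles = profiles,
         labels = c(rep(1, spec$n_pos), rep(-1, spec$n_neg)),
         ids = ids)
  })
}

#' Write a synthetic corpus to disk
#'
#' Materialises a [synth_spec()] as the same file set the real pipeline
#' consumes: one FASTA file of all sequences, one ASCII PSSM file per
#' sequence (via [write_pssm()]) and a tab-separated label table with
#' columns `id` and `label`.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the corpus (`profiles`, `labels`, `ids`)
#'   and the paths `fasta`, `pssm_dir`, `labels_path`.
#' @export
generate_corpus <- function(spec, dir) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  corpus <- generate_profiles(spec)
  fasta <- file.path(dir, "sequences.fasta")
  write_fasta(data.frame(id = corpus$ids,
                         residues = vapply(corpus$profiles, `[[`,
                                           character(1), "residues"),
                         stringsAsFactors = FALSE),
              fasta)
  pssm_dir <- file.path(dir, "pssm")
  if (!dir.exists(pssm_dir)) dir.create(pssm_dir)
  for (p in corpus$profiles) {
    write_pssm(p, file.path(pssm_dir, paste0(p$id, ".pssm")))
  }
  labels_path <- file.path(dir, "labels.tsv")
  utils::write.table(data.frame(id = corpus$ids, label = corpus$labels),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(corpus, list(fasta = fasta, pssm_dir = pssm_dir,
                           labels_path = labels_path)))
}

#' Read a label table
#'
#' Reads the tab-separated `id`/`label` table written by
#' [generate_corpus()] (labels over +1/-1).
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `id` and `label`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df))) {
    stop("label table must have columns 'id' and 'label': ", path,
         call. = FALSE)
  }
  df$label <- check_labels(df$label, "label")
  df
}
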