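pair_labels <- function() paste0(NUC_PAIRS[, 1], ">", NUC_PAIRS[, 2])

#' ddG of a central substitution versus footprint position
#'
#' For one odd-length sequence, substitutes the central base and computes
#' `ddG` (change in footprint opening free energy, kcal/mol) for every
#' footprint start position and each of the 6 unordered nucleotide pairs
#' \{a,b\}, evaluated in the fixed lexicographic direction a -> b after
#' first setting the central base to a. The reverse direction is the exact
#' negation, so it carries no extra information.
#'
#' @param seq Odd-length RNA string; the substitution site is the central
#'   base `(n+1)/2`.
#' @param footprint Footprint width in nt (7 or 10 in practice).
#' @param model An [energy_model()].
#' @return Numeric matrix, 6 rows (rownames `"A>C"`, ..., `"G>U"`) by
#'   `n - footprint + 1` columns (1-based footprint start positions).
#' @export
scan_sequence <- function(seq, footprint = 7, model = energy_model()) {
  s <- norm_rna(seq)
  n <- nchar(s)
  if (n %% 2L == 0L)
    stop("`seq` must have odd length so a central base exists",
         call. = FALSE)
  center <- (n + 1L) %/% 2L
  kT <- model$kT
  # opening free-energy profile for each identity of the central base
  dg <- lapply(setNames(BASES, BASES), function(b) {
    p <- open_profile(sub_base(s, center, b), footprint, model)
    -kT * log(as.numeric(p))
  })
  out <- matrix(NA_real_, nrow = nrow(NUC_PAIRS), ncol = n - footprint + 1L,
                dimnames = list(pair_labels(), NULL))
  for (r in seq_len(nrow(NUC_PAIRS)))
    out[r, ] <- dg[[NUC_PAIRS[r, 2]]] - dg[[NUC_PAIRS[r, 1]]]
  out
}

#' Random-sequence scan of substitution effects
#'
#' Draws `n_sequences` uniform-random RNA sequences, applies
#' [scan_sequence()] to each, and aggregates the per-pair, per-position
#' mean and population standard deviation of ddG over the sequence
#' ensemble. This is the in-silico experiment showing that substitutions
#' far from a footprint have zero mean but non-zero spread of effect.
#'
#' @param n_sequences Number of random sequences (>= 2).
#' @param length Odd sequence length in nt (101, 201 or 401 by
#'   convention).
#' @param footprint Footprint width in nt.
#' @param model An [energy_model()].
#' @param seed Integer seed; the scan is deterministic given the seed.
#' @param keep_values Keep the full `6 x positions x n_sequences` array of
#'   ddG values (needed for pooled standard errors).
#' @return Object of class `scan_profile`: list with matrices `mean` and
#'   `sd` (6 x positions), `center`, `footprint`, `length`,
#'   `n_sequences`, `seed`, and optionally `values`.
#' @export
run_random_scan <- function(n_sequences, length, footprint = 7,
                            model = energy_model(), seed,
                            keep_values = FALSE) {
  stopifnot(n_sequences >= 2)
  if (length %% 2L == 0L)
    stop("`length` must be odd", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  seqs <- gen_random_sequences(n_sequences, length, seed)
  npos <- length - footprint + 1L
  vals <- array(NA_real_, dim = c(6L, npos, n_sequences),
                dimnames = list(pair_labels(), NULL, NULL))
  for (i in seq_len(n_sequences))
    vals[, , i] <- scan_sequence(seqs[i], footprint, model)
  mu <- apply(vals, c(1, 2), mean)
  # population (n-denominator) standard deviation
  sdev <- sqrt(apply(vals, c(1, 2), function(v) mean((v - mean(v))^2)))
  structure(
    list(mean = mu, sd = sdev, center = (length + 1L) %/% 2L,
         footprint = footprint, length = length,
         n_sequences = n_sequences, seed = seed,
         values = if (keep_values) vals else NULL),
    class = "scan_profile")
}

#' @export
print.scan_profile <- function(x, ...) {
  cat(sprintf(paste0("Random-sequence ddG scan: %d sequences x %d nt, ",
                     "footprint %d nt (seed %s)\n"),
              x$n_sequences, x$length, x$footprint, format(x$seed)))
  cat(sprintf("  max |mean ddG| %.4g, max sd %.4g kcal/mol\n",
              max(abs(x$mean)), max(x$sd)))
  invisible(x)
}

#' @export
as.data.frame.scan_profile <- function(x, ...) {
  npos <- ncol(x$mean)
  data.frame(pair = rep(rownames(x$mean), npos),
             start = rep(seq_len(npos), each = 6L),
             mean_ddG_kcal_mol = as.vector(x$mean),
             sd_ddG_kcal_mol = as.vector(x$sd),
             stringsAsFactors = FALSE)
}

#' Centred running mean
#'
#' Smooths a positional profile with a centred running average. The window
#' shrinks symmetrically at the edges; `window = 1` is the identity. Even
#' windows are rounded up to the next odd width so the average stays
#' centred. Applied to a [run_random_scan()] profile it first averages the
#' standard deviation across the 6 substitution pairs and then smooths
#' along position.
#'
#' @param x Numeric vector, or a `scan_profile`.
#' @param window Window width in positions (default 10).
#' @param ... Unused.
#' @return Numeric vector of the same length.
#' @export
smooth_profile <- function(x, window = 10, ...) UseMethod("smooth_profile")

#' @rdname smooth_profile
#' @export
smooth_profile.default <- function(x, window = 10, ...) {
  stopifnot(is.numeric(x), window >= 1)
  h <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(p) {
    m <- min(h, p - 1L, n - p)
    mean(x[(p - m):(p + m)])
  }, numeric(1))
}

#' @rdname smooth_profile
#' @export
smooth_profile.scan_profile <- function(x, window = 10, ...) {
  smooth_profile.default(colMeans(x$sd), window)
}

#' Write a scan profile as TSV
#'
#' Columns: pair, start (1-based footprint start, nt), mean and
#' population-sd ddG (kcal/mol), and the pair-averaged smoothed sd.
#'
#' @param profile A `scan_profile`.
#' @param path Output path.
#' @param window Smoothing window for the last column.
#' @export
write_scan_profile <- function(profile, path, window = 10) {
  df <- as.data.frame(profile)
  sm <- smooth_profile(profile, window)
  df$smoothed_sd_kcal_mol <- sm[df$start]
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.scan_profile <- function(x, which = c("sd", "mean"), window = 10, ...) {
  which <- match.arg(which)
  pos <- seq_len(ncol(x$mean)) - x$center
  if (which == "sd") {
    y <- colMeans(x$sd)
    plot(pos, y, type = "l", col = "grey60",
         xlab = "footprint start - substitution position (nt)",
         ylab = "sd of ddG (kcal/mol)", ...)
    lines(pos, smooth_profile(x, window), col = "blue", lwd = 2)
    legend("topright", c("per-position", "smoothed"), lwd = c(1, 2),
           col = c("grey60", "blue"), bty = "n")
  } else {
    y <- colMeans(x$mean)
    plot(pos, y, type = "l", xlab =
           "footprint start - substitution position (nt)",
         ylab = "mean ddG (kcal/mol)", ...)
    abline(h = 0, lty = 2, col = "red")
  }
  abline(v = 0, lty = 3, col = "red")
  invisible(x)
}
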