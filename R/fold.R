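#' Boltzmann partition function of RNA secondary structures
#'
#' Sums `exp(-E/kT)` over every pseudoknot-free secondary structure of the
#' sequence under the canonical pair set (GC, AU, GU), with hairpin loops of
#' at least `min_hairpin_loop` unpaired bases, excluding any structure that
#' pairs a position listed in `forced_unpaired`. The open chain has energy 0
#' and weight 1, so `Z >= 1` and the ensemble free energy
#' `G = -kT * log(Z)` is never positive. The recursion is the standard
#' O(N^3) dynamic programme.
#'
#' @param seq Character string; RNA (or DNA, T is read as U).
#' @param model An [energy_model()].
#' @param forced_unpaired Integer vector of 1-based positions constrained to
#'   stay unpaired (hard constraint, the in-silico protein footprint).
#' @return An object of class `ensemble_result`: list with `Z`, `log_Z` and
#'   `G` (kcal/mol). `Z` may overflow to `Inf` for long, pairing-rich
#'   windows; `log_Z` is always finite and is what downstream code uses.
#' @examples
#' partition_function("GGGAAAACCC")
#' partition_function("GGGAAAACCC", forced_unpaired = 1:3)
#' @export
partition_function <- function(seq, model = energy_model(),
                               forced_unpaired = integer(0)) {
  s <- norm_rna(seq)
  n <- nchar(s)
  forced <- forced_mask(forced_unpaired, n)
  a <- model_args(model)
  log_z <- c_log_partition(rna_ints(s), forced, a$e_gc, a$e_au, a$e_gu,
                           a$stack_bonus, a$kT, a$minhp)
  structure(list(Z = exp(log_z), log_Z = log_z, G = -a$kT * log_z + 0),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("RNA ensemble: log Z = %.6g, G = %.6g kcal/mol\n",
              x$log_Z, x$G))
  invisible(x)
}

forced_mask <- function(forced_unpaired, n) {
  if (length(forced_unpaired) == 0L) return(logical(n))
  p <- as.integer(forced_unpaired)
  if (anyNA(p) || any(p < 1L) || any(p > n))
    stop("`forced_unpaired` positions must lie in [1, ", n, "]",
         call. = FALSE)
  mask <- logical(n)
  mask[p] <- TRUE
  mask
}

#' Probability that an interval is entirely unpaired
#'
#' Ratio of the constrained to the unconstrained partition function:
#' the Boltzmann probability that no base in the footprint
#' `[start, start + width - 1]` is paired in the equilibrium ensemble.
#'
#' @param seq Character string; RNA (T read as U).
#' @param start 1-based start of the interval.
#' @param width Interval width in nt (`width = 0` is the empty constraint
#'   and returns 1).
#' @param model An [energy_model()].
#' @return A probability in (0, 1].
#' @examples
#' prob_unpaired("GGGAAAACCC", start = 4, width = 4)
#' @export
prob_unpaired <- function(seq, start, width, model = energy_model()) {
  s <- norm_rna(seq)
  n <- nchar(s)
  start <- as.integer(start)
  width <- as.integer(width)
  if (is.na(start) || is.na(width) || width < 0L || start < 1L ||
      start + width - 1L > n)
    stop("interval [", start, ", ", start + width - 1L,
         "] is outside the sequence (length ", n, ")", call. = FALSE)
  if (width == 0L) return(1)
  a <- model_args(model)
  si <- rna_ints(s)
  lz0 <- c_log_partition(si, logical(n), a$e_gc, a$e_au, a$e_gu,
                         a$stack_bonus, a$kT, a$minhp)
  mask <- logical(n)
  mask[start:(start + width - 1L)] <- TRUE
  lzc <- c_log_partition(si, mask, a$e_gc, a$e_au, a$e_gu,
                         a$stack_bonus, a$kT, a$minhp)
  exp(lzc - lz0)
}

# opening probability of every width-k footprint; returns numeric vector
# indexed by 1-based footprint start, with the unconstrained log Z as attr
open_profile <- function(seq, width, model = energy_model()) {
  s <- norm_rna(seq)
  n <- nchar(s)
  width <- as.integer(width)
  if (width < 1L || width > n)
    stop("footprint width must be in [1, sequence length]", call. = FALSE)
  a <- model_args(model)
  c_open_profile(rna_ints(s), width, a$e_gc, a$e_au, a$e_gu,
                 a$stack_bonus, a$kT, a$minhp)
}

#' Exhaustively enumerate RNA secondary structures
#'
#' Lists every admissible secondary structure of a short sequence (<= 25 nt)
#' together with its energy under the model. This is the package's ground
#' truth: summing `exp(-E/kT)` over the enumeration must reproduce
#' [partition_function()], and filtering on dot-bracket substrings gives
#' exact footprint opening probabilities and effective dissociation
#' constants by brute force.
#'
#' @inheritParams partition_function
#' @return A data.frame with columns `structure` (dot-bracket) and `energy`
#'   (kcal/mol), one row per structure, with attribute `Z` (the Boltzmann
#'   sum).
#' @examples
#' enumerate_structures("GAAAC")  # open chain + the single G-C pair
#' @export
enumerate_structures <- function(seq, model = energy_model(),
                                 forced_unpaired = integer(0)) {
  s <- norm_rna(seq)
  n <- nchar(s)
  if (n > 25L)
    stop("exhaustive enumeration is limited to sequences of <= 25 nt ",
         "(got ", n, ")", call. = FALSE)
  b <- rna_ints(s)
  forced <- forced_mask(forced_unpaired, n)
  pe <- model$pair_energies
  minhp <- model$min_hairpin_loop
  en <- matrix(NA_real_, 4, 4)
  en[3, 2] <- en[2, 3] <- pe[["GC"]]
  en[1, 4] <- en[4, 1] <- pe[["AU"]]
  en[3, 4] <- en[4, 3] <- pe[["GU"]]

  memo <- new.env(parent = emptyenv())
  # structures of [i..j] as flat integer vectors c(i1,j1, i2,j2, ...)
  recur <- function(i, j) {
    if (i >= j) return(list(integer(0)))
    key <- paste0(i, ",", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- recur(i + 1L, j)
    if (!forced[i]) {
      lo <- i + minhp + 1L
      if (lo <= j) {
        for (l in lo:j) {
          if (!forced[l] && !is.na(en[b[i], b[l]])) {
            left <- recur(i + 1L, l - 1L)
            right <- recur(l + 1L, j)
            for (L in left) for (R in right)
              out[[length(out) + 1L]] <- c(i, l, L, R)
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }
  structs <- recur(1L, n)

  db <- character(length(structs))
  energy <- numeric(length(structs))
  for (si in seq_along(structs)) {
    p <- structs[[si]]
    dots <- rep(".", n)
    e <- 0
    if (length(p)) {
      op <- p[seq(1, length(p), by = 2)]
      cl <- p[seq(2, length(p), by = 2)]
      dots[op] <- "("
      dots[cl] <- ")"
      e <- sum(en[cbind(b[op], b[cl])])
      if (model$stack_bonus != 0) {
        key <- paste0(op, ":", cl)
        stacked <- paste0(op + 1L, ":", cl - 1L) %in% key
        e <- e + model$stack_bonus * sum(stacked)
      }
    }
    db[si] <- paste(dots, collapse = "")
    energy[si] <- e
  }
  res <- data.frame(structure = db, energy = energy,
                    stringsAsFactors = FALSE)
  attr(res, "Z") <- sum(exp(-energy / model$kT))
  res
}
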