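#' Simplified nearest-neighbour RNA energy model
#'
#' The built-in folding model assigns one stacking-independent energy to each
#' canonical base pair (GC, AU, GU wobble) plus an optional bonus per
#' adjacent stacked pair, folds at a fixed temperature, and forbids hairpin
#' loops shorter than `min_hairpin_loop` unpaired bases. It is deliberately
#' self-contained: it reproduces the qualitative physics of
#' accessibility-mediated binding (helices sequester footprints, a point
#' substitution re-weights the ensemble) without the full Turner parameter
#' set, so that every result in the package can be checked against an
#' exhaustive enumeration oracle.
#'
#' `kT` is computed as 0.0019872 kcal/(mol K) times `temperature`; the
#' default 310.15 K gives kT = 0.61633 kcal/mol.
#'
#' @param temperature Folding temperature in Kelvin (default 310.15, i.e.
#'   37 C).
#' @param pair_energies Named numeric vector of per-pair energies in
#'   kcal/mol; must contain `GC`, `AU` and `GU`. More negative = more stable.
#' @param stack_bonus Energy in kcal/mol added for every pair of adjacent
#'   stacked base pairs (i,j) and (i+1,j-1); default 0 (off).
#' @param min_hairpin_loop Minimum number of unpaired bases in a hairpin
#'   loop; must be >= 3 (steric limit), default 3.
#' @return An object of class `energy_model`.
#' @examples
#' m <- energy_model()
#' m$kT
#' @export
energy_model <- function(temperature = 310.15,
                         pair_energies = c(GC = -3, AU = -2, GU = -1),
                         stack_bonus = 0,
                         min_hairpin_loop = 3) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  if (!all(c("GC", "AU", "GU") %in% names(pair_energies)))
    stop("`pair_energies` must have entries named GC, AU and GU",
         call. = FALSE)
  pair_energies <- pair_energies[c("GC", "AU", "GU")]
  if (!all(is.finite(pair_energies)))
    stop("all pair energies must be finite", call. = FALSE)
  stopifnot(is.numeric(stack_bonus), length(stack_bonus) == 1L,
            is.finite(stack_bonus))
  min_hairpin_loop <- as.integer(min_hairpin_loop)
  if (is.na(min_hairpin_loop) || min_hairpin_loop < 3L)
    stop("`min_hairpin_loop` must be an integer >= 3", call. = FALSE)
  structure(
    list(temperature = temperature,
         kT = 0.0019872 * temperature,
         pair_energies = pair_energies,
         stack_bonus = stack_bonus,
         min_hairpin_loop = min_hairpin_loop),
    class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Simplified nearest-neighbour RNA energy model\n")
  cat(sprintf("  temperature: %.2f K (kT = %.5f kcal/mol)\n",
              x$temperature, x$kT))
  cat(sprintf("  pair energies (kcal/mol): GC %.2f, AU %.2f, GU %.2f\n",
              x$pair_energies[["GC"]], x$pair_energies[["AU"]],
              x$pair_energies[["GU"]]))
  cat(sprintf("  stack bonus: %.2f kcal/mol, min hairpin loop: %d nt\n",
              x$stack_bonus, x$min_hairpin_loop))
  invisible(x)
}

# internal: argument list handed to the C++ kernels
model_args <- function(model) {
  list(e_gc = model$pair_energies[["GC"]],
       e_au = model$pair_energies[["AU"]],
       e_gu = model$pair_energies[["GU"]],
       stack_bonus = model$stack_bonus,
       kT = model$kT,
       minhp = model$min_hairpin_loop)
}
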