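#' k-mer affinity table
#'
#' A complete map from every k-mer to the dissociation constant K_D (nM) of
#' a single-stranded-RNA-binding protein for that k-mer on unstructured RNA,
#' in the style of RNAcompete-derived tables. `Inf` marks a non-binder and
#' contributes exactly zero to effective-affinity sums.
#'
#' @param kd Named numeric vector: names are the k-mers (A/C/G/U, all the
#'   same length k), values K_D in nM (> 0 or `Inf`). Must be complete
#'   (all 4^k k-mers present).
#' @return Object of class `affinity_table` (a named numeric vector with
#'   attribute `k`).
#' @seealso [read_affinity_table()], [gen_affinity_table()],
#'   [effective_kd()]
#' @export
affinity_table <- function(kd) {
  if (!is.numeric(kd) || is.null(names(kd)))
    stop("`kd` must be a named numeric vector", call. = FALSE)
  nm <- chartr("T", "U", toupper(names(kd)))
  k <- unique(nchar(nm))
  if (length(k) != 1L)
    stop("all k-mers must have the same length", call. = FALSE)
  if (any(grepl("[^ACGU]", nm)))
    stop("k-mer names must use the A/C/G/U alphabet", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicated k-mers in affinity table", call. = FALSE)
  if (length(nm) != 4^k)
    stop("affinity table is incomplete: expected ", 4^k, " ", k,
         "-mers, got ", length(nm), call. = FALSE)
  if (anyNA(kd) || any(kd <= 0))
    stop("all K_D values must be > 0 (Inf allowed)", call. = FALSE)
  kd <- as.numeric(kd)
  names(kd) <- nm
  # radix order = lexicographic A<C<G<U, the order kmer_indices() assumes
  structure(kd[order(nm, method = "radix")], k = k,
            class = "affinity_table")
}

#' @export
print.affinity_table <- function(x, ...) {
  k <- attr(x, "k")
  fin <- x[is.finite(x)]
  cat(sprintf("Affinity table: %d %d-mers, K_D (nM)\n", length(x), k))
  cat(sprintf("  finite entries: %d; range %.4g - %.4g nM\n",
              length(fin), min(fin), max(fin)))
  best <- names(x)[which.min(x)]
  cat(sprintf("  tightest binder: %s (%.4g nM)\n", best, min(x)))
  invisible(x)
}

#' Read / write an affinity table as 2-column TSV
#'
#' Format: header `kmer<TAB>kd_nM`, one row per k-mer, `inf` for
#' non-binders. Values are written with 17 significant digits so that a
#' write/read round trip is bit-exact.
#'
#' @param path File path.
#' @return For `read_affinity_table`, an [affinity_table()].
#' @export
read_affinity_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character"))
  if (!identical(names(df), c("kmer", "kd_nM")))
    stop("affinity TSV must have header 'kmer\\tkd_nM'", call. = FALSE)
  vals <- ifelse(tolower(df$kd_nM) == "inf", Inf,
                 suppressWarnings(as.numeric(df$kd_nM)))
  if (anyNA(vals))
    stop("non-numeric K_D in affinity table", call. = FALSE)
  affinity_table(setNames(vals, df$kmer))
}

#' @param table An [affinity_table()].
#' @rdname read_affinity_table
#' @export
write_affinity_table <- function(table, path) {
  stopifnot(inherits(table, "affinity_table"))
  vals <- ifelse(is.finite(table), sprintf("%.17g", unclass(table)), "inf")
  writeLines(c("kmer\tkd_nM", paste(names(table), vals, sep = "\t")), path)
  invisible(path)
}

#' Opening free energy of a protein footprint
#'
#' `dG_open = -kT * log(p_open)` where `p_open` is the ensemble probability
#' that the whole footprint is unpaired (see [prob_unpaired()]): the free
#' energy the protein must pay to find its site single-stranded.
#'
#' @inheritParams prob_unpaired
#' @param width Footprint width in nt (default 7, the HuR footprint).
#' @return List with `p_open` and `dG_open` (kcal/mol, >= 0).
#' @export
opening_free_energy <- function(seq, start, width = 7,
                                model = energy_model()) {
  p <- prob_unpaired(seq, start, width, model)
  list(p_open = p, dG_open = -model$kT * log(p))
}

#' Change in opening free energy between two alleles
#'
#' For a fixed footprint, `ddG = dG_open(mut) - dG_open(wt)`. The protein's
#' intrinsic (sequence-specific) binding energy is the same for both
#' alleles when the substitution lies outside the footprint, so it cancels
#' and the four fold configurations (each allele with and without bound
#' protein) reduce to two constrained folds per allele. Positive `ddG`
#' means the mutant footprint is harder to open.
#'
#' @param seq_wt,seq_mut Two sequences differing at exactly one position.
#' @param start,width Footprint interval (1-based start).
#' @param model An [energy_model()].
#' @return `ddG` in kcal/mol.
#' @export
ddG <- function(seq_wt, seq_mut, start, width = 7, model = energy_model()) {
  wt <- norm_rna(seq_wt)
  mut <- norm_rna(seq_mut)
  nd <- length(diff_positions(wt, mut))
  if (identical(wt, mut)) return(0)
  if (nd != 1L)
    stop("`seq_wt` and `seq_mut` must differ at exactly one position ",
         "(differ at ", nd, ")", call. = FALSE)
  g_wt <- opening_free_energy(wt, start, width, model)$dG_open
  g_mut <- opening_free_energy(mut, start, width, model)$dG_open
  g_mut - g_wt
}

#' Structure-aware effective dissociation constant
#'
#' Dilute, single-occupancy limit of protein binding to a structured RNA:
#' each footprint placement contributes in parallel, discounted by the
#' probability that its bases are unpaired,
#' `1 / K_eff = sum_i p_open(i) / K_D(w_i)`,
#' where `w_i` is the k-mer starting at `i`. In `ensemble` mode the sum
#' runs over every footprint placement in the window (placements
#' overhanging the 3' end are not counted); in `single_site` mode only a
#' designated footprint interval contributes, which isolates the effect of
#' a variant on one site.
#'
#' @param seq RNA window (character string).
#' @param table An [affinity_table()]; its k defines the footprint width.
#' @param model An [energy_model()].
#' @param mode `"ensemble"` (default) or `"single_site"`.
#' @param site_start 1-based start of the designated footprint
#'   (required in `single_site` mode).
#' @return K_eff in nM (`Inf` when every placement is a non-binder).
#' @examples
#' tab <- two_tier_affinity_table("AUUUAUU", k = 7)
#' effective_kd(paste0(strrep("A", 20), "AUUUAUU", strrep("A", 20)), tab)
#' @export
effective_kd <- function(seq, table, model = energy_model(),
                         mode = c("ensemble", "single_site"),
                         site_start = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "affinity_table"))
  s <- norm_rna(seq)
  k <- attr(table, "k")
  if (nchar(s) < k)
    stop("sequence shorter than the footprint (", k, " nt)", call. = FALSE)
  if (mode == "ensemble") {
    p <- open_profile(s, k, model)
    kd <- unname(unclass(table)[kmer_indices(seq_kmers(s, k), k)])
    inv <- sum(p / kd)  # 1/Inf == 0 exactly
  } else {
    if (is.null(site_start))
      stop("`site_start` is required in single_site mode", call. = FALSE)
    p <- prob_unpaired(s, site_start, k, model)
    w <- substr(s, site_start, site_start + k - 1L)
    inv <- p / unclass(table)[[kmer_indices(w, k)]]
  }
  if (inv == 0) Inf else 1 / inv
}

#' Affinity ratio between two alleles
#'
#' `effective_kd(alt) / effective_kd(ref)` for two windows differing at a
#' single position. A ratio above 1 means the alternate allele makes
#' protein binding harder.
#'
#' @param seq_ref,seq_alt Windows differing at exactly one position.
#' @inheritParams effective_kd
#' @return Dimensionless ratio (> 0).
#' @export
affinity_ratio <- function(seq_ref, seq_alt, table, model = energy_model(),
                           mode = c("ensemble", "single_site"),
                           site_start = NULL) {
  mode <- match.arg(mode)
  ref <- norm_rna(seq_ref)
  alt <- norm_rna(seq_alt)
  nd <- length(diff_positions(ref, alt))
  if (nd != 1L && !identical(ref, alt))
    stop("alleles must differ at exactly one position (differ at ", nd,
         ")", call. = FALSE)
  effective_kd(alt, table, model, mode, site_start) /
    effective_kd(ref, table, model, mode, site_start)
}
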