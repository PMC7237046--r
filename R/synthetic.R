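# Seeded generators for synthetic transcripts, affinity tables, planted
# structure-switch fixtures and whole cohorts. All generators are pure
# functions of (parameters, seed): they save and restore the caller's RNG
# state.

with_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is required", call. = FALSE)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# independent sub-seeds derived from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Uniform-random RNA sequences
#'
#' i.i.d. bases with equal probability 1/4 for A, C, G, U; deterministic
#' given the seed.
#'
#' @param n Number of sequences.
#' @param length Length of each sequence (nt).
#' @param seed Integer seed.
#' @return Character vector of length `n`.
#' @export
gen_random_sequences <- function(n, length, seed) {
  stopifnot(n >= 1, length >= 1)
  with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(BASES, length, replace = TRUE), collapse = "")
  }, character(1)))
}

#' Synthetic RNAcompete-style affinity table
#'
#' Complete 4^k table with `K_D(w) = K0 * exp(beta * GC(w))` times a seeded
#' lognormal jitter, where `GC(w)` is the fraction of G/C in the k-mer.
#' With `beta > 0` AU-rich k-mers bind tighter, emulating an AU-rich-motif
#' binder such as HuR. Defaults give low-nM binding for the tightest
#' AU-rich 7-mers and micromolar K_D for GC-rich ones.
#'
#' @param k Footprint size (default 7).
#' @param K0 K_D (nM) of a GC-free k-mer before jitter; > 0.
#' @param beta GC-content penalty on log K_D (default 6).
#' @param sdlog Standard deviation of the lognormal jitter (0 disables).
#' @param seed Integer seed.
#' @return An [affinity_table()].
#' @export
gen_affinity_table <- function(k = 7, K0 = 5, beta = 6, sdlog = 0.25,
                               seed) {
  stopifnot(K0 > 0, k >= 1, sdlog >= 0)
  kmers <- all_kmers(k)
  gc <- (nchar(kmers) - nchar(gsub("[GC]", "", kmers))) / k
  kd <- K0 * exp(beta * gc)
  if (sdlog > 0)
    kd <- with_seed(seed, kd * exp(rnorm(length(kmers), 0, sdlog)))
  affinity_table(setNames(kd, kmers))
}

all_kmers <- function(k) {
  m <- do.call(expand.grid,
               c(rep(list(BASES), k), KEEP.OUT.ATTRS = FALSE,
                 stringsAsFactors = FALSE))
  # leftmost position varies slowest, giving lexicographic order
  sort(do.call(paste0, m), method = "radix")
}

#' Two-tier affinity table for planted fixtures
#'
#' A designed table in which a single motif binds at `kd_motif` and every
#' other k-mer at `kd_background`. Used by the planted-switch fixtures so
#' that the effective K_D of a window is dominated by the planted motif and
#' the recovered effect direction is unambiguous.
#'
#' @param motif The k-mer with high affinity.
#' @param kd_motif,kd_background K_D values in nM.
#' @param k Footprint size (defaults to `nchar(motif)`).
#' @return An [affinity_table()].
#' @export
two_tier_affinity_table <- function(motif, kd_motif = 10,
                                    kd_background = 1e6,
                                    k = nchar(motif)) {
  motif <- norm_rna(motif)
  stopifnot(nchar(motif) == k, kd_motif > 0, kd_background > 0)
  kd <- setNames(rep(kd_background, 4^k), all_kmers(k))
  kd[motif] <- kd_motif
  affinity_table(kd)
}

# Fixed building blocks of the planted switch (see gen_planted_switch).
# The designed helix is pure GC (motif C7 against arm G7) and the flanks
# are drawn from {A, U} only, so no flank base can pair a motif base:
# the motif's accessibility is controlled entirely by the designed
# decoy/arm competition and the planted direction cannot be washed out
# by chance flank complementarity.
SWITCH_MOTIF <- "CCCCCCC"
SWITCH_TARGET <- SWITCH_MOTIF

#' Affinity table keyed to the planted-switch motif
#'
#' Two-tier [affinity_table()] with a 10 nM K_D for the motif used by
#' [gen_planted_switch()] and a 1 uM background, the table under which
#' planted fixtures are designed to be read out.
#'
#' @return An [affinity_table()].
#' @export
planted_switch_table <- function() two_tier_affinity_table(SWITCH_MOTIF)

#' Planted structure-switch fixture
#'
#' Constructs a transcript in which a distal substitution toggles whether
#' the protein's motif is sequestered by a helix. Layout (1-based, motif
#' center `c = (L+1)/2`):
#' decoy `CCCCCCC` at `[c-23, c-17]` -- arm `GGGGGGG` at `[c-13, c-7]` --
#' target motif `CCCCCCC` at `[c-3, c+3]`, with 3-nt A loops between the
#' elements. The arm can pair either the decoy or the target motif
#' (mutually exclusive, pure GC helices). With the decoy intact the arm
#' is titrated away from the motif, which stays accessible; the SNP at
#' the decoy center (20 nt upstream of the motif center) breaks a strong
#' GC pair of the decoy helix and the decoy's motif copy at once, freeing
#' the arm to sequester the real motif. Flanks are random over \{A, U\}
#' only, so no flank base can pair a motif base and the planted direction
#' follows from the construction alone (C pairs only G; the motif's sole
#' possible partner is the designed arm).
#'
#' @param seed Integer seed.
#' @param direction `"harder"` (alternate allele sequesters the motif, so
#'   the affinity ratio is > 1) or `"easier"` (the reverse).
#' @param L Odd transcript length >= 61 (the fold window equals the
#'   transcript).
#' @param transcript_id Transcript name.
#' @return Object of class `planted_switch`: list with `transcript`
#'   (sequence carrying the reference allele), `transcript_id`, `site`
#'   (start/end of a 40-nt binding-site interval), `snp`
#'   (pos/ref/alt), `motif` (string), `motif_start`, `truth` (planted
#'   direction and sequestering allele), `seed`.
#' @export
gen_planted_switch <- function(seed, direction = c("harder", "easier"),
                               L = 101, transcript_id = "tx1") {
  direction <- match.arg(direction)
  L <- as.integer(L)
  if (L %% 2L == 0L || L < 61L)
    stop("`L` must be odd and >= 61", call. = FALSE)
  ctr <- (L + 1L) %/% 2L
  arm <- revcomp_rna(SWITCH_TARGET)  # GGGGGGG
  good <- "C"  # decoy intact: motif accessible
  bad <- "A"   # decoy broken: arm pairs the motif, sequestering it
  snp_pos <- ctr - 20L  # decoy center, facing an arm G
  core_start <- ctr - 23L
  core <- paste0(SWITCH_TARGET, "AAA",    # decoy + loop
                 arm, "AAA",              # arm + loop
                 SWITCH_TARGET)           # target: motif at [c-3, c+3]
  core_end <- ctr + 3L
  with_seed(seed, {
    left <- paste(sample(c("A", "U"), core_start - 1L, replace = TRUE),
                  collapse = "")
    right <- paste(sample(c("A", "U"), L - core_end, replace = TRUE),
                   collapse = "")
    tx <- paste0(left, core, right)
    ref <- if (direction == "harder") good else bad
    alt <- if (direction == "harder") bad else good
    tx <- sub_base(tx, snp_pos, ref)
    structure(
      list(transcript = tx, transcript_id = transcript_id,
           site = c(start = ctr - 13L, end = ctr + 26L),
           snp = list(pos = snp_pos, ref = ref, alt = alt),
           motif = SWITCH_MOTIF, motif_start = ctr - 3L,
           truth = list(direction = direction, sequestering_allele = bad),
           L = L, seed = seed),
      class = "planted_switch")
  })
}

#' @export
print.planted_switch <- function(x, ...) {
  cat(sprintf(paste0("Planted structure switch (%s): %d nt, motif %s at ",
                     "%d, SNP %s>%s at %d (seed %s)\n"),
              x$truth$direction, x$L, x$motif, x$motif_start,
              x$snp$ref, x$snp$alt, x$snp$pos, format(x$seed)))
  invisible(x)
}

#' Synthetic SNP/binding-site cohort
#'
#' Generates a cohort of transcripts, each carrying one binding site and
#' one SNP, mixing planted structure switches (direction drawn with
#' probability `asymmetry` toward ratio > 1) and neutral cases (random
#' transcript, random SNP near the site, no designed effect). Stands in
#' for the dbSNP + PAR-CLIP + RNAcompete inputs of a transcriptome-wide
#' analysis.
#'
#' @param n_sites Number of sites (one per transcript).
#' @param frac_planted Fraction of sites carrying a planted switch
#'   (default 1).
#' @param asymmetry Probability that a planted effect points toward
#'   ratio > 1; 0.5 is the symmetric null.
#' @param seed Integer seed.
#' @param L Odd window/transcript length (default 201).
#' @param table Affinity table used for the cohort (default: two-tier
#'   table keyed to the planted motif).
#' @return Object of class `cohort_fixture`: list with `transcripts`
#'   (named character), `sites`, `snps`, `truth` (data.frames), `table`,
#'   and `params`.
#' @export
gen_cohort <- function(n_sites, frac_planted = 1, asymmetry = 0.5, seed,
                       L = 201, table = planted_switch_table()) {
  stopifnot(n_sites >= 1, frac_planted >= 0, frac_planted <= 1,
            asymmetry >= 0, asymmetry <= 1)
  L <- as.integer(L)
  if (L %% 2L == 0L || L < 61L)
    stop("`L` must be odd and >= 61", call. = FALSE)
  seeds <- derive_seeds(seed, n_sites + 1L)
  plan <- with_seed(seeds[n_sites + 1L], {
    list(planted = runif(n_sites) < frac_planted,
         harder = runif(n_sites) < asymmetry)
  })
  ids <- sprintf("tx%05d", seq_len(n_sites))
  transcripts <- character(n_sites)
  sites <- vector("list", n_sites)
  snps <- vector("list", n_sites)
  truth <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    if (plan$planted[i]) {
      dir <- if (plan$harder[i]) "harder" else "easier"
      sw <- gen_planted_switch(seeds[i], dir, L, transcript_id = ids[i])
      transcripts[i] <- sw$transcript
      sites[[i]] <- data.frame(transcript_id = ids[i],
                               start = sw$site[["start"]],
                               end = sw$site[["end"]])
      snps[[i]] <- data.frame(transcript_id = ids[i], pos = sw$snp$pos,
                              ref = sw$snp$ref, alt = sw$snp$alt)
      truth[[i]] <- data.frame(transcript_id = ids[i],
                               truth = dir)
    } else {
      nt <- with_seed(seeds[i], {
        tx <- paste(sample(BASES, L + 80L, replace = TRUE), collapse = "")
        mid <- (L + 80L) %/% 2L
        st <- mid - 19L
        en <- st + 39L
        smid <- (st - 1L + en) %/% 2L + 1L
        pos <- smid + sample(-40:40, 1L)
        ref <- substr(tx, pos, pos)
        alt <- sample(setdiff(BASES, ref), 1L)
        list(tx = tx, st = st, en = en, pos = pos, ref = ref, alt = alt)
      })
      transcripts[i] <- nt$tx
      sites[[i]] <- data.frame(transcript_id = ids[i], start = nt$st,
                               end = nt$en)
      snps[[i]] <- data.frame(transcript_id = ids[i], pos = nt$pos,
                              ref = nt$ref, alt = nt$alt)
      truth[[i]] <- data.frame(transcript_id = ids[i], truth = "neutral")
    }
  }
  structure(
    list(transcripts = setNames(transcripts, ids),
         sites = do.call(rbind, sites),
         snps = do.call(rbind, snps),
         truth = do.call(rbind, truth),
         table = table,
         params = list(n_sites = n_sites, frac_planted = frac_planted,
                       asymmetry = asymmetry, seed = seed, L = L)),
    class = "cohort_fixture")
}

#' @export
print.cohort_fixture <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("Synthetic cohort: %d sites (%.0f%% planted, ",
                     "asymmetry %.2f), L = %d, seed %s\n"),
              p$n_sites, 100 * p$frac_planted, p$asymmetry, p$L,
              format(p$seed)))
  invisible(x)
}

#' Write / read a cohort fixture as standard files
#'
#' Writes `transcripts.fa`, `snps.vcf`, `sites.bed`, `affinity.tsv` and
#' `truth.tsv` under `dir`; `read_cohort()` reads them back into a
#' `cohort_fixture` (without the generator parameters).
#'
#' @param fixture A `cohort_fixture`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns `dir`; `read_cohort` a
#'   `cohort_fixture`.
#' @export
write_cohort <- function(fixture, dir) {
  stopifnot(inherits(fixture, "cohort_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixture$transcripts, file.path(dir, "transcripts.fa"))
  write_snps_vcf(fixture$snps, file.path(dir, "snps.vcf"))
  write_sites(fixture$sites, file.path(dir, "sites.bed"))
  write_affinity_table(fixture$table, file.path(dir, "affinity.tsv"))
  write.table(fixture$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  structure(
    list(transcripts = read_fasta(file.path(dir, "transcripts.fa")),
         snps = read_snps(file.path(dir, "snps.vcf")),
         sites = read_sites(file.path(dir, "sites.bed")),
         truth = read.table(file.path(dir, "truth.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE),
         table = read_affinity_table(file.path(dir, "affinity.tsv")),
         params = NULL),
    class = "cohort_fixture")
}
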