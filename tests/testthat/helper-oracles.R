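# Brute-force oracles built on the exhaustive enumeration, used to check
# the dynamic-programming paths on small sequences.

# Boltzmann weights of every enumerated structure
enum_weights <- function(seq, model = energy_model(),
                         forced_unpaired = integer(0)) {
  en <- enumerate_structures(seq, model, forced_unpaired)
  list(structures = en$structure, w = exp(-en$energy / model$kT))
}

enum_Z <- function(seq, model = energy_model(),
                   forced_unpaired = integer(0)) {
  sum(enum_weights(seq, model, forced_unpaired)$w)
}

# opening probability of [start, start+width-1] by filtering dot-bracket
enum_p_open <- function(seq, start, width, model = energy_model()) {
  ew <- enum_weights(seq, model)
  open <- substr(ew$structures, start, start + width - 1L) ==
    strrep(".", width)
  sum(ew$w[open]) / sum(ew$w)
}

# effective K_D by explicit enumeration of (structure, bound-state) pairs:
# a protein can occupy footprint i in a structure iff the footprint is
# unpaired there; in the dilute limit K_eff = Z / sum_i Z_open(i)/K_D(w_i)
enum_effective_kd <- function(seq, table, model = energy_model(),
                              mode = "ensemble", site_start = NULL) {
  k <- attr(table, "k")
  ew <- enum_weights(seq, model)
  n <- nchar(seq)
  starts <- if (mode == "ensemble") seq_len(n - k + 1L) else site_start
  bound <- 0
  for (st in starts) {
    open <- substr(ew$structures, st, st + k - 1L) == strrep(".", k)
    kd <- unclass(table)[[foldbind:::kmer_indices(
      substr(seq, st, st + k - 1L), k)]]
    if (is.finite(kd)) bound <- bound + sum(ew$w[open]) / kd
  }
  if (bound == 0) Inf else sum(ew$w) / bound
}

# independent structure-counting recursion (no reuse of the enumerator):
# N(i,j) = N(i+1,j) + sum_l pairable(i,l) N(i+1,l-1) N(l+1,j)
count_structures <- function(seq, min_loop = 3) {
  b <- strsplit(seq, "")[[1]]
  can <- function(x, y) paste0(x, y) %in%
    c("GC", "CG", "AU", "UA", "GU", "UG")
  n <- length(b)
  memo <- new.env()
  cnt <- function(i, j) {
    if (i >= j) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- cnt(i + 1, j)
    for (l in seq_len(j)) {
      if (l > i + min_loop && can(b[i], b[l]))
        total <- total + cnt(i + 1, l - 1) * cnt(l + 1, j)
    }
    memo[[key]] <- total
    total
  }
  cnt(1, n)
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

all_kmers2 <- function() foldbind:::all_kmers(2)
all_kmers3 <- function() foldbind:::all_kmers(3)

# small complete table over k-mers with seeded lognormal spread
toy_table <- function(k = 3, seed = 5)
  gen_affinity_table(k = k, K0 = 20, beta = 2, sdlog = 0.3, seed = seed)
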