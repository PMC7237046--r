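#' Normalise a nucleotide sequence to the RNA alphabet
#'
#' Uppercases the input and converts T to U. Any character outside
#' A/C/G/U after normalisation (including IUPAC ambiguity codes) is an
#' error: the folding model is defined on the 4-letter alphabet only.
#'
#' @param seq Single character string (RNA or DNA).
#' @return The normalised sequence string.
#' @examples
#' norm_rna("acgt")  # "ACGU"
#' @export
norm_rna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("`seq` must be a single character string", call. = FALSE)
  s <- chartr("T", "U", toupper(seq))
  if (nchar(s) < 1L)
    stop("`seq` must contain at least one base", call. = FALSE)
  if (grepl("[^ACGU]", s))
    stop("`seq` contains characters outside the A/C/G/U alphabet: ",
         paste(unique(strsplit(gsub("[ACGU]", "", s), "")[[1]]),
               collapse = ", "),
         call. = FALSE)
  s
}

# integer encoding 1=A 2=C 3=G 4=U used by the C++ recursions
rna_ints <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], BASES)
}

# substitute a single base (1-based position), returning a new string
sub_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# all k-mers of a sequence, in order of their start position
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

# positions (1-based) at which seq_ref and seq_alt differ
diff_positions <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences have different lengths", call. = FALSE)
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# lexicographic (A<C<G<U) rank of each k-mer, 1-based; this matches the
# storage order of an affinity_table, so tables can be indexed
# arithmetically instead of by name
kmer_indices <- function(kmers, k) {
  m <- matrix(match(unlist(strsplit(kmers, "", fixed = TRUE)), BASES) - 1L,
              nrow = k)
  as.integer(colSums(m * 4^((k - 1L):0))) + 1L
}

# reverse complement in RNA alphabet (used by the synthetic generators)
revcomp_rna <- function(seq) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}
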