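# The AC-alphabet motif below cannot pair with poly-A flanks (A-A and A-C
# are not canonical), giving windows with no possible pairs at all.
AC_MOTIF <- "ACCACCA"
ac_context <- function(flank = 15)
  paste0(strrep("A", flank), AC_MOTIF, strrep("A", flank))

test_that("affinity table validation and TSV round trip", {
  expect_error(affinity_table(c(AA = 1)), "incomplete")
  expect_error(affinity_table(setNames(rep(1, 16), all_kmers2())),
               NA)
  kd <- setNames(rep(1, 16), all_kmers2())
  kd[3] <- -1
  expect_error(affinity_table(kd), "> 0")
  # bit-exact round trip through TSV, including Inf
  set.seed(2)
  tab <- toy_table(k = 3, seed = 2)
  tab[c(5, 40)] <- Inf
  tab <- affinity_table(setNames(unclass(tab), names(tab)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_affinity_table(tab, f)
  back <- read_affinity_table(f)
  expect_identical(unclass(back), unclass(tab))
})

test_that("opening free energy: trivial, closed form, oracle", {
  r <- opening_free_energy("AAAAAAA", 1, 7)
  expect_equal(r$p_open, 1.0)
  expect_equal(r$dG_open, 0.0)
  # p_open = 1/2 corresponds to kT log 2 = 0.42721 kcal/mol at 310.15 K
  m <- energy_model()
  expect_equal(-m$kT * log(0.5), 0.42721, tolerance = 1e-4)
  # hairpin toy against the enumeration oracle
  s <- "GGGGAAAAAAACCCC"
  r2 <- opening_free_energy(s, 5, 7)
  expect_equal(r2$p_open, enum_p_open(s, 5, 7), tolerance = 1e-9)
  expect_equal(r2$dG_open, -m$kT * log(enum_p_open(s, 5, 7)),
               tolerance = 1e-9)
  expect_gte(r2$dG_open, 0)
})

test_that("ddG identity, antisymmetry and input validation", {
  s <- ac_context()
  expect_identical(ddG(s, s, 10, 7), 0)
  mut <- foldbind:::sub_base(s, 19, "C")
  expect_equal(ddG(s, mut, 10, 7), -ddG(mut, s, 10, 7))
  # poly-A with a central A->C admits no pairs under either allele
  pa <- strrep("A", 21)
  expect_equal(ddG(pa, foldbind:::sub_base(pa, 11, "C"), 3, 7), 0)
  mut2 <- foldbind:::sub_base(mut, 2, "G")
  expect_error(ddG(s, mut2, 10, 7), "exactly one position")
})

test_that("effective K_D: exact closed forms on unstructured windows", {
  tab <- two_tier_affinity_table(AC_MOTIF, kd_motif = 10,
                                 kd_background = Inf)
  # single accessible motif: one term with p_open = 1
  expect_identical(effective_kd(ac_context(), tab), 10)
  # two disjoint copies combine in parallel
  s2 <- paste0(strrep("A", 8), AC_MOTIF, strrep("A", 8), AC_MOTIF,
               strrep("A", 8))
  expect_identical(effective_kd(s2, tab), 5)
  # all-non-binder window
  expect_identical(effective_kd(strrep("A", 20), tab), Inf)
})

test_that("fully-open limit equals the harmonic sum of table values", {
  # A/C sequences admit no pairs, so every p_open is exactly 1
  set.seed(21)
  tab <- toy_table(k = 3, seed = 21)
  s <- paste(sample(c("A", "C"), 15, TRUE), collapse = "")
  kmers <- foldbind:::seq_kmers(s, 3)
  expected <- 1 / sum(1 / unclass(tab)[foldbind:::kmer_indices(kmers, 3)])
  expect_equal(effective_kd(s, tab), expected, tolerance = 1e-12)
})

test_that("table scaling moves K_eff linearly and cancels in ratios", {
  set.seed(22)
  tab <- toy_table(k = 3, seed = 22)
  s <- random_rna(14)
  alt <- foldbind:::sub_base(s, 7, setdiff(c("A", "C", "G", "U"),
                                           substr(s, 7, 7))[1])
  scaled <- affinity_table(setNames(unclass(tab) * 3.7, names(tab)))
  expect_equal(effective_kd(s, scaled), 3.7 * effective_kd(s, tab),
               tolerance = 1e-12)
  expect_equal(affinity_ratio(s, alt, scaled),
               affinity_ratio(s, alt, tab), tolerance = 1e-12)
})

test_that("effective K_D matches the statistical-mechanics oracle", {
  tab <- toy_table(k = 3, seed = 5)
  set.seed(23)
  for (i in 1:10) {
    s <- random_rna(sample(10:16, 1))
    expect_equal(effective_kd(s, tab), enum_effective_kd(s, tab),
                 tolerance = 1e-9)
    st <- sample(nchar(s) - 2, 1)
    expect_equal(effective_kd(s, tab, mode = "single_site",
                              site_start = st),
                 enum_effective_kd(s, tab, mode = "single_site",
                                   site_start = st),
                 tolerance = 1e-9)
  }
})

test_that("K_eff respects its parallel-sum and accessibility bounds", {
  tab <- toy_table(k = 3, seed = 5)
  m <- energy_model()
  set.seed(24)
  for (i in 1:10) {
    s <- random_rna(14)
    kd <- unclass(tab)[foldbind:::kmer_indices(
      foldbind:::seq_kmers(s, 3), 3)]
    p <- vapply(seq_along(kd),
                function(st) prob_unpaired(s, st, 3, m), numeric(1))
    K <- effective_kd(s, tab, m)
    expect_gte(K, 1 / sum(1 / kd) - 1e-12)
    expect_lte(K, min(kd / p) + 1e-9)
  }
})

test_that("affinity ratio reciprocity and planted stem-switch sign", {
  tab <- toy_table(k = 3, seed = 5)
  set.seed(25)
  s <- random_rna(14)
  alt <- foldbind:::sub_base(s, 7, setdiff(c("A", "C", "G", "U"),
                                           substr(s, 7, 7))[1])
  expect_equal(affinity_ratio(s, alt, tab) * affinity_ratio(alt, s, tab),
               1, tolerance = 1e-12)
  # a neutral substitution in an unstructured context leaves K unchanged:
  # the A->C change sits outside every footprint's k-mer identity change
  un <- "ACCACCACCACCA"
  tab2 <- two_tier_affinity_table("CCACC", kd_motif = 10,
                                  kd_background = Inf, k = 5)
  # both alleles keep the same single accessible motif placements
  expect_equal(affinity_ratio(un, foldbind:::sub_base(un, 1, "C"), tab2),
               1, tolerance = 1e-12)
  # mini stem switch, small enough for the enumeration oracle: the ref
  # window has no G at all, so the CCC motif is always open; the alt
  # allele introduces a single G that can pair (and sequester) motif Cs
  tab3 <- two_tier_affinity_table("CCC", kd_motif = 10,
                                  kd_background = 1e5, k = 3)
  ref <- paste0(strrep("A", 5), "CCC", strrep("A", 8))
  altc <- foldbind:::sub_base(ref, 16, "G")
  r_engine <- affinity_ratio(ref, altc, tab3)
  r_oracle <- enum_effective_kd(altc, tab3) / enum_effective_kd(ref, tab3)
  expect_equal(r_engine, r_oracle, tolerance = 1e-9)
  expect_gt(r_engine, 1)  # sequestering allele raises K_eff
})

test_that("single-site ddG and ratio agree on a uniform table", {
  # with a sequence-independent table, -kT log(ratio) = -ddG exactly
  m <- energy_model()
  k <- 3
  tab <- affinity_table(setNames(rep(50, 64), all_kmers3()))
  set.seed(26)
  for (i in 1:5) {
    s <- random_rna(15)
    pos <- sample(15, 1)
    alt <- foldbind:::sub_base(s, pos,
                               setdiff(c("A", "C", "G", "U"),
                                       substr(s, pos, pos))[1])
    st <- sample(13, 1)
    r <- affinity_ratio(s, alt, tab, m, mode = "single_site",
                        site_start = st)
    dd <- ddG(s, alt, st, k, m)
    expect_equal(-m$kT * log(r), -dd, tolerance = 1e-9)
  }
})
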