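test_that("random sequence generator is seeded, uniform and pure", {
  s1 <- gen_random_sequences(5, 80, seed = 1)
  s2 <- gen_random_sequences(5, 80, seed = 1)
  expect_identical(s1, s2)
  expect_false(identical(s1, gen_random_sequences(5, 80, seed = 2)))
  expect_true(all(nchar(s1) == 80))
  # base frequencies over 1e5 draws within 3 sigma of 1/4
  big <- gen_random_sequences(1, 1e5, seed = 3)
  freq <- table(strsplit(big, "")[[1]]) / 1e5
  sigma <- sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(freq - 0.25) < 3 * sigma))
  # generator does not disturb the caller's RNG stream
  set.seed(10); a <- runif(1)
  set.seed(10); invisible(gen_random_sequences(1, 10, seed = 4))
  expect_identical(runif(1), a)
})

test_that("synthetic affinity tables are complete with AU preference", {
  tab <- gen_affinity_table(k = 7, seed = 11)
  expect_identical(length(unclass(tab)), 16384L)
  expect_true(all(unclass(tab) > 0))
  nojit <- gen_affinity_table(k = 7, sdlog = 0, seed = 11)
  expect_lt(nojit[["UUUUUUU"]], nojit[["GGGGGGG"]])
  expect_equal(unname(nojit[["AUAUAUA"]]), 5, tolerance = 1e-12)
  expect_identical(unclass(gen_affinity_table(k = 3, seed = 7)),
                   unclass(gen_affinity_table(k = 3, seed = 7)))
})

test_that("planted switch fixtures obey their construction contract", {
  for (s in c(1, 2, 3)) {
    sw <- gen_planted_switch(s, "harder", L = 101)
    tx <- sw$transcript
    expect_identical(nchar(tx), 101L)
    # reference allele is embedded in the transcript
    expect_identical(substr(tx, sw$snp$pos, sw$snp$pos), sw$snp$ref)
    # ref and alt windows differ at exactly one position
    alt <- foldbind:::sub_base(tx, sw$snp$pos, sw$snp$alt)
    expect_identical(length(foldbind:::diff_positions(tx, alt)), 1L)
    # SNP is well outside the motif
    expect_gte(abs(sw$snp$pos - sw$motif_start), 10L)
    # motif occurs inside the site interval
    expect_identical(substr(tx, sw$motif_start, sw$motif_start + 6L),
                     sw$motif)
    expect_gte(sw$motif_start, sw$site[["start"]])
    expect_lte(sw$motif_start + 6L, sw$site[["end"]])
  }
  expect_error(gen_planted_switch(1, L = 60), "odd")
  expect_error(gen_planted_switch(1, L = 59), ">= 61")
})

test_that("planted switch direction is recovered by the engine", {
  tab <- planted_switch_table()
  for (s in 1:8) {
    dir <- if (s %% 2) "harder" else "easier"
    sw <- gen_planted_switch(s, dir, L = 61)
    alt <- foldbind:::sub_base(sw$transcript, sw$snp$pos, sw$snp$alt)
    r <- affinity_ratio(sw$transcript, alt, tab, mode = "single_site",
                        site_start = sw$motif_start)
    if (dir == "harder") expect_gt(r, 1) else expect_lt(r, 1)
  }
})

test_that("cohorts mix planted and neutral cases as configured", {
  tab <- planted_switch_table()
  co <- gen_cohort(20, frac_planted = 0.5, asymmetry = 0.5, seed = 5,
                   L = 61, table = tab)
  expect_identical(nrow(co$snps), 20L)
  expect_identical(nrow(co$sites), 20L)
  expect_identical(length(co$transcripts), 20L)
  expect_true(all(co$truth$truth %in% c("harder", "easier", "neutral")))
  expect_true(any(co$truth$truth == "neutral"))
  # every site/SNP references an existing transcript; truth covers all
  expect_true(all(co$sites$transcript_id %in% names(co$transcripts)))
  expect_true(all(co$snps$transcript_id %in% names(co$transcripts)))
  expect_identical(co$truth$transcript_id, co$snps$transcript_id)
  # reference alleles match their transcripts
  expect_true(all(mapply(function(id, p, r)
    substr(co$transcripts[[id]], p, p) == r,
    co$snps$transcript_id, co$snps$pos, co$snps$ref)))
  # determinism
  co2 <- gen_cohort(20, frac_planted = 0.5, asymmetry = 0.5, seed = 5,
                    L = 61, table = tab)
  expect_identical(co$transcripts, co2$transcripts)
  expect_identical(co$snps, co2$snps)
})

test_that("asymmetry = 1 cohorts put every planted effect above 1", {
  tab <- planted_switch_table()
  co <- gen_cohort(12, frac_planted = 1, asymmetry = 1, seed = 6,
                   L = 61, table = tab)
  expect_true(all(co$truth$truth == "harder"))
  fit <- snp_binding_effects(co$transcripts, co$snps, co$sites, tab,
                             L = 61, mode = "single_site")
  expect_identical(asymmetry_test(fit)$n_below, 0L)
})

test_that("cohort files round-trip through FASTA/VCF/BED/TSV", {
  tab <- planted_switch_table()
  co <- gen_cohort(8, frac_planted = 0.75, asymmetry = 0.5, seed = 9,
                   L = 61, table = tab)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$transcripts, co$transcripts)
  expect_identical(back$snps$transcript_id, co$snps$transcript_id)
  expect_identical(back$snps$pos, co$snps$pos)
  expect_identical(back$snps$ref, co$snps$ref)
  expect_identical(back$snps$alt, co$snps$alt)
  expect_identical(back$sites$start, co$sites$start)
  expect_identical(back$sites$end, co$sites$end)
  expect_identical(unclass(back$table), unclass(co$table))
  expect_identical(back$truth$truth, co$truth$truth)
})
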