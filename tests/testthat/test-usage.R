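test_that("CDS counting scans frame 0 at codon stride with exclusions", {
  db <- tiny_refdb()
  # 12-nt CDS: windows AGAAAAAAA (offset 1) and AAAAAAAAA (offset 4)
  cnt <- count_cds_ninemers("AGAAAAAAAAAA", db)
  expect_equal(unname(cnt["AGAAAAAAA"]), 1L)
  expect_equal(unname(cnt["AAAAAAAAA"]), 1L)
  expect_equal(sum(cnt), 2L)

  # shorter than 9 nt: excluded entirely
  cnt8 <- count_cds_ninemers("AGAAAAAA", db)
  expect_equal(sum(cnt8), 0L)
  expect_equal(attr(cnt8, "excluded"), 1L)

  # ambiguous nucleotide: excluded entirely
  cntN <- count_cds_ninemers("AGAAAAAAANAA", db)
  expect_equal(sum(cntN), 0L)
  expect_equal(attr(cntN, "excluded"), 1L)

  # off-frame occurrences are not counted (stride 3 from position 1)
  cnt_off <- count_cds_ninemers("TAGAAAAAAA", db)
  expect_equal(sum(cnt_off), 0L)
})

test_that("non-CDS counting covers all six frames", {
  db <- tiny_refdb()
  # GATGATCAT only matchable on the reverse strand of its complement
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GATGATCAT")))
  cnt <- count_noncds_ninemers(rc, db)
  expect_equal(unname(cnt["GATGATCAT"]), 1L)

  expect_equal(sum(count_noncds_ninemers(character(0), db)), 0L)

  # independent oracle: brute-force enumeration of all six frames
  set.seed(1)
  seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  wins <- unlist(enumerate_windows(seq))
  expected <- table(factor(wins[wins %in% db$entries$ninemer],
                           levels = db$entries$ninemer))
  got <- count_noncds_ninemers(seq, db)
  expect_equal(as.integer(got), as.integer(expected))

  # a 9-mer whose reverse complement is also stored is counted in both
  # orientations (here AAAAAAAAA and its partner are both checked by hand)
  cnt2 <- count_noncds_ninemers("AAAAAAAAA", db)
  expect_equal(unname(cnt2["AAAAAAAAA"]), 1L)  # fwd +1 only; rc is TTT...
})

test_that("usage tables normalise within hierarchy cells", {
  # one char trimer AAA holding RKK (counted 6), KKK (3), KKR-like absent;
  # build a reference where AAA holds exactly three trimers
  db <- trimer_refdb(c("RKK", "KKK", "KKR"),
                     c("AGAAAAAAA", "AAAAAAAAA", "AAAAAACGT"))
  cnt <- stats::setNames(c(6L, 3L, 1L), db$entries$ninemer)
  cnt <- cnt[db$entries$ninemer]
  cnt[] <- c(6L, 3L, 1L)[match(db$entries$trimer, c("RKK", "KKK", "KKR"))]
  tab <- build_usage_tables(cnt, db, pseudocount = 1e-9)
  u <- tab$aa_trimer_usage[match(c("RKK", "KKK", "KKR"), tab$trimer)]
  expect_equal(u, c(0.6, 0.3, 0.1), tolerance = 1e-6)
  # each trimer holds a single 9-mer, so 3-codon usage is 1
  expect_equal(tab$codon3_usage, rep(1, 3), tolerance = 1e-6)
  expect_error(build_usage_tables(cnt, db, pseudocount = 0), "positive")

  # all-zero counts with unit pseudocount: uniform within cells
  kkk <- tiny_refdb()
  zero <- stats::setNames(integer(nrow(kkk$entries)), kkk$entries$ninemer)
  tz <- build_usage_tables(zero, kkk, pseudocount = 1)
  in_kkk <- tz$trimer == "KKK"
  expect_equal(tz$codon3_usage[in_kkk], rep(1 / 8, 8))
})

test_that("usage invariants hold on randomized fixtures", {
  for (seed in c(2, 3)) {
    db <- suppressWarnings(generate_refdb_fixture(80, 5, seed = seed))
    set.seed(seed)
    cnt <- stats::setNames(rpois(nrow(db$entries), 4), db$entries$ninemer)
    tab <- build_usage_tables(cnt, db)
    # inner tables sum to 1 within every cell
    tri_first <- !duplicated(tab$trimer)
    aa_sums <- tapply(tab$aa_trimer_usage[tri_first],
                      tab$char_trimer[tri_first], sum)
    expect_true(all(abs(aa_sums - 1) < 1e-9))
    c3_sums <- tapply(tab$codon3_usage, tab$trimer, sum)
    expect_true(all(abs(c3_sums - 1) < 1e-9))
    # biases under one char trimer sum to 1
    b_sums <- tapply(tab$bias, tab$char_trimer, sum)
    expect_true(all(abs(b_sums - 1) < 1e-9))
    expect_true(all(tab$bias > 0 & tab$bias <= 1))
  }
})

test_that("with vanishing pseudocount usages approach relative frequencies", {
  db <- tiny_refdb()
  cnt <- stats::setNames(integer(nrow(db$entries)), db$entries$ninemer)
  cnt["AAAAAAAAA"] <- 900L
  cnt["AAGAAGAAG"] <- 100L
  tab <- build_usage_tables(cnt, db, pseudocount = 1e-9)
  expect_equal(trimer_usage_bias(tab, "AAAAAAAAA") /
                 tab$aa_trimer_usage[match("AAAAAAAAA", tab$ninemer)],
               0.9, tolerance = 1e-6)
})

test_that("counting is additive over pooled genomes", {
  db <- small_world()$db
  cds <- small_world()$comm$cds[[1]]
  a <- count_cds_ninemers(cds[1:5], db)
  b <- count_cds_ninemers(cds[6:10], db)
  ab <- count_cds_ninemers(cds[1:10], db)
  expect_equal(as.integer(a) + as.integer(b), as.integer(ab))
})

test_that("mono usage tables are within-family relative frequencies", {
  # a CDS using AAA (K) twice and AGA (R) once, no other codons
  mono <- build_mono_tables("AAAAAAAGA", pseudocount = 1e-9)
  expect_equal(unname(mono$avg_codon_usage["AAA"]), 1, tolerance = 1e-6)
  # K:2, R:1 within char class A
  expect_equal(unname(mono$avg_aa_usage["K"]), 2 / 3, tolerance = 1e-6)
  expect_equal(unname(mono$avg_aa_usage["R"]), 1 / 3, tolerance = 1e-6)

  # all 64 codons once: K has 2 codons, so AAA|K = 0.5
  all64 <- paste(names(Biostrings::GENETIC_CODE), collapse = "")
  m64 <- build_mono_tables(all64, pseudocount = 1e-9)
  expect_equal(unname(m64$avg_codon_usage["AAA"]), 0.5, tolerance = 1e-6)
  fam_sums <- tapply(m64$avg_codon_usage,
                     Biostrings::GENETIC_CODE[names(m64$avg_codon_usage)],
                     sum)
  expect_true(all(abs(fam_sums - 1) < 1e-9))
})

test_that("expected usages are products of mono usages", {
  db <- tiny_refdb()
  mono <- build_mono_tables("AAAAAAAGA", pseudocount = 1e-9)
  # force a known codon usage: AAA|K = 0.7
  mono$avg_codon_usage["AAA"] <- 0.7
  mono$avg_codon_usage["AAG"] <- 0.3
  exp_tab <- build_expected_tables(mono, db)
  i <- match("AAAAAAAAA", exp_tab$ninemer)
  expect_equal(exp_tab$expected_3codon_usage[i], 0.7^3)
  # the full synonymous family of KKK is stored: expected sums to 1
  kkk <- exp_tab$trimer == "KKK"
  expect_equal(sum(exp_tab$expected_3codon_usage[kkk]), 1, tolerance = 1e-9)
})

test_that("standardized usage is observed over expected", {
  db <- tiny_refdb()
  cnt <- stats::setNames(integer(nrow(db$entries)), db$entries$ninemer)
  cnt[db$entries$trimer == "KKK"] <- 1L
  cnt["AAAAAAAAA"] <- 9L  # over-represented within its family of 8
  tab <- build_usage_tables(cnt, db, pseudocount = 1e-9)
  mono <- build_mono_tables(paste(rep(c("AAA", "AAG"), 8), collapse = ""),
                            pseudocount = 1e-9)
  exp_tab <- build_expected_tables(mono, db)
  s <- standardized_3codon_usage(tab, exp_tab, "AAAAAAAAA")
  # observed 9/16 vs expected (1/2)^3 = 1/8: ratio 4.5
  expect_equal(s, (9 / 16) / (1 / 8), tolerance = 1e-6)
  # observed == expected gives 1
  cnt2 <- stats::setNames(rep(2L, nrow(db$entries)), db$entries$ninemer)
  tab2 <- build_usage_tables(cnt2, db, pseudocount = 1e-9)
  s2 <- standardized_3codon_usage(tab2, exp_tab, "AAAAAAAAA")
  expect_equal(s2, (1 / 8) / (1 / 8), tolerance = 1e-4)
  expect_error(standardized_3codon_usage(tab2, exp_tab, "CCCCCCCCC"),
               "not in reference")
})
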