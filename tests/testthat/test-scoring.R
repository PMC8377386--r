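test_that("six-frame scanning windows match brute-force enumeration", {
  db <- small_world()$db
  expect_length(scan_frames("ACGTACGTA", db), 6L)
  s9 <- scan_frames("ACGTACGTA", db)
  expect_length(s9[["+1"]]$ninemer, 1L)
  expect_length(s9[["+2"]]$ninemer, 0L)
  expect_length(s9[["+3"]]$ninemer, 0L)

  set.seed(4)
  for (len in c(30, 156, 200)) {
    seq <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    sc <- scan_frames(seq, db)
    ref <- enumerate_windows(seq)
    for (f in names(ref)) expect_equal(sc[[f]]$ninemer, ref[[f]])
  }
  # a 156-nt query holds 52 codons, hence 50 windows in frame +1
  seq156 <- paste(rep("ACG", 52), collapse = "")
  expect_length(scan_frames(seq156, db)[["+1"]]$ninemer, 50L)

  expect_error(scan_frames("ACGTACGT", db), class = "trimertax_too_short")

  # ambiguous windows are skipped, not fatal
  sN <- scan_frames("ACGTNCGTACGTACG", db)
  expect_false(any(grepl("N", unlist(lapply(sN, `[[`, "ninemer")))))
})

test_that("frames swap and 9-mers reverse-complement under strand flip", {
  db <- small_world()$db
  set.seed(9)
  seq <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  a <- scan_frames(seq, db)
  b <- scan_frames(rc, db)
  for (k in 1:3) {
    expect_equal(b[[k]]$ninemer, a[[k + 3]]$ninemer)
    expect_equal(b[[k + 3]]$ninemer, a[[k]]$ninemer)
  }
})

test_that("frame scores are mean log biases, invariant to duplication", {
  w <- small_world()
  gdb <- w$fit$genus_dbs[[1]]$cds
  nin <- w$db$entries$ninemer[c(3, 7)]
  scan1 <- list(frame_id = "+1", offset = 1L, ninemer = nin[1],
                ref_idx = 3L)
  s1 <- frame_genus_score(scan1, gdb)
  expect_equal(s1$n_matches, 1L)
  expect_equal(s1$log_score, log(gdb$bias[3]))
  # duplicating a match leaves the mean log score unchanged
  scan2 <- list(frame_id = "+1", offset = c(1L, 1L), ninemer = rep(nin[1], 2),
                ref_idx = c(3L, 3L))
  expect_equal(frame_genus_score(scan2, gdb)$log_score, s1$log_score)
  # no matches: excluded
  scan0 <- list(frame_id = "+2", offset = integer(0), ninemer = character(0),
                ref_idx = NA_integer_[0])
  expect_true(is.na(frame_genus_score(scan0, gdb)$log_score))
})

test_that("genus ranking is ascending with the stated tie handling", {
  v <- c(0.1, 0.5, 0.3, 0.9)
  expect_equal(genus_ranks(v), c(1, 3, 2, 4))
  expect_equal(genus_ranks(rep(1, 54)), rep(27.5, 54))
  # ordinal mode: earlier (manifest-order) genus wins the higher rank
  r <- genus_ranks(c(5, 5, 1), ties = "ordinal")
  expect_equal(r, c(3L, 2L, 1L))
})

test_that("Kruskal-Wallis H matches the formula and stats::kruskal.test", {
  # equal group mean ranks: H = 0
  expect_equal(kruskal_wallis_h(c(1, 3, 2, 4), c("a", "b", "b", "a")), 0)
  expect_equal(kruskal_wallis_h(1:4, c("a", "a", "b", "b")), 2.4)
  # relabeling invariance
  expect_equal(kruskal_wallis_h(1:4, c("b", "b", "a", "a")), 2.4)
  # all tied: defined as 0
  expect_equal(kruskal_wallis_h(rep(2.5, 4), c("a", "a", "b", "b")), 0)
  # agreement with kruskal.test on untied and tied data
  set.seed(6)
  x <- rnorm(30)
  g <- rep(letters[1:3], 10)
  expect_equal(kruskal_wallis_h(rank(x), g),
               unname(stats::kruskal.test(x, factor(g))$statistic))
  xt <- sample(1:5, 30, TRUE)  # heavy ties
  expect_equal(kruskal_wallis_h(rank(xt), g),
               unname(stats::kruskal.test(xt, factor(g))$statistic))
})

test_that("rank-probability scores centre to zero and reward top groups", {
  groups <- rep(c("g1", "g2", "g3"), c(18, 18, 18))
  # all genera equal: H = 0, all scores 0
  bias <- matrix(1, 2, 54)
  std <- matrix(1, 2, 54)
  expect_true(all(build_rank_scores(bias, std, groups) == 0))

  # one group uniformly on top on both statistics
  v <- c(rep(3, 18), rep(2, 18), rep(1, 18)) + (1:54) * 1e-6
  bias2 <- matrix(v, 2, 54, byrow = TRUE)
  sc <- build_rank_scores(bias2, bias2, groups)
  expect_true(all(sc[1, groups == "g1"] > 0))
  expect_true(all(sc[1, groups == "g3"] < 0))
  expect_equal(unname(sc[1, 1]), max(sc[1, ]))
  # shared within groups
  expect_equal(length(unique(round(sc[1, groups == "g2"], 12))), 1L)
  # group-size-weighted scores sum to zero (centred ranks)
  expect_equal(sum(sc[1, ]), 0, tolerance = 1e-9)

  set.seed(8)
  b3 <- matrix(runif(5 * 54), 5, 54)
  s3 <- matrix(runif(5 * 54), 5, 54)
  sc3 <- build_rank_scores(b3, s3, groups)
  expect_equal(rowSums(sc3), rep(0, 5), tolerance = 1e-9)
})

test_that("answer sets shrink with the cutoff and keep order", {
  scores <- stats::setNames(c(0.60, 0.57, 0.05), c("g1", "g2", "g3"))
  sel05 <- trimertax:::.answer_set(scores, 0.05)
  expect_equal(names(scores)[sel05], c("g1", "g2"))
  sel01 <- trimertax:::.answer_set(scores, 0.01)
  expect_equal(names(scores)[sel01], "g1")
  # monotone growth over the six allowed cutoffs
  set.seed(10)
  sc <- runif(54)
  sizes <- vapply(allowed_cutoffs(), function(co) {
    length(trimertax:::.answer_set(sc, co))
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("classification is strand-symmetric and score-normalised", {
  w <- small_world()
  frag <- substring(w$comm$cds[[2]][1], 1, 180)
  p1 <- predict(w$fit, c(q = frag), detail = TRUE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  p2 <- predict(w$fit, c(q = rc), detail = TRUE)
  expect_equal(p1$best_genus, p2$best_genus)
  expect_equal(p1$db_call, p2$db_call)
  # mirrored frame call: +k <-> -k
  mirror <- c("+1" = "-1", "+2" = "-2", "+3" = "-3",
              "-1" = "+1", "-2" = "+2", "-3" = "+3")
  expect_equal(unname(mirror[p1$best_frame]), p2$best_frame)
  # normalised scores sum to 1 over genera within every scored frame
  det <- attr(p1, "detail")[[1]]
  for (db in c("CDS", "nonCDS")) {
    sums <- rowSums(det$norm[[db]])
    expect_equal(unname(sums[is.finite(sums)]),
                 rep(1, sum(is.finite(sums))), tolerance = 1e-9)
  }
})

test_that("answer sets grow monotonically in cutoff end to end", {
  w <- small_world()
  frag <- substring(w$comm$cds[[3]][2], 10, 220)
  sizes <- vapply(allowed_cutoffs(), function(co) {
    predict(w$fit, c(q = frag), cutoff = co)$n_answer
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
})
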