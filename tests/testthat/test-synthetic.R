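test_that("the reference fixture is consistent and deterministic", {
  db1 <- generate_refdb_fixture(10, 2, seed = 70)
  db2 <- generate_refdb_fixture(10, 2, seed = 70)
  expect_identical(db1$entries, db2$entries)
  db3 <- generate_refdb_fixture(10, 2, seed = 71)
  expect_false(identical(db1$entries, db3$entries))

  one <- generate_refdb_fixture(1, 1, seed = 72)
  expect_equal(nrow(one$entries), 1L)
  expect_equal(match_ninemer(one, one$entries$ninemer)$level, "full")

  # over-asking caps at the family size with a warning
  expect_warning(generate_refdb_fixture(50, 500, seed = 73), "capped")
})

test_that("the default manifest mirrors the 54-genus, 13-group layout", {
  man <- synthetic_manifest(54)
  expect_equal(nrow(man), 54L)
  expect_length(unique(man$taxon_group), 13L)
  expect_equal(sum(man$kingdom == "bacteria"), 45L)
  expect_equal(sum(man$kingdom == "fungi"), 9L)
  expect_equal(sum(man$taxon_group == "AMF"), 1L)
  man6 <- synthetic_manifest(6)
  expect_equal(nrow(man6), 6L)
  expect_gt(length(unique(man6$taxon_group)), 1L)
})

test_that("generated coding sequences have codon structure", {
  w <- small_world()
  lens <- nchar(unlist(w$comm$cds))
  expect_true(all(lens %% 3 == 0))
  expect_true(all(lens %% 9 == 0))  # chained 9-mers
  # chained windows are reference 9-mers: frame +1 matches are plentiful
  cnt <- count_cds_ninemers(w$comm$cds[[1]], w$db)
  expect_gt(sum(cnt), length(w$comm$cds[[1]]) * 10)
  # non-coding sequences contain no ambiguity codes
  expect_false(any(grepl("[^ACGT]", unlist(w$comm$noncds))))
})

test_that("fragment sampling follows the length and count protocol", {
  w <- small_world()
  ts <- sample_fragments(w$comm, per_genus = 7, seed = 80)
  expect_true(all(nchar(ts$sequence) >= 150 & nchar(ts$sequence) <= 300))
  expect_equal(nrow(ts), 7L * 2L * nrow(w$man))
  expect_equal(unname(table(ts$true_db_type)), c(7L * 6L, 7L * 6L),
               ignore_attr = TRUE)
  # determinism under a fixed seed
  ts2 <- sample_fragments(w$comm, per_genus = 7, seed = 80)
  expect_identical(ts, ts2)
  # non-CDS fragments carry no frame; CDS fragments carry a forward frame
  expect_true(all(is.na(ts$true_frame[ts$true_db_type == "nonCDS"])))
  expect_true(all(ts$true_frame[ts$true_db_type == "CDS"] %in%
                    c("+1", "+2", "+3")))
})

test_that("recorded true frames align fragments to codon boundaries", {
  # build one long CDS and check the frame arithmetic directly
  w <- small_world()
  src <- w$comm$cds[[1]][1]
  comm1 <- list(manifest = w$man[1, ], cds = list(genus01 = src),
                noncds = list(genus01 = "ACGT"))
  ts <- suppressWarnings(sample_fragments(comm1, per_genus = 30,
                                          db_types = "CDS", seed = 81))
  offs <- match(ts$true_frame, c("+1", "+2", "+3")) - 1L
  starts <- vapply(ts$sequence, function(f) regexpr(f, src, fixed = TRUE)[1],
                   integer(1))
  # the recorded frame offset must land on a codon boundary of the source
  expect_true(all((starts + offs - 1L) %% 3L == 0L))
})

test_that("evaluation reproduces the worked accuracy arithmetic", {
  n <- 4500L
  truth <- data.frame(query_id = sprintf("q%04d", 1:n),
                      true_genus = rep("gA", n),
                      true_taxon_group = rep("grpA", n),
                      true_db_type = rep("CDS", n),
                      stringsAsFactors = FALSE)
  pred <- data.frame(query_id = truth$query_id, status = "ok",
                     db_call = "CDS", best_frame = "+1",
                     best_genus = c(rep("gA", 3185L), rep("gB", n - 3185L)),
                     answer = c(rep("gA", 3185L), rep("gB", n - 3185L)),
                     n_answer = 1L, taxon_of_best = "grpA",
                     taxon_call = "grpA", n_matches = 10L, rank_sum = 300L,
                     pvalue_score = 0.01, log10_inv_p = 2,
                     stringsAsFactors = FALSE)
  rep <- evaluate_predictions(pred, truth,
                              genus_groups = c(gA = "grpA", gB = "grpB"))
  expect_equal(rep$n_correct_genus, 3185L)
  expect_equal(rep$pct_correct_genus, 71)  # (3185/4500) x 100, rounded
})

test_that("answer-set taxon proportions score mixed answers correctly", {
  truth <- data.frame(query_id = c("a", "b", "c"),
                      true_genus = "g1", true_taxon_group = "grp1",
                      true_db_type = "CDS", stringsAsFactors = FALSE)
  base <- data.frame(status = "ok", db_call = "CDS", best_frame = "+1",
                     n_answer = 1L, taxon_of_best = "grp1",
                     taxon_call = "grp1", n_matches = 5L, rank_sum = 100L,
                     pvalue_score = 0.02, log10_inv_p = 1.7,
                     stringsAsFactors = FALSE)
  pred <- cbind(query_id = c("a", "b", "c"),
                best_genus = c("g1", "g1", "g3"),
                answer = c("g1", "g1;g3", "g3"), base)
  gg <- c(g1 = "grp1", g3 = "grp3")
  rep <- evaluate_predictions(pred, truth, genus_groups = gg)
  # proportions: 1, 0.5, 0 -> mean 0.5
  expect_equal(rep$taxon_prop_mean, 0.5)
  # all-correct case: proportion 1, sd 0
  pred1 <- pred; pred1$answer <- "g1"; pred1$best_genus <- "g1"
  rep1 <- evaluate_predictions(pred1, truth, genus_groups = gg)
  expect_equal(rep1$taxon_prop_mean, 1)
  expect_equal(rep1$taxon_prop_sd, 0)
  expect_error(evaluate_predictions(transform(pred, query_id = c("a", "b", "zz")),
                                    truth, genus_groups = gg),
               "missing from truth")
})
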