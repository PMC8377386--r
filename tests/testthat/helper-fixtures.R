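# Shared fixtures, built once per test run.

# a tiny hand-written reference: RKK with two 9-mers, DDH with one,
# plus the full synonymous family of KKK (8 9-mers) for normalisation checks
tiny_refdb <- function() {
  kkk <- as.vector(outer(outer(c("AAA", "AAG"), c("AAA", "AAG"), paste0),
                         c("AAA", "AAG"), paste0))
  trimer_refdb(
    trimer = c("RKK", "RKK", "DDH", rep("KKK", 8L)),
    ninemer = c("AGAAAAAAA", "CGTAAAAAG", "GATGATCAT", kkk)
  )
}

# small 6-genus world reused across files (fast: ~2 s)
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      db <- suppressWarnings(generate_refdb_fixture(200, 6, seed = 42))
      man <- synthetic_manifest(6)
      comm <- synthetic_community(man, db, n_seqs = 15, mean_len = 600,
                                  seed = 43)
      fit <- trimer_classifier(man, comm$cds, comm$noncds, db)
      cache <<- list(db = db, man = man, comm = comm, fit = fit)
    }
    cache
  }
})

# brute-force six-frame window enumeration, independent of scan_frames
enumerate_windows <- function(seq) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- list()
  for (k in 1:6) {
    s <- if (k <= 3) seq else rc
    from <- (k - 1) %% 3 + 1
    wins <- character(0)
    i <- from
    while (i + 8 <= nchar(s)) {
      wins <- c(wins, substr(s, i, i + 8))
      i <- i + 3
    }
    out[[c("+1", "+2", "+3", "-1", "-2", "-3")[k]]] <- wins
  }
  out
}
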