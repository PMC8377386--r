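# Per-genus usage tables. The genus signal is the trimer usage bias:
#   bias(9-mer) = P(trimer | char trimer) * P(9-mer | trimer),
# both estimated from counts of reference-matching 9-mers in the genus's
# sequences, with Laplace smoothing so the product never vanishes.

# coerce FASTA-ish input (DNAStringSet, named list, character) to a plain
# uppercase character vector
.as_seq_chr <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.list(seqs)) seqs <- unlist(seqs, use.names = FALSE)
  toupper(as.character(seqs))
}

# windows of width 9 at stride 3 starting at 1-based offset `from`
.frame_windows <- function(seq, from = 1L) {
  n <- nchar(seq)
  if (n - from + 1L < 9L) return(character(0))
  starts <- seq.int(from, n - 8L, by = 3L)
  substring(seq, starts, starts + 8L)
}

#' Count reference-matching 9-mers in coding sequences
#'
#' Scans annotated CDS in their given orientation and frame only (windows of
#' 9 nt at codon stride, i.e. consecutive codon triplets overlapping by two
#' codons). Sequences shorter than 9 nt — the minimum able to host one
#' 3-codon 9-mer — or containing an ambiguous (non-ACGT) nucleotide are
#' excluded. Only 9-mers stored in the reference contribute.
#'
#' @param seqs CDS sequences: a character vector, list, or
#'   `Biostrings::DNAStringSet`.
#' @param db A [trimer_refdb] object.
#' @return Named integer vector of counts, one entry per reference 9-mer
#'   (in `db$entries` order), with attribute `excluded` giving the number of
#'   excluded sequences.
#' @export
count_cds_ninemers <- function(seqs, db) {
  stopifnot(inherits(db, "trimer_refdb"))
  seqs <- .as_seq_chr(seqs)
  keep <- nchar(seqs) >= 9L & !grepl("[^ACGT]", seqs)
  wins <- unlist(lapply(seqs[keep], .frame_windows), use.names = FALSE)
  idx <- .match_idx(db, wins)
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(db$entries))
  structure(stats::setNames(as.integer(counts), db$entries$ninemer),
            excluded = sum(!keep))
}

#' Count reference-matching 9-mers in non-coding sequences
#'
#' Non-coding sequence has no reading frame, so all six frames are scanned:
#' offsets 0, 1, 2 on the forward strand and on the reverse complement, each
#' at codon stride. Exclusion rules are as in [count_cds_ninemers].
#'
#' @inheritParams count_cds_ninemers
#' @return Named integer vector as in [count_cds_ninemers].
#' @export
count_noncds_ninemers <- function(seqs, db) {
  stopifnot(inherits(db, "trimer_refdb"))
  seqs <- .as_seq_chr(seqs)
  keep <- nchar(seqs) >= 9L & !grepl("[^ACGT]", seqs)
  fwd <- seqs[keep]
  if (length(fwd)) {
    rev <- .revcomp(fwd)
    wins <- unlist(lapply(c(fwd, rev), function(s) {
      c(.frame_windows(s, 1L), .frame_windows(s, 2L), .frame_windows(s, 3L))
    }), use.names = FALSE)
  } else {
    wins <- character(0)
  }
  idx <- .match_idx(db, wins)
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(db$entries))
  structure(stats::setNames(as.integer(counts), db$entries$ninemer),
            excluded = sum(!keep))
}

#' Build usage tables from 9-mer counts
#'
#' Estimates, with Laplace smoothing, the amino-acid-trimer usage (relative
#' frequency of each trimer within its characteristic trimer) and the
#' 3-codon usage (relative frequency of each 9-mer within its synonymous
#' family of stored 9-mers), and their product, the trimer usage bias.
#'
#' @param counts Counts as returned by [count_cds_ninemers] /
#'   [count_noncds_ninemers], aligned with `db$entries`.
#' @param db A [trimer_refdb] object.
#' @param pseudocount Positive smoothing constant added to every reference
#'   entry (default 1), guaranteeing strictly positive usages.
#' @return A data frame of class `usage_tables` with columns `char_trimer`,
#'   `trimer`, `ninemer`, `count`, `aa_trimer_usage`, `codon3_usage`, `bias`.
#' @export
build_usage_tables <- function(counts, db, pseudocount = 1) {
  stopifnot(inherits(db, "trimer_refdb"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be a positive number")
  }
  e <- db$entries
  if (length(counts) != nrow(e)) {
    counts <- counts[e$ninemer]
    counts[is.na(counts)] <- 0L
  }
  counts <- as.numeric(counts)

  # trimer totals within each characteristic trimer (smoothing applied at
  # the trimer level: one pseudocount per trimer)
  n_tri <- rowsum(counts, e$trimer)[, 1L]
  tri_first <- !duplicated(e$trimer)
  tri_tab <- data.frame(char_trimer = e$char_trimer[tri_first],
                        trimer = e$trimer[tri_first],
                        n = n_tri[e$trimer[tri_first]] + pseudocount)
  tri_tab$usage <- tri_tab$n / stats::ave(tri_tab$n, tri_tab$char_trimer,
                                          FUN = sum)
  aa_usage <- stats::setNames(tri_tab$usage, tri_tab$trimer)

  sm <- counts + pseudocount
  codon3 <- sm / stats::ave(sm, e$trimer, FUN = sum)

  out <- data.frame(e, count = as.integer(counts),
                    aa_trimer_usage = unname(aa_usage[e$trimer]),
                    codon3_usage = codon3,
                    stringsAsFactors = FALSE)
  out$bias <- out$aa_trimer_usage * out$codon3_usage
  structure(out, class = c("usage_tables", "data.frame"),
            pseudocount = pseudocount)
}

#' Trimer usage bias of a reference 9-mer
#'
#' @param tables A `usage_tables` data frame from [build_usage_tables].
#' @param ninemer 9-mer(s) to look up; must be stored in the reference.
#' @return Numeric vector of biases in (0, 1].
#' @export
trimer_usage_bias <- function(tables, ninemer) {
  stopifnot(inherits(tables, "usage_tables"))
  i <- match(toupper(ninemer), tables$ninemer)
  if (anyNA(i)) {
    stop("9-mer(s) not in reference: ",
         paste(unique(ninemer[is.na(i)]), collapse = ", "))
  }
  tables$bias[i]
}

#' Build average mono-usage tables from coding sequences
#'
#' Counts all in-frame codons of the CDS set and derives the average codon
#' usage (relative frequency of each codon within its synonymous family,
#' stop codons forming one family) and the average amino-acid usage
#' (relative frequency of each residue within its characteristic class).
#' These are the per-genus baselines from which context-free expected
#' usages are computed.
#'
#' @param seqs CDS sequences (character / list / `DNAStringSet`).
#' @param pseudocount Positive smoothing constant (default 1).
#' @return A list of class `mono_usage` with elements `avg_codon_usage`
#'   (named over the 64 codons) and `avg_aa_usage` (named over the 20
#'   residues plus `"*"`).
#' @export
build_mono_tables <- function(seqs, pseudocount = 1) {
  seqs <- .as_seq_chr(seqs)
  keep <- nchar(seqs) >= 3L & !grepl("[^ACGT]", seqs)
  codons <- unlist(lapply(seqs[keep], function(s) {
    starts <- seq.int(1L, nchar(s) - 2L, by = 3L)
    substring(s, starts, starts + 2L)
  }), use.names = FALSE)
  all_codons <- names(.GENETIC_CODE)
  cnt <- table(factor(codons, levels = all_codons))
  cnt <- as.numeric(cnt) + pseudocount
  names(cnt) <- all_codons

  fam <- .GENETIC_CODE[all_codons]                   # codon -> residue
  codon_usage <- cnt / stats::ave(cnt, fam, FUN = sum)

  aa_cnt <- rowsum(cnt, fam)[, 1L]
  grp <- .AA_CHAR[names(aa_cnt)]                     # residue -> char class
  aa_usage <- aa_cnt / stats::ave(aa_cnt, grp, FUN = sum)

  structure(list(avg_codon_usage = codon_usage, avg_aa_usage = aa_usage),
            class = "mono_usage")
}

#' Expected usages under the context-free mono model
#'
#' The expected 3-codon usage of a 9-mer is the product of the average codon
#' usages of its three codons; the expected trimer usage of an amino-acid
#' trimer is the product of the average residue usages of its three
#' residues. Both integrate to 1 over the full synonymous family / the full
#' characteristic cell, so they are the no-context reference against which
#' observed usages are standardised.
#'
#' @param mono A `mono_usage` object from [build_mono_tables].
#' @param db A [trimer_refdb] object.
#' @return A data frame of class `expected_usage` aligned with `db$entries`,
#'   with columns `expected_trimer_usage` and `expected_3codon_usage`.
#' @export
build_expected_tables <- function(mono, db) {
  stopifnot(inherits(mono, "mono_usage"), inherits(db, "trimer_refdb"))
  e <- db$entries
  cu <- mono$avg_codon_usage
  au <- mono$avg_aa_usage
  if (anyNA(cu) || anyNA(au)) stop("incomplete mono-usage tables")
  exp9 <- cu[substring(e$ninemer, 1L, 3L)] *
    cu[substring(e$ninemer, 4L, 6L)] *
    cu[substring(e$ninemer, 7L, 9L)]
  expt <- au[substring(e$trimer, 1L, 1L)] *
    au[substring(e$trimer, 2L, 2L)] *
    au[substring(e$trimer, 3L, 3L)]
  structure(data.frame(e, expected_trimer_usage = unname(expt),
                       expected_3codon_usage = unname(exp9),
                       stringsAsFactors = FALSE),
            class = c("expected_usage", "data.frame"))
}

#' Standardized 3-codon usage
#'
#' Observed 3-codon usage divided by its expected value under the mono
#' (context-free) codon model. Because the observed usage is a distribution
#' over the 9-mers stored in the reference, the expected usage is first
#' conditioned on the same stored subset (renormalised within each
#' synonymous family); with a fully stored family this is the plain
#' observed/expected ratio. A value of 1 means no codon-context effect
#' beyond single-codon bias; values above 1 mean the 9-mer is used more
#' than its codons alone predict.
#'
#' @param tables `usage_tables` from [build_usage_tables].
#' @param expected `expected_usage` from [build_expected_tables].
#' @param ninemer 9-mer(s) to look up.
#' @return Numeric vector of non-negative ratios.
#' @export
standardized_3codon_usage <- function(tables, expected, ninemer) {
  stopifnot(inherits(tables, "usage_tables"), inherits(expected, "expected_usage"))
  ninemer <- toupper(ninemer)
  i <- match(ninemer, tables$ninemer)
  j <- match(ninemer, expected$ninemer)
  if (anyNA(i) || anyNA(j)) {
    stop("9-mer(s) not in reference: ",
         paste(unique(ninemer[is.na(i) | is.na(j)]), collapse = ", "))
  }
  cond <- .conditional_expected(expected)
  tables$codon3_usage[i] / cond[j]
}

# expected 3-codon usage conditioned on the stored subset of each
# synonymous family, making it comparable with the observed 3-codon usage
.conditional_expected <- function(expected) {
  es <- expected$expected_3codon_usage
  es / stats::ave(es, expected$trimer, FUN = sum)
}

# standardized usage for ranking: the observed family distribution is
# smoothed towards the context-free null (a Dirichlet prior centred on the
# conditional expected usage, `pseudocount` pseudo-observations per stored
# family member), so that families without counts score a neutral 1 rather
# than an artefactual uniform/expected ratio
.shrunk_standardized_usage <- function(tables, expected, pseudocount = 1) {
  cond <- .conditional_expected(expected)
  n_d <- tables$count
  n_tri <- stats::ave(n_d, tables$trimer, FUN = sum)
  m <- pseudocount * stats::ave(rep(1, length(n_d)), tables$trimer,
                                FUN = sum)
  ((n_d + m * cond) / (n_tri + m)) / cond
}
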