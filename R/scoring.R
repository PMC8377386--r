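# Six-frame scanning and the two scoring methods.
#
# A query is scanned in frames +1..+3 (forward offsets 0,1,2) and -1..-3
# (reverse complement, offsets 0,1,2); within a frame, 9-nt windows advance
# at codon stride. Per frame and genus the score is the mean natural-log
# trimer usage bias over full-level matches (a geometric mean, so frames
# with different match counts are comparable), normalised to sum to one
# over the genera within each (frame, database-type) pair.

FRAME_IDS <- c("+1", "+2", "+3", "-1", "-2", "-3")

#' Scan a query sequence in all six reading frames
#'
#' @param seq A single DNA sequence (character or `DNAString`).
#' @param db A [trimer_refdb] object.
#' @return A list of class `frame_scan_set`, one element per frame id
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`), each a list with `frame_id`, `offset`
#'   (1-based window starts within the frame's strand), `ninemer`, and
#'   `ref_idx` (row into `db$entries` for full matches, `NA` otherwise).
#'   Windows containing non-ACGT characters are skipped. A query shorter
#'   than 9 nt (unable to host one 9-mer) is rejected with an error of
#'   class `trimertax_too_short`.
#' @export
scan_frames <- function(seq, db) {
  stopifnot(inherits(db, "trimer_refdb"))
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L)
  if (nchar(seq) < 9L) {
    stop(structure(class = c("trimertax_too_short", "error", "condition"),
                   list(message = paste0("query of length ", nchar(seq),
                                         " cannot host a 9-mer"),
                        call = sys.call())))
  }
  rc <- .revcomp(seq)
  scans <- vector("list", 6L)
  for (k in 1:6) {
    strand_seq <- if (k <= 3L) seq else rc
    from <- ((k - 1L) %% 3L) + 1L
    n <- nchar(strand_seq)
    if (n - from + 1L >= 9L) {
      starts <- seq.int(from, n - 8L, by = 3L)
      wins <- substring(strand_seq, starts, starts + 8L)
      ok <- !grepl("[^ACGT]", wins)
      starts <- starts[ok]; wins <- wins[ok]
    } else {
      starts <- integer(0); wins <- character(0)
    }
    scans[[k]] <- list(frame_id = FRAME_IDS[k], offset = starts,
                       ninemer = wins, ref_idx = .match_idx(db, wins))
  }
  names(scans) <- FRAME_IDS
  structure(scans, class = "frame_scan_set", query_length = nchar(seq))
}

#' Score one frame scan against one genus usage database
#'
#' @param scan One element of a [scan_frames] result.
#' @param gdb A `usage_tables` data frame for one genus (built against the
#'   same reference the scan used).
#' @return List with `n_matches` and `log_score` (mean natural-log trimer
#'   usage bias over the full-level matches; `NA` and the frame excluded
#'   when there is no match).
#' @export
frame_genus_score <- function(scan, gdb) {
  stopifnot(inherits(gdb, "usage_tables"))
  idx <- scan$ref_idx[!is.na(scan$ref_idx)]
  n <- length(idx)
  list(n_matches = n,
       log_score = if (n == 0L) NA_real_ else mean(log(gdb$bias[idx])))
}

#' Rank genera by a per-9-mer statistic
#'
#' Ascending ranks: the genus with the highest value receives rank `s` (the
#' number of genera). Ties receive average ranks for the rank-probability
#' statistics, or are broken by manifest order (`ordinal`; earlier genus
#' wins the higher rank) where integer rank sums are required by the
#' P-value tables.
#'
#' @param values Numeric vector, one value per genus in manifest order.
#' @param ties `"average"` or `"ordinal"`.
#' @return Numeric (average) or integer (ordinal) ranks.
#' @export
genus_ranks <- function(values, ties = c("average", "ordinal")) {
  ties <- match.arg(ties)
  rank(values, ties.method = if (ties == "average") "average" else "last")
}

#' Kruskal-Wallis H statistic on pre-computed ranks
#'
#' \deqn{H = \frac{12}{N(N+1)} \sum_g n_g (\bar r_g - \tfrac{N+1}{2})^2}
#' divided by the tie correction \eqn{1 - \sum_t (t^3 - t)/(N^3 - N)} over
#' tie groups of size t. When all values are tied the statistic is defined
#' as 0.
#'
#' @param ranks Numeric vector of ranks of the N observations (average
#'   ranks for ties).
#' @param groups Factor or vector of group labels, same length.
#' @return Non-negative scalar H.
#' @export
kruskal_wallis_h <- function(ranks, groups) {
  stopifnot(length(ranks) == length(groups))
  N <- length(ranks)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need at least 2 groups")
  rbar <- tapply(ranks, groups, mean)
  ng <- tapply(ranks, groups, length)
  h <- 12 / (N * (N + 1)) * sum(ng * (rbar - (N + 1) / 2)^2, na.rm = TRUE)
  tie <- table(ranks)
  corr <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (corr <= 0) return(0)  # all observations tied
  h / corr
}

#' Per-9-mer rank-probability scores for all genera
#'
#' For every reference 9-mer the genera are ranked twice — by trimer usage
#' bias and by standardized 3-codon usage (average ranks for ties). For each
#' ranking the Kruskal-Wallis H over the taxon groups and the centred group
#' mean ranks \eqn{\bar r_G - (N+1)/2} are computed; the score of genus g
#' for that ranking is \eqn{H \cdot (\bar r_{G(g)} - (N+1)/2) / N}, and the
#' final score is the mean over the two rankings. Genera of the same taxon
#' group share the value; a large positive score means the 9-mer separates
#' the groups strongly and g's group sits at the top.
#'
#' @param bias Numeric matrix, reference 9-mers x genera, of trimer usage
#'   biases (CDS).
#' @param std_usage Numeric matrix, same shape, of standardized 3-codon
#'   usages.
#' @param taxon_groups Factor/character of length `ncol(bias)` mapping each
#'   genus to its taxon group.
#' @return Numeric matrix, same shape as `bias`, of rank-probability
#'   scores.
#' @export
build_rank_scores <- function(bias, std_usage, taxon_groups) {
  stopifnot(is.matrix(bias), all(dim(bias) == dim(std_usage)))
  G <- ncol(bias)
  stopifnot(length(taxon_groups) == G)
  groups <- as.factor(taxon_groups)
  N <- G
  center <- (N + 1) / 2
  memb <- sapply(levels(groups), function(l) as.numeric(groups == l))  # G x n_groups
  ng <- colSums(memb)

  score_one <- function(vals) {
    r <- rank(vals, ties.method = "average")
    m <- as.vector(r %*% memb) / ng                   # group mean ranks
    tie <- table(r)
    corr <- 1 - sum(tie^3 - tie) / (N^3 - N)
    h <- 12 / (N * (N + 1)) * sum(ng * (m - center)^2)
    h <- if (corr <= 0) 0 else h / corr
    (h * (m - center) / N)[as.integer(groups)]        # per genus
  }
  s1 <- t(apply(bias, 1L, score_one))
  s2 <- t(apply(std_usage, 1L, score_one))
  out <- (s1 + s2) / 2
  dimnames(out) <- dimnames(bias)
  out
}
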