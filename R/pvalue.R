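# Exact null distribution of a genus's rank sum over n matched 9-mers.
# Under the null each matched 9-mer assigns the genus a uniform rank in
# 1..s (s = number of genera, 54 in the reference configuration), so the
# rank sum is distributed as the sum of n fair s-sided dice.

#' Dice-sum probability (closed form)
#'
#' Exact probability that `n` independent fair `s`-sided dice sum to `p`,
#' by inclusion-exclusion:
#' \deqn{P(p,n,s) = s^{-n} \sum_{k=0}^{\lfloor (p-n)/s \rfloor}
#'       (-1)^k \binom{n}{k} \binom{p - sk - 1}{n - 1}.}
#' The alternating sum is numerically delicate for large `n`; production
#' tables use [build_pvalue_table] (convolution) and this closed form serves
#' as the independent small-`n` reference.
#'
#' @param p Integer rank sum (vectorised).
#' @param n Integer number of dice (matched 9-mers), `n >= 1`.
#' @param s Integer number of faces (genera), `s >= 2`; default 54.
#' @return Numeric vector of probabilities; 0 outside the support
#'   `[n, s*n]`.
#' @export
dice_sum_pmf <- function(p, n, s = 54L) {
  if (any(p != round(p)) || n != round(n) || s != round(s)) {
    stop("p, n, s must be integers")
  }
  if (n < 1L || s < 2L) stop("need n >= 1, s >= 2")
  vapply(p, function(pp) {
    if (pp < n || pp > n * s) return(0)
    kmax <- floor((pp - n) / s)
    k <- 0:kmax
    sum((-1)^k * choose(n, k) * choose(pp - s * k - 1, n - 1)) / s^n
  }, numeric(1))
}

#' Exact rank-sum distribution table for n matched 9-mers
#'
#' Builds the probability mass function of the rank sum over the full
#' support `[n, s*n]` by iterated convolution with the uniform distribution
#' on `1..s` (a sliding-window sum, numerically stable at any `n`), and
#' records the modal sum. For even `n(s+1)` the distribution has two tied
#' modes; the smaller is recorded.
#'
#' @param n Number of matched 9-mers, `n >= 1`.
#' @param s Number of genera (faces), default 54.
#' @return An object of class `pvalue_table`: list with `n`, `s`, `support`
#'   (integer vector `n:(s*n)`), `pmf` (numeric, same length), `mode_sum`.
#' @export
build_pvalue_table <- function(n, s = 54L) {
  stopifnot(n >= 1L, s >= 2L, n == round(n), s == round(s))
  n <- as.integer(n); s <- as.integer(s)
  pmf <- rep(1 / s, s)                       # support 1..s
  if (n > 1L) for (i in 2:n) pmf <- .convolve_uniform_step(pmf, i, s)
  .as_pvalue_table(pmf, n, s)
}

# one convolution step: pmf over support i-1 .. s*(i-1) convolved with the
# uniform on 1..s; the new mass at sum v is the mean of the previous pmf
# over sums v-s .. v-1
.convolve_uniform_step <- function(pmf, i, s) {
  padded <- c(numeric(s), pmf, numeric(s))
  win <- stats::filter(padded, rep(1 / s, s), sides = 1)
  as.numeric(win[(s + 1L):(s + 1L + (s - 1L) * i)])
}

.as_pvalue_table <- function(pmf, n, s) {
  support <- seq.int(n, s * n)
  stopifnot(length(pmf) == length(support))
  structure(list(n = as.integer(n), s = as.integer(s), support = support,
                 pmf = pmf, mode_sum = support[which.max(pmf)]),
            class = "pvalue_table")
}

#' @export
print.pvalue_table <- function(x, ...) {
  cat("Rank-sum null distribution: n =", x$n, "matched 9-mers,", x$s,
      "genera\n  support [", min(x$support), ",", max(x$support),
      "], mode at", x$mode_sum, "\n")
  invisible(x)
}

#' Signed P-value score of an observed rank sum
#'
#' The score magnitude is the exact probability mass of the observed rank
#' sum under the null. Rank sums below the distribution's mode (the most
#' probable, central sum) lie on the non-significant side and the score is
#' negated; sums at or above the mode are reported positive. Downstream the
#' magnitude is summarised as `log10(1/|score|)`.
#'
#' @param rank_sum Observed integer rank sum.
#' @param table A `pvalue_table` from [build_pvalue_table].
#' @return List with `magnitude` (probability), `sign` (+1 or -1) and
#'   `score` (`sign * magnitude`).
#' @export
pvalue_score <- function(rank_sum, table) {
  stopifnot(inherits(table, "pvalue_table"), length(rank_sum) == 1L)
  if (rank_sum != round(rank_sum)) stop("rank_sum must be an integer")
  i <- match(as.integer(rank_sum), table$support)
  if (is.na(i)) {
    stop("rank sum ", rank_sum, " outside support [", min(table$support),
         ", ", max(table$support), "]")
  }
  sgn <- if (rank_sum < table$mode_sum) -1 else 1
  list(magnitude = table$pmf[i], sign = sgn, score = sgn * table$pmf[i])
}

#' Build the P-value table database
#'
#' One exact rank-sum table per number of matched 9-mers. The reference
#' configuration covers 2 to 625 matches (624 tables); tables can also be
#' cached to a TSV and reloaded.
#'
#' @param n_min Smallest number of matches (default 2).
#' @param n_max Largest number of matches (default 625).
#' @param s Number of genera (default 54).
#' @return An object of class `pvalue_db`: list with `s`, `n_min`, `n_max`
#'   and `tables` (list of `pvalue_table`, named by `n`).
#' @export
build_pvalue_database <- function(n_min = 2L, n_max = 625L, s = 54L) {
  stopifnot(n_min <= n_max, n_min >= 1L)
  ns <- seq.int(n_min, n_max)
  # one incremental convolution pass shared by all tables
  tables <- vector("list", length(ns))
  pmf <- rep(1 / s, s)
  n <- 1L
  for (j in seq_along(ns)) {
    while (n < ns[j]) {
      n <- n + 1L
      pmf <- .convolve_uniform_step(pmf, n, s)
    }
    tables[[j]] <- .as_pvalue_table(pmf, n, s)
  }
  names(tables) <- ns
  structure(list(s = as.integer(s), n_min = as.integer(n_min),
                 n_max = as.integer(n_max), tables = tables),
            class = "pvalue_db")
}

#' @export
print.pvalue_db <- function(x, ...) {
  cat("P-value table database:", length(x$tables), "tables covering",
      x$n_min, "-", x$n_max, "matched 9-mers,", x$s, "genera\n")
  invisible(x)
}

#' Write / read a P-value table cache
#'
#' TSV with one row per (n, rank sum, probability); regenerate with
#' [build_pvalue_database] when absent.
#'
#' @param db A `pvalue_db`.
#' @param path File path.
#' @return `path` invisibly (write); a `pvalue_db` (read).
#' @export
write_pvalue_db <- function(db, path) {
  stopifnot(inherits(db, "pvalue_db"))
  rows <- do.call(rbind, lapply(db$tables, function(tb) {
    data.frame(n = tb$n, p = tb$support, pmf = tb$pmf)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# rank-sum pmf cache, s=", db$s), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_pvalue_db
#' @export
read_pvalue_db <- function(path) {
  hdr <- readLines(path, n = 1L)
  s <- as.integer(sub(".*s=", "", hdr))
  rows <- utils::read.table(path, sep = "\t", header = TRUE,
                            comment.char = "#")
  tables <- lapply(split(rows, rows$n), function(d) {
    d <- d[order(d$p), ]
    structure(list(n = d$n[1L], s = s, support = as.integer(d$p),
                   pmf = d$pmf, mode_sum = as.integer(d$p[which.max(d$pmf)])),
              class = "pvalue_table")
  })
  ns <- as.integer(names(tables))
  structure(list(s = s, n_min = min(ns), n_max = max(ns),
                 tables = tables[order(ns)]),
            class = "pvalue_db")
}
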