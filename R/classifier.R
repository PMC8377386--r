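# The fitted classifier: per-genus usage databases plus derived matrices,
# built once from training sequences; classification is prediction.

ALLOWED_CUTOFFS <- c(0.01, 0.05, 0.1, 0.15, 0.2, 0.3)

#' Allowed answer-set cut-off values
#'
#' The score-difference cut-off may take one of six values; the default in
#' [predict.trimer_classifier] is 0.05. The lower the cut-off, the fewer
#' genera are included in an answer.
#'
#' @return Numeric vector of the six allowed cut-offs.
#' @export
allowed_cutoffs <- function() ALLOWED_CUTOFFS

# genera whose normalised score differs from the maximum by less than the
# cut-off, ordered best first (ties by manifest order)
.answer_set <- function(scores, cutoff) {
  top <- max(scores)
  in_ans <- which(top - scores < cutoff)
  in_ans[order(-scores[in_ans], in_ans)]
}

#' Fit a codon-trimer usage classifier
#'
#' Builds, for every genus in the manifest, the CDS and non-CDS usage
#' databases (amino-acid-trimer usage, 3-codon usage, and their product,
#' the trimer usage bias), the CDS mono-usage and expected tables, the
#' standardized 3-codon usages, and — when `rank_scores = TRUE` — the
#' per-9-mer rank-probability scores over the taxon groups. The returned
#' object is the fitted state that [predict.trimer_classifier] scores
#' queries against.
#'
#' @param manifest Data frame with columns `genus_id`, `taxon_group`, and
#'   optionally `kingdom`; one row per genus, in the order that defines
#'   manifest-order tie-breaking.
#' @param cds Named list (by `genus_id`) of CDS sequence sets (character
#'   vectors or `DNAStringSet`), given in coding orientation and frame.
#' @param noncds Named list (by `genus_id`) of non-coding sequence sets.
#' @param refdb A [trimer_refdb] object.
#' @param pseudocount Laplace smoothing constant for every usage table
#'   (default 1).
#' @param rank_scores Build the rank-probability score matrix (CDS only)?
#' @return An object of class `trimer_classifier`.
#' @seealso [predict.trimer_classifier], [build_usage_tables],
#'   [build_rank_scores]
#' @export
trimer_classifier <- function(manifest, cds, noncds, refdb,
                              pseudocount = 1, rank_scores = TRUE) {
  stopifnot(inherits(refdb, "trimer_refdb"),
            is.data.frame(manifest),
            all(c("genus_id", "taxon_group") %in% names(manifest)))
  genera <- as.character(manifest$genus_id)
  if (anyDuplicated(genera)) stop("duplicate genus_id in manifest")
  missing_cds <- setdiff(genera, names(cds))
  missing_non <- setdiff(genera, names(noncds))
  if (length(missing_cds) || length(missing_non)) {
    stop("sequences missing for genera: ",
         paste(union(missing_cds, missing_non), collapse = ", "))
  }
  G <- length(genera)
  R <- nrow(refdb$entries)

  genus_dbs <- vector("list", G)
  names(genus_dbs) <- genera
  log_bias <- list(CDS = matrix(NA_real_, R, G, dimnames = list(NULL, genera)),
                   nonCDS = matrix(NA_real_, R, G, dimnames = list(NULL, genera)))
  bias_cds <- matrix(NA_real_, R, G, dimnames = list(NULL, genera))
  std_cds <- matrix(NA_real_, R, G, dimnames = list(NULL, genera))

  for (g in seq_len(G)) {
    id <- genera[g]
    tab_cds <- build_usage_tables(count_cds_ninemers(cds[[id]], refdb),
                                  refdb, pseudocount)
    tab_non <- build_usage_tables(count_noncds_ninemers(noncds[[id]], refdb),
                                  refdb, pseudocount)
    mono <- build_mono_tables(cds[[id]], pseudocount)
    expected <- build_expected_tables(mono, refdb)
    genus_dbs[[g]] <- list(genus_id = id, cds = tab_cds, noncds = tab_non,
                           mono = mono, expected = expected)
    log_bias$CDS[, g] <- log(tab_cds$bias)
    log_bias$nonCDS[, g] <- log(tab_non$bias)
    bias_cds[, g] <- tab_cds$bias
    std_cds[, g] <- .shrunk_standardized_usage(tab_cds, expected, pseudocount)
  }

  # ordinal (manifest-order) per-9-mer genus ranks, for integer rank sums
  ranks <- lapply(log_bias, function(L) {
    t(apply(L, 1L, rank, ties.method = "last"))
  })

  rs <- NULL
  if (isTRUE(rank_scores)) {
    rs <- build_rank_scores(bias_cds, std_cds, manifest$taxon_group)
  }

  structure(list(manifest = manifest, refdb = refdb, genus_dbs = genus_dbs,
                 log_bias = log_bias, ranks = ranks,
                 bias_cds = bias_cds, std_cds = std_cds,
                 rank_scores = rs, pseudocount = pseudocount,
                 n_genera = G,
                 pvalue_cache = new.env(parent = emptyenv())),
            class = "trimer_classifier")
}

#' @export
print.trimer_classifier <- function(x, ...) {
  cat("Codon-trimer usage classifier\n",
      "  genera:        ", x$n_genera, " (",
      length(unique(x$manifest$taxon_group)), " taxon groups)\n",
      "  reference:     ", nrow(x$refdb$entries), " 9-mers / ",
      length(unique(x$refdb$entries$trimer)), " trimers\n",
      "  databases:     CDS + non-CDS per genus (pseudocount ",
      x$pseudocount, ")\n",
      "  rank scores:   ", if (is.null(x$rank_scores)) "not built" else "built",
      "\n", sep = "")
  invisible(x)
}

#' @method summary trimer_classifier
#' @export
summary.trimer_classifier <- function(object, ...) {
  grp <- table(object$manifest$taxon_group)
  cat("Codon-trimer usage classifier fitted over", object$n_genera,
      "genera\n\nGenera per taxon group:\n")
  print(grp)
  tot_cds <- vapply(object$genus_dbs, function(d) sum(d$cds$count), 0)
  tot_non <- vapply(object$genus_dbs, function(d) sum(d$noncds$count), 0)
  cat("\nReference-matching 9-mer counts per genus:\n")
  print(summary(tot_cds))
  cat("CDS total:", sum(tot_cds), "  non-CDS total:", sum(tot_non), "\n")
  invisible(list(groups = grp, cds_counts = tot_cds, noncds_counts = tot_non))
}

# lazily built, cached exact rank-sum table for n matches
.get_pvtable <- function(object, n) {
  key <- as.character(n)
  tb <- object$pvalue_cache[[key]]
  if (is.null(tb)) {
    tb <- build_pvalue_table(n, s = object$n_genera)
    object$pvalue_cache[[key]] <- tb
  }
  tb
}

# signed p-value scores for a vector of rank sums under one table
.signed_pvalues <- function(rank_sums, tb) {
  i <- match(as.integer(round(rank_sums)), tb$support)
  sgn <- ifelse(rank_sums < tb$mode_sum, -1, 1)
  sgn * tb$pmf[i]
}

#' Classify query sequences
#'
#' Scans each query in six reading frames, scores every (frame, database
#' type, genus) combination by mean log trimer usage bias, normalises the
#' scores within each (frame, database type) over the genera, and calls the
#' overall maximum. The answer set contains all genera of the winning frame
#' and database type whose normalised score is within `cutoff` of the
#' maximum. When the classifier carries rank-probability scores, a taxon
#' group is additionally called from the winning CDS frame. A signed
#' P-value score is attached from the exact rank-sum null distribution.
#'
#' @param object A fitted [trimer_classifier].
#' @param newdata Queries: named character vector, `DNAStringSet`, or path
#'   to a FASTA file.
#' @param cutoff Score-difference cut-off for the answer set; one of 0.01,
#'   0.05, 0.1, 0.15, 0.2, 0.3 (default 0.05). Lower cut-off, fewer genera.
#' @param methods Character subset of `c("trimer_usage",
#'   "rank_probability")`.
#' @param detail Keep per-frame, per-genus detail (needed by
#'   [write_detail])?
#' @param ... Unused.
#' @return A data frame of class `trimer_classification`, one row per
#'   query: `query_id`, `status` (`ok`, `too_short` or `unclassifiable`),
#'   `db_call`, `best_frame`, `best_genus`, `answer` (semicolon-joined,
#'   best first), `n_answer`, `taxon_of_best`, `taxon_call` (rank method),
#'   `n_matches`, `rank_sum`, `pvalue_score`, `log10_inv_p`. With
#'   `detail = TRUE` the per-query detail is attached as attribute
#'   `"detail"`.
#' @export
predict.trimer_classifier <- function(object, newdata, cutoff = 0.05,
                                      methods = c("trimer_usage",
                                                  "rank_probability"),
                                      detail = FALSE, ...) {
  if (!isTRUE(any(abs(cutoff - ALLOWED_CUTOFFS) < 1e-12)) ||
      length(cutoff) != 1L) {
    stop("cutoff must be one of ", paste(ALLOWED_CUTOFFS, collapse = ", "))
  }
  methods <- match.arg(methods, several.ok = TRUE)
  do_rank <- "rank_probability" %in% methods && !is.null(object$rank_scores)

  if (is.character(newdata) && length(newdata) == 1L &&
      file.exists(newdata) && is.null(names(newdata))) {
    newdata <- read_fasta(newdata)
  }
  if (inherits(newdata, "DNAStringSet")) {
    newdata <- stats::setNames(as.character(newdata), names(newdata))
  }
  ids <- names(newdata)
  newdata <- toupper(as.character(newdata))
  names(newdata) <- ids
  if (is.null(names(newdata)) || any(names(newdata) == "")) {
    names(newdata) <- paste0("query", seq_along(newdata))
  }

  rows <- vector("list", length(newdata))
  details <- if (detail) vector("list", length(newdata)) else NULL
  for (q in seq_along(newdata)) {
    res <- .classify_query(object, newdata[[q]], names(newdata)[q],
                           cutoff, do_rank, detail)
    rows[[q]] <- res$row
    if (detail) details[[q]] <- res$detail
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trimer_classification", "data.frame")
  attr(out, "cutoff") <- cutoff
  attr(out, "n_genera") <- object$n_genera
  if (detail) {
    names(details) <- out$query_id
    attr(out, "detail") <- details
  }
  out
}

# classify one query; returns list(row = 1-row data.frame, detail = list)
.classify_query <- function(object, seq, id, cutoff, do_rank, detail) {
  genera <- as.character(object$manifest$genus_id)
  groups <- as.character(object$manifest$taxon_group)
  empty_row <- function(status) {
    data.frame(query_id = id, status = status, db_call = NA_character_,
               best_frame = NA_character_, best_genus = NA_character_,
               answer = NA_character_, n_answer = 0L,
               taxon_of_best = NA_character_, taxon_call = NA_character_,
               n_matches = 0L, rank_sum = NA_integer_,
               pvalue_score = NA_real_, log10_inv_p = NA_real_,
               stringsAsFactors = FALSE)
  }
  if (nchar(seq) < 9L) {
    return(list(row = empty_row("too_short"), detail = list(status = "too_short")))
  }
  scans <- scan_frames(seq, object$refdb)
  idx_list <- lapply(scans, function(s) s$ref_idx[!is.na(s$ref_idx)])
  n_match <- vapply(idx_list, length, 0L)
  if (all(n_match == 0L)) {
    return(list(row = empty_row("unclassifiable"),
                detail = list(status = "unclassifiable", scans = scans)))
  }

  db_types <- c("CDS", "nonCDS")
  # norm[[db]][frame, genus]; NA rows for matchless frames
  norm <- log_sc <- list()
  for (db in db_types) {
    L <- object$log_bias[[db]]
    M <- matrix(NA_real_, 6L, length(genera),
                dimnames = list(FRAME_IDS, genera))
    for (f in which(n_match > 0L)) {
      M[f, ] <- colMeans(L[idx_list[[f]], , drop = FALSE])
    }
    log_sc[[db]] <- M
    W <- exp(M - apply(M, 1L, max))
    norm[[db]] <- W / rowSums(W)
  }

  # global argmax; ties resolved by db-type order (CDS first), then frame
  # order, then manifest order
  best <- list(val = -Inf)
  for (db in db_types) for (f in which(n_match > 0L)) {
    v <- norm[[db]][f, ]
    g <- which.max(v)
    if (v[g] > best$val) best <- list(val = v[g], db = db, frame = f, genus = g)
  }
  ans_scores <- norm[[best$db]][best$frame, ]
  answer <- genera[.answer_set(ans_scores, cutoff)]

  n_best <- n_match[best$frame]
  rank_sum <- NA_integer_; pscore <- NA_real_
  if (n_best >= 2L) {
    rs <- sum(object$ranks[[best$db]][idx_list[[best$frame]], best$genus])
    tb <- .get_pvtable(object, n_best)
    pscore <- .signed_pvalues(rs, tb)
    rank_sum <- as.integer(rs)
  }

  taxon_call <- NA_character_
  rank_totals <- NULL
  if (do_rank) {
    # frame chosen among CDS scores only; query assumed coding
    cds_best_f <- which.max(apply(norm$CDS, 1L, function(v) {
      if (all(is.na(v))) -Inf else max(v)
    }))
    totals <- colSums(object$rank_scores[idx_list[[cds_best_f]], ,
                                         drop = FALSE])
    rank_totals <- tapply(totals, groups, mean)
    taxon_call <- names(rank_totals)[which.max(rank_totals)]
  }

  row <- data.frame(
    query_id = id, status = "ok",
    db_call = best$db,
    best_frame = FRAME_IDS[best$frame],
    best_genus = genera[best$genus],
    answer = paste(answer, collapse = ";"),
    n_answer = length(answer),
    taxon_of_best = groups[best$genus],
    taxon_call = taxon_call,
    n_matches = as.integer(n_best),
    rank_sum = rank_sum,
    pvalue_score = pscore,
    log10_inv_p = if (is.na(pscore)) NA_real_ else log10(1 / abs(pscore)),
    stringsAsFactors = FALSE
  )

  det <- NULL
  if (detail) {
    det <- list(status = "ok", scans = scans, norm = norm, log_sc = log_sc,
                n_match = n_match, best = best,
                rank_totals = rank_totals)
    # per-genus signed p-values per scored frame/db
    det$pvalues <- lapply(db_types, function(db) {
      P <- matrix(NA_real_, 6L, length(genera),
                  dimnames = list(FRAME_IDS, genera))
      for (f in which(n_match >= 2L)) {
        sums <- colSums(object$ranks[[db]][idx_list[[f]], , drop = FALSE])
        P[f, ] <- .signed_pvalues(sums, .get_pvtable(object, n_match[f]))
      }
      P
    })
    names(det$pvalues) <- db_types
  }
  list(row = row, detail = det)
}

#' Classify one query with the trimer-usage probability method
#'
#' Convenience single-query wrapper around [predict.trimer_classifier]
#' restricted to the trimer-usage method.
#'
#' @param seq A single DNA sequence.
#' @param object A fitted [trimer_classifier].
#' @param cutoff Answer-set cut-off (see [predict.trimer_classifier]).
#' @return One-row classification data frame.
#' @export
classify_trimer_usage <- function(seq, object, cutoff = 0.05) {
  predict(object, stats::setNames(as.character(seq), "query"),
          cutoff = cutoff, methods = "trimer_usage")
}

#' Classify one query with the rank-probability method
#'
#' Assumes the query is coding; chooses the best frame under the CDS
#' databases and sums the per-9-mer rank-probability scores per taxon
#' group.
#'
#' @inheritParams classify_trimer_usage
#' @return List with `taxon_call` and the named vector `group_totals`.
#' @export
classify_rank_probability <- function(seq, object, cutoff = 0.05) {
  if (is.null(object$rank_scores)) stop("classifier built without rank scores")
  res <- predict(object, stats::setNames(as.character(seq), "query"),
                 cutoff = cutoff, detail = TRUE)
  det <- attr(res, "detail")[[1L]]
  if (!identical(det$status, "ok")) {
    return(list(taxon_call = NA_character_, group_totals = NULL,
                status = det$status))
  }
  list(taxon_call = res$taxon_call, group_totals = det$rank_totals,
       status = "ok")
}
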