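# File interfaces: FASTA ingestion, genus manifest, usage-table
# serialization, and the two-stage classification output (per-frame detail
# file and one-line-per-query summary).

#' Read a FASTA file
#'
#' Record ids are taken up to the first whitespace; sequences are
#' concatenated across wrapped lines and uppercased. Duplicate ids are
#' suffixed (`.2`, `.3`, ...) with a warning; an empty file yields an empty
#' result with a warning.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (!length(nonblank)) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  if (!startsWith(lines[nonblank[1L]], ">")) {
    stop("malformed FASTA at line ", nonblank[1L],
         ": expected a '>' header in ", path)
  }
  set <- Biostrings::readBStringSet(path)  # BString: tolerate any letters,
  seqs <- toupper(as.character(set))       # window filtering happens later
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA id(s) suffixed: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids <- make.unique(ids, sep = ".")
  }
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a genus manifest TSV
#'
#' Columns: `genus_id`, `taxon_group`, `kingdom`, `cds_fasta`,
#' `noncds_fasta`; the two path columns may hold several paths separated by
#' semicolons (multiple genomes per genus are pooled).
#'
#' @param path Path to the manifest.
#' @return Data frame, one row per genus.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         comment.char = "#", stringsAsFactors = FALSE)
  need <- c("genus_id", "taxon_group")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  m
}

#' Load training sequences named by a manifest
#'
#' Reads and pools (per genus) the CDS and non-CDS FASTA files listed in a
#' manifest, resolving relative paths against the manifest's directory.
#'
#' @param manifest Data frame from [read_manifest] (needs `cds_fasta` and
#'   `noncds_fasta` columns).
#' @param base_dir Directory against which relative paths are resolved.
#' @return List with `cds` and `noncds`: named lists of character vectors.
#' @export
load_training_sequences <- function(manifest, base_dir = ".") {
  read_pooled <- function(paths) {
    files <- trimws(strsplit(paths, ";", fixed = TRUE)[[1L]])
    files <- ifelse(file.exists(files), files, file.path(base_dir, files))
    unlist(lapply(files, function(f) unname(read_fasta(f))), use.names = FALSE)
  }
  cds <- lapply(manifest$cds_fasta, read_pooled)
  noncds <- lapply(manifest$noncds_fasta, read_pooled)
  names(cds) <- names(noncds) <- manifest$genus_id
  list(cds = cds, noncds = noncds)
}

#' Serialize usage tables to TSV
#'
#' Columns `char_trimer`, `trimer`, `ninemer`, `count`, `aa_trimer_usage`,
#' `codon3_usage`, `bias`, optionally extended with `std_usage` and
#' `rank_score`.
#'
#' @param tables A `usage_tables` data frame.
#' @param path Output path.
#' @param std_usage,rank_score Optional numeric vectors aligned with
#'   `tables` rows.
#' @return `path`, invisibly.
#' @export
write_usage_tables <- function(tables, path, std_usage = NULL,
                               rank_score = NULL) {
  stopifnot(inherits(tables, "usage_tables"))
  out <- as.data.frame(tables)
  if (!is.null(std_usage)) out$std_usage <- std_usage
  if (!is.null(rank_score)) out$rank_score <- rank_score
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read serialized usage tables
#'
#' @param path Path written by [write_usage_tables].
#' @return A `usage_tables` data frame.
#' @export
read_usage_tables <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         comment.char = "#", stringsAsFactors = FALSE)
  structure(d, class = c("usage_tables", "data.frame"))
}

#' Write a test set as FASTA plus truth TSV
#'
#' @param test_set A `test_set` data frame from [sample_fragments].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_test_set <- function(test_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(stats::setNames(test_set$sequence, test_set$query_id),
              file.path(dir, "queries.fasta"))
  utils::write.table(test_set[setdiff(names(test_set), "sequence")],
                     file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Write the per-frame detail file
#'
#' One flat TSV holding, per query and reading frame, the matched
#' characteristic trimers / amino-acid trimers / 9-mers with their offsets
#' (`record = "match"`), and per (frame, database type) the full genus
#' table with rank, mean-log score, normalised score and signed P-value
#' score, best rank first (`record = "genus"`; a single `n_matches = 0` row
#' marks a matchless frame). Queries without a prediction get a `status`
#' row. The summary file is derivable from this file alone.
#'
#' @param results A `trimer_classification` from
#'   [predict.trimer_classifier] run with `detail = TRUE`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detail <- function(results, path) {
  details <- attr(results, "detail")
  if (is.null(details)) stop("results lack detail; run predict(detail = TRUE)")
  rows <- list()
  blank <- data.frame(record = NA_character_, query_id = NA_character_,
                      frame = NA_character_, db_type = NA_character_,
                      offset = NA_integer_, ninemer = NA_character_,
                      trimer = NA_character_, char_trimer = NA_character_,
                      genus = NA_character_, rank = NA_integer_,
                      n_matches = NA_integer_, log_score = NA_real_,
                      norm_score = NA_real_, pvalue_score = NA_real_,
                      stringsAsFactors = FALSE)
  for (qid in names(details)) {
    det <- details[[qid]]
    if (!identical(det$status, "ok")) {
      r <- blank; r$record <- "status"; r$query_id <- qid
      r$db_type <- det$status
      rows[[length(rows) + 1L]] <- r
      next
    }
    for (f in seq_along(FRAME_IDS)) {
      scan <- det$scans[[f]]
      full <- which(!is.na(scan$ref_idx))
      if (length(full)) {
        r <- blank[rep(1L, length(full)), ]
        r$record <- "match"; r$query_id <- qid; r$frame <- FRAME_IDS[f]
        r$offset <- scan$offset[full]
        r$ninemer <- scan$ninemer[full]
        r$trimer <- ninemer_to_trimer(r$ninemer)
        r$char_trimer <- trimer_to_char_trimer(r$trimer)
        rows[[length(rows) + 1L]] <- r
      }
      for (db in names(det$norm)) {
        if (det$n_match[f] == 0L) {
          r <- blank; r$record <- "genus"; r$query_id <- qid
          r$frame <- FRAME_IDS[f]; r$db_type <- db; r$n_matches <- 0L
          rows[[length(rows) + 1L]] <- r
          next
        }
        ns <- det$norm[[db]][f, ]
        rk <- genus_ranks(ns, ties = "ordinal")
        ord <- order(-rk)
        r <- blank[rep(1L, length(ns)), ]
        r$record <- "genus"; r$query_id <- qid; r$frame <- FRAME_IDS[f]
        r$db_type <- db
        r$genus <- names(ns)[ord]
        r$rank <- rk[ord]
        r$n_matches <- det$n_match[f]
        r$log_score <- det$log_sc[[db]][f, ord]
        r$norm_score <- ns[ord]
        r$pvalue_score <- det$pvalues[[db]][f, ord]
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-frame classification detail", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a detail file back
#'
#' @param path Path written by [write_detail].
#' @return Data frame of the detail rows.
#' @export
read_detail <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = c(frame = "character"))
}

#' Write the one-line-per-query summary file
#'
#' Columns: `query_id`, `status`, `db_call`, `best_frame`, `answer`
#' (semicolon-joined genera, best first), `taxon_call`, `pvalue_score`,
#' `n_matches`. Queries rejected as too short or without any reference
#' match keep their status flag and an empty answer.
#'
#' @param results A `trimer_classification` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(results, path) {
  cols <- c("query_id", "status", "db_call", "best_frame", "answer",
            "taxon_call", "pvalue_score", "n_matches")
  out <- as.data.frame(results)[, cols]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# classification summary (cutoff ",
                    attr(results, "cutoff"), ")"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report
#'
#' Human-readable text plus TSV tables (per-genus counts and the
#' quartile analysis) under a common file prefix.
#'
#' @param report An `evaluation_report` from [evaluate_predictions].
#' @param prefix Output path prefix; writes `<prefix>.txt`,
#'   `<prefix>_per_genus.tsv`, and (when available)
#'   `<prefix>_quartiles.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_evaluation <- function(report, prefix) {
  stopifnot(inherits(report, "evaluation_report"))
  txt <- file.path(paste0(prefix, ".txt"))
  sink(txt); on.exit(sink())
  print(report)
  sink(); on.exit()
  utils::write.table(report$per_genus, paste0(prefix, "_per_genus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$quartiles)) {
    utils::write.table(report$quartiles, paste0(prefix, "_quartiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
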