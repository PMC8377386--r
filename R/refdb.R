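# Trimer reference database: three-level hierarchy
#   characteristic trimer -> amino-acid trimer -> 3-codon DNA 9-mers.
# Stored flat as one row per (trimer, 9-mer) pair; the characteristic level
# is always derived, never read from file.

#' Construct a trimer reference database
#'
#' Builds the three-level reference hierarchy (characteristic trimer ->
#' amino-acid trimer -> 3-codon DNA 9-mers) from a set of (trimer, 9-mer)
#' pairs. Every 9-mer must translate, under the standard genetic code, to the
#' trimer it is filed under; reference trimers may not contain the stop
#' symbol. Duplicate pairs are removed.
#'
#' @param trimer Character vector of amino-acid trimers (length-3 residue
#'   strings).
#' @param ninemer Character vector (same length) of 9-nt DNA strings.
#' @return An object of class `trimer_refdb`: a list with element `entries`,
#'   a data frame with columns `char_trimer`, `trimer`, `ninemer`, one row
#'   per stored 9-mer, sorted by hierarchy.
#' @export
trimer_refdb <- function(trimer, ninemer) {
  stopifnot(length(trimer) == length(ninemer))
  if (length(trimer) == 0L) stop("empty reference: no (trimer, 9-mer) rows")
  trimer <- toupper(as.character(trimer))
  ninemer <- toupper(as.character(ninemer))
  if (any(grepl("\\*", trimer))) {
    stop("reference trimers may not contain the stop symbol: row(s) ",
         paste(which(grepl("\\*", trimer)), collapse = ", "))
  }
  tr <- ninemer_to_trimer(ninemer)
  bad <- tr != trimer
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("inconsistent row ", i, ": 9-mer ", ninemer[i], " translates to ",
         tr[i], ", not ", trimer[i])
  }
  entries <- unique(data.frame(
    char_trimer = trimer_to_char_trimer(trimer),
    trimer = trimer,
    ninemer = ninemer,
    stringsAsFactors = FALSE
  ))
  entries <- entries[order(entries$char_trimer, entries$trimer,
                           entries$ninemer), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "trimer_refdb")
}

#' Load a trimer reference database from a TSV file
#'
#' One row per (amino-acid trimer, 9-mer) pair, two tab-separated columns;
#' lines starting with `#` are ignored. Input case is normalised to upper
#' case. Consistency (each 9-mer translating to its trimer) is enforced at
#' load and violations are reported with their row.
#'
#' @param path Path to the TSV file.
#' @return A [trimer_refdb] object.
#' @export
load_refdb <- function(path) {
  raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                           colClasses = "character", header = FALSE,
                           blank.lines.skip = TRUE)
  if (ncol(raw) < 2L) stop("reference TSV must have 2 tab-separated columns")
  trimer_refdb(raw[[1L]], raw[[2L]])
}

#' Write a trimer reference database to TSV
#'
#' @param db A [trimer_refdb] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refdb <- function(db, path) {
  stopifnot(inherits(db, "trimer_refdb"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# trimer reference: trimer<TAB>ninemer", con)
  utils::write.table(db$entries[c("trimer", "ninemer")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.trimer_refdb <- function(x, ...) {
  e <- x$entries
  cat("Trimer reference database\n",
      "  characteristic trimers: ", length(unique(e$char_trimer)), "\n",
      "  amino-acid trimers:     ", length(unique(e$trimer)), "\n",
      "  3-codon DNA 9-mers:     ", nrow(e), "\n", sep = "")
  invisible(x)
}

#' Match a 9-mer against the reference hierarchy
#'
#' Descends the hierarchy: characteristic trimer, then amino-acid trimer,
#' then the 9-mer itself. Only a full (deepest-level) match carries usage
#' information and contributes to scoring; absence at any level is a valid
#' result, not an error. A 9-mer containing a stop codon can never reach the
#' characteristic level because reference trimers are stop-free.
#'
#' @param db A [trimer_refdb] object.
#' @param ninemer A single 9-nt DNA string.
#' @return A list with elements `level` (one of `"none"`, `"char_only"`,
#'   `"trimer_only"`, `"full"`), `matched_9mer`, `matched_trimer`,
#'   `matched_char_trimer` (the latter three `NA` below their level).
#' @export
match_ninemer <- function(db, ninemer) {
  stopifnot(inherits(db, "trimer_refdb"), length(ninemer) == 1L)
  ninemer <- toupper(ninemer)
  tri <- ninemer_to_trimer(ninemer)
  ch <- trimer_to_char_trimer(tri)
  e <- db$entries
  if (ninemer %in% e$ninemer) {
    list(level = "full", matched_9mer = ninemer, matched_trimer = tri,
         matched_char_trimer = ch)
  } else if (tri %in% e$trimer) {
    list(level = "trimer_only", matched_9mer = NA_character_,
         matched_trimer = tri, matched_char_trimer = ch)
  } else if (ch %in% e$char_trimer) {
    list(level = "char_only", matched_9mer = NA_character_,
         matched_trimer = NA_character_, matched_char_trimer = ch)
  } else {
    list(level = "none", matched_9mer = NA_character_,
         matched_trimer = NA_character_, matched_char_trimer = NA_character_)
  }
}

# internal: vectorised full-level lookup; row index into db$entries, NA if
# the 9-mer is not stored (containing a non-ACGT window is the caller's
# responsibility to exclude)
.match_idx <- function(db, ninemers) {
  match(ninemers, db$entries$ninemer)
}
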