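# Synthetic benchmark: reference fixtures, genus-labelled sequence sets
# with controllable compositional divergence, fragment test sets following
# the evaluation protocol (100 fragments per genus per database type,
# 150-300 bp), and the evaluation statistics.

.TAXON_GROUPS <- c("Clostridia", "Bacilli", "Oscillatoriophycideae",
                   "Nostocales", "Acidobacteriales", "Betaproteobacteria",
                   "Deltaproteobacteria", "Gammaproteobacteria",
                   "Alphaproteobacteria", "Actinobacteria",
                   "AMF", "Agaricomycotina", "Pezizomycotina")

.AA20 <- setdiff(names(.AA_CHAR), "*")

# run expr with a local RNG state seeded by `seed` (NULL = use current)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Default genus manifest for the synthetic benchmark
#'
#' The reference configuration mirrors the target application: 54 genera in
#' 13 taxon groups — 45 bacterial genera spread over the 10 bacterial
#' groups and 9 fungal genera over AMF (1), Agaricomycotina (4) and
#' Pezizomycotina (4). Smaller configurations assign genera round-robin to
#' proportionally fewer groups.
#'
#' @param n_genera Number of genera (default 54).
#' @return Data frame with columns `genus_id`, `taxon_group`, `kingdom`.
#' @export
synthetic_manifest <- function(n_genera = 54L) {
  stopifnot(n_genera >= 2L)
  if (n_genera == 54L) {
    bact <- rep(.TAXON_GROUPS[1:10], length.out = 45L)
    fung <- c("AMF", rep(c("Agaricomycotina", "Pezizomycotina"), 4L))
    groups <- c(sort(bact), sort(fung))
    kingdom <- rep(c("bacteria", "fungi"), c(45L, 9L))
  } else {
    ngrp <- max(2L, min(13L, ceiling(n_genera / 4L)))
    groups <- sort(rep(.TAXON_GROUPS[seq_len(ngrp)], length.out = n_genera))
    kingdom <- ifelse(groups %in% c("AMF", "Agaricomycotina",
                                    "Pezizomycotina"), "fungi", "bacteria")
  }
  data.frame(genus_id = sprintf("genus%02d", seq_len(n_genera)),
             taxon_group = groups, kingdom = kingdom,
             stringsAsFactors = FALSE)
}

#' Generate a consistent trimer reference fixture
#'
#' Samples distinct stop-free amino-acid trimers, then for each trimer a
#' subset of its synonymous 3-codon 9-mers. The hierarchy is consistent by
#' construction. A request exceeding a trimer's synonymous family size is
#' capped with a warning.
#'
#' @param n_trimers Number of amino-acid trimers (default 1200).
#' @param ninemers_per_trimer 9-mers sampled per trimer (default 12).
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @return A [trimer_refdb] object.
#' @export
generate_refdb_fixture <- function(n_trimers = 1200L,
                                   ninemers_per_trimer = 12L, seed = NULL) {
  stopifnot(n_trimers >= 1L, ninemers_per_trimer >= 1L)
  .with_seed(seed, {
    max_tri <- length(.AA20)^3
    n_trimers <- min(n_trimers, max_tri)
    # sample distinct residue triples by index
    ids <- sample.int(max_tri, n_trimers) - 1L
    r1 <- .AA20[ids %% 20L + 1L]
    r2 <- .AA20[(ids %/% 20L) %% 20L + 1L]
    r3 <- .AA20[ids %/% 400L + 1L]
    trimers <- paste0(r1, r2, r3)
    capped <- FALSE
    tri_list <- lapply(seq_len(n_trimers), function(i) {
      fams <- lapply(c(r1[i], r2[i], r3[i]), .codons_of)
      size <- prod(lengths(fams))
      k <- ninemers_per_trimer
      if (k > size) { capped <<- TRUE; k <- size }
      picks <- sample.int(size, k)
      # decode mixed-radix index into the three codon choices
      p0 <- picks - 1L
      nine <- paste0(fams[[1L]][p0 %% lengths(fams)[1L] + 1L],
                     fams[[2L]][(p0 %/% lengths(fams)[1L]) %% lengths(fams)[2L] + 1L],
                     fams[[3L]][p0 %/% (lengths(fams)[1L] * lengths(fams)[2L]) + 1L])
      data.frame(trimer = trimers[i], ninemer = nine,
                 stringsAsFactors = FALSE)
    })
    if (capped) {
      warning("ninemers_per_trimer exceeded a synonymous family size; capped")
    }
    all <- do.call(rbind, tri_list)
    trimer_refdb(all$trimer, all$ninemer)
  })
}

#' Generate genus profiles with hierarchical compositional divergence
#'
#' Each taxon group draws a group-level codon preference (a Dirichlet draw
#' within every synonymous codon family) and a group-level trimer
#' preference over the reference trimers; each genus then draws its own
#' preferences around its group's (Dirichlet centred on the group
#' preference). Low concentrations give spiky, well-separated profiles;
#' high concentrations make genera converge towards uniform usage. A
#' per-genus order-0 nucleotide composition drives the non-coding model.
#'
#' @param manifest Genus manifest ([synthetic_manifest]).
#' @param refdb Reference fixture ([generate_refdb_fixture]).
#' @param codon_conc Dirichlet concentration for group codon preferences
#'   (default 0.5; smaller = more divergent genera).
#' @param trimer_conc Concentration for group trimer preferences (default 1).
#' @param within_group_conc Precision of genus preferences around the group
#'   preference (default 50; larger = tighter taxon groups).
#' @param nt_conc Concentration for per-genus non-coding base composition
#'   (default 5).
#' @param seed Integer seed.
#' @return Named list of `genus_profile` objects (fields `genus_id`,
#'   `taxon_group`, `codon_pref`, `trimer_pref`, `nt_freq`).
#' @export
generate_genus_profiles <- function(manifest, refdb, codon_conc = 0.5,
                                    trimer_conc = 1, within_group_conc = 50,
                                    nt_conc = 5, seed = NULL) {
  stopifnot(inherits(refdb, "trimer_refdb"))
  .with_seed(seed, {
    codons <- names(.GENETIC_CODE)
    fam <- .GENETIC_CODE[codons]
    trimers <- unique(refdb$entries$trimer)
    groups <- unique(manifest$taxon_group)

    group_codon <- lapply(groups, function(g) {
      pref <- unlist(lapply(split(codons, fam), function(cs) {
        stats::setNames(.rdirichlet(rep(codon_conc, length(cs))), cs)
      }))
      names(pref) <- sub("^[^.]*\\.", "", names(pref))
      pref[codons]
    })
    names(group_codon) <- groups
    group_trimer <- lapply(groups, function(g) {
      stats::setNames(.rdirichlet(rep(trimer_conc, length(trimers))), trimers)
    })
    names(group_trimer) <- groups

    profiles <- lapply(seq_len(nrow(manifest)), function(i) {
      grp <- manifest$taxon_group[i]
      gc <- group_codon[[grp]]
      codon_pref <- unlist(lapply(split(seq_along(codons), fam), function(ix) {
        stats::setNames(.rdirichlet(within_group_conc * gc[ix] +
                                      .Machine$double.eps), codons[ix])
      }))
      names(codon_pref) <- sub("^[^.]*\\.", "", names(codon_pref))
      codon_pref <- codon_pref[codons]
      trimer_pref <- .rdirichlet(within_group_conc * group_trimer[[grp]] +
                                   .Machine$double.eps)
      names(trimer_pref) <- trimers
      structure(list(genus_id = manifest$genus_id[i], taxon_group = grp,
                     codon_pref = codon_pref, trimer_pref = trimer_pref,
                     nt_freq = stats::setNames(.rdirichlet(rep(nt_conc, 4L)),
                                               c("A", "C", "G", "T"))),
                class = "genus_profile")
    })
    names(profiles) <- manifest$genus_id
    profiles
  })
}

#' Generate coding and non-coding sequences for one genus
#'
#' Coding sequences are built by chaining reference trimers sampled by the
#' genus trimer preference; each trimer is realised as one of its stored
#' synonymous 9-mers with probability proportional to the product of the
#' genus codon preferences of its three codons, creating genus-specific
#' 3-codon usage. CDS lengths are multiples of 3 and have their reading
#' frame at offset 0. Non-coding sequences are drawn from the genus's
#' order-0 nucleotide composition, a model with no codon structure. No
#' ambiguity codes are emitted.
#'
#' @param profile A `genus_profile`.
#' @param refdb The [trimer_refdb] fixture the profile was built against.
#' @param n_seqs Sequences per set (default 40).
#' @param mean_len Approximate sequence length in nt (default 900).
#' @param seed Integer seed.
#' @return List with character vectors `cds` and `noncds`.
#' @export
generate_genus_sequences <- function(profile, refdb, n_seqs = 40L,
                                     mean_len = 900L, seed = NULL) {
  stopifnot(inherits(profile, "genus_profile"), inherits(refdb, "trimer_refdb"))
  .with_seed(seed, {
    e <- refdb$entries
    trimers <- unique(e$trimer)
    # per-trimer stored 9-mers and their genus-specific selection weights
    by_tri <- split(e$ninemer, e$trimer)[trimers]
    cp <- profile$codon_pref
    w_tri <- lapply(by_tri, function(nm) {
      w <- cp[substring(nm, 1, 3)] * cp[substring(nm, 4, 6)] *
        cp[substring(nm, 7, 9)]
      s <- sum(w)
      if (!is.finite(s) || s <= 0) rep(1 / length(w), length(w)) else w / s
    })
    tp <- profile$trimer_pref[trimers]

    cds <- vapply(seq_len(n_seqs), function(i) {
      n_chain <- max(6L, stats::rpois(1L, mean_len / 9))
      tri_idx <- sample.int(length(trimers), n_chain, replace = TRUE,
                            prob = tp)
      paste(vapply(tri_idx, function(j) {
        nm <- by_tri[[j]]
        if (length(nm) == 1L) nm else sample(nm, 1L, prob = w_tri[[j]])
      }, character(1)), collapse = "")
    }, character(1))

    noncds <- vapply(seq_len(n_seqs), function(i) {
      len <- max(150L, stats::rpois(1L, mean_len))
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                   prob = profile$nt_freq), collapse = "")
    }, character(1))

    list(cds = cds, noncds = noncds)
  })
}

#' Generate a full synthetic community
#'
#' Convenience orchestrator: profiles plus per-genus CDS and non-CDS
#' sequence sets for every genus in the manifest.
#'
#' @inheritParams generate_genus_profiles
#' @inheritParams generate_genus_sequences
#' @return List with `manifest`, `profiles`, `cds` (named list), `noncds`
#'   (named list).
#' @export
synthetic_community <- function(manifest, refdb, codon_conc = 0.5,
                                trimer_conc = 1, within_group_conc = 50,
                                nt_conc = 5, n_seqs = 40L, mean_len = 900L,
                                seed = NULL) {
  .with_seed(seed, {
    profiles <- generate_genus_profiles(manifest, refdb, codon_conc,
                                        trimer_conc, within_group_conc,
                                        nt_conc, seed = NULL)
    seqs <- lapply(profiles, generate_genus_sequences, refdb = refdb,
                   n_seqs = n_seqs, mean_len = mean_len, seed = NULL)
    list(manifest = manifest, profiles = profiles,
         cds = lapply(seqs, `[[`, "cds"),
         noncds = lapply(seqs, `[[`, "noncds"))
  })
}

#' Sample a fragment test set
#'
#' Follows the benchmark protocol: per genus and database type,
#' `per_genus` fragments with a uniformly random start and an end chosen so
#' the length falls in `len_range` (150-300 bp by default) and within the
#' source sequence. The true reading frame is recorded for CDS fragments.
#' Source sequences shorter than the minimum length are skipped with a
#' warning.
#'
#' @param community A [synthetic_community] result (or any list with
#'   `manifest`, `cds`, `noncds`).
#' @param per_genus Fragments per genus per database type (default 100).
#' @param len_range Length bounds in nt (default `c(150, 300)`).
#' @param db_types Which source sets to fragment (default both).
#' @param seed Integer seed.
#' @return Data frame of class `test_set`: `query_id`, `sequence`,
#'   `true_genus`, `true_taxon_group`, `true_db_type`, `true_frame`.
#' @export
sample_fragments <- function(community, per_genus = 100L,
                             len_range = c(150L, 300L),
                             db_types = c("CDS", "nonCDS"), seed = NULL) {
  stopifnot(len_range[1] <= len_range[2], len_range[1] >= 9L)
  manifest <- community$manifest
  .with_seed(seed, {
    out <- list()
    skipped <- 0L
    for (i in seq_len(nrow(manifest))) {
      id <- manifest$genus_id[i]
      for (db in db_types) {
        src <- if (db == "CDS") community$cds[[id]] else community$noncds[[id]]
        ok <- nchar(src) >= len_range[1]
        skipped <- skipped + sum(!ok)
        src <- src[ok]
        if (!length(src)) next
        pick <- sample.int(length(src), per_genus, replace = TRUE)
        frag <- character(per_genus)
        frames <- rep(NA_character_, per_genus)
        for (j in seq_len(per_genus)) {
          s <- src[pick[j]]
          L <- nchar(s)
          start <- sample.int(L - len_range[1] + 1L, 1L)
          lens <- seq.int(len_range[1], min(len_range[2], L - start + 1L))
          len <- lens[sample.int(length(lens), 1L)]
          frag[j] <- substring(s, start, start + len - 1L)
          if (db == "CDS") {
            off <- (3L - (start - 1L) %% 3L) %% 3L
            frames[j] <- FRAME_IDS[off + 1L]
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          query_id = sprintf("%s_%s_%03d", id, db, seq_len(per_genus)),
          sequence = frag, true_genus = id,
          true_taxon_group = manifest$taxon_group[i],
          true_db_type = db, true_frame = frames,
          stringsAsFactors = FALSE)
      }
    }
    if (skipped > 0L) warning(skipped, " source sequence(s) too short; skipped")
    ts <- do.call(rbind, out)
    rownames(ts) <- NULL
    class(ts) <- c("test_set", "data.frame")
    ts
  })
}

#' Evaluate classifications against a truth table
#'
#' A genus prediction is correct when the answer set contains the true
#' genus; a taxon-group prediction when the answer contains a genus of the
#' true group. Reported statistics: per-genus correct counts; mean percent
#' correct at genus and taxon-group level (rounded to integer percent);
#' mean and SD of the per-answer correct-taxon proportion (1 = answers held
#' the correct group only, 0 = only wrong groups); quartile table of
#' log10(1/|P-value score|) against the correct-prediction proportion; and
#' the rank-position distribution of the first correct-group genus in the
#' answer. Queries without a prediction (`status != "ok"`) are excluded
#' from the denominator ("predictions made") and counted separately.
#'
#' @param predictions A `trimer_classification` data frame from
#'   [predict.trimer_classifier].
#' @param truth A `test_set` data frame (or any data frame with `query_id`,
#'   `true_genus`, `true_taxon_group`, `true_db_type`).
#' @param genus_groups Named character vector mapping genus to taxon group
#'   (defaults to the mapping implied by `truth`); needed to translate
#'   answer genera into groups.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(predictions, truth, genus_groups = NULL) {
  stopifnot(is.data.frame(predictions), is.data.frame(truth))
  m <- match(predictions$query_id, truth$query_id)
  if (anyNA(m)) stop("query id(s) missing from truth table")
  truth <- truth[m, , drop = FALSE]
  if (is.null(genus_groups)) {
    genus_groups <- stats::setNames(truth$true_taxon_group, truth$true_genus)
    genus_groups <- genus_groups[!duplicated(names(genus_groups))]
  }

  made <- predictions$status == "ok"
  pr <- predictions[made, , drop = FALSE]
  tr <- truth[made, , drop = FALSE]
  ans <- strsplit(pr$answer, ";", fixed = TRUE)

  genus_correct <- mapply(function(a, g) g %in% a, ans, tr$true_genus)
  ans_groups <- lapply(ans, function(a) unname(genus_groups[a]))
  taxon_correct <- mapply(function(ag, g) g %in% ag, ans_groups,
                          tr$true_taxon_group)
  taxon_prop <- mapply(function(ag, g) mean(ag == g), ans_groups,
                       tr$true_taxon_group)
  db_correct <- pr$db_call == tr$true_db_type
  # 1-based position of the first correct-group genus in the answer (NA if
  # absent)
  first_pos <- mapply(function(ag, g) {
    p <- which(ag == g)[1L]
    if (length(p)) p else NA_integer_
  }, ans_groups, tr$true_taxon_group)

  per_genus <- stats::aggregate(
    cbind(correct = as.integer(genus_correct),
          taxon_correct = as.integer(taxon_correct)),
    by = list(genus = tr$true_genus, db_type = tr$true_db_type), FUN = sum)
  n_per <- stats::aggregate(list(n = rep(1L, nrow(tr))),
                            by = list(genus = tr$true_genus,
                                      db_type = tr$true_db_type), FUN = sum)
  per_genus <- merge(per_genus, n_per)

  # quartile analysis of log10(1/|P|)
  lp <- pr$log10_inv_p
  okp <- is.finite(lp)
  quart <- NULL
  if (sum(okp) >= 8L) {
    qb <- stats::quantile(lp[okp], probs = seq(0, 1, 0.25), names = FALSE)
    qb[1] <- qb[1] - 1e-9
    bin <- cut(lp[okp], breaks = unique(qb), include.lowest = TRUE)
    quart <- data.frame(
      quartile = seq_len(nlevels(bin)),
      range = levels(bin),
      mean_correct = as.numeric(tapply(genus_correct[okp], bin, mean)),
      sd_correct = as.numeric(tapply(genus_correct[okp], bin, stats::sd)),
      n = as.integer(table(bin)))
  }

  structure(list(
    n_total = nrow(predictions),
    n_predicted = nrow(pr),
    n_unpredicted = sum(!made),
    n_correct_genus = sum(genus_correct),
    n_correct_taxon = sum(taxon_correct),
    pct_correct_genus = round(100 * mean(genus_correct)),
    pct_correct_taxon = round(100 * mean(taxon_correct)),
    db_call_accuracy = mean(db_correct),
    taxon_prop_mean = mean(taxon_prop),
    taxon_prop_sd = stats::sd(taxon_prop),
    per_genus = per_genus,
    quartiles = quart,
    rank_position = table(factor(first_pos, levels = 1:5)),
    frame_accuracy = {
      cds <- tr$true_db_type == "CDS" & !is.na(tr$true_frame)
      if (any(cds)) mean(pr$best_frame[cds] == tr$true_frame[cds]) else NA_real_
    }
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Classification evaluation\n",
      "  predictions made:      ", x$n_predicted, " of ", x$n_total,
      " (", x$n_unpredicted, " unclassifiable/too short)\n",
      "  correct genus:         ", x$n_correct_genus, " (",
      x$pct_correct_genus, "%)\n",
      "  correct taxon group:   ", x$n_correct_taxon, " (",
      x$pct_correct_taxon, "%)\n",
      "  CDS/non-CDS call:      ", round(100 * x$db_call_accuracy), "%\n",
      "  frame recovery (CDS):  ",
      if (is.na(x$frame_accuracy)) "-" else paste0(round(100 * x$frame_accuracy), "%"),
      "\n",
      "  correct-taxon proportion per answer: ",
      sprintf("%.2f +/- %.2f", x$taxon_prop_mean, x$taxon_prop_sd), "\n",
      sep = "")
  if (!is.null(x$quartiles)) {
    cat("  correct proportion by log10(1/|P|) quartile:\n")
    print(x$quartiles, row.names = FALSE)
  }
  invisible(x)
}
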