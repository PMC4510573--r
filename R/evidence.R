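# Multi-source function evidence: filtering, description normalization,
# intrinsic-overlap de-duplication, consensus confidence voting (1/5 - 5/5),
# category reclassification and census bookkeeping.

EVIDENCE_SOURCES <- c("PSI_BLAST", "BLASTO", "PFAM", "INTERPROSCAN", "ANNIE")
INTEGRATED_SOURCES <- c("INTERPROSCAN", "ANNIE")

# generic words that carry no functional information on their own
DESCRIPTION_STOPWORDS <- c("protein", "domain", "containing", "family",
                           "putative", "probable", "like", "hypothetical")

#' Construct an evidence table
#'
#' One row per tool hit for a CDS. `member_database` is only meaningful for
#' integrated sources (INTERPROSCAN, ANNIE) and names the underlying
#' signature database of the hit.
#'
#' @param cds_id locus tags.
#' @param source one of PSI_BLAST, BLASTO, PFAM, INTERPROSCAN, ANNIE.
#' @param member_database underlying database for integrated sources (else "").
#' @param description free-text functional description.
#' @param e_value non-negative e-value (NA allowed).
#' @param identity_pct percent identity in `[0, 100]` (alignment sources).
#' @param score optional raw score.
#' @return data.frame with class `evidence_table`.
#' @export
evidence_table <- function(cds_id, source = character(),
                           member_database = "",
                           description = "", e_value = NA_real_,
                           identity_pct = NA_real_, score = NA_real_) {
  n <- length(cds_id)
  df <- data.frame(
    cds_id = as.character(cds_id),
    source = rep_len(toupper(as.character(source)), n),
    member_database = rep_len(toupper(as.character(member_database)), n),
    description = rep_len(as.character(description), n),
    e_value = rep_len(as.numeric(e_value), n),
    identity_pct = rep_len(as.numeric(identity_pct), n),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  if (!all(df$source %in% EVIDENCE_SOURCES))
    stop("unknown evidence source: ",
         paste(setdiff(df$source, EVIDENCE_SOURCES), collapse = ", "))
  if (any(nzchar(df$member_database) &
          !(df$source %in% INTEGRATED_SOURCES)))
    stop("member_database only allowed for integrated sources")
  if (any(!is.na(df$e_value) & df$e_value < 0))
    stop("negative e-value")
  class(df) <- c("evidence_table", "data.frame")
  df
}

#' Filter PSI-BLAST hits to best hits
#'
#' Retains hits with identity strictly above 40% and e-value strictly below
#' 1e-52 (both thresholds configurable). Records lacking identity or e-value
#' are skipped with a warning.
#'
#' @param hits evidence rows with source PSI_BLAST.
#' @param min_identity strict lower bound on percent identity (default 40).
#' @param max_evalue strict upper bound on e-value (default 1e-52).
#' @return the retained rows.
#' @export
filter_psiblast <- function(hits, min_identity = 40, max_evalue = 1e-52) {
  if (nrow(hits) == 0L) return(hits)
  if (!all(hits$source == "PSI_BLAST"))
    stop("filter_psiblast expects PSI_BLAST rows only")
  incomplete <- is.na(hits$identity_pct) | is.na(hits$e_value)
  if (any(incomplete)) {
    warning(sum(incomplete),
            " PSI-BLAST record(s) missing identity or e-value; skipped")
    hits <- hits[!incomplete, , drop = FALSE]
  }
  keep <- hits$identity_pct > min_identity & hits$e_value < max_evalue
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter Pfam hits by e-value
#'
#' Retains hits with e-value at or below the cut-off (default 1e-02,
#' inclusive).
#'
#' @param hits evidence rows with source PFAM.
#' @param max_evalue inclusive e-value cut-off (default 1e-02).
#' @return the retained rows.
#' @export
filter_pfam <- function(hits, max_evalue = 1e-2) {
  if (nrow(hits) == 0L) return(hits)
  if (!all(hits$source == "PFAM"))
    stop("filter_pfam expects PFAM rows only")
  incomplete <- is.na(hits$e_value)
  if (any(incomplete)) {
    warning(sum(incomplete), " Pfam record(s) missing e-value; skipped")
    hits <- hits[!incomplete, , drop = FALSE]
  }
  out <- hits[hits$e_value <= max_evalue, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply per-source filters to a mixed evidence table
#'
#' PSI_BLAST rows pass through [filter_psiblast()], PFAM rows through
#' [filter_pfam()]; other sources are kept as-is (their native filtering is
#' upstream).
#'
#' @param ev evidence table.
#' @param psiblast_identity,psiblast_evalue PSI-BLAST thresholds.
#' @param pfam_evalue Pfam cut-off.
#' @return the filtered evidence table.
#' @export
filter_evidence <- function(ev, psiblast_identity = 40,
                            psiblast_evalue = 1e-52, pfam_evalue = 1e-2) {
  psi <- ev[ev$source == "PSI_BLAST", , drop = FALSE]
  pfm <- ev[ev$source == "PFAM", , drop = FALSE]
  rest <- ev[!(ev$source %in% c("PSI_BLAST", "PFAM")), , drop = FALSE]
  out <- rbind(filter_psiblast(psi, psiblast_identity, psiblast_evalue),
               filter_pfam(pfm, pfam_evalue),
               rest)
  out <- out[order(match(out$cds_id, unique(ev$cds_id)),
                   match(out$source, EVIDENCE_SOURCES)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize a functional description to a canonical token set
#'
#' Lower-cases, strips punctuation, removes generic stop-words (protein,
#' domain, containing, family, putative, probable, like, hypothetical) and
#' sorts the remaining tokens, so that descriptions differing only in word
#' order or generic filler compare equal.
#'
#' @param text character vector of descriptions.
#' @return a list of sorted token vectors (one per input element).
#' @export
normalize_description <- function(text) {
  lapply(as.character(text), function(x) {
    x <- tolower(x)
    x <- gsub("[^a-z0-9]+", " ", x)
    toks <- strsplit(trimws(x), " +")[[1L]]
    toks <- toks[nzchar(toks)]
    toks <- setdiff(toks, DESCRIPTION_STOPWORDS)
    sort(unique(toks))
  })
}

token_jaccard <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

descriptions_equivalent <- function(a, b, threshold = 0.6) {
  token_jaccard(normalize_description(a)[[1L]],
                normalize_description(b)[[1L]]) >= threshold
}

#' Collapse evidence for one CDS into effective per-source votes
#'
#' Integrated-source records (INTERPROSCAN, ANNIE) whose `member_database`
#' names a source that is already voting with an equivalent description are
#' dropped (intrinsic-overlap avoidance); at most one vote per source is
#' kept (the lowest e-value, then first occurrence).
#'
#' @param ev evidence rows sharing one `cds_id`.
#' @param agree_threshold Jaccard threshold for description equivalence.
#' @return data.frame of effective votes: `source`, `description`.
#' @export
dedupe_sources <- function(ev, agree_threshold = 0.6) {
  if (nrow(ev) == 0L)
    return(data.frame(source = character(), description = character(),
                      stringsAsFactors = FALSE))
  if (length(unique(ev$cds_id)) > 1L)
    stop("dedupe_sources expects records for a single CDS")

  drop <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (!(ev$source[i] %in% INTEGRATED_SOURCES)) next
    mdb <- ev$member_database[i]
    if (!nzchar(mdb)) next
    prior <- which(ev$source == mdb)
    if (length(prior) == 0L) next
    dup <- any(vapply(prior, function(j)
      descriptions_equivalent(ev$description[i], ev$description[j],
                              agree_threshold), TRUE))
    if (dup) drop[i] <- TRUE
  }
  ev <- ev[!drop, , drop = FALSE]

  # one vote per source: best (lowest) e-value wins, NA last, then input order
  ord <- order(match(ev$source, EVIDENCE_SOURCES),
               ifelse(is.na(ev$e_value), Inf, ev$e_value),
               seq_len(nrow(ev)))
  ev <- ev[ord, , drop = FALSE]
  ev <- ev[!duplicated(ev$source), , drop = FALSE]
  data.frame(source = ev$source, description = ev$description,
             stringsAsFactors = FALSE)
}

largest_agreeing_cluster <- function(tokens, threshold) {
  # largest subset of votes that pairwise agree (Jaccard >= threshold);
  # enumerates subsets (vote counts are <= 5 sources)
  n <- length(tokens)
  if (n == 0L) return(integer())
  agree <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    token_jaccard(tokens[[i]], tokens[[j]]) >= threshold))
  best <- integer()
  for (size in n:1) {
    if (size <= length(best)) break
    combs <- utils::combn(n, size, simplify = FALSE)
    for (s in combs) {
      if (all(agree[s, s])) { best <- s; break }
    }
    if (length(best)) break
  }
  best
}

#' Consensus function call with 1/5 - 5/5 confidence
#'
#' Clusters the effective votes by normalized-description similarity; the
#' confidence level is the size of the largest mutually agreeing cluster and
#' the consensus description is the most frequent raw description within it
#' (ties broken lexicographically). The call class is DEFINED when the
#' consensus is informative and corroborated by an alignment source
#' (PSI_BLAST or BLASTO), PUTATIVE when the evidence is motif/domain-only or
#' the description carries a "putative"/"probable" marker, and NONE when no
#' informative evidence survives.
#'
#' @param ev filtered evidence rows for one CDS (may be empty).
#' @param agree_threshold Jaccard agreement threshold (default 0.6).
#' @param cds_id locus tag for the returned call (taken from `ev` when
#'   present).
#' @return one-row data.frame: `cds_id`, `consensus_description`,
#'   `confidence`, `call_class`, `supporting_sources`.
#' @export
assign_confidence <- function(ev, agree_threshold = 0.6,
                              cds_id = NULL) {
  if (is.null(cds_id))
    cds_id <- if (nrow(ev)) ev$cds_id[1L] else NA_character_
  none <- data.frame(cds_id = cds_id, consensus_description = "",
                     confidence = 0L, call_class = "NONE",
                     supporting_sources = "", stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) return(none)

  votes <- dedupe_sources(ev, agree_threshold)
  tokens <- normalize_description(votes$description)
  informative <- lengths(tokens) > 0L
  votes <- votes[informative, , drop = FALSE]
  tokens <- tokens[informative]
  if (nrow(votes) == 0L) return(none)

  idx <- largest_agreeing_cluster(tokens, agree_threshold)
  cluster <- votes[idx, , drop = FALSE]
  tab <- table(cluster$description)
  desc <- sort(names(tab)[tab == max(tab)])[1L]

  marked_putative <- any(grepl("\\b(putative|probable)\\b",
                               tolower(cluster$description)))
  motif_only <- all(cluster$source %in% c("PFAM", "INTERPROSCAN"))
  call_class <- if (motif_only || marked_putative) "PUTATIVE" else "DEFINED"

  data.frame(
    cds_id = cds_id,
    consensus_description = desc,
    confidence = length(idx),
    call_class = call_class,
    supporting_sources = paste(sort(cluster$source), collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Consensus calls for a whole evidence table
#'
#' @param ev filtered evidence table (many CDSs).
#' @param cds_ids optional full set of locus tags; tags with no evidence get
#'   a NONE call.
#' @param agree_threshold Jaccard agreement threshold.
#' @return data.frame of function calls, one row per CDS.
#' @export
consensus_calls <- function(ev, cds_ids = NULL, agree_threshold = 0.6) {
  if (is.null(cds_ids)) cds_ids <- unique(ev$cds_id)
  rows <- lapply(cds_ids, function(id)
    assign_confidence(ev[ev$cds_id == id, , drop = FALSE],
                      agree_threshold, cds_id = id))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reclassify a gene record from its consensus call
#'
#' HYPOTHETICAL/NEW/PUTATIVE records with a DEFINED call at confidence at
#' least `min_conf_known` are promoted to KNOWN; a DEFINED call below that
#' confidence, or a PUTATIVE call, makes the record PUTATIVE with "putative "
#' prefixed to the product; a NONE call leaves the category unchanged.
#' KNOWN records are never demoted and PSEUDOGENE records never change.
#'
#' @param record one-row [gene_table()].
#' @param call one-row function call (see [assign_confidence()]).
#' @param min_conf_known promotion threshold (default 2: at least two
#'   independent methods).
#' @return the updated one-row gene table.
#' @export
reclassify <- function(record, call, min_conf_known = 2L) {
  stopifnot(nrow(record) == 1L, nrow(call) == 1L)
  if (min_conf_known < 1L || min_conf_known > 5L)
    stop("min_conf_known must be in 1..5")
  cat0 <- record$category
  if (cat0 == "PSEUDOGENE" || call$call_class == "NONE") return(record)
  if (cat0 == "KNOWN") {
    # never demoted; a defined consensus still refreshes the product
    if (call$call_class == "DEFINED") {
      record$product <- call$consensus_description
      record$confidence <- as.integer(call$confidence)
    }
    return(record)
  }
  if (call$call_class == "DEFINED" && call$confidence >= min_conf_known) {
    record$category <- "KNOWN"
    record$product <- call$consensus_description
    record$confidence <- as.integer(call$confidence)
  } else {
    record$category <- "PUTATIVE"
    desc <- if (nzchar(call$consensus_description))
      call$consensus_description else record$product
    record$product <- if (grepl("^putative ", desc)) desc
                      else paste0("putative ", desc)
    record$confidence <- as.integer(call$confidence)
  }
  record
}

#' Reclassify every gene in a table
#'
#' @param genes a [gene_table()].
#' @param calls function-call table covering the genes (by `cds_id`).
#' @param min_conf_known promotion threshold.
#' @return the updated gene table.
#' @export
reclassify_all <- function(genes, calls, min_conf_known = 2L) {
  for (i in seq_len(nrow(genes))) {
    j <- match(genes$locus_tag[i], calls$cds_id)
    if (is.na(j)) next
    genes[i, ] <- reclassify(genes[i, , drop = FALSE],
                             calls[j, , drop = FALSE], min_conf_known)
  }
  genes
}

#' Apply category moves to a census
#'
#' Bookkeeping for before/after re-annotation comparisons: each move shifts
#' `count` genes from one category to another; the total is conserved and a
#' move may never overdraw its source category.
#'
#' @param before a `category_census`.
#' @param moves data.frame with columns `from`, `to`, `count` (applied in
#'   row order).
#' @return the updated `category_census`.
#' @export
update_census <- function(before, moves) {
  counts <- before$counts
  if (nrow(moves)) {
    for (i in seq_len(nrow(moves))) {
      from <- moves$from[i]; to <- moves$to[i]; k <- as.integer(moves$count[i])
      if (!(from %in% names(counts)) || !(to %in% names(counts)))
        stop("unknown category in move: ", from, " -> ", to)
      if (k < 0L) stop("negative move count")
      if (counts[[from]] < k)
        stop(sprintf("move overdraws %s: have %d, moving %d",
                     from, counts[[from]], k))
      counts[[from]] <- counts[[from]] - k
      counts[[to]] <- counts[[to]] + k
    }
  }
  category_census(counts)
}
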