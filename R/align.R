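# Pairwise local alignment and alignment-coverage (minLrap/maxLrap) metrics.
#
# Smith-Waterman optimal local alignment is delegated to
# Biostrings::pairwiseAlignment; this module wraps it into the
# AlignmentResult contract the orthology layer consumes (Lmatch counted over
# all alignment columns, gap columns included, configurable).

default_scoring <- function() {
  list(matrix = "BLOSUM62", gap_opening = 0, gap_extension = 8)
}

get_submat <- function(scoring) {
  if (is.matrix(scoring$matrix)) return(scoring$matrix)
  e <- new.env()
  utils::data(list = scoring$matrix, package = "Biostrings", envir = e)
  get(scoring$matrix, envir = e)
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman local alignment under a substitution matrix and linear gap
#' penalty (default BLOSUM62, gap -8 per gapped position). `Lmatch` counts
#' alignment columns (gap columns included by default; set
#' `count_gap_columns = FALSE` for match-columns-only). A best score of 0 or
#' less means no local alignment (`Lmatch = 0`).
#'
#' @param a,b protein sequences (character scalars).
#' @param scoring list with `matrix` (name of a Biostrings matrix or an
#'   actual matrix), `gap_opening`, `gap_extension`.
#' @param count_gap_columns include gap columns in `Lmatch` (default TRUE).
#' @param query_id,subject_id identifiers carried into the result.
#' @return one-row data.frame: `query_id`, `subject_id`, `raw_score`,
#'   `Lmatch`, `identity_pct`, `query_len`, `subject_len`.
#' @export
local_align <- function(a, b, scoring = default_scoring(),
                        count_gap_columns = TRUE,
                        query_id = "query", subject_id = "subject") {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = get_submat(scoring),
    gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension)
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    lmatch <- 0L; ident <- 0
  } else {
    lmatch <- if (count_gap_columns) Biostrings::nchar(aln)
              else Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
    ident <- if (lmatch > 0)
      100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln) else 0
  }
  data.frame(query_id = query_id, subject_id = subject_id,
             raw_score = sc, Lmatch = as.integer(lmatch),
             identity_pct = ident,
             query_len = nchar(a), subject_len = nchar(b),
             stringsAsFactors = FALSE)
}

#' minLrap/maxLrap coverage metrics for an alignment
#'
#' `minLrap = Lmatch / min(Lprot1, Lprot2)` and
#' `maxLrap = Lmatch / max(Lprot1, Lprot2)`. The alignment class follows the
#' three interpretive cases: FULL when both ratios equal 1 (the two proteins
#' align over their whole length), PARTIAL when minLrap = 1 but maxLrap < 1
#' (one protein longer, or partial alignment), POOR when both are below 1.
#'
#' @param aln one-row alignment result from [local_align()], or a list with
#'   `Lmatch`, `query_len`, `subject_len`.
#' @return list with `minLrap`, `maxLrap`, `align_class`.
#' @export
lrap <- function(aln) {
  l1 <- aln$query_len; l2 <- aln$subject_len; lm <- aln$Lmatch
  if (l1 <= 0 || l2 <= 0) stop("zero-length protein")
  min_lrap <- lm / min(l1, l2)
  max_lrap <- lm / max(l1, l2)
  cls <- if (min_lrap >= 1 && max_lrap >= 1) "FULL"
         else if (min_lrap >= 1) "PARTIAL"
         else "POOR"
  list(minLrap = min_lrap, maxLrap = max_lrap, align_class = cls)
}

score_against_set <- function(query_seq, targets, scoring) {
  # vector of local-alignment scores of one query against a protein set
  subj <- Biostrings::AAStringSet(targets)
  aln <- Biostrings::pairwiseAlignment(
    subj, Biostrings::AAString(query_seq), type = "local",
    substitutionMatrix = get_submat(scoring),
    gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension,
    scoreOnly = TRUE)
  stats::setNames(aln, names(targets))
}

#' Best hit of a query in a target protein set
#'
#' The subject maximizing the local-alignment raw score; ties are broken by
#' higher identity, then lexicographically smaller subject id. Returns `NULL`
#' when the best score is 0 or negative.
#'
#' @param query_seq query protein sequence.
#' @param targets named character vector of target proteins.
#' @param scoring scoring scheme (see [local_align()]).
#' @param query_id identifier for the query.
#' @return one-row alignment result (see [local_align()]) or `NULL`.
#' @export
best_hit <- function(query_seq, targets, scoring = default_scoring(),
                     query_id = "query") {
  if (length(targets) == 0L) stop("target genome is empty")
  scores <- score_against_set(query_seq, targets, scoring)
  top <- max(scores)
  if (top <= 0) return(NULL)
  cand <- names(scores)[scores == top]
  if (length(cand) > 1L) {
    alns <- lapply(cand, function(id)
      local_align(query_seq, targets[[id]], scoring,
                  query_id = query_id, subject_id = id))
    idents <- vapply(alns, function(x) x$identity_pct, 0)
    cand <- cand[idents == max(idents)]
    cand <- sort(cand)[1L]
    return(alns[[match(cand, vapply(alns, function(x) x$subject_id, ""))]])
  }
  local_align(query_seq, targets[[cand]], scoring,
              query_id = query_id, subject_id = cand)
}

#' Bidirectional best hits between two genomes
#'
#' A pair (x, y) is reported iff y is x's best hit in genome B and x is y's
#' best hit in genome A — the standard orthology proxy. Each gene appears in
#' at most one pair.
#'
#' @param genome_a,genome_b named character vectors of proteins.
#' @param scoring scoring scheme.
#' @return data.frame (`ortholog_table`): `query_id`, `subject_id`,
#'   `raw_score`, `identity_pct`, `Lmatch`, `minLrap`, `maxLrap`,
#'   `align_class`.
#' @export
bbh <- function(genome_a, genome_b, scoring = default_scoring()) {
  if (length(genome_a) == 0L || length(genome_b) == 0L)
    stop("empty genome")
  best_ab <- lapply(names(genome_a), function(id)
    best_hit(genome_a[[id]], genome_b, scoring, query_id = id))
  names(best_ab) <- names(genome_a)
  best_ba <- lapply(names(genome_b), function(id)
    best_hit(genome_b[[id]], genome_a, scoring, query_id = id))
  names(best_ba) <- names(genome_b)

  rows <- list()
  for (x in names(genome_a)) {
    hit <- best_ab[[x]]
    if (is.null(hit)) next
    y <- hit$subject_id
    back <- best_ba[[y]]
    if (is.null(back) || back$subject_id != x) next
    lr <- lrap(hit)
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = x, subject_id = y, raw_score = hit$raw_score,
      identity_pct = hit$identity_pct, Lmatch = hit$Lmatch,
      minLrap = lr$minLrap, maxLrap = lr$maxLrap,
      align_class = lr$align_class, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), subject_id = character(),
               raw_score = numeric(), identity_pct = numeric(),
               Lmatch = integer(), minLrap = numeric(), maxLrap = numeric(),
               align_class = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ortholog_table", "data.frame")
  out
}

#' Filter BBH pairs by homology constraints
#'
#' Default constraints: minLrap strictly above 0.8 and identity strictly
#' above 30%.
#'
#' @param orthologs an `ortholog_table` from [bbh()].
#' @param min_minLrap strict minLrap bound (default 0.8).
#' @param min_identity strict percent-identity bound (default 30).
#' @return the retained pairs.
#' @export
homolog_pairs <- function(orthologs, min_minLrap = 0.8, min_identity = 30) {
  keep <- orthologs$minLrap > min_minLrap &
          orthologs$identity_pct > min_identity
  out <- orthologs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
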