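# Comparative layer on top of BBH orthology: core genome and
# genome-specific genes, minimal-gene-set (essential gene) screening, and
# COG assignment by genome-specific best hits (BeTs).

#' Core genome and genome-specific genes of a pivot genome
#'
#' A pivot gene is in the core iff it has a constraint-passing homolog
#' (BBH with minLrap and identity above the bounds) in EVERY other genome;
#' it is genome-specific iff it has none in ANY other genome. The two sets
#' are disjoint by construction.
#'
#' @param pivot named character vector of pivot-genome proteins.
#' @param others list of named character vectors (the comparison genomes).
#' @param scoring scoring scheme (see [local_align()]).
#' @param min_minLrap,min_identity homology constraints (defaults 0.8, 30).
#' @param precomputed optional list of `ortholog_table`s, one per other
#'   genome, to skip the alignment stage.
#' @return list with `core` and `specific` character vectors of pivot ids.
#' @export
core_genome <- function(pivot, others, scoring = default_scoring(),
                        min_minLrap = 0.8, min_identity = 30,
                        precomputed = NULL) {
  if (length(others) < 1L) stop("need at least one comparison genome")
  hit_matrix <- vapply(seq_along(others), function(i) {
    tab <- if (!is.null(precomputed)) precomputed[[i]]
           else bbh(pivot, others[[i]], scoring)
    tab <- homolog_pairs(tab, min_minLrap, min_identity)
    names(pivot) %in% tab$query_id
  }, logical(length(pivot)))
  hit_matrix <- matrix(hit_matrix, nrow = length(pivot))
  list(core = names(pivot)[rowSums(hit_matrix) == length(others)],
       specific = names(pivot)[rowSums(hit_matrix) == 0L])
}

#' Screen a genome against a reference essential-gene set
#'
#' A reference essential gene is "found" iff some genome gene shares a BBH
#' relationship with it at minLrap strictly above `min_minLrap` (default
#' 0.5), OR some genome gene belongs to the same synteny group. With an
#' empty synteny map this reduces to the pure BBH + minLrap criterion.
#'
#' @param genome named character vector of genome proteins.
#' @param reference named character vector of reference essential proteins.
#' @param synteny_groups optional named character vector mapping gene ids
#'   (genome and reference alike) to synteny-group labels.
#' @param scoring scoring scheme.
#' @param min_minLrap strict minLrap bound (default 0.5).
#' @return list with `found` and `missing` character vectors of reference
#'   ids, and the supporting `ortholog_table`.
#' @export
essential_genes <- function(genome, reference,
                            synteny_groups = character(),
                            scoring = default_scoring(),
                            min_minLrap = 0.5) {
  if (length(reference) == 0L) stop("empty essential reference")
  if (anyDuplicated(names(reference)))
    stop("reference identifiers must be unique")
  tab <- bbh(genome, reference, scoring)
  by_bbh <- unique(tab$subject_id[tab$minLrap > min_minLrap])

  by_synteny <- character()
  if (length(synteny_groups)) {
    ref_grp <- synteny_groups[names(reference)]
    gen_grp <- synteny_groups[names(genome)]
    shared <- intersect(ref_grp[!is.na(ref_grp)], gen_grp[!is.na(gen_grp)])
    by_synteny <- names(reference)[!is.na(ref_grp) & ref_grp %in% shared]
  }
  found <- sort(union(by_bbh, by_synteny))
  list(found = found,
       missing = sort(setdiff(names(reference), found)),
       orthologs = tab)
}

#' COG assignment by genome-specific best hits (BeTs)
#'
#' For each COG-labeled reference genome the query's best hit (its BeT) is
#' computed; the protein is assigned to a COG iff at least `bet_cutoff` BeTs
#' (default 3) carry that COG label.
#'
#' @param protein query protein sequence.
#' @param cog_reference list of reference genomes, each a list with
#'   `proteins` (named character vector) and `cogs` (named character vector
#'   mapping protein id to COG id).
#' @param scoring scoring scheme.
#' @param bet_cutoff minimum number of agreeing BeTs (default 3).
#' @return character vector of assigned COG ids (possibly empty).
#' @export
cognitor_assign <- function(protein, cog_reference,
                            scoring = default_scoring(), bet_cutoff = 3L) {
  if (length(cog_reference) < bet_cutoff)
    stop("need at least bet_cutoff reference genomes")
  bet_cogs <- character()
  for (ref in cog_reference) {
    hit <- best_hit(protein, ref$proteins, scoring)
    if (is.null(hit)) next
    cog <- ref$cogs[[hit$subject_id]]
    if (!is.null(cog) && !is.na(cog) && nzchar(cog))
      bet_cogs <- c(bet_cogs, cog)
  }
  if (length(bet_cogs) == 0L) return(character())
  tab <- table(bet_cogs)
  sort(names(tab)[tab >= bet_cutoff])
}

#' Per-category COG census with old/new CDS split
#'
#' Tallies genes per COG functional-category letter, split into old and new
#' CDSs (the X/Y convention), plus the counts of genes with at least one COG
#' and with none.
#'
#' @param assignments list: per gene, a character vector of COG ids (names
#'   are gene ids).
#' @param cog_categories named character vector mapping COG id to its
#'   category letter(s) (multi-letter memberships allowed, e.g. `"KT"`).
#' @param is_new logical vector (named like `assignments`): TRUE for new
#'   CDSs.
#' @return list with `table` (data.frame: category, old, new, combined),
#'   `n_classified`, `n_unclassified`.
#' @export
cog_census <- function(assignments, cog_categories, is_new = NULL) {
  genes <- names(assignments)
  if (is.null(is_new)) is_new <- stats::setNames(rep(FALSE, length(genes)), genes)
  all_cogs <- unique(unlist(assignments, use.names = FALSE))
  unmapped <- setdiff(all_cogs, names(cog_categories))
  if (length(unmapped))
    stop("COG id(s) with no category letter: ",
         paste(unmapped, collapse = ", "))

  old_counts <- new_counts <- integer()
  for (g in genes) {
    letters_g <- unique(unlist(strsplit(cog_categories[assignments[[g]]], "")))
    for (L in letters_g) {
      if (isTRUE(is_new[[g]])) {
        new_counts[L] <- (if (L %in% names(new_counts)) new_counts[[L]] else 0L) + 1L
      } else {
        old_counts[L] <- (if (L %in% names(old_counts)) old_counts[[L]] else 0L) + 1L
      }
    }
  }
  cats <- sort(union(names(old_counts), names(new_counts)))
  tab <- data.frame(
    category = cats,
    old = vapply(cats, function(L)
      if (L %in% names(old_counts)) old_counts[[L]] else 0L, 0L),
    new = vapply(cats, function(L)
      if (L %in% names(new_counts)) new_counts[[L]] else 0L, 0L),
    stringsAsFactors = FALSE
  )
  tab$combined <- tab$old + tab$new
  rownames(tab) <- NULL
  n_classified <- sum(lengths(assignments) > 0L)
  list(table = tab, n_classified = n_classified,
       n_unclassified = length(assignments) - n_classified)
}
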