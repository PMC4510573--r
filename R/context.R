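# Genomic-context layer: synteny-group detection from ortholog pairs and
# gene order, neighborhood-conservation and co-occurrence scoring, combined
# confidence with the 0.4 medium-confidence threshold, and label transfer to
# uncharacterized genes.

#' Detect synteny groups between two ordered genomes
#'
#' Chains BBH pairs into maximal runs with monotone (or uniformly reversed,
#' for inverted blocks) gene-index progression on genome B, where
#' consecutive pairs are separated by at most `max_gap` intervening genes on
#' both genomes. Singleton chains are kept but flagged.
#'
#' @param orthologs `ortholog_table` (columns `query_id`, `subject_id`).
#' @param order_a,order_b named integer vectors: gene index (1-based rank in
#'   genome order) per locus tag.
#' @param max_gap maximum intervening genes between consecutive pairs
#'   (default 5).
#' @return data.frame: `group_id`, `query_id`, `subject_id`, `idx_a`,
#'   `idx_b`, `n_pairs`, `singleton`, `orientation` (+1 collinear, -1
#'   inverted, 0 undetermined singleton).
#' @export
build_synteny_groups <- function(orthologs, order_a, order_b, max_gap = 5L) {
  if (nrow(orthologs) == 0L)
    return(data.frame(group_id = integer(), query_id = character(),
                      subject_id = character(), idx_a = integer(),
                      idx_b = integer(), n_pairs = integer(),
                      singleton = logical(), orientation = integer(),
                      stringsAsFactors = FALSE))
  miss_a <- setdiff(orthologs$query_id, names(order_a))
  miss_b <- setdiff(orthologs$subject_id, names(order_b))
  if (length(miss_a) || length(miss_b))
    stop("gene missing from order map: ",
         paste(c(miss_a, miss_b), collapse = ", "))

  df <- data.frame(query_id = orthologs$query_id,
                   subject_id = orthologs$subject_id,
                   idx_a = as.integer(order_a[orthologs$query_id]),
                   idx_b = as.integer(order_b[orthologs$subject_id]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$idx_a), , drop = FALSE]

  group_id <- integer(nrow(df))
  orientation <- integer(nrow(df))
  gid <- 0L
  i <- 1L
  while (i <= nrow(df)) {
    gid <- gid + 1L
    group_id[i] <- gid
    dir <- 0L                       # chain direction on B, fixed by 2nd pair
    j <- i
    while (j < nrow(df)) {
      gap_a <- df$idx_a[j + 1L] - df$idx_a[j] - 1L
      step_b <- df$idx_b[j + 1L] - df$idx_b[j]
      gap_b <- abs(step_b) - 1L
      ok <- gap_a <= max_gap && gap_b <= max_gap && step_b != 0L &&
        (dir == 0L || sign(step_b) == dir)
      if (!ok) break
      if (dir == 0L) dir <- sign(step_b)
      j <- j + 1L
      group_id[j] <- gid
    }
    orientation[group_id == gid] <- dir
    i <- j + 1L
  }
  sizes <- table(group_id)
  df$group_id <- group_id
  df$n_pairs <- as.integer(sizes[as.character(group_id)])
  df$singleton <- df$n_pairs == 1L
  df$orientation <- orientation
  rownames(df) <- NULL
  df[, c("group_id", "query_id", "subject_id", "idx_a", "idx_b",
         "n_pairs", "singleton", "orientation")]
}

#' Neighborhood-conservation score for two gene families
#'
#' Fraction of genomes containing members of both families in which some
#' member pair lies within `max_dist` gene indices on the same strand.
#' Genomes lacking either family do not enter the denominator; if no genome
#' contains both, the score is 0 (no evidence is not evidence of absence).
#'
#' @param family_a,family_b family identifiers.
#' @param genomes list of per-genome data.frames with columns `family`,
#'   `index`, `strand`.
#' @param max_dist maximum index separation (default 3).
#' @return fraction in `[0, 1]`.
#' @export
neighborhood_score <- function(family_a, family_b, genomes, max_dist = 3L) {
  n_both <- 0L; n_close <- 0L
  for (g in genomes) {
    ia <- g$index[g$family == family_a]
    ib <- g$index[g$family == family_b]
    sa <- g$strand[g$family == family_a]
    sb <- g$strand[g$family == family_b]
    if (length(ia) == 0L || length(ib) == 0L) next
    n_both <- n_both + 1L
    close <- FALSE
    for (k in seq_along(ia)) {
      hit <- abs(ib - ia[k]) <= max_dist & sb == sa[k]
      if (any(hit)) { close <- TRUE; break }
    }
    if (close) n_close <- n_close + 1L
  }
  if (n_both == 0L) return(0)
  n_close / n_both
}

#' Co-occurrence score of two phylogenetic profiles
#'
#' Jaccard similarity of the presence sets; 0 when both profiles are empty.
#'
#' @param pa,pb logical vectors of equal length (presence per genome).
#' @return fraction in `[0, 1]`.
#' @export
cooccurrence_score <- function(pa, pb) {
  if (length(pa) != length(pb)) stop("profile length mismatch")
  pa <- as.logical(pa); pb <- as.logical(pb)
  u <- sum(pa | pb)
  if (u == 0L) return(0)
  sum(pa & pb) / u
}

#' Combine context-evidence scores
#'
#' STRING-style combination `1 - prod(1 - s_i)`; monotone (never below the
#' largest component) and equal to the single component when only one source
#' is present. Passing requires the combined score to exceed the threshold
#' strictly (default 0.4, "medium confidence").
#'
#' @param components numeric vector of scores in `[0, 1]`.
#' @param threshold strict pass threshold (default 0.4).
#' @return list with `combined` and `passes`.
#' @export
combine_scores <- function(components, threshold = 0.4) {
  if (any(components < 0 | components > 1))
    stop("component score outside [0, 1]")
  combined <- 1 - prod(1 - components)
  list(combined = combined, passes = combined > threshold)
}

#' Score all gene pairs of a family set
#'
#' Convenience wrapper producing the association TSV schema: neighborhood,
#' co-occurrence, combined score and pass flag per family pair.
#'
#' @param families character vector of family ids.
#' @param genomes per-genome data.frames (see [neighborhood_score()]).
#' @param threshold combined-score pass threshold.
#' @param max_dist neighborhood distance bound.
#' @return data.frame: `gene_a`, `gene_b`, `neighborhood`, `cooccurrence`,
#'   `combined`, `passes`.
#' @export
association_scores <- function(families, genomes, threshold = 0.4,
                               max_dist = 3L) {
  present <- vapply(genomes, function(g) families %in% g$family,
                    logical(length(families)))
  present <- matrix(present, nrow = length(families),
                    dimnames = list(families, NULL))
  pairs <- utils::combn(families, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    nb <- neighborhood_score(p[1L], p[2L], genomes, max_dist)
    co <- cooccurrence_score(present[p[1L], ], present[p[2L], ])
    cmb <- combine_scores(c(nb, co), threshold)
    data.frame(gene_a = p[1L], gene_b = p[2L], neighborhood = nb,
               cooccurrence = co, combined = cmb$combined,
               passes = cmb$passes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transfer process labels to uncharacterized genes
#'
#' Each unknown gene receives the majority process label among its labeled
#' partners on passing association edges; ties and genes with no passing
#' labeled edge yield no call (`NA`).
#'
#' @param unknown_genes character vector of gene/family ids to label.
#' @param associations data.frame from [association_scores()] (needs
#'   `gene_a`, `gene_b`, `passes`).
#' @param labels named character vector: process label per characterized
#'   gene.
#' @return named character vector of predicted labels (`NA` = no call).
#' @export
associate_unknowns <- function(unknown_genes, associations, labels) {
  out <- stats::setNames(rep(NA_character_, length(unknown_genes)),
                         unknown_genes)
  passing <- associations[associations$passes, , drop = FALSE]
  for (g in unknown_genes) {
    partners <- c(passing$gene_b[passing$gene_a == g],
                  passing$gene_a[passing$gene_b == g])
    partner_labels <- labels[partners]
    partner_labels <- partner_labels[!is.na(partner_labels)]
    if (length(partner_labels) == 0L) next
    tab <- table(partner_labels)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) out[[g]] <- winners
  }
  out
}
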