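# Synthetic genome families with known ground truth: an ancestral proteome
# evolved along a star topology with per-branch residue substitutions, gene
# losses, duplications and block inversions; per-source function evidence
# with planted correctness rates; essential-gene references; rating cases
# for ROC evaluation. Every generator is deterministic under the config
# seed, with independent sub-streams per generator.

#' Simulation configuration
#'
#' Defaults describe a desk-scale genome family: four genomes of ~50 genes
#' with ~80-residue proteins, 2% substitutions per site per branch, 10% gene
#' loss per lineage, occasional block inversions; five evidence sources that
#' report the true function 80% of the time, a decoy 10% and nothing 10%;
#' 20% of families essential; well-separated rating distributions on the
#' 2--5 scale.
#'
#' @param seed integer seed; all sub-generators derive their streams from it.
#' @param n_genomes number of genomes in the family.
#' @param genes_per_genome ancestral gene-family count.
#' @param mean_protein_len mean ancestral protein length (residues).
#' @param substitution_rate per-site substitution probability per branch.
#' @param duplication_prob per-family per-genome duplication probability.
#' @param loss_prob per-family per-genome loss probability.
#' @param inversion_prob per-genome probability of one inverted block.
#' @param sources named list: per source, `p_correct`, `p_wrong`,
#'   `p_nocall` (must sum to 1).
#' @param essential_fraction fraction of families marked essential.
#' @param rating_scale ordinal ratings used (default 2:5).
#' @param rating_pos,rating_neg rating probabilities per truth class over
#'   `rating_scale`.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_genomes = 4L,
                              genes_per_genome = 50L,
                              mean_protein_len = 80L,
                              substitution_rate = 0.02,
                              duplication_prob = 0,
                              loss_prob = 0.1,
                              inversion_prob = 0.5,
                              sources = NULL,
                              essential_fraction = 0.2,
                              rating_scale = 2:5,
                              rating_pos = c(0.05, 0.10, 0.25, 0.60),
                              rating_neg = c(0.60, 0.25, 0.10, 0.05)) {
  if (is.null(sources)) {
    sources <- stats::setNames(
      rep(list(list(p_correct = 0.8, p_wrong = 0.1, p_nocall = 0.1)),
          length(EVIDENCE_SOURCES)), EVIDENCE_SOURCES)
  }
  for (nm in names(sources)) {
    s <- sources[[nm]]
    p <- c(s$p_correct, s$p_wrong, s$p_nocall)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("source ", nm, ": p_correct + p_wrong + p_nocall must equal 1")
  }
  probs <- c(substitution_rate, duplication_prob, loss_prob, inversion_prob,
             essential_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (loss_prob >= 1)
    stop("loss_prob 1 leaves no survivors: impossible configuration")
  if (abs(sum(rating_pos) - 1) > 1e-9 || abs(sum(rating_neg) - 1) > 1e-9)
    stop("rating distributions must sum to 1")
  structure(list(
    seed = as.integer(seed), n_genomes = as.integer(n_genomes),
    genes_per_genome = as.integer(genes_per_genome),
    mean_protein_len = as.integer(mean_protein_len),
    substitution_rate = substitution_rate,
    duplication_prob = duplication_prob, loss_prob = loss_prob,
    inversion_prob = inversion_prob, sources = sources,
    essential_fraction = essential_fraction,
    rating_scale = as.integer(rating_scale),
    rating_pos = rating_pos, rating_neg = rating_neg
  ), class = "simulation_config")
}

sub_seed <- function(config, k) {
  # independent deterministic streams per sub-generator, kept below 2^31
  (as.numeric(config$seed) * 48271 + k * 16807) %% 2147483629
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch)
      sample(setdiff(AA_ALPHABET, ch), 1L), "")
  }
  paste(chars, collapse = "")
}

true_function_label <- function(i) sprintf("synthase subunit f%04d", i)
decoy_function_label <- function(i) sprintf("decoy transporter d%04d", i)

#' Simulate a genome family with ground truth
#'
#' An ancestral proteome evolves along a star topology: each genome is an
#' independent branch with per-site substitutions, per-family losses and
#' duplications, and (with probability `inversion_prob`) one inverted gene
#' block. Deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `genomes` (per genome: named protein vector), `orders`
#'   (per genome: data.frame locus_tag, index, strand, family), and `truth`
#'   (ancestral proteins, family labels, presence matrix, core families,
#'   essential families, inversion blocks, per-gene family map).
#' @export
simulate_genome_family <- function(config) {
  set.seed(sub_seed(config, 1L))
  n_fam <- config$genes_per_genome
  fam_ids <- sprintf("FAM%04d", seq_len(n_fam))
  lens <- pmax(30L, stats::rpois(n_fam, config$mean_protein_len))
  ancestral <- stats::setNames(vapply(lens, random_protein, ""), fam_ids)
  strands <- sample(c("+", "-"), n_fam, replace = TRUE)
  labels <- stats::setNames(vapply(seq_len(n_fam), true_function_label, ""),
                            fam_ids)
  essential <- sort(sample(fam_ids,
                           round(config$essential_fraction * n_fam)))

  genomes <- list(); orders <- list(); blocks <- list()
  presence <- matrix(FALSE, n_fam, config$n_genomes,
                     dimnames = list(fam_ids, NULL))
  gene_family <- character()

  for (g in seq_len(config$n_genomes)) {
    gid <- sprintf("G%d", g)
    lost <- stats::runif(n_fam) < config$loss_prob
    kept <- fam_ids[!lost]
    dup <- kept[stats::runif(length(kept)) < config$duplication_prob]
    fams <- c(kept, dup)
    fams <- fams[order(match(fams, fam_ids))]

    idx <- seq_along(fams)
    strand_g <- strands[match(fams, fam_ids)]
    inv <- NULL
    if (length(fams) >= 4L && stats::runif(1L) < config$inversion_prob) {
      a <- sample(seq_len(length(fams) - 2L), 1L)
      b <- min(length(fams), a + sample(2:6, 1L))
      idx[a:b] <- rev(idx[a:b])
      strand_g[a:b] <- ifelse(strand_g[a:b] == "+", "-", "+")
      inv <- c(a, b)
    }
    ord <- order(idx)
    fams <- fams[ord]; strand_g <- strand_g[ord]

    tags <- sprintf("%s_%04d", gid, seq_along(fams))
    prots <- vapply(fams, function(f)
      mutate_protein(ancestral[[f]], config$substitution_rate), "")
    names(prots) <- tags
    genomes[[gid]] <- prots
    orders[[gid]] <- data.frame(genome_id = gid, locus_tag = tags,
                                index = seq_along(fams), strand = strand_g,
                                family = fams, stringsAsFactors = FALSE)
    blocks[[gid]] <- inv
    presence[unique(fams), g] <- TRUE
    gene_family[tags] <- fams
  }

  list(
    genomes = genomes,
    orders = orders,
    truth = list(
      ancestral = ancestral,
      labels = labels,
      strands = stats::setNames(strands, fam_ids),
      presence = presence,
      core_families = fam_ids[rowSums(presence) == config$n_genomes],
      essential_families = essential,
      inversion_blocks = blocks,
      gene_family = gene_family
    )
  )
}

#' Simulate per-source function evidence with planted error rates
#'
#' For every gene of the chosen genome and every source: with `p_correct`
#' the true family label is emitted (with an e-value below and an identity
#' above the module filter thresholds), with `p_wrong` a decoy label from a
#' disjoint vocabulary, and with `p_nocall` nothing. The expected consensus
#' per gene is book-kept from the planted outcomes.
#'
#' @param config a [simulation_config()].
#' @param family output of [simulate_genome_family()].
#' @param genome_id which genome to generate evidence for (default first).
#' @return list with `evidence` (an [evidence_table()]), `expected`
#'   (data.frame: cds_id, n_correct, expected_confidence), and `outcomes`
#'   (gene x source character matrix: "correct"/"wrong"/"nocall").
#' @export
simulate_evidence <- function(config, family, genome_id = NULL) {
  set.seed(sub_seed(config, 2L))
  if (is.null(genome_id)) genome_id <- names(family$genomes)[1L]
  ord <- family$orders[[genome_id]]
  labels <- family$truth$labels
  src_names <- names(config$sources)

  n <- nrow(ord)
  outcomes <- matrix("nocall", n, length(src_names),
                     dimnames = list(ord$locus_tag, src_names))
  per_source <- list()
  for (s in src_names) {
    p <- config$sources[[s]]
    u <- stats::runif(n)
    out_s <- ifelse(u < p$p_correct, "correct",
                    ifelse(u < p$p_correct + p$p_wrong, "wrong", "nocall"))
    outcomes[, s] <- out_s
    emit <- out_s != "nocall"
    m <- sum(emit)
    if (m == 0L) next
    desc <- character(m)
    is_corr <- out_s[emit] == "correct"
    desc[is_corr] <- labels[ord$family[emit][is_corr]]
    desc[!is_corr] <- vapply(sample.int(10000L, sum(!is_corr),
                                        replace = TRUE),
                             decoy_function_label, "")
    ev <- switch(s,
      PSI_BLAST = list(e = 10^-stats::runif(m, 60, 150),
                       id = stats::runif(m, 55, 95)),
      BLASTO = list(e = 10^-stats::runif(m, 20, 100),
                    id = stats::runif(m, 45, 90)),
      PFAM = list(e = 10^-stats::runif(m, 3, 30), id = rep(NA_real_, m)),
      list(e = 10^-stats::runif(m, 5, 50), id = rep(NA_real_, m)))
    per_source[[s]] <- data.frame(
      cds_id = ord$locus_tag[emit], source = s, member_database = "",
      description = desc, e_value = ev$e, identity_pct = ev$id,
      score = NA_real_, stringsAsFactors = FALSE)
  }
  evidence <- if (length(per_source)) {
    df <- do.call(rbind, per_source)
    df <- df[order(match(df$cds_id, ord$locus_tag),
                   match(df$source, src_names)), , drop = FALSE]
    evidence_table(df$cds_id, df$source, df$member_database, df$description,
                   df$e_value, df$identity_pct, df$score)
  } else evidence_table(character())

  n_correct <- rowSums(outcomes == "correct")
  expected <- data.frame(
    cds_id = ord$locus_tag,
    n_correct = as.integer(n_correct[ord$locus_tag]),
    stringsAsFactors = FALSE
  )
  # expected confidence: the correct votes form the dominant cluster unless
  # decoys happen to collide; decoy vocabulary makes collisions negligible
  expected$expected_confidence <- pmax(expected$n_correct,
                                       as.integer(rowSums(outcomes ==
                                                          "wrong") > 0L))
  list(evidence = evidence, expected = expected, outcomes = outcomes)
}

#' Simulate rating cases for ROC evaluation
#'
#' Positives and negatives draw their ordinal ratings from the configured
#' per-class distributions; the closed-form expected AUC is
#' `P(r1 > r0) + 0.5 P(r1 = r0)` (see [expected_auc()]).
#'
#' @param config a [simulation_config()].
#' @param n_cases number of cases.
#' @param prevalence fraction of truly positive cases.
#' @param stream integer offsetting the random stream (one per source).
#' @return a [rating_cases()] table.
#' @export
simulate_rating_cases <- function(config, n_cases = 500L, prevalence = 0.5,
                                  stream = 0L) {
  set.seed(sub_seed(config, 3L + stream))
  truth <- stats::rbinom(n_cases, 1L, prevalence)
  rating <- integer(n_cases)
  n_pos <- sum(truth == 1L)
  rating[truth == 1L] <- sample(config$rating_scale, n_pos, replace = TRUE,
                                prob = config$rating_pos)
  rating[truth == 0L] <- sample(config$rating_scale, n_cases - n_pos,
                                replace = TRUE, prob = config$rating_neg)
  rating_cases(truth, rating)
}

#' Closed-form expected AUC of two rating distributions
#'
#' @param p_pos,p_neg probability vectors over the same ordinal scale for
#'   the positive and negative class.
#' @return `P(r1 > r0) + 0.5 P(r1 = r0)`.
#' @export
expected_auc <- function(p_pos, p_neg) {
  stopifnot(length(p_pos) == length(p_neg))
  k <- length(p_pos)
  total <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- if (i > j) 1 else if (i == j) 0.5 else 0
      total <- total + w * p_pos[i] * p_neg[j]
    }
  }
  total
}
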