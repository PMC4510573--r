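ortho_pairs <- function(qa, sb) {
  data.frame(query_id = qa, subject_id = sb, stringsAsFactors = FALSE)
}

test_that("identical gene orders collapse to a single synteny group", {
  n <- 8
  a <- sprintf("a%02d", 1:n); b <- sprintf("b%02d", 1:n)
  groups <- build_synteny_groups(ortho_pairs(a, b),
                                 stats::setNames(1:n, a),
                                 stats::setNames(1:n, b))
  expect_equal(length(unique(groups$group_id)), 1)
  expect_equal(groups$n_pairs, rep(n, n))
  expect_false(any(groups$singleton))
  expect_true(all(groups$orientation == 1))

  empty <- build_synteny_groups(ortho_pairs(character(), character()),
                                integer(), integer())
  expect_equal(nrow(empty), 0)
})

test_that("an inversion and a translocation break blocks as planted", {
  # genome B carries A's genes 1..12 with 5..8 inverted and 11..12 moved
  a <- sprintf("a%02d", 1:12)
  idx_b <- c(1, 2, 3, 4, 8, 7, 6, 5, 9, 10, 30, 31)
  groups <- build_synteny_groups(ortho_pairs(a, paste0("b_", a)),
                                 stats::setNames(1:12, a),
                                 stats::setNames(idx_b, paste0("b_", a)),
                                 max_gap = 2)
  block_of <- stats::setNames(groups$group_id, groups$query_id)
  expect_equal(length(unique(block_of[c("a01", "a02", "a03", "a04")])), 1)
  expect_equal(length(unique(block_of[c("a05", "a06", "a07", "a08")])), 1)
  expect_equal(length(unique(block_of[c("a11", "a12")])), 1)
  # the inverted block is distinct and marked reversed
  expect_false(block_of[["a05"]] == block_of[["a04"]])
  expect_equal(unique(groups$orientation[groups$query_id %in%
                                           c("a05", "a06", "a07", "a08")]),
               -1)
  # the translocated tail is split off by the index jump
  expect_false(block_of[["a11"]] == block_of[["a10"]])
  expect_error(build_synteny_groups(ortho_pairs("a", "b"),
                                    stats::setNames(1, "a"), integer()),
               "missing from order map")
})

test_that("synteny groups depend only on order, not on gene labels", {
  set.seed(13)
  n <- 10
  a <- sprintf("x%02d", 1:n); b <- sprintf("y%02d", 1:n)
  idx_b <- sample(1:n)
  g1 <- build_synteny_groups(ortho_pairs(a, b), stats::setNames(1:n, a),
                             stats::setNames(idx_b, b))
  a2 <- sprintf("LONG_NAME_%02d", 1:n); b2 <- sprintf("Q%02d", 1:n)
  g2 <- build_synteny_groups(ortho_pairs(a2, b2), stats::setNames(1:n, a2),
                             stats::setNames(idx_b, b2))
  expect_equal(g1$group_id, g2$group_id)
  expect_equal(g1$idx_b, g2$idx_b)
})

test_that("neighborhood score counts co-localized co-oriented genomes", {
  mk <- function(fams, idx, strand) data.frame(family = fams, index = idx,
                                               strand = strand,
                                               stringsAsFactors = FALSE)
  adjacent <- list(mk(c("fA", "fB"), c(5, 6), c("+", "+")),
                   mk(c("fA", "fB"), c(9, 10), c("-", "-")))
  expect_equal(neighborhood_score("fA", "fB", adjacent), 1)

  apart <- list(mk(c("fA", "fB"), c(1, 30), c("+", "+")))
  expect_equal(neighborhood_score("fA", "fB", apart), 0)

  opposite <- list(mk(c("fA", "fB"), c(5, 6), c("+", "-")))
  expect_equal(neighborhood_score("fA", "fB", opposite), 0)

  never <- list(mk("fA", 1, "+"), mk("fB", 1, "+"))
  expect_equal(neighborhood_score("fA", "fB", never), 0)

  # random orders agree with a per-genome brute-force check
  set.seed(29)
  for (rep in 1:10) {
    genomes <- lapply(1:4, function(g) {
      fams <- sample(c("fA", "fB", "fC", "fD"), sample(2:4, 1))
      mk(fams, sample(1:10, length(fams)),
         sample(c("+", "-"), length(fams), TRUE))
    })
    got <- neighborhood_score("fA", "fB", genomes, max_dist = 3)
    both <- close_ <- 0
    for (g in genomes) {
      ia <- g$index[g$family == "fA"]; ib <- g$index[g$family == "fB"]
      if (!length(ia) || !length(ib)) next
      both <- both + 1
      sa <- g$strand[g$family == "fA"]; sb <- g$strand[g$family == "fB"]
      if (any(outer(ia, ib, function(x, y) abs(x - y) <= 3) &
                outer(sa, sb, "=="))) close_ <- close_ + 1
    }
    expect_equal(got, if (both == 0) 0 else close_ / both)
  }
})

test_that("co-occurrence is the Jaccard similarity of presence profiles", {
  expect_equal(cooccurrence_score(c(TRUE, TRUE, FALSE),
                                  c(TRUE, TRUE, FALSE)), 1)
  expect_equal(cooccurrence_score(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_equal(cooccurrence_score(c(FALSE, FALSE), c(FALSE, FALSE)), 0)
  expect_error(cooccurrence_score(TRUE, c(TRUE, FALSE)), "length mismatch")
  set.seed(37)
  for (rep in 1:10) {
    pa <- runif(8) < 0.5; pb <- runif(8) < 0.5
    want <- if (!any(pa | pb)) 0 else
      length(intersect(which(pa), which(pb))) /
      length(union(which(pa), which(pb)))
    expect_equal(cooccurrence_score(pa, pb), want)
    expect_equal(cooccurrence_score(pb, pa),
                 cooccurrence_score(pa, pb))
  }
})

test_that("combined confidence follows 1 - prod(1 - s) with a strict 0.4 gate", {
  res <- combine_scores(c(0.5, 0.5))
  expect_equal(res$combined, 0.75)
  expect_true(res$passes)
  # a single 0.4 component does NOT pass the strict threshold
  res4 <- combine_scores(0.4)
  expect_equal(res4$combined, 0.4)
  expect_false(res4$passes)
  expect_error(combine_scores(c(0.2, 1.3)), "outside")

  set.seed(43)
  for (rep in 1:20) {
    s <- runif(sample(1:4, 1))
    res <- combine_scores(s)
    expect_equal(res$combined, 1 - prod(1 - s))
    expect_gte(res$combined, max(s) - 1e-12)  # monotone combination
    extended <- combine_scores(c(s, runif(1)))
    expect_gte(extended$combined, res$combined - 1e-12)
  }
})

test_that("unknown genes inherit the majority label of passing partners", {
  assoc <- data.frame(
    gene_a = c("u1", "u1", "u2", "u3"),
    gene_b = c("k1", "k2", "k3", "k4"),
    passes = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  labels <- c(k1 = "oxidation reduction", k2 = "oxidation reduction",
              k3 = "transport", k4 = NA)
  out <- associate_unknowns(c("u1", "u2", "u3"), assoc, labels)
  expect_equal(out[["u1"]], "oxidation reduction")
  expect_true(is.na(out[["u2"]]))   # only edge does not pass
  expect_true(is.na(out[["u3"]]))   # partner has no label

  # a tie yields no call
  tie <- data.frame(gene_a = c("u", "u"), gene_b = c("k1", "k3"),
                    passes = TRUE, stringsAsFactors = FALSE)
  expect_true(is.na(associate_unknowns("u", tie, labels)[["u"]]))
})

test_that("planted module labels are recovered through context transfer", {
  set.seed(59)
  # two modules of tightly linked genes; unknowns linked to their module
  n_per <- 6
  genes <- c(sprintf("m1_%d", 1:n_per), sprintf("m2_%d", 1:n_per))
  labels <- stats::setNames(rep(c("modA", "modB"), each = n_per), genes)
  unknowns <- c("u1", "u2")
  assoc <- rbind(
    data.frame(gene_a = "u1", gene_b = sprintf("m1_%d", 1:4), passes = TRUE),
    data.frame(gene_a = "u1", gene_b = "m2_1", passes = TRUE),
    data.frame(gene_a = "u2", gene_b = sprintf("m2_%d", 1:5), passes = TRUE))
  out <- associate_unknowns(unknowns, assoc, labels)
  expect_equal(unname(out), c("modA", "modB"))
})
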