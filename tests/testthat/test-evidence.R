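ev_row <- function(source = "PSI_BLAST", e = 1e-60, id = 45,
                   desc = "beta-xylosidase family 43", cds = "X_0001",
                   mdb = "") {
  evidence_table(cds, source, mdb, desc, e, id)
}

test_that("PSI-BLAST filter applies strict identity and e-value bounds", {
  hits <- rbind(ev_row(e = 1e-60, id = 45),   # both pass
                ev_row(e = 1e-80, id = 39),   # identity fails
                ev_row(e = 1e-40, id = 80),   # e-value fails
                ev_row(e = 1e-10, id = 10))   # both fail
  out <- filter_psiblast(hits)
  expect_equal(nrow(out), 1)
  expect_equal(out$identity_pct, 45)

  # boundary: identity exactly 40.0 and e-value exactly 1e-52 are rejected
  expect_equal(nrow(filter_psiblast(ev_row(e = 1e-60, id = 40.0))), 0)
  expect_equal(nrow(filter_psiblast(ev_row(e = 1e-52, id = 80))), 0)
  expect_equal(nrow(filter_psiblast(hits[0, ])), 0)
  expect_warning(out <- filter_psiblast(ev_row(e = NA, id = 50)), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("Pfam filter is inclusive at its 1e-02 cut-off", {
  expect_equal(nrow(filter_pfam(ev_row("PFAM", e = 1e-3, id = NA))), 1)
  expect_equal(nrow(filter_pfam(ev_row("PFAM", e = 1e-2, id = NA))), 1)
  expect_equal(nrow(filter_pfam(ev_row("PFAM", e = 2e-2, id = NA))), 0)
  expect_equal(nrow(filter_pfam(ev_row("PFAM")[0, ])), 0)
})

test_that("description normalization is word-order and filler invariant", {
  a <- normalize_description("Beta-xylosidase, family 43 glycosyl hydrolase")[[1]]
  b <- normalize_description("glycosyl hydrolase family 43 beta-xylosidase")[[1]]
  expect_identical(a, b)
  expect_length(normalize_description("hypothetical protein")[[1]], 0)
  expect_length(normalize_description("")[[1]], 0)
  expect_identical(normalize_description("ABC transporter; ATP-binding")[[1]],
                   sort(c("abc", "transporter", "atp", "binding")))
})

test_that("integrated-source duplicates contribute no extra vote", {
  ev <- rbind(
    ev_row("PFAM", e = 1e-5, id = NA, desc = "glycosyl hydrolase family 43"),
    ev_row("INTERPROSCAN", e = 1e-6, id = NA,
           desc = "glycosyl hydrolase family 43", mdb = "PFAM"))
  votes <- dedupe_sources(ev)
  expect_equal(nrow(votes), 1)
  expect_equal(votes$source, "PFAM")

  # same member database but a genuinely different description still votes
  ev2 <- rbind(
    ev_row("PFAM", e = 1e-5, id = NA, desc = "glycosyl hydrolase family 43"),
    ev_row("INTERPROSCAN", e = 1e-6, id = NA,
           desc = "sulfatase modifying factor", mdb = "PFAM"))
  expect_equal(nrow(dedupe_sources(ev2)), 2)

  # five sources, five distinct descriptions -> five votes
  ev5 <- do.call(rbind, lapply(seq_along(c("PSI_BLAST", "BLASTO", "PFAM",
                                           "INTERPROSCAN", "ANNIE")),
    function(i) ev_row(c("PSI_BLAST", "BLASTO", "PFAM", "INTERPROSCAN",
                         "ANNIE")[i], desc = paste("enzyme class", i),
                       id = NA)))
  expect_equal(nrow(dedupe_sources(ev5)), 5)

  # at most one vote per source
  ev_dup <- rbind(ev_row(e = 1e-60), ev_row(e = 1e-70))
  expect_equal(nrow(dedupe_sources(ev_dup)), 1)
})

test_that("confidence equals the largest mutually agreeing vote cluster", {
  srcs <- c("PSI_BLAST", "BLASTO", "PFAM", "INTERPROSCAN", "ANNIE")
  # five equivalent descriptions -> 5/5, DEFINED
  ev5 <- do.call(rbind, lapply(srcs, function(s)
    ev_row(s, desc = "glucokinase ROK", id = NA)))
  call <- assign_confidence(ev5)
  expect_equal(call$confidence, 5)
  expect_equal(call$call_class, "DEFINED")
  expect_equal(call$supporting_sources, paste(sort(srcs), collapse = ";"))

  # 3 equivalent + 2 distinct -> 3
  ev32 <- do.call(rbind, c(
    lapply(srcs[1:3], function(s) ev_row(s, desc = "glucokinase ROK", id = NA)),
    list(ev_row("INTERPROSCAN", desc = "sulfatase", id = NA),
         ev_row("ANNIE", desc = "ferredoxin oxidoreductase", id = NA))))
  expect_equal(assign_confidence(ev32)$confidence, 3)

  # no evidence -> NONE with confidence 0
  none <- assign_confidence(ev5[0, ], cds_id = "X_0001")
  expect_equal(none$confidence, 0)
  expect_equal(none$call_class, "NONE")
  expect_equal(none$consensus_description, "")
})

test_that("confidence clustering agrees with the exhaustive partition oracle", {
  set.seed(21)
  vocab <- c("glucokinase ROK", "ROK glucokinase sugar",
             "sulfatase factor", "ferredoxin oxidoreductase",
             "oxidoreductase ferredoxin iron", "amidase")
  srcs <- c("PSI_BLAST", "BLASTO", "PFAM", "INTERPROSCAN", "ANNIE")
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    descs <- sample(vocab, n, replace = TRUE)
    ev <- do.call(rbind, lapply(seq_len(n), function(i)
      ev_row(srcs[i], desc = descs[i], id = NA)))
    got <- assign_confidence(ev)$confidence
    toks <- lapply(descs, function(d) normalize_description(d)[[1]])
    expect_equal(got, oracle_max_agreeing(toks, 0.6),
                 info = paste(descs, collapse = " | "))
  }
})

test_that("confidence is order-invariant and monotone in agreeing evidence", {
  srcs <- c("PSI_BLAST", "BLASTO", "PFAM", "INTERPROSCAN")
  ev <- do.call(rbind, c(
    lapply(srcs[1:2], function(s) ev_row(s, desc = "glucokinase ROK", id = NA)),
    list(ev_row("PFAM", desc = "sulfatase", id = NA))))
  base <- assign_confidence(ev)
  for (p in list(c(3, 1, 2), c(2, 3, 1))) {
    expect_equal(assign_confidence(ev[p, ]), base)
  }
  more <- rbind(ev, ev_row("ANNIE", desc = "ROK glucokinase", id = NA))
  expect_gte(assign_confidence(more)$confidence, base$confidence)
  # never exceeds the number of distinct methods
  expect_lte(assign_confidence(more)$confidence, 5)
})

test_that("motif-only and 'putative'-marked consensus yields PUTATIVE", {
  motif_only <- rbind(
    ev_row("PFAM", desc = "glycosyl hydrolase family 43", id = NA),
    ev_row("INTERPROSCAN", desc = "glycosyl hydrolase 43", id = NA))
  expect_equal(assign_confidence(motif_only)$call_class, "PUTATIVE")

  marked <- rbind(
    ev_row("PSI_BLAST", desc = "putative sugar kinase"),
    ev_row("BLASTO", desc = "putative sugar kinase", id = NA))
  expect_equal(assign_confidence(marked)$call_class, "PUTATIVE")

  aligned <- rbind(
    ev_row("PSI_BLAST", desc = "sugar kinase"),
    ev_row("PFAM", desc = "sugar kinase", id = NA))
  expect_equal(assign_confidence(aligned)$call_class, "DEFINED")
})

test_that("reclassification follows the category x call-class rule table", {
  call_of <- function(class, conf) data.frame(
    cds_id = "X_0001", consensus_description = "sugar kinase",
    confidence = conf, call_class = class, supporting_sources = "",
    stringsAsFactors = FALSE)
  rec_of <- function(cat) gene_table("X_0001", start = 1, end = 90,
                                     product = "hypothetical protein",
                                     category = cat)
  for (cat in c("KNOWN", "HYPOTHETICAL", "PUTATIVE", "NEW", "PSEUDOGENE")) {
    for (class in c("DEFINED", "PUTATIVE", "NONE")) {
      for (conf in 0:5) {
        if (class == "NONE" && conf > 0) next
        if (class != "NONE" && conf == 0) next
        out <- reclassify(rec_of(cat), call_of(class, conf), 2)
        expected <-
          if (cat == "PSEUDOGENE") "PSEUDOGENE"
          else if (class == "NONE") cat
          else if (cat == "KNOWN") "KNOWN"
          else if (class == "DEFINED" && conf >= 2) "KNOWN"
          else "PUTATIVE"
        expect_equal(out$category, expected,
                     info = sprintf("%s/%s/conf=%d", cat, class, conf))
        if (expected == "PUTATIVE" && cat != "PUTATIVE")
          expect_match(out$product, "^putative ")
      }
    }
  }
  # KNOWN + NONE is the identity
  rec <- rec_of("KNOWN")
  expect_equal(reclassify(rec, call_of("NONE", 0)), rec)
})

test_that("census updates conserve totals and refuse overdraws", {
  before <- category_census(c(KNOWN = 1854, HYPOTHETICAL = 781,
                              PUTATIVE = 47, NEW = 231, PSEUDOGENE = 104))
  moves <- data.frame(from = c("HYPOTHETICAL", "HYPOTHETICAL", "PUTATIVE"),
                      to = c("KNOWN", "PUTATIVE", "KNOWN"),
                      count = c(385, 24, 46))
  after <- update_census(before, moves)
  expect_equal(after$counts[["KNOWN"]], 2285)
  expect_equal(after$counts[["HYPOTHETICAL"]], 372)
  expect_equal(after$counts[["PUTATIVE"]], 25)
  expect_equal(after$total, before$total)

  expect_equal(update_census(before, moves[0, ]), before)
  expect_error(update_census(category_census(c(KNOWN = 5)),
                             data.frame(from = "KNOWN", to = "NEW",
                                        count = 6)), "overdraw")
})

test_that("random move sequences match aggregate flow accounting", {
  set.seed(17)
  cats <- c("KNOWN", "HYPOTHETICAL", "PUTATIVE", "NEW", "PSEUDOGENE")
  for (rep in 1:10) {
    counts <- stats::setNames(sample(50:200, 5), cats)
    before <- category_census(counts)
    running <- counts
    moves <- do.call(rbind, lapply(1:8, function(i) {
      from <- sample(cats[running > 0], 1)
      to <- sample(setdiff(cats, from), 1)
      k <- sample(0:running[[from]], 1)
      running[[from]] <<- running[[from]] - k
      running[[to]] <<- running[[to]] + k
      data.frame(from = from, to = to, count = k)
    }))
    after <- update_census(before, moves)
    # independent accounting: net flow per category
    outflow <- tapply(moves$count, moves$from, sum)
    inflow <- tapply(moves$count, moves$to, sum)
    for (k in cats) {
      expected <- counts[[k]] -
        (if (k %in% names(outflow)) outflow[[k]] else 0) +
        (if (k %in% names(inflow)) inflow[[k]] else 0)
      expect_equal(after$counts[[k]], expected)
    }
    expect_equal(after$total, before$total)
  }
})

test_that("evidence tables round-trip through the TSV schema", {
  ev <- rbind(ev_row(), ev_row("PFAM", e = 1e-4, id = NA, desc = "kinase"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_evidence_tsv(ev, tsv)
  back <- read_evidence_tsv(tsv)
  expect_equal(back$source, ev$source)
  expect_equal(back$e_value, ev$e_value)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("cds_id\tsource\n a\tPFAM", bad)
  expect_error(read_evidence_tsv(bad), "required columns")
})
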