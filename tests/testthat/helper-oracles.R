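# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use different algorithms from the
# package code paths.

# --- six-frame ORF oracle -------------------------------------------------
# Enumerate every (start codon, stop codon) pair per frame and strand; keep
# pairs with no internal in-frame stop whose start is the earliest start
# sharing that stop; report forward-strand coordinates.
oracle_orfs <- function(dna, min_len_nt = 60) {
  starts <- c("ATG", "GTG", "TTG"); stops <- c("TAA", "TAG", "TGA")
  scan_strand <- function(chars) {
    L <- length(chars)
    res <- list()
    cod <- function(p) paste0(chars[p], chars[p + 1], chars[p + 2])
    for (f in 0:2) {
      pos <- seq(1 + f, L - 2, by = 3)
      if (length(pos) == 0) next
      start_pos <- pos[vapply(pos, function(p) cod(p) %in% starts, TRUE)]
      stop_pos <- pos[vapply(pos, function(p) cod(p) %in% stops, TRUE)]
      cand <- list()
      for (s in start_pos) {
        downstream <- stop_pos[stop_pos > s]
        internal_free <- downstream[vapply(downstream, function(e)
          !any(stop_pos > s & stop_pos < e), TRUE)]
        if (length(internal_free))
          cand[[length(cand) + 1]] <- c(s, min(internal_free) + 2)
      }
      if (length(cand)) {
        m <- do.call(rbind, cand)
        # maximality: earliest start per stop
        for (e in unique(m[, 2])) {
          s <- min(m[m[, 2] == e, 1])
          len <- e - s + 1
          if (len > min_len_nt && !any(chars[s:e] == "N"))
            res[[length(res) + 1]] <- c(s, e)
        }
      }
    }
    res
  }
  chars <- strsplit(toupper(dna), "")[[1]]
  L <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- rev(unname(comp[chars]))
  fwd <- scan_strand(chars)
  rev_ <- scan_strand(rc)
  rows <- c(
    lapply(fwd, function(o) data.frame(start = o[1], end = o[2],
                                       strand = "+")),
    lapply(rev_, function(o) data.frame(start = L - o[2] + 1,
                                        end = L - o[1] + 1, strand = "-")))
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$end, factor(df$strand, c("+", "-"))), ]
  rownames(df) <- NULL
  df
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# --- exhaustive local-alignment oracle ------------------------------------
# Best local score = max over all substring pairs of the global
# Needleman-Wunsch score under the same matrix and linear gap penalty.
oracle_global_score <- function(a, b, submat, gap) {
  n <- nchar(a); m <- nchar(b)
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- (0:n) * gap
  D[1, ] <- (0:m) * gap
  for (i in seq_len(n)) for (j in seq_len(m))
    D[i + 1, j + 1] <- max(D[i, j] + submat[ac[i], bc[j]],
                           D[i, j + 1] + gap, D[i + 1, j] + gap)
  D[n + 1, m + 1]
}

oracle_local_score <- function(a, b, submat, gap) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (j1 in i1:nchar(a))
    for (i2 in seq_len(nchar(b))) for (j2 in i2:nchar(b)) {
      sc <- oracle_global_score(substr(a, i1, j1), substr(b, i2, j2),
                                submat, gap)
      if (sc > best) best <- sc
    }
  best
}

simple_submat <- function(alphabet = c("A", "R", "N"), match = 2,
                          mismatch = -1) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

random_protein_seq <- function(n, alphabet = c("A", "R", "N")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- PROSITE window oracle ------------------------------------------------
# Iterative boolean DP over (element, position): reach[k, p] is TRUE when
# elements 1..k can consume exactly the window prefix ending before p.
oracle_prosite_window_ok <- function(window_chars, elements) {
  W <- length(window_chars)
  reach <- matrix(FALSE, length(elements) + 1, W + 1)
  reach[1, 1] <- TRUE
  for (k in seq_along(elements)) {
    el <- elements[[k]]
    for (p in which(reach[k, ])) {
      for (r in el$min_rep:el$max_rep) {
        q <- (p - 1) + r
        if (q > W) break
        if (r > 0 &&
            !all(window_chars[seq.int(p - 1 + 1, q)] %in% el$allowed))
          break
        reach[k + 1, q + 1] <- TRUE
      }
    }
  }
  reach[length(elements) + 1, W + 1]
}

oracle_prosite_scan <- function(seq, pattern) {
  chars <- strsplit(seq, "")[[1]]
  els <- pattern$elements
  min_len <- sum(vapply(els, `[[`, 0L, "min_rep"))
  max_len <- sum(vapply(els, `[[`, 0L, "max_rep"))
  res <- list()
  starts <- if (pattern$anchor_n) 1 else seq_along(chars)
  for (s in starts) {
    for (w in min_len:max_len) {
      e <- s + w - 1
      if (w < 1 || e > length(chars)) next
      if (pattern$anchor_c && e != length(chars)) next
      if (oracle_prosite_window_ok(chars[s:e], els))
        res[[length(res) + 1]] <- c(s, e)
    }
  }
  if (!length(res)) return(data.frame(start = integer(), end = integer()))
  df <- unique(do.call(rbind.data.frame, lapply(res, function(x)
    list(start = x[1], end = x[2]))))
  df <- df[order(df$start, df$end), ]
  rownames(df) <- NULL
  df
}

random_prosite_pattern <- function(max_elements = 6) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_el <- sample(2:max_elements, 1)
  els <- vapply(seq_len(n_el), function(i) {
    kind <- sample(c("fixed", "set", "excl", "x"), 1,
                   prob = c(0.4, 0.25, 0.15, 0.2))
    base <- switch(kind,
      fixed = sample(aa, 1),
      set = paste0("[", paste(sample(aa, sample(2:4, 1)), collapse = ""), "]"),
      excl = paste0("{", paste(sample(aa, sample(1:15, 1)), collapse = ""), "}"),
      x = "x")
    if (runif(1) < 0.3) {
      lo <- sample(0:2, 1); hi <- lo + sample(0:2, 1)
      base <- if (runif(1) < 0.5 && hi > lo)
        paste0(base, "(", lo, ",", hi, ")") else paste0(base, "(", max(lo, 1), ")")
    }
    base
  }, "")
  paste(els, collapse = "-")
}

# --- all-pairs Mann-Whitney AUC oracle ------------------------------------
oracle_auc <- function(truth, rating) {
  pos <- rating[truth == 1]; neg <- rating[truth == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# --- set-partition oracle for consensus clustering ------------------------
# All partitions of 1..n; a block is valid when all members pairwise agree;
# returns the largest valid block size over partitions restricted to valid
# blocks (equivalently, the maximum mutually-agreeing subset).
oracle_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in oracle_partitions(n - 1)) {
    for (i in seq_along(p)) {
      q <- p; q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

oracle_max_agreeing <- function(tokens, threshold) {
  jac <- function(a, b) {
    if (!length(a) && !length(b)) return(1)
    length(intersect(a, b)) / length(union(a, b))
  }
  n <- length(tokens)
  best <- 0L
  for (p in oracle_partitions(n)) {
    ok <- vapply(p, function(block) {
      if (length(block) < 2) return(TRUE)
      prs <- combn(block, 2)
      all(apply(prs, 2, function(ij)
        jac(tokens[[ij[1]]], tokens[[ij[2]]]) >= threshold))
    }, TRUE)
    if (all(ok)) best <- max(best, max(lengths(p)))
  }
  best
}
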