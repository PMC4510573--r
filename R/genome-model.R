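#' @keywords internal
"_PACKAGE"

GENE_CATEGORIES <- c("KNOWN", "HYPOTHETICAL", "PUTATIVE", "NEW", "PSEUDOGENE")

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS  <- c("TAA", "TAG", "TGA")

#' Construct a table of gene records
#'
#' A gene record describes one CDS: a locus tag (`<PREFIX>_<4 digits>`),
#' coordinates (1-based inclusive, forward-strand), strand, a free-text
#' product, one of the five annotation categories
#' (KNOWN, HYPOTHETICAL, PUTATIVE, NEW, PSEUDOGENE), a confidence level
#' 0--5 and an optional semicolon-joined set of COG identifiers.
#'
#' @param locus_tag character vector of locus tags.
#' @param genome_id genome identifier (recycled).
#' @param start,end 1-based inclusive nucleotide coordinates, `end >= start`.
#' @param strand `"+"` or `"-"`.
#' @param product free-text product description.
#' @param category one of the five categories.
#' @param confidence integer 0--5; only KNOWN/PUTATIVE records may carry a
#'   positive confidence.
#' @param cog_ids character vector, semicolon-joined COG ids (may be `""`).
#' @return a `data.frame` with class `gene_table`, one row per CDS.
#' @export
gene_table <- function(locus_tag, genome_id = "genome",
                       start = integer(), end = integer(),
                       strand = "+", product = "", category = "NEW",
                       confidence = 0L, cog_ids = "") {
  n <- length(locus_tag)
  df <- data.frame(
    locus_tag = as.character(locus_tag),
    genome_id = rep_len(as.character(genome_id), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    product = rep_len(as.character(product), n),
    category = rep_len(as.character(category), n),
    confidence = rep_len(as.integer(confidence), n),
    cog_ids = rep_len(as.character(cog_ids), n),
    stringsAsFactors = FALSE
  )
  validate_gene_table(df)
  class(df) <- c("gene_table", "data.frame")
  df
}

validate_gene_table <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$end < df$start))
    stop("gene record with end < start")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(df$category %in% GENE_CATEGORIES))
    stop("unknown category: ",
         paste(setdiff(df$category, GENE_CATEGORIES), collapse = ", "))
  if (any(df$confidence < 0L | df$confidence > 5L))
    stop("confidence must be in 0..5")
  bad_conf <- df$confidence > 0L & !(df$category %in% c("KNOWN", "PUTATIVE"))
  if (any(bad_conf))
    stop("confidence > 0 requires category KNOWN or PUTATIVE")
  for (g in unique(df$genome_id)) {
    tags <- df$locus_tag[df$genome_id == g]
    if (anyDuplicated(tags))
      stop("duplicate locus tags within genome ", g)
  }
  invisible(df)
}

#' Construct a genome annotation
#'
#' Bundles a genome identifier, its sequence length, GC fraction and an
#' ordered gene table (sorted by start coordinate).
#'
#' @param genome_id genome identifier.
#' @param sequence_length chromosome length in nt.
#' @param gc_fraction G+C fraction in `[0, 1]`.
#' @param genes a [gene_table()].
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, sequence_length, gc_fraction = NA_real_,
                              genes = gene_table(character())) {
  if (nrow(genes) > 0L) {
    if (any(genes$start < 1L) || any(genes$end > sequence_length))
      stop("gene coordinates outside [1, sequence_length]")
    genes <- genes[order(genes$start, factor(genes$strand, c("+", "-"))), ,
                   drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(
    list(genome_id = genome_id,
         sequence_length = as.integer(sequence_length),
         gc_fraction = gc_fraction,
         genes = genes),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d nt, GC %.3f, %d genes\n",
              x$genome_id, x$sequence_length,
              ifelse(is.na(x$gc_fraction), NaN, x$gc_fraction),
              nrow(x$genes)))
  invisible(x)
}

check_dna <- function(dna) {
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna))
    stop("sequence contains non-nucleotide characters (only A/C/G/T/N allowed)")
  dna
}

#' G+C fraction of a nucleotide sequence
#'
#' Ambiguous bases (N) are excluded from the denominator.
#'
#' @param dna nucleotide sequence (character scalar over A/C/G/T/N).
#' @return fraction of unambiguous bases that are G or C.
#' @export
gc_content <- function(dna) {
  dna <- check_dna(dna)
  chars <- strsplit(dna, "", fixed = TRUE)[[1L]]
  n_acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (n_acgt == 0L)
    stop("no unambiguous bases: GC content undefined")
  sum(chars %in% c("G", "C")) / n_acgt
}

codons_at <- function(chars, pos) {
  # codon strings starting at each element of pos (vectorised)
  paste0(chars[pos], chars[pos + 1L], chars[pos + 2L])
}

orfs_one_strand <- function(chars, min_len_nt) {
  # maximal ORFs on the given (forward-oriented) character vector:
  # in each frame, between consecutive in-frame stops, the ORF runs from the
  # FIRST start codon to the closing stop (stop codon included in the length)
  L <- length(chars)
  out <- list()
  for (frame in 0:2) {
    pos <- seq.int(1L + frame, L - 2L, by = 3L)
    if (length(pos) == 0L) next
    cod <- codons_at(chars, pos)
    is_stop <- cod %in% STOP_CODONS
    is_start <- cod %in% START_CODONS
    seg_start_i <- 1L                     # codon index opening current segment
    for (i in seq_along(pos)) {
      if (is_stop[i]) {
        j <- seg_start_i
        while (j < i && !is_start[j]) j <- j + 1L
        if (j < i && is_start[j]) {
          s <- pos[j]; e <- pos[i] + 2L
          len <- e - s + 1L
          if (len > min_len_nt && !any(chars[s:e] == "N"))
            out[[length(out) + 1L]] <- c(s, e)
        }
        seg_start_i <- i + 1L
      }
    }
  }
  out
}

revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

#' Enumerate maximal open reading frames
#'
#' Scans all six frames for maximal CDSs: each ORF begins at the first start
#' codon (ATG/GTG/TTG) after the previous in-frame stop, ends at the next
#' in-frame stop codon (included in the length), and is retained only if its
#' length strictly exceeds `min_len_nt`. ORFs containing an N are discarded.
#' Minus-strand ORFs are reported in forward-strand coordinates.
#'
#' @param dna nucleotide sequence over A/C/G/T/N.
#' @param min_len_nt minimum length in nt (strict; default 60, i.e. the
#'   "greater than 60 bp" retention rule).
#' @param circular if `TRUE`, ORFs spanning the origin are also found and
#'   reported on the unrolled circle (`end` may exceed the sequence length;
#'   flagged in the `wraps` column).
#' @return data.frame with columns `start`, `end`, `strand` (and `wraps`
#'   when `circular = TRUE`), sorted by start then strand (+ before -).
#' @export
find_orfs <- function(dna, min_len_nt = 60L, circular = FALSE) {
  if (min_len_nt < 3L) stop("min_len_nt must be >= 3")
  dna <- check_dna(dna)
  chars <- strsplit(dna, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  scan_chars <- if (circular) c(chars, chars) else chars

  fwd <- orfs_one_strand(scan_chars, min_len_nt)
  rev_ <- orfs_one_strand(revcomp_chars(scan_chars), min_len_nt)
  Ls <- length(scan_chars)

  rows <- list()
  for (o in fwd)
    rows[[length(rows) + 1L]] <- list(start = o[1], end = o[2], strand = "+")
  for (o in rev_)
    rows[[length(rows) + 1L]] <- list(start = Ls - o[2] + 1L,
                                      end = Ls - o[1] + 1L, strand = "-")
  df <- if (length(rows)) {
    data.frame(start = vapply(rows, `[[`, 0, "start"),
               end = vapply(rows, `[[`, 0, "end"),
               strand = vapply(rows, `[[`, "", "strand"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  }

  if (circular && nrow(df) > 0L) {
    # fold back onto the circle; keep each distinct ORF once
    len <- df$end - df$start + 1L
    df <- df[len <= L, , drop = FALSE]
    len <- df$end - df$start + 1L
    df$start <- (df$start - 1L) %% L + 1L
    df$end <- df$start + len - 1L          # unrolled circle: end may exceed L
    df$wraps <- df$end > L
    df <- df[!duplicated(df[c("start", "end", "strand")]), , drop = FALSE]
  }

  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df <- df[order(df$start, df$end, factor(df$strand, c("+", "-"))), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assign sequential locus tags to ORFs
#'
#' Tags are `<prefix>_0001`, `<prefix>_0002`, ... in start order, zero-padded
#' to four digits (five with a warning beyond 9999 ORFs), matching the
#' CALS8_#### convention. Input is pre-sorted by start; ties (same start)
#' place '+' before '-'. Category is initialised to NEW.
#'
#' @param orfs data.frame with `start`, `end`, `strand` columns.
#' @param prefix locus-tag prefix, e.g. `"CALS8"`.
#' @param genome_id genome identifier for the records.
#' @return a [gene_table()] of NEW records in start order.
#' @export
assign_locus_tags <- function(orfs, prefix, genome_id = "genome") {
  orfs <- orfs[order(orfs$start, factor(orfs$strand, c("+", "-"))), ,
               drop = FALSE]
  n <- nrow(orfs)
  if (n == 0L) return(gene_table(character()))
  width <- 4L
  if (n > 9999L) {
    width <- 5L
    warning("more than 9999 ORFs: locus-tag width grows to 5 digits")
  }
  tags <- sprintf(paste0("%s_%0", width, "d"), prefix, seq_len(n))
  gene_table(locus_tag = tags, genome_id = genome_id,
             start = orfs$start, end = orfs$end, strand = orfs$strand,
             category = "NEW")
}

#' Category census of an annotation
#'
#' Counts genes per annotation category; the counts partition the gene list.
#'
#' @param annotation a [genome_annotation()] or a [gene_table()].
#' @return a `category_census`: named list `counts` over the five categories
#'   plus `total`.
#' @export
census <- function(annotation) {
  genes <- if (inherits(annotation, "genome_annotation")) annotation$genes
           else annotation
  counts <- vapply(GENE_CATEGORIES,
                   function(k) sum(genes$category == k), 0L)
  category_census(counts)
}

#' Build a census from explicit counts
#'
#' @param counts named integer vector (names among the five categories;
#'   missing categories count 0).
#' @return a `category_census` object.
#' @export
category_census <- function(counts) {
  full <- stats::setNames(integer(length(GENE_CATEGORIES)), GENE_CATEGORIES)
  if (length(counts)) {
    if (is.null(names(counts)))
      stop("counts must be named by category")
    bad <- setdiff(names(counts), GENE_CATEGORIES)
    if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
    if (any(counts < 0)) stop("negative category count")
    full[names(counts)] <- as.integer(counts)
  }
  structure(list(counts = full, total = sum(full)),
            class = "category_census")
}

#' @export
print.category_census <- function(x, ...) {
  cat("<category_census>\n")
  for (k in names(x$counts)) cat(sprintf("  %-12s %d\n", k, x$counts[[k]]))
  cat(sprintf("  %-12s %d\n", "total", x$total))
  invisible(x)
}
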