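# File interchange: FASTA via Biostrings, GFF3/TSV writers for gene tables,
# evidence and function-call TSVs, census JSON.

#' Read protein or nucleotide FASTA
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return a named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write a gene table as TSV
#'
#' Columns: locus_tag, genome_id, start, end, strand, category, confidence,
#' product, cog_ids (semicolon-joined).
#'
#' @param genes a [gene_table()].
#' @param path output file.
#' @export
write_gene_tsv <- function(genes, path) {
  cols <- c("locus_tag", "genome_id", "start", "end", "strand",
            "category", "confidence", "product", "cog_ids")
  utils::write.table(genes[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene table from TSV
#'
#' @param path TSV written by [write_gene_tsv()].
#' @return a [gene_table()].
#' @export
read_gene_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(cog_ids = "character",
                                         product = "character"))
  df$product[is.na(df$product)] <- ""
  df$cog_ids[is.na(df$cog_ids)] <- ""
  gene_table(locus_tag = df$locus_tag, genome_id = df$genome_id,
             start = df$start, end = df$end, strand = df$strand,
             product = df$product, category = df$category,
             confidence = df$confidence, cog_ids = df$cog_ids)
}

#' Write a gene table as GFF3
#'
#' @param genes a [gene_table()].
#' @param path output file.
#' @param source source field for column 2.
#' @export
write_gene_gff3 <- function(genes, path, source = "reannotator") {
  lines <- "##gff-version 3"
  if (nrow(genes)) {
    attr_str <- sprintf("ID=%s;product=%s;category=%s;confidence=%d",
                        genes$locus_tag,
                        gsub("[;=,]", " ", genes$product),
                        genes$category, genes$confidence)
    lines <- c(lines, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                              genes$genome_id, source, genes$start,
                              genes$end, genes$strand, attr_str))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Emit a census as JSON
#'
#' @param cns a `category_census`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
census_json <- function(cns, path = NULL) {
  obj <- c(as.list(cns$counts), list(total = cns$total))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read an evidence table from TSV
#'
#' Required header: cds_id, source, member_database, description, e_value,
#' identity_pct, score.
#'
#' @param path TSV file.
#' @return an evidence data.frame (see [evidence_table()]).
#' @export
read_evidence_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("cds_id", "source", "member_database", "description",
            "e_value", "identity_pct", "score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("evidence TSV lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  df$member_database[is.na(df$member_database)] <- ""
  evidence_table(cds_id = df$cds_id, source = df$source,
                 member_database = df$member_database,
                 description = df$description, e_value = df$e_value,
                 identity_pct = df$identity_pct, score = df$score)
}

#' Write an evidence table as TSV
#'
#' @param ev evidence data.frame.
#' @param path output file.
#' @export
write_evidence_tsv <- function(ev, path) {
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write consensus function calls as TSV
#'
#' Columns: cds_id, consensus_description, confidence (as `k/5`),
#' call_class, supporting_sources (semicolon-joined).
#'
#' @param calls data.frame of function calls (see [assign_confidence()]).
#' @param path output file.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- data.frame(
    cds_id = calls$cds_id,
    consensus_description = calls$consensus_description,
    confidence = sprintf("%d/5", calls$confidence),
    call_class = calls$call_class,
    supporting_sources = calls$supporting_sources,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an ortholog table as TSV
#'
#' @param orthologs BBH table from [bbh()].
#' @param path output file.
#' @export
write_ortholog_tsv <- function(orthologs, path) {
  utils::write.table(orthologs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read rating cases (truth TAB rating) from file
#'
#' "Format 1"-style input: one case per line, binary truth then ordinal
#' rating, tab-separated, no header.
#'
#' @param path input file.
#' @return data.frame with columns `truth`, `rating`.
#' @export
read_rating_tsv <- function(path) {
  df <- utils::read.table(path, col.names = c("truth", "rating"))
  rating_cases(truth = df$truth, rating = df$rating)
}
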