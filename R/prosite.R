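# PROSITE-syntax pattern compiler and scanner.
#
# Supported syntax subset: fixed residues (e.g. E), alternatives [HQ],
# exclusions {P}, wildcard x, repeat counts on any element as (n) or (n,m),
# N-terminal anchor '<' and C-terminal anchor '>'. Elements separated by '-';
# an optional trailing '.' is tolerated.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Compile a PROSITE-syntax pattern
#'
#' @param pattern_text pattern string, e.g. `"[HQ]-E-G-P-N-V-F"` or
#'   `"C-x(2)-C"`.
#' @return an object of class `pros_pattern` with the element list, anchors
#'   and the original text.
#' @export
prosite_compile <- function(pattern_text) {
  txt <- trimws(pattern_text)
  body <- sub("\\.$", "", txt)
  anchor_n <- startsWith(body, "<")
  if (anchor_n) body <- substring(body, 2L)
  anchor_c <- endsWith(body, ">")
  if (anchor_c) body <- substring(body, 1L, nchar(body) - 1L)
  if (!nzchar(body)) stop("empty PROSITE pattern")

  parts <- strsplit(body, "-", fixed = TRUE)[[1L]]
  elements <- lapply(seq_along(parts), function(i) {
    el <- parts[i]
    if (!nzchar(el))
      stop("malformed PROSITE pattern: empty element at position ", i)
    min_rep <- 1L; max_rep <- 1L
    rep_m <- regmatches(el, regexec("\\((\\d+)(?:,(\\d+))?\\)$", el))[[1L]]
    if (length(rep_m)) {
      min_rep <- as.integer(rep_m[2L])
      max_rep <- if (nzchar(rep_m[3L])) as.integer(rep_m[3L]) else min_rep
      if (max_rep < min_rep)
        stop("malformed repeat count in element '", el, "'")
      el <- sub("\\(\\d+(,\\d+)?\\)$", "", el)
    }
    if (el == "x" || el == "X") {
      allowed <- AA_ALPHABET
    } else if (grepl("^\\[[A-Za-z]+\\]$", el)) {
      allowed <- unique(strsplit(toupper(gsub("[][]", "", el)), "")[[1L]])
    } else if (grepl("^\\{[A-Za-z]+\\}$", el)) {
      excluded <- unique(strsplit(toupper(gsub("[{}]", "", el)), "")[[1L]])
      allowed <- setdiff(AA_ALPHABET, excluded)
    } else if (grepl("^[A-Wa-wYyZz]$", el) && toupper(el) %in% AA_ALPHABET) {
      allowed <- toupper(el)
    } else {
      stop("malformed PROSITE element '", parts[i], "' at position ", i)
    }
    list(raw = parts[i], allowed = allowed,
         min_rep = min_rep, max_rep = max_rep)
  })
  structure(list(pattern_text = txt, elements = elements,
                 anchor_n = anchor_n, anchor_c = anchor_c),
            class = "pros_pattern")
}

#' Render a compiled pattern back to PROSITE syntax
#'
#' Compiling then rendering reproduces the input up to whitespace.
#'
#' @param pattern a `pros_pattern`.
#' @return the pattern string.
#' @export
prosite_render <- function(pattern) {
  body <- paste(vapply(pattern$elements, `[[`, "", "raw"), collapse = "-")
  paste0(if (pattern$anchor_n) "<" else "", body,
         if (pattern$anchor_c) ">" else "")
}

#' @export
print.pros_pattern <- function(x, ...) {
  cat("<pros_pattern>", prosite_render(x), "\n")
  invisible(x)
}

match_elements_from <- function(chars, pos, elements, k) {
  # all end positions (inclusive) of matches of elements[k..] starting at pos
  if (k > length(elements)) return(pos - 1L)
  el <- elements[[k]]
  ends <- integer()
  # consume r repetitions of this element, r in [min_rep, max_rep]
  p <- pos
  r <- 0L
  while (r < el$max_rep) {
    if (p > length(chars) || !(chars[p] %in% el$allowed)) break
    p <- p + 1L; r <- r + 1L
    if (r >= el$min_rep)
      ends <- c(ends, match_elements_from(chars, p, elements, k + 1L))
  }
  if (el$min_rep == 0L)   # zero-repetition path is always admissible
    ends <- c(ends, match_elements_from(chars, pos, elements, k + 1L))
  unique(ends)
}

#' Scan a protein sequence for a PROSITE pattern
#'
#' Reports every (possibly overlapping) window satisfying the pattern, as
#' 1-based inclusive (start, end) coordinates in ascending start order.
#'
#' @param seq protein sequence (character scalar, 20-letter alphabet).
#' @param pattern a `pros_pattern` or a pattern string.
#' @return data.frame with columns `start`, `end`.
#' @export
prosite_scan <- function(seq, pattern) {
  if (is.character(pattern)) pattern <- prosite_compile(pattern)
  seq <- toupper(seq)
  if (grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seq))
    stop("sequence contains non-amino-acid characters")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  starts_to_try <- if (pattern$anchor_n) 1L else seq_along(chars)
  res_start <- integer(); res_end <- integer()
  for (s in starts_to_try) {
    ends <- match_elements_from(chars, s, pattern$elements, 1L)
    ends <- ends[ends >= s]
    if (pattern$anchor_c) ends <- ends[ends == length(chars)]
    if (length(ends)) {
      res_start <- c(res_start, rep.int(s, length(ends)))
      res_end <- c(res_end, sort(ends))
    }
  }
  data.frame(start = res_start, end = res_end)
}
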