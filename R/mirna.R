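#' @title miRNA mention grammar
#' @description
#' The extraction grammar accepts, case-insensitively: an optional
#' three-letter species prefix (`hsa-`, `mmu-`, `rno-`, ...), one of the
#' prefix spellings `microRNA` / `micro RNA` / `miRNA` / `miR`, an
#' optional hyphen or single-space separator, a run of digits, an
#' optional letter suffix (paralog letter, e.g. `146a`), any number of
#' trailing `-<digits>` paralog indices or `-3p`/`-5p` arm suffixes, and
#' word boundaries on both sides. Cluster notations such as `miR-17-92`
#' are a single token normalizing to the first integer.
#' @keywords internal
#' @name mirna_grammar
NULL

# One token of the grammar (perl, case-insensitive).
.mir_token_re <- paste0(
  "(?<!\\w)",                      # left word boundary (hyphens allowed: anti-miR-21)
  "(?:[a-z]{3}-)?",                # species prefix
  "(?:micro[ -]?rna|mirna|mir)",   # prefix spellings
  "[- ]?",                         # separator
  "\\d+",                          # family index (required)
  "[a-z]?",                        # paralog letter
  "(?:-(?:[35]p|\\d+))*",          # arm suffix / paralog index / cluster tail
  "(?!\\w)"                        # right word boundary
)

#' Normalize a miRNA token to its family identifier
#'
#' Collapses species prefixes (`hsa-`, `mmu-`, ...), prefix spellings
#' (`miR` / `miRNA` / `microRNA` / `micro RNA`, any case), letter
#' suffixes (`a`, `b`, ...), paralog indices (`-1`, `-2`), and arm
#' suffixes (`-3p`, `-5p`) onto the canonical family label `miR-N`,
#' where `N` is the first integer following the prefix. Lettered
#' paralogs are grouped at the family level, so `miR-146a` and
#' `miR-146b` both normalize to `miR-146`.
#'
#' Normalization is idempotent: `normalize_mirna("miR-146")` is
#' `"miR-146"`.
#'
#' @param token Character vector of tokens produced by the extraction
#'   grammar (each must contain a miR-like prefix followed by digits).
#' @return Character vector of family identifiers (`"miR-N"`).
#' @examples
#' normalize_mirna("hsa-miR-125b-1")  # "miR-125"
#' normalize_mirna("microRNA-21")     # "miR-21"
#' @export
normalize_mirna <- function(token) {
  m <- stringr::str_match(
    token,
    stringr::regex("(?:micro[ -]?rna|mirna|mir)[- ]?(\\d+)", ignore_case = TRUE)
  )[, 2]
  if (anyNA(m)) {
    bad <- token[is.na(m)]
    stop("not a miRNA token (no digits after a miR-like prefix): ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  paste0("miR-", as.integer(m))
}

#' Extract the set of miRNA families mentioned in a text
#'
#' Scans free text with the mention grammar (see [normalize_mirna()] for
#' the normalization rules) and returns the deduplicated set of family
#' identifiers, sorted by family index. A bare `miR` / `miRNA` /
#' `microRNA` with no following number yields nothing.
#'
#' @param text A single character string (empty allowed).
#' @return Character vector of distinct families (`"miR-N"`), sorted by
#'   increasing index.
#' @examples
#' extract_mirnas("Inhibition of miR-21 or overexpression of miR-29a")
#' extract_mirnas("miRNAs are small non-coding RNAs")  # character(0)
#' @export
extract_mirnas <- function(text) {
  stopifnot(length(text) == 1L)
  extract_mirnas_list(text)[[1]]
}

# Vectorized extraction: one family set per input text.
extract_mirnas_list <- function(texts) {
  hits <- stringr::str_extract_all(
    texts, stringr::regex(.mir_token_re, ignore_case = TRUE)
  )
  purrr::map(hits, function(tok) {
    if (length(tok) == 0L) return(character(0))
    fam <- unique(normalize_mirna(tok))
    fam[order(family_index(fam))]
  })
}

#' Numeric index of a miRNA family identifier
#'
#' @param family Character vector of `"miR-N"` identifiers.
#' @return Integer vector of the `N` indices; used as the deterministic
#'   tie-break in rankings.
#' @export
family_index <- function(family) {
  as.integer(sub("^miR-", "", family))
}
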