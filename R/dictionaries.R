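#' Built-in concept dictionaries: cell types, cytokines, processes
#'
#' Returns the three curated term lists mined against every title and
#' abstract: 14 cell types, 11 cytokines, and 15 pathological processes.
#' Each canonical term carries matching variants; hyphen/space
#' interchange (`T-cell` / `T cell`) is generated automatically, and a
#' few synonym variants are built in (`T-reg` is also matched by `Treg`
#' and `regulatory T`, `TNF` by `tumor necrosis factor`, each `IL-n` by
#' `interleukin-n`). The generic term `interleukin` is its own canonical
#' entry and matches independently of the specific `IL-n` entries.
#'
#' @return A tibble with columns `category` (`cell_type`, `cytokine`,
#'   `process`), `canonical`, and `variants` (list-column).
#' @seealso [match_terms()], [read_dictionaries()]
#' @export
default_dictionaries <- function() {
  cell_types <- list(
    macrophage = "macrophage",
    `dendritic cells` = "dendritic cell",
    monocyte = "monocyte",
    `T-cell` = "T-cell",
    `T-reg` = c("T-reg", "Treg", "regulatory T"),
    `B-Cell` = "B-cell",
    fibroblast = "fibroblast",
    osteoclast = "osteoclast",
    osteoblast = "osteoblast",
    endothelial = "endothelial",
    epithelial = "epithelial",
    chondrocyte = "chondrocyte",
    nerve = "nerve",
    neuron = "neuron"
  )
  il <- function(n) c(paste0("IL-", n), paste0("interleukin-", n))
  cytokines <- list(
    `GM-CSF` = "GM-CSF",
    `IL-1` = il(1), `IL-2` = il(2), `IL-6` = il(6), `IL-8` = il(8),
    `IL-18` = il(18), `IL-17` = il(17), `IL-10` = il(10),
    TNF = c("TNF", "tumor necrosis factor", "tumour necrosis factor"),
    RANKL = "RANKL",
    interleukin = "interleukin"
  )
  processes <- c(
    "angiogenesis", "apoptosis", "autoantibody", "biomarker",
    "degeneration", "diagnosis", "fatigue", "fibrosis", "inflammation",
    "invasion", "metabolism", "migration", "pain", "proliferation",
    "therapy"
  )
  build <- function(category, entries) {
    tibble::tibble(
      category = category,
      canonical = names(entries),
      variants = purrr::map(unname(entries), expand_variants)
    )
  }
  dplyr::bind_rows(
    build("cell_type", cell_types),
    build("cytokine", cytokines),
    build("process", stats::setNames(as.list(processes), processes))
  )
}

# Hyphen <-> space interchange on every variant.
expand_variants <- function(variants) {
  extra <- unlist(purrr::map(variants, function(v) {
    c(gsub("-", " ", v, fixed = TRUE), gsub(" ", "-", v, fixed = TRUE))
  }))
  unique(c(variants, extra))
}

escape_regex <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

# Matching pattern for one variant, with the two boundary guards:
# (a) variants ending in a digit require a non-digit next (IL-1 must not
#     fire inside IL-10/17/18, while IL-1β still matches);
# (b) single-letter-prefixed variants (T-cell, T reg, B-cell) require a
#     word boundary before the letter.
variant_pattern <- function(variant) {
  pat <- escape_regex(variant)
  if (grepl("^[A-Za-z][- ]", variant)) pat <- paste0("(?<![A-Za-z0-9])", pat)
  if (grepl("[0-9]$", variant)) pat <- paste0(pat, "(?![0-9])")
  stringr::regex(pat, ignore_case = TRUE)
}

# Long table of (category, canonical, variant, pattern) for fast
# vectorized matching over a corpus.
variant_table <- function(dicts) {
  tbl <- tidyr::unnest(
    dplyr::select(dicts, "category", "canonical", "variants"),
    "variants"
  )
  tbl <- dplyr::rename(tbl, variant = "variants")
  tbl$pattern <- purrr::map(tbl$variant, variant_pattern)
  tbl
}

#' Match dictionary terms in free text
#'
#' A canonical term matches when at least one of its variants occurs in
#' the text, case-insensitively, as a substring subject to the boundary
#' guards described in [default_dictionaries()]. Substring semantics
#' cover plural forms (`fibroblast` matches inside `fibroblasts`) and
#' Greek-letter suffixes (`IL-1` matches inside `IL-1β`).
#'
#' @param text A single character string.
#' @param dicts A dictionary tibble (default: all three built-in
#'   dictionaries). Pass a filtered tibble to match one category.
#' @return A tibble with columns `category` and `canonical`, one row per
#'   matched term, in dictionary order (set semantics: each term at most
#'   once).
#' @examples
#' match_terms("IL-17 drives inflammation in synovial fibroblasts")
#' @export
match_terms <- function(text, dicts = default_dictionaries()) {
  stopifnot(length(text) == 1L)
  match_terms_list(text, dicts)[[1]]
}

# Vectorized matcher: list of matched (category, canonical) tibbles.
match_terms_list <- function(texts, dicts) {
  vt <- variant_table(dicts)
  n <- length(texts)
  if (n == 0L) return(list())
  # variants x texts logical matrix
  hit <- vapply(vt$pattern, function(p) stringr::str_detect(texts, p),
                logical(n))
  if (n == 1L) hit <- matrix(hit, nrow = 1L)
  key <- paste(vt$category, vt$canonical, sep = "\r")
  terms <- dplyr::distinct(dicts[, c("category", "canonical")])
  term_key <- paste(terms$category, terms$canonical, sep = "\r")
  purrr::map(seq_len(n), function(i) {
    matched <- unique(key[hit[i, ]])
    terms[term_key %in% matched, , drop = FALSE]
  })
}

#' Read concept dictionaries from a YAML config file
#'
#' The file maps each category to a list of entries with `canonical`
#' and optional `variants`; the packaged default file
#' (`system.file("extdata", "dictionaries.yml", package = "mirmine")`)
#' reproduces [default_dictionaries()] exactly. Hyphen/space variant
#' interchange is applied after reading, as for the built-ins.
#'
#' @param path Path to the YAML file.
#' @return A dictionary tibble (`category`, `canonical`, `variants`).
#' @export
read_dictionaries <- function(path) {
  cfg <- yaml::read_yaml(path)
  rows <- purrr::imap(cfg, function(entries, category) {
    tibble::tibble(
      category = category,
      canonical = purrr::map_chr(entries, "canonical"),
      variants = purrr::map(entries, function(e) {
        v <- e$variants %||% e$canonical
        expand_variants(as.character(v))
      })
    )
  })
  dplyr::bind_rows(rows)
}

#' @importFrom rlang %||%
NULL

#' Write concept dictionaries to a YAML config file
#'
#' @param dicts A dictionary tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionaries <- function(dicts, path) {
  # store pre-interchange variants compactly: keep one representative per
  # hyphen/space-interchange equivalence class (the first listed)
  cfg <- purrr::map(split(dicts, dicts$category), function(d) {
    purrr::map2(d$canonical, d$variants, function(can, v) {
      keep <- v[!duplicated(gsub("-", " ", v, fixed = TRUE))]
      list(canonical = can, variants = as.list(keep))
    })
  })
  # preserve category order as in the tibble
  cfg <- cfg[unique(dicts$category)]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Stable content hash of a dictionary set (for run manifests)
#'
#' @param dicts A dictionary tibble.
#' @return An MD5 hex string of the canonical serialization.
#' @export
dictionary_hash <- function(dicts) {
  canon <- paste(
    dicts$category, dicts$canonical,
    purrr::map_chr(dicts$variants,
                   ~ paste(sort(.x, method = "radix"), collapse = ",")),
    sep = "|", collapse = "\n"
  )
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon, tmp, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}
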