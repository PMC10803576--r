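#' Read a MEDLINE/PubMed tagged-format citation file
#'
#' Parses the plain-text "PubMed format" produced by the PubMed
#' *save citations to file* menu option. Records are blank-line-separated
#' blocks of `TAG - value` lines; the tag occupies a 4-character field
#' (right-padded, e.g. `TI  - `), and continuation lines start with exactly
#' six spaces and are joined to the previous value with a single space.
#'
#' Recognized tags: `PMID`, `TI` (title), `AB` (abstract), `DP` (date,
#' the first 4-digit token becomes `year`), `PT` (publication type, may
#' repeat), `JT` (journal). All fields, known or not, are preserved in
#' order in the `raw_fields` list-column so that [write_medline()] can
#' round-trip a corpus.
#'
#' @param path Path to a MEDLINE file, or a character vector of lines
#'   (when `text = TRUE`).
#' @param label Corpus label (e.g. the disease name). Defaults to the
#'   file name without extension.
#' @param text If `TRUE`, `path` is treated as the file content itself
#'   (a single string or a vector of lines).
#' @return A tibble with one row per citation record and columns
#'   `corpus`, `pmid`, `title`, `abstract`, `year`, `pub_types`
#'   (list-column of character vectors), `journal`, and `raw_fields`
#'   (list-column of `tag`/`value` tibbles in file order).
#' @details Blocks without a `PMID` field are skipped with a warning.
#'   A malformed field line inside a record (neither a tagged line nor a
#'   six-space continuation) is treated as a continuation of the previous
#'   field, with a warning. Undecodable bytes are replaced rather than
#'   raising an error.
#' @examples
#' txt <- c("PMID- 1", "TI  - miR-21 in lupus", "      nephritis.",
#'          "AB  - We studied miR-21.", "DP  - 2020 Jan 9",
#'          "PT  - Journal Article")
#' read_medline(txt, label = "demo", text = TRUE)
#' @export
read_medline <- function(path, label = NULL, text = FALSE) {
  if (text) {
    lines <- if (length(path) == 1L && grepl("\n", path, fixed = TRUE)) {
      strsplit(path, "\n", fixed = TRUE)[[1]]
    } else {
      as.character(path)
    }
    if (is.null(label)) label <- "corpus"
  } else {
    lines <- readr::read_lines(path, locale = readr::locale(encoding = "UTF-8"))
    if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  }
  lines <- enc2utf8(lines)
  # strip trailing whitespace; parsing must be insensitive to it
  lines <- sub("[ \t\r]+$", "", lines)

  blank <- !nzchar(lines)
  block_id <- cumsum(blank & !c(TRUE, blank[-length(blank)])) + 1L
  blocks <- split(lines[!blank], block_id[!blank])

  records <- purrr::map(unname(blocks), parse_medline_block)
  records <- purrr::compact(records)
  if (length(records) == 0L) {
    return(empty_corpus(label))
  }
  out <- dplyr::bind_rows(records)
  out$corpus <- label
  dplyr::relocate(out, "corpus")
}

# Parse one blank-line-delimited block into a one-row tibble, or NULL if
# the block carries no PMID.
parse_medline_block <- function(block_lines) {
  tag_re <- "^([A-Z0-9]{1,4}) {0,3}- (.*)$"
  tags <- character(0)
  values <- character(0)
  for (line in block_lines) {
    if (grepl(tag_re, line)) {
      tags <- c(tags, sub(tag_re, "\\1", line))
      values <- c(values, sub(tag_re, "\\2", line))
    } else if (grepl("^ {6}", line)) {
      if (length(values) == 0L) next
      cont <- sub("^ {6}", "", line)
      values[length(values)] <- paste(values[length(values)], cont)
    } else {
      if (length(values) == 0L) next
      warning("malformed field line treated as continuation: ",
              substr(line, 1, 40), call. = FALSE)
      values[length(values)] <- paste(values[length(values)], trimws(line))
    }
  }
  if (!"PMID" %in% tags) {
    warning("record block without PMID skipped", call. = FALSE)
    return(NULL)
  }
  raw <- tibble::tibble(tag = tags, value = values)
  first_of <- function(tg) {
    v <- values[tags == tg]
    if (length(v)) v[[1]] else NA_character_
  }
  dp <- first_of("DP")
  tibble::tibble(
    pmid = first_of("PMID"),
    title = first_of("TI") %|na|% "",
    abstract = first_of("AB") %|na|% "",
    year = parse_year(dp),
    pub_types = list(values[tags == "PT"]),
    journal = first_of("JT"),
    raw_fields = list(raw)
  )
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

# First 4-digit token of a DP value; NA if absent or unparseable.
parse_year <- function(dp) {
  if (is.null(dp) || is.na(dp)) return(NA_integer_)
  m <- stringr::str_match(dp, "\\b(\\d{4})\\b")[, 2]
  if (is.na(m)) NA_integer_ else as.integer(m)
}

empty_corpus <- function(label = "corpus") {
  tibble::tibble(
    corpus = character(0), pmid = character(0), title = character(0),
    abstract = character(0), year = integer(0), pub_types = list(),
    journal = character(0), raw_fields = list()
  )[0, ]
}

#' Serialize citation records back to MEDLINE tagged format
#'
#' The inverse of [read_medline()]: re-parsing the output yields a corpus
#' identical on all mined fields (`pmid`, `title`, `abstract`, `year`,
#' `pub_types`). Values longer than the line width are wrapped at
#' single-space boundaries into six-space continuation lines; values
#' containing runs of multiple spaces are left unwrapped so the
#' join-with-one-space rule remains an exact inverse.
#'
#' @param records A citation tibble as returned by [read_medline()] or
#'   the fixture generator. If `raw_fields` is populated it is written
#'   verbatim (re-wrapped); otherwise fields are reconstructed from the
#'   structured columns.
#' @param path Optional output file; when `NULL` the text is returned.
#' @param width Maximum line width before wrapping (default 78).
#' @return The MEDLINE text as a single string (invisibly when `path`
#'   is given).
#' @export
write_medline <- function(records, path = NULL, width = 78) {
  if (nrow(records) == 0L) {
    txt <- ""
  } else {
    blocks <- purrr::pmap_chr(
      list(records$pmid, records$title, records$abstract,
           records$year, records$pub_types, records$journal,
           records$raw_fields),
      function(pmid, title, abstract, year, pts, journal, raw) {
        if (!is.null(raw) && nrow(raw) > 0L) {
          tags <- raw$tag; values <- raw$value
        } else {
          tags <- "PMID"; values <- pmid
          if (nzchar(title)) { tags <- c(tags, "TI"); values <- c(values, title) }
          if (nzchar(abstract)) { tags <- c(tags, "AB"); values <- c(values, abstract) }
          if (!is.na(year)) { tags <- c(tags, "DP"); values <- c(values, as.character(year)) }
          for (pt in pts) { tags <- c(tags, "PT"); values <- c(values, pt) }
          if (!is.null(journal) && !is.na(journal)) {
            tags <- c(tags, "JT"); values <- c(values, journal)
          }
        }
        paste(purrr::map2_chr(tags, values, format_medline_field, width = width),
              collapse = "\n")
      }
    )
    txt <- paste0(paste(blocks, collapse = "\n\n"), "\n")
  }
  if (is.null(path)) return(txt)
  readr::write_file(txt, path)
  invisible(txt)
}

format_medline_field <- function(tag, value, width = 78) {
  head_line <- sprintf("%-4s- ", tag)
  pieces <- wrap_at_single_spaces(value, width - nchar(head_line))
  lines <- c(paste0(head_line, pieces[[1]]),
             if (length(pieces) > 1) paste0(strrep(" ", 6), pieces[-1]))
  paste(lines, collapse = "\n")
}

# Greedy wrap at single-space boundaries only; multi-space runs are never
# split so that joining lines with one space reconstructs the value.
wrap_at_single_spaces <- function(value, width) {
  if (nchar(value) <= width || grepl("  ", value, fixed = TRUE)) {
    return(value)
  }
  words <- strsplit(value, " ", fixed = TRUE)[[1]]
  lines <- character(0)
  cur <- words[[1]]
  for (w in words[-1]) {
    if (nchar(cur) + 1L + nchar(w) <= width) {
      cur <- paste(cur, w)
    } else {
      lines <- c(lines, cur)
      cur <- w
    }
  }
  c(lines, cur)
}

#' Drop review articles from a corpus
#'
#' Mirrors the `NOT (Review[Publication Type])` clause of the PubMed
#' query: a record is excluded when any of its publication types equals
#' `"Review"` (case-insensitive exact token match). Record order is
#' preserved.
#'
#' @param records A citation tibble.
#' @return The tibble without review records.
#' @export
filter_reviews <- function(records) {
  keep <- !purrr::map_lgl(records$pub_types,
                          ~ any(tolower(.x) == "review"))
  records[keep, , drop = FALSE]
}

#' Text mined for mentions: title and abstract joined by one space
#'
#' All matchers operate on this concatenation; records with an empty
#' abstract are mined on the title alone (and vice versa).
#'
#' @param records A citation tibble.
#' @return A character vector, one mining text per record.
#' @export
mining_text <- function(records) {
  trimws(paste(records$title, records$abstract))
}

#' Export a corpus as a flat delimited table
#'
#' @param records A citation tibble.
#' @param path Output path for a CSV (pmid, year, title, abstract,
#'   pub_types joined by `|`).
#' @return The flattened tibble, invisibly when written.
#' @export
export_corpus_table <- function(records, path = NULL) {
  out <- tibble::tibble(
    pmid = records$pmid,
    year = records$year,
    title = records$title,
    abstract = records$abstract,
    pub_types = purrr::map_chr(records$pub_types, paste, collapse = "|")
  )
  if (is.null(path)) return(out)
  readr::write_csv(out, path)
  invisible(out)
}
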