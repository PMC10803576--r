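#' Per-article-deduplicated miRNA publication counts
#'
#' Counts, for each miRNA family, the number of records whose mining
#' text (title + abstract) mentions it. Each record contributes at most
#' one count per family regardless of how often the family is mentioned,
#' so counts are article counts, not mention counts.
#'
#' @param records A citation tibble (see [read_medline()]).
#' @return A tibble with columns `family` and `n`, sorted by decreasing
#'   count, ties broken by increasing family index.
#' @export
count_mirna_articles <- function(records) {
  fams <- extract_mirnas_list(mining_text(records))
  tally_families(fams)
}

tally_families <- function(fams) {
  all_f <- unlist(fams)
  if (length(all_f) == 0L) {
    return(tibble::tibble(family = character(0), n = integer(0)))
  }
  tab <- table(all_f)
  out <- tibble::tibble(family = names(tab), n = as.integer(tab))
  dplyr::arrange(out, dplyr::desc(.data$n), family_index(.data$family))
}

#' miRNA-family-by-term co-occurrence matrix
#'
#' Counts, once per article, records whose mining text both mentions a
#' miRNA family and matches a dictionary term. Returned in long form
#' with every (family, term) cell present, including zero cells, so
#' downstream layouts are fixed; columns are ordered by dictionary
#' category (`cell_type`, `cytokine`, `process`) then dictionary order.
#'
#' @param records A citation tibble.
#' @param dicts Dictionary tibble (default [default_dictionaries()]).
#' @param families Optional character vector restricting (and ordering)
#'   the matrix rows, e.g. the top-7 families of the corpus. `NULL`
#'   keeps every family observed in the corpus, sorted by index.
#' @return A tibble `family`, `category`, `term`, `n` whose attribute
#'   `corpus` carries the corpus label when the input has one.
#' @export
count_cooccurrence <- function(records, dicts = default_dictionaries(),
                               families = NULL) {
  texts <- mining_text(records)
  fams <- extract_mirnas_list(texts)
  terms <- match_terms_list(texts, dicts)

  if (is.null(families)) {
    families <- as.character(unique(unlist(fams)))
    families <- families[order(family_index(families))]
  }
  term_axis <- dplyr::distinct(dicts[, c("category", "canonical")])
  term_axis <- dplyr::rename(term_axis, term = "canonical")

  pairs <- purrr::map2(fams, terms, function(f, t) {
    f <- intersect(f, families)
    if (length(f) == 0L || nrow(t) == 0L) return(NULL)
    tibble::tibble(
      family = rep(f, each = nrow(t)),
      category = rep(t$category, times = length(f)),
      term = rep(t$canonical, times = length(f))
    )
  })
  counted <- dplyr::bind_rows(pairs)
  grid <- tidyr::expand_grid(family = families, term_axis)
  if (nrow(counted) == 0L) {
    out <- dplyr::mutate(grid, n = 0L)
  } else {
    cc <- dplyr::count(counted, .data$family, .data$category, .data$term)
    out <- dplyr::left_join(grid, cc,
                            by = c("family", "category", "term"))
    out$n <- as.integer(tidyr::replace_na(out$n, 0L))
  }
  lbl <- unique(records$corpus)
  if (length(lbl) == 1L) attr(out, "corpus") <- lbl
  out
}

#' Top-k most-published miRNA families
#'
#' Ranks families by article count, descending; ties are broken by
#' ascending family index (`miR-21` before `miR-125`) so rankings are
#' reproducible. Families with zero count never appear; the ranking is
#' truncated to `k` entries.
#'
#' @param counts A tibble with columns `family` and `n`, as returned by
#'   [count_mirna_articles()].
#' @param k Rank depth (default 7, the usual "top seven").
#' @return A tibble `rank`, `family`, `n` with attribute `k`.
#' @export
top_families <- function(counts, k = 7) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  out <- dplyr::filter(counts, .data$n >= 1L)
  out <- dplyr::arrange(out, dplyr::desc(.data$n), family_index(.data$family))
  out <- utils::head(out, k)
  out <- tibble::tibble(rank = seq_len(nrow(out)),
                        family = out$family, n = out$n)
  attr(out, "k") <- as.integer(k)
  out
}

#' Cross-corpus breadth of top-ranked families
#'
#' For each miRNA family appearing in at least one top-k ranking, counts
#' the number of corpora (diseases) in whose top-k it appears. A family
#' in the top seven of all nine disease corpora has breadth 9.
#'
#' @param rankings A named list of ranking tibbles from
#'   [top_families()], one per corpus; all must share the same `k`.
#' @return A tibble `family`, `n_corpora`, sorted by decreasing breadth
#'   then increasing family index.
#' @export
family_breadth <- function(rankings) {
  ks <- unique(purrr::map_int(rankings, ~ attr(.x, "k") %||% NA_integer_))
  if (length(ks) > 1L || anyNA(ks)) {
    stop("all rankings must share the same `k`", call. = FALSE)
  }
  fams <- unlist(purrr::map(rankings, "family"))
  if (length(fams) == 0L) {
    return(tibble::tibble(family = character(0), n_corpora = integer(0)))
  }
  tab <- table(fams)
  out <- tibble::tibble(family = names(tab), n_corpora = as.integer(tab))
  dplyr::arrange(out, dplyr::desc(.data$n_corpora),
                 family_index(.data$family))
}

#' Aggregate family counts across disease corpora
#'
#' Elementwise sum of per-corpus article counts. An article indexed in
#' two disease corpora counts once per corpus: the nine disease files
#' are processed independently, and a shared-PMID diagnostic is reported
#' separately by [mine_corpora()].
#'
#' @param counts_list A list of `family`/`n` tibbles, one per corpus.
#' @return A single `family`/`n` tibble with summed counts, in the
#'   standard count-descending order.
#' @export
aggregate_family_counts <- function(counts_list) {
  all <- dplyr::bind_rows(counts_list)
  if (nrow(all) == 0L) {
    return(tibble::tibble(family = character(0), n = integer(0)))
  }
  out <- dplyr::summarise(dplyr::group_by(all, .data$family),
                          n = sum(.data$n), .groups = "drop")
  out$n <- as.integer(out$n)
  dplyr::arrange(out, dplyr::desc(.data$n), family_index(.data$family))
}

#' Publications per year for a corpus
#'
#' @param records A citation tibble.
#' @param quiet Suppress the message reporting records without a
#'   parseable year (such records are excluded from the trend only,
#'   never from counts).
#' @return A tibble `year`, `n` sorted by year.
#' @export
yearly_trend <- function(records, quiet = FALSE) {
  n_missing <- sum(is.na(records$year))
  if (n_missing > 0L && !quiet) {
    message(n_missing, " record(s) without a parseable year excluded from trend")
  }
  yrs <- records$year[!is.na(records$year)]
  if (length(yrs) == 0L) {
    return(tibble::tibble(year = integer(0), n = integer(0)))
  }
  tab <- table(yrs)
  tibble::tibble(year = as.integer(names(tab)), n = as.integer(tab))
}
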