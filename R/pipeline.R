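#' Run the full literature-relevance pipeline over disease corpora
#'
#' Applies the review filter, then per corpus computes deduplicated
#' family article counts, the top-k ranking, the co-occurrence matrix
#' restricted to the top-k families, and the yearly publication trend;
#' across corpora it computes the aggregate family counts and the
#' breadth map (number of corpora in whose top-k each family appears).
#' The result is deterministic given the inputs.
#'
#' @param corpora A named list of citation tibbles (one per disease), or
#'   a single citation tibble whose `corpus` column labels the corpora.
#' @param dicts Dictionary tibble (default [default_dictionaries()]).
#' @param k Rank depth (default 7).
#' @param keep_reviews If `TRUE`, skip the review filter.
#' @param quiet Suppress progress messages.
#' @return A `mirmine_result` object: a list with elements
#'   `counts`, `rankings`, `cooccurrence`, `trends` (tibbles with a
#'   `corpus` column), `aggregate`, `breadth`, `shared_pmids`
#'   (diagnostic of PMIDs present in more than one corpus),
#'   `corpus_sizes`, `k`, and `dictionary_hash`.
#' @examples
#' fx <- simulate_disease_corpora(seed = 1, scale = 0.05)
#' res <- mine_corpora(fx$corpora)
#' tidy(res)
#' @export
mine_corpora <- function(corpora, dicts = default_dictionaries(), k = 7,
                         keep_reviews = FALSE, quiet = TRUE) {
  corpora <- as_corpus_list(corpora)
  if (length(corpora) < 1L) stop("need at least one corpus", call. = FALSE)

  mined <- if (keep_reviews) corpora else purrr::map(corpora, filter_reviews)

  counts <- purrr::map(mined, count_mirna_articles)
  rankings <- purrr::map(counts, top_families, k = k)
  coocs <- purrr::imap(mined, function(recs, lbl) {
    count_cooccurrence(recs, dicts, families = rankings[[lbl]]$family)
  })
  trends <- purrr::map(mined, yearly_trend, quiet = quiet)

  bind_labeled <- function(lst) {
    dplyr::bind_rows(purrr::imap(lst, ~ dplyr::mutate(.x, corpus = .y,
                                                      .before = 1)))
  }

  all_pmids <- dplyr::bind_rows(purrr::imap(
    mined, ~ tibble::tibble(corpus = .y, pmid = .x$pmid)))
  shared <- dplyr::filter(
    dplyr::count(dplyr::distinct(all_pmids), .data$pmid,
                 name = "n_corpora"),
    .data$n_corpora > 1L)

  structure(
    list(
      counts = bind_labeled(counts),
      rankings = bind_labeled(rankings),
      cooccurrence = bind_labeled(coocs),
      trends = bind_labeled(trends),
      aggregate = aggregate_family_counts(counts),
      breadth = family_breadth(rankings),
      shared_pmids = dplyr::arrange(shared, .data$pmid),
      corpus_sizes = tibble::tibble(
        corpus = names(mined),
        n_records = purrr::map_int(corpora, nrow),
        n_after_review_filter = purrr::map_int(mined, nrow)
      ),
      k = as.integer(k),
      keep_reviews = keep_reviews,
      dictionary_hash = dictionary_hash(dicts)
    ),
    class = "mirmine_result"
  )
}

as_corpus_list <- function(corpora) {
  if (is.data.frame(corpora)) {
    stopifnot("corpus" %in% names(corpora))
    corpora <- split(corpora, factor(corpora$corpus,
                                     levels = unique(corpora$corpus)))
  }
  if (is.null(names(corpora)) || any(!nzchar(names(corpora)))) {
    lbl <- purrr::map_chr(corpora, ~ unique(.x$corpus)[1] %||% NA_character_)
    if (anyNA(lbl)) stop("corpora must be named", call. = FALSE)
    names(corpora) <- lbl
  }
  if (anyDuplicated(names(corpora))) {
    stop("corpus labels must be unique", call. = FALSE)
  }
  corpora
}

#' @export
print.mirmine_result <- function(x, ...) {
  cat("<mirmine_result>\n")
  cat("  corpora:   ", nrow(x$corpus_sizes), " (",
      sum(x$corpus_sizes$n_after_review_filter), " records after review filter)\n",
      sep = "")
  cat("  families:  ", nrow(x$aggregate), " distinct, top-k depth k = ",
      x$k, "\n", sep = "")
  if (nrow(x$aggregate) > 0) {
    top <- utils::head(x$aggregate, 3)
    cat("  most published: ",
        paste(sprintf("%s (%d)", top$family, top$n), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a pipeline result into its per-corpus rankings
#'
#' @param x A `mirmine_result`.
#' @param ... Unused.
#' @return The rankings tibble (`corpus`, `rank`, `family`, `n`).
#' @exportS3Method generics::tidy
tidy.mirmine_result <- function(x, ...) {
  x$rankings
}

#' One-row summary of a pipeline result
#'
#' @param x A `mirmine_result`.
#' @param ... Unused.
#' @return A one-row tibble: number of corpora, records mined, distinct
#'   families, rank depth, maximum breadth, and the most-published
#'   family with its aggregate count.
#' @exportS3Method generics::glance
glance.mirmine_result <- function(x, ...) {
  tibble::tibble(
    n_corpora = nrow(x$corpus_sizes),
    n_records = sum(x$corpus_sizes$n_after_review_filter),
    n_families = nrow(x$aggregate),
    k = x$k,
    max_breadth = if (nrow(x$breadth)) max(x$breadth$n_corpora) else 0L,
    top_family = if (nrow(x$aggregate)) x$aggregate$family[1] else NA_character_,
    top_family_n = if (nrow(x$aggregate)) x$aggregate$n[1] else NA_integer_
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
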