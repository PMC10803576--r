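# Synthetic MEDLINE corpora with sampling-time ground truth.
#
# The generator records which families and terms it put into each record
# BEFORE rendering them through noisy surface forms, so the truth tables
# are an oracle that is independent of the extraction/matching path they
# are used to test.

# Filler vocabulary: verified disjoint from every dictionary variant and
# free of miR-like tokens and digits (tested by running both matchers
# over filler-only text).
.filler_words <- c(
  "we", "examined", "expression", "profiles", "in", "synovium", "from",
  "patients", "using", "quantitative", "assays", "and", "observed",
  "altered", "levels", "of", "the", "candidate", "molecules", "under",
  "study", "these", "findings", "were", "consistent", "across",
  "cohorts", "suggesting", "a", "role", "for", "post-transcriptional",
  "control", "during", "disease", "onset", "further", "work", "is",
  "needed", "to", "establish", "causality", "within", "this", "context",
  "samples", "showed", "marked", "changes", "relative", "controls"
)

.species_prefixes <- c("", "hsa-", "mmu-", "rno-")
.prefix_spellings <- c("miR", "miR", "miR", "miRNA", "microRNA", "micro RNA")

#' Specify a synthetic corpus
#'
#' @param seed Integer seed; the same spec always renders byte-identical
#'   MEDLINE text.
#' @param n_records Number of citation records.
#' @param family_probs Named numeric vector: per-record inclusion
#'   probability of each miRNA family (names must be `"miR-N"`).
#' @param term_probs Tibble `category`, `term`, `prob`: per-record
#'   inclusion probability of each dictionary term.
#' @param review_prob Probability a record is tagged `Review`.
#' @param year_range Inclusive integer pair for publication years.
#' @param surface_noise If `TRUE`, mentions are rendered through random
#'   surface forms (species prefixes, arm suffixes, spelling and case
#'   variants, plural terms) that the matchers must still resolve.
#' @param label Corpus label.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed, n_records, family_probs, term_probs,
                         review_prob = 0.1, year_range = c(1994L, 2022L),
                         surface_noise = TRUE, label = "synthetic") {
  if (length(family_probs) > 0) {
    if (is.null(names(family_probs)) ||
        !all(grepl("^miR-[0-9]+$", names(family_probs)))) {
      stop("family_probs names must be canonical \"miR-N\" identifiers",
           call. = FALSE)
    }
  }
  probs <- c(unname(family_probs), term_probs$prob, review_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(year_range) == 2L, year_range[1] <= year_range[2],
            n_records >= 0)
  structure(
    list(seed = as.integer(seed), n_records = as.integer(n_records),
         family_probs = family_probs, term_probs = term_probs,
         review_prob = review_prob, year_range = as.integer(year_range),
         surface_noise = isTRUE(surface_noise), label = label),
    class = "fixture_spec"
  )
}

#' Uniform term-probability table over the default dictionaries
#'
#' @param prob Single probability applied to every term, or a vector
#'   recycled across terms.
#' @param dicts Dictionary tibble.
#' @return A `category`/`term`/`prob` tibble for [fixture_spec()].
#' @export
uniform_term_probs <- function(prob = 0.15, dicts = default_dictionaries()) {
  tibble::tibble(category = dicts$category, term = dicts$canonical,
                 prob = rep_len(prob, nrow(dicts)))
}

#' Generate a synthetic MEDLINE corpus and its ground truth
#'
#' Each record's title and abstract embed, in filler sentences, exactly
#' the families and terms sampled for it, rendered through surface forms
#' that normalize/match back to the sampled identifiers; the filler
#' vocabulary triggers neither matcher. Ground truth is recorded at
#' sampling time, so the returned truth tables are an independent oracle
#' for the counting engine.
#'
#' @param spec A [fixture_spec()].
#' @param dicts Dictionary tibble used to pick safe surface variants.
#' @return A list:
#'   \describe{
#'     \item{records}{citation tibble (as from [read_medline()])}
#'     \item{medline}{the corpus as MEDLINE tagged text}
#'     \item{truth}{per-record tibble of sampled `families`, `terms`,
#'       `year`, `is_review`}
#'   }
#' @export
generate_corpus <- function(spec, dicts = default_dictionaries()) {
  stopifnot(inherits(spec, "fixture_spec"))
  safe <- safe_surface_variants(dicts)
  withr::with_seed(spec$seed, {
    n <- spec$n_records
    fams <- purrr::map(seq_len(max(n, 0)), function(i) {
      p <- spec$family_probs
      names(p)[stats::runif(length(p)) < p]
    })
    trms <- purrr::map(seq_len(max(n, 0)), function(i) {
      keep <- stats::runif(nrow(spec$term_probs)) < spec$term_probs$prob
      spec$term_probs[keep, c("category", "term")]
    })
    is_review <- stats::runif(n) < spec$review_prob
    years <- if (n > 0) {
      sample(seq(spec$year_range[1], spec$year_range[2]), n, replace = TRUE)
    } else integer(0)

    rendered <- purrr::map2(fams, trms, render_record,
                            noise = spec$surface_noise, safe = safe)
    records <- tibble::tibble(
      corpus = rep(spec$label, n),
      pmid = as.character(seq_len(max(n, 0))),
      title = purrr::map_chr(rendered, "title"),
      abstract = purrr::map_chr(rendered, "abstract"),
      year = as.integer(years),
      pub_types = purrr::map(is_review,
                             ~ if (.x) c("Journal Article", "Review")
                               else "Journal Article"),
      journal = rep(NA_character_, n),
      raw_fields = rep(list(NULL), n)
    )
    if (n == 0L) records <- empty_corpus(spec$label)
    truth <- tibble::tibble(
      pmid = records$pmid,
      families = fams,
      terms = trms,
      year = records$year,
      is_review = is_review
    )
    list(records = records, medline = write_medline(records), truth = truth)
  })
}

# Surface variants whose match set is exactly their own canonical term.
# Variants that also hit another entry (e.g. "interleukin-6" hits the
# generic "interleukin") are excluded so sampling-time truth stays exact;
# forms like "IL-17", which must NOT count as "IL-1", stay in and
# exercise the matcher guards. Plural forms of cell-type terms are added
# when they remain safe.
safe_surface_variants <- function(dicts) {
  vt <- variant_table(dicts)
  candidates <- dplyr::bind_rows(
    vt[, c("category", "canonical", "variant")],
    dplyr::mutate(
      dplyr::filter(vt, .data$category == "cell_type",
                    !stringr::str_detect(.data$variant, "[ -]$")),
      variant = paste0(.data$variant, "s")
    )[, c("category", "canonical", "variant")]
  )
  candidates <- dplyr::distinct(candidates)
  hits <- match_terms_list(candidates$variant, dicts)
  ok <- purrr::map_lgl(seq_len(nrow(candidates)), function(i) {
    h <- hits[[i]]
    nrow(h) == 1L && h$category == candidates$category[i] &&
      h$canonical == candidates$canonical[i]
  })
  split(candidates$variant[ok],
        paste(candidates$category[ok], candidates$canonical[ok], sep = "\r"))
}

# Random surface form of a family that normalizes back to it.
render_family_mention <- function(family, noise) {
  if (!noise) return(family)
  idx <- sub("^miR-", "", family)
  spelling <- sample(.prefix_spellings, 1)
  species <- if (spelling == "miR") sample(.species_prefixes, 1) else ""
  sep <- sample(c("-", "-", "-", "", " "), 1)
  letter <- sample(c("", "", "a", "b"), 1)
  paralog <- if (nzchar(letter)) sample(c("", "", "-1", "-2"), 1) else ""
  arm <- sample(c("", "", "", "-3p", "-5p"), 1)
  tok <- paste0(species, spelling, sep, idx, letter, paralog, arm)
  if (stats::runif(1) < 0.15) tok <- toupper(tok)
  else if (stats::runif(1) < 0.15) tok <- tolower(tok)
  tok
}

render_term_mention <- function(category, term, noise, safe) {
  pool <- safe[[paste(category, term, sep = "\r")]]
  if (is.null(pool) || length(pool) == 0L) pool <- term
  tok <- if (noise) sample(pool, 1) else pool[[1]]
  if (noise && stats::runif(1) < 0.2) tok <- toupper(tok)
  tok
}

# Assemble title/abstract sentences; every mention is separated by at
# least one filler word so multi-word variants cannot form by adjacency.
render_record <- function(families, terms, noise, safe) {
  mentions <- c(
    purrr::map_chr(families, render_family_mention, noise = noise),
    if (nrow(terms) > 0)
      purrr::map2_chr(terms$category, terms$term, render_term_mention,
                      noise = noise, safe = safe)
  )
  if (length(mentions) > 1) mentions <- sample(mentions)
  phrase <- function(m) {
    paste(c(sample(.filler_words, sample(2:4, 1), replace = TRUE), m),
          collapse = " ")
  }
  filler_sentence <- paste(
    sample(.filler_words, sample(4:8, 1), replace = TRUE), collapse = " ")
  n_title <- min(length(mentions), sample(0:2, 1))
  title_m <- mentions[seq_len(n_title)]
  abs_m <- mentions[-seq_len(n_title)]
  if (n_title == 0L) abs_m <- mentions
  title <- paste0(
    paste(c(purrr::map_chr(title_m, phrase),
            sample(.filler_words, 3, replace = TRUE)), collapse = " "), ".")
  abstract <- paste0(
    paste(c(filler_sentence,
            purrr::map_chr(abs_m, phrase)), collapse = " "), ".")
  list(title = title, abstract = abstract)
}

#' Brute-force truth tables from sampling-time record truth
#'
#' Recomputes, by definition (direct enumeration over the per-record
#' sampled sets), the tables the counting engine must reproduce:
#' deduplicated family article counts, family-by-term co-occurrence
#' counts, yearly trends, and the review count.
#'
#' @param truth The `truth` tibble from [generate_corpus()].
#' @param dicts Dictionary tibble (fixes the term axis of the
#'   co-occurrence table).
#' @param keep_reviews If `FALSE` (default), review-tagged records are
#'   dropped first, matching the pipeline's review filter.
#' @return A list of tibbles: `family_counts`, `cooccurrence`,
#'   `trend`, plus `n_reviews` and `n_records`.
#' @export
truth_tables <- function(truth, dicts = default_dictionaries(),
                         keep_reviews = FALSE) {
  kept <- if (keep_reviews) truth else truth[!truth$is_review, , drop = FALSE]
  family_counts <- tally_families(kept$families)

  families <- as.character(unique(unlist(kept$families)))
  families <- families[order(family_index(families))]
  term_axis <- dplyr::rename(
    dplyr::distinct(dicts[, c("category", "canonical")]), term = "canonical")
  grid <- tidyr::expand_grid(family = families, term_axis)
  pairs <- dplyr::bind_rows(purrr::map2(kept$families, kept$terms,
    function(f, t) {
      if (length(f) == 0L || nrow(t) == 0L) return(NULL)
      tibble::tibble(family = rep(f, each = nrow(t)),
                     category = rep(t$category, times = length(f)),
                     term = rep(t$term, times = length(f)))
    }))
  cooc <- if (nrow(pairs) == 0L) {
    dplyr::mutate(grid, n = 0L)
  } else {
    cc <- dplyr::count(pairs, .data$family, .data$category, .data$term)
    out <- dplyr::left_join(grid, cc, by = c("family", "category", "term"))
    out$n <- as.integer(tidyr::replace_na(out$n, 0L))
    out
  }
  yrs <- kept$year[!is.na(kept$year)]
  trend <- if (length(yrs) == 0L) {
    tibble::tibble(year = integer(0), n = integer(0))
  } else {
    tab <- table(yrs)
    tibble::tibble(year = as.integer(names(tab)), n = as.integer(tab))
  }
  list(family_counts = family_counts, cooccurrence = cooc, trend = trend,
       n_reviews = sum(truth$is_review), n_records = nrow(truth))
}

# Paper-shaped nine-disease corpus sizes (primary-article counts of the
# 2023 snapshot the study design describes); the packaged fixture keeps
# the shape and scales the sizes down.
.disease_sizes <- c(
  "ankylosing spondylitis" = 113L, "gout" = 32L,
  "juvenile idiopathic arthritis" = 21L, "osteoarthritis" = 1277L,
  "psoriatic arthritis" = 24L, "rheumatoid arthritis" = 822L,
  "Sjogren's syndrome" = 74L, "systemic lupus erythematosus" = 417L,
  "systemic sclerosis" = 103L
)

.fixture_family_pool <- c(
  "miR-21", "miR-223", "miR-125", "miR-124", "miR-26", "miR-34",
  "miR-145", "miR-140", "miR-20", "miR-196", "miR-17", "miR-29"
)

#' Nine-disease demonstration fixture
#'
#' Generates one synthetic corpus per rheumatic disease, with sizes
#' proportional to the nine-corpus design (scaled by `scale`) and
#' skewed family probabilities: `miR-146` and `miR-155` are included
#' with probability 1 in every corpus, so by construction they rank in
#' every top-7 and reach breadth 9; the remaining pool families get
#' corpus-specific random probabilities.
#'
#' @param seed Integer seed; reruns with the same seed produce identical
#'   corpora and truths.
#' @param scale Multiplier on the nine corpus sizes (default 0.25; a
#'   minimum of 10 records per corpus is enforced).
#' @param dicts Dictionary tibble.
#' @return A list with `corpora` (named list of citation tibbles),
#'   `truths` (named list of truth tibbles), and `specs`.
#' @export
simulate_disease_corpora <- function(seed = 20230829, scale = 0.25,
                                     dicts = default_dictionaries()) {
  sizes <- stats::setNames(pmax(10L, as.integer(round(.disease_sizes * scale))),
                           names(.disease_sizes))
  sub_seeds <- withr::with_seed(seed, {
    sample.int(.Machine$integer.max - 1L, length(sizes) * 2L)
  })
  out <- purrr::imap(stats::setNames(seq_along(sizes), names(sizes)),
    function(i, disease) {
      pool_probs <- withr::with_seed(sub_seeds[2L * i - 1L], {
        stats::setNames(stats::runif(length(.fixture_family_pool), 0.03, 0.45),
                        .fixture_family_pool)
      })
      spec <- fixture_spec(
        seed = sub_seeds[2L * i],
        n_records = sizes[[i]],
        family_probs = c("miR-146" = 1.0, "miR-155" = 1.0, pool_probs),
        term_probs = uniform_term_probs(0.12, dicts),
        review_prob = 0.12,
        year_range = c(1994L, 2022L),
        surface_noise = TRUE,
        label = disease
      )
      generate_corpus(spec, dicts)
    })
  list(
    corpora = purrr::map(out, "records"),
    truths = purrr::map(out, "truth"),
    specs = NULL
  )
}
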