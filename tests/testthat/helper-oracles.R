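# Independent oracles and small fixture helpers shared across tests.

# Brute-force extraction oracle: enumerate every substring of the text,
# test it against an anchored restatement of the mention grammar, check
# the word boundaries on the adjacent characters, normalize, dedup.
# Deliberately written without reusing the package's scanning path.
oracle_token_re <- paste0(
  "^(?:[a-z]{3}-)?(?:micro[ -]?rna|mirna|mir)[- ]?",
  "[0-9]+[a-z]?(?:-(?:[35]p|[0-9]+))*$"
)

oracle_extract <- function(text) {
  n <- nchar(text)
  fams <- character(0)
  for (i in seq_len(n)) {
    before <- if (i == 1) "" else substr(text, i - 1, i - 1)
    if (grepl("\\w", before)) next
    for (j in i:min(n, i + 40)) {
      after <- if (j == n) "" else substr(text, j + 1, j + 1)
      if (grepl("\\w", after)) next
      tok <- substr(text, i, j)
      if (grepl(oracle_token_re, tok, perl = TRUE, ignore.case = TRUE)) {
        fams <- c(fams, normalize_mirna(tok))
      }
    }
  }
  fams <- unique(fams)
  fams[order(family_index(fams))]
}

# Brute-force per-article counting oracle: double loop over records and
# families/terms, one increment per record at most.
oracle_family_counts <- function(records) {
  tab <- integer(0)
  for (i in seq_len(nrow(records))) {
    fams <- extract_mirnas(mining_text(records[i, ]))
    for (f in fams) tab[f] <- (if (f %in% names(tab)) tab[[f]] else 0L) + 1L
  }
  if (length(tab) == 0L) {
    return(tibble::tibble(family = character(0), n = integer(0)))
  }
  out <- tibble::tibble(family = names(tab), n = unname(tab))
  dplyr::arrange(out, dplyr::desc(n), family_index(family))
}

# A small record tibble built in code.
make_records <- function(titles, abstracts = rep("", length(titles)),
                         years = rep(2020L, length(titles)),
                         pub_types = NULL, label = "test") {
  n <- length(titles)
  if (is.null(pub_types)) pub_types <- rep(list("Journal Article"), n)
  tibble::tibble(
    corpus = rep(label, n),
    pmid = as.character(seq_len(n)),
    title = titles,
    abstract = abstracts,
    year = as.integer(years),
    pub_types = pub_types,
    journal = rep(NA_character_, n),
    raw_fields = rep(list(NULL), n)
  )
}

# A randomized fixture spec for property tests.
random_fixture_spec <- function(seed, n_max = 150) {
  withr::with_seed(seed, {
    fam_pool <- paste0("miR-", sample(c(1:30, 120:230, 1200:1300), 8))
    fixture_spec(
      seed = sample.int(1e6, 1),
      n_records = sample.int(n_max, 1),
      family_probs = stats::setNames(stats::runif(8, 0.05, 0.9), fam_pool),
      term_probs = uniform_term_probs(stats::runif(1, 0.05, 0.3)),
      review_prob = stats::runif(1, 0, 0.3),
      year_range = c(1994L, 2022L),
      surface_noise = sample(c(TRUE, FALSE), 1)
    )
  })
}
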