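test_that("family counts are per-article deduplicated", {
  recs <- make_records(
    c("miR-155 and again miR-155 here", "one miR-155 mention", "none"),
    c("hsa-miR-155-5p repeated", "", ""))
  counts <- count_mirna_articles(recs)
  expect_equal(counts, tibble::tibble(family = "miR-155", n = 2L))
  expect_equal(nrow(count_mirna_articles(recs[0, ])), 0L)
})

test_that("family counts agree with the brute-force loop oracle", {
  withr::with_seed(55, {
    for (i in 1:5) {
      fx <- generate_corpus(random_fixture_spec(300 + i, n_max = 60))
      expect_equal(count_mirna_articles(fx$records),
                   oracle_family_counts(fx$records))
    }
  })
})

test_that("co-occurrence counts pair families and terms once per article", {
  recs <- make_records("miR-146 suppresses inflammation in fibroblasts")
  m <- count_cooccurrence(recs)
  expect_equal(m$n[m$family == "miR-146" & m$term == "inflammation"], 1L)
  expect_equal(m$n[m$family == "miR-146" & m$term == "fibroblast"], 1L)
  expect_equal(sum(m$n), 2L)
  # zero cells are retained for the full dictionary axis
  expect_equal(nrow(m), nrow(default_dictionaries()))
  # empty corpus: empty family axis, all-zero matrix
  expect_equal(nrow(count_cooccurrence(recs[0, ])), 0L)
})

test_that("row restriction limits and orders the matrix rows", {
  recs <- make_records(c("miR-21 and miR-9 in inflammation",
                         "miR-9 alone with pain"))
  m <- count_cooccurrence(recs, families = c("miR-21", "miR-9"))
  expect_equal(unique(m$family), c("miR-21", "miR-9"))
  m2 <- count_cooccurrence(recs, families = "miR-21")
  expect_equal(unique(m2$family), "miR-21")
  expect_equal(m2$n[m2$term == "inflammation"], 1L)
})

test_that("every matrix cell respects the marginal bound", {
  withr::with_seed(66, {
    for (i in 1:5) {
      fx <- generate_corpus(random_fixture_spec(400 + i, n_max = 80))
      recs <- fx$records
      counts <- count_mirna_articles(recs)
      m <- count_cooccurrence(recs)
      texts <- mining_text(recs)
      per_record <- purrr::map(texts, match_terms)
      term_keys <- unlist(purrr::map(per_record,
                                     ~ paste(.x$category, .x$canonical)))
      margin_tab <- table(term_keys)
      term_margin <- as.integer(margin_tab[paste(m$category, m$term)])
      term_margin[is.na(term_margin)] <- 0L
      fam_margin <- counts$n[match(m$family, counts$family)]
      expect_true(all(m$n <= pmin(fam_margin, term_margin)))
      expect_true(all(m$n <= nrow(recs)))
    }
  })
})

test_that("top_families ranks by count then ascending family index", {
  counts <- tibble::tibble(family = c("miR-146", "miR-155", "miR-223", "miR-21"),
                           n = c(94L, 77L, 37L, 29L))
  r <- top_families(counts, k = 2)
  expect_equal(r$family, c("miR-146", "miR-155"))
  expect_equal(r$n, c(94L, 77L))
  expect_equal(r$rank, 1:2)
  # tie break: lower family index wins
  tie <- tibble::tibble(family = c("miR-5", "miR-2"), n = c(3L, 3L))
  expect_equal(top_families(tie, k = 1)$family, "miR-2")
  # zero-count families never appear; empty input gives empty ranking
  z <- tibble::tibble(family = c("miR-1", "miR-2"), n = c(0L, 2L))
  expect_equal(top_families(z, k = 5)$family, "miR-2")
  expect_equal(nrow(top_families(tibble::tibble(family = character(0),
                                                n = integer(0)), k = 7)), 0L)
  expect_error(top_families(counts, k = 0), "k")
})

test_that("top-k is stable under removal of low-ranked families", {
  withr::with_seed(88, {
    for (i in 1:5) {
      fx <- generate_corpus(random_fixture_spec(500 + i, n_max = 120))
      counts <- count_mirna_articles(fx$records)
      k <- 3
      full <- top_families(counts, k)
      keep <- utils::head(counts, k + 1)  # counts are already sorted
      expect_equal(top_families(keep, k), full)
    }
  })
})

test_that("breadth counts rankings containing each family", {
  mk <- function(fams, k = 7) {
    r <- tibble::tibble(rank = seq_along(fams), family = fams,
                        n = rev(seq_along(fams)))
    attr(r, "k") <- k
    r
  }
  rankings <- list(a = mk(c("miR-146", "miR-21")),
                   b = mk(c("miR-146", "miR-9")),
                   c = mk("miR-146"))
  b <- family_breadth(rankings)
  expect_equal(b$n_corpora[b$family == "miR-146"], 3L)
  expect_equal(b$n_corpora[b$family == "miR-21"], 1L)
  expect_false("miR-999" %in% b$family)
  expect_true(all(b$n_corpora <= length(rankings)))
  expect_error(family_breadth(list(mk("miR-1", k = 7), mk("miR-1", k = 5))),
               "same `k`")
})

test_that("aggregate counts sum elementwise across corpora", {
  a <- tibble::tibble(family = "miR-21", n = 29L)
  b <- tibble::tibble(family = c("miR-21", "miR-146"), n = c(39L, 94L))
  agg <- aggregate_family_counts(list(a, b))
  expect_equal(agg$n[agg$family == "miR-21"], 68L)
  expect_equal(agg$n[agg$family == "miR-146"], 94L)
  expect_equal(aggregate_family_counts(list(a)), a)
  expect_equal(nrow(aggregate_family_counts(list())), 0L)
})

test_that("yearly trend counts parseable years and excludes the rest", {
  recs <- make_records(c("a", "b", "c"), years = c(2020L, 2020L, 2022L))
  expect_equal(yearly_trend(recs, quiet = TRUE),
               tibble::tibble(year = c(2020L, 2022L), n = c(2L, 1L)))
  recs$year[2] <- NA_integer_
  expect_message(tr <- yearly_trend(recs), "1 record")
  expect_equal(sum(tr$n), 2L)
  expect_equal(nrow(yearly_trend(recs[0, ], quiet = TRUE)), 0L)
})

test_that("all counting results are permutation and duplication invariant", {
  withr::with_seed(99, {
    fx <- generate_corpus(random_fixture_spec(600, n_max = 80))
    recs <- fx$records
    perm <- recs[sample(nrow(recs)), ]
    expect_equal(count_mirna_articles(perm), count_mirna_articles(recs))
    expect_equal(dplyr::arrange(count_cooccurrence(perm), family, category, term),
                 dplyr::arrange(count_cooccurrence(recs), family, category, term),
                 ignore_attr = TRUE)
    expect_equal(yearly_trend(perm, quiet = TRUE),
                 yearly_trend(recs, quiet = TRUE))

    # duplicating a mention inside a record changes nothing
    rich <- which(purrr::map_int(mining_text(recs),
                                 ~ length(extract_mirnas(.x))) > 0)[1]
    expect_false(is.na(rich))
    dup_mention <- recs
    dup_mention$abstract[rich] <- paste(dup_mention$abstract[rich],
                                        dup_mention$abstract[rich])
    expect_equal(count_mirna_articles(dup_mention),
                 count_mirna_articles(recs))

    # duplicating the record under a new pmid increments its counts by 1
    extra <- recs[rich, ]
    extra$pmid <- "duplicate"
    more <- dplyr::bind_rows(recs, extra)
    c0 <- count_mirna_articles(recs)
    c1 <- count_mirna_articles(more)
    fams <- extract_mirnas(mining_text(recs[rich, ]))
    for (f in fams) {
      expect_equal(c1$n[c1$family == f], c0$n[c0$family == f] + 1L)
    }
  })
})
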