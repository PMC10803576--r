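test_that("a tagged block parses into one record with joined continuations", {
  txt <- paste0("PMID- 1\nTI  - miR-21 in lupus\n      nephritis.\n",
                "AB  - We studied miR-21.\nDP  - 2020 Jan 9\n",
                "PT  - Journal Article\n")
  rec <- read_medline(txt, text = TRUE)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$pmid, "1")
  expect_equal(rec$title, "miR-21 in lupus nephritis.")
  expect_equal(rec$abstract, "We studied miR-21.")
  expect_equal(rec$year, 2020L)
  expect_equal(rec$pub_types[[1]], "Journal Article")
})

test_that("empty input and blank-line separation behave structurally", {
  expect_equal(nrow(read_medline("", text = TRUE)), 0L)
  two <- "PMID- 1\nTI  - first\n\nPMID- 2\nTI  - second\n"
  rec <- read_medline(two, text = TRUE)
  expect_equal(rec$pmid, c("1", "2"))
  # extra blank lines and trailing whitespace change nothing
  messy <- "PMID- 1  \nTI  - first\t\n\n\n\nPMID- 2\nTI  - second\n\n"
  expect_equal(read_medline(messy, text = TRUE)$title,
               c("first", "second"))
})

test_that("blocks without PMID are skipped and malformed lines absorbed", {
  txt <- "TI  - orphan title\n\nPMID- 9\nTI  - kept\nstray line\n"
  expect_warning(expect_warning(rec <- read_medline(txt, text = TRUE),
                                "without PMID"),
                 "malformed")
  expect_equal(rec$pmid, "9")
  expect_equal(rec$title, "kept stray line")
})

test_that("repeated PT tags accumulate and year comes from first 4-digit token", {
  txt <- paste0("PMID- 3\nPT  - Journal Article\nPT  - Clinical Trial\n",
                "DP  - 1999 Dec\n")
  rec <- read_medline(txt, text = TRUE)
  expect_equal(rec$pub_types[[1]], c("Journal Article", "Clinical Trial"))
  expect_equal(rec$year, 1999L)
  expect_true(is.na(read_medline("PMID- 4\nDP  - winter\n",
                                 text = TRUE)$year))
  expect_true(is.na(read_medline("PMID- 5\n", text = TRUE)$year))
})

test_that("write_medline is an exact inverse on mined fields", {
  expect_equal(write_medline(make_records(character(0))[0, ]), "")
  for (seed in c(11, 12, 13)) {
    fx <- generate_corpus(random_fixture_spec(seed))
    rt <- read_medline(fx$medline, label = unique(fx$records$corpus),
                       text = TRUE)
    expect_equal(rt$pmid, fx$records$pmid)
    expect_equal(rt$title, fx$records$title)
    expect_equal(rt$abstract, fx$records$abstract)
    expect_equal(rt$year, fx$records$year)
    expect_equal(rt$pub_types, fx$records$pub_types)
  }
})

test_that("long values wrap to continuation lines and join back exactly", {
  long_abs <- paste(rep("alpha beta gamma delta", 20), collapse = " ")
  rec <- make_records("t", long_abs)
  txt <- write_medline(rec)
  expect_true(any(grepl("^ {6}", strsplit(txt, "\n")[[1]])))
  expect_identical(read_medline(txt, text = TRUE)$abstract, long_abs)
  # a 300-character unbroken value is emitted unwrapped, byte-identical
  blob <- strrep("x", 300)
  rt <- read_medline(write_medline(make_records("t", blob)), text = TRUE)
  expect_identical(rt$abstract, blob)
  # runs of multiple spaces survive because such values are never wrapped
  spaced <- paste0(strrep("word ", 30), "double  spaced tail")
  rt2 <- read_medline(write_medline(make_records("t", spaced)), text = TRUE)
  expect_identical(rt2$abstract, spaced)
})

test_that("greek letters survive the io path", {
  txt <- "PMID- 1\nAB  - IL-1β and TNF-α signalling via NF-κB.\n"
  rec <- read_medline(txt, text = TRUE)
  expect_match(rec$abstract, "IL-1β")
  rt <- read_medline(write_medline(rec), text = TRUE)
  expect_identical(rt$abstract, rec$abstract)
})

test_that("filter_reviews drops any record carrying a Review type", {
  recs <- make_records(
    c("a", "b", "c"),
    pub_types = list("Journal Article",
                     c("Journal Article", "Review"),
                     "review"))
  kept <- filter_reviews(recs)
  expect_equal(kept$pmid, "1")
  n_reviews <- sum(purrr::map_lgl(recs$pub_types,
                                  ~ any(tolower(.x) == "review")))
  expect_equal(nrow(kept) + n_reviews, nrow(recs))
  # corpus without reviews is untouched, order preserved
  clean <- make_records(c("x", "y"))
  expect_identical(filter_reviews(clean), clean)
})

test_that("export_corpus_table flattens pub_types with pipes", {
  recs <- make_records("t", pub_types = list(c("Journal Article", "Letter")))
  tbl <- export_corpus_table(recs)
  expect_equal(tbl$pub_types, "Journal Article|Letter")
  expect_named(tbl, c("pmid", "year", "title", "abstract", "pub_types"))
})
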