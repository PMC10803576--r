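---
title: "Counting miRNA relevance in disease literature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting miRNA relevance in disease literature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mirmine)
```

## The counting model

`mirmine` treats a literature corpus as a bag of articles and asks one
question per article: *which miRNA families and which concepts does
this article mention at all?* Every downstream statistic is built from
those per-article sets.

For a corpus $A$ (one disease), the mining text of article $a$ is its
title and abstract joined by a single space. Let $M(a)$ be the set of
miRNA families extracted from that text and $T(a)$ the set of matched
dictionary terms. Then

- publication count: $N(f) = |\{a \in A : f \in M(a)\}|$,
- co-occurrence: $C(f,t) = |\{a \in A : f \in M(a),\ t \in T(a)\}|$,
- top-$k$ ranking: the $k$ families with largest $N(f)$,
- breadth: the number of corpora in whose top-$k$ a family appears,
- trend: articles per publication year.

Because counts are over sets, they are deduplicated per article by
construction: repeating a mention inside an abstract changes nothing,
and shuffling the article order changes nothing. Both invariants are
property-tested. Cell bounds follow immediately:
$C(f,t) \le \min(N(f), N(t)) \le |A|$.

The assumption doing the work here is that *mention co-occurrence in a
title/abstract approximates research relevance*. That is a bibliometric
proxy, not a biological claim: an article that mentions `miR-146` and
`inflammation` need not link them causally, and the counts inherit
whatever selection the underlying query imposed.

## Mention grammar and normalization

The extraction rule is "a miR-like prefix followed by a number". The
grammar accepts, case-insensitively: an optional three-letter species
prefix (`hsa-`, `mmu-`, `rno-`, ...), one of the spellings `microRNA`,
`micro RNA`, `miRNA`, `miR` (all three spellings appear in the query
that typically produces these corpora, so all are mined), an optional
hyphen or single space, digits, an optional paralog letter, and any run
of `-<digits>` or `-3p`/`-5p` tails, with word boundaries on both
sides. Normalization keeps only the first integer: lettered paralogs
(`miR-146a/b`), arms (`-5p`), paralog indices (`-1`, `-2`) and species
prefixes all collapse onto the family identifier `miR-N`, which is the
level at which publication counts are aggregated.

Deliberate consequences of this grammar:

- Cluster notations (`miR-17-92`) are one token normalizing to the
  first integer, `miR-17`; the cluster is not split into two mentions.
- The space-separated form `miR 146` is accepted. This is the loosest
  point of the grammar; an analyst wanting hyphen-only matching can
  test the sensitivity by post-filtering, but the default errs toward
  recall.
- `let-7` and other non-`miR` names are *not* extracted — a documented
  blind spot of the numeric-suffix rule. The dictionary layer is the
  extension point if those families matter for a use case.
- No family whitelist is applied: any integer is accepted, since large
  indices (e.g. `miR-1207`) genuinely occur.

A record with no abstract is mined on its title alone; the source
format does not guarantee abstracts, and dropping such records would
silently bias counts against older articles.

## Dictionaries and matching guards

The three built-in dictionaries are fixed curated lists — 14 cell
types, 11 cytokines, 15 pathological processes — user-overridable via a
YAML config whose packaged default reproduces the built-ins exactly.
Matching is case-insensitive substring matching with two guards:

1. a variant ending in a digit must not be followed by a digit, so
   `IL-1` never fires inside `IL-10`, `IL-17`, `IL-18` while `IL-1β`
   and `IL-1b` still count;
2. a single-letter-prefixed variant (`T-cell`, `T reg`, `B-cell`)
   requires a word boundary before the letter, so `ACT-cell` is not a
   T-cell mention.

Substring semantics are chosen over tokenization because they absorb
plurals (`fibroblasts`) and Greek-letter suffixes (`TNF-α`) without a
stemmer. The cost is occasional over-matching (`pain` inside an
unrelated longer word); with these particular term lists that risk is
low, and the guards remove the conflations that demonstrably occur
among the listed terms themselves. The generic term `interleukin` is
its own dictionary entry and matches independently of the specific
`IL-n` entries — `interleukin-6` counts both — since the lists name it
separately; analysts who want exclusive counting can drop the generic
entry from the config.

## Ranking, ties and degenerate inputs

`k` defaults to 7 and is configurable. Ties in $N(f)$ are broken by
ascending family index (`miR-21` before `miR-125`), a deterministic
rule chosen so that reruns and cross-machine runs produce identical
rankings; no source of randomness enters the pipeline. Zero-count
families never enter rankings; empty corpora yield empty (zero-row)
tables rather than errors everywhere downstream; records without a
parseable year are excluded from trend series only — never from counts
— and their number is reported.

Aggregate counts across corpora are plain elementwise sums: an article
retrieved by two disease queries counts once per corpus, because the
corpus files are processed independently. The pipeline reports shared
PMIDs as a diagnostic rather than deduplicating, making the overlap
visible without changing the per-corpus semantics.

## The synthetic generator as oracle

The paperless problem with bibliometric pipelines is that live-database
snapshots drift, so correct counts cannot be pinned to an external
reference. The generator solves this by *recording the truth at
sampling time*: each synthetic record samples a set of families and
terms first, then renders them into filler sentences through random
surface forms (species prefixes, arms, spelling and case variants,
plural terms). The truth tables are recomputed from the sampled sets by
direct enumeration, so comparing engine output against them exercises
the full extraction → matching → counting path against an independent
answer.

Two details keep that comparison exact:

- the filler vocabulary is verified (by test) to trigger neither
  matcher, so no accidental mentions appear;
- surface forms are drawn only from variants whose match set is exactly
  their own canonical term. `interleukin-6` is excluded (it would also
  hit the generic `interleukin` entry and falsify the sampled truth),
  while `IL-17` stays in — deliberately exercising the digit guard,
  since it must *not* count as `IL-1`.

The nine-corpus demonstration fixture mirrors the nine-disease study
shape, with corpus sizes proportional to a real 2,883-article snapshot
(113, 32, 21, 1277, 24, 822, 74, 417, 103) scaled by 0.25 — roughly
720 records in total, enough for stable rankings while keeping the full
suite fast — and years drawn from 1994–2022, the span over which this
literature actually accumulated. Two families, `miR-146` and
`miR-155`, are included with probability 1 in every record, so their
breadth of 9 is forced by construction and recovering it is a sharp
end-to-end check. Term inclusion probability defaults to 0.12 per term
and the review rate to 0.12, both in the range of what the matchers see
in real rheumatology abstracts. Test sweeps use 20 randomized
specifications with corpus sizes up to 2,000 records and mixed surface
noise.

What the generator does *not* emulate: linguistically realistic
abstracts, correlated mention structure (real articles mention
related families together), section structure, or the query behaviour
of PubMed itself. Passing the oracle therefore certifies the counting
machinery, not the ecological validity of any particular corpus.

## Serialization

The MEDLINE tagged format is parsed with the dialect PubMed's export
actually uses: a 4-character right-padded tag, `- `, the value, with
6-space continuation lines joined by a single space and blank lines
between records. Writing wraps values only at single-space boundaries —
a value containing a run of multiple spaces is emitted on one long line
— so that parse(write(x)) is an exact inverse on mined fields, a
property tested on every generated corpus. Undecodable bytes are
replaced rather than fatal, and Greek letters are preserved because
cytokine matching depends on characters adjacent to them. Blocks
without a PMID are skipped with a warning; malformed lines inside a
record are absorbed into the previous field with a warning, which keeps
one corrupt line from discarding a whole file.

## Known limitations

- Family-level grouping is deliberate but lossy: `miR-146a` and
  `miR-146b` are distinct genes with distinct targets, and arm products
  differ functionally; this tool ranks attention, not mechanism.
- No negation or hedging detection: "miR-21 was *not* associated"
  counts the same as a positive finding.
- Gene symbols embedding digits adjacent to `miR`-like strings could in
  principle confuse extraction; the word-boundary rules remove the
  cases observed in practice.
- The heatmap colour scale normalizes per corpus panel by default
  (configurable to global); per-panel was chosen because corpus sizes
  differ by an order of magnitude and a global scale flattens the small
  corpora to invisibility.
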