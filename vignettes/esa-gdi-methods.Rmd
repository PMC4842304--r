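---
title: "Enhanced suffix arrays with guide, DC and integrated layouts"
author: "esagdi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhanced suffix arrays with guide, DC and integrated layouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esagdi)
```

# The problem

Exact pattern search in a genome — counting the occurrences of a query
string and locating their positions — is the inner loop of read alignment.
A suffix array (SA) answers both tasks in `O(m log n)` by binary search; an
*enhanced* suffix array (ESA) adds a longest-common-prefix (LCP) array and a
child array encoding the hierarchy of common prefixes, bringing search to
`O(m |Σ|)`, independent of genome size. The price is memory: the LCP and
child arrays are each as large as the suffix array itself when stored as
32-bit integers.

This package implements an ESA for DNA texts together with three devices
that make the auxiliary arrays both small and fast to consult:

1. **Bytecoding with exception guide (EG) arrays.** LCP and child values
   are mostly tiny; each is kept in one byte, with the value 255 reserved as
   a flag meaning "look me up in a sorted key/value exception array". An EG
   array stores, at a fixed key interval `G`, the position of the first
   exception with key `>= g*G`, so resolving a flagged key needs a binary
   search over only one bucket's window rather than the whole exception
   array — the behavior of a hash table whose hash function is division
   by `G`.
2. **A discriminating-character (DC) array.** At the l-index `k` separating
   two sibling child intervals, the two adjacent suffixes first differ at
   the characters `S[SA[k-1] + LCP[k]]` and `S[SA[k] + LCP[k]]`. Storing
   these two characters per l-index (15 possible ordered pairs over
   `{$, a, c, g, t, x}` — one nibble each, two per byte) lets child
   selection run without touching the suffix array or the genome text at
   all.
3. **An integrated layout.** During one descent step the algorithm needs
   `LCP[k]`, `Child[k]` and `DC[k]` for the same `k`; interleaving them in
   5-byte blocks (two LCP bytes, two child bytes, one DC byte covering two
   adjacent indices) makes the three values one block read apart. Exception
   and guide arrays stay in side structures; the suffix array itself stays
   uncompressed, because the locating task enumerates many `SA` entries per
   query and decompression there would dominate.

# Data model

The text is a DNA string over `a, c, g, t` plus the ambiguity character `x`
(any IUPAC code other than the four bases), terminated by `$`, with the
total order `$ < a < c < g < t < x`. Queries are `a/c/g/t` only: `x` never
matches a query character, so `x` runs can safely act as separators between
concatenated sequences (multi-FASTA input is joined with a configurable
`x` run, one global terminator at the end). Positions are 0-based; position
`n` holds the terminator. Queries run over SA indices `1..n` — index 0, the
terminator suffix, can never match a query and is excluded from the root
interval.

The running example throughout the package is the string `acaaacatat$`:

```{r}
esa <- buildEsa(encodeGenome("acaaacatat"))
suffixArray(esa)
lcpArray(esa)[-1]
```

# Construction

* **Suffix array** — prefix doubling over the integer symbol codes with
  radix ordering. The algorithm choice is deliberately unremarkable:
  construction speed is not a contract here, and the result is validated
  against a naive sort-all-suffixes oracle in the tests.
* **LCP array** — Kasai's text-order scan (amortized linear).
* **Child array** — the Next/Down/Up relations of the lcp-interval tree are
  computed by the standard stack scans. A virtual boundary value of `-Inf`
  at index `n+1` closes all intervals, and the l-index `n+1` is taken to
  have an Up relationship to l-index 1, stored at slot `n`, so the root
  needs no special case at construction time. The three relations merge
  into one slot per index: Next takes precedence over Down, and the Up
  value of `k` lives at slot `k-1` (the three claims are mutually exclusive
  per slot; construction asserts that no slot is written twice). Values are
  stored relative (`|absolute - index| - 1`), which keeps them small for
  bytecoding.
* **DC array** — read directly off the two index formulas above; index 0
  has no predecessor suffix and carries the reserved nibble 15.
* **Bucket array (optional)** — start/end SA indices per q-mer; since `x`
  is part of the text alphabet but not of any q-mer, both bounds must be
  stored explicitly (`4^q * 4` bytes each). A lookup replaces the first `q`
  descent steps when `m >= q`; an empty bucket proves the q-mer absent and
  search falls back to a plain descent to recover the partial match length.

# Search

Search is *blind descent*: from the root `[1..n]`, the child interval is
selected by the single pattern character at the parent's depth, without
verifying the characters between branch points. At a singleton interval, a
failed selection, or once the interval depth reaches `m`, one
`countMatches` call against a single suffix of the final interval fixes the
true match length `c` — any suffix of that interval gives the same value,
because all of them agree with the pattern on every branching character
along the path. The reported interval is the shallowest interval on the
descent path whose depth reaches `c` (the root when `c = 0`); locating
reports `SA[i..j]` sorted, counting reports `j - i + 1`, both only for full
matches (`c = m`).

Child selection comes in two interchangeable forms:

* **genome-based**: walk the l-index chain; each candidate child's branch
  character is `S[SA[left] + depth]`. Children are in ascending character
  order, so the walk stops early once the branch character exceeds `p`.
* **DC-based**: at the first l-index read the pair `(s1, s2)`; `p = s1`
  selects the left child, `p < s1` or `s1 < p < s2` proves `p` absent, and
  along the Next chain only the right character `s2` of each subsequent
  l-index is consulted. No suffix-array or genome access occurs until the
  final verification.

## Recovering direction without role tags

The in-memory child array keeps a 2-bit role per slot (Next / Down /
Up-of-next-slot). The compressed layouts store only the relative values,
and the traversal recovers direction from context:

* *First l-index of `[i..j]`*: try the up-decode of slot `j`
  (`j - stored`). If `[i..j]` is a genuine lcp-interval, slot `j` cannot
  hold a Next or Down value — either would imply an entry of
  `lcp <= depth` strictly inside `(i..j]`, contradicting the interval's
  depth — so slot `j` holds the Up value of some interval ending at `j`.
  If that value lands in `(i..j]` it is the first l-index; if it belongs
  to a strictly larger enclosing interval it lands at or below `i`
  (its lcp would otherwise contradict the depth of `[i..j]`), and the
  forward decode of slot `i` (`i + stored + 1`) yields the Down value
  instead. Exactly one route applies.
* *Next sibling of `k` at depth `d` inside `[i..j]`*: the forward decode is
  a Next value exactly when it lands at or before `j` with an LCP equal to
  `d`; a Down value decodes inside the child (LCP `> d`), and an Up value
  only occupies slot `k` when the child starting at `k` is a singleton, in
  which case the forward decode lands beyond `j`. Both rejections are
  cheap LCP lookups.
* *Root*: the root rule (first l-index 1 via the Up value at slot `n`,
  producing an empty leading child `[1..0]` that traversal skips) applies
  only on first entry. A child interval may share the root's bounds — on a
  text whose suffixes all share their first character — and is re-entered
  under the general rule, which strictly increases the depth, so descent
  always progresses.

The equivalence of tagged and context-recovered traversal is asserted
interval-by-interval on randomized genomes in the test suite.

# Codecs

`byteGuideEncode`/`byteGuideGet` implement bytecoding with EG arrays. The
guide interval must be a power of two (default 1024, the value also used by
the integrated layout; smaller intervals buy a narrower search window for a
few more bytes — the guide adds `4 * (ceil(N/G) + 1)` bytes to
`N + 8E`). Exceptions are parallel 32-bit key and value arrays in ascending
key order; the in-bucket search is binary. The value 255 itself is an
exception: only values strictly below 255 fit a byte.

`bp64Encode`/`bp64Get` implement direct blockwise bitpacking: blocks of 64
values, per-block even width 2..32 chosen by the block maximum (all-zero
blocks pay the minimum width of 2 bits/value). The layout is vertical over
32-bit words: value `i` belongs to lane `i mod 4` at lane slot
`floor(i/4)`, each lane a stride-4 word series — so scalar random access
needs only 16 distinct bit-offset cases per width rather than 64. The final
block is zero-padded. Word order and bit order within a word are fixed
little-endian for bit-exact serialization; the layout contract is asserted
through the package's own encode/decode pair.

Both vectors serialize to versioned, little-endian byte strings with magic
headers; the whole-index container (`saveIndex`/`loadIndex`) wraps sections
(genome, suffix array, bytecoded arrays or integrated blocks, exceptions,
guides, bucket array) in a tagged section table with a trailing checksum.
Within an integrated 5-byte block, byte order is
`LCP[2b], LCP[2b+1], Child[2b], Child[2b+1], DC byte` with the even index
in the low DC nibble; the choice is arbitrary but frozen by the format.
Odd-tail padding is zero.

# Synthetic genomes and what the tests show

`synthGenome` draws an i.i.d. uniform `a/c/g/t` background, plants
`dupCount` duplicate segments of `dupLen` at non-overlapping positions, and
optionally masks both ends with `x` runs (telomere-like). A planted
duplication of length `L` forces adjacent suffixes sharing at least `L`
characters, so `dupLen = 300 > 255` deliberately drives LCP values into the
exception path; duplications also create the non-specific, many-match
queries that make locating expensive. What the generator does *not*
emulate: the long-range repeat structure, GC skew and compositional
heterogeneity of real genomes, which shape the real exception *rates* (a
few percent of LCP entries in real genomes) and cache behavior. Passing
tests therefore certify correctness of the structures and algorithms and
the internal consistency of the space accounting — not the wall-clock or
space figures one would measure on a real genome.

Query sampling draws substrings uniformly over x-free windows, which
matches how benchmark queries are usually generated and guarantees at least
one occurrence per query; absent patterns are exercised separately with
random strings.

# Benchmark harness

`benchLcpRetrieval`, `benchChildSelection` and `benchSearch` reproduce the
measurement protocol at desk scale: random indices / sampled non-singleton
parent intervals (reached by descending on random genomic 12-mers) /
random queries of lengths 12, 24 and 36; an odd number of trials (default
9) with per-trial random method order; medians with the median time of a
bare iterate-and-checksum loop subtracted; and a checksum over results that
must agree across representations — the functions stop if it does not.
Timing columns are reported, never asserted; checksums, sizes and counts
are the asserted artifacts. The default query count is `1e4` per
configuration, a deliberate desk-scale choice for a pure-R harness where
per-query interpreter overhead dominates; scale is a parameter, and the
published protocol's `1e6` remains reachable by flag for long runs.

Problem sizes used by the shipped test suite: oracle equivalence runs 50
random genomes of up to 2,000 bp with over 1,000 queries across the five
representations; interval-selection equivalence enumerates every reachable
(interval, character) pair on 50 genomes of up to 1,000 bp; the exception
path uses a 10 kb genome with two planted 300 bp duplications. These sizes
keep the whole suite around a minute while exercising every code path,
including exceptions, x runs, and degenerate one-character texts.

# Degenerate inputs and tie-breaks

* Empty genome (`n = 0`): searches return `c = 0` with an empty interval.
* Unary texts (`aaaa...`): the root's only child shares the root's bounds;
  handled by the root-rule/general-rule split described above.
* Bucket-seeded search on an absent q-mer falls back to plain descent so
  seeded and unseeded searches are always identical.
* Branch characters at one depth are distinct by construction, so child
  selection never ties.
* `charAt(genome, n)` is the terminator; `countMatches` stops at `$` and
  `x` automatically since neither equals a query code.

# Limitations

* Pure R: per-operation overhead makes absolute timings incomparable to
  compiled implementations; the harness measures *relative* behavior of
  the representations and verifies their agreement.
* No reverse-complement indexing, no generalized suffix array with
  per-sequence terminators, no approximate matching.
* The memory-layout claims (cache-line co-retrieval of the 5-byte blocks)
  are implemented as a layout contract; hardware cache behavior is not
  certified.
* Suffix-array construction is `O(n log^2 n)` prefix doubling — fine for
  the megabase scale this package targets, not for whole mammalian
  genomes.
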