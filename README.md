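# esagdi

Enhanced suffix array (ESA) genome indexing for exact pattern search, with
three devices that make the auxiliary arrays small *and* fast:

* **bytecoding with exception guide (EG) arrays** — LCP and child values
  live in one byte each; the flag byte 255 redirects to a key-sorted
  exception array, and a guide array bounds the binary-search window for a
  flagged key to one bucket;
* **a discriminating-character (DC) array** — the pair of characters at
  which the two suffixes adjacent to each l-index first differ, packed two
  nibbles per byte (15 valid pairs over `{$, a, c, g, t, x}`), which lets
  child-interval selection run with no suffix-array or genome access;
* **an integrated layout** — 5-byte blocks interleaving two LCP bytes, two
  child bytes and one DC byte, so the three values needed per descent step
  are retrieved together.

The package is aimed at people studying index data structures for DNA
search: it builds the full ESA (suffix array, LCP array, combined
Next/Down/Up child array, DC array, optional q-mer bucket array), searches
it with genome-based or DC-based branch lookup, serializes indexes to a
versioned binary container, and ships a benchmark harness for the
count/locate protocol with cross-representation checksums.

## The core structures

For a text `S` of length `n` over `{a,c,g,t,x}` terminated by `$`
(ordered `$ < a < c < g < t < x`), `SA[k]` lists suffix start positions in
lexicographic order and `LCP[k]` the longest common prefix of the suffixes
ranked `k-1` and `k`. Maximal ranges of suffixes sharing a prefix form
lcp-intervals `[i..j]`, separated by l-indices `k_1 < ... < k_t` with
`LCP[k_1] = ... = LCP[k_t] = depth`. The child array stores, per SA slot,
the Next sibling l-index (precedence), else the Down value, else the Up
value of the next slot, relative-encoded as `|absolute - index| - 1`; the
virtual l-index `n+1` has an Up relationship to l-index 1 so the root needs
no special case. The DC pair at l-index `k` is
`(S[SA[k-1] + LCP[k]], S[SA[k] + LCP[k]])`. Search is blind descent —
children are chosen by the single pattern character `P[depth]` — with one
final character count fixing the true matched prefix length `c`; counting
returns `j - i + 1` and locating `SA[i..j]`, for full matches.

## Worked example

The running example text is `acaaacatat$`:

```r
library(esagdi)
esa <- buildEsa(encodeGenome("acaaacatat"))
suffixArray(esa)       # 10 2 3 0 4 8 6 1 5 9 7
lcpArray(esa)[-1]      # 0 2 1 3 1 2 0 2 0 1     (LCP[8] = 2)
childAbsolute(esa, 1)  # role "next", value 7    (Next[1] = 7)
childAbsolute(esa, 7)  # role "next", value 9    (Next[7] = 9)
dcPairDecode(dcArray(esa)[9])     # "a" "t"      (DC[8])

esaSearch(esa, "aca")
#> SearchResult for 'aca' (m = 3)
#>   matched prefix c = 3 (full match)
#>   interval [3..4] (2 suffixes)
esaLocate(esa, "at")   # 6 8
esaCount(esa, "a")     # 6
```

`esaSearch(..., variant = "dc")` uses DC-based branch lookup and returns
identical results. On larger inputs, a synthetic genome with planted 300 bp
duplications drives LCP values past 255 into the exception path:

```r
g <- synthGenome(10000, dupCount = 2, dupLen = 300, seed = 7)
idx <- buildIntegrated(buildEsa(g))
idx
#> IntegratedESA over a genome of length 10000
#>   5001 five-byte blocks; exceptions: lcp 92, child 29; guide interval 1024
integratedSizeBytes(idx)
#>     blocks exceptions     guides      total
#>      25005        968         88      26061
```

The five search representations (`esa`, `byte`, `guide`, `dc`, `gdi`; see
`esaVariant()`) are result-identical by construction and by test;
`benchLcpRetrieval()`, `benchChildSelection()` and `benchSearch()` time
them under the randomized-trial, median, overhead-subtracted protocol and
stop if any cross-representation checksum disagrees.

A thin command line lives at `inst/cli/esagdi`
(`synth`, `build`, `search`, `bench`, `selftest`), e.g.:

```sh
Rscript inst/cli/esagdi synth --length 10000 --dup-count 2 --dup-len 300 \
    --seed 7 -o genome.fa
Rscript inst/cli/esagdi build -g genome.fa -o idx.esa --layout integrated
Rscript inst/cli/esagdi search --index idx.esa --queries q.txt --task locate
```

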