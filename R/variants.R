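# The five benchmark representations of one ESA.

.VARIANT_NAMES <- c("esa", "byte", "guide", "dc", "gdi")

#' Create a named search representation over an ESA
#'
#' The five representations mirror the benchmark ladder: raw integer arrays
#' with genome-based branch lookup (`"esa"`); bytecoded LCP and child arrays
#' without (`"byte"`) and with (`"guide"`) exception guide arrays, still
#' genome-based; bytecoded arrays with guides plus DC-based branch lookup
#' (`"dc"`); and the integrated 5-byte-block layout with DC-based lookup
#' (`"gdi"`). All five return identical search results; they differ in
#' storage and in which memory is touched per descent step.
#'
#' @param esa an [EnhancedSuffixArray].
#' @param name one of `"esa"`, `"byte"`, `"guide"`, `"dc"`, `"gdi"`.
#' @param guideInterval guide interval for `"guide"`, `"dc"` and `"gdi"`.
#' @return an [EsaVariant].
#' @examples
#' esa <- buildEsa(encodeGenome("acaaacatat"))
#' v <- esaVariant(esa, "gdi")
#' esaCount(v, "aca")
#' @export
esaVariant <- function(esa, name = .VARIANT_NAMES, guideInterval = 1024L) {
  name <- match.arg(name)
  stopifnot(is(esa, "EnhancedSuffixArray"))
  lcpStore <- childStore <- integrated <- NULL
  mode <- "genome"
  if (name %in% c("byte", "guide", "dc")) {
    gi <- if (name == "byte") NULL else guideInterval
    lcpStore <- byteGuideEncode(esa@lcp, gi)
    childStore <- byteGuideEncode(esa@child@rel, gi)
  }
  if (name == "dc") mode <- "dc"
  if (name == "gdi") {
    integrated <- buildIntegrated(esa, guideInterval)
    mode <- "dc"
  }
  new("EsaVariant", name = name, esa = esa, lcpStore = lcpStore,
      childStore = childStore, integrated = integrated, branchMode = mode)
}

.accessorsVariant <- function(v) {
  if (v@name == "esa") {
    .accessorsRaw(v@esa, mode = "genome")
  } else if (v@name == "gdi") {
    .accessorsIntegrated(v@integrated, mode = "dc")
  } else {
    .accessorsBgv(v@esa, v@lcpStore, v@childStore, mode = v@branchMode)
  }
}

#' @describeIn esaVariant auxiliary-array payload bytes of a variant
#'   (suffix array and genome excluded): raw arrays count 4 bytes per LCP
#'   and child entry; bytecoded variants use the [bgvSizeBytes()]
#'   accounting plus the packed DC array where it is consulted; the
#'   integrated layout uses [integratedSizeBytes()].
#' @param v an [EsaVariant].
#' @export
variantSizeBytes <- function(v) {
  n1 <- v@esa@genome@n + 1
  dcBytes <- ceiling(n1 / 2)
  switch(v@name,
    esa = 8 * n1,
    byte = ,
    guide = unname(bgvSizeBytes(v@lcpStore)["total"] +
                     bgvSizeBytes(v@childStore)["total"]),
    dc = unname(bgvSizeBytes(v@lcpStore)["total"] +
                  bgvSizeBytes(v@childStore)["total"]) + dcBytes,
    gdi = unname(integratedSizeBytes(v@integrated)["total"]))
}

setMethod("show", "EsaVariant", function(object) {
  cat("EsaVariant '", object@name, "' (", object@branchMode,
      "-based branch lookup) over a genome of length ",
      object@esa@genome@n, "\n", sep = "")
})
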