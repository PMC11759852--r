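#' @importFrom Biostrings DNAString DNAStringSet reverseComplement translate
#'   readDNAStringSet writeXStringSet PDict vcountPDict
#' @importFrom IRanges IRanges
#' @importFrom stats median rbeta rbinom rnorm runif setNames quantile
#'   aggregate
#' @importFrom utils read.csv write.csv read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character DNA (A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## fast scalar substring on an already-split character vector of bases
.paste_bases <- function(bases) paste(bases, collapse = "")

.is_dna <- function(x) grepl("^[ACGT]+$", x)

.is_base <- function(x) x %in% c("A", "C", "G", "T")

.has_homopolymer <- function(x, n = 5L) {
  grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}", n, n, n, n), x)
}

.stop_codons <- c("TAA", "TAG", "TGA")

.translate_dna <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 3L) unname(Biostrings::GENETIC_CODE[[s]])
    else as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}

## deterministic child seed derived from a user seed and a stream label,
## kept below 2^31 so it is a valid R integer
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

variant_id <- function(contig, pos, ref, alt) {
  sprintf("%s:%d%s>%s", contig, as.integer(pos), ref, alt)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.empty_variant_df <- function() {
  data.frame(
    variant = character(0), source = character(0), contig = character(0),
    pos = integer(0), ref = character(0), alt = character(0),
    hgvs_c = character(0), hgvs_p = character(0),
    consequence = character(0), significance_raw = character(0),
    class_label = character(0), allele_count = integer(0),
    stringsAsFactors = FALSE
  )
}
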