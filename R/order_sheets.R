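#' Emit ordering sheets for a designed library
#'
#' Collects everything that goes to the oligo vendor: one archetypal
#' epegRNA duplex set per window (spacer duplex, extension duplex; the
#' phosphorylated scaffold is a shared constant), the single-stranded
#' oligo-pool entries (epegRNA core flanked by the constant primer-landing
#' tails), the two constant BsaI-appending pool-amplification primers, the
#' nicking-gRNA duplexes, and the constant amplicon-sequencing primers for
#' the plasmid-pool cassette (including the Illumina adaptor tails for
#' locus amplicon primers). Designs flagged with an internal BsaI site are
#' excluded from the pool sheet and listed in a rejects tab.
#'
#' @param designs list of `epeg_design` objects.
#' @param ngrnas list of `nicking_grna` objects.
#' @param params a [design_params()].
#' @return object of class `order_sheets`: a named list of data.frames
#'   (`archetypes`, `opool`, `pool_primers`, `nicking`, `ampseq_primers`,
#'   `rejects`).
#' @export
emit_order_sheets <- function(designs, ngrnas = list(),
                              params = design_params()) {
  if (length(designs) == 0L) stop("nothing to emit: no designs supplied")
  const <- pe_constants()
  flagged <- vapply(designs, function(d) "internal_bsai" %in% d$flags, TRUE)
  ok <- designs[!flagged]

  ## archetype per window: the design closest to the nick
  by_win <- split(designs, vapply(designs, function(d) d$window_id, ""))
  archetypes <- do.call(rbind, lapply(by_win, function(ds) {
    d <- ds[[order(vapply(ds, function(x) x$offset, 0L),
                   vapply(ds, function(x) x$variant, ""))[1]]]
    data.frame(
      window_id = d$window_id, variant = d$variant,
      spacer_top = paste0("CACC", d$spacer_seq),
      spacer_bottom = paste0("AAAC", revcomp(d$spacer_seq)),
      extension_top = paste0(d$rtt_seq, d$pbs_seq, d$motif_seq),
      extension_bottom = revcomp(paste0(d$rtt_seq, d$pbs_seq, d$motif_seq)),
      stringsAsFactors = FALSE)
  }))
  rownames(archetypes) <- NULL

  opool <- data.frame(
    name = vapply(ok, function(d) d$variant, ""),
    window_id = vapply(ok, function(d) d$window_id, ""),
    sequence = vapply(ok, function(d) d$pool_oligo_seq, ""),
    stringsAsFactors = FALSE)

  pool_primers <- data.frame(
    name = c("oPool_BsaI_F", "oPool_BsaI_R"),
    sequence = c(
      paste0(params$bsai_primer_ext, params$pool_tail_left),
      paste0(params$bsai_primer_ext, revcomp(params$pool_tail_right))),
    stringsAsFactors = FALSE)

  nicking <- if (length(ngrnas)) do.call(rbind, lapply(ngrnas, function(g) {
    data.frame(window_id = g$window_id, spacer = g$spacer_seq,
               nick_offset = g$nick_offset,
               top_oligo = g$top_oligo, bottom_oligo = g$bottom_oligo,
               stringsAsFactors = FALSE)
  })) else data.frame(window_id = character(0), spacer = character(0),
                      nick_offset = integer(0), top_oligo = character(0),
                      bottom_oligo = character(0))
  rownames(nicking) <- NULL

  ampseq_primers <- data.frame(
    name = c("tevopreqPCR1_ampSeqF", "tevopreqPCR1_ampSeqR",
             "illumina_tail_F", "illumina_tail_R"),
    sequence = c(const$ampseq_primer_f, const$ampseq_primer_r,
                 const$illumina_tail_f, const$illumina_tail_r),
    stringsAsFactors = FALSE)

  rejects <- data.frame(
    name = vapply(designs[flagged], function(d) d$variant, ""),
    reason = rep("internal_bsai", sum(flagged)),
    stringsAsFactors = FALSE)

  structure(list(archetypes = archetypes, opool = opool,
                 pool_primers = pool_primers, nicking = nicking,
                 ampseq_primers = ampseq_primers, rejects = rejects),
            class = "order_sheets")
}

#' @export
print.order_sheets <- function(x, ...) {
  cat(sprintf(
    "order_sheets: %d archetype(s), %d oPool entries (+%d rejected), %d nicking duplex(es)\n",
    nrow(x$archetypes), nrow(x$opool), nrow(x$rejects), nrow(x$nicking)))
  invisible(x)
}

#' Write order sheets to CSV files
#'
#' One CSV per sheet, named `<prefix>_<sheet>.csv`, with byte-identical
#' output for identical inputs.
#'
#' @param sheets an `order_sheets` object.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return named vector of written paths, invisibly.
#' @export
write_order_sheets <- function(sheets, dir, prefix = "library") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(sheets), function(nm) {
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, nm))
    write.csv(sheets[[nm]], p, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

## ---- in-silico Golden-Gate round trip -------------------------------------

## exact-match PCR: each primer's 3' end must anneal (>= min_anneal nt) to
## the template; product carries the full primer sequences at its ends
pcr_amplify <- function(template, fwd, rev, min_anneal = 12L) {
  find_suffix <- function(primer, subject) {
    for (k in seq(nchar(primer), min_anneal)) {
      suf <- substr(primer, nchar(primer) - k + 1L, nchar(primer))
      hit <- .count_fixed(subject, suf)
      if (length(hit) == 1L) return(list(k = k, at = hit))
      if (length(hit) > 1L) return(NULL)
    }
    NULL
  }
  f <- find_suffix(fwd, template)
  if (is.null(f)) return(NULL)
  r <- find_suffix(rev, revcomp(template))
  if (is.null(r)) return(NULL)
  r_end_plus <- nchar(template) - r$at + 1L  # plus-strand end of rev landing
  f_end <- f$at + f$k - 1L
  if (r_end_plus - r$k + 1L <= f_end) return(NULL)
  paste0(fwd, substr(template, f_end + 1L, r_end_plus - r$k),
         revcomp(rev))
}

## locate BsaI sites on both strands of a product and return the insert
## between the two cuts plus its 4-nt overhangs
bsai_digest <- function(product) {
  L <- nchar(product)
  top <- .count_fixed(product, "GGTCTC")
  bot <- .count_fixed(product, "GAGACC")
  if (length(top) != 1L || length(bot) != 1L)
    stop("expected exactly one BsaI site per strand")
  p <- top[1]; q <- bot[1]
  ## top-strand site GGTCTC at p: top cut after p+6, bottom after p+10
  ins_start <- p + 7L
  left_ov <- substr(product, ins_start, ins_start + 3L)
  ## bottom-strand site (GAGACC on top at q): top cut after q-7, bottom
  ## cut after q-3; the ligated footprint runs through q-2 and the
  ## bottom-strand 5' overhang is the reverse complement of [q-5, q-2]
  ins_end <- q - 2L
  right_ov <- revcomp(substr(product, ins_end - 3L, ins_end))
  if (ins_end <= ins_start) stop("BsaI cuts do not bracket an insert")
  list(insert = substr(product, ins_start, ins_end),
       overhang_left = left_ov, overhang_right = right_ov)
}

#' Simulate Golden-Gate assembly of an emitted pool oligo
#'
#' Round-trip model of library cloning: the pool entry is PCR-amplified
#' with the constant BsaI-appending primers, digested with BsaI, and
#' ligated into a modelled acceptor whose overhangs match the landing-tail
#' junctions. Returns the reconstructed cassette and the recovered epegRNA
#' core, which must equal the design's `full_seq`.
#'
#' @param oligo_seq one pool entry sequence.
#' @param params a [design_params()].
#' @return list with `cassette` and `core`.
#' @export
simulate_golden_gate <- function(oligo_seq, params = design_params()) {
  fwd <- paste0(params$bsai_primer_ext, params$pool_tail_left)
  rev <- paste0(params$bsai_primer_ext, revcomp(params$pool_tail_right))
  product <- pcr_amplify(oligo_seq, fwd, rev)
  if (is.null(product)) stop("pool primers fail to amplify the oligo")
  dig <- bsai_digest(product)
  exp_left <- substr(params$pool_tail_left, 1L, 4L)
  exp_right <- revcomp(substr(params$pool_tail_right,
                              nchar(params$pool_tail_right) - 3L,
                              nchar(params$pool_tail_right)))
  if (dig$overhang_left != exp_left || dig$overhang_right != exp_right)
    stop("insert overhangs do not match the modelled acceptor")
  cassette <- paste0(params$acceptor_left, dig$insert,
                     params$acceptor_right)
  core <- sub(paste0(".*", params$pool_tail_left), "",
              sub(paste0(params$pool_tail_right, ".*"), "", cassette))
  list(cassette = cassette, core = core)
}
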