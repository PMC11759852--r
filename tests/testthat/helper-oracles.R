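# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately written as brute-force re-derivations, not calls into the
# package code paths they check.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s)
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

## exhaustive protospacer scan on both strands: 20-mers followed by NGG
oracle_scan_spacers <- function(seq) {
  n <- nchar(seq)
  hits <- list()
  for (p in seq_len(max(0, n - 22L))) {
    pam <- substr(seq, p + 20L, p + 22L)
    if (substr(pam, 2, 3) == "GG")
      hits[[length(hits) + 1L]] <- data.frame(
        strand = "+", protospacer = substr(seq, p, p + 19L), pam = pam,
        nick = p + 16L, stringsAsFactors = FALSE)
  }
  rc <- oracle_revcomp(seq)
  for (p in seq_len(max(0, n - 22L))) {
    pam <- substr(rc, p + 20L, p + 22L)
    if (substr(pam, 2, 3) == "GG") {
      ## map the rc-coordinate nick back to plus coordinates
      nick_rc <- p + 16L
      hits[[length(hits) + 1L]] <- data.frame(
        strand = "-", protospacer = substr(rc, p, p + 19L), pam = pam,
        nick = n - nick_rc, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(strand = character(0), protospacer = character(0),
                      pam = character(0), nick = integer(0)))
  df <- do.call(rbind, hits)
  df[order(df$nick, df$strand), , drop = FALSE]
}

## naive sliding-window scan for dictionary k-mers in reads
oracle_count_kmers <- function(reads, kmers, canonical = TRUE) {
  counts <- setNames(integer(length(kmers)), kmers)
  for (r in reads) {
    L <- nchar(r)
    k <- nchar(kmers[1])
    if (L < k) next
    wins <- substring(r, 1:(L - k + 1L), k:L)
    for (i in seq_along(kmers)) {
      hits <- sum(wins == kmers[i])
      if (canonical) hits <- hits + sum(wins == oracle_revcomp(kmers[i]))
      counts[i] <- counts[i] + hits
    }
  }
  unname(counts)
}

## independent flap synthesis: copy the 3' flap encoded by the RT template
## onto the nicked strand and return the resulting locus sequence
oracle_flap_synthesis <- function(sequence, design) {
  flap <- oracle_revcomp(design$rtt_seq)  # 5'->3' on the edited strand
  L <- nchar(flap)
  if (design$strand == "+") {
    paste0(substr(sequence, 1, design$nick), flap,
           substr(sequence, design$nick + L + 1L, nchar(sequence)))
  } else {
    ## edited strand is the minus strand; flap runs leftward in plus coords
    plus_seg <- oracle_revcomp(flap)
    paste0(substr(sequence, 1, design$nick - L), plus_seg,
           substr(sequence, design$nick + 1L, nchar(sequence)))
  }
}

## brute-force stop-gain enumeration: substitute, splice, translate
oracle_ptc_scan <- function(ctx, interval) {
  bases <- c("A", "C", "G", "T")
  splice_translate <- function(seq) {
    pieces <- vapply(seq_len(nrow(ctx$cds)), function(i)
      substr(seq, ctx$cds$start[i], ctx$cds$end[i]), "")
    cds <- paste(pieces, collapse = "")
    if (ctx$strand == "-") cds <- oracle_revcomp(cds)
    strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds))), "")[[1]]
  }
  ref_prot <- splice_translate(ctx$sequence)
  n_codon <- length(ref_prot)
  out <- list()
  for (pos in seq.int(interval[1], interval[2])) {
    ref <- substr(ctx$sequence, pos, pos)
    for (alt in setdiff(bases, ref)) {
      mut <- ctx$sequence
      substr(mut, pos, pos) <- alt
      prot <- splice_translate(mut)
      changed <- which(prot != ref_prot)
      if (length(changed) == 1L && prot[changed] == "*" &&
          changed != n_codon)
        out[[length(out) + 1L]] <- data.frame(pos = pos, ref = ref,
                                              alt = alt,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(pos = integer(0), ref = character(0),
                  alt = character(0))
}

## random single-exon coding mini-gene (no internal stops)
random_mini_ctx <- function(n_codons = 40L, strand = "+",
                            flank = 30L) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  cds <- paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE)),
               collapse = "")
  if (strand == "-") cds_genomic <- oracle_revcomp(cds) else
    cds_genomic <- cds
  f5 <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  f3 <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  seq <- paste0(f5, cds_genomic, f3)
  exons <- data.frame(start = flank + 1L, end = flank + nchar(cds))
  gene_context(seq, strand = strand, exons = exons, cds = exons)
}

write_random_fastq <- function(path, n_reads, read_len,
                               alphabet = c("A", "C", "G", "T")) {
  reads <- vapply(seq_len(n_reads), function(i)
    paste(sample(alphabet, read_len, TRUE), collapse = ""), "")
  writeLines(as.vector(rbind(paste0("@r", seq_len(n_reads)), reads, "+",
                             strrep("I", read_len))), path)
  reads
}

## shared end-to-end fixture: one synthetic locus and its designed
## library, generated once per test run
.fixture_env <- new.env(parent = emptyenv())

shared_design <- function() {
  if (!exists("design", .fixture_env)) {
    cfg <- sim_config(seed = 101L)
    loc <- make_synthetic_locus(cfg, file.path(tempdir(), "pegmave_fix"))
    cv <- parse_clinvar_export(loc$clinvar_tsv)
    gn <- parse_gnomad_export(loc$gnomad_csv)
    recs <- classify_variants(rbind(cv$records, gn$records))
    des <- design_library(loc$ctx, recs)
    assign("design", list(cfg = cfg, locus = loc, records = recs,
                          design = des), .fixture_env)
  }
  get("design", .fixture_env)
}
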