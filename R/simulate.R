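## fast SNV consequence table over a set of plus-strand positions:
## one row per (pos, alt) with the transcript-frame consequence
.snv_consequences <- function(ctx, positions) {
  cpos <- cds_positions(ctx)
  cds <- cds_seq(ctx)
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seq_bases <- strsplit(ctx$sequence, "", fixed = TRUE)[[1]]
  n_codon <- length(cpos) %/% 3L
  pos <- rep(positions, each = 3L)
  ref <- seq_bases[pos]
  alt <- unlist(lapply(seq_bases[positions], setdiff,
                       x = bases), use.names = FALSE)
  i <- match(pos, cpos)
  codon_i <- (i - 1L) %/% 3L + 1L
  off <- (i - 1L) %% 3L + 1L
  in_cds <- !is.na(i)
  ref_codon <- substring(cds, 3L * codon_i - 2L, 3L * codon_i)
  ref_codon[!in_cds] <- NA
  alt_t <- if (ctx$strand == "-") comp[alt] else alt
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt_t
  aa1 <- ifelse(in_cds, code[ref_codon], NA)
  aa2 <- ifelse(in_cds, code[alt_codon], NA)
  consequence <- ifelse(!in_cds, "other",
                  ifelse(aa1 == aa2, "synonymous",
                   ifelse(aa2 == "*", "nonsense",
                    ifelse(aa1 == "*", "other", "missense"))))
  data.frame(pos = pos, ref = ref, alt = alt, consequence = consequence,
             codon_i = codon_i, last_codon = codon_i == n_codon,
             stringsAsFactors = FALSE)
}

## codon weights favouring codons with synonymous and stop-gain SNV
## neighbours, so curated windows carry enough truth-set capacity
.codon_weights <- function() {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  bases <- c("A", "C", "G", "T")
  w <- vapply(sense, function(cod) {
    n_syn <- 0L; n_stop <- 0L
    for (p in 1:3) for (b in setdiff(bases, substr(cod, p, p))) {
      alt <- cod
      substr(alt, p, p) <- b
      if (code[[alt]] == code[[cod]]) n_syn <- n_syn + 1L
      if (code[[alt]] == "*") n_stop <- n_stop + 1L
    }
    1 + 2 * n_syn + 2.5 * n_stop
  }, 0)
  w / sum(w)
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

#' Generate a synthetic locus with variant catalogs
#'
#' Builds a random protein-coding gene (biased toward codons rich in
#' synonymous and stop-gain single-nucleotide neighbours so that curated
#' editing windows carry enough truth-set variants), plants the requested
#' catalog classes into two dense, well-separated editing windows, and
#' writes the four pipeline inputs: contig FASTA, exon table, a
#' ClinVar-style missense TSV and a gnomAD-style CSV. Catalog files parse
#' back through the catalog module with zero rejects, and the planted
#' windows plus their stop-gain controls satisfy the default truth-set
#' minimums.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with `ctx`, file paths (`fasta`, `exon_tsv`, `clinvar_tsv`,
#'   `gnomad_csv`), the planted `records` (classified, including the
#'   stop-gain controls), `ptc_records`, the planned window `intervals`
#'   and the resulting `truth_report`.
#' @export
make_synthetic_locus <- function(config = sim_config(), dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- design_params()
  for (attempt in seq_len(25L)) {
    set.seed(derive_seed(config$seed, paste0("locus", attempt)))
    loc <- .try_synthetic_locus(config, params)
    if (!is.null(loc)) break
  }
  if (is.null(loc))
    stop("failed to generate a locus with sufficient truth-set capacity")
  ctx <- loc$ctx
  fasta <- file.path(dir, "locus.fasta")
  exon_tsv <- file.path(dir, "locus_exons.tsv")
  write_gene_context(ctx, fasta, exon_tsv)
  clinvar_tsv <- file.path(dir, "clinvar_missense.tsv")
  gnomad_csv <- file.path(dir, "gnomad_variants.csv")
  .write_clinvar_tsv(loc$clinvar, ctx, clinvar_tsv)
  .write_gnomad_csv(loc$gnomad, ctx, gnomad_csv)
  records <- classify_variants(rbind(loc$clinvar, loc$gnomad))
  all_records <- rbind(records, loc$ptc)
  list(ctx = ctx, fasta = fasta, exon_tsv = exon_tsv,
       clinvar_tsv = clinvar_tsv, gnomad_csv = gnomad_csv,
       records = all_records, ptc_records = loc$ptc,
       intervals = loc$intervals,
       truth_report = validate_truth_sets(all_records))
}

## one attempt at building a valid locus; NULL when the sampled sequence
## lacks capacity for the requested catalog
.try_synthetic_locus <- function(config, params) {
  flank <- 150L
  intron <- 150L
  n_ex <- config$n_exons
  cds_avail <- config$gene_len - 2L * flank - (n_ex - 1L) * intron
  codons_per_exon <- (cds_avail %/% 3L) %/% n_ex
  wts <- .codon_weights()
  sense <- names(wts)
  exon_seqs <- lapply(seq_len(n_ex), function(i) {
    cods <- sample(sense, codons_per_exon, replace = TRUE, prob = wts)
    if (i == 1L) cods[1] <- "ATG"
    paste(cods, collapse = "")
  })
  pieces <- character(0)
  exons <- data.frame(start = integer(0), end = integer(0))
  cursor <- 0L
  add <- function(s) { pieces <<- c(pieces, s); cursor <<- cursor + nchar(s) }
  add(.rand_dna(flank))
  for (i in seq_len(n_ex)) {
    exons <- rbind(exons, data.frame(start = cursor + 1L,
                                     end = cursor + nchar(exon_seqs[[i]])))
    add(exon_seqs[[i]])
    if (i < n_ex) add(.rand_dna(intron))
  }
  add(.rand_dna(flank))
  ## genomic stop codon appended at the end of the last exon
  seq <- paste(pieces, collapse = "")
  ctx <- gene_context(seq, exons = exons, cds = exons)

  ## candidate windows: spacers in the CDS whose full edit interval is
  ## coding and which have a PE3 nicking candidate
  cds_span <- c(min(ctx$cds$start), max(ctx$cds$end))
  spacers <- enumerate_spacers(ctx, cds_span)
  cpos <- cds_positions(ctx)
  cand <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers[i, , drop = FALSE]
    iv <- edit_interval_of(sp, params$max_edit_offset)
    if (iv[1] < 1L || iv[2] > nchar(seq)) next
    if (!all(seq.int(iv[1], iv[2]) %in% cpos)) next
    cand[[length(cand) + 1L]] <- list(spacer = sp, interval = iv)
  }
  if (length(cand) < 2L) return(NULL)
  caps <- lapply(cand, function(w) {
    cq <- .snv_consequences(ctx, seq.int(w$interval[1], w$interval[2]))
    list(syn = cq[cq$consequence == "synonymous", , drop = FALSE],
         mis = cq[cq$consequence == "missense", , drop = FALSE],
         ptc = cq[cq$consequence == "nonsense" & !cq$last_codon, ,
                  drop = FALSE])
  })
  score <- vapply(caps, function(cp)
    2 * min(nrow(cp$syn), 15L) + 2 * min(nrow(cp$ptc), 12L) +
      min(nrow(cp$mis), 45L), 0)
  ord <- order(-score,
               vapply(cand, function(w) w$spacer$nick, 0L))
  i1 <- ord[1]
  i2 <- NA_integer_
  for (j in ord[-1]) {
    if (abs(cand[[j]]$spacer$nick - cand[[i1]]$spacer$nick) > 300L) {
      i2 <- j; break
    }
  }
  if (is.na(i2)) return(NULL)
  picks <- c(i1, i2)

  ## capacity check across the two windows
  syn_cap <- sum(vapply(caps[picks], function(cp) nrow(cp$syn), 0L))
  ptc_cap <- sum(vapply(caps[picks], function(cp) nrow(cp$ptc), 0L))
  mis_cap <- vapply(caps[picks], function(cp) nrow(cp$mis), 0L)
  n_mis <- config$n_vus + config$n_plp + config$n_blb +
    config$n_pop_missense
  if (syn_cap < config$n_pop_syn || ptc_cap < config$n_ptc ||
      sum(mis_cap) < n_mis || any(mis_cap < n_mis %/% 2L - 5L))
    return(NULL)

  ## split each class roughly evenly across the two windows
  take <- function(pool_list, n_total) {
    n1 <- nrow(pool_list[[1]]); n2 <- nrow(pool_list[[2]])
    k1 <- min(n1, ceiling(n_total * n1 / (n1 + n2)))
    k2 <- n_total - k1
    if (k2 > n2) { k1 <- k1 + (k2 - n2); k2 <- n2 }
    rbind(
      pool_list[[1]][sample.int(n1, k1), , drop = FALSE],
      pool_list[[2]][sample.int(n2, k2), , drop = FALSE])
  }
  syn_pools <- lapply(caps[picks], function(cp) cp$syn)
  mis_pools <- lapply(caps[picks], function(cp) cp$mis)
  syn_take <- take(syn_pools, config$n_pop_syn)
  mis_take <- take(mis_pools, n_mis)
  mis_take <- mis_take[sample.int(nrow(mis_take)), , drop = FALSE]
  splits <- rep(c("VUS", "PLP", "BLB", "POP_MISSENSE"),
                c(config$n_vus, config$n_plp, config$n_blb,
                  config$n_pop_missense))
  mk_rec <- function(df, source, consequence, sig = NA_character_,
                     ac = NA_integer_) {
    if (!nrow(df)) return(.empty_variant_df())
    data.frame(
      variant = variant_id(ctx$contig_id, df$pos, df$ref, df$alt),
      source = source, contig = ctx$contig_id, pos = df$pos,
      ref = df$ref, alt = df$alt, hgvs_c = NA_character_,
      hgvs_p = NA_character_, consequence = consequence,
      significance_raw = sig, class_label = NA_character_,
      allele_count = ac, stringsAsFactors = FALSE)
  }
  sig_for <- function(cls, n) switch(cls,
    VUS = rep("Uncertain significance", n),
    PLP = sample(c("Pathogenic", "Likely pathogenic",
                   "Pathogenic/Likely pathogenic"), n, replace = TRUE),
    BLB = sample(c("Benign", "Likely benign", "Benign/Likely benign"),
                 n, replace = TRUE))
  clinvar <- list(); gnomad <- list()
  for (cls in c("VUS", "PLP", "BLB")) {
    sub <- mis_take[splits == cls, , drop = FALSE]
    sig <- sig_for(cls, nrow(sub))
    ## exercise the "(Last reviewed ...)" suffix on some rows
    dated <- seq_len(nrow(sub)) %% 3L == 0L
    sig[dated] <- paste0(sig[dated], "(Last reviewed: Jan 1, 2024)")
    clinvar[[cls]] <- mk_rec(sub, "clinvar", "missense", sig = sig)
  }
  gnomad$syn <- mk_rec(syn_take, "gnomad", "synonymous",
                       ac = sample(5:2000, nrow(syn_take), replace = TRUE))
  pm <- mis_take[splits == "POP_MISSENSE", , drop = FALSE]
  gnomad$mis <- mk_rec(pm, "gnomad", "missense",
                       ac = sample(5:2000, nrow(pm), replace = TRUE))
  ## a few below-threshold decoys that classify as OTHER
  spare <- caps[[picks[1]]]$mis
  spare <- spare[!variant_id(ctx$contig_id, spare$pos, spare$ref,
                             spare$alt) %in%
                   variant_id(ctx$contig_id, mis_take$pos, mis_take$ref,
                              mis_take$alt), , drop = FALSE]
  if (nrow(spare) >= 3L) {
    low <- spare[sample.int(nrow(spare), 3L), , drop = FALSE]
    gnomad$low <- mk_rec(low, "gnomad", "missense",
                         ac = sample(1:4, 3L, replace = TRUE))
  }
  clinvar <- do.call(rbind, clinvar)
  gnomad <- do.call(rbind, gnomad)
  rownames(clinvar) <- rownames(gnomad) <- NULL
  intervals <- lapply(cand[picks], function(w) w$interval)
  ptc <- do.call(rbind, lapply(intervals, function(iv)
    generate_ptc_controls(ctx, iv)))
  ptc <- ptc[!duplicated(ptc$variant), , drop = FALSE]
  list(ctx = ctx, clinvar = clinvar, gnomad = gnomad, ptc = ptc,
       intervals = intervals)
}

.write_clinvar_tsv <- function(records, ctx, path) {
  tab <- data.frame(
    Name = sprintf("%s(%s):c.%d%s>%s", ctx$transcript_id,
                   ctx$gene_symbol, records$pos, records$ref, records$alt),
    `Gene(s)` = ctx$gene_symbol,
    `Protein change` = "",
    `Condition(s)` = "not provided",
    `Clinical significance (Last reviewed)` = records$significance_raw,
    `Review status` = "criteria provided, single submitter",
    GRCh38Chromosome = records$contig,
    GRCh38Location = records$pos,
    `Canonical SPDI` = sprintf("%s:%d:%s:%s", records$contig,
                               records$pos - 1L, records$ref, records$alt),
    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = TRUE, row.names = FALSE)
  invisible(path)
}

.write_gnomad_csv <- function(records, ctx, path) {
  tab <- data.frame(
    Chromosome = records$contig,
    Position = records$pos,
    rsIDs = "",
    Reference = records$ref,
    Alternate = records$alt,
    `VEP Annotation` = ifelse(records$consequence == "synonymous",
                              "synonymous_variant", "missense_variant"),
    `Allele Count` = records$allele_count,
    `Allele Number` = 1613860L,
    check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Simulate edited-cell pool compositions
#'
#' Each designed variant is independently dropped (all-or-none) with the
#' configured dropout probability; surviving variants receive a
#' control-pool allele fraction proportional to a Beta-distributed
#' per-variant editing efficiency (with small lognormal between-replicate
#' jitter). Selected-pool fractions multiply the control fraction by the
#' class fitness and renormalise against the unedited (wild-type)
#' remainder.
#'
#' @param config a [sim_config()].
#' @param variants data.frame of designed variants (`variant`,
#'   `class_label`, optionally `window_id`).
#' @return data.frame with `variant`, `class_label`, `replicate`,
#'   `f_control`, `f_selected`; attributes `dropped`, `efficiency` and
#'   `wt_fraction` (per replicate x condition).
#' @export
simulate_pools <- function(config, variants) {
  set.seed(derive_seed(config$seed, "pools"))
  n <- nrow(variants)
  dropped <- runif(n) < config$dropout_prob
  eff <- rbeta(n, config$editing_shape1, config$editing_shape2)
  fit <- config$fitness[variants$class_label]
  fit[is.na(fit)] <- 1.0
  out <- list()
  wt <- list()
  for (r in seq_len(config$replicates)) {
    w <- ifelse(dropped, 0, eff * exp(rnorm(n, 0, 0.15)))
    f_ctrl <- w / n
    wt_ctrl <- 1 - sum(f_ctrl)
    raw_sel <- f_ctrl * fit
    tot_sel <- sum(raw_sel) + wt_ctrl
    f_sel <- raw_sel / tot_sel
    out[[r]] <- data.frame(
      variant = variants$variant, class_label = variants$class_label,
      window_id = if ("window_id" %in% names(variants))
        variants$window_id else NA_character_,
      replicate = r, f_control = f_ctrl, f_selected = f_sel,
      stringsAsFactors = FALSE)
    wt[[r]] <- c(control = wt_ctrl, selected = wt_ctrl / tot_sel)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dropped") <- setNames(dropped, variants$variant)
  attr(res, "efficiency") <- setNames(eff, variants$variant)
  attr(res, "wt_fraction") <- do.call(rbind, wt)
  res
}

## apply uniform per-base substitution errors to equal-length reads
.add_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  len <- nchar(reads[1])
  m <- rbinom(1L, length(reads) * len, error_rate)
  if (m == 0L) return(reads)
  bases <- c("A", "C", "G", "T")
  ri <- sample.int(length(reads), m, replace = TRUE)
  pp <- sample.int(len, m, replace = TRUE)
  cur <- substring(reads[ri], pp, pp)
  d <- sample.int(3L, m, replace = TRUE)
  repl <- bases[(match(cur, bases) + d - 1L) %% 4L + 1L]
  for (j in seq_len(m)) {
    x <- reads[ri[j]]
    substr(x, pp[j], pp[j]) <- repl[j]
    reads[ri[j]] <- x
  }
  reads
}

.write_fastq_file <- function(path, ids, reads, qual) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  if (length(reads))
    writeLines(as.vector(rbind(paste0("@", ids), reads, "+", qual)), con)
  else writeLines(character(0), con)
  invisible(path)
}

#' Write simulated paired-end amplicon FASTQ files
#'
#' Draws reads multinomially from the simulated pool fractions (wild-type
#' remainder split across windows), takes read 1 from the amplicon 5' end
#' and read 2 as the reverse complement of its 3' end, applies uniform
#' per-base substitution errors, and writes one gzipped FASTQ pair per
#' (condition, replicate) sample. Amplicons are shorter than 250 bp so
#' both mates cover the variant k-mer window.
#'
#' @param pools output of [simulate_pools()].
#' @param variants data.frame with `variant`, `window_id`, `pos`, `alt`.
#' @param ctx the [gene_context()].
#' @param amplicons named list (`window_id` -> length-2 interval).
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return sample-sheet data.frame (`file`, `sample_id`, `condition`,
#'   `replicate`, `mate`, `n_reads`).
#' @export
write_fastq <- function(pools, variants, ctx, amplicons, config,
                        dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(config$seed, "reads"))
  wids <- names(amplicons)
  amp_of <- function(iv) substr(ctx$sequence, iv[1], iv[2])
  v_meta <- variants[match(unique(pools$variant), variants$variant), ,
                     drop = FALSE]
  allele_seq <- vapply(seq_len(nrow(v_meta)), function(i) {
    iv <- amplicons[[v_meta$window_id[i]]]
    s <- amp_of(iv)
    rel <- v_meta$pos[i] - iv[1] + 1L
    substr(s, rel, rel) <- v_meta$alt[i]
    s
  }, "")
  wt_seq <- vapply(wids, function(w) amp_of(amplicons[[w]]), "")
  alleles <- c(allele_seq, wt_seq)
  rl <- config$read_len
  r1_of <- substring(alleles, 1L, rl)
  r2_of <- substring(revcomp(alleles), 1L, rl)
  qual <- strrep("I", rl)
  wt_frac <- attr(pools, "wt_fraction")
  sheet <- list()
  for (cond in c("control", "selected")) {
    for (r in sort(unique(pools$replicate))) {
      sub <- pools[pools$replicate == r, , drop = FALSE]
      sub <- sub[match(v_meta$variant, sub$variant), , drop = FALSE]
      fr <- if (cond == "control") sub$f_control else sub$f_selected
      wtf <- wt_frac[r, cond]
      prob <- c(fr, rep(wtf / length(wids), length(wids)))
      sample_id <- sprintf("%s_rep%d", cond, r)
      idx <- if (config$depth > 0L)
        sample.int(length(alleles), config$depth, replace = TRUE,
                   prob = prob) else integer(0)
      ids <- sprintf("sim:%s:%d", sample_id, seq_along(idx))
      r1 <- .add_read_errors(r1_of[idx], config$error_rate)
      r2 <- .add_read_errors(r2_of[idx], config$error_rate)
      f1 <- file.path(dir, sprintf("%s_R1.fastq.gz", sample_id))
      f2 <- file.path(dir, sprintf("%s_R2.fastq.gz", sample_id))
      .write_fastq_file(f1, ids, r1, qual)
      .write_fastq_file(f2, ids, r2, qual)
      sheet[[length(sheet) + 1L]] <- data.frame(
        file = c(f1, f2), sample_id = sample_id, condition = cond,
        replicate = r, mate = c(1L, 2L), n_reads = length(idx),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, sheet)
}
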