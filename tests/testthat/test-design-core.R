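# helper: a context with no CDS requirements for pure sequence-geometry
# tests (one dummy zero-length-free CDS covering a codon multiple)
plain_ctx <- function(seq) {
  n <- nchar(seq)
  cds_len <- (n %/% 3L) * 3L
  gene_context(seq, exons = data.frame(start = 1L, end = cds_len))
}

test_that("spacer enumeration finds a single planted plus-strand site", {
  ## protospacer at 1..20, PAM AGG at 21..23; no other GG/CC dinucleotide
  seq <- paste0("ATCATCATCATCATCATCAT", "AGG", "ATCATCA")
  ctx <- plain_ctx(seq)
  sp <- enumerate_spacers(ctx, c(1L, nchar(seq)))
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$strand, "+")
  expect_equal(sp$protospacer, "ATCATCATCATCATCATCAT")
  expect_equal(sp$pam, "AGG")
  ## nick 3 nt 5' of the PAM: between protospacer bases 17 and 18
  expect_equal(sp$nick, 17L)
})

test_that("spacer enumeration returns nothing without a PAM", {
  ctx <- plain_ctx(strrep("A", 60))
  expect_equal(nrow(enumerate_spacers(ctx, c(1L, 60L))), 0L)
  expect_error(enumerate_spacers(ctx, c(1L, 100L)), "bounds")
})

test_that("spacer enumeration matches the exhaustive scan oracle and is
           strand-symmetric", {
  set.seed(31)
  for (i in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    ctx <- plain_ctx(seq)
    got <- enumerate_spacers(ctx, c(1L, nchar(seq)))
    want <- oracle_scan_spacers(seq)
    ## oracle has no region clipping; restrict to nicks inside the region
    want <- want[want$nick >= 1 & want$nick <= nchar(seq) - 1L, ]
    expect_equal(got$nick, want$nick)
    expect_equal(got$protospacer, want$protospacer)
    ## reverse-complementing the sequence mirrors the site list
    rc_sp <- enumerate_spacers(plain_ctx(oracle_revcomp(seq)),
                               c(1L, nchar(seq)))
    expect_equal(sort(nchar(seq) - rc_sp$nick), sort(got$nick))
    expect_setequal(rc_sp$protospacer, got$protospacer)
  }
})

mk_variants <- function(pos, class_label, ctx) {
  bases <- strsplit(ctx$sequence, "")[[1]]
  ref <- bases[pos]
  alt <- ifelse(ref == "A", "G", "A")
  data.frame(variant = sprintf("v%d", seq_along(pos)),
             source = "clinvar", contig = ctx$contig_id, pos = pos,
             ref = ref, alt = alt, hgvs_c = NA, hgvs_p = NA,
             consequence = "missense", significance_raw = NA,
             class_label = class_label, allele_count = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("editing windows include variants up to the maximum edit offset", {
  seq <- paste0("ATCATCATCATCATCATCAT", "AGG", strrep("ATC", 20))
  ctx <- plain_ctx(seq)
  sp <- enumerate_spacers(ctx, c(1L, nchar(seq)))[1, ]
  params <- design_params()
  vars <- mk_variants(c(17L + params$max_edit_offset,
                        17L + params$max_edit_offset + 1L),
                      c("VUS", "VUS"), ctx)
  w <- build_windows(sp, vars, params)[[1]]
  expect_equal(w$edit_start, 18L)
  expect_equal(w$edit_end, 17L + params$max_edit_offset)
  expect_equal(w$variant_ids, "v1")

  ## tallies are a per-class hand count
  vars2 <- mk_variants(c(20L, 21L, 25L, 30L, 31L),
                       c("VUS", "VUS", "VUS", "PLP", "PLP"), ctx)
  w2 <- build_windows(sp, vars2, params)[[1]]
  expect_equal(unname(w2$tallies["VUS"]), 3L)
  expect_equal(unname(w2$tallies["PLP"]), 2L)

  ## a spacer with nothing in reach keeps an empty, rankable window
  w3 <- build_windows(sp, mk_variants(100L, "VUS", ctx), params)[[1]]
  expect_length(w3$variant_ids, 0L)
})

test_that("window selection maximises the strategy score", {
  fix <- shared_design()
  recs <- fix$records
  spacers <- enumerate_spacers(fix$locus$ctx,
                               c(min(fix$locus$ctx$cds$start),
                                 max(fix$locus$ctx$cds$end)))
  windows <- build_windows(spacers, recs, design_params())
  pick_vus <- select_windows(windows, recs, "vus", n_target = 1L)
  pick_ctl <- select_windows(windows, recs, "controls", n_target = 1L)
  n_of <- function(w, cls) sum(recs$class_label[
    match(w$variant_ids, recs$variant)] %in% cls)
  best_vus <- max(vapply(windows, n_of, 0, cls = "VUS"))
  best_ctl <- max(vapply(windows, n_of, 0, cls = c("PLP", "BLB")))
  expect_equal(n_of(pick_vus[[1]], "VUS"), best_vus)
  expect_equal(n_of(pick_ctl[[1]], c("PLP", "BLB")), best_ctl)
})

test_that("strategy dominance: vus strategy covers at least as many VUS", {
  fix <- shared_design()
  recs <- fix$records
  spacers <- enumerate_spacers(fix$locus$ctx,
                               c(min(fix$locus$ctx$cds$start),
                                 max(fix$locus$ctx$cds$end)))
  windows <- build_windows(spacers, recs, design_params())
  for (n_target in 1:3) {
    cov <- function(strategy) {
      sel <- select_windows(windows, recs, strategy, n_target = n_target)
      ids <- unique(unlist(lapply(sel, function(w) w$variant_ids)))
      sum(recs$class_label[match(ids, recs$variant)] == "VUS")
    }
    expect_gte(cov("vus"), cov("controls"))
  }
})

test_that("selection truncates oversized windows to the library cap", {
  ## one spacer whose window holds 90 eligible variants (30 positions x 3)
  set.seed(41)
  seq <- paste0("ATCATCATCATCATCATCAT", "AGG",
                paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                      collapse = ""))
  ctx <- plain_ctx(seq)
  sp <- enumerate_spacers(ctx, c(16L, 19L))
  sp <- sp[sp$strand == "+" & sp$nick == 17L, ]
  bases <- strsplit(seq, "")[[1]]
  vars <- do.call(rbind, lapply(18:47, function(p) {
    do.call(rbind, lapply(setdiff(c("A", "C", "G", "T"), bases[p]),
                          function(alt) {
      data.frame(variant = sprintf("v%d%s", p, alt), source = "clinvar",
                 contig = ctx$contig_id, pos = p, ref = bases[p],
                 alt = alt, hgvs_c = NA, hgvs_p = NA,
                 consequence = "missense", significance_raw = NA,
                 class_label = "VUS", allele_count = NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  }))
  expect_equal(nrow(vars), 90L)
  w <- build_windows(sp, vars, design_params())
  sel <- select_windows(w, vars, "vus", n_target = 1L)
  expect_length(sel[[1]]$variant_ids, 60L)
  designs <- lapply(sel[[1]]$variant_ids, function(vid)
    design_epegrna(sel[[1]], vars[match(vid, vars$variant), ], ctx))
  expect_length(designs, 60L)
  expect_warning(select_windows(w, vars, "vus", n_target = 2L),
                 "only 1 candidate")
})

test_that("epegRNA geometry follows the stated construction rules", {
  seq <- paste0("ATCATCATCATCATCATCAT", "AGG",
                "TTGACCTGAACCTGAACCTGAACCTGAATT")
  ctx <- plain_ctx(seq)
  sp <- enumerate_spacers(ctx, c(1L, nchar(seq)))
  sp <- sp[sp$strand == "+", ][1, ]
  params <- design_params()
  vars <- mk_variants(18L, "VUS", ctx)  # variant at nick+1
  w <- build_windows(sp, vars, params)[[1]]
  d <- design_epegrna(w, vars[1, ], ctx, params)
  ## RTT spans nick+1 .. edit + 10 nt homology: offset 1 -> 11 nt
  expect_equal(nchar(d$rtt_seq), 11L)
  ## PBS is the reverse complement of the 13 nt 5' of the nick on the
  ## protospacer strand
  expect_equal(d$pbs_seq, oracle_revcomp(substr(seq, 17L - 13L + 1L, 17L)))
  ## spacer starts with A, so the U6 G is prepended
  expect_equal(substr(d$spacer_seq, 1, 2), "GA")
  expect_equal(nchar(d$spacer_seq), 21L)
  ## full sequence concatenation order
  expect_equal(d$full_seq, paste0(d$spacer_seq, d$scaffold_seq, d$rtt_seq,
                                  d$pbs_seq, d$motif_seq))
  ## RTT carries the substitution
  expect_equal(oracle_revcomp(d$rtt_seq),
               paste0(vars$alt[1], substr(seq, 19L, 28L)))
})

test_that("designs for variants the RTT cannot reach are rejected", {
  seq <- paste0("ATCATCATCATCATCATCAT", "AGG", strrep("ATC", 20))
  ctx <- plain_ctx(seq)
  sp <- enumerate_spacers(ctx, c(1L, nchar(seq)))[1, ]
  params <- design_params()
  w <- build_windows(sp, mk_variants(25L, "VUS", ctx), params)[[1]]
  ## a variant 5' of the nick (inside the protospacer) cannot be encoded
  up <- mk_variants(10L, "VUS", ctx)
  rej <- design_epegrna(w, up, ctx, params)
  expect_s3_class(rej, "design_rejection")
  expect_equal(rej$reason, "rtt_cannot_cover")
  ## far outside the window is a caller error
  expect_error(design_epegrna(w, mk_variants(100L, "VUS", ctx), ctx,
                              params),
               "outside the window")
})

test_that("flap synthesis of every emitted design reproduces the locus with
           exactly the intended substitution", {
  fix <- shared_design()
  seq <- fix$locus$ctx$sequence
  seq_bases <- strsplit(seq, "")[[1]]
  expect_gt(length(fix$design$designs), 80L)
  for (d in fix$design$designs) {
    recon <- oracle_flap_synthesis(seq, d)
    diff <- which(strsplit(recon, "")[[1]] != seq_bases)
    expect_identical(diff, d$pos)
    expect_equal(substr(recon, d$pos, d$pos), d$alt)
  }
})

test_that("internal BsaI sites are flagged, never mutated", {
  ## plant GGTCTC immediately downstream of the nick so the RTT contains
  ## its reverse complement
  seq <- paste0("ATCATCATCATCATCATCAT", "AGG",
                "TGGTCTCTTACCTGAACCTGAATTATTATT")
  ctx <- plain_ctx(seq)
  sp <- enumerate_spacers(ctx, c(1L, 30L))
  sp <- sp[sp$strand == "+" & sp$nick == 17L, ]
  vars <- mk_variants(40L, "VUS", ctx)
  w <- build_windows(sp, vars, design_params())[[1]]
  d <- design_epegrna(w, vars[1, ], ctx)
  expect_true("internal_bsai" %in% d$flags)
  expect_true(grepl("GGTCTC|GAGACC", d$full_seq))
})

test_that("PE3 nicking oligos follow the sticky-end convention", {
  fix <- shared_design()
  expect_gt(length(fix$design$ngrnas), 0L)
  for (g in fix$design$ngrnas) {
    expect_equal(g$strand != fix$design$windows[[
      which(vapply(fix$design$windows, function(w) w$window_id, "") ==
              g$window_id)]]$strand, TRUE)
    expect_true(abs(g$nick_offset) >= 40 && abs(g$nick_offset) <= 90)
    if (substr(g$spacer_seq, 1, 1) == "G") {
      expect_equal(g$top_oligo, paste0("CACC", g$spacer_seq))
      expect_equal(g$bottom_oligo,
                   paste0("AAAC", oracle_revcomp(g$spacer_seq)))
    } else {
      expect_equal(g$top_oligo, paste0("CACCG", g$spacer_seq))
      expect_equal(g$bottom_oligo,
                   paste0("AAAC", oracle_revcomp(g$spacer_seq), "C"))
    }
    ## annealing the oligos leaves 4-nt 5' overhangs CACC and AAAC:
    ## everything after the overhangs is a perfect duplex
    expect_equal(substring(g$top_oligo, 5L),
                 oracle_revcomp(substring(g$bottom_oligo, 5L)))
    expect_equal(substr(g$top_oligo, 1, 4), "CACC")
    expect_equal(substr(g$bottom_oligo, 1, 4), "AAAC")
  }
})

test_that("nicking design prefers offsets near 60 and reports absence", {
  fix <- shared_design()
  ctx <- fix$locus$ctx
  w <- fix$design$windows[[1]]
  g <- design_nicking(w, ctx)
  cand <- enumerate_spacers(ctx, c(w$nick - 120L, w$nick + 120L))
  cand <- cand[cand$strand != w$strand, ]
  off <- abs(cand$nick - w$nick)
  off <- off[off >= 40 & off <= 90]
  expect_equal(min(abs(off - 60)), abs(abs(g$nick_offset) - 60))
  ## a PAM-free locus has no PE3 candidate
  ctx2 <- plain_ctx(paste0(strrep("AT", 40), "AGG", strrep("AT", 40)))
  sp2 <- enumerate_spacers(ctx2, c(1L, nchar(ctx2$sequence)))
  w2 <- build_windows(sp2[1, ], mk_variants(100L, "VUS", ctx2),
                      design_params())[[1]]
  rej <- design_nicking(w2, ctx2)
  expect_s3_class(rej, "design_rejection")
  expect_equal(rej$reason, "no_pe3_nick")
})

test_that("editing-fraction QC applies a strict 15% boundary", {
  expect_true(qc_editing_fraction(16, 100)$pass)
  expect_false(qc_editing_fraction(15, 100)$pass)
  r <- qc_editing_fraction(0, 100)
  expect_false(r$pass)
  expect_equal(r$fraction_pct, 0)
  expect_error(qc_editing_fraction(0, 0), "zero")
})

test_that("amplicon validation enforces length, uniqueness and clearance", {
  set.seed(51)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  ctx <- plain_ctx(seq)
  edit_iv <- c(180L, 220L)
  fwd <- substr(seq, 101L, 120L)
  rev249 <- oracle_revcomp(substr(seq, 330L, 349L))  # amplicon 249 bp
  rev250 <- oracle_revcomp(substr(seq, 331L, 350L))  # amplicon 250 bp
  expect_true(validate_amplicon(fwd, rev249, ctx, edit_iv)$ok)
  expect_equal(validate_amplicon(fwd, rev249, ctx, edit_iv)$length, 249L)
  r250 <- validate_amplicon(fwd, rev250, ctx, edit_iv)
  expect_false(r250$ok)
  expect_equal(r250$reason, "amplicon_too_long")
  ## primer overlapping the assayed interval
  fwd_bad <- substr(seq, 175L, 194L)
  r_ov <- validate_amplicon(fwd_bad, rev249, ctx, edit_iv)
  expect_false(r_ov$ok)
  expect_equal(r_ov$reason, "primer_overlaps_target")
  ## same primer twice: same strand, not convergent
  r_same <- validate_amplicon(fwd, fwd, ctx, edit_iv)
  expect_false(r_same$ok)
  expect_equal(r_same$reason, "not_convergent")
  ## absent primer
  expect_equal(validate_amplicon(strrep("ACGT", 5), rev249, ctx,
                                 edit_iv)$reason,
               "primer_not_found")
})
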