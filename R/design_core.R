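#' Enumerate SpCas9 spacer sites in a region
#'
#' Finds every 20-nt protospacer adjacent to an NGG PAM on either strand
#' whose nick position lies inside `region`. The nick falls between
#' protospacer bases 17 and 18 (3 nt 5' of the PAM); it is reported as the
#' plus-strand coordinate `nick` such that the nick lies between `nick` and
#' `nick + 1`.
#'
#' @param ctx a [gene_context()].
#' @param region length-2 integer vector, 1-based inclusive plus-strand
#'   interval the nick must fall in.
#' @return data.frame with `strand`, `protospacer` (on its strand), `pam`,
#'   `protospacer_start` (plus-strand footprint start) and `nick`, in
#'   deterministic ascending (`nick`, strand) order.
#' @export
enumerate_spacers <- function(ctx, region) {
  n <- nchar(ctx$sequence)
  stopifnot(length(region) == 2L)
  if (region[1] < 1L || region[2] > n || region[1] > region[2])
    stop("region outside sequence bounds")
  seq <- ctx$sequence
  gg <- gregexpr("(?=GG)", seq, perl = TRUE)[[1]]
  cc <- gregexpr("(?=CC)", seq, perl = TRUE)[[1]]
  out <- list()
  ## plus strand: protospacer p..p+19, PAM p+20..p+22 (NGG);
  ## GG at q..q+1 with q = p+21
  if (gg[1] != -1L) for (q in as.integer(gg)) {
    p <- q - 21L
    if (p < 1L) next
    nick <- p + 16L
    if (nick < region[1] || nick > region[2] - 1L) next
    out[[length(out) + 1L]] <- data.frame(
      strand = "+", protospacer = substr(seq, p, p + 19L),
      pam = substr(seq, p + 20L, p + 22L),
      protospacer_start = p, nick = nick, stringsAsFactors = FALSE)
  }
  ## minus strand: CCN at q..q+2 on plus is the PAM; protospacer plus
  ## footprint g..g+19 with g = q+3; nick between plus g+2 and g+3
  if (cc[1] != -1L) for (q in as.integer(cc)) {
    g <- q + 3L
    if (g + 19L > n) next
    nick <- g + 2L
    if (nick < region[1] || nick > region[2] - 1L) next
    out[[length(out) + 1L]] <- data.frame(
      strand = "-", protospacer = revcomp(substr(seq, g, g + 19L)),
      pam = revcomp(substr(seq, q, q + 2L)),
      protospacer_start = g, nick = nick, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(strand = character(0), protospacer = character(0),
                      pam = character(0), protospacer_start = integer(0),
                      nick = integer(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$nick, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

window_id_of <- function(nick, strand)
  sprintf("w%06d%s", nick, ifelse(strand == "+", "p", "m"))

## plus-strand edit interval reachable by the RT template from a spacer
edit_interval_of <- function(spacer, max_edit_offset) {
  if (spacer$strand == "+")
    c(spacer$nick + 1L, spacer$nick + max_edit_offset)
  else
    c(spacer$nick - max_edit_offset + 1L, spacer$nick)
}

## signed offset of a plus-strand position from the nick, in the edited
## strand direction (offset 1 = first editable base)
edit_offset_of <- function(spacer, pos) {
  if (spacer$strand == "+") pos - spacer$nick else spacer$nick - pos + 1L
}

#' Build editing windows from spacer sites
#'
#' One window per spacer: the edit interval spans nick+1 to
#' nick+`max_edit_offset` in the edited-strand direction. Classified
#' variants falling in the interval are attached, with per-class tallies.
#'
#' @param spacers data.frame from [enumerate_spacers()].
#' @param variants classified variant data.frame.
#' @param params a [design_params()].
#' @return list of `editing_window` objects.
#' @export
build_windows <- function(spacers, variants, params = design_params()) {
  lapply(seq_len(nrow(spacers)), function(i) {
    sp <- spacers[i, , drop = FALSE]
    iv <- edit_interval_of(sp, params$max_edit_offset)
    hit <- variants$pos >= iv[1] & variants$pos <= iv[2]
    ids <- variants$variant[hit]
    cls <- variants$class_label[hit]
    structure(list(
      window_id = window_id_of(sp$nick, sp$strand),
      spacer = sp, strand = sp$strand, nick = sp$nick,
      edit_start = iv[1], edit_end = iv[2],
      variant_ids = ids,
      tallies = table(factor(cls, levels = c("VUS", "PLP", "BLB",
                                             "POP_SYN", "POP_MISSENSE",
                                             "PTC_CTRL", "OTHER")))
    ), class = "editing_window")
  })
}

#' @export
print.editing_window <- function(x, ...) {
  cat(sprintf("editing_window %s: nick %d (%s), edit %d-%d, %d variant(s)\n",
              x$window_id, x$nick, x$strand, x$edit_start, x$edit_end,
              length(x$variant_ids)))
  invisible(x)
}

.class_priority <- function(strategy) {
  if (strategy == "vus")
    c("VUS", "PLP", "BLB", "PTC_CTRL", "POP_SYN", "POP_MISSENSE", "OTHER")
  else
    c("PLP", "BLB", "PTC_CTRL", "POP_SYN", "POP_MISSENSE", "VUS", "OTHER")
}

## order and truncate a window's variant list to the library cap
truncate_window <- function(window, variants, strategy, library_cap) {
  v <- variants[match(window$variant_ids, variants$variant), , drop = FALSE]
  pri <- match(v$class_label, .class_priority(strategy))
  ord <- order(pri, v$pos, v$alt)
  keep <- head(window$variant_ids[ord], library_cap)
  window$variant_ids <- keep
  cls <- variants$class_label[match(keep, variants$variant)]
  window$tallies <- table(factor(cls, levels = names(window$tallies)))
  window
}

#' Select editing windows under a design strategy
#'
#' Greedy cover: each pick maximises the strategy score on variants not yet
#' covered by earlier picks (`vus`: count of VUS; `controls`: count of
#' PLP+BLB). Ties break by the other strategy's score, then by leftmost
#' nick, then strand. Each selected window's variant list is truncated to
#' the library cap by class priority (strategy class first, then clinical
#' controls, then PTC/population controls, then position).
#'
#' @param windows list from [build_windows()].
#' @param variants classified variant data.frame.
#' @param strategy `"vus"` (maximise VUS density) or `"controls"`
#'   (maximise ClinVar PLP/BLB coverage).
#' @param n_target number of windows (epegRNA libraries) to select.
#' @param params a [design_params()].
#' @return list of selected `editing_window`s (fewer than `n_target`, with
#'   a warning, if the candidates run out).
#' @export
select_windows <- function(windows, variants,
                           strategy = c("vus", "controls"),
                           n_target = 1L, params = design_params()) {
  strategy <- match.arg(strategy)
  stopifnot(n_target >= 1L)
  cls_of <- setNames(variants$class_label, variants$variant)
  score <- function(ids, classes) sum(cls_of[ids] %in% classes)
  main_cls <- if (strategy == "vus") "VUS" else c("PLP", "BLB")
  other_cls <- if (strategy == "vus") c("PLP", "BLB") else "VUS"
  covered <- character(0)
  pool <- windows
  picked <- list()
  while (length(picked) < n_target && length(pool) > 0L) {
    uncov <- lapply(pool, function(w) setdiff(w$variant_ids, covered))
    s_main <- vapply(uncov, score, 0, classes = main_cls)
    s_other <- vapply(uncov, score, 0, classes = other_cls)
    nicks <- vapply(pool, function(w) w$nick, 0L)
    strands <- vapply(pool, function(w) w$strand, "")
    ord <- order(-s_main, -s_other, nicks, strands)
    best <- ord[1]
    picked[[length(picked) + 1L]] <- pool[[best]]
    covered <- union(covered, pool[[best]]$variant_ids)
    pool <- pool[-best]
  }
  if (length(picked) < n_target)
    warning(sprintf("only %d candidate window(s) available (requested %d)",
                    length(picked), n_target))
  lapply(picked, truncate_window, variants = variants, strategy = strategy,
         library_cap = params$library_cap)
}

#' Design an epegRNA for one variant in an editing window
#'
#' Constructs spacer, RT template (RTT), primer-binding site (PBS) and the
#' full epegRNA (spacer + scaffold + RTT + PBS + 3' motif). The RTT is the
#' reverse complement of the edited-strand segment from nick+1 through the
#' edit plus `rtt_3p_homology` nt of downstream homology, with the variant
#' base substituted; the PBS is the reverse complement of the `pbs_len`
#' bases immediately 5' of the nick on the protospacer strand. A leading G
#' is prepended to the spacer (U6 rule) only when its first base is not
#' already G. Designs containing a BsaI site or a homopolymer run of 5+ in
#' the variable segments are flagged, never silently mutated.
#'
#' @param window an `editing_window`.
#' @param variant one-row variant data.frame.
#' @param ctx the [gene_context()].
#' @param params a [design_params()].
#' @return an `epeg_design`, or a `design_rejection` (with `$reason`) when
#'   the RT template cannot cover the variant.
#' @export
design_epegrna <- function(window, variant, ctx, params = design_params()) {
  stopifnot(nrow(variant) == 1L)
  pos <- variant$pos
  d <- edit_offset_of(window$spacer, pos)
  if (d < 1L)
    return(structure(list(variant = variant$variant,
                          window_id = window$window_id,
                          reason = "rtt_cannot_cover"),
                     class = "design_rejection"))
  if (pos < window$edit_start || pos > window$edit_end)
    stop("variant lies outside the window's edit interval")
  seq <- ctx$sequence
  if (substr(seq, pos, pos) != variant$ref)
    stop(sprintf("reference mismatch for %s: genome has %s",
                 variant$variant, substr(seq, pos, pos)))
  nick <- window$nick
  L <- d + params$rtt_3p_homology
  seq_ed <- seq
  substr(seq_ed, pos, pos) <- variant$alt
  if (window$strand == "+") {
    if (nick + L > nchar(seq) || nick - params$pbs_len + 1L < 1L)
      stop("RTT/PBS extends beyond the contig")
    flap <- substr(seq_ed, nick + 1L, nick + L)
    rtt <- revcomp(flap)
    pbs <- revcomp(substr(seq, nick - params$pbs_len + 1L, nick))
  } else {
    if (nick - L + 1L < 1L || nick + params$pbs_len > nchar(seq))
      stop("RTT/PBS extends beyond the contig")
    rtt <- substr(seq_ed, nick - L + 1L, nick)
    flap <- revcomp(rtt)
    pbs <- substr(seq, nick + 1L, nick + params$pbs_len)
  }
  spacer_seq <- window$spacer$protospacer
  if (substr(spacer_seq, 1L, 1L) != "G")
    spacer_seq <- paste0("G", spacer_seq)
  full <- paste0(spacer_seq, params$scaffold_seq, rtt, pbs,
                 params$motif_seq)
  flags <- c(
    if (any(vapply(params$bsai_sites, grepl, TRUE, x = full,
                   fixed = TRUE))) "internal_bsai",
    if (.has_homopolymer(spacer_seq) || .has_homopolymer(paste0(rtt, pbs)))
      "homopolymer_ge5")
  design <- structure(list(
    variant = variant$variant, class_label = variant$class_label,
    window_id = window$window_id, strand = window$strand, nick = nick,
    pos = pos, ref = variant$ref, alt = variant$alt, offset = d,
    spacer_seq = spacer_seq, scaffold_seq = params$scaffold_seq,
    rtt_seq = rtt, pbs_seq = pbs, motif_seq = params$motif_seq,
    full_seq = full,
    pool_oligo_seq = paste0(params$pool_tail_left, full,
                            params$pool_tail_right),
    flags = as.character(flags)
  ), class = "epeg_design")
  ## defensive self-check: flap synthesis must reproduce the locus with
  ## exactly the one intended substitution
  recon <- .apply_flap(ctx$sequence, design)
  diffs <- which(strsplit(recon, "")[[1]] != strsplit(ctx$sequence, "")[[1]])
  if (!identical(diffs, pos) || substr(recon, pos, pos) != variant$alt)
    stop("internal error: flap reconstruction failed for ", variant$variant)
  design
}

## replace the nicked-strand segment with the 3' flap encoded by the RTT
.apply_flap <- function(sequence, design) {
  L <- nchar(design$rtt_seq)
  if (design$strand == "+") {
    flap <- revcomp(design$rtt_seq)
    substr(sequence, design$nick + 1L, design$nick + L) <- flap
  } else {
    substr(sequence, design$nick - L + 1L, design$nick) <- design$rtt_seq
  }
  sequence
}

#' @export
print.epeg_design <- function(x, ...) {
  cat(sprintf("epeg_design %s [%s] offset %d nt, %d-nt RTT, %d-nt PBS%s\n",
              x$variant, x$window_id, x$offset, nchar(x$rtt_seq),
              nchar(x$pbs_seq),
              if (length(x$flags)) paste0(" flags: ",
                                          paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Design the PE3 nicking gRNA for an editing window
#'
#' Scans the strand opposite the pegRNA for NGG spacers whose nick-to-nick
#' distance falls in the allowed range, picking the candidate closest to
#' the preferred distance (ties: smaller distance, then leftmost). Cloning
#' oligos follow the U6 sticky-end convention: the top oligo is
#' `CACCG` + spacer (or `CACC` + spacer when the spacer natively starts
#' with G) and the bottom oligo is `AAAC` + reverse complement of the
#' spacer (+ trailing `C` in the added-G case).
#'
#' @param window an `editing_window`.
#' @param ctx the [gene_context()].
#' @param params a [design_params()].
#' @return a `nicking_grna`, or a `design_rejection` with reason
#'   `"no_pe3_nick"`.
#' @export
design_nicking <- function(window, ctx, params = design_params()) {
  rng <- params$ngrna_offset_range
  lo <- max(1L, window$nick - rng[2] - 30L)
  hi <- min(nchar(ctx$sequence), window$nick + rng[2] + 30L)
  cand <- enumerate_spacers(ctx, c(lo, hi))
  cand <- cand[cand$strand != window$strand, , drop = FALSE]
  if (nrow(cand)) {
    off <- cand$nick - window$nick
    keep <- abs(off) >= rng[1] & abs(off) <= rng[2]
    cand <- cand[keep, , drop = FALSE]
    off <- off[keep]
  }
  if (!nrow(cand))
    return(structure(list(window_id = window$window_id,
                          reason = "no_pe3_nick"),
                     class = "design_rejection"))
  ord <- order(abs(abs(off) - params$ngrna_offset_pref), abs(off),
               cand$nick)
  sp <- cand[ord[1], , drop = FALSE]
  spacer <- sp$protospacer
  native_g <- substr(spacer, 1L, 1L) == "G"
  top <- paste0(if (native_g) "CACC" else "CACCG", spacer)
  bottom <- paste0("AAAC", revcomp(spacer), if (native_g) "" else "C")
  structure(list(
    window_id = window$window_id, spacer_seq = spacer,
    strand = sp$strand, nick = sp$nick,
    nick_offset = sp$nick - window$nick,
    top_oligo = top, bottom_oligo = bottom
  ), class = "nicking_grna")
}

#' @export
print.nicking_grna <- function(x, ...) {
  cat(sprintf("nicking_grna for %s: offset %+d bp (%s strand)\n",
              x$window_id, x$nick_offset, x$strand))
  invisible(x)
}

#' Editing-efficiency QC on aligned read counts
#'
#' Computes the edited fraction at a target and applies the archetypal
#' epegRNA screen rule: pass only if strictly more than `threshold_pct`
#' percent of reads carry the edit.
#'
#' @param edited,total nonnegative aligned read counts (total > 0).
#' @param threshold_pct pass boundary in percent (strict `>`).
#' @return list with `fraction_pct` and `pass`.
#' @export
qc_editing_fraction <- function(edited, total, threshold_pct = 15) {
  stopifnot(edited >= 0, total >= edited)
  if (total == 0) stop("editing fraction undefined: total count is zero")
  frac <- 100 * edited / total
  list(fraction_pct = frac, pass = frac > threshold_pct)
}

.count_fixed <- function(subject, pattern) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Validate an amplicon-sequencing primer pair
#'
#' Both primers must map uniquely to the contig on opposite, convergent
#' strands. The amplicon must be shorter than `max_len` (to maximise read
#' depth over the target with 2 x 150 bp reads) and neither primer may
#' overlap the assayed edit interval (so small indels remain detectable).
#'
#' @param fwd,rev primer sequences (rev as ordered, i.e. reverse
#'   complement of the plus strand).
#' @param ctx the [gene_context()].
#' @param edit_interval length-2 plus-strand interval being assayed.
#' @param max_len exclusive amplicon length bound in bp.
#' @return list with `ok`, `reason` (`NA` when ok), `length`, `interval`.
#' @export
validate_amplicon <- function(fwd, rev, ctx, edit_interval,
                              max_len = 250L) {
  seq <- ctx$sequence
  bad <- function(reason) list(ok = FALSE, reason = reason,
                               length = NA_integer_, interval = NULL)
  f_plus <- .count_fixed(seq, fwd)
  f_minus <- .count_fixed(seq, revcomp(fwd))
  r_minus <- .count_fixed(seq, revcomp(rev))  # rev binds the plus strand here
  r_plus <- .count_fixed(seq, rev)
  if (length(f_plus) + length(f_minus) == 0L ||
      length(r_minus) + length(r_plus) == 0L)
    return(bad("primer_not_found"))
  if (length(f_plus) + length(f_minus) > 1L ||
      length(r_minus) + length(r_plus) > 1L)
    return(bad("primer_multimaps"))
  if (length(f_plus) != 1L || length(r_minus) != 1L)
    return(bad("not_convergent"))
  f_start <- f_plus[1]; f_end <- f_start + nchar(fwd) - 1L
  r_start <- r_minus[1]; r_end <- r_start + nchar(rev) - 1L
  if (r_start <= f_end) return(bad("not_convergent"))
  len <- r_end - f_start + 1L
  if (len >= max_len) return(bad("amplicon_too_long"))
  overlaps <- function(a1, a2) a1 <= edit_interval[2] && a2 >= edit_interval[1]
  if (overlaps(f_start, f_end) || overlaps(r_start, r_end))
    return(bad("primer_overlaps_target"))
  list(ok = TRUE, reason = NA_character_, length = len,
       interval = c(f_start, r_end))
}

#' Check the archetypal epegRNA screen size
#'
#' At least `min_archetypes` archetypal epegRNAs should be screened; with
#' a 50-75% dropout at the screen stage this typically yields 3-6 usable
#' libraries.
#'
#' @param n_archetypes number of archetypal epegRNAs planned.
#' @param min_archetypes recommended minimum.
#' @return list with `pass`, `n`, `min`.
#' @export
check_archetype_count <- function(n_archetypes,
                                  min_archetypes = design_params()$min_archetypes) {
  list(pass = n_archetypes >= min_archetypes, n = n_archetypes,
       min = min_archetypes)
}
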