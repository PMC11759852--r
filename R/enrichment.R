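#' Compute allele frequencies from count records
#'
#' Allele frequency is the variant k-mer count relative to the depth of
#' sequencing of its sample.
#'
#' @param count_records data.frame from [counts_to_table()].
#' @return the records with an `af` column.
#' @export
compute_af <- function(count_records) {
  if (any(count_records$total_reads <= 0))
    stop("allele frequency undefined: sample with zero total reads")
  count_records$af <- count_records$count / count_records$total_reads
  count_records
}

#' Filter variants on unselected-pool allele frequency
#'
#' Variants below the allele-frequency threshold in the unselected
#' (control) pools tend to have out-of-range enrichment scores and high
#' replicate variability, so they are excluded before scoring. The test is
#' strict (`af < threshold`); a variant exactly at the threshold is
#' retained. Under `any_replicate` (conservative default) one low control
#' replicate suffices for exclusion; under `all_replicates` every control
#' replicate must be low.
#'
#' @param af_table output of [compute_af()].
#' @param threshold allele-frequency exclusion boundary (default 0.001,
#'   i.e. 0.1%).
#' @param mode `"any_replicate"` or `"all_replicates"`.
#' @return list with `table` (retained rows) and `excluded` (data.frame
#'   `variant`, `reason`).
#' @export
filter_low_af <- function(af_table, threshold = 0.001,
                          mode = c("any_replicate", "all_replicates")) {
  mode <- match.arg(mode)
  ctrl <- af_table[af_table$condition == "control", , drop = FALSE]
  if (!nrow(ctrl)) stop("no control-condition records present")
  low <- tapply(ctrl$af < threshold, ctrl$variant,
                if (mode == "any_replicate") any else all)
  excluded_ids <- names(low)[low]
  list(
    table = af_table[!af_table$variant %in% excluded_ids, , drop = FALSE],
    excluded = data.frame(
      variant = excluded_ids,
      reason = rep(sprintf("control_af_below_%g_(%s)", threshold, mode),
                   length(excluded_ids)),
      stringsAsFactors = FALSE))
}

#' Per-replicate enrichment scores
#'
#' For each variant and replicate with both conditions present, the score
#' is the natural-log ratio of pseudocounted frequencies,
#' `s = ln((c_sel + 0.5)/N_sel) - ln((c_ctrl + 0.5)/N_ctrl)`, with
#' count-reciprocal variance `v = 1/(c_sel + 0.5) + 1/(c_ctrl + 0.5)`
#' (Enrich2-style). Replicates missing a condition are dropped with a
#' warning.
#'
#' @param count_records data.frame with `condition`, `replicate`,
#'   `variant`, `count`, `total_reads`.
#' @param pseudocount added to every count (default 0.5).
#' @return data.frame with `variant`, `replicate`, `s`, `v`.
#' @export
replicate_scores <- function(count_records, pseudocount = 0.5) {
  key <- interaction(count_records$variant, count_records$replicate,
                     drop = TRUE)
  out <- lapply(split(count_records, key), function(g) {
    sel <- g[g$condition == "selected", , drop = FALSE]
    ctr <- g[g$condition == "control", , drop = FALSE]
    if (nrow(sel) != 1L || nrow(ctr) != 1L) {
      warning(sprintf("replicate %s of %s lacks a condition; dropped",
                      g$replicate[1], g$variant[1]))
      return(NULL)
    }
    data.frame(
      variant = g$variant[1], replicate = g$replicate[1],
      s = log((sel$count + pseudocount) / sel$total_reads) -
        log((ctr$count + pseudocount) / ctr$total_reads),
      v = 1 / (sel$count + pseudocount) + 1 / (ctr$count + pseudocount),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$variant, out$replicate), , drop = FALSE]
}

#' DerSimonian-Laird random-effects combination
#'
#' Combines per-replicate scores into a single functional score (beta)
#' with standard error, allowing between-replicate heterogeneity:
#' `tau2 = max(0, (Q - (R-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' `w = 1/v` and Q the weighted heterogeneity statistic; then
#' `beta = sum(w* s)/sum(w*)` and `se = sqrt(1/sum(w*))` with
#' `w* = 1/(v + tau2)`. A single replicate collapses to `beta = s`,
#' `se = sqrt(v)`, `tau2 = 0`.
#'
#' @param s numeric vector of per-replicate scores.
#' @param v numeric vector of their variances (positive).
#' @return list with `beta`, `se`, `tau2`, `Q`, `r`.
#' @export
random_effects <- function(s, v) {
  if (length(s) == 0L) stop("no replicate scores supplied")
  stopifnot(length(s) == length(v), all(v > 0))
  r <- length(s)
  w <- 1 / v
  mu_fe <- sum(w * s) / sum(w)
  Q <- sum(w * (s - mu_fe)^2)
  tau2 <- if (r > 1L) max(0, (Q - (r - 1)) / (sum(w) - sum(w^2) / sum(w)))
          else 0
  ws <- 1 / (v + tau2)
  beta <- sum(ws * s) / sum(ws)
  list(beta = beta, se = sqrt(1 / sum(ws)), tau2 = tau2, Q = Q, r = r)
}

#' Score variants from count records
#'
#' Full scoring pass: allele frequencies, the unselected-AF filter,
#' per-replicate log-enrichment scores, and the random-effects
#' combination into beta and SE per variant. Dictionary WT entries
#' (names starting `WT_`) are excluded from scoring.
#'
#' @param count_records data.frame from [counts_to_table()] or
#'   [read_counts_csv()].
#' @param classes optional data.frame with `variant`, `class_label` used
#'   to annotate scores.
#' @param af_threshold,filter_mode passed to [filter_low_af()].
#' @param pseudocount passed to [replicate_scores()].
#' @return data.frame of class `score_table`: `variant`, `class_label`,
#'   `n_rep`, `beta`, `se`, `tau2`, `filtered`, `filter_reason`; the
#'   per-replicate scores are attached as attribute `"replicates"`.
#' @export
score_variants <- function(count_records, classes = NULL,
                           af_threshold = 0.001,
                           filter_mode = "any_replicate",
                           pseudocount = 0.5) {
  count_records <- count_records[!startsWith(count_records$variant, "WT_"),
                                 , drop = FALSE]
  af <- compute_af(count_records)
  flt <- filter_low_af(af, threshold = af_threshold, mode = filter_mode)
  variants <- sort(unique(count_records$variant))
  scored <- if (nrow(flt$table)) replicate_scores(flt$table,
                                                  pseudocount = pseudocount)
            else NULL
  rows <- lapply(variants, function(vid) {
    if (vid %in% flt$excluded$variant) {
      return(data.frame(variant = vid, n_rep = 0L, beta = NA_real_,
                        se = NA_real_, tau2 = NA_real_, filtered = TRUE,
                        filter_reason = flt$excluded$reason[
                          match(vid, flt$excluded$variant)],
                        stringsAsFactors = FALSE))
    }
    g <- scored[scored$variant == vid, , drop = FALSE]
    fit <- random_effects(g$s, g$v)
    data.frame(variant = vid, n_rep = fit$r, beta = fit$beta, se = fit$se,
               tau2 = fit$tau2, filtered = FALSE,
               filter_reason = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$class_label <- if (!is.null(classes))
    classes$class_label[match(out$variant, classes$variant)]
  else NA_character_
  out <- out[, c("variant", "class_label", "n_rep", "beta", "se", "tau2",
                 "filtered", "filter_reason")]
  attr(out, "replicates") <- scored
  class(out) <- c("score_table", "data.frame")
  out
}

#' Score a paired-column counts CSV
#'
#' Reads a counts CSV (variant column plus `counts_control_repN` /
#' `counts_selected_repN` pairs), scores it, and writes the output CSV:
#' the unfiltered input rows with exactly two appended columns, `beta`
#' and `SE`.
#'
#' @param input_csv,output_csv file paths.
#' @param totals optional per-sample totals (see [read_counts_csv()]).
#' @param ... passed to [score_variants()].
#' @return the score table, invisibly.
#' @export
score_counts_csv <- function(input_csv, output_csv, totals = NULL, ...) {
  records <- read_counts_csv(input_csv, totals = totals)
  scores <- score_variants(records, ...)
  tab <- read.csv(input_csv, check.names = FALSE, stringsAsFactors = FALSE)
  m <- match(tab[[1]], scores$variant)
  tab$beta <- scores$beta[m]
  tab$SE <- scores$se[m]
  tab <- tab[!is.na(tab$beta), , drop = FALSE]
  write.csv(tab, output_csv, row.names = FALSE)
  invisible(scores)
}

#' Normalise functional scores across epegRNA libraries
#'
#' Centres each library's neutral class at zero by subtracting the median
#' beta of its synonymous and BLB variants; optionally rescales by the
#' absolute median PTC beta so loss-of-function sits near -1 (or 1 unit).
#' Libraries with too few anchors are left unnormalised with a warning.
#'
#' @param score_tables list of `score_table`s, one per library.
#' @param scale_by_ptc divide by |median PTC beta| when at least
#'   `min_anchors` PTC variants are scored.
#' @param min_anchors minimum neutral anchors (POP_SYN + BLB) required.
#' @return list of score tables with adjusted `beta` (and `se` when
#'   rescaled); each carries a `normalization` attribute.
#' @export
normalize_scores <- function(score_tables, scale_by_ptc = FALSE,
                             min_anchors = 3L) {
  lapply(score_tables, function(tab) {
    ok <- !tab$filtered
    anchors <- ok & tab$class_label %in% c("POP_SYN", "BLB")
    if (sum(anchors) < min_anchors) {
      warning("too few neutral anchors; library left unnormalised")
      attr(tab, "normalization") <- list(center = 0, scale = 1,
                                         applied = FALSE)
      return(tab)
    }
    center <- median(tab$beta[anchors])
    tab$beta <- tab$beta - center
    scale <- 1
    ptc <- ok & tab$class_label == "PTC_CTRL"
    if (scale_by_ptc && sum(ptc) >= min_anchors) {
      scale <- abs(median(tab$beta[ptc]))
      if (scale > 0) {
        tab$beta <- tab$beta / scale
        tab$se <- tab$se / scale
      }
    }
    attr(tab, "normalization") <- list(center = center, scale = scale,
                                       applied = TRUE)
    tab
  })
}

## rank-based AUROC: probability a draw from `hi` exceeds one from `lo`
## (ties count 1/2); equals the Mann-Whitney U statistic scaled to [0,1]
.auroc <- function(hi, lo) {
  if (!length(hi) || !length(lo)) return(NA_real_)
  r <- rank(c(hi, lo))
  (sum(r[seq_along(hi)]) - length(hi) * (length(hi) + 1) / 2) /
    (length(hi) * length(lo))
}

#' Evaluate truth-set separation of functional scores
#'
#' Reports per-class summaries and rank-based AUROC for the two truth-set
#' contrasts: population synonymous vs PTC (assay validation) and ClinVar
#' BLB vs PLP (clinical). AUROC is the probability that a negative-control
#' variant scores above a positive-control variant, i.e. 1.0 means the
#' depleted class is perfectly separated below the neutral class.
#'
#' @param scores a `score_table` (filtered rows are ignored).
#' @return object of class `separation_report`.
#' @export
evaluate_truth_sets <- function(scores) {
  ok <- scores[!scores$filtered & !is.na(scores$beta), , drop = FALSE]
  if (length(unique(ok$class_label[!is.na(ok$class_label)])) < 2L)
    stop("need scored variants from at least two classes")
  cls_stats <- do.call(rbind, lapply(
    split(ok, ok$class_label), function(g)
      data.frame(class_label = g$class_label[1], n = nrow(g),
                 median = median(g$beta),
                 iqr = unname(diff(quantile(g$beta, c(0.25, 0.75)))),
                 stringsAsFactors = FALSE)))
  rownames(cls_stats) <- NULL
  beta_of <- function(cl) ok$beta[ok$class_label == cl]
  auroc_syn_ptc <- .auroc(beta_of("POP_SYN"), beta_of("PTC_CTRL"))
  auroc_blb_plp <- .auroc(beta_of("BLB"), beta_of("PLP"))
  verdict <- paste0(
    if (is.na(auroc_syn_ptc)) "assay validation contrast not computable"
    else sprintf("synonymous/PTC separation AUROC %.3f (%s)",
                 auroc_syn_ptc,
                 if (auroc_syn_ptc > 0.95) "well separated"
                 else "weak separation"),
    "; ",
    if (is.na(auroc_blb_plp)) "clinical contrast not computable"
    else sprintf("BLB/PLP separation AUROC %.3f", auroc_blb_plp))
  structure(list(class_stats = cls_stats,
                 auroc_syn_vs_ptc = auroc_syn_ptc,
                 auroc_blb_vs_plp = auroc_blb_plp,
                 verdict = verdict),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("Truth-set separation\n")
  print(x$class_stats, row.names = FALSE)
  cat(" ", x$verdict, "\n")
  invisible(x)
}

#' Write a separation report to JSON and markdown
#'
#' @param report a `separation_report`.
#' @param json_path,md_path output paths (either may be `NULL`).
#' @return the paths, invisibly.
#' @export
write_separation_report <- function(report, json_path = NULL,
                                    md_path = NULL) {
  if (!is.null(json_path))
    .write_json(list(class_stats = report$class_stats,
                     auroc_syn_vs_ptc = report$auroc_syn_vs_ptc,
                     auroc_blb_vs_plp = report$auroc_blb_vs_plp,
                     verdict = report$verdict), json_path)
  if (!is.null(md_path)) {
    lines <- c("# Truth-set separation", "",
               "| class | n | median beta | IQR |",
               "|---|---|---|---|",
               sprintf("| %s | %d | %.3f | %.3f |",
                       report$class_stats$class_label,
                       report$class_stats$n, report$class_stats$median,
                       report$class_stats$iqr),
               "", report$verdict)
    writeLines(lines, md_path)
  }
  invisible(c(json = json_path, md = md_path))
}
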