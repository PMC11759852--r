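mk_counts <- function(counts_ctrl, counts_sel, n_ctrl = 300000L,
                      n_sel = 300000L, variants = NULL) {
  r <- length(counts_ctrl[[1]])
  variants <- variants %||% names(counts_ctrl)
  out <- list()
  for (i in seq_along(variants)) for (rep_i in seq_len(r)) {
    out[[length(out) + 1L]] <- data.frame(
      sample_id = sprintf("control_rep%d", rep_i), condition = "control",
      replicate = rep_i, variant = variants[i],
      count = counts_ctrl[[i]][rep_i], total_reads = n_ctrl,
      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      sample_id = sprintf("selected_rep%d", rep_i),
      condition = "selected", replicate = rep_i, variant = variants[i],
      count = counts_sel[[i]][rep_i], total_reads = n_sel,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("allele frequency is count over sequencing depth", {
  cr <- mk_counts(list(v1 = 300L), list(v1 = 0L))
  af <- compute_af(cr)
  expect_equal(af$af[af$condition == "control"], 0.001)
  expect_equal(af$af[af$condition == "selected"], 0)
  cr$total_reads <- 0L
  expect_error(compute_af(cr), "zero total")
})

test_that("the unselected-AF filter is strict at 0.1%", {
  cr <- mk_counts(
    list(low = c(270L, 400L), at = c(300L, 300L), zero = c(0L, 0L)),
    list(low = c(100L, 100L), at = c(100L, 100L), zero = c(0L, 0L)))
  af <- compute_af(cr)  # low: 0.0009 in replicate 1
  any_mode <- filter_low_af(af, mode = "any_replicate")
  expect_setequal(any_mode$excluded$variant, c("low", "zero"))
  expect_true("at" %in% any_mode$table$variant)  # exactly 0.001 retained
  all_mode <- filter_low_af(af, mode = "all_replicates")
  expect_setequal(all_mode$excluded$variant, "zero")
})

test_that("raising the AF threshold never un-excludes a variant", {
  set.seed(71)
  cr <- mk_counts(as.list(setNames(replicate(30, rpois(3, 400),
                                             simplify = FALSE),
                                   paste0("v", 1:30))),
                  as.list(setNames(replicate(30, rpois(3, 200),
                                             simplify = FALSE),
                                   paste0("v", 1:30))))
  af <- compute_af(cr)
  prev <- character(0)
  for (thr in c(0.0005, 0.001, 0.0013, 0.0016, 0.002)) {
    ex <- filter_low_af(af, threshold = thr)$excluded$variant
    expect_true(all(prev %in% ex))
    prev <- ex
  }
})

test_that("replicate scores follow the pseudocounted log-ratio", {
  ## symmetric counts give score zero
  cr <- mk_counts(list(v = c(50L)), list(v = c(50L)))
  s <- replicate_scores(cr)
  expect_equal(s$s, 0)
  ## hand-computed oracle: ln(99.5/9.5), v = 1/99.5 + 1/9.5
  cr2 <- mk_counts(list(v = c(9L)), list(v = c(99L)),
                   n_ctrl = 100000L, n_sel = 100000L)
  s2 <- replicate_scores(cr2)
  expect_equal(s2$s, log(99.5 / 9.5), tolerance = 1e-12)
  expect_equal(s2$s, 2.349, tolerance = 1e-3)
  expect_equal(s2$v, 1 / 99.5 + 1 / 9.5, tolerance = 1e-12)
  expect_equal(s2$v, 0.1153, tolerance = 1e-3)
  ## zero selected count stays finite through the pseudocount
  cr3 <- mk_counts(list(v = c(80L)), list(v = c(0L)))
  expect_true(is.finite(replicate_scores(cr3)$s))
  ## a replicate missing one condition is dropped with a warning
  cr4 <- mk_counts(list(v = c(10L, 20L)), list(v = c(10L, 20L)))
  cr4 <- cr4[!(cr4$replicate == 2 & cr4$condition == "selected"), ]
  expect_warning(s4 <- replicate_scores(cr4), "dropped")
  expect_equal(nrow(s4), 1L)
})

test_that("random-effects combination matches its closed forms", {
  ## single replicate collapses to the replicate score
  fit1 <- random_effects(1.7, 0.04)
  expect_equal(fit1$beta, 1.7)
  expect_equal(fit1$se, 0.2)
  expect_equal(fit1$tau2, 0)
  ## identical replicates: Q = 0, tau2 = 0, se = sqrt(v/R)
  fit3 <- random_effects(rep(1.2, 3), rep(0.09, 3))
  expect_equal(fit3$tau2, 0)
  expect_equal(fit3$beta, 1.2)
  expect_equal(fit3$se, sqrt(0.09 / 3))
  ## symmetric heterogeneous fixture centres on the middle value
  fith <- random_effects(c(1, 2, 3), c(0.1, 0.1, 0.1))
  expect_equal(fith$beta, 2)
  expect_gt(fith$tau2, 0)
  expect_error(random_effects(numeric(0), numeric(0)), "no replicate")
})

test_that("random-effects matches an independent DerSimonian-Laird fit", {
  skip_if_not_installed("metafor")
  set.seed(72)
  for (i in 1:50) {
    r <- sample(2:6, 1)
    s <- rnorm(r, sd = 2)
    v <- runif(r, 0.005, 0.5)
    mine <- random_effects(s, v)
    ref <- metafor::rma(yi = s, vi = v, method = "DL")
    expect_equal(mine$beta, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(mine$se, ref$se, tolerance = 1e-8)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-8)
  }
})

test_that("beta is invariant to rescaling depth and se shrinks as 1/sqrt(R)", {
  set.seed(73)
  counts_c <- list(v = c(400L, 380L, 420L))
  counts_s <- list(v = c(150L, 160L, 140L))
  base <- score_variants(mk_counts(counts_c, counts_s))
  scaled <- score_variants(mk_counts(counts_c, counts_s,
                                     n_ctrl = 3000000L, n_sel = 3000000L),
                           af_threshold = 0)
  expect_equal(base$beta, scaled$beta, tolerance = 1e-12)
  ## homogeneous replicates: se at 4 replicates = se at 1 / 2
  fit1 <- random_effects(0.5, 0.16)
  fit4 <- random_effects(rep(0.5, 4), rep(0.16, 4))
  expect_equal(fit4$se, fit1$se / 2)
})

test_that("score_variants assembles filtered and scored records", {
  cr <- mk_counts(list(good = c(600L, 650L, 580L), low = c(5L, 900L, 900L),
                       WT_w1 = c(1000L, 1000L, 1000L)),
                  list(good = c(60L, 65L, 58L), low = c(5L, 900L, 900L),
                       WT_w1 = c(1000L, 1000L, 1000L)))
  classes <- data.frame(variant = c("good", "low"),
                        class_label = c("PLP", "VUS"))
  sc <- score_variants(cr, classes = classes)
  expect_equal(nrow(sc), 2L)  # WT entries never scored
  expect_true(sc$filtered[sc$variant == "low"])
  expect_true(is.na(sc$beta[sc$variant == "low"]))
  good <- sc[sc$variant == "good", ]
  expect_false(good$filtered)
  expect_equal(good$n_rep, 3L)
  expect_lt(good$beta, 0)
  expect_gt(good$se, 0)
  reps <- attr(sc, "replicates")
  expect_true(good$beta >= min(reps$s[reps$variant == "good"]) &
                good$beta <= max(reps$s[reps$variant == "good"]))
})

test_that("scored CSV equals the input plus exactly beta and SE columns", {
  cr <- mk_counts(list(v1 = c(600L, 650L), v2 = c(700L, 720L),
                       dead = c(0L, 0L)),
                  list(v1 = c(60L, 65L), v2 = c(700L, 720L),
                       dead = c(0L, 0L)))
  in_csv <- tempfile(fileext = ".csv")
  out_csv <- tempfile(fileext = ".csv")
  write_counts_csv(cr, in_csv)
  totals <- unique(cr[, c("condition", "replicate", "total_reads")])
  score_counts_csv(in_csv, out_csv, totals = totals)
  input <- read.csv(in_csv, check.names = FALSE)
  output <- read.csv(out_csv, check.names = FALSE)
  expect_equal(names(output), c(names(input), "beta", "SE"))
  ## unfiltered rows only, otherwise identical to the input
  expect_equal(output$variant, c("v1", "v2"))
  expect_equal(output[names(input)],
               input[input$variant %in% c("v1", "v2"), ],
               ignore_attr = TRUE)
})

mk_scores <- function(betas, classes, filtered = FALSE) {
  out <- data.frame(variant = paste0("v", seq_along(betas)),
                    class_label = classes, n_rep = 3L, beta = betas,
                    se = 0.1, tau2 = 0, filtered = filtered,
                    filter_reason = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

test_that("normalisation centres the neutral class median at zero", {
  tab <- mk_scores(c(0.4, 0.4, 0.42, -1.2, -1.0, 0.38),
                   c("POP_SYN", "POP_SYN", "BLB", "PTC_CTRL", "PLP",
                     "POP_SYN"))
  out <- normalize_scores(list(tab))[[1]]
  expect_equal(median(out$beta[out$class_label %in%
                                 c("POP_SYN", "BLB")]), 0)
  expect_equal(out$beta[1], 0.4 - 0.4)
  ## an already-centred library is unchanged
  again <- normalize_scores(list(out))[[1]]
  expect_equal(again$beta, out$beta)
  ## too few anchors: warn and leave untouched
  small <- mk_scores(c(0.4, -1), c("POP_SYN", "PTC_CTRL"))
  expect_warning(res <- normalize_scores(list(small)), "anchors")
  expect_equal(res[[1]]$beta, small$beta)
})

test_that("congruent libraries align after normalisation", {
  set.seed(74)
  classes <- rep(c("POP_SYN", "BLB", "PTC_CTRL", "PLP", "VUS"),
                 times = c(8, 4, 8, 4, 10))
  true_effect <- ifelse(classes %in% c("PTC_CTRL", "PLP"), -1.5, 0)
  libA <- mk_scores(true_effect + rnorm(34, 0, 0.05) + 0.7, classes)
  libB <- mk_scores(true_effect + rnorm(34, 0, 0.05) - 0.3, classes)
  out <- normalize_scores(list(libA, libB))
  medA <- tapply(out[[1]]$beta, out[[1]]$class_label, median)
  medB <- tapply(out[[2]]$beta, out[[2]]$class_label, median)
  expect_equal(unname(medA[c("PTC_CTRL", "POP_SYN", "VUS")]),
               unname(medB[c("PTC_CTRL", "POP_SYN", "VUS")]),
               tolerance = 0.1)
})

test_that("separation report computes rank AUROC with edge cases", {
  perfect <- mk_scores(c(0.1, 0.2, 0.05, -2, -1.8, -2.2),
                       rep(c("POP_SYN", "PTC_CTRL"), each = 3))
  rep1 <- evaluate_truth_sets(perfect)
  expect_equal(rep1$auroc_syn_vs_ptc, 1.0)
  expect_true(is.na(rep1$auroc_blb_vs_plp))
  ## identical distributions sit near 0.5
  set.seed(75)
  x <- rnorm(400)
  null <- mk_scores(x, rep(c("POP_SYN", "PTC_CTRL"), 200))
  expect_equal(evaluate_truth_sets(null)$auroc_syn_vs_ptc, 0.5,
               tolerance = 0.08)
  expect_error(evaluate_truth_sets(mk_scores(1, "POP_SYN")),
               "two classes")
})

test_that("rank AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(76)
  scores <- mk_scores(c(rnorm(25, 0, 0.5), rnorm(20, -1, 0.7)),
                      rep(c("POP_SYN", "PTC_CTRL"), c(25, 20)))
  mine <- evaluate_truth_sets(scores)$auroc_syn_vs_ptc
  ref <- pROC::auc(pROC::roc(
    response = scores$class_label == "POP_SYN",
    predictor = scores$beta, quiet = TRUE, direction = "<"))
  expect_equal(mine, as.numeric(ref), tolerance = 1e-12)
})
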