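# Per-timepoint genetic classification of elicitor-responsive transcripts.
# This is the pipeline's central decision procedure: responsiveness from the
# within-genotype time contrasts, MKP1 dependence from the wild-type vs
# single-mutant contrast, and the MPK6 subdivision from the double-mutant
# contrasts. All thresholds are inclusive (>=, <=).

#' Classification thresholds
#'
#' @param lfc_min Minimum |log2 fold-change| for responsiveness (default 1,
#'   i.e. 2-fold).
#' @param q_resp FDR gate for responsiveness (default 0.01).
#' @param dep_fold_min Minimum linear fold difference between wild type and
#'   the single mutant for MKP1 dependence (default 1.5, applied as
#'   `|log2 fc| >= log2(1.5)` in either direction).
#' @param q_dep FDR gate for the dependence and subdivision contrasts
#'   (default 0.01).
#' @return Object of class `call_thresholds`.
#' @export
call_thresholds <- function(lfc_min = 1, q_resp = 0.01,
                            dep_fold_min = 1.5, q_dep = 0.01) {
  if (lfc_min <= 0 || dep_fold_min <= 0) {
    abort_input("fold thresholds must be positive")
  }
  if (q_resp <= 0 || q_resp >= 1 || q_dep <= 0 || q_dep >= 1) {
    abort_input("q thresholds must lie in (0, 1)")
  }
  structure(list(lfc_min = lfc_min, q_resp = q_resp,
                 dep_fold_min = dep_fold_min, q_dep = q_dep),
            class = "call_thresholds")
}

# Lookup of one contrast's records by gene: only status == "OK" rows are
# usable for decisions; everything else counts as a gap.
contrast_lookup <- function(diffs, condition_a, condition_b, genes) {
  sel <- diffs$sample_1 == condition_a & diffs$sample_2 == condition_b &
    diffs$status == "OK" & !is.na(diffs$q_value)
  sub <- diffs[sel, , drop = FALSE]
  i <- match(genes, sub$gene_id)
  list(lfc = sub$log2_fc[i], q = sub$q_value[i], present = !is.na(i))
}

#' Call elicitor responsiveness per gene and timepoint
#'
#' A gene is responsive at timepoint t iff `|log2_fc| >= lfc_min` and
#' `q <= q_resp` in the wild-type t-vs-0 contrast OR in the single-mutant
#' t-vs-0 contrast (union over genotypes). Direction is the sign of the
#' qualifying fold-change; the wild-type contrast takes precedence when both
#' qualify, and opposite-sign qualification is counted in the `conflicts`
#' attribute. Genes missing both contrasts are called not responsive and
#' counted in the `gaps` attribute.
#'
#' @param diffs Stacked differential records ([test_all_contrasts()]).
#' @param thresholds A [call_thresholds()].
#' @param genotypes Ordered genotype labels (wild type first).
#' @param timepoints_min Post-elicitation timepoints (default `c(30, 90)`).
#' @param baseline_min Untreated timepoint label (default 0).
#' @return Data frame `gene_id`, `timepoint_min`, `responsive`, `direction`
#'   with attributes `gaps` and `conflicts`.
#' @export
call_responsive <- function(diffs, thresholds = call_thresholds(),
                            genotypes = c("Ws", "mkp1", "mkp1_mpk6"),
                            timepoints_min = c(30, 90), baseline_min = 0) {
  genes <- sort(unique(diffs$gene_id))
  wt <- genotypes[1]; mut <- genotypes[2]
  gaps <- 0L; conflicts <- 0L
  out <- lapply(timepoints_min, function(t) {
    w <- contrast_lookup(diffs, condition_label(wt, baseline_min),
                         condition_label(wt, t), genes)
    m <- contrast_lookup(diffs, condition_label(mut, baseline_min),
                         condition_label(mut, t), genes)
    qual_w <- w$present & abs(w$lfc) >= thresholds$lfc_min &
      w$q <= thresholds$q_resp
    qual_m <- m$present & abs(m$lfc) >= thresholds$lfc_min &
      m$q <= thresholds$q_resp
    qual_w[is.na(qual_w)] <- FALSE
    qual_m[is.na(qual_m)] <- FALSE
    responsive <- qual_w | qual_m
    gaps <<- gaps + sum(!w$present & !m$present)
    conflicts <<- conflicts +
      sum(qual_w & qual_m & sign(w$lfc) != sign(m$lfc), na.rm = TRUE)
    direction <- rep("none", length(genes))
    direction[responsive] <- ifelse(qual_w[responsive],
                                    ifelse(w$lfc[responsive] > 0,
                                           "induced", "repressed"),
                                    ifelse(m$lfc[responsive] > 0,
                                           "induced", "repressed"))
    data.frame(gene_id = genes, timepoint_min = t,
               responsive = responsive, direction = direction,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "gaps") <- gaps
  attr(res, "conflicts") <- conflicts
  res
}

#' Flag MKP1 dependence among responsive calls
#'
#' A responsive gene is MKP1 dependent at t iff the wild-type vs
#' single-mutant contrast at matched treatment shows at least
#' `dep_fold_min`-fold difference in either direction
#' (`|log2_fc| >= log2(dep_fold_min)`) at `q <= q_dep`. Everything
#' responsive that fails the gate (including genes whose dependence contrast
#' is missing) is MKP1 independent - the independent set is defined by
#' subtraction.
#'
#' @param diffs Stacked differential records.
#' @param responsive_calls Output of [call_responsive()].
#' @inheritParams call_responsive
#' @return `responsive_calls` with a logical `mkp1_dependent` column.
#' @export
call_mkp1_dependence <- function(diffs, responsive_calls,
                                 thresholds = call_thresholds(),
                                 genotypes = c("Ws", "mkp1", "mkp1_mpk6")) {
  wt <- genotypes[1]; mut <- genotypes[2]
  res <- responsive_calls
  res$mkp1_dependent <- FALSE
  lfc_gate <- log2(thresholds$dep_fold_min)
  for (t in unique(res$timepoint_min)) {
    rows <- which(res$timepoint_min == t)
    d <- contrast_lookup(diffs, condition_label(wt, t),
                         condition_label(mut, t), res$gene_id[rows])
    dep <- res$responsive[rows] & d$present & abs(d$lfc) >= lfc_gate &
      d$q <= thresholds$q_dep
    dep[is.na(dep)] <- FALSE
    res$mkp1_dependent[rows] <- dep
  }
  res
}

#' Subdivide MKP1-dependent calls by MPK6 requirement
#'
#' Within the MKP1-dependent set the subdivision gates are q-only: a gene is
#' `MKP1_MPK6_dependent` iff the single mutant differs from the double
#' mutant (`q <= q_dep`) while the double mutant matches wild type
#' (`q > q_dep`) - the mutant change is reverted by losing the kinase.
#' The reverse pattern is `MKP1_dep_MPK6_indep`. Everything else dependent
#' (including genes with a missing subdivision contrast) is the residual
#' `MKP1_dep_partial_MPK6`.
#'
#' @param diffs Stacked differential records.
#' @param dependence_calls Output of [call_mkp1_dependence()].
#' @inheritParams call_responsive
#' @return Calls with the final `category` column: one of
#'   `MKP1_independent`, `MKP1_MPK6_dependent`, `MKP1_dep_MPK6_indep`,
#'   `MKP1_dep_partial_MPK6`, `not_responsive`.
#' @export
subdivide_mpk6 <- function(diffs, dependence_calls,
                           thresholds = call_thresholds(),
                           genotypes = c("Ws", "mkp1", "mkp1_mpk6")) {
  wt <- genotypes[1]; mut <- genotypes[2]; dbl <- genotypes[3]
  res <- dependence_calls
  res$category <- ifelse(!res$responsive, "not_responsive",
                         ifelse(res$mkp1_dependent, "MKP1_dep_partial_MPK6",
                                "MKP1_independent"))
  for (t in unique(res$timepoint_min)) {
    rows <- which(res$timepoint_min == t & res$mkp1_dependent)
    if (!length(rows)) next
    a <- contrast_lookup(diffs, condition_label(mut, t),
                         condition_label(dbl, t), res$gene_id[rows])
    b <- contrast_lookup(diffs, condition_label(wt, t),
                         condition_label(dbl, t), res$gene_id[rows])
    sig_a <- a$present & a$q <= thresholds$q_dep
    sig_b <- b$present & b$q <= thresholds$q_dep
    sig_a[is.na(sig_a)] <- FALSE
    sig_b[is.na(sig_b)] <- FALSE
    cat_t <- rep("MKP1_dep_partial_MPK6", length(rows))
    cat_t[sig_a & !sig_b & a$present & b$present] <- "MKP1_MPK6_dependent"
    cat_t[!sig_a & sig_b & a$present & b$present] <- "MKP1_dep_MPK6_indep"
    res$category[rows] <- cat_t
  }
  res
}

#' Classify genes into pathway-dependency categories
#'
#' Chains [call_responsive()], [call_mkp1_dependence()] and
#' [subdivide_mpk6()], and flags genes with a pre-existing (0-min) genotype
#' difference passing the dependence gates (flagged, never excluded). The
#' per-timepoint labels are independent: a gene may legitimately switch
#' category between 30 and 90 min.
#'
#' @inheritParams call_responsive
#' @param baseline_min Untreated timepoint (default 0).
#' @return Data frame `gene_id`, `timepoint_min`, `responsive`, `direction`,
#'   `category`, `baseline_diff` (+ `gaps`/`conflicts` attributes).
#' @export
classify_genes <- function(diffs, thresholds = call_thresholds(),
                           genotypes = c("Ws", "mkp1", "mkp1_mpk6"),
                           timepoints_min = c(30, 90), baseline_min = 0) {
  resp <- call_responsive(diffs, thresholds, genotypes, timepoints_min,
                          baseline_min)
  dep <- call_mkp1_dependence(diffs, resp, thresholds, genotypes)
  calls <- subdivide_mpk6(diffs, dep, thresholds, genotypes)

  wt <- genotypes[1]
  lfc_gate <- log2(thresholds$dep_fold_min)
  base_flag <- rep(FALSE, length(unique(calls$gene_id)))
  genes <- sort(unique(calls$gene_id))
  for (g2 in genotypes[-1]) {
    d <- contrast_lookup(diffs, condition_label(wt, baseline_min),
                         condition_label(g2, baseline_min), genes)
    f <- d$present & abs(d$lfc) >= lfc_gate & d$q <= thresholds$q_dep
    f[is.na(f)] <- FALSE
    base_flag <- base_flag | f
  }
  calls$baseline_diff <- base_flag[match(calls$gene_id, genes)]
  out <- calls[c("gene_id", "timepoint_min", "responsive", "direction",
                 "category", "baseline_diff")]
  attr(out, "gaps") <- attr(resp, "gaps")
  attr(out, "conflicts") <- attr(resp, "conflicts")
  out
}

#' Summarize category counts and percentages per timepoint
#'
#' Reproduces the headline summary arithmetic: per timepoint and direction,
#' the MKP1-dependent share of responsive transcripts (numerator = all three
#' dependent subcategories), and per timepoint the MPK6 split of the
#' MKP1-dependent set. Percentages are reported both rounded to the nearest
#' integer (prose style) and to two decimals (table style); an empty
#' denominator yields `NA`, never zero.
#'
#' @param calls Classification calls ([classify_genes()] output or a
#'   compatible data frame).
#' @return Data frame with one row per summary statistic: `timepoint_min`,
#'   `statistic`, `numerator`, `denominator`, `pct_int`, `pct_2dp`.
#' @export
summarize_categories <- function(calls) {
  dep_cats <- c("MKP1_MPK6_dependent", "MKP1_dep_MPK6_indep",
                "MKP1_dep_partial_MPK6")
  rows <- list()
  add <- function(t, stat, num, den) {
    rows[[length(rows) + 1]] <<- data.frame(
      timepoint_min = t, statistic = stat,
      numerator = num, denominator = den,
      pct_int = percent_of(num, den, 0),
      pct_2dp = percent_of(num, den, 2),
      stringsAsFactors = FALSE)
  }
  for (t in sort(unique(calls$timepoint_min))) {
    ct <- calls[calls$timepoint_min == t, , drop = FALSE]
    resp <- ct[ct$responsive, , drop = FALSE]
    add(t, "responsive_of_all", nrow(resp), nrow(ct))
    for (dir in c("induced", "repressed")) {
      cd <- resp[resp$direction == dir, , drop = FALSE]
      add(t, paste0("mkp1_dependent_of_", dir),
          sum(cd$category %in% dep_cats), nrow(cd))
    }
    dep <- resp[resp$category %in% dep_cats, , drop = FALSE]
    add(t, "mpk6_dependent_of_mkp1_dependent",
        sum(dep$category == "MKP1_MPK6_dependent"), nrow(dep))
    add(t, "mpk6_independent_of_mkp1_dependent",
        sum(dep$category == "MKP1_dep_MPK6_indep"), nrow(dep))
    add(t, "partial_mpk6_of_mkp1_dependent",
        sum(dep$category == "MKP1_dep_partial_MPK6"), nrow(dep))
    # the discrete split excludes the partial residual from the denominator:
    # only transcripts discretely classifiable as MPK6 dependent/independent
    n_disc <- sum(dep$category != "MKP1_dep_partial_MPK6")
    add(t, "mpk6_dependent_of_discrete",
        sum(dep$category == "MKP1_MPK6_dependent"), n_disc)
    add(t, "mpk6_independent_of_discrete",
        sum(dep$category == "MKP1_dep_MPK6_indep"), n_disc)
    for (cat in c("MKP1_independent", dep_cats)) {
      add(t, paste0("count_", cat), sum(resp$category == cat), nrow(resp))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
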