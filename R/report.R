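# Pipeline orchestration and paper-style summary tables: per-gene call
# table, cluster table, enrichment tables under both backgrounds, optional
# qPCR validation stage, and a cross-tabulation of clusters by genetic
# category with its assigned-fraction totals row.

#' Pipeline configuration
#'
#' Bundles the simulation settings, thresholds and stage parameters of one
#' deterministic end-to-end run. Sub-stage seeds are derived from `seed` by
#' fixed small offsets, so a single integer reproduces the whole bundle.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_genes Number of genes to simulate (default 2000).
#' @param seed Master seed (keep below 2^31 - 100).
#' @param sim Optional [sim_config()]; by default built from `n_genes` and
#'   `seed`.
#' @param thresholds A [call_thresholds()].
#' @param max_unit_change,max_profiles Clustering parameters (defaults 2
#'   and 50).
#' @param n_terms,n_enriched Annotation simulation parameters.
#' @param q_enrich Enrichment significance cutoff (default 0.05).
#' @param with_qpcr Run the qPCR validation stage (default TRUE).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_genes = 2000, seed = 1L,
                            sim = NULL,
                            thresholds = call_thresholds(),
                            max_unit_change = 2, max_profiles = 50,
                            n_terms = 40, n_enriched = 4,
                            q_enrich = 0.05, with_qpcr = TRUE) {
  if (seed >= 2^31 - 100) abort_input("seed too large (must be < 2^31 - 100)")
  structure(list(out_dir = out_dir, n_genes = n_genes, seed = as.integer(seed),
                 sim = sim %||% sim_config(n_genes, seed = seed),
                 thresholds = thresholds,
                 max_unit_change = max_unit_change,
                 max_profiles = max_profiles,
                 n_terms = n_terms, n_enriched = n_enriched,
                 q_enrich = q_enrich, with_qpcr = with_qpcr),
            class = "pipeline_config")
}

#' Run the full pipeline and emit the report bundle
#'
#' Simulates inputs, runs the differential tests over the standard
#' contrasts, classifies genes, clusters the responsive set on wild-type
#' temporal profiles, performs enrichment under both backgrounds, optionally
#' runs the qPCR validation stage, and writes the summary tables. Every
#' output is TSV; reruns with the same configuration are byte-identical.
#' A stage failure aborts with the stage name and removes partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the key in-memory tables and the vector
#'   of written paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort_input("config must come from pipeline_config()")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv(df, path)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    stage <- "simulate"
    sim <- simulate_expression(config$sim)
    emit(sim$expression, "expression.tsv")
    emit(sim$truth, "truth.tsv")

    stage <- "de"
    contrasts <- standard_contrasts(config$sim$genotypes,
                                    config$sim$timepoints_min)
    diffs <- test_all_contrasts(sim$expression, contrasts)
    emit(diffs, "diff_table.tsv")

    stage <- "classify"
    calls <- classify_genes(diffs, config$thresholds, config$sim$genotypes,
                            config$sim$timepoints_min[-1],
                            config$sim$timepoints_min[1])
    emit(calls, "gene_calls.tsv")
    summary_tab <- summarize_categories(calls)
    emit(summary_tab, "summary.tsv")

    stage <- "cluster"
    resp_genes <- sort(unique(calls$gene_id[calls$responsive]))
    profiles <- enumerate_profiles(length(config$sim$timepoints_min),
                                   config$max_unit_change,
                                   config$max_profiles)
    assignments <- NULL
    if (length(resp_genes) >= 2) {
      ratios <- temporal_ratios(sim$expression, resp_genes,
                                config$sim$genotypes[1])
      assignments <- assign_profiles(ratios, profiles)
      emit(assignments, "cluster_assignments.tsv")
      emit(profile_significance(ratios, profiles), "profile_stats.tsv")
      for (t in config$sim$timepoints_min[-1]) {
        ct <- crosstab_cluster_by_category(calls, assignments, t)
        emit(ct$formatted, sprintf("crosstab_%d.tsv", t))
      }
    }

    stage <- "enrich"
    dep_cats <- c("MKP1_MPK6_dependent", "MKP1_dep_MPK6_indep",
                  "MKP1_dep_partial_MPK6")
    all_genes <- sort(unique(calls$gene_id))
    dep_genes <- sort(unique(calls$gene_id[calls$category %in% dep_cats]))
    resp_all <- resp_genes
    ann <- simulate_annotations(all_genes, config$n_terms, config$n_enriched,
                                study_genes = dep_genes,
                                seed = config$seed + 11L)
    emit(ann$term_map, "term_map.tsv")
    if (length(dep_genes)) {
      enr_a <- fisher_enrich(dep_genes, resp_all, ann$term_map,
                             config$q_enrich)
      emit(enr_a, "enrichment_vs_responsive.tsv")
      enr_b <- fisher_enrich(dep_genes, all_genes, ann$term_map,
                             config$q_enrich)
      emit(enr_b, "enrichment_vs_genome.tsv")
    }

    qpcr <- NULL
    if (isTRUE(config$with_qpcr)) {
      stage <- "qpcr"
      qpcr <- qpcr_validation_stage(sim, calls, config, emit)
    }

    stage <- "report"
    gaps <- attr(calls, "gaps") %||% 0L
    conflicts <- attr(calls, "conflicts") %||% 0L
    assigned <- if (is.null(assignments)) 0L else
      sum(!is.na(assignments$profile_id))
    log_tab <- data.frame(
      metric = c("genes", "responsive_genes", "contrast_gaps",
                 "direction_conflicts", "clustered_genes",
                 "assigned_fraction_pct"),
      value = c(length(all_genes), length(resp_genes), gaps, conflicts,
                assigned,
                percent_of(assigned, max(length(resp_genes), 0))),
      stringsAsFactors = FALSE)
    emit(log_tab, "run_log.tsv")

    list(calls = calls, summary = summary_tab, assignments = assignments,
         qpcr = qpcr, paths = written)
  }, error = function(e) {
    unlink(written)
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c(class(e)[1], "elicitr_stage_error", "error")))
  })
  invisible(result)
}

# Small qPCR validation panel: one dependent marker (if any was planted)
# plus the reference amplicon, with per-sample template quantities taken
# from the simulated mean expression so the planted genotype effect is
# visible in the folds.
qpcr_validation_stage <- function(sim, calls, config, emit) {
  dep <- sim$truth$gene_id[sim$truth$category %in%
                             c("MKP1_MPK6_dependent", "MKP1_dep_MPK6_indep")]
  target <- if (length(dep)) dep[1] else sim$truth$gene_id[1]
  expr <- sim$expression
  sub <- expr[expr$gene_id == target, , drop = FALSE]
  agg <- stats::aggregate(fpkm ~ genotype + timepoint_min, sub, mean)
  scale_q <- 1e-5 / max(agg$fpkm)

  meta <- expand.grid(genotype = config$sim$genotypes,
                      timepoint_min = config$sim$timepoints_min,
                      replicate = seq_len(config$sim$n_replicates),
                      stringsAsFactors = FALSE)
  n_s <- nrow(meta)
  i <- match(paste(meta$genotype, meta$timepoint_min),
             paste(agg$genotype, agg$timepoint_min))
  q_target <- agg$fpkm[i] * scale_q
  reactions <- rbind(
    data.frame(meta, target = target, quantity = q_target,
               efficiency = 1.9, stringsAsFactors = FALSE),
    data.frame(meta, target = "At2g28390", quantity = 1e-5,
               efficiency = 1.9, stringsAsFactors = FALSE))
  reactions$reaction_id <- sprintf("R%03d", seq_len(nrow(reactions)))
  curves <- simulate_qpcr(nrow(reactions), reactions$efficiency,
                          reactions$quantity, cycles = 40,
                          noise_sd = 0.01, seed = config$seed + 23L)
  curves$truth$reaction_id <- reactions$reaction_id
  cv <- curves$curves
  cv$reaction_id <- reactions$reaction_id[match(cv$reaction_id,
                                                sprintf("R%03d",
                                                        seq_len(nrow(reactions))))]
  levels <- qpcr_quantify(cv, reactions[c("reaction_id", "target", "genotype",
                                          "timepoint_min", "replicate")])
  nt <- normalize_and_test(levels)
  emit(nt$folds, "qpcr_folds.tsv")
  emit(nt$tests, "qpcr_tests.tsv")
  nt
}

#' Cross-tabulate archetype clusters by genetic category
#'
#' Cell (cluster, category) counts genes assigned to the cluster among the
#' responsive genes of the category at one timepoint; percentages are over
#' the category column total, and the `Total` row reports each category's
#' assigned fraction (rounded to the nearest integer, matching prose
#' style). Formatted cells read `"44.58%(1136/2548)"`; empty categories
#' yield `"undef"` cells, never an error.
#'
#' @param calls Classification calls covering every assigned gene.
#' @param assignments Output of [assign_profiles()].
#' @param timepoint_min Timepoint to tabulate.
#' @return List with `counts` (9 x categories integer matrix, last row the
#'   assigned totals), `formatted` (character data frame for the report),
#'   and `totals` (category sizes).
#' @export
crosstab_cluster_by_category <- function(calls, assignments, timepoint_min) {
  missing_genes <- setdiff(assignments$gene_id, calls$gene_id)
  if (length(missing_genes)) {
    abort_input("%d gene(s) in assignments are absent from calls",
                length(missing_genes))
  }
  cats <- c("MKP1_independent", "MKP1_MPK6_dependent",
            "MKP1_dep_MPK6_indep", "MKP1_dep_partial_MPK6")
  ct <- calls[calls$timepoint_min == timepoint_min & calls$responsive, ,
              drop = FALSE]
  arch <- assignments$archetype[match(ct$gene_id, assignments$gene_id)]
  counts <- matrix(0L, nrow = 9, ncol = length(cats),
                   dimnames = list(c(as.character(1:8), "assigned"), cats))
  totals <- integer(length(cats)); names(totals) <- cats
  for (ci in seq_along(cats)) {
    in_cat <- ct$category == cats[ci]
    totals[ci] <- sum(in_cat)
    a <- arch[in_cat]
    counts[1:8, ci] <- tabulate(a[!is.na(a)], nbins = 8)
    counts[9, ci] <- sum(!is.na(a))
  }
  formatted <- data.frame(cluster = rownames(counts), stringsAsFactors = FALSE)
  for (ci in seq_along(cats)) {
    col <- c(percent_label(counts[1:8, ci], totals[ci], digits = 2),
             percent_label(counts[9, ci], totals[ci], digits = 0))
    formatted[[cats[ci]]] <- col
  }
  list(counts = counts, formatted = formatted, totals = totals)
}
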