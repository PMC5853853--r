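# Synthetic-data module: generates every pipeline input with known ground
# truth (expression tables, annotation maps, qPCR amplification curves).

#' Simulation configuration
#'
#' Describes the world the generator emulates: a 3-genotype (wild type,
#' phosphatase mutant, phosphatase-kinase double mutant) by 3-timepoint
#' elicitor time course with replicate-level FPKM-like values. Planted
#' per-gene categories encode the epistasis structure the classifier must
#' recover; planted archetypes (clusters 1-8) encode the temporal shape in
#' the wild type.
#'
#' Replicate noise is multiplicative log-normal with the stated coefficient
#' of variation: FPKM values are positive and right-skewed, and the pipeline
#' consumes FPKM-like values rather than counts, so a negative-binomial count
#' layer is deliberately not simulated.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_replicates Biological replicates per genotype x timepoint
#'   (default 3, the design of the emulated experiment; must be >= 2).
#' @param genotypes Ordered genotype labels: wild type, single mutant,
#'   double mutant.
#' @param timepoints_min Ordered sampling times in minutes post-elicitation.
#' @param category_mix Named proportions over the five planted categories
#'   `nonresponsive`, `MKP1_independent`, `MKP1_MPK6_dependent`,
#'   `MKP1_dep_MPK6_indep`, `partial_MPK6`; must sum to 1.
#' @param archetype_mix Proportions over the eight temporal archetypes
#'   (clusters 1-8); must sum to 1.
#' @param base_log2_expression Named vector `c(mean=, sd=)` of baseline
#'   log2 FPKM across genes.
#' @param responsive_effect_log2 Elicitor response amplitude in log2 units
#'   per unit of archetype shape (default 2).
#' @param mkp1_effect_log2 Genotype effect in log2 units added, in the
#'   direction of the response, to the mutant genotypes of dependent
#'   categories (default 1).
#' @param noise_cv Coefficient of variation of replicate noise (default 0.2).
#' @param seed Random seed (integer below 2^31).
#' @param force_category,force_archetype Optionally force every gene's
#'   category / archetype (scalar or length-`n_genes` vector); used for
#'   controlled fixtures.
#' @return An object of class `sim_config`.
#' @seealso [simulate_expression()]
#' @export
sim_config <- function(n_genes,
                       n_replicates = 3,
                       genotypes = c("Ws", "mkp1", "mkp1_mpk6"),
                       timepoints_min = c(0, 30, 90),
                       category_mix = c(nonresponsive = 0.65,
                                        MKP1_independent = 0.25,
                                        MKP1_MPK6_dependent = 0.04,
                                        MKP1_dep_MPK6_indep = 0.04,
                                        partial_MPK6 = 0.02),
                       archetype_mix = c(0.25, 0.15, 0.10, 0.12,
                                         0.08, 0.12, 0.12, 0.06),
                       base_log2_expression = c(mean = 5, sd = 2),
                       responsive_effect_log2 = 2,
                       mkp1_effect_log2 = 1,
                       noise_cv = 0.2,
                       seed = 1L,
                       force_category = NULL,
                       force_archetype = NULL) {
  if (!is_count(n_genes)) abort_input("n_genes must be a positive integer")
  if (!is_count(n_replicates) || n_replicates < 2) {
    abort_input("n_replicates must be an integer >= 2")
  }
  if (length(genotypes) != 3) abort_input("exactly three genotypes expected")
  if (length(timepoints_min) < 2 || is.unsorted(timepoints_min)) {
    abort_input("timepoints_min must be increasing")
  }
  want <- c("nonresponsive", "MKP1_independent", "MKP1_MPK6_dependent",
            "MKP1_dep_MPK6_indep", "partial_MPK6")
  if (!setequal(names(category_mix), want)) {
    abort_input("category_mix must be named over: %s",
                paste(want, collapse = ", "))
  }
  category_mix <- category_mix[want]
  if (abs(sum(category_mix) - 1) > 1e-9 || any(category_mix < 0)) {
    abort_input("category_mix proportions must be >= 0 and sum to 1")
  }
  if (length(archetype_mix) != 8 || abs(sum(archetype_mix) - 1) > 1e-9 ||
      any(archetype_mix < 0)) {
    abort_input("archetype_mix must be 8 non-negative proportions summing to 1")
  }
  if (!all(is.finite(c(responsive_effect_log2, mkp1_effect_log2)))) {
    abort_input("effect sizes must be finite")
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    abort_input("noise_cv must be >= 0")
  }
  if (!is.null(force_archetype) &&
      !all(force_archetype %in% 1:8)) {
    abort_input("unknown archetype id: %s",
                paste(setdiff(force_archetype, 1:8), collapse = ", "))
  }
  if (!is.null(force_category) && !all(force_category %in% want)) {
    abort_input("unknown category: %s",
                paste(setdiff(force_category, want), collapse = ", "))
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 genotypes = genotypes,
                 timepoints_min = timepoints_min,
                 category_mix = category_mix,
                 archetype_mix = archetype_mix,
                 base_log2_expression = base_log2_expression,
                 responsive_effect_log2 = responsive_effect_log2,
                 mkp1_effect_log2 = mkp1_effect_log2,
                 noise_cv = noise_cv,
                 seed = as.integer(seed),
                 force_category = force_category,
                 force_archetype = force_archetype),
            class = "sim_config")
}

#' Unit temporal shapes of the eight archetype clusters
#'
#' Cumulative unit shapes over (0, 30, 90) min: clusters 1-4 are the induced
#' shapes (transient, late, sustained, amplified), clusters 5-8 their
#' repressed mirrors. Multiplying a row by the responsive effect gives the
#' planted log2 ratio versus the 0-min baseline.
#'
#' @return An 8 x 3 numeric matrix, one row per archetype.
#' @export
archetype_shapes <- function() {
  m <- rbind(c(0, 1, 0),    # 1 early induced, transient
             c(0, 0, 1),    # 2 late induced
             c(0, 1, 1),    # 3 early induced, sustained
             c(0, 1, 2),    # 4 early induced, amplified
             c(0, -1, 0),   # 5 early repressed, transient
             c(0, -1, -1),  # 6 early repressed, sustained
             c(0, 0, -1),   # 7 late repressed
             c(0, -1, -2))  # 8 early repressed, amplified
  rownames(m) <- as.character(1:8)
  m
}

#' Simulate a replicate-level expression table with planted ground truth
#'
#' Generates FPKM-like values for every gene x genotype x timepoint x
#' replicate cell. Planted categories are realized through genotype offsets
#' applied wherever the gene responds: `MKP1_MPK6_dependent` genes differ
#' from wild type in the single mutant but match wild type in the double
#' mutant; `MKP1_dep_MPK6_indep` genes differ from wild type equally in both
#' mutants; `partial_MPK6` genes place the double mutant halfway (in log2)
#' between wild type and the single mutant. Offsets point in the direction
#' of the response (hyper-response in the mutant). Output is deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` (long-format data frame:
#'   `gene_id`, `genotype`, `timepoint_min`, `replicate`, `fpkm`) and
#'   `truth` (per gene: planted `category`, `archetype`, `direction`).
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_input("config must be created with sim_config()")
  }
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))

  category <- if (!is.null(config$force_category)) {
    rep_len(config$force_category, n)
  } else {
    sample(names(config$category_mix), n, replace = TRUE,
           prob = config$category_mix)
  }
  responsive <- category != "nonresponsive"
  arch_draw <- if (!is.null(config$force_archetype)) {
    rep_len(as.integer(config$force_archetype), n)
  } else {
    sample.int(8L, n, replace = TRUE, prob = config$archetype_mix)
  }
  archetype <- ifelse(responsive, arch_draw, NA_integer_)

  base <- stats::rnorm(n, config$base_log2_expression[["mean"]],
                       config$base_log2_expression[["sd"]])

  shapes <- archetype_shapes()
  tp <- config$timepoints_min
  n_t <- length(tp)
  shape_gt <- matrix(0, n, n_t)  # unit shape per gene x timepoint
  if (any(responsive)) {
    # timepoints beyond the canonical three reuse the last shape column
    cols <- pmin(seq_len(n_t), ncol(shapes))
    shape_gt[responsive, ] <- shapes[archetype[responsive], cols, drop = FALSE]
  }

  # genotype multipliers for the planted epistasis structure
  mult <- cbind(0,
                ifelse(category %in% c("MKP1_MPK6_dependent",
                                       "MKP1_dep_MPK6_indep",
                                       "partial_MPK6"), 1, 0),
                ifelse(category == "MKP1_dep_MPK6_indep", 1,
                       ifelse(category == "partial_MPK6", 0.5, 0)))

  sdlog <- if (config$noise_cv > 0) sqrt(log1p(config$noise_cv^2)) else 0
  blocks <- vector("list", 3L * n_t * config$n_replicates)
  b <- 0L
  for (gi in seq_along(config$genotypes)) {
    for (ti in seq_len(n_t)) {
      mu <- base + shape_gt[, ti] * config$responsive_effect_log2 +
        sign(shape_gt[, ti]) * config$mkp1_effect_log2 * mult[, gi]
      for (r in seq_len(config$n_replicates)) {
        fpkm <- if (sdlog == 0) {
          2^mu
        } else {
          stats::rlnorm(n, meanlog = mu * log(2) - sdlog^2 / 2, sdlog = sdlog)
        }
        b <- b + 1L
        blocks[[b]] <- data.frame(gene_id = gene_id,
                                  genotype = config$genotypes[gi],
                                  timepoint_min = tp[ti],
                                  replicate = r,
                                  fpkm = fpkm,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  expression <- do.call(rbind, blocks)
  expression <- expression[order(expression$gene_id,
                                 match(expression$genotype, config$genotypes),
                                 expression$timepoint_min,
                                 expression$replicate), , drop = FALSE]
  rownames(expression) <- NULL

  direction <- rep(NA_character_, n)
  direction[responsive] <- ifelse(archetype[responsive] <= 4,
                                  "induced", "repressed")
  truth <- data.frame(gene_id = gene_id, category = category,
                      archetype = archetype, direction = direction,
                      stringsAsFactors = FALSE)
  list(expression = expression, truth = truth)
}

#' Expected per-timepoint calls implied by the planted ground truth
#'
#' A gene is expected responsive at a timepoint exactly where its planted
#' archetype shape is non-zero; there it carries its planted category and
#' the direction given by the shape's sign. Where the shape is zero the
#' expected call is `not_responsive`.
#'
#' @param truth The `truth` component of [simulate_expression()] output.
#' @param timepoints_min Post-elicitation timepoints to expand (default
#'   `c(30, 90)`).
#' @return Data frame `gene_id`, `timepoint_min`, `responsive`, `direction`,
#'   `category` matching the classifier's output contract.
#' @export
planted_calls <- function(truth, timepoints_min = c(30, 90)) {
  shapes <- archetype_shapes()
  canonical <- c(0, 30, 90)
  out <- lapply(timepoints_min, function(t) {
    ti <- match(t, canonical)
    if (is.na(ti)) abort_input("timepoint %s has no archetype column", t)
    v <- numeric(nrow(truth))
    ok <- !is.na(truth$archetype)
    v[ok] <- shapes[cbind(truth$archetype[ok], ti)]
    responsive <- v != 0
    data.frame(gene_id = truth$gene_id,
               timepoint_min = t,
               responsive = responsive,
               direction = ifelse(responsive,
                                  ifelse(v > 0, "induced", "repressed"),
                                  "none"),
               category = ifelse(responsive, truth$category,
                                 "not_responsive"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a flat gene-to-term annotation map with planted enriched terms
#'
#' Every gene is annotated to each term independently at a base rate;
#' enriched terms receive elevated membership among a designated study set
#' at the stated odds ratio. With `n_enriched = 0` (or odds ratio 1) the map
#' is a pure null for type-I error simulations.
#'
#' @param genes Character vector of gene ids (the background universe).
#' @param n_terms Number of terms to simulate.
#' @param n_enriched Number of planted enriched terms (<= `n_terms`).
#' @param study_genes Genes forming the designated study set (subset of
#'   `genes`); required when `n_enriched > 0`.
#' @param base_rate Per-gene membership probability of an unenriched term.
#' @param odds_ratio Planted odds ratio of study-set membership for
#'   enriched terms (default 8).
#' @param seed Random seed.
#' @return List with `term_map` (data frame `gene_id`, `term_id`) and
#'   `truth` (per term: `enriched` flag).
#' @export
simulate_annotations <- function(genes, n_terms, n_enriched = 0,
                                 study_genes = character(),
                                 base_rate = 0.05, odds_ratio = 8,
                                 seed = 1L) {
  if (length(genes) == 0) abort_input("gene list is empty")
  if (!is_count(n_terms)) abort_input("n_terms must be a positive integer")
  if (n_enriched > n_terms) abort_input("n_enriched must be <= n_terms")
  if (n_enriched > 0 && length(study_genes) == 0) {
    abort_input("study_genes required when planting enriched terms")
  }
  if (!all(study_genes %in% genes)) {
    abort_input("study_genes must be a subset of genes")
  }
  set.seed(seed)
  term_id <- sprintf("T%03d", seq_len(n_terms))
  enriched <- seq_len(n_terms) <= n_enriched
  odds0 <- base_rate / (1 - base_rate)
  p_enr <- odds_ratio * odds0 / (1 + odds_ratio * odds0)
  in_study <- genes %in% study_genes
  maps <- vector("list", n_terms)
  for (j in seq_len(n_terms)) {
    p <- rep(base_rate, length(genes))
    if (enriched[j]) p[in_study] <- p_enr
    member <- stats::runif(length(genes)) < p
    if (any(member)) {
      maps[[j]] <- data.frame(gene_id = genes[member], term_id = term_id[j],
                              stringsAsFactors = FALSE)
    }
  }
  term_map <- do.call(rbind, maps) %||%
    data.frame(gene_id = character(), term_id = character())
  rownames(term_map) <- NULL
  list(term_map = term_map,
       truth = data.frame(term_id = term_id, enriched = enriched,
                          stringsAsFactors = FALSE))
}

#' Simulate qPCR amplification curves
#'
#' Fluorescence follows `baseline + cap(q0 * E^cycle)` where the cap
#' saturates the exponential to a fixed plateau (100x baseline by default).
#' The cap is sharp (a high-order soft-minimum), so the sub-plateau portion
#' of the curve stays exponential and presents a realistic
#' window-of-linearity problem without biasing the low/mid fluorescence
#' band. Noise is multiplicative Gaussian with the stated fractional sd.
#'
#' @param n_reactions Number of reactions.
#' @param efficiency Per-cycle amplification factor(s) in (1, 2]; recycled.
#' @param true_quantity Initial template quantity(ies) > 0, in baseline
#'   fluorescence units; recycled.
#' @param cycles Number of cycles (>= 25).
#' @param noise_sd Fractional sd of multiplicative noise.
#' @param baseline Baseline fluorescence (arbitrary units).
#' @param plateau_factor Plateau as a multiple of baseline.
#' @param cap_sharpness Order of the soft-minimum cap (higher = sharper).
#' @param seed Random seed.
#' @return List with `curves` (data frame `reaction_id`, `cycle`,
#'   `fluorescence`) and `truth` (per reaction: `efficiency`,
#'   `true_quantity`).
#' @export
simulate_qpcr <- function(n_reactions, efficiency, true_quantity,
                          cycles = 40, noise_sd = 0.01, baseline = 1,
                          plateau_factor = 100, cap_sharpness = 6,
                          seed = 1L) {
  if (!is_count(n_reactions)) abort_input("n_reactions must be positive")
  if (any(efficiency <= 1) || any(efficiency > 2)) {
    abort_input("efficiency must lie in (1, 2]")
  }
  if (any(true_quantity <= 0)) abort_input("true_quantity must be > 0")
  if (!is_count(cycles) || cycles < 25) abort_input("cycles must be >= 25")
  set.seed(seed)
  efficiency <- rep_len(efficiency, n_reactions)
  true_quantity <- rep_len(true_quantity, n_reactions)
  reaction_id <- sprintf("R%03d", seq_len(n_reactions))
  plateau <- plateau_factor * baseline
  h <- cap_sharpness
  cyc <- seq_len(cycles)
  out <- vector("list", n_reactions)
  for (i in seq_len(n_reactions)) {
    q <- true_quantity[i] * efficiency[i]^cyc
    s <- q / (1 + (q / plateau)^h)^(1 / h)
    f <- baseline + s
    if (noise_sd > 0) f <- f * (1 + stats::rnorm(cycles, 0, noise_sd))
    out[[i]] <- data.frame(reaction_id = reaction_id[i], cycle = cyc,
                           fluorescence = f, stringsAsFactors = FALSE)
  }
  list(curves = do.call(rbind, out),
       truth = data.frame(reaction_id = reaction_id,
                          efficiency = efficiency,
                          true_quantity = true_quantity,
                          stringsAsFactors = FALSE))
}
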