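# Short time-series model-profile clustering (STEM-style): enumerate integer
# model profiles with bounded per-step change, assign genes by Pearson
# correlation of their log2-ratio vectors with the profile's cumulative
# levels, test profile over-representation against timepoint permutations,
# and group non-flat profiles into the eight temporal archetypes.

#' Enumerate integer model profiles
#'
#' All `(2c+1)^(T-1)` cumulative integer profiles starting at 0 with
#' per-step change in `[-c, c]`, in lexicographic step order. When more
#' than `max_profiles` candidates exist, a representative subset is chosen
#' by greedy max-min distance (distance = 1 - Pearson correlation of the
#' cumulative level vectors), seeded with the largest-amplitude profile;
#' all ties resolve lexicographically, so selection is deterministic.
#'
#' @param n_timepoints Number of timepoints T (>= 2).
#' @param max_unit_change Maximum |level change| per step c (default 2).
#' @param max_profiles Maximum number of model profiles m (default 50).
#' @return Object of class `model_profiles`: list with `levels` (profiles x
#'   T matrix), `steps`, and `profile_id`.
#' @export
enumerate_profiles <- function(n_timepoints = 3, max_unit_change = 2,
                               max_profiles = 50) {
  if (!is_count(n_timepoints) || n_timepoints < 2) {
    abort_input("n_timepoints must be an integer >= 2")
  }
  if (!is_count(max_unit_change)) abort_input("max_unit_change must be >= 1")
  if (!is_count(max_profiles)) abort_input("max_profiles must be >= 1")
  c_ <- max_unit_change
  step_opts <- rep(list(seq(-c_, c_)), n_timepoints - 1)
  grid <- as.matrix(rev(expand.grid(rev(step_opts))))
  colnames(grid) <- paste0("d", seq_len(n_timepoints - 1))
  # lexicographic order on steps
  grid <- grid[do.call(order, as.data.frame(grid)), , drop = FALSE]
  levels <- if (ncol(grid) == 1) {
    cbind(0, grid[, 1])
  } else {
    cbind(0, t(apply(grid, 1, cumsum)))
  }
  colnames(levels) <- paste0("v", seq_len(n_timepoints) - 1)

  if (nrow(levels) > max_profiles) {
    keep <- greedy_maxmin(levels, max_profiles)
    levels <- levels[keep, , drop = FALSE]
    grid <- grid[keep, , drop = FALSE]
  }
  structure(list(levels = unname(levels), steps = unname(grid),
                 profile_id = sprintf("M%02d", seq_len(nrow(levels)))),
            class = "model_profiles")
}

# Greedy max-min selection over profile rows; deterministic.
greedy_maxmin <- function(levels, m) {
  n <- nrow(levels)
  d <- 1 - safe_cor_matrix(levels, levels)
  amp <- apply(levels, 1, function(v) max(v) - min(v))
  start <- which(amp == max(amp))[1]  # rows already in lexicographic order
  sel <- start
  while (length(sel) < m) {
    mind <- apply(d[, sel, drop = FALSE], 1, min)
    mind[sel] <- -Inf
    cand <- which(mind == max(mind))[1]
    sel <- c(sel, cand)
  }
  sort(sel)
}

# Row-wise correlations between two matrices with degenerate-variance
# fallback: rows are mean-centered; rows with (numerically) zero variance
# get zero similarity against anything non-degenerate, 1 against another
# degenerate row. 3-point vectors make Pearson fragile, hence the explicit
# guard rather than relying on stats::cor warnings.
safe_cor_matrix <- function(a, b) {
  ca <- a - rowMeans(a)
  cb <- b - rowMeans(b)
  na_ <- sqrt(rowSums(ca^2))
  nb_ <- sqrt(rowSums(cb^2))
  za <- na_ < 1e-12
  zb <- nb_ < 1e-12
  ca <- ca / ifelse(za, 1, na_)
  cb <- cb / ifelse(zb, 1, nb_)
  m <- tcrossprod(ca, cb)
  if (any(za) || any(zb)) {
    m[za, ] <- 0
    m[, zb] <- 0
    if (any(za) && any(zb)) m[za, zb] <- 1
  }
  m
}

#' Temporal log2-ratio vectors in one genotype
#'
#' Mean expression per gene and timepoint in the chosen genotype,
#' transformed to log2 ratios versus the first timepoint (pseudocount
#' applied); the first column is identically 0.
#'
#' @param expr Long-format expression data frame.
#' @param genes Genes to include (default all).
#' @param genotype Genotype whose temporal profile is used (default the
#'   wild type, `"Ws"`).
#' @param pseudocount Added to mean FPKM before the ratio (default 1).
#' @return Numeric matrix genes x timepoints with gene ids as rownames.
#' @export
temporal_ratios <- function(expr, genes = NULL, genotype = "Ws",
                            pseudocount = 1) {
  sub <- expr[expr$genotype == genotype, , drop = FALSE]
  if (nrow(sub) == 0) abort_input("genotype not in matrix: %s", genotype)
  if (is.null(genes)) genes <- sort(unique(sub$gene_id))
  sub <- sub[sub$gene_id %in% genes, , drop = FALSE]
  tps <- sort(unique(sub$timepoint_min))
  f <- factor(sub$gene_id, levels = genes)
  tf <- factor(sub$timepoint_min, levels = tps)
  means <- tapply(sub$fpkm, list(f, tf), mean)
  ratios <- log2((means + pseudocount) / (means[, 1] + pseudocount))
  ratios[, 1] <- 0
  colnames(ratios) <- tps
  ratios
}

#' Assign genes to model profiles by correlation
#'
#' Each gene's ratio vector is assigned to the model profile maximizing the
#' Pearson correlation with the profile's cumulative levels. Distinct
#' profiles with proportional level vectors (e.g. (0,1,1) and (0,2,2)) have
#' mathematically identical correlation with every gene; such a tie is
#' resolved to the first profile when all tied profiles share one archetype,
#' since the scale of an integer profile carries no shape information.
#' Ties spanning different archetypes, genes whose best correlation involves
#' a flat profile, and constant ratio vectors are left unassigned.
#'
#' @param ratios Gene x timepoint ratio matrix ([temporal_ratios()]).
#' @param profiles A [enumerate_profiles()] object.
#' @return Data frame `gene_id`, `profile_id`, `score`, `archetype`
#'   (cluster 1-8, NA when unassigned).
#' @export
assign_profiles <- function(ratios, profiles) {
  if (!inherits(profiles, "model_profiles")) {
    abort_input("profiles must come from enumerate_profiles()")
  }
  if (ncol(ratios) != ncol(profiles$levels)) {
    abort_input("ratio vectors and profiles differ in timepoint count")
  }
  arch <- group_archetypes(profiles$levels)
  gene_norm <- sqrt(rowSums((ratios - rowMeans(ratios))^2))
  scores <- safe_cor_matrix(ratios, profiles$levels)
  flat <- apply(profiles$levels, 1, function(v) all(v == v[1]))

  n <- nrow(ratios)
  profile_id <- rep(NA_character_, n)
  score <- rep(NA_real_, n)
  archetype <- rep(NA_integer_, n)
  assignable <- gene_norm >= 1e-12
  best <- apply(scores, 1, max)
  for (i in which(assignable)) {
    tied <- which(scores[i, ] >= best[i] - 1e-9)
    if (any(flat[tied])) next                      # flat best: unassigned
    a <- unique(arch[tied])
    if (length(a) != 1L) next                      # ambiguous shape
    j <- tied[1]
    profile_id[i] <- profiles$profile_id[j]
    score[i] <- scores[i, j]
    archetype[i] <- a
  }
  data.frame(gene_id = rownames(ratios) %||% as.character(seq_len(n)),
             profile_id = profile_id, score = score, archetype = archetype,
             stringsAsFactors = FALSE)
}

#' Permutation significance of profile assignment counts
#'
#' The expected assignment count of each profile is estimated by re-running
#' the assignment under every permutation of the timepoints (T! in total,
#' exact for T = 3): each permuted ratio vector is re-referenced to its new
#' first timepoint. The p-value is the upper tail of Binomial(n,
#' expected/n) at the observed count, adjusted across profiles by
#' Benjamini-Hochberg.
#'
#' @param ratios Gene x timepoint ratio matrix.
#' @param profiles A [enumerate_profiles()] object.
#' @return Data frame `profile_id`, `observed`, `expected`, `p_value`,
#'   `q_value`.
#' @export
profile_significance <- function(ratios, profiles) {
  perms <- permutations(ncol(ratios))
  n <- nrow(ratios)
  counts <- sapply(seq_len(nrow(perms)), function(k) {
    p <- perms[k, ]
    r <- ratios[, p, drop = FALSE] - ratios[, p[1]]
    asg <- assign_profiles(r, profiles)
    tabulate(match(asg$profile_id, profiles$profile_id),
             nbins = length(profiles$profile_id))
  })
  observed <- counts[, 1]  # first permutation is the identity
  expected <- rowMeans(counts)
  p <- stats::pbinom(observed - 1, n, pmin(expected / n, 1),
                     lower.tail = FALSE)
  data.frame(profile_id = profiles$profile_id, observed = observed,
             expected = expected, p_value = p, q_value = bh_adjust(p),
             stringsAsFactors = FALSE)
}

# All permutations of 1:n in lexicographic order (identity first); n is the
# timepoint count, so tiny.
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Group non-flat model profiles into the eight temporal archetypes
#'
#' Decision table on the first step `d1 = v1 - v0` and the second-phase
#' trend `v2` vs `v1` (T = 3): induced shapes map to clusters 1 (transient),
#' 2 (late), 3 (sustained), 4 (amplified); repressed shapes to their mirrors
#' 5-8. The table partitions all 24 non-flat profiles at `c = 2`; the flat
#' profile maps to `NA`.
#'
#' @param levels A profile level vector of length 3, or a matrix with one
#'   profile per row.
#' @return Integer archetype id(s) in 1-8, `NA` for flat profiles.
#' @export
group_archetypes <- function(levels) {
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1)
  if (ncol(levels) != 3) {
    abort_input("archetype grouping is defined for 3-timepoint profiles")
  }
  d1 <- levels[, 2] - levels[, 1]
  v1 <- levels[, 2]; v2 <- levels[, 3]
  out <- rep(NA_integer_, nrow(levels))
  up <- d1 > 0; lv <- d1 == 0; dn <- d1 < 0
  out[up & v2 > v1] <- 4L
  out[up & v2 == v1] <- 3L
  out[up & v2 < v1] <- 1L
  out[lv & v2 > 0] <- 2L
  out[lv & v2 < 0] <- 7L
  out[dn & v2 < v1] <- 8L
  out[dn & v2 == v1] <- 6L
  out[dn & v2 > v1] <- 5L
  out
}
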