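# qPCR quantification: window-of-linearity efficiency estimation from raw
# amplification curves, Ct extraction, the E^-dCt expression formula with
# reference-gene and baseline-condition normalization, and genotype-contrast
# t-tests. Reconstructs the behaviour of per-reaction curve-fitting tools:
# baseline subtraction, a log-linear window below the plateau, E from the
# fitted slope.

#' Estimate amplification efficiency and Ct from one curve
#'
#' Baseline (mean fluorescence of `baseline_cycles`) is subtracted; the
#' exponential window is the contiguous `window`-cycle stretch with
#' fluorescence inside `band` (fractions of the plateau, default 5-60%)
#' maximizing the R-squared of log10(F) vs cycle, and `E = 10^slope`,
#' clamped to (1, 2]. When an in-band stretch is shorter than `window` the
#' whole stretch (minimum 3 cycles) is fitted instead - with E near 2 the
#' curve crosses a 12-fold band in fewer than 5 cycles, so a fixed-width
#' window cannot exist there. Ct is the interpolated cycle where the
#' baseline-subtracted curve crosses `ct_fraction` of the plateau.
#' Reactions with no window reaching `r2_min` are flagged unreliable.
#'
#' @param fluorescence Numeric vector of fluorescence per cycle (>= 25
#'   cycles).
#' @param cycles Cycle numbers (default `seq_along(fluorescence)`).
#' @param window Target window width in cycles (default 5).
#' @param band Lower/upper fluorescence bounds as fractions of the plateau
#'   (default `c(0.05, 0.60)`).
#' @param r2_min Minimum R-squared for a reliable fit (default 0.99).
#' @param ct_fraction Threshold for Ct as a fraction of the plateau
#'   (default 0.10).
#' @param baseline_cycles Cycles averaged for the baseline (default 3-10).
#' @return List of class `qpcr_fit`: `efficiency`, `ct`, `r_squared`,
#'   `window` (cycle numbers used), `baseline`, `plateau`, `reliable`.
#' @export
estimate_efficiency <- function(fluorescence,
                                cycles = seq_along(fluorescence),
                                window = 5, band = c(0.05, 0.60),
                                r2_min = 0.99, ct_fraction = 0.10,
                                baseline_cycles = 3:10) {
  if (length(fluorescence) < 25) {
    abort_input("amplification curve needs >= 25 cycles")
  }
  if (length(cycles) != length(fluorescence)) {
    abort_input("cycles and fluorescence lengths differ")
  }
  baseline <- mean(fluorescence[cycles %in% baseline_cycles])
  s <- fluorescence - baseline
  plateau <- max(s)
  if (plateau <= 0) {
    return(structure(list(efficiency = NA_real_, ct = NA_real_,
                          r_squared = NA_real_, window = integer(),
                          baseline = baseline, plateau = plateau,
                          reliable = FALSE), class = "qpcr_fit"))
  }
  eligible <- s > 0 & s >= band[1] * plateau & s <= band[2] * plateau

  best <- list(r2 = -Inf, slope = NA_real_, idx = integer())
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= 3)
  for (j in runs) {
    lo <- starts[j]; hi <- ends[j]
    w <- min(window, hi - lo + 1)
    for (st in lo:(hi - w + 1)) {
      idx <- st:(st + w - 1)
      fit <- loglinear_fit(cycles[idx], log10(s[idx]))
      if (fit$r2 > best$r2) best <- list(r2 = fit$r2, slope = fit$slope,
                                         idx = idx)
    }
  }
  efficiency <- if (is.finite(best$slope)) min(10^best$slope, 2) else NA_real_
  reliable <- is.finite(best$r2) && best$r2 >= r2_min &&
    !is.na(efficiency) && efficiency > 1

  # Ct: first crossing of the threshold, log-interpolated between cycles
  thr <- ct_fraction * plateau
  above <- which(s >= thr)
  ct <- NA_real_
  if (length(above)) {
    i <- above[1]
    if (i == 1) {
      ct <- cycles[1]
    } else if (s[i - 1] > 0) {
      ct <- cycles[i - 1] + (cycles[i] - cycles[i - 1]) *
        (log10(thr) - log10(s[i - 1])) / (log10(s[i]) - log10(s[i - 1]))
    } else {
      ct <- cycles[i - 1] + (cycles[i] - cycles[i - 1]) *
        (thr - s[i - 1]) / (s[i] - s[i - 1])
    }
  }
  structure(list(efficiency = efficiency, ct = ct, r_squared = best$r2,
                 window = if (length(best$idx)) cycles[best$idx] else integer(),
                 baseline = baseline, plateau = plateau,
                 reliable = reliable), class = "qpcr_fit")
}

# Least-squares slope and R^2 of y on x without lm() overhead.
loglinear_fit <- function(x, y) {
  if (!all(is.finite(y))) return(list(slope = NA_real_, r2 = -Inf))
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  if (syy < 1e-30) return(list(slope = 0, r2 = -Inf))
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  list(slope = slope, r2 = sxy^2 / (sxx * syy))
}

#' Fit every curve in a long-format table
#'
#' @param curves Data frame `reaction_id`, `cycle`, `fluorescence`.
#' @param ... Passed to [estimate_efficiency()].
#' @return Data frame `reaction_id`, `efficiency`, `ct`, `r_squared`,
#'   `reliable`. Unreliable reactions are kept (flagged) so the caller
#'   decides on exclusion; a warning reports their count.
#' @export
qpcr_fit_curves <- function(curves, ...) {
  ids <- unique(curves$reaction_id)
  fits <- lapply(ids, function(id) {
    sub <- curves[curves$reaction_id == id, , drop = FALSE]
    sub <- sub[order(sub$cycle), , drop = FALSE]
    estimate_efficiency(sub$fluorescence, sub$cycle, ...)
  })
  out <- data.frame(reaction_id = ids,
                    efficiency = vapply(fits, `[[`, 0, "efficiency"),
                    ct = vapply(fits, `[[`, 0, "ct"),
                    r_squared = vapply(fits, `[[`, 0, "r_squared"),
                    reliable = vapply(fits, `[[`, TRUE, "reliable"),
                    stringsAsFactors = FALSE)
  if (any(!out$reliable)) {
    warning(sprintf("%d unreliable qPCR reaction(s) flagged",
                    sum(!out$reliable)))
  }
  out
}

#' Efficiency-corrected expression level
#'
#' `level = E^-(Ct_target - Ct_reference)`; with E = 2 this reduces exactly
#' to the classical 2^-dCt.
#'
#' @param ct_target Target-gene Ct (vectorized).
#' @param ct_reference Reference-gene Ct in the same sample.
#' @param efficiency Target amplicon efficiency in (1, 2].
#' @return Dimensionless expression level(s).
#' @export
expression_level <- function(ct_target, ct_reference, efficiency) {
  if (any(efficiency <= 1 | efficiency > 2)) {
    abort_input("efficiency must lie in (1, 2]")
  }
  efficiency^-(ct_target - ct_reference)
}

#' Quantify a qPCR experiment from raw curves
#'
#' Joins curve fits with reaction metadata, averages the per-reaction
#' efficiencies of reliable reactions per amplicon (target), and computes
#' each sample's expression level against the reference gene measured in
#' the same (genotype, timepoint, replicate) sample. Samples lacking a
#' reliable reference reaction are excluded.
#'
#' @param curves Data frame `reaction_id`, `cycle`, `fluorescence`.
#' @param reactions Metadata: `reaction_id`, `target`, `genotype`,
#'   `timepoint_min`, `replicate`.
#' @param reference_gene Reference amplicon label (default `"At2g28390"`,
#'   the SAND-family reference).
#' @param ... Passed to [estimate_efficiency()].
#' @return Data frame `target`, `genotype`, `timepoint_min`, `replicate`,
#'   `efficiency`, `delta_ct`, `level`.
#' @export
qpcr_quantify <- function(curves, reactions,
                          reference_gene = "At2g28390", ...) {
  need <- c("reaction_id", "target", "genotype", "timepoint_min", "replicate")
  miss <- setdiff(need, names(reactions))
  if (length(miss)) {
    abort_input("reactions metadata missing column(s): %s",
                paste(miss, collapse = ", "))
  }
  fits <- qpcr_fit_curves(curves, ...)
  m <- merge(reactions, fits, by = "reaction_id")
  m <- m[m$reliable & !is.na(m$ct), , drop = FALSE]
  if (!any(m$target == reference_gene)) {
    abort_input("no reliable reaction for reference gene %s", reference_gene)
  }
  eff <- tapply(m$efficiency, m$target, mean)
  ref <- m[m$target == reference_gene, , drop = FALSE]
  key <- function(d) paste(d$genotype, d$timepoint_min, d$replicate)
  tgt <- m[m$target != reference_gene, , drop = FALSE]
  i <- match(key(tgt), key(ref))
  keep <- !is.na(i)
  tgt <- tgt[keep, , drop = FALSE]
  dct <- tgt$ct - ref$ct[i[keep]]
  e_t <- as.numeric(eff[tgt$target])
  data.frame(target = tgt$target, genotype = tgt$genotype,
             timepoint_min = tgt$timepoint_min, replicate = tgt$replicate,
             efficiency = e_t, delta_ct = dct,
             level = e_t^-dct, stringsAsFactors = FALSE)
}

#' Normalize levels to a reference condition and test genotype contrasts
#'
#' Folds are levels divided by the mean level of the reference condition
#' (wild type at 0 min by construction equals 1 on average). Genotype
#' differences at each timepoint are tested per target with the equal-
#' variance two-sample unpaired t-test (Student's); significance stars at
#' p < 0.05 (*) and p < 0.01 (**). Zero variance in both groups yields
#' p = 1 when the means agree.
#'
#' @param levels Output of [qpcr_quantify()].
#' @param reference_genotype,reference_timepoint Reference condition
#'   (default wild type `"Ws"` at 0 min).
#' @param group_a,group_b Genotypes contrasted per timepoint (default
#'   `"Ws"` vs `"mkp1"`).
#' @return List with `folds` (per target x sample fold-changes) and `tests`
#'   (per target x timepoint: `p_value`, `stars`).
#' @export
normalize_and_test <- function(levels, reference_genotype = "Ws",
                               reference_timepoint = 0,
                               group_a = "Ws", group_b = "mkp1") {
  folds <- do.call(rbind, lapply(split(levels, levels$target), function(d) {
    ref <- d$level[d$genotype == reference_genotype &
                     d$timepoint_min == reference_timepoint]
    if (!length(ref)) {
      abort_input("no reference-condition level for target %s", d$target[1])
    }
    d$fold <- d$level / mean(ref)
    d
  }))
  rownames(folds) <- NULL

  tests <- list()
  for (tg in unique(folds$target)) {
    for (t in sort(unique(folds$timepoint_min))) {
      fa <- folds$fold[folds$target == tg & folds$timepoint_min == t &
                         folds$genotype == group_a]
      fb <- folds$fold[folds$target == tg & folds$timepoint_min == t &
                         folds$genotype == group_b]
      if (length(fa) < 2 || length(fb) < 2) next
      p <- student_t_p(fa, fb)
      tests[[length(tests) + 1]] <- data.frame(
        target = tg, timepoint_min = t,
        mean_a = mean(fa), mean_b = mean(fb), p_value = p,
        stars = if (is.na(p)) "" else if (p < 0.01) "**"
                else if (p < 0.05) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(target = character(), timepoint_min = numeric(),
               mean_a = numeric(), mean_b = numeric(),
               p_value = numeric(), stars = character())
  rownames(tests) <- NULL
  list(folds = folds, tests = tests)
}

# Equal-variance two-sample t with the degenerate-variance convention.
student_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  d <- mean(b) - mean(a)
  if (s2 < 1e-24) return(if (abs(d) < 1e-12) 1 else 1e-300)
  tt <- d / sqrt(s2 * (1 / na + 1 / nb))
  2 * stats::pt(abs(tt), na + nb - 2, lower.tail = FALSE)
}
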