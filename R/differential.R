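# Stand-in pairwise differential-expression test. The original pipeline used
# Cuffdiff's negative-binomial machinery; this module reproduces only its
# table contract (log2 fold-change, p, BH-adjusted q per contrast).
#
# The default test is a moderated t on log2(FPKM + pseudocount): per-gene
# pooled variances are shrunk toward a common prior (limma's empirical Bayes
# squeeze), mirroring how the replaced tool shares dispersion information
# across genes. With 2-3 replicates an unmoderated Welch t has ~4 residual
# df, and its heavy null tails make strict FDR gates (q <= 0.01)
# unattainable at realistic effect sizes; `method = "welch"` retains the
# plain test for comparison.

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: with order statistics `p_(1) <= ... <=
#' p_(m)`, `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1. Order
#' preserving and monotone; `q >= p` elementwise.
#'
#' @param p Vector of p-values in \[0, 1\]; `NaN` is fatal, `NA` propagates.
#' @return Adjusted q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) abort_input("NaN p-value passed to bh_adjust")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort_input("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0) return(q)
  o <- order(p[ok])
  ps <- p[ok][o]
  qs <- rev(cummin(rev(ps * m / seq_len(m))))
  q[ok][o] <- pmin(qs, 1)
  q
}

#' Standard contrasts of the three-genotype elicitor time course
#'
#' For each post-elicitation timepoint: elicitor response within wild type
#' and within the single mutant (t vs 0), plus the three between-genotype
#' contrasts at matched treatment the classifier consumes. Baseline (0-min)
#' genotype contrasts are included for the pre-existing-difference flag.
#'
#' @param genotypes Ordered labels: wild type, single mutant, double mutant.
#' @param timepoints_min Timepoints; the first is the untreated baseline.
#' @return Data frame `condition_a`, `condition_b`.
#' @export
standard_contrasts <- function(genotypes = c("Ws", "mkp1", "mkp1_mpk6"),
                               timepoints_min = c(0, 30, 90)) {
  t0 <- timepoints_min[1]
  later <- timepoints_min[-1]
  wt <- genotypes[1]; mut <- genotypes[2]; dbl <- genotypes[3]
  rows <- list()
  for (t in later) {
    rows[[length(rows) + 1]] <- c(condition_label(wt, t0), condition_label(wt, t))
    rows[[length(rows) + 1]] <- c(condition_label(mut, t0), condition_label(mut, t))
    rows[[length(rows) + 1]] <- c(condition_label(wt, t), condition_label(mut, t))
    rows[[length(rows) + 1]] <- c(condition_label(mut, t), condition_label(dbl, t))
    rows[[length(rows) + 1]] <- c(condition_label(wt, t), condition_label(dbl, t))
  }
  rows[[length(rows) + 1]] <- c(condition_label(wt, t0), condition_label(mut, t0))
  rows[[length(rows) + 1]] <- c(condition_label(wt, t0), condition_label(dbl, t0))
  m <- do.call(rbind, rows)
  data.frame(condition_a = m[, 1], condition_b = m[, 2],
             stringsAsFactors = FALSE)
}

# Per-gene replicate summaries for one condition: mean fpkm, mean/var of
# log2(fpkm + pseudocount), replicate count. Gene order follows `genes`.
condition_summary <- function(expr, condition, genes, pseudocount) {
  lab <- condition_label(expr$genotype, expr$timepoint_min)
  sub <- expr[lab == condition, , drop = FALSE]
  if (nrow(sub) == 0) abort_input("condition not found in matrix: %s", condition)
  f <- factor(sub$gene_id, levels = genes)
  lx <- log2(sub$fpkm + pseudocount)
  n <- as.vector(tapply(lx, f, length))
  n[is.na(n)] <- 0
  list(mean_fpkm = as.vector(tapply(sub$fpkm, f, mean)),
       mean_log = as.vector(tapply(lx, f, mean)),
       var_log = as.vector(tapply(lx, f, stats::var)),
       n = n)
}

#' Pairwise differential test on a long-format expression matrix
#'
#' Computes, per gene, `log2_fc = log2((mean_b + pc) / (mean_a + pc))` and a
#' two-sample test on log2-transformed replicate values. `method =
#' "moderated"` (default) shrinks per-gene pooled variances with
#' [limma::squeezeVar()] before forming the t statistic; `method = "welch"`
#' is the plain Welch t. q-values are Benjamini-Hochberg within the
#' contrast.
#'
#' Degenerate variance convention: when both conditions have (numerically)
#' zero residual variance, p is 1 if the means agree and a 1e-300 floor
#' otherwise. Genes with fewer than 2 replicates in either condition get
#' `status = "NOTEST"`; genes whose means are both below the pseudocount get
#' `status = "LOWDATA"`.
#'
#' @param expr Long-format expression data frame.
#' @param condition_a,condition_b Condition labels (`"<genotype>_<minutes>"`);
#'   must differ and exist in the matrix.
#' @param pseudocount Added to FPKM before ratios and logs (default 1).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return Data frame of differential records (see [read_diff_table()]).
#' @export
test_contrast <- function(expr, condition_a, condition_b, pseudocount = 1,
                          method = c("moderated", "welch")) {
  method <- match.arg(method)
  if (identical(condition_a, condition_b)) {
    abort_input("contrast conditions must differ")
  }
  if (pseudocount < 0) abort_input("pseudocount must be >= 0")
  genes <- sort(unique(expr$gene_id))
  a <- condition_summary(expr, condition_a, genes, pseudocount)
  b <- condition_summary(expr, condition_b, genes, pseudocount)

  lfc <- log2((b$mean_fpkm + pseudocount) / (a$mean_fpkm + pseudocount))
  dlog <- b$mean_log - a$mean_log
  notest <- a$n < 2 | b$n < 2
  eps <- 1e-24

  p <- rep(NA_real_, length(genes))
  t_ok <- which(!notest)
  if (length(t_ok)) {
    va <- a$var_log[t_ok]; vb <- b$var_log[t_ok]
    na <- a$n[t_ok]; nb <- b$n[t_ok]
    degen <- va < eps & vb < eps
    if (method == "welch") {
      se2 <- va / na + vb / nb
      tt <- dlog[t_ok] / sqrt(se2)
      df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
      pp <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    } else {
      s2 <- (va * (na - 1) + vb * (nb - 1)) / (na + nb - 2)
      df <- na + nb - 2
      s2post <- s2
      df_prior <- 0
      if (sum(!degen) >= 2) {
        sq <- limma::squeezeVar(s2[!degen], df[!degen])
        s2post[!degen] <- sq$var.post
        df_prior <- sq$df.prior[1]
        if (!is.finite(df_prior)) df_prior <- Inf
      }
      df_tot <- df + df_prior
      tt <- dlog[t_ok] / sqrt(s2post * (1 / na + 1 / nb))
      pp <- 2 * stats::pt(abs(tt), df_tot, lower.tail = FALSE)
      degen <- degen | s2post < eps
    }
    pp[degen] <- ifelse(abs(dlog[t_ok][degen]) < 1e-12, 1, 1e-300)
    p[t_ok] <- pp
  }
  q <- bh_adjust(p)

  status <- rep("OK", length(genes))
  status[b$mean_fpkm < pseudocount & a$mean_fpkm < pseudocount] <- "LOWDATA"
  status[notest] <- "NOTEST"
  data.frame(gene_id = genes,
             sample_1 = condition_a, sample_2 = condition_b,
             value_1 = a$mean_fpkm, value_2 = b$mean_fpkm,
             log2_fc = lfc, p_value = p, q_value = q, status = status,
             stringsAsFactors = FALSE)
}

#' Run a set of contrasts and stack the records
#' @param expr Long-format expression data frame.
#' @param contrasts Data frame `condition_a`, `condition_b`
#'   (default [standard_contrasts()]).
#' @param ... Passed to [test_contrast()].
#' @return Stacked differential records.
#' @export
test_all_contrasts <- function(expr, contrasts = standard_contrasts(), ...) {
  out <- mapply(function(a, b) test_contrast(expr, a, b, ...),
                contrasts$condition_a, contrasts$condition_b,
                SIMPLIFY = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
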