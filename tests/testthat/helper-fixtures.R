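# Fixtures are built in code; no binary data.

# One differential record with sensible defaults.
diff_row <- function(gene, a, b, lfc = 0, q = 1, p = q,
                     v1 = 10, v2 = v1 * 2^lfc, status = "OK") {
  data.frame(gene_id = gene, sample_1 = a, sample_2 = b,
             value_1 = v1, value_2 = v2, log2_fc = lfc,
             p_value = p, q_value = q, status = status,
             stringsAsFactors = FALSE)
}

# Full standard-contrast table for one gene from a named spec list, e.g.
# list(Ws_30 = c(lfc, q), dep_30 = c(lfc, q), ...). Unspecified contrasts
# default to null (lfc 0, q 1).
gene_diffs <- function(gene, spec = list()) {
  con <- list(
    Ws_30 = c("Ws_0", "Ws_30"), mkp1_30 = c("mkp1_0", "mkp1_30"),
    dep_30 = c("Ws_30", "mkp1_30"), mpk6a_30 = c("mkp1_30", "mkp1_mpk6_30"),
    mpk6b_30 = c("Ws_30", "mkp1_mpk6_30"),
    Ws_90 = c("Ws_0", "Ws_90"), mkp1_90 = c("mkp1_0", "mkp1_90"),
    dep_90 = c("Ws_90", "mkp1_90"), mpk6a_90 = c("mkp1_90", "mkp1_mpk6_90"),
    mpk6b_90 = c("Ws_90", "mkp1_mpk6_90"),
    base_mkp1 = c("Ws_0", "mkp1_0"), base_dbl = c("Ws_0", "mkp1_mpk6_0"))
  rows <- lapply(names(con), function(k) {
    v <- spec[[k]] %||% c(0, 1)
    diff_row(gene, con[[k]][1], con[[k]][2], lfc = v[1], q = v[2])
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random differential fixture over the full standard contrast set; q values
# are spiked near the thresholds so all rule branches are exercised.
random_diffs <- function(n_genes, seed) {
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  con <- rbind(c("Ws_0", "Ws_30"), c("mkp1_0", "mkp1_30"),
               c("Ws_30", "mkp1_30"), c("mkp1_30", "mkp1_mpk6_30"),
               c("Ws_30", "mkp1_mpk6_30"),
               c("Ws_0", "Ws_90"), c("mkp1_0", "mkp1_90"),
               c("Ws_90", "mkp1_90"), c("mkp1_90", "mkp1_mpk6_90"),
               c("Ws_90", "mkp1_mpk6_90"))
  out <- lapply(seq_len(nrow(con)), function(i) {
    lfc <- round(stats::rnorm(n_genes, 0, 1.2), 3)
    q <- sample(c(0.001, 0.005, 0.01, 0.011, 0.05, 0.3, 1), n_genes,
                replace = TRUE)
    diff_row(genes, con[i, 1], con[i, 2], lfc = lfc, q = q)
  })
  do.call(rbind, out)
}

# Naive per-gene re-evaluation of every classification predicate; the
# independent oracle for the vectorized classifier.
classify_oracle <- function(diffs, th = call_thresholds()) {
  genes <- sort(unique(diffs$gene_id))
  get <- function(g, a, b) {
    r <- diffs[diffs$gene_id == g & diffs$sample_1 == a &
                 diffs$sample_2 == b & diffs$status == "OK", ]
    if (nrow(r) == 0) NULL else r[1, ]
  }
  rows <- list()
  for (g in genes) {
    for (t in c(30, 90)) {
      w <- get(g, "Ws_0", paste0("Ws_", t))
      m <- get(g, "mkp1_0", paste0("mkp1_", t))
      qw <- !is.null(w) && abs(w$log2_fc) >= th$lfc_min && w$q_value <= th$q_resp
      qm <- !is.null(m) && abs(m$log2_fc) >= th$lfc_min && m$q_value <= th$q_resp
      responsive <- qw || qm
      direction <- "none"
      if (responsive) {
        direction <- if (qw) {
          if (w$log2_fc > 0) "induced" else "repressed"
        } else {
          if (m$log2_fc > 0) "induced" else "repressed"
        }
      }
      category <- "not_responsive"
      if (responsive) {
        d <- get(g, paste0("Ws_", t), paste0("mkp1_", t))
        dep <- !is.null(d) && abs(d$log2_fc) >= log2(th$dep_fold_min) &&
          d$q_value <= th$q_dep
        if (!dep) {
          category <- "MKP1_independent"
        } else {
          a <- get(g, paste0("mkp1_", t), paste0("mkp1_mpk6_", t))
          b <- get(g, paste0("Ws_", t), paste0("mkp1_mpk6_", t))
          category <- "MKP1_dep_partial_MPK6"
          if (!is.null(a) && !is.null(b)) {
            sa <- a$q_value <= th$q_dep
            sb <- b$q_value <= th$q_dep
            if (sa && !sb) category <- "MKP1_MPK6_dependent"
            if (!sa && sb) category <- "MKP1_dep_MPK6_indep"
          }
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g, timepoint_min = t, responsive = responsive,
        direction = direction, category = category, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$timepoint_min, out$gene_id), ]
}

# Brute-force BH step-up: literal definition on the order statistics,
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  qs <- numeric(m)
  for (i in seq_len(m)) {
    qs[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- qs
  q
}

# Small long-format expression table from a gene x condition mean matrix
# with exact replicate values (vector per cell allowed via a function).
expr_from_means <- function(means, n_rep = 3, jitter = NULL) {
  conds <- colnames(means)
  rows <- list()
  for (g in rownames(means)) {
    for (cond in conds) {
      gt <- sub("_[0-9]+$", "", cond)
      tp <- as.numeric(sub("^.*_", "", cond))
      vals <- rep(means[g, cond], n_rep)
      if (!is.null(jitter)) vals <- vals * jitter(n_rep)
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g, genotype = gt, timepoint_min = tp,
        replicate = seq_len(n_rep), fpkm = vals, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
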