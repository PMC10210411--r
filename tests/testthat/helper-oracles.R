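# Shared fixtures and independent oracles used across test files.

# Build a small panel tibble from a marker-by-population frequency matrix.
make_panel <- function(fm, pops = NULL) {
  M <- nrow(fm)
  K <- ncol(fm)
  if (is.null(pops)) {
    pops <- if (K == 5) c("AFR", "AMR", "EAS", "EUR", "SAS") else paste0("P", seq_len(K))
  }
  colnames(fm) <- paste0("f_", pops)
  dplyr::bind_cols(
    tibble::tibble(
      chrom = "1", pos = seq_len(M),
      ref = "A", alt = "G"
    ),
    tibble::as_tibble(pmin(pmax(fm, 1e-6), 1 - 1e-6))
  )
}

# Hudson-type FST estimator (ratio of averages) from two population
# frequency vectors.
hudson_fst <- function(p1, p2) {
  mean((p1 - p2)^2) / mean(p1 * (1 - p2) + p2 * (1 - p1))
}

# Exhaustive grid maximization of the K=2 supervised admixture likelihood.
grid_fit_k2 <- function(gv, f, step = 1e-4) {
  q1 <- seq(0, 1, by = step)
  a <- outer(f[, 1], q1) + outer(f[, 2], 1 - q1)
  a <- pmin(pmax(a, 1e-12), 1 - 1e-12)
  ll <- colSums(gv * log(a) + (2 - gv) * log1p(-a))
  list(q1 = q1[which.max(ll)], loglik = max(ll))
}

# Step-up BH from its definition: adj_i = min over { j : p_j >= p_i } of
# n p_j / rank_j, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    cand <- which(p >= p[i])
    min(1, min(n * p[cand] / r[cand]))
  }, numeric(1))
}

# Log-likelihood trajectory of the admixture EM obtained by re-running with
# increasing iteration caps (tol = -1 disables early convergence).
em_loglik_trajectory <- function(g, panel, iters = 1:10) {
  vapply(iters, function(it) {
    estimate_admixture(g, panel, tol = -1, max_iter = it)$loglik[1]
  }, numeric(1))
}

# A clinical tibble with exact level counts per group (no sampling noise).
clinical_from_counts <- function(stage_aa, stage_ea, subtype_aa, subtype_ea,
                                 grade_aa, grade_ea) {
  expand_group <- function(stage, subtype, grade, grp) {
    n <- sum(stage)
    tibble::tibble(
      age = 55,
      stage = rep(names(stage), stage),
      subtype = sample(rep(names(subtype), subtype)),
      grade = sample(rep(names(grade), grade)),
      group = grp
    )
  }
  out <- dplyr::bind_rows(
    expand_group(stage_aa, subtype_aa, grade_aa, "AA"),
    expand_group(stage_ea, subtype_ea, grade_ea, "EA")
  )
  out$patient_id <- sprintf("P%05d", seq_len(nrow(out)))
  out
}

# Table-1-style counts of the published cohort (623 AA / 2810 EA).
published_cohort_counts <- function() {
  list(
    stage_aa = c("0" = 0, "I" = 11, "II" = 48, "III" = 45, "IV" = 519),
    stage_ea = c("0" = 1, "I" = 92, "II" = 152, "III" = 193, "IV" = 2372),
    subtype_aa = c(HRpos_HER2neg = 221, TNBC = 143, Other = 259),
    subtype_ea = c(HRpos_HER2neg = 1281, TNBC = 400, Other = 1129),
    grade_aa = c(low = 163, high = 354, unknown = 106),
    grade_ea = c(low = 980, high = 1198, unknown = 632)
  )
}
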