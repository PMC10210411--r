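#' Log2 counts-per-million with a prior count
#'
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)`, with library sizes
#' taken as column sums. The prior count keeps zeros finite; values are
#' invariant to jointly scaling counts and library sizes up to the prior
#' perturbation.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param prior_count Pseudo-count added to each observation (default 0.5).
#' @return Real matrix of the same shape.
#' @export
logcpm <- function(counts, prior_count = 0.5) {
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  if (any(libsize <= 0)) rlang::abort("zero library size")
  t(log2(t(counts + prior_count) / (libsize + 2 * prior_count) * 1e6))
}

#' Invert the trigamma function
#'
#' Newton iteration on `1/x` (where trigamma is nearly linear), as used when
#' fitting the scaled-F prior of the moderated t-statistic.
#'
#' @param y Positive value(s) of trigamma.
#' @return `x` such that `trigamma(x) = y`, elementwise.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) {
      return(NA_real_)
    }
    if (yi > 1e7) {
      return(1 / sqrt(yi))
    }
    if (yi < 1e-6) {
      return(1 / yi)
    }
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes prior for gene-wise variances
#'
#' Fits the scaled-inverse-chi-squared prior `sigma_g^2 ~ s0^2 d0 / chi^2_d0`
#' to observed residual variances by the method of moments on
#' `z_g = log(s_g^2)`: the prior degrees of freedom `d0` solve
#' `trigamma(d0/2) = max(0, var(z) - trigamma(df/2))` (via
#' [trigamma_inverse()]), and `log(s0^2) = mean(z) - digamma(df/2) +
#' log(df/2) + digamma(d0/2) - log(d0/2)` (the last two terms vanish in the
#' `d0 = Inf` limit, which is returned whenever the excess spread of `z` is
#' at most 1e-8).
#'
#' @param s_sq Per-gene residual variances (>= 20 genes). Non-positive
#'   values are floored at 1e-12 with a warning.
#' @param df Residual degrees of freedom of each variance (single value,
#'   >= 1).
#' @return A list of class `eb_prior` with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_eb_prior <- function(s_sq, df) {
  if (length(s_sq) < 20) rlang::abort("need at least 20 genes to fit the prior")
  if (df < 1) rlang::abort("df must be >= 1")
  if (any(s_sq <= 0)) {
    rlang::warn("non-positive variances floored at 1e-12")
    s_sq <- pmax(s_sq, 1e-12)
  }
  z <- log(s_sq)
  excess <- stats::var(z) - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 1e-8) {
    d0 <- Inf
    log_s0 <- mean(z) - digamma(df / 2) + log(df / 2)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    log_s0 <- mean(z) - digamma(df / 2) + log(df / 2) + digamma(d0 / 2) - log(d0 / 2)
  }
  structure(list(d0 = d0, s0_sq = exp(log_s0)), class = "eb_prior")
}

# Moderated two-sample t per row of a real matrix (AA - EA, EA reference).
# prior = NULL fits the EB prior from the data; d0 = 0 reduces to the
# ordinary pooled t.
moderated_t <- function(mat, groups, prior = NULL) {
  groups <- as.character(groups)
  i1 <- groups == "AA"
  i2 <- groups == "EA"
  n1 <- sum(i1)
  n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) rlang::abort("need at least 2 samples per group")
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  v1 <- apply(mat[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(mat[, i2, drop = FALSE], 1, stats::var)
  df <- n1 + n2 - 2
  s_sq <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  if (is.null(prior)) prior <- estimate_eb_prior(pmax(s_sq, 1e-12), df)
  d0 <- prior$d0
  if (is.infinite(d0)) {
    s_tilde <- rep(prior$s0_sq, length(s_sq))
    df_total <- Inf
  } else {
    s_tilde <- (d0 * prior$s0_sq + df * s_sq) / (d0 + df)
    df_total <- d0 + df
  }
  se <- sqrt(s_tilde * (1 / n1 + 1 / n2))
  lfc <- m1 - m2
  tstat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  tibble::tibble(
    gene = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    logFC = unname(lfc), t = unname(tstat), p = unname(p), n1 = n1, n2 = n2
  )
}

#' Moderated-t differential expression within one assay batch
#'
#' Computes log2-CPM values ([logcpm()]), then a two-sample moderated
#' t-statistic per gene with empirical-Bayes variance shrinkage
#' ([estimate_eb_prior()]): the pooled variance is shrunk toward the prior,
#' `s~^2 = (d0 s0^2 + df s^2) / (d0 + df)`, and the statistic is referred
#' to a Student t with `d0 + df` degrees of freedom (normal at `d0 = Inf`).
#' Log fold-changes are AA minus EA (EA is the reference population).
#'
#' @param counts Count matrix genes x samples for one batch.
#' @param groups Character vector (`"AA"`/`"EA"`) per sample.
#' @param prior Optional `eb_prior` to reuse; fitted from the data when
#'   `NULL`. Pass `list(d0 = 0, s0_sq = 1)` to recover the ordinary pooled
#'   t-test.
#' @param prior_count Pseudo-count for [logcpm()].
#' @return A tibble: `gene`, `logFC`, `t`, `p`, `n1`, `n2`.
#' @export
batch_de <- function(counts, groups, prior = NULL, prior_count = 0.5) {
  if (!all(c("AA", "EA") %in% groups)) rlang::abort("both groups must be present in the batch")
  moderated_t(logcpm(counts, prior_count), groups, prior)
}

#' Weighted-Fisher (wFisher) p-value combination
#'
#' Combines per-batch two-sided p-values into one two-sided meta p-value
#' with sample-size weights, respecting effect direction. With batch
#' weights `w_i = n_i / sum(n)`, each two-sided `p_i` is converted to a
#' one-sided value toward the fixed positive reference direction (AA up):
#' `p_i' = p_i/2` when the batch effect is positive, `1 - p_i/2` otherwise.
#' The statistic `T = sum_i Qgamma(1 - p_i'; shape = K w_i, scale = 2)` is
#' referred to Gamma(shape = K, scale = 2) — under the null each `p_i'` is
#' uniform, the gamma components sum to Gamma(K, 2) by construction, and
#' the one-sided meta p is exactly uniform. The two-sided value is
#' `min(1, 2 min(meta, 1 - meta))`, which is therefore also exactly
#' uniform under the null. At equal weights the gamma components are
#' exponentials and `T = -2 sum log p_i'`, the classical Fisher statistic
#' against chi-squared with 2K df.
#'
#' The one-sided conversion is anchored to a fixed direction rather than a
#' direction estimated from the same data: a data-driven anchor makes the
#' converted `p_i'` non-uniform under the null and destroys the exact
#' null calibration above.
#'
#' @param p Two-sided per-batch p-values in (0, 1\]; zeros are clamped to
#'   1e-300 with a warning.
#' @param signs Per-batch effect signs (the sign of each batch logFC).
#' @param n Per-batch sample sizes (positive); batches with zero weight are
#'   dropped.
#' @param logfc Optional per-batch logFC used (with `n`) to label the
#'   overall direction; defaults to `signs`.
#' @return A list with `meta_p` (two-sided), `meta_one` (the one-sided
#'   meta p toward the positive reference direction), and `direction`
#'   (+1/-1, the sign of the sample-size-weighted logFC).
#' @export
wfisher_combine <- function(p, signs, n, logfc = signs) {
  stopifnot(length(p) == length(signs), length(p) == length(n))
  if (any(p <= 0)) {
    rlang::warn("p = 0 clamped to 1e-300")
    p <- pmax(p, 1e-300)
  }
  if (any(p > 1)) rlang::abort("p-values must lie in (0, 1]")
  keep <- n > 0
  p <- p[keep]
  signs <- signs[keep]
  n <- n[keep]
  logfc <- logfc[keep]
  K <- length(p)
  if (K == 0) rlang::abort("no batches with positive weight")
  w <- n / sum(n)
  direction <- sign(sum(w * logfc))
  if (direction == 0) direction <- 1
  p_one <- ifelse(sign(signs) > 0, p / 2, 1 - p / 2)
  T_stat <- sum(stats::qgamma(p_one, shape = K * w, scale = 2, lower.tail = FALSE))
  meta_one <- stats::pgamma(T_stat, shape = K, scale = 2, lower.tail = FALSE)
  meta_p <- min(1, 2 * min(meta_one, 1 - meta_one))
  list(meta_p = meta_p, meta_one = meta_one, direction = direction)
}

#' Sample-size-weighted average of per-batch log fold-changes
#'
#' @param logfc Per-batch logFC vector.
#' @param n Per-batch sample sizes; `sum(n)` must be positive.
#' @return The weighted mean `sum(n * logfc) / sum(n)`.
#' @export
combine_logfc <- function(logfc, n) {
  stopifnot(length(logfc) == length(n))
  if (sum(n) <= 0) rlang::abort("total sample size must be positive")
  sum(n * logfc) / sum(n)
}

#' Batch-aware differential-expression meta-analysis
#'
#' Runs the two-batch pipeline: moderated-t differential expression within
#' each assay batch separately ([batch_de()]), weighted-Fisher combination
#' of the per-gene p-values ([wfisher_combine()]) with weights equal to the
#' batch sample sizes, sample-size-weighted averaging of the log
#' fold-changes ([combine_logfc()]), a direction-concordance filter (both
#' batches must agree on the sign), and a Bonferroni significance cutoff
#' `alpha_family / G` where `G` is the number of genes tested (e.g. the
#' conventional family level 0.01 over 10,000 genes gives 1e-06).
#'
#' @param counts Count matrix genes x samples.
#' @param samples Tibble with `sample`, `group` (`"AA"`/`"EA"`), `batch`
#'   (`"v1"`/`"v2"`) matching the count columns.
#' @param alpha_family Family-wise error target (default 0.01).
#' @return A tibble of class `meta_de` with per-gene columns `gene`,
#'   `logFC_v1`, `p_v1`, `logFC_v2`, `p_v2`, `meta_logFC`, `meta_p`,
#'   `concordant`, `significant`; run metadata (`cutoff`, `n_genes`,
#'   `alpha_family`, `engine`) is stored in attributes and surfaced by
#'   [generics::glance()].
#' @export
meta_de <- function(counts, samples, alpha_family = 0.01) {
  counts <- as.matrix(counts)
  samples <- samples[match(colnames(counts), samples$sample), ]
  if (any(is.na(samples$sample))) rlang::abort("every count column needs sample metadata")
  batches <- sort(unique(samples$batch))
  if (length(batches) != 2) rlang::abort("expected exactly two batches")
  res <- lapply(batches, function(b) {
    idx <- samples$batch == b
    batch_de(counts[, idx, drop = FALSE], samples$group[idx])
  })
  n_b <- vapply(res, function(r) r$n1[1] + r$n2[1], numeric(1))
  G <- nrow(counts)
  lfc1 <- res[[1]]$logFC
  lfc2 <- res[[2]]$logFC
  p1 <- res[[1]]$p
  p2 <- res[[2]]$p
  meta <- purrr::map(seq_len(G), function(i) {
    wfisher_combine(
      p = c(p1[i], p2[i]), signs = sign(c(lfc1[i], lfc2[i])),
      n = n_b, logfc = c(lfc1[i], lfc2[i])
    )
  })
  meta_p <- vapply(meta, `[[`, numeric(1), "meta_p")
  meta_lfc <- vapply(seq_len(G), function(i) combine_logfc(c(lfc1[i], lfc2[i]), n_b), numeric(1))
  cutoff <- alpha_family / G
  out <- tibble::tibble(
    gene = res[[1]]$gene,
    logFC_v1 = lfc1, p_v1 = p1, logFC_v2 = lfc2, p_v2 = p2,
    meta_logFC = meta_lfc, meta_p = meta_p,
    concordant = sign(lfc1) == sign(lfc2) & sign(lfc1) != 0,
    significant = sign(lfc1) == sign(lfc2) & sign(lfc1) != 0 & meta_p < cutoff
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "n_genes") <- G
  attr(out, "alpha_family") <- alpha_family
  attr(out, "engine") <- "moderated t on logCPM + wFisher"
  class(out) <- c("meta_de", class(out))
  out
}

#' @method glance meta_de
#' @export
glance.meta_de <- function(x, ...) {
  tibble::tibble(
    n_genes = attr(x, "n_genes"),
    alpha_family = attr(x, "alpha_family"),
    cutoff = attr(x, "cutoff"),
    n_significant = sum(x$significant),
    n_concordant = sum(x$concordant),
    engine = attr(x, "engine")
  )
}

#' Volcano plot of a meta-analysis result
#'
#' @param object A `meta_de` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meta_de
#' @export
autoplot.meta_de <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$meta_logFC, -log10(pmax(.data$meta_p, 1e-300)),
      colour = .data$significant
    )
  ) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "cutoff")), linetype = 2) +
    ggplot2::labs(
      x = "meta logFC (AA vs EA)", y = "-log10 meta P",
      colour = "significant"
    )
}
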