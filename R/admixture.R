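#' Read an ancestry-informative-marker (AIM) panel from TSV
#'
#' Expects a tab-separated file with header columns `chrom`, `pos`, `ref`,
#' `alt` and one alternate-allele frequency column per reference population
#' (`f_AFR`, `f_AMR`, `f_EAS`, `f_EUR`, `f_SAS` for the five continental
#' populations; any `f_*` set is accepted). Positions are 1-based.
#' Frequencies are validated to \[0, 1\] and then clamped to
#' \[1e-6, 1 - 1e-6\] so the admixture likelihood never evaluates log(0).
#'
#' @param path Path to the panel TSV.
#' @return A panel tibble in file order with clamped frequency columns.
#' @export
read_aim_panel <- function(path) {
  panel <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("panel is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  fc <- grep("^f_", names(panel), value = TRUE)
  if (length(fc) == 0) rlang::abort("panel has no frequency columns (f_*)")
  key <- paste(panel$chrom, panel$pos, panel$ref, panel$alt)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicate marker at line %d: %s", dup[1] + 1L, key[dup[1]]))
  }
  for (col in fc) {
    bad <- which(!is.finite(panel[[col]]) | panel[[col]] < 0 | panel[[col]] > 1)
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "frequency outside [0, 1] in column %s at line %d", col, bad[1] + 1L
      ))
    }
    panel[[col]] <- pmin(pmax(panel[[col]], 1e-6), 1 - 1e-6)
  }
  panel$chrom <- as.character(panel$chrom)
  panel
}

#' Estimate supervised admixture proportions by EM
#'
#' Maximizes, for each sample independently, the binomial genotype
#' log-likelihood
#' `l(q) = sum_m [ g_m log(a_m) + (2 - g_m) log(1 - a_m) ]` with
#' `a_m = sum_k q_k f_km`, over the K-simplex, with the reference
#' population allele frequencies `f_km` held fixed (the supervised setting).
#' The EM update
#' `q_k <- (1 / 2M') sum_m q_k [ g_m f_km / a_m + (2 - g_m)(1 - f_km)/(1 - a_m) ]`
#' is run from a uniform start until the log-likelihood improves by less
#' than `tol` or `max_iter` is reached; this likelihood is concave in `q`,
#' so no restarts are needed. Missing genotypes (`NA`) are dropped per
#' sample (`M'` = non-missing markers).
#'
#' @param g Genotype matrix, samples x markers, alt-allele dosages in
#'   \{0, 1, 2\} or `NA`; marker columns must match the panel's markers in
#'   order and count.
#' @param panel Panel tibble (see [read_aim_panel()]).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations. The default is generous because
#'   near-boundary solutions approach the tight `tol` slowly; iterations are
#'   cheap (one `M x K` sweep each).
#' @return A tibble of class `admixture_fit` with one row per sample:
#'   `sample`, one `q_<pop>` column per population, `loglik`, `n_iter`,
#'   `converged`, `n_markers_used`. Samples whose markers are all missing
#'   get `NA` estimates with `converged = FALSE`; others proceed.
#' @export
estimate_admixture <- function(g, panel, tol = 1e-8, max_iter = 20000L) {
  fm <- panel_freq_matrix(panel) # M x K
  g <- as.matrix(g)
  if (ncol(g) != nrow(fm)) {
    rlang::abort("genotype matrix columns must match the panel's markers")
  }
  if (any(!(g %in% c(0, 1, 2, NA)))) rlang::abort("dosages must be 0, 1, 2, or NA")
  K <- ncol(fm)
  pops <- colnames(fm)
  n <- nrow(g)
  ids <- rownames(g) %||% sprintf("S%04d", seq_len(n))

  fit_one <- function(gi) {
    keep <- !is.na(gi)
    mprime <- sum(keep)
    if (mprime == 0) {
      return(list(
        q = rep(NA_real_, K), loglik = NA_real_, n_iter = 0L,
        converged = FALSE, used = 0L
      ))
    }
    gv <- gi[keep]
    f <- fm[keep, , drop = FALSE]
    q <- rep(1 / K, K)
    ll <- function(q) {
      a <- drop(f %*% q)
      sum(gv * log(a) + (2 - gv) * log1p(-a))
    }
    ll_old <- ll(q)
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      a <- drop(f %*% q)
      # responsibilities summed over markers, one term per allele copy
      num <- colSums(gv / a * f) * q + colSums((2 - gv) / (1 - a) * (1 - f)) * q
      q <- num / (2 * mprime)
      q <- q / sum(q) # guard against accumulated rounding
      ll_new <- ll(q)
      if (ll_new - ll_old < tol) {
        converged <- TRUE
        ll_old <- ll_new
        break
      }
      ll_old <- ll_new
    }
    list(q = q, loglik = ll_old, n_iter = iter, converged = converged, used = mprime)
  }

  fits <- lapply(seq_len(n), function(i) fit_one(g[i, ]))
  qmat <- do.call(rbind, lapply(fits, `[[`, "q"))
  colnames(qmat) <- paste0("q_", pops)
  out <- tibble::tibble(sample = ids) |>
    dplyr::bind_cols(tibble::as_tibble(qmat)) |>
    dplyr::mutate(
      loglik = vapply(fits, `[[`, numeric(1), "loglik"),
      n_iter = vapply(fits, `[[`, integer(1), "n_iter"),
      converged = vapply(fits, `[[`, logical(1), "converged"),
      n_markers_used = vapply(fits, `[[`, integer(1), "used")
    )
  class(out) <- c("admixture_fit", class(out))
  out
}

#' Ancestry classification thresholds
#'
#' Threshold rules on the admixture proportion vector: a sample is called
#' African ancestry (AA) when its African component exceeds `afr_min`, its
#' Americas component is below `amr_max`, and African + European combined
#' exceed `afr_plus_eur_min`; European ancestry (EA) when the European
#' component exceeds `eur_min` and the Americas component is below
#' `amr_max`. All inequalities are strict, so boundary values are excluded.
#'
#' @param afr_min,amr_max,afr_plus_eur_min,eur_min Threshold values in (0, 1).
#' @return A named list of class `ancestry_thresholds`.
#' @export
ancestry_thresholds <- function(afr_min = 0.20, amr_max = 0.10,
                                afr_plus_eur_min = 0.70, eur_min = 0.80) {
  vals <- c(afr_min, amr_max, afr_plus_eur_min, eur_min)
  if (any(vals <= 0 | vals >= 1)) rlang::abort("thresholds must lie in (0, 1)")
  structure(
    list(
      afr_min = afr_min, amr_max = amr_max,
      afr_plus_eur_min = afr_plus_eur_min, eur_min = eur_min
    ),
    class = "ancestry_thresholds"
  )
}

#' Classify samples as AA / EA / EXCLUDED from admixture proportions
#'
#' Applies the strict threshold rules of [ancestry_thresholds()] to named
#' five-population proportions. The AA rule is evaluated first; the two
#' rules are mutually exclusive (an African component above 20% forces the
#' European component below 80%). Anything satisfying neither rule is
#' `EXCLUDED`.
#'
#' @param q Either a named numeric vector with components `AFR`, `AMR`,
#'   `EAS`, `EUR`, `SAS` (order-free), or an `admixture_fit` tibble with
#'   `q_AFR` ... `q_SAS` columns.
#' @param thresholds An [ancestry_thresholds()] object.
#' @return For a vector: a single label. For a tibble: the tibble with an
#'   `ancestry` column appended.
#' @export
classify_ancestry <- function(q, thresholds = ancestry_thresholds()) {
  if (is.data.frame(q)) {
    need <- paste0("q_", c("AFR", "AMR", "EUR"))
    if (!all(need %in% names(q))) {
      rlang::abort("expected columns q_AFR, q_AMR, q_EUR (named five-population fit)")
    }
    lab <- classify_q(q$q_AFR, q$q_AMR, q$q_EUR, thresholds)
    return(dplyr::mutate(q, ancestry = lab))
  }
  if (is.null(names(q)) || !all(c("AFR", "AMR", "EUR") %in% names(q))) {
    rlang::abort("q must carry population names incl. AFR, AMR, EUR")
  }
  classify_q(q[["AFR"]], q[["AMR"]], q[["EUR"]], thresholds)
}

classify_q <- function(afr, amr, eur, thr) {
  dplyr::case_when(
    is.na(afr) | is.na(amr) | is.na(eur) ~ NA_character_,
    afr > thr$afr_min & amr < thr$amr_max & (afr + eur) > thr$afr_plus_eur_min ~ "AA",
    eur > thr$eur_min & amr < thr$amr_max ~ "EA",
    TRUE ~ "EXCLUDED"
  )
}

#' Per-population concordance of two admixture estimates
#'
#' Pearson correlation of each ancestry component across samples between two
#' estimates of the same individuals (e.g. tumor vs matched normal tissue).
#' A component with zero variance in either estimate is reported as
#' undefined (`NA`) and flagged rather than forced to 1.
#'
#' @param est_a,est_b `admixture_fit` tibbles over the same samples (matched
#'   by the `sample` column), at least 3 samples.
#' @return A tibble with columns `population`, `r`, `degenerate`.
#' @export
ancestry_concordance <- function(est_a, est_b) {
  qcols <- grep("^q_", names(est_a), value = TRUE)
  if (!identical(qcols, grep("^q_", names(est_b), value = TRUE))) {
    rlang::abort("estimates must share the same population columns")
  }
  est_b <- est_b[match(est_a$sample, est_b$sample), ]
  if (any(is.na(est_b$sample)) || nrow(est_a) < 3) {
    rlang::abort("estimates must cover the same samples, n >= 3")
  }
  purrr::map_dfr(qcols, function(col) {
    xa <- est_a[[col]]
    xb <- est_b[[col]]
    if (stats::sd(xa) < .Machine$double.eps^0.5 || stats::sd(xb) < .Machine$double.eps^0.5) {
      tibble::tibble(population = sub("^q_", "", col), r = NA_real_, degenerate = TRUE)
    } else {
      tibble::tibble(
        population = sub("^q_", "", col),
        r = stats::cor(xa, xb), degenerate = FALSE
      )
    }
  })
}

#' @method tidy admixture_fit
#' @export
tidy.admixture_fit <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(x, "sample", dplyr::starts_with("q_")),
    dplyr::starts_with("q_"),
    names_to = "population", names_prefix = "q_", values_to = "proportion"
  )
}

#' @method glance admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    n_converged = sum(x$converged),
    mean_iter = mean(x$n_iter),
    mean_markers_used = mean(x$n_markers_used)
  )
}
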