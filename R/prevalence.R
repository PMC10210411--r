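#' Group-stratified carrier prevalence per gene
#'
#' Counts carriers of pathogenic alterations per gene in the AA and EA
#' groups, optionally restricted to one receptor subtype, and reports exact
#' carrier frequencies (`n_carrier / n`).
#'
#' @param mut Logical (or 0/1) matrix patients x genes; rownames are patient
#'   ids joining to `clinical$patient_id`.
#' @param clinical Clinical tibble with `patient_id`, `group`, `subtype`.
#' @param stratum `"all"` (default) or a subtype value such as
#'   `"HRpos_HER2neg"` or `"TNBC"`.
#' @return A tibble with one row per gene: `gene`, `n_carrier_AA`, `n_AA`,
#'   `n_carrier_EA`, `n_EA`, `freq_AA`, `freq_EA`. The stratum is recorded
#'   in the `"stratum"` attribute.
#' @export
prevalence_table <- function(mut, clinical, stratum = "all") {
  mut <- as.matrix(mut)
  if (is.numeric(mut)) {
    if (any(!mut %in% c(0, 1))) rlang::abort("carrier matrix must be boolean (0/1)")
    mut <- mut == 1
  }
  clin <- clinical[match(rownames(mut), clinical$patient_id), ]
  if (any(is.na(clin$patient_id))) {
    rlang::abort("every carrier-matrix patient must appear in the clinical table")
  }
  keep <- if (identical(stratum, "all")) rep(TRUE, nrow(clin)) else clin$subtype == stratum
  grp <- clin$group[keep]
  if (sum(grp == "AA") == 0 || sum(grp == "EA") == 0) {
    rlang::abort(sprintf("stratum '%s' is empty in one of the groups", stratum))
  }
  sub <- mut[keep, , drop = FALSE]
  out <- tibble::tibble(
    gene = colnames(sub),
    n_carrier_AA = colSums(sub[grp == "AA", , drop = FALSE]),
    n_AA = sum(grp == "AA"),
    n_carrier_EA = colSums(sub[grp == "EA", , drop = FALSE]),
    n_EA = sum(grp == "EA")
  ) |>
    dplyr::mutate(
      freq_AA = .data$n_carrier_AA / .data$n_AA,
      freq_EA = .data$n_carrier_EA / .data$n_EA
    )
  attr(out, "stratum") <- stratum
  out
}

#' Rank genes by pooled carrier frequency
#'
#' Orders genes by total carriers over total patients (both groups pooled),
#' descending, with alphabetical tie-breaking — the ordering used for
#' top-N oncoplot panels.
#'
#' @param tbl A [prevalence_table()] tibble.
#' @param n Number of genes to return (default 15). If `n` exceeds the
#'   number of genes, all genes are returned with a warning.
#' @return Character vector of gene names in rank order.
#' @export
rank_top_genes <- function(tbl, n = 15) {
  if (nrow(tbl) == 0) rlang::abort("prevalence table is empty")
  if (n > nrow(tbl)) {
    rlang::warn("fewer genes than requested; returning all")
    n <- nrow(tbl)
  }
  pooled <- (tbl$n_carrier_AA + tbl$n_carrier_EA) / (tbl$n_AA + tbl$n_EA)
  ord <- order(-pooled, tbl$gene)
  tbl$gene[ord][seq_len(n)]
}

#' Test AA-vs-EA prevalence differences per gene
#'
#' Adds a continuity-corrected 2x2 Pearson chi-squared test per gene and a
#' Benjamini-Hochberg adjusted p-value computed over all genes in the
#' table. Raw p-values remain the reference for the top-ranked genes;
#' adjusted values are for scanning beyond them. A gene with a zero margin
#' (no carriers or all carriers in both groups) gets p = 1 by convention
#' and is flagged.
#'
#' @param tbl A [prevalence_table()] tibble.
#' @return The table with `chi2`, `p`, `p_adj`, `degenerate` columns
#'   appended; the adjustment method is recorded in the `"p_adjust_method"`
#'   attribute.
#' @export
compare_prevalence <- function(tbl) {
  res <- purrr::pmap_dfr(
    tbl[c("n_carrier_AA", "n_AA", "n_carrier_EA", "n_EA")],
    function(n_carrier_AA, n_AA, n_carrier_EA, n_EA) {
      r <- two_by_two_chisq(
        n_carrier_AA, n_AA - n_carrier_AA,
        n_carrier_EA, n_EA - n_carrier_EA,
        correction = TRUE
      )
      tibble::tibble(chi2 = r$statistic, p = r$p_value, degenerate = r$degenerate)
    }
  )
  out <- dplyr::bind_cols(tbl, res)
  out$p_adj <- bh_adjust(out$p)
  attr(out, "stratum") <- attr(tbl, "stratum")
  attr(out, "p_adjust_method") <- "BH"
  out
}

#' Oncoplot-style prevalence plot
#'
#' Side-by-side carrier frequencies per group for the top-ranked genes.
#'
#' @param tbl A [compare_prevalence()] or [prevalence_table()] tibble.
#' @param n Number of top genes to show.
#' @return A ggplot object.
#' @export
plot_prevalence <- function(tbl, n = 15) {
  top <- rank_top_genes(tbl, n)
  long <- tbl |>
    dplyr::filter(.data$gene %in% top) |>
    dplyr::mutate(gene = factor(.data$gene, levels = rev(top))) |>
    tidyr::pivot_longer(c("freq_AA", "freq_EA"),
      names_to = "group", names_prefix = "freq_", values_to = "frequency"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$frequency, .data$gene, fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "carrier frequency", y = NULL, fill = "ancestry",
      title = "Pathogenic-alteration carrier prevalence"
    )
}
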