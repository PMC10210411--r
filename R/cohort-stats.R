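#' Pearson chi-squared test for a 2x2 table with Yates continuity correction
#'
#' Tests independence in a 2x2 contingency table laid out as carriers /
#' non-carriers (rows) by group (columns). The Yates correction subtracts 0.5
#' from each |O - E|, capped so the corrected deviation never goes negative —
#' the convention under which the cohort-characteristics comparisons in this
#' package reproduce published two-group tests.
#'
#' @param a,b Counts in the first column (e.g. carriers and non-carriers in
#'   group 1).
#' @param c,d Counts in the second column.
#' @param correction Apply the Yates continuity correction? Default `TRUE`.
#'
#' @return A tibble of class `chisq_result` with columns `statistic`, `df`,
#'   `p_value`, `correction_applied`, and `degenerate` (`TRUE` when a zero
#'   margin forced the convention statistic 0, p = 1). The observed table is
#'   kept in the `"observed"` attribute.
#' @examples
#' two_by_two_chisq(143, 480, 400, 2410) # TNBC vs other by ancestry group
#' @export
two_by_two_chisq <- function(a, b, c, d, correction = TRUE) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("counts must be non-negative integers")
  }
  tab <- matrix(counts, nrow = 2)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (sum(tab) == 0) rlang::abort("at least one count must be nonzero")
  if (degenerate) {
    out <- tibble::tibble(
      statistic = 0, df = 1L, p_value = 1,
      correction_applied = correction, degenerate = TRUE
    )
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correction))
    out <- tibble::tibble(
      statistic = unname(ht$statistic), df = 1L,
      p_value = unname(ht$p.value),
      correction_applied = correction, degenerate = FALSE
    )
  }
  attr(out, "observed") <- tab
  class(out) <- c("chisq_result", class(out))
  out
}

#' Pearson chi-squared test for an r x c table
#'
#' No continuity correction is applied (the correction is a 2x2-only
#' convention). Rows or columns with a zero margin are dropped with a warning
#' before testing.
#'
#' @param table A matrix of non-negative integer counts, at least 2x2.
#' @return A tibble of class `chisq_result` (see [two_by_two_chisq()]);
#'   `df = (r-1)(c-1)` for the retained rows/columns.
#' @export
rxc_chisq <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    rlang::abort("counts must be non-negative integers")
  }
  if (nrow(table) < 2 || ncol(table) < 2) rlang::abort("table must be at least 2x2")
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  if (!all(keep_r) || !all(keep_c)) {
    rlang::warn("dropping zero-margin rows/columns before testing")
    table <- table[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    out <- tibble::tibble(
      statistic = 0, df = 0L, p_value = 1,
      correction_applied = FALSE, degenerate = TRUE
    )
  } else {
    ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    out <- tibble::tibble(
      statistic = unname(ht$statistic), df = as.integer(ht$parameter),
      p_value = unname(ht$p.value),
      correction_applied = FALSE, degenerate = FALSE
    )
  }
  attr(out, "observed") <- table
  class(out) <- c("chisq_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' Step-up false-discovery-rate adjustment; output is elementwise no smaller
#' than the input and capped at 1. `NA`/`NaN` inputs propagate with a warning.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p))) rlang::warn("NA p-values propagated unadjusted")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) rlang::abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cohort-characteristics summary with between-group tests
#'
#' Builds a clinical summary of the kind printed in cohort papers: per-group
#' counts and percentages for stage, subtype, and tumor grade, age
#' moments, and chi-squared comparisons between the African-ancestry (AA)
#' and European-ancestry (EA) groups. Stage is compared as IV vs other;
#' each subtype as that level vs the rest; grade both as high vs low
#' (unknown excluded) and as the full low/high/unknown table, since the
#' published grouping convention varies.
#'
#' @param clinical A clinical tibble as produced by [simulate_clinical()]:
#'   columns `patient_id`, `age`, `stage`, `subtype`, `grade`, `group`.
#' @return An object of class `cohort_table`: a list with `summary` (long
#'   tibble of level counts/percentages per group, percentages at 2 d.p.),
#'   `age` (mean/SD/median per group), and `tests` (one row per comparison
#'   with statistic and p-value).
#' @export
build_cohort_table <- function(clinical) {
  stopifnot(is.data.frame(clinical))
  clinical <- dplyr::mutate(clinical, group = as.character(.data$group))
  groups <- sort(unique(clinical$group))
  if (!setequal(groups, c("AA", "EA"))) {
    rlang::abort("clinical must contain both AA and EA groups")
  }
  n_aa <- sum(clinical$group == "AA")
  n_ea <- sum(clinical$group == "EA")

  level_summary <- function(var) {
    clinical |>
      dplyr::count(.data$group, level = as.character(.data[[var]])) |>
      tidyr::pivot_wider(names_from = "group", values_from = "n", values_fill = 0L) |>
      dplyr::mutate(
        characteristic = var,
        pct_AA = round(100 * .data$AA / n_aa, 2),
        pct_EA = round(100 * .data$EA / n_ea, 2)
      ) |>
      dplyr::select("characteristic", "level",
        n_AA = "AA", "pct_AA", n_EA = "EA", "pct_EA"
      )
  }
  summary_tbl <- dplyr::bind_rows(lapply(c("stage", "subtype", "grade"), level_summary))

  age_tbl <- clinical |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean_age = mean(.data$age), sd_age = stats::sd(.data$age),
      median_age = stats::median(.data$age), .groups = "drop"
    )

  counts2 <- function(flag) {
    c(
      sum(flag & clinical$group == "AA"), sum(!flag & clinical$group == "AA"),
      sum(flag & clinical$group == "EA"), sum(!flag & clinical$group == "EA")
    )
  }
  test_row <- function(label, flag) {
    k <- counts2(flag)
    if (k[1] + k[2] == 0 || k[3] + k[4] == 0 || (k[1] + k[3]) == 0 || (k[2] + k[4]) == 0) {
      return(tibble::tibble(
        comparison = label, statistic = NA_real_, p_value = NA_real_,
        note = "degenerate level, comparison skipped"
      ))
    }
    res <- two_by_two_chisq(k[1], k[2], k[3], k[4], correction = TRUE)
    tibble::tibble(
      comparison = label, statistic = res$statistic, p_value = res$p_value,
      note = NA_character_
    )
  }

  tests <- dplyr::bind_rows(
    test_row("stage IV vs other", clinical$stage == "IV"),
    dplyr::bind_rows(lapply(
      sort(unique(as.character(clinical$subtype))),
      function(s) test_row(paste0("subtype ", s, " vs rest"), clinical$subtype == s)
    )),
    {
      known <- clinical[clinical$grade %in% c("low", "high"), ]
      if (length(unique(known$grade)) == 2 && length(unique(known$group)) == 2) {
        k <- c(
          sum(known$grade == "high" & known$group == "AA"),
          sum(known$grade == "low" & known$group == "AA"),
          sum(known$grade == "high" & known$group == "EA"),
          sum(known$grade == "low" & known$group == "EA")
        )
        res <- two_by_two_chisq(k[1], k[2], k[3], k[4], correction = TRUE)
        tibble::tibble(
          comparison = "grade high vs low (unknown excluded)",
          statistic = res$statistic, p_value = res$p_value, note = NA_character_
        )
      } else {
        tibble::tibble(
          comparison = "grade high vs low (unknown excluded)",
          statistic = NA_real_, p_value = NA_real_,
          note = "degenerate level, comparison skipped"
        )
      }
    },
    {
      tab <- table(as.character(clinical$grade), clinical$group)
      if (nrow(tab) >= 2) {
        res <- suppressWarnings(rxc_chisq(unclass(tab)))
        tibble::tibble(
          comparison = "grade full table", statistic = res$statistic,
          p_value = res$p_value, note = NA_character_
        )
      } else {
        tibble::tibble(
          comparison = "grade full table", statistic = NA_real_,
          p_value = NA_real_, note = "degenerate level, comparison skipped"
        )
      }
    }
  )

  structure(
    list(summary = summary_tbl, age = age_tbl, tests = tests,
         n = c(AA = n_aa, EA = n_ea)),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d AA, %d EA patients\n", x$n["AA"], x$n["EA"]))
  print(x$summary, n = Inf)
  cat("\nBetween-group comparisons:\n")
  print(x$tests, n = Inf)
  invisible(x)
}

#' @method tidy cohort_table
#' @export
tidy.cohort_table <- function(x, ...) x$summary

#' @method glance cohort_table
#' @export
glance.cohort_table <- function(x, ...) {
  tibble::tibble(
    n_AA = unname(x$n["AA"]), n_EA = unname(x$n["EA"]),
    n_comparisons = nrow(x$tests),
    min_p = suppressWarnings(min(x$tests$p_value, na.rm = TRUE))
  )
}
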