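# Regenerates the synthetic fixtures shipped under inst/extdata/.
# Both files are synthetic stand-ins built with the package's own
# generators under fixed seeds; they are not derived from any external
# data release.
#
# Run from the package root: Rscript data-raw/make_fixtures.R

devtools::load_all(".", quiet = TRUE)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

# 654-marker, five-population AIM panel (Balding-Nichols, F = 0.15)
panel <- simulate_reference_panel(M = 654, K = 5, F = rep(0.15, 5), seed = 20230525)
readr::write_tsv(
  dplyr::mutate(panel, dplyr::across(dplyr::starts_with("f_"), ~ round(.x, 6))),
  "inst/extdata/aim_panel_synthetic.tsv"
)

# 239 synthetic gene sets: 50 hallmark-like + 189 oncogenic-signature-like,
# drawn from a 2000-gene universe (GENE00001..GENE02000, matching the
# count simulator's gene names at G = 2000).
set.seed(20230525)
universe <- sprintf("GENE%05d", 1:2000)
make_sets <- function(prefix, n) {
  lapply(seq_len(n), function(i) {
    size <- sample(8:30, 1)
    list(
      name = sprintf("%s_%03d", prefix, i),
      desc = "synthetic",
      genes = sample(universe, size)
    )
  })
}
sets <- c(make_sets("HM_SYNTH", 50), make_sets("ONC_SYNTH", 189))
lines <- vapply(sets, function(s) {
  paste(c(s$name, s$desc, s$genes), collapse = "\t")
}, character(1))
writeLines(lines, "inst/extdata/genesets_synthetic.gmt")

cat("panel markers:", nrow(panel), " gmt sets:", length(lines), "\n")
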