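#' Simulation configuration for a synthetic ancestry-stratified cohort
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' defaults reproduce the statistical structure the downstream pipeline
#' assumes: a five-population reference panel with moderate differentiation,
#' a two-group clinical composition matching a large real-world breast-cancer
#' cohort, per-gene mutation prevalences taken from that cohort's published
#' percentages, and negative-binomial expression counts with a two-level
#' assay batch effect and planted ancestry effects.
#'
#' @param seed Integer seed; the same configuration and seed give
#'   bit-identical output from every generator.
#' @param n_AA,n_EA Patients per ancestry group (defaults 623 and 2810).
#' @param M Number of ancestry-informative markers (default 654).
#' @param K Number of reference populations (default 5).
#' @param F Length-`K` Balding-Nichols differentiation parameters, each
#'   strictly in (0, 1). Default 0.15 per population, a typical
#'   continental-scale FST.
#' @param clinical_probs Per-group categorical probabilities for stage,
#'   subtype, and grade plus age moments; see [default_clinical_probs()].
#' @param prevalences Long table of per-gene carrier probabilities; see
#'   [default_prevalences()].
#' @param G Number of expression genes (default 2000).
#' @param de_fraction Fraction of genes with a planted ancestry effect.
#' @param effect_size Magnitude of the planted log2 fold-change.
#' @param batch_effect_sd SD of the per-gene log2 shift between assay
#'   versions (default 0.3, a minor batch effect).
#' @param dispersion_meanlog,dispersion_sdlog Lognormal parameters of the
#'   per-gene NB dispersion (defaults give median dispersion 0.1).
#' @param libsize_range Lower/upper bounds of per-sample library sizes.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_AA = 623L, n_EA = 2810L,
                       M = 654L, K = 5L, F = rep(0.15, K),
                       clinical_probs = default_clinical_probs(),
                       prevalences = default_prevalences(),
                       G = 2000L, de_fraction = 0.05, effect_size = 2,
                       batch_effect_sd = 0.3,
                       dispersion_meanlog = log(0.1), dispersion_sdlog = 0.5,
                       libsize_range = c(5e6, 2e7)) {
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_AA >= 1, n_EA >= 1, M >= 1, K >= 1, length(F) == K,
    G >= 10, de_fraction >= 0, de_fraction <= 1,
    effect_size >= 0, batch_effect_sd >= 0, dispersion_sdlog >= 0
  )
  if (any(!is.finite(F)) || any(F <= 0) || any(F >= 1)) {
    rlang::abort("F must be strictly inside (0, 1)")
  }
  if (length(libsize_range) != 2 || any(!is.finite(libsize_range)) ||
    libsize_range[1] <= 0 || libsize_range[1] > libsize_range[2]) {
    rlang::abort("degenerate libsize_range")
  }
  for (grp in names(clinical_probs)) {
    for (fld in c("stage", "subtype", "grade")) {
      pr <- clinical_probs[[grp]][[fld]]
      if (any(pr < 0 | pr > 1) || abs(sum(pr) - 1) > 1e-9) {
        rlang::abort(sprintf("clinical probabilities for %s/%s must sum to 1", grp, fld))
      }
    }
  }
  if (any(prevalences$prev < 0 | prevalences$prev > 1)) {
    rlang::abort("prevalences must lie in [0, 1]")
  }
  structure(
    list(
      seed = as.integer(seed), n_AA = as.integer(n_AA), n_EA = as.integer(n_EA),
      M = as.integer(M), K = as.integer(K), F = as.numeric(F),
      clinical_probs = clinical_probs, prevalences = prevalences,
      G = as.integer(G), de_fraction = de_fraction, effect_size = effect_size,
      batch_effect_sd = batch_effect_sd,
      dispersion_meanlog = dispersion_meanlog, dispersion_sdlog = dispersion_sdlog,
      libsize_range = libsize_range
    ),
    class = "sim_config"
  )
}

#' Default clinical composition
#'
#' Per-group categorical probabilities for stage at diagnosis, receptor
#' subtype, and tumor grade, plus age mean/SD, set to the composition of a
#' published real-world metastatic-enriched breast-cancer cohort of 623
#' African-ancestry and 2810 European-ancestry patients (e.g. the AA stage-IV
#' probability is 519/623 = 0.8331).
#'
#' @return A named list with `AA` and `EA` elements, each holding `stage`,
#'   `subtype`, `grade` probability vectors and `age_mean`, `age_sd`.
#' @export
default_clinical_probs <- function() {
  list(
    AA = list(
      stage = c("0" = 0, "I" = 11, "II" = 48, "III" = 45, "IV" = 519) / 623,
      subtype = c(HRpos_HER2neg = 221, TNBC = 143, Other = 259) / 623,
      grade = c(low = 163, high = 354, unknown = 106) / 623,
      age_mean = 54.01, age_sd = 12.59
    ),
    EA = list(
      stage = c("0" = 1, "I" = 92, "II" = 152, "III" = 193, "IV" = 2372) / 2810,
      subtype = c(HRpos_HER2neg = 1281, TNBC = 400, Other = 1129) / 2810,
      grade = c(low = 980, high = 1198, unknown = 632) / 2810,
      age_mean = 55.90, age_sd = 13.37
    )
  )
}

#' Default per-gene mutation carrier prevalences
#'
#' Long table of carrier probabilities per gene, ancestry group, and subtype.
#' Values are the published oncoplot percentages for the most frequently
#' altered genes in a real-world breast-cancer cohort (e.g. PIK3CA in
#' HR+/HER2- disease: 34% AA vs 42% EA; KMT2C in TNBC: 23% AA vs 12% EA).
#' The subtype `"*"` is a fallback applied to subtypes without a specific
#' entry; genes/strata with no entry at all simulate as non-carriers.
#'
#' @return A tibble with columns `gene`, `group`, `subtype`, `prev`.
#' @export
default_prevalences <- function() {
  tibble::tribble(
    ~gene, ~group, ~subtype, ~prev,
    "TP53", "AA", "*", 0.59, "TP53", "EA", "*", 0.49,
    "TP53", "AA", "HRpos_HER2neg", 0.40, "TP53", "EA", "HRpos_HER2neg", 0.37,
    "TP53", "AA", "TNBC", 0.90, "TP53", "EA", "TNBC", 0.88,
    "PIK3CA", "AA", "*", 0.28, "PIK3CA", "EA", "*", 0.37,
    "PIK3CA", "AA", "HRpos_HER2neg", 0.34, "PIK3CA", "EA", "HRpos_HER2neg", 0.42,
    "PTEN", "AA", "HRpos_HER2neg", 0.06, "PTEN", "EA", "HRpos_HER2neg", 0.12,
    "GATA3", "AA", "HRpos_HER2neg", 0.22, "GATA3", "EA", "HRpos_HER2neg", 0.14,
    "KMT2C", "AA", "HRpos_HER2neg", 0.24, "KMT2C", "EA", "HRpos_HER2neg", 0.15,
    "KMT2C", "AA", "TNBC", 0.23, "KMT2C", "EA", "TNBC", 0.12,
    "FGFR1", "AA", "HRpos_HER2neg", 0.18, "FGFR1", "EA", "HRpos_HER2neg", 0.12,
    "BRCA1", "AA", "TNBC", 0.08, "BRCA1", "EA", "TNBC", 0.12,
    "APOB", "AA", "TNBC", 0.13, "APOB", "EA", "TNBC", 0.08
  )
}

pop_names <- function(K) {
  if (K == 5) c("AFR", "AMR", "EAS", "EUR", "SAS") else paste0("pop", seq_len(K))
}

#' Simulate a Balding-Nichols reference allele-frequency panel
#'
#' Draws an ancestral alternate-allele frequency per marker from
#' Uniform(0.05, 0.95), then per-population frequencies from the
#' Balding-Nichols beta model
#' `Beta(f(1-F_k)/F_k, (1-f)(1-F_k)/F_k)`, whose mean is the ancestral
#' frequency and whose spread grows with the differentiation parameter
#' `F_k` (an FST analogue). Frequencies are clamped to
#' \[1e-6, 1 - 1e-6\] so downstream likelihoods never take log(0).
#' Marker coordinates and alleles are synthetic placeholders.
#'
#' @param M Number of markers.
#' @param K Number of populations.
#' @param F Length-`K` differentiation parameters, each in (0, 1).
#' @param seed Integer seed; deterministic given (M, K, F, seed).
#' @return An AIM panel tibble: `chrom`, `pos`, `ref`, `alt`, and one
#'   frequency column per population (`f_AFR`, ..., for K = 5).
#' @export
simulate_reference_panel <- function(M, K = 5L, F = rep(0.15, K), seed = 1L) {
  stopifnot(M >= 1, K >= 1, length(F) == K)
  if (any(!is.finite(F)) || any(F <= 0) || any(F >= 1)) {
    rlang::abort("F must be strictly inside (0, 1)")
  }
  withr::with_seed(seed, {
    f_anc <- stats::runif(M, 0.05, 0.95)
    freqs <- vapply(seq_len(K), function(k) {
      lambda <- (1 - F[k]) / F[k]
      stats::rbeta(M, f_anc * lambda, (1 - f_anc) * lambda)
    }, numeric(M))
    freqs <- pmin(pmax(freqs, 1e-6), 1 - 1e-6)
    if (M == 1) freqs <- matrix(freqs, nrow = 1)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, M, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    panel <- tibble::tibble(
      chrom = as.character(sample(1:22, M, replace = TRUE)),
      pos = sort(sample.int(2.5e8, M)),
      ref = ref, alt = unname(alt)
    )
    colnames(freqs) <- paste0("f_", pop_names(K))
    dplyr::bind_cols(panel, tibble::as_tibble(freqs))
  })
}

panel_freq_matrix <- function(panel) {
  fc <- grep("^f_", names(panel), value = TRUE)
  if (length(fc) == 0) rlang::abort("panel has no frequency columns (f_*)")
  fm <- as.matrix(panel[fc])
  colnames(fm) <- sub("^f_", "", fc)
  fm
}

marker_ids <- function(panel) {
  paste(panel$chrom, panel$pos, panel$ref, panel$alt, sep = ":")
}

#' Simulate per-sample admixture proportions
#'
#' Dirichlet draws on the K-simplex, the standard model for admixed
#' individual ancestry fractions.
#'
#' @param n Number of samples.
#' @param alpha Dirichlet concentration vector (length K); the default
#'   `rep(1, 5)` is uniform on the five-population simplex.
#' @param seed Integer seed.
#' @return Matrix n x K with rows summing to 1.
#' @export
simulate_admixture_proportions <- function(n, alpha = rep(1, 5), seed = 1L) {
  stopifnot(n >= 1, all(alpha > 0))
  withr::with_seed(seed, {
    x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
      nrow = n, byrow = TRUE
    )
    x / rowSums(x)
  })
}

#' Simulate admixed genotype dosages
#'
#' Given a reference panel and per-sample admixture proportions, draws
#' alternate-allele dosages `g ~ Binomial(2, sum_k q_k f_k)` per marker —
#' the generative counterpart of the supervised admixture likelihood used
#' by [estimate_admixture()].
#'
#' @param panel Panel tibble from [simulate_reference_panel()] or
#'   [read_aim_panel()].
#' @param q_matrix Numeric matrix, samples x populations; each row must sum
#'   to 1 within 1e-6.
#' @param seed Integer seed.
#' @return Integer matrix samples x markers with values in \{0, 1, 2\};
#'   rownames are sample ids, colnames are `chrom:pos:ref:alt` marker ids.
#' @export
simulate_genotypes <- function(panel, q_matrix, seed = 1L) {
  fm <- panel_freq_matrix(panel)
  q_matrix <- as.matrix(q_matrix)
  if (ncol(q_matrix) != ncol(fm)) {
    rlang::abort("q_matrix columns must match the panel's populations")
  }
  if (any(abs(rowSums(q_matrix) - 1) > 1e-6) || any(q_matrix < 0)) {
    rlang::abort("each row of q_matrix must be a probability vector summing to 1")
  }
  withr::with_seed(seed, {
    a <- q_matrix %*% t(fm) # samples x markers expected alt frequency
    g <- matrix(
      stats::rbinom(length(a), size = 2L, prob = as.vector(a)),
      nrow = nrow(a)
    )
    dimnames(g) <- list(
      rownames(q_matrix) %||% sprintf("S%04d", seq_len(nrow(a))),
      marker_ids(panel)
    )
    g
  })
}

#' Simulate a clinical table
#'
#' Independent categorical draws per patient for stage, subtype, and grade,
#' and normal age draws, using per-group probabilities (defaults match a
#' published cohort's composition; see [default_clinical_probs()]).
#'
#' @param n_AA,n_EA Patients per group; both must be positive.
#' @param probs Probability list as from [default_clinical_probs()].
#' @param seed Integer seed.
#' @return A tibble with columns `patient_id`, `age`, `stage`, `subtype`,
#'   `grade`, `group`.
#' @export
simulate_clinical <- function(n_AA, n_EA, probs = default_clinical_probs(),
                              seed = 1L) {
  if (n_AA <= 0 || n_EA <= 0) rlang::abort("group sizes must be positive")
  withr::with_seed(seed, {
    draw_group <- function(n, grp) {
      pr <- probs[[grp]]
      tibble::tibble(
        age = stats::rnorm(n, pr$age_mean, pr$age_sd),
        stage = sample(names(pr$stage), n, replace = TRUE, prob = pr$stage),
        subtype = sample(names(pr$subtype), n, replace = TRUE, prob = pr$subtype),
        grade = sample(names(pr$grade), n, replace = TRUE, prob = pr$grade),
        group = grp
      )
    }
    out <- dplyr::bind_rows(draw_group(n_AA, "AA"), draw_group(n_EA, "EA"))
    out$patient_id <- sprintf("P%05d", seq_len(nrow(out)))
    dplyr::select(out, "patient_id", "age", "stage", "subtype", "grade", "group")
  })
}

#' Simulate a pathogenic-alteration carrier matrix
#'
#' For each patient and gene, carrier status is Bernoulli with probability
#' looked up by (gene, group, subtype) in the prevalence table; a `"*"`
#' subtype row acts as fallback, and genes with no applicable entry are
#' non-carriers. Genes are simulated independently.
#'
#' @param clinical Clinical tibble (see [simulate_clinical()]).
#' @param prevalences Long prevalence table (see [default_prevalences()]).
#' @param seed Integer seed.
#' @return Logical matrix patients x genes; rownames are patient ids.
#' @export
simulate_mutations <- function(clinical, prevalences = default_prevalences(),
                               seed = 1L) {
  valid_groups <- c("AA", "EA")
  valid_subtypes <- c(names(default_clinical_probs()$AA$subtype), "*")
  if (!all(prevalences$group %in% valid_groups)) {
    rlang::abort("unknown group key in prevalence table")
  }
  if (!all(prevalences$subtype %in% valid_subtypes)) {
    rlang::abort("unknown subtype key in prevalence table")
  }
  genes <- sort(unique(prevalences$gene))
  n <- nrow(clinical)
  withr::with_seed(seed, {
    mat <- matrix(FALSE, n, length(genes), dimnames = list(clinical$patient_id, genes))
    for (g in genes) {
      sub <- prevalences[prevalences$gene == g, ]
      key <- paste(sub$group, sub$subtype)
      exact <- match(paste(clinical$group, clinical$subtype), key)
      fallback <- match(paste(clinical$group, "*"), key)
      idx <- ifelse(is.na(exact), fallback, exact)
      pr <- ifelse(is.na(idx), 0, sub$prev[idx])
      mat[, g] <- stats::runif(n) < pr
    }
    mat
  })
}

#' Simulate an RNA-seq count matrix with batch and ancestry effects
#'
#' Assigns each patient to assay batch v1 or v2 by a fair coin (matching the
#' near-50/50 split of a two-version assay cohort), then draws counts from a
#' negative binomial with log2 mean
#' `baseline_g + b_g 1[batch = v2] + beta_g 1[group = AA] + log2(libsize/1e6)`
#' and variance `mu + phi mu^2` with lognormal per-gene dispersion `phi`.
#' A `de_fraction` subset of genes gets `beta_g = +/- effect_size`
#' (random sign); all others have no ancestry effect. The planted-effect
#' registry is returned so recovery can be scored against ground truth.
#'
#' @param clinical Clinical tibble; only `patient_id` and `group` are used.
#' @param cfg A [sim_config()] object (fields `G`, `de_fraction`,
#'   `effect_size`, `batch_effect_sd`, dispersion and library-size settings,
#'   and `seed`).
#' @return A list of class `sim_counts`: `counts` (integer matrix genes x
#'   samples), `samples` (tibble: `sample`, `group`, `batch`, `libsize`),
#'   and `truth` (tibble: `gene`, `beta`, `is_de`).
#' @export
simulate_counts <- function(clinical, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(clinical)
  G <- cfg$G
  withr::with_seed(cfg$seed, {
    genes <- sprintf("GENE%05d", seq_len(G))
    batch <- ifelse(stats::runif(n) < 0.5, "v1", "v2")
    libsize <- stats::runif(n, cfg$libsize_range[1], cfg$libsize_range[2])
    baseline <- stats::runif(G, 1, 9)
    b <- stats::rnorm(G, 0, cfg$batch_effect_sd)
    phi <- stats::rlnorm(G, cfg$dispersion_meanlog, cfg$dispersion_sdlog)
    n_de <- floor(cfg$de_fraction * G)
    beta <- numeric(G)
    if (n_de > 0) {
      de_idx <- sample.int(G, n_de)
      beta[de_idx] <- cfg$effect_size * sample(c(-1, 1), n_de, replace = TRUE)
    }
    mu_log2 <- outer(baseline, rep(1, n)) +
      outer(b, as.numeric(batch == "v2")) +
      outer(beta, as.numeric(clinical$group == "AA")) +
      outer(rep(1, G), log2(libsize / 1e6))
    counts <- matrix(
      stats::rnbinom(G * n, mu = 2^mu_log2, size = rep(1 / phi, n)),
      nrow = G,
      dimnames = list(genes, clinical$patient_id)
    )
    structure(
      list(
        counts = counts,
        samples = tibble::tibble(
          sample = clinical$patient_id, group = clinical$group,
          batch = batch, libsize = libsize
        ),
        truth = tibble::tibble(gene = genes, beta = beta, is_de = beta != 0)
      ),
      class = "sim_counts"
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
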