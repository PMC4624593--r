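# Shared fixture builders: everything is generated in code at test time.

# A small platform matrix with explicit values.
pm <- function(tag, values, entity = NULL) {
  platform_matrix(tag, values, entity)
}

mat_named <- function(x, features, samples) {
  matrix(x, nrow = length(features),
         dimnames = list(features, samples), byrow = TRUE)
}

# A clinical table from a named list of parameter vectors (one value per
# sample, NA allowed).
ct <- function(samples, params, metadata, source = "src") {
  df <- as.data.frame(params, stringsAsFactors = FALSE, optional = TRUE)
  rownames(df) <- samples
  clinical_table(df, source = source, metadata = metadata)
}

stage_meta <- function() {
  list(ClinicalStage = param_meta("ordinal", c("I", "II", "III", "IV")))
}

# Standard small cohort config used across tests.
small_config <- function(seed = 1, n_samples = 60, n_planted = 2,
                         missing_rate = 0, platform_dropout = 0,
                         n_conflicts = 0) {
  cohort_config(
    n_samples = n_samples,
    platforms = list(platform_spec("CNV", 15), platform_spec("MUT", 15),
                     platform_spec("RNASEQ", 15), platform_spec("METH", 10)),
    n_planted = n_planted,
    effect_sizes = rep(c(1.5, -1.5), length.out = n_planted),
    noise_sd = 1,
    clinical_params = list(
      clinical_param_spec("ClinicalStage", "ordinal", c("I", "II", "III", "IV")),
      clinical_param_spec("Gender", "binary", c("female", "male"))),
    missing_rate = missing_rate, platform_dropout = platform_dropout,
    n_conflicts = n_conflicts, seed = seed)
}

# The study-scale cohort used for recovery checks: 400 samples, 300
# features over three platforms, 10 planted unit effects.
recovery_config <- function(seed = 1, n_planted = 10) {
  cohort_config(
    n_samples = 400,
    platforms = list(platform_spec("CNV", 100), platform_spec("RNASEQ", 100),
                     platform_spec("METH", 100)),
    n_planted = n_planted,
    effect_sizes = rep(c(1, -1), length.out = n_planted),
    noise_sd = 1, seed = seed)
}

# Generate, encode the stage outcome, normalize and integrate (gene
# group over the full gene pool).
integrated_from <- function(coh) {
  y <- encode_outcome(consolidate_clinical(coh$clinical), "ClinicalStage")
  norm <- lapply(coh$platforms, normalize_features)
  tg <- target_list(sprintf("GENE%04d", 1:100))
  X <- integrate_platforms(intersect_samples(norm), "gene", tg)
  list(X = X, y = y)
}
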