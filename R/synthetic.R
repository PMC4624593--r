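#' Configure a synthetic multi-platform cohort
#'
#' The generator emulates the statistical structure the association
#' pipeline assumes: a latent outcome that is linear in a small set of
#' planted molecular features, observed through multiple platforms with
#' heterogeneous feature scales, and clinical annotations derived from
#' that outcome. It exists so that every downstream stage (encoding,
#' integration, elastic-net selection, post-hoc testing) can be exercised
#' and validated without any external download.
#'
#' @param n_samples number of tumor samples.
#' @param platforms list of [platform_spec()] entries.
#' @param n_planted number of features carrying a true effect on the
#'   latent outcome.
#' @param effect_sizes numeric vector of length `n_planted`: the true
#'   linear coefficients.
#' @param noise_sd standard deviation of the Gaussian noise added to the
#'   latent outcome.
#' @param clinical_params list of [clinical_param_spec()] entries.
#' @param missing_rate per-cell missingness probability applied by
#'   [degrade_cohort()], in `[0,1)`.
#' @param platform_dropout fraction of samples removed from each platform
#'   by [degrade_cohort()], in `[0,1)`.
#' @param n_conflicts number of contradictory duplicate clinical records
#'   injected into a second source by [degrade_cohort()].
#' @param seed integer RNG seed; the same config and seed regenerate the
#'   cohort bit-for-bit.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples,
                          platforms,
                          n_planted = 0L,
                          effect_sizes = numeric(0),
                          noise_sd = 1,
                          clinical_params = list(
                            clinical_param_spec("ClinicalStage", "ordinal",
                                                c("I", "II", "III", "IV"))),
                          missing_rate = 0,
                          platform_dropout = 0,
                          n_conflicts = 0L,
                          seed = 1L) {
  if (n_samples < 1) stop("n_samples must be positive")
  if (!length(platforms)) stop("at least one platform spec required")
  total_features <- sum(vapply(platforms, function(p) p$n_features, 0))
  if (n_planted > total_features)
    stop("n_planted exceeds the total feature count")
  if (length(effect_sizes) != n_planted)
    stop("effect_sizes must have length n_planted")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (missing_rate < 0 || missing_rate >= 1 ||
      platform_dropout < 0 || platform_dropout >= 1)
    stop("missing_rate and platform_dropout must be in [0,1)")
  for (cp in clinical_params) {
    if (cp$kind %in% c("ordinal", "binary") && length(cp$levels) < 2)
      stop("ordinal/binary parameters need at least 2 ordered levels")
  }
  structure(list(n_samples = as.integer(n_samples), platforms = platforms,
                 n_planted = as.integer(n_planted),
                 effect_sizes = as.numeric(effect_sizes),
                 noise_sd = noise_sd, clinical_params = clinical_params,
                 missing_rate = missing_rate,
                 platform_dropout = platform_dropout,
                 n_conflicts = as.integer(n_conflicts),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @param tag platform tag (see [platform_matrix()]).
#' @param n_features number of features on this platform.
#' @export
platform_spec <- function(tag, n_features) {
  tag <- match.arg(tag, PLATFORM_TAGS)
  if (n_features < 1) stop("n_features must be positive")
  list(tag = tag, n_features = as.integer(n_features))
}

#' @rdname cohort_config
#' @param name clinical parameter name.
#' @param kind one of `"ordinal"`, `"binary"`, `"categorical"`.
#' @param levels ordered level labels (order is meaningful for ordinal and
#'   binary parameters).
#' @export
clinical_param_spec <- function(name, kind = c("ordinal", "binary", "categorical"),
                                levels) {
  kind <- match.arg(kind)
  if (anyDuplicated(levels)) stop("levels must be duplicate-free")
  list(name = name, kind = kind, levels = as.character(levels))
}

#' Read a cohort configuration from YAML or JSON
#'
#' The file mirrors the arguments of [cohort_config()]; `platforms` is a
#' list of `{tag, n_features}` entries and `clinical_params` a list of
#' `{name, kind, levels}` entries.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [cohort_config()].
#' @export
cohort_config_from_file <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the `yaml` package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  plats <- lapply(raw$platforms, function(p) platform_spec(p$tag, p$n_features))
  cps <- lapply(raw$clinical_params %||% list(), function(cp)
    clinical_param_spec(cp$name, cp$kind, unlist(cp$levels)))
  if (!length(cps)) cps <- NULL
  args <- raw[setdiff(names(raw), c("platforms", "clinical_params"))]
  args$platforms <- plats
  if (!is.null(cps)) args$clinical_params <- cps
  args$effect_sizes <- unlist(args$effect_sizes) %||% numeric(0)
  do.call(cohort_config, args)
}

feature_ids_for <- function(tag, n) {
  switch(tag,
         CNV = ,
         MUT = ,
         RNASEQ = sprintf("GENE%04d", seq_len(n)),
         METH = sprintf("cg%06d", seq_len(n)),
         MIRSEQ = sprintf("MIR%04d", seq_len(n)),
         RPPA = sprintf("PROT%04d", seq_len(n)))
}

# Balanced rank cut: order samples by y and split into L contiguous
# blocks whose sizes differ by at most one sample.
rank_cut <- function(y, levels) {
  n <- length(y)
  L <- length(levels)
  sizes <- rep(n %/% L, L)
  extra <- n %% L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lab <- rep(levels, times = sizes)
  out <- character(n)
  out[order(y)] <- lab
  out
}

#' Generate a seeded synthetic cohort
#'
#' Continuous platforms (RNASEQ, METH, MIRSEQ, RPPA) are Gaussian with
#' per-feature scales drawn log-uniformly from `[0.5, 20]` so that the
#' downstream scale normalization has observable effect; CNV features are
#' discrete calls in \{-2,...,2\}; mutation features are Bernoulli
#' indicators. A latent outcome
#' `y = sum(beta_k * f_k / sd(f_k)) + N(0, noise_sd^2)`
#' is built over the planted features — effects act on unit-variance
#' features so one unit of `beta` carries the same signal on every
#' platform, matching the scale-normalized feature space the regression
#' operates in; every ordinal or binary clinical
#' parameter is derived from `y` by a balanced quantile cut into its
#' levels (binary = median split), while categorical parameters are
#' assigned uniformly at random.
#'
#' Gene-level platforms (CNV, MUT, RNASEQ) share the `GENE....` entity
#' space so one gene can be measured on several platforms; methylation
#' probes carry a probe-to-gene annotation into that same space.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort`: list with `platforms` (named list of
#'   [platform_matrix()]), `clinical` (list of [clinical_table()] sources),
#'   `truth` (data frame `feature`, `platform`, `entity`, `beta`),
#'   `latent_y`, `seed`, and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    samples <- sprintf("SAMPLE%04d", seq_len(n))
    gene_platforms <- c("CNV", "MUT", "RNASEQ")
    n_genes <- max(c(1L, vapply(config$platforms, function(p)
      if (p$tag %in% c(gene_platforms, "METH")) p$n_features else 0L, 0L)))
    gene_pool <- sprintf("GENE%04d", seq_len(n_genes))

    platforms <- list()
    for (p in config$platforms) {
      nf <- p$n_features
      feats <- feature_ids_for(p$tag, nf)
      entity <- feats
      if (p$tag == "METH") {
        # probes annotate to genes cyclically; several probes may share a gene
        entity <- gene_pool[((seq_len(nf) - 1L) %% n_genes) + 1L]
      }
      vals <- switch(p$tag,
        CNV = matrix(sample(-2:2, nf * n, replace = TRUE,
                            prob = c(0.05, 0.15, 0.60, 0.15, 0.05)),
                     nrow = nf),
        MUT = {
          rate <- stats::runif(nf, 0.02, 0.30)
          matrix(stats::rbinom(nf * n, 1L, rep(rate, times = n)), nrow = nf)
        },
        {
          sc <- exp(stats::runif(nf, log(0.5), log(20)))
          matrix(stats::rnorm(nf * n, sd = rep(sc, times = n)), nrow = nf)
        })
      storage.mode(vals) <- "double"
      rownames(vals) <- feats
      colnames(vals) <- samples
      platforms[[p$tag]] <- platform_matrix(p$tag, vals, entity)
    }

    all_feats <- do.call(rbind, lapply(platforms, function(m)
      data.frame(feature = features_of(m), platform = m$tag,
                 entity = unname(m$entity), stringsAsFactors = FALSE)))
    rownames(all_feats) <- NULL

    if (config$n_planted > 0) {
      idx <- sample.int(nrow(all_feats), config$n_planted)
      truth <- all_feats[idx, , drop = FALSE]
      truth$beta <- config$effect_sizes
      rownames(truth) <- NULL
    } else {
      truth <- data.frame(feature = character(0), platform = character(0),
                          entity = character(0), beta = numeric(0),
                          stringsAsFactors = FALSE)
    }

    y <- stats::rnorm(n, sd = config$noise_sd)
    if (nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        f <- platforms[[truth$platform[i]]]$values[truth$feature[i], ]
        s <- stats::sd(f)
        if (s == 0) s <- 1  # degenerate constant feature carries no signal
        y <- y + truth$beta[i] * f / s
      }
    }
    names(y) <- samples

    vals <- data.frame(row.names = samples)
    meta <- list()
    for (cp in config$clinical_params) {
      vals[[cp$name]] <- if (cp$kind == "categorical") {
        sample(cp$levels, n, replace = TRUE)
      } else {
        rank_cut(y, cp$levels)
      }
      meta[[cp$name]] <- param_meta(cp$kind, cp$levels)
    }
    clin <- clinical_table(vals, source = "source_a", metadata = meta)

    structure(list(platforms = platforms, clinical = list(clin),
                   truth = truth, latent_y = y, seed = config$seed,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' Inject real-data pathologies into a synthetic cohort
#'
#' Applies, in a seeded and logged way, the degradations the pipeline's
#' consolidation and imputation stages must handle: uniform per-cell
#' missingness at `missing_rate` on each platform, removal of a
#' `platform_dropout` fraction of samples from each platform, and
#' `n_conflicts` clinical records duplicated into a second source with a
#' contradictory value. The planted-effect truth record is never altered.
#' With all rates zero the cohort is returned unchanged.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config the [cohort_config()] carrying the degradation rates.
#' @return the degraded `synthetic_cohort`, with a `degrade_log` attribute.
#' @export
degrade_cohort <- function(cohort, config) {
  stopifnot(inherits(cohort, "synthetic_cohort"), inherits(config, "cohort_config"))
  if (config$missing_rate < 0 || config$missing_rate >= 1 ||
      config$platform_dropout < 0 || config$platform_dropout >= 1)
    stop("rates must be in [0,1)")
  if (config$missing_rate == 0 && config$platform_dropout == 0 &&
      config$n_conflicts == 0)
    return(cohort)

  with_seed(child_seed(config$seed, 1L), {
    log <- list(masked = integer(0), dropped = list(), conflicts = NULL)
    for (tag in names(cohort$platforms)) {
      m <- cohort$platforms[[tag]]
      if (config$missing_rate > 0) {
        mask <- matrix(stats::runif(length(m$values)) < config$missing_rate,
                       nrow = nrow(m$values))
        m$values[mask] <- NA_real_
        log$masked[tag] <- sum(mask)
      }
      if (config$platform_dropout > 0) {
        ndrop <- floor(config$platform_dropout * ncol(m$values))
        if (ndrop > 0) {
          drop <- sample(colnames(m$values), ndrop)
          m$values <- m$values[, setdiff(colnames(m$values), drop), drop = FALSE]
          m$entity <- m$entity  # feature map unchanged
          log$dropped[[tag]] <- drop
        }
      }
      cohort$platforms[[tag]] <- platform_matrix(m$tag, m$values, unname(m$entity))
    }

    if (config$n_conflicts > 0) {
      src <- cohort$clinical[[1]]
      cells <- which(!is.na(as.matrix(src$values)), arr.ind = TRUE)
      # a conflict needs an alternative level to contradict with
      ok <- vapply(seq_len(nrow(cells)), function(i) {
        p <- colnames(src$values)[cells[i, 2]]
        length(src$metadata[[p]]$levels) >= 2
      }, TRUE)
      cells <- cells[ok, , drop = FALSE]
      if (nrow(cells) < config$n_conflicts)
        stop("not enough clinical records available to inject conflicts")
      pick <- cells[sample.int(nrow(cells), config$n_conflicts), , drop = FALSE]
      vals_b <- as.data.frame(matrix(NA_character_, nrow(src$values),
                                     ncol(src$values)),
                              stringsAsFactors = FALSE)
      rownames(vals_b) <- rownames(src$values)
      colnames(vals_b) <- colnames(src$values)
      conf <- data.frame(sample = character(0), parameter = character(0),
                         value_a = character(0), value_b = character(0),
                         stringsAsFactors = FALSE)
      for (i in seq_len(nrow(pick))) {
        s <- rownames(src$values)[pick[i, 1]]
        p <- colnames(src$values)[pick[i, 2]]
        cur <- src$values[s, p]
        alt <- sample(setdiff(src$metadata[[p]]$levels, cur), 1L)
        vals_b[s, p] <- alt
        conf[nrow(conf) + 1L, ] <- list(s, p, cur, alt)
      }
      cohort$clinical[[2]] <- clinical_table(vals_b, source = "source_b",
                                             metadata = src$metadata)
      log$conflicts <- conf
    }
    attr(cohort, "degrade_log") <- log
    cohort
  })
}
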