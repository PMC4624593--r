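# Firehose-style on-disk representation of a cohort: one tab-separated
# matrix per platform (features as rows, header row of sample ids, first
# column the feature id, missing cells encoded "NA"), one clinical table
# per source, parameter metadata, the planted-effect truth table, and a
# JSON manifest. Numeric cells are written with 17 significant digits so
# a write/read round trip reproduces every double bit-for-bit.

#' Write a cohort as Firehose-style files
#'
#' @param cohort a [generate_cohort()] (optionally [degrade_cohort()])
#'   result.
#' @param dir output directory (created if needed).
#' @return the manifest (named list of the files written), invisibly the
#'   same list; also serialized as `manifest.json` in `dir`.
#' @export
write_firehose <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(platform_files = list(), annotation_files = list(),
                   clinical_files = list(), metadata_file = NULL,
                   truth_file = NULL, latent_file = NULL,
                   seed = cohort$seed)

  for (tag in names(cohort$platforms)) {
    m <- cohort$platforms[[tag]]
    fn <- paste0(tag, ".tsv")
    df <- cbind(feature_id = features_of(m),
                as.data.frame(matrix(num_chr(m$values), nrow(m$values),
                                     dimnames = dimnames(m$values)),
                              stringsAsFactors = FALSE))
    write.table(df, file.path(dir, fn), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$platform_files[[tag]] <- fn
    if (!identical(unname(m$entity), features_of(m))) {
      an <- paste0(tag, "_annotation.tsv")
      write.table(data.frame(feature = features_of(m),
                             entity = unname(m$entity)),
                  file.path(dir, an), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      manifest$annotation_files[[tag]] <- an
    }
  }

  for (ct in cohort$clinical) {
    fn <- paste0("clinical_", ct$source, ".tsv")
    df <- cbind(sample_id = rownames(ct$values), ct$values)
    write.table(df, file.path(dir, fn), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
    manifest$clinical_files[[ct$source]] <- fn
  }
  meta <- lapply(cohort$clinical[[1]]$metadata, function(m)
    list(kind = m$kind, levels = m$levels))
  jsonlite::write_json(meta, file.path(dir, "clinical_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$metadata_file <- "clinical_metadata.json"

  if (length(cohort$platforms)) {
    tr <- cohort$truth
    tr$beta <- num_chr(tr$beta)
    write.table(tr, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$truth_file <- "truth.tsv"
    if (!is.null(cohort$latent_y)) {
      write.table(data.frame(sample_id = names(cohort$latent_y),
                             y = num_chr(cohort$latent_y)),
                  file.path(dir, "latent_outcome.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest$latent_file <- "latent_outcome.tsv"
    }
  }

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Read a cohort back from Firehose-style files
#'
#' Inverse of [write_firehose()]; reconstructs every platform matrix
#' (values and missing mask), clinical source, metadata, truth table and
#' latent outcome exactly.
#'
#' @param dir directory containing a `manifest.json`.
#' @return a `synthetic_cohort` (its `config` is `NULL`).
#' @export
read_firehose <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  platforms <- list()
  for (tag in names(manifest$platform_files)) {
    df <- utils::read.delim(file.path(dir, manifest$platform_files[[tag]]),
                            check.names = FALSE, stringsAsFactors = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- df$feature_id
    entity <- NULL
    an <- manifest$annotation_files[[tag]]
    if (!is.null(an)) {
      ann <- utils::read.delim(file.path(dir, an), stringsAsFactors = FALSE)
      entity <- ann$entity[match(df$feature_id, ann$feature)]
    }
    platforms[[tag]] <- platform_matrix(tag, vals, entity)
  }

  meta_raw <- jsonlite::read_json(file.path(dir, manifest$metadata_file),
                                  simplifyVector = TRUE)
  metadata <- lapply(meta_raw, function(m) param_meta(m$kind, m$levels))

  clinical <- list()
  for (src in names(manifest$clinical_files)) {
    df <- utils::read.delim(file.path(dir, manifest$clinical_files[[src]]),
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character", na.strings = "NA")
    rownames(df) <- df$sample_id
    df$sample_id <- NULL
    clinical[[length(clinical) + 1L]] <-
      clinical_table(df, source = src, metadata = metadata)
  }

  truth <- data.frame(feature = character(0), platform = character(0),
                      entity = character(0), beta = numeric(0),
                      stringsAsFactors = FALSE)
  if (!is.null(manifest$truth_file)) {
    truth <- utils::read.delim(file.path(dir, manifest$truth_file),
                               stringsAsFactors = FALSE,
                               colClasses = c("character", "character",
                                              "character", "numeric"))
  }
  latent <- NULL
  if (!is.null(manifest$latent_file)) {
    ldf <- utils::read.delim(file.path(dir, manifest$latent_file),
                             stringsAsFactors = FALSE)
    latent <- ldf$y
    names(latent) <- ldf$sample_id
  }

  structure(list(platforms = platforms, clinical = clinical, truth = truth,
                 latent_y = latent, seed = manifest$seed, config = NULL),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d platform(s), %d clinical source(s), %d planted effect(s)>\n",
              length(x$platforms), length(x$clinical), nrow(x$truth)))
  invisible(x)
}
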