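#' Platform matrices and target lists
#'
#' A `platform_matrix` holds one molecular platform's feature-by-sample
#' numeric table. Missing measurements are stored as `NA`; discrete
#' platforms are validated against their call alphabets (mutation
#' indicators in \{0,1\}, GISTIC-style copy-number calls in \{-2,...,2\}).
#'
#' @param tag platform tag, one of `"CNV"`, `"MUT"`, `"RNASEQ"`, `"METH"`,
#'   `"MIRSEQ"`, `"RPPA"`.
#' @param values numeric matrix, features as rows (unique rownames = feature
#'   ids), samples as columns (unique colnames = sample ids). `NA` marks a
#'   missing measurement.
#' @param entity optional character vector mapping each feature to the
#'   entity (gene/miR/protein) it measures; defaults to the feature ids.
#'   Methylation probes typically map several probes to one gene.
#' @param validate check discrete call alphabets; disabled internally for
#'   scale-normalized matrices, whose rescaled calls leave the alphabet.
#' @return an object of class `platform_matrix`.
#' @export
platform_matrix <- function(tag, values, entity = NULL, validate = TRUE) {
  tag <- match.arg(tag, PLATFORM_TAGS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)")
  # zero-extent matrices (e.g. no mutation records) may drop dimnames
  if (nrow(values) > 0 &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values))))
    stop("feature ids (rownames) must be present and unique")
  if (ncol(values) > 0 &&
      (is.null(colnames(values)) || anyDuplicated(colnames(values))))
    stop("sample ids (colnames) must be present and unique")
  if (validate) {
    v <- values[!is.na(values)]
    if (tag == "MUT" && !all(v %in% c(0, 1)))
      stop("MUT values must be in {0,1}")
    if (tag == "CNV" && !all(v %in% -2:2))
      stop("CNV values must be in {-2,-1,0,1,2}")
  }
  if (is.null(entity)) entity <- rownames(values)
  if (length(entity) != nrow(values))
    stop("`entity` must have one element per feature")
  entity <- as.character(entity)
  names(entity) <- rownames(values)
  structure(list(tag = tag, values = values, entity = entity),
            class = "platform_matrix")
}

PLATFORM_TAGS <- c("CNV", "MUT", "RNASEQ", "METH", "MIRSEQ", "RPPA")

# Platforms whose values are treated as continuous measurements.
CONTINUOUS_TAGS <- c("RNASEQ", "METH", "MIRSEQ", "RPPA")

#' @export
print.platform_matrix <- function(x, ...) {
  cat(sprintf("<platform_matrix %s: %d features x %d samples, %.1f%% missing>\n",
              x$tag, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @rdname platform_matrix
#' @param x object to test.
#' @export
is_platform_matrix <- function(x) inherits(x, "platform_matrix")

#' Accessors for platform matrices
#'
#' @param m a [platform_matrix()].
#' @return character vector of sample ids / feature ids.
#' @export
samples_of <- function(m) colnames(m$values)

#' @rdname samples_of
#' @export
features_of <- function(m) rownames(m$values)

#' Vetted target list for the gene-oriented analysis
#'
#' The gene-oriented analysis is restricted to a vetted list of known and
#' putative cancer genes (e.g. literature-curated genes, drug targets, and
#' genes with recurrent mutations or focal copy-number peaks). Duplicate
#' ids arising from overlapping provenances are collapsed; the first
#' provenance seen for an id is retained.
#'
#' @param ids character vector of gene ids (may contain duplicates across
#'   provenances).
#' @param provenance character vector parallel to `ids`, e.g. `"COSMIC"`,
#'   `"TARGET"`, `"MutSig"`, `"CN-AmpPeak"`, `"CN-DelPeak"`.
#' @return a `target_list`: data frame with columns `id`, `provenance`,
#'   one row per unique id.
#' @export
target_list <- function(ids, provenance = rep("unspecified", length(ids))) {
  stopifnot(length(ids) == length(provenance))
  keep <- !duplicated(ids)
  structure(data.frame(id = as.character(ids[keep]),
                       provenance = as.character(provenance[keep]),
                       stringsAsFactors = FALSE),
            class = c("target_list", "data.frame"))
}

#' Read a target list from a TSV file
#'
#' Expects columns `id` and `provenance` (tab-separated, header row).
#'
#' @param path file path.
#' @return a [target_list()].
#' @export
read_target_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "provenance") %in% names(df)))
    stop("target list file needs columns `id` and `provenance`")
  target_list(df$id, df$provenance)
}
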