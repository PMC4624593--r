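#' Update feature symbols against a nomenclature snapshot
#'
#' Genomic symbols drift between annotation releases; before integration
#' every feature id is updated against a static symbol-map snapshot
#' (columns `old`, `new`, `status`). Ids covered by the map are renamed;
#' ids flagged obsolete without a replacement (`status == "obsolete"` or
#' empty `new`) are dropped and returned. When two old ids map to the same
#' current id, the feature with fewer missing values is kept; exact ties
#' keep the lexicographically smallest original id (logged).
#'
#' @param matrix a [platform_matrix()].
#' @param mapping data frame with columns `old`, `new`, and optionally
#'   `status` (`"current"`/`"updated"`/`"obsolete"`).
#' @return the updated `platform_matrix`, with attributes `removed`
#'   (dropped obsolete ids) and `collisions` (data frame of collision
#'   resolutions, if any).
#' @export
update_symbols <- function(matrix, mapping) {
  stopifnot(is_platform_matrix(matrix))
  stopifnot(all(c("old", "new") %in% names(mapping)))
  if (is.null(mapping$status)) mapping$status <- rep("updated", nrow(mapping))
  if (anyDuplicated(mapping$old)) stop("mapping must be total: duplicate old ids")

  feats <- features_of(matrix)
  idx <- match(feats, mapping$old)
  new_ids <- feats
  obsolete <- rep(FALSE, length(feats))
  hit <- !is.na(idx)
  if (any(hit)) {
    repl <- mapping$new[idx[hit]]
    obs <- mapping$status[idx[hit]] == "obsolete" | is.na(repl) | repl == ""
    obsolete[hit] <- obs
    new_ids[hit][!obs] <- repl[!obs]
  }
  removed <- feats[obsolete]
  keep <- !obsolete
  vals <- matrix$values[keep, , drop = FALSE]
  ids <- new_ids[keep]
  ent <- unname(matrix$entity[keep])
  ent[ent == feats[keep]] <- ids[ent == feats[keep]]  # rename entities that equal the feature id

  collisions <- data.frame(id = character(0), kept = character(0),
                           dropped = character(0), rule = character(0),
                           stringsAsFactors = FALSE)
  if (anyDuplicated(ids)) {
    orig <- feats[keep]
    keep2 <- rep(TRUE, length(ids))
    for (dup in unique(ids[duplicated(ids)])) {
      at <- which(ids == dup)
      nmiss <- rowSums(is.na(vals[at, , drop = FALSE]))
      best <- at[nmiss == min(nmiss)]
      rule <- "fewer missing values"
      if (length(best) > 1) {
        best <- best[order(orig[best])][1]
        rule <- "tie: lexicographically smallest original id"
      }
      drop_at <- setdiff(at, best)
      keep2[drop_at] <- FALSE
      collisions[nrow(collisions) + 1L, ] <-
        list(dup, orig[best], paste(orig[drop_at], collapse = ";"), rule)
    }
    vals <- vals[keep2, , drop = FALSE]
    ids <- ids[keep2]
    ent <- ent[keep2]
  }
  rownames(vals) <- ids
  out <- platform_matrix(matrix$tag, vals, ent)
  attr(out, "removed") <- removed
  attr(out, "collisions") <- collisions
  out
}

# Variant classifications that do not alter the protein product (or fall
# outside it); such records do not count as a mutation event.
SILENT_CLASSES <- c("Silent", "Intron", "3'UTR", "5'UTR", "IGR", "RNA")

#' Build a binary mutation matrix from MAF-lite records
#'
#' The association analysis consumes a gene-by-sample indicator matrix:
#' cell `(g, s)` is 1 iff sample `s` carries at least one non-silent
#' variant in gene `g`. Non-silent means the variant classification is
#' outside \{Silent, Intron, 3'UTR, 5'UTR, IGR, RNA\}. Samples in the
#' cohort list but absent from the records get all-zero columns; records
#' referencing samples outside the list are rejected and logged.
#'
#' @param records data frame with columns `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode`, `Variant_Classification`.
#' @param samples character vector of cohort sample ids.
#' @return a MUT [platform_matrix()] with a `rejected` attribute holding
#'   any out-of-cohort records.
#' @export
mutation_matrix_from_maf <- function(records, samples) {
  stopifnot(all(c("Hugo_Symbol", "Tumor_Sample_Barcode",
                  "Variant_Classification") %in% names(records)))
  bad <- !(records$Tumor_Sample_Barcode %in% samples)
  rejected <- records[bad, , drop = FALSE]
  records <- records[!bad, , drop = FALSE]
  nonsilent <- records[!(records$Variant_Classification %in% SILENT_CLASSES), ,
                       drop = FALSE]
  genes <- sort(unique(records$Hugo_Symbol))
  vals <- matrix(0, length(genes), length(samples),
                 dimnames = list(genes, samples))
  if (nrow(nonsilent)) {
    ij <- cbind(match(nonsilent$Hugo_Symbol, genes),
                match(nonsilent$Tumor_Sample_Barcode, samples))
    vals[ij] <- 1
  }
  out <- platform_matrix("MUT", vals)
  attr(out, "rejected") <- rejected
  out
}

#' Harmonize methylation platforms
#'
#' Cohorts profiled on two methylation arrays (e.g. HM27 and HM450) are
#' merged to increase sample coverage: in `"common-probes"` mode the
#' output rows are the probes shared by both platforms and the columns the
#' union of samples, each sample's values taken from whichever platform
#' measured it (the higher-density platform wins when both did). In
#' `"hm450-only"` mode the higher-density platform is passed through
#' unchanged — the rule for cohorts fully covered by both arrays.
#'
#' @param hm27,hm450 METH [platform_matrix()] objects.
#' @param mode `"common-probes"` or `"hm450-only"`.
#' @return a METH `platform_matrix`.
#' @export
harmonize_methylation <- function(hm27, hm450,
                                  mode = c("common-probes", "hm450-only")) {
  mode <- match.arg(mode)
  stopifnot(is_platform_matrix(hm27), is_platform_matrix(hm450))
  if (mode == "hm450-only") return(hm450)
  probes <- intersect(features_of(hm27), features_of(hm450))
  if (!length(probes)) stop("empty probe intersection between platforms")
  s27 <- samples_of(hm27)
  s450 <- samples_of(hm450)
  samples <- union(s450, s27)
  vals <- matrix(NA_real_, length(probes), length(samples),
                 dimnames = list(probes, samples))
  only27 <- setdiff(s27, s450)
  vals[, s450] <- hm450$values[probes, s450]
  if (length(only27)) vals[, only27] <- hm27$values[probes, only27]
  platform_matrix("METH", vals, unname(hm450$entity[probes]))
}

#' Restrict platform matrices to their common samples
#'
#' The integrated analysis uses only samples profiled on every available
#' platform of the analysis group; all matrices are restricted to that
#' common sample set, in a single shared column order.
#'
#' @param matrices list of [platform_matrix()] objects.
#' @return list of `platform_matrix` objects over the common samples.
#' @export
intersect_samples <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  common <- Reduce(intersect, lapply(matrices, samples_of))
  if (!length(common)) stop("no samples are shared by all platforms")
  lapply(matrices, function(m)
    platform_matrix(m$tag, m$values[, common, drop = FALSE], unname(m$entity),
                    validate = FALSE))
}

#' Drop poorly measured features and impute the rest
#'
#' Features missing in `max_missing` (default 3 %) or more of the samples
#' are removed; remaining missing cells are replaced with the feature's
#' median across the non-missing samples, so the output has no missing
#' values.
#'
#' @param matrix a [platform_matrix()].
#' @param max_missing missingness threshold in `[0,1)`; a feature is
#'   dropped when its missing fraction is `>= max_missing`.
#' @return a complete `platform_matrix` with attributes `dropped`
#'   (removed feature ids) and `imputed` (feature ids that received
#'   imputed values).
#' @export
filter_and_impute <- function(matrix, max_missing = 0.03) {
  stopifnot(is_platform_matrix(matrix))
  if (max_missing < 0 || max_missing >= 1) stop("max_missing must be in [0,1)")
  frac <- rowMeans(is.na(matrix$values))
  drop <- frac >= max_missing
  if (all(drop)) stop("all features dropped by the missingness filter")
  vals <- matrix$values[!drop, , drop = FALSE]
  discrete <- matrix$tag %in% c("MUT", "CNV")
  imputed <- character(0)
  for (i in which(rowSums(is.na(vals)) > 0)) {
    med <- stats::median(vals[i, ], na.rm = TRUE)
    # discrete call alphabets admit no half-integer medians: round to the
    # nearest valid call
    if (discrete) med <- round(med)
    vals[i, is.na(vals[i, ])] <- med
    imputed <- c(imputed, rownames(vals)[i])
  }
  out <- platform_matrix(matrix$tag, vals, unname(matrix$entity[!drop]))
  attr(out, "dropped") <- features_of(matrix)[drop]
  attr(out, "imputed") <- imputed
  out
}

#' Scale-normalize features within a platform
#'
#' Each measurement is divided by the feature's standard deviation plus
#' the tenth percentile of all feature standard deviations on the
#' platform:
#' \deqn{\hat g(i,j) = g(i,j) / (sd(g(i)) + sd_{10}(g))}
#' The additive `sd10` term keeps near-constant features from blowing up
#' into outliers under normalization. Standard deviations use the n-1
#' denominator; the percentile uses linear interpolation between order
#' statistics.
#'
#' @param matrix a complete (no missing values) [platform_matrix()] with
#'   at least 2 samples.
#' @return the normalized `platform_matrix` with attributes `feature_sd`
#'   (named per-feature sd) and `sd10` (the percentile value).
#' @export
normalize_features <- function(matrix) {
  stopifnot(is_platform_matrix(matrix))
  if (anyNA(matrix$values)) stop("normalize_features requires complete data")
  if (ncol(matrix$values) < 2) stop("at least 2 samples required")
  sds <- apply(matrix$values, 1, stats::sd)
  if (all(sds == 0)) stop("all feature sds are zero: nothing to normalize")
  sd10 <- pctl(sds, 0.10)
  vals <- matrix$values / (sds + sd10)
  out <- platform_matrix(matrix$tag, vals, unname(matrix$entity),
                         validate = FALSE)
  attr(out, "feature_sd") <- sds
  attr(out, "sd10") <- sd10
  out
}

#' Integrate normalized platform blocks into one analysis matrix
#'
#' Row-concatenates the platform matrices of one analysis group into a
#' single feature space, restricted for the gene group to entities on the
#' vetted target list (miR and protein groups keep all features, as those
#' platforms are already pre-selected). Each platform block is then
#' rescaled by a single scalar chosen so the mean per-feature sd within
#' the block equals 1, putting the platforms on a common scale; the
#' scalars are recorded so original values are exactly recoverable.
#'
#' @param matrices list of complete [platform_matrix()] objects sharing an
#'   identical sample order (see [intersect_samples()]).
#' @param group `"gene"`, `"miR"` or `"protein"`.
#' @param targets a [target_list()]; required for the gene group.
#' @return an `integrated_matrix`: list with `values` (rows = tagged
#'   features, columns = samples), `feature` / `entity` / `platform`
#'   row annotations, and `platform_scale` (named scalars applied per
#'   block). Row names are `"<feature>|<platform>"` tags.
#' @export
integrate_platforms <- function(matrices, group = c("gene", "miR", "protein"),
                                targets = NULL) {
  group <- match.arg(group)
  stopifnot(length(matrices) >= 1)
  smp <- samples_of(matrices[[1]])
  for (m in matrices) {
    stopifnot(is_platform_matrix(m))
    if (!identical(samples_of(m), smp))
      stop("platform matrices must share an identical sample order")
    if (anyNA(m$values)) stop("integrate_platforms requires complete data")
  }
  if (group == "gene" && is.null(targets))
    stop("the gene group requires a target list")

  blocks <- list()
  ann <- list()
  scales <- numeric(0)
  for (m in matrices) {
    keep <- rep(TRUE, nrow(m$values))
    if (group == "gene") keep <- unname(m$entity) %in% targets$id
    if (!any(keep)) next
    v <- m$values[keep, , drop = FALSE]
    sds <- apply(v, 1, stats::sd)
    sc <- if (mean(sds) > 0) 1 / mean(sds) else 1
    blocks[[m$tag]] <- v * sc
    scales[m$tag] <- sc
    ann[[m$tag]] <- data.frame(feature = rownames(v),
                               entity = unname(m$entity[keep]),
                               platform = m$tag, stringsAsFactors = FALSE)
  }
  if (!length(blocks)) stop("no features remain after target filtering")
  values <- do.call(rbind, blocks)
  ann <- do.call(rbind, ann)
  rownames(ann) <- NULL
  rownames(values) <- paste(ann$feature, ann$platform, sep = "|")
  structure(list(values = values, feature = ann$feature,
                 entity = ann$entity, platform = ann$platform,
                 platform_scale = scales, group = group),
            class = "integrated_matrix")
}

#' @export
print.integrated_matrix <- function(x, ...) {
  cat(sprintf("<integrated_matrix (%s): %d features x %d samples, %d platform(s)>\n",
              x$group, nrow(x$values), ncol(x$values),
              length(unique(x$platform))))
  invisible(x)
}
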