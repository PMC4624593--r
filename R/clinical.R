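#' Clinical annotation tables
#'
#' A `clinical_table` holds raw (string-valued) clinical annotations for a
#' cohort: one row per sample, one column per clinical parameter, `NA` for
#' missing, together with per-parameter metadata classifying each
#' parameter as ordinal (ordered subtypes, e.g. clinical stage I-IV),
#' binary (two subtypes, e.g. sex), or categorical (unordered subtypes,
#' e.g. smoking history), and its ordered level list.
#'
#' @param values data frame of raw values; rownames are sample ids,
#'   columns are parameter names, entries are character (or coercible)
#'   with `NA` for missing.
#' @param source provenance label for this table (e.g. which portal the
#'   annotations came from).
#' @param metadata named list: parameter name -> [param_meta()].
#' @return an object of class `clinical_table`.
#' @export
clinical_table <- function(values, source = "unspecified", metadata) {
  stopifnot(is.data.frame(values))
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("`values` must have sample ids as rownames")
  values[] <- lapply(values, as.character)
  missing_meta <- setdiff(colnames(values), names(metadata))
  if (length(missing_meta))
    stop("parameters without metadata: ", paste(missing_meta, collapse = ", "))
  structure(list(values = values, source = source, metadata = metadata),
            class = "clinical_table")
}

#' @rdname clinical_table
#' @param kind `"ordinal"`, `"binary"` or `"categorical"`.
#' @param levels ordered, duplicate-free level labels.
#' @export
param_meta <- function(kind = c("ordinal", "binary", "categorical"), levels) {
  kind <- match.arg(kind)
  levels <- as.character(levels)
  if (anyDuplicated(levels)) stop("levels must be duplicate-free")
  if (kind == "binary" && length(levels) != 2)
    stop("binary parameters have exactly 2 levels")
  list(kind = kind, levels = levels)
}

#' @export
print.clinical_table <- function(x, ...) {
  cat(sprintf("<clinical_table '%s': %d samples x %d parameters>\n",
              x$source, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Consolidate clinical annotations from multiple sources
#'
#' Clinical metrics for the same cohort are often fragmented across
#' sources. This merges them into one table: the union of all
#' sample-parameter records is kept; where a single source reports, or
#' several sources agree, that value is retained; where two or more
#' sources give unequal non-missing values for the same sample-parameter
#' pair, the merged value is set to missing (`NA`) and the conflict is
#' logged. Any pairwise disagreement voids the record, so the operation is
#' idempotent.
#'
#' @param sources list of [clinical_table()] objects. Parameters shared
#'   across sources must agree in metadata kind.
#' @return a consolidated `clinical_table` (source `"consolidated"`) with
#'   a `conflicts` attribute: data frame `sample`, `parameter`, `values`
#'   (the disagreeing raw values, `;`-joined).
#' @export
consolidate_clinical <- function(sources) {
  stopifnot(length(sources) >= 1)
  for (s in sources) stopifnot(inherits(s, "clinical_table"))
  meta <- list()
  for (s in sources) {
    for (p in names(s$metadata)) {
      if (is.null(meta[[p]])) {
        meta[[p]] <- s$metadata[[p]]
      } else if (!identical(meta[[p]]$kind, s$metadata[[p]]$kind)) {
        stop("metadata kind mismatch across sources for parameter ", p)
      }
    }
  }
  samples <- unique(unlist(lapply(sources, function(s) rownames(s$values))))
  params <- unique(unlist(lapply(sources, function(s) colnames(s$values))))
  merged <- as.data.frame(matrix(NA_character_, length(samples), length(params)),
                          stringsAsFactors = FALSE)
  rownames(merged) <- samples
  colnames(merged) <- params
  conflicts <- data.frame(sample = character(0), parameter = character(0),
                          values = character(0), stringsAsFactors = FALSE)
  for (p in params) {
    for (s in samples) {
      vals <- character(0)
      for (src in sources) {
        if (p %in% colnames(src$values) && s %in% rownames(src$values)) {
          v <- src$values[s, p]
          if (!is.na(v)) vals <- c(vals, v)
        }
      }
      u <- unique(vals)
      if (length(u) == 1) {
        merged[s, p] <- u
      } else if (length(u) > 1) {
        conflicts[nrow(conflicts) + 1L, ] <-
          list(s, p, paste(u, collapse = ";"))
      }
    }
  }
  out <- clinical_table(merged, source = "consolidated", metadata = meta)
  attr(out, "conflicts") <- conflicts
  out
}

#' Encode a clinical parameter as a numeric outcome vector
#'
#' Converts raw clinical values into the integer outcome used as the
#' regression's dependent variable: ordinal levels map to their 1-based
#' position in the ordered level list (stage I, II, III, IV -> 1, 2, 3,
#' 4); binary parameters map the first metadata level to 0 and the second
#' to 1; categorical parameters are binarized one-vs-rest, the selected
#' class -> 1 and all other classes -> 0. Samples without an available
#' clinical value are excluded from analysis and listed with the reason
#' `"no clinical value"`.
#'
#' @param table a [clinical_table()].
#' @param parameter parameter name.
#' @param selected_class for categorical parameters only: the class
#'   encoded as 1.
#' @return an `outcome_vector`: list with `parameter`, `selected_class`,
#'   `values` (named numeric over encoded samples), `excluded` (data frame
#'   `sample`, `reason`), `kind`, and `levels`.
#' @export
encode_outcome <- function(table, parameter, selected_class = NULL) {
  stopifnot(inherits(table, "clinical_table"))
  meta <- table$metadata[[parameter]]
  if (is.null(meta)) stop("unknown parameter: ", parameter)
  if (meta$kind == "categorical") {
    if (is.null(selected_class))
      stop("categorical parameters require `selected_class`")
    if (!selected_class %in% meta$levels)
      stop("selected_class not in the level list: ", selected_class)
  } else if (!is.null(selected_class)) {
    stop("`selected_class` is only meaningful for categorical parameters")
  }
  if (!parameter %in% colnames(table$values))
    stop("parameter has no recorded values: ", parameter)
  raw <- table$values[[parameter]]
  names(raw) <- rownames(table$values)
  miss <- is.na(raw)
  excluded <- data.frame(sample = names(raw)[miss],
                         reason = rep("no clinical value", sum(miss)),
                         stringsAsFactors = FALSE)
  obs <- raw[!miss]
  bad <- setdiff(unique(obs), meta$levels)
  if (length(bad))
    stop("values not in the level list for ", parameter, ": ",
         paste(bad, collapse = ", "))
  values <- switch(meta$kind,
    ordinal = as.numeric(match(obs, meta$levels)),
    binary = as.numeric(match(obs, meta$levels) - 1L),
    categorical = as.numeric(obs == selected_class))
  names(values) <- names(obs)
  structure(list(parameter = parameter, selected_class = selected_class,
                 values = values, excluded = excluded,
                 kind = meta$kind, levels = meta$levels),
            class = "outcome_vector")
}

#' Plan the elastic-net runs for a cohort
#'
#' One association analysis is run per analysis group and clinical
#' parameter; categorical parameters expand into one run per class
#' (one-vs-rest binarization). Parameters with fewer encodable samples
#' than `min_samples` are dropped from the plan and logged.
#'
#' @param table a [clinical_table()].
#' @param groups analysis groups, subset of `c("gene", "miR", "protein")`.
#' @param min_samples minimum number of non-missing samples a parameter
#'   needs to be analyzed (default 20).
#' @return data frame with columns `group`, `parameter`, `selected_class`
#'   (`NA` for ordinal/binary runs), plus a `dropped` attribute listing
#'   parameters excluded for insufficient samples.
#' @export
enumerate_runs <- function(table, groups, min_samples = 20) {
  stopifnot(inherits(table, "clinical_table"))
  if (!length(groups)) stop("empty group list")
  if (!all(groups %in% c("gene", "miR", "protein")))
    stop("groups must be a subset of gene/miR/protein")
  plan <- data.frame(group = character(0), parameter = character(0),
                     selected_class = character(0), stringsAsFactors = FALSE)
  dropped <- data.frame(parameter = character(0), n_encodable = integer(0),
                        stringsAsFactors = FALSE)
  for (p in colnames(table$values)) {
    n_enc <- sum(!is.na(table$values[[p]]))
    if (n_enc < min_samples) {
      dropped[nrow(dropped) + 1L, ] <- list(p, n_enc)
      next
    }
    meta <- table$metadata[[p]]
    classes <- if (meta$kind == "categorical") meta$levels else NA_character_
    for (g in groups) {
      for (cl in classes) {
        plan[nrow(plan) + 1L, ] <- list(g, p, cl)
      }
    }
  }
  attr(plan, "dropped") <- dropped
  plan
}
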