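# Portal-style descriptive statistics and query operations.

#' Mutation and copy-number alteration frequencies for one entity
#'
#' Reports, per platform measuring the entity: mutation frequency
#' (percent of samples with an indicator of 1), amplification frequency
#' (percent of samples with a copy-number call > 0) and deletion
#' frequency (percent with a call < 0). Missing measurements are excluded
#' from the denominator.
#'
#' @param matrices list of [platform_matrix()] objects.
#' @param entity gene/miR/protein id.
#' @return data frame `platform`, `feature`, `metric`, `percent`, `n`.
#' @export
alteration_frequencies <- function(matrices, entity) {
  rows <- list()
  for (mat in matrices) {
    at <- which(unname(mat$entity) == entity)
    for (i in at) {
      v <- mat$values[i, ]
      v <- v[!is.na(v)]
      n <- length(v)
      if (n == 0) stop("zero samples with a measurement for ", entity)
      f <- features_of(mat)[i]
      if (mat$tag == "MUT") {
        rows[[length(rows) + 1L]] <- data.frame(
          platform = "MUT", feature = f, metric = "mutation",
          percent = 100 * sum(v == 1) / n, n = n, stringsAsFactors = FALSE)
      } else if (mat$tag == "CNV") {
        rows[[length(rows) + 1L]] <- data.frame(
          platform = "CNV", feature = f,
          metric = c("amplification", "deletion"),
          percent = 100 * c(sum(v > 0), sum(v < 0)) / n,
          n = n, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    stop("target name not recognized, please try another target name")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

subgroup_stats <- function(mat, i, members) {
  v <- mat$values[i, intersect(members, samples_of(mat))]
  v <- v[!is.na(v)]
  n <- length(v)
  if (mat$tag == "MUT") {
    list(n = n, mutated_percent = if (n) 100 * sum(v == 1) / n else NA_real_)
  } else if (mat$tag == "CNV") {
    calls <- factor(v, levels = -2:2)
    pct <- if (n) 100 * as.numeric(table(calls)) / n else rep(NA_real_, 5)
    names(pct) <- c("-2", "-1", "0", "1", "2")
    list(n = n, call_percent = pct)
  } else {
    list(n = n,
         summary = if (n) five_number(v) else
           stats::setNames(rep(NA_real_, 5),
                           c("min", "q1", "median", "q3", "max")))
  }
}

#' Profile an entity across the subgroups of a clinical parameter
#'
#' For every clinical subgroup, computes the entity's per-platform
#' statistics: mutation frequency, copy-number call distribution
#' (percent per call level), and five-number summaries (minimum, first
#' quartile, median, third quartile, maximum) for continuous platforms,
#' together with subgroup sample counts.
#'
#' @param entity gene/miR/protein id.
#' @param matrices list of [platform_matrix()] objects.
#' @param subgroups named character vector: sample id -> raw clinical
#'   subgroup label (e.g. one column of a [clinical_table()]). Samples
#'   with `NA` labels are ignored.
#' @param ranking optional `gene_ranking`; when supplied and the entity
#'   is not among its candidates, the advisory
#'   `"no association with clinical parameters was found"` is attached.
#' @return a `profile_summary`: list with `entity`, `subgroups` (per
#'   subgroup: per-platform statistics and counts), and possibly an
#'   `advisory` attribute.
#' @export
profile_query <- function(entity, matrices, subgroups, ranking = NULL) {
  subgroups <- subgroups[!is.na(subgroups)]
  if (!length(subgroups)) stop("no samples with a subgroup label")
  hits <- list()
  for (mat in matrices) {
    at <- which(unname(mat$entity) == entity)
    for (i in at) hits[[length(hits) + 1L]] <- list(mat = mat, i = i)
  }
  if (!length(hits))
    stop("target name not recognized, please try another target name")
  labs <- sort(unique(subgroups))
  per <- lapply(labs, function(lab) {
    members <- names(subgroups)[subgroups == lab]
    stats <- lapply(hits, function(h) {
      c(list(platform = h$mat$tag, feature = features_of(h$mat)[h$i]),
        subgroup_stats(h$mat, h$i, members))
    })
    list(n = length(members), platforms = stats)
  })
  names(per) <- labs
  out <- structure(list(entity = entity, subgroups = per),
                   class = "profile_summary")
  if (!is.null(ranking) && !entity %in% ranking$entity)
    attr(out, "advisory") <- "no association with clinical parameters was found"
  out
}

#' @export
print.profile_summary <- function(x, ...) {
  cat(sprintf("<profile_summary %s: %d subgroup(s)>\n",
              x$entity, length(x$subgroups)))
  invisible(x)
}

#' Two-hit query: stratify one profile by another alteration
#'
#' Splits the common samples by the second target's status — mutation
#' status (mutated vs wild-type) or copy-number class (amplified /
#' neutral / deleted) — and summarizes the first target's values within
#' each stratum (call distribution for discrete platforms, five-number
#' summary for continuous ones). The second target is limited to the
#' mutation and copy-number platforms: it is not feasible to split
#' samples by setting an arbitrary cutoff for expression levels.
#'
#' @param first list/vector `(entity, platform)` for the profiled target.
#' @param second list/vector `(entity, platform)` for the stratifying
#'   target; platform must be `"MUT"` or `"CNV"`.
#' @param matrices list of [platform_matrix()] objects.
#' @return a `two_hit_result`: list of strata, each with `n`, the member
#'   sample ids, and the first target's summary (empty when `n = 0`).
#' @export
two_hit_query <- function(first, second, matrices) {
  first <- as.list(first); second <- as.list(second)
  if (!second[[2]] %in% c("MUT", "CNV"))
    stop("the second target is limited to mutation and copy number; ",
         "it is not feasible to split samples by setting an arbitrary ",
         "cutoff for expression levels")
  find_row <- function(entity, platform) {
    for (mat in matrices) {
      if (mat$tag != platform) next
      i <- which(unname(mat$entity) == entity)
      if (length(i)) return(list(mat = mat, i = i[1]))
    }
    stop("target name not recognized, please try another target name")
  }
  f <- find_row(first[[1]], first[[2]])
  s <- find_row(second[[1]], second[[2]])
  common <- intersect(samples_of(f$mat), samples_of(s$mat))
  sv <- s$mat$values[s$i, common]
  strata <- if (second[[2]] == "MUT") {
    list(`wild-type` = common[!is.na(sv) & sv == 0],
         mutated = common[!is.na(sv) & sv == 1])
  } else {
    list(deleted = common[!is.na(sv) & sv < 0],
         neutral = common[!is.na(sv) & sv == 0],
         amplified = common[!is.na(sv) & sv > 0])
  }
  out <- lapply(strata, function(members) {
    if (!length(members))
      return(list(n = 0L, samples = character(0), summary = NULL))
    st <- subgroup_stats(f$mat, f$i, members)
    list(n = st$n, samples = members, summary = st[-1])
  })
  structure(list(first = first, second = second, strata = out,
                 n_common = length(common)),
            class = "two_hit_result")
}

#' @export
print.two_hit_result <- function(x, ...) {
  cat(sprintf("<two_hit_result %s:%s by %s:%s, %d common samples>\n",
              x$first[[1]], x$first[[2]], x$second[[1]], x$second[[2]],
              x$n_common))
  invisible(x)
}

fmt6 <- function(x) {
  out <- sprintf("%.6g", signif(x, 6))
  out[is.na(x)] <- "NA"
  out
}

#' Export a candidate table in portal style
#'
#' Writes the ranked candidate list of one analysis (cancer x clinical
#' parameter x analysis group) as a TSV table and a JSON mirror, both
#' byte-stable: keys sorted, floats at 6 significant digits. Columns:
#' rank, entity, score, selection frequency, score variance, supporting
#' platforms with direction signs, and the minimum Bonferroni-corrected P
#' across the entity's post-hoc tests (when post-hoc results are given).
#'
#' @param ranking a `gene_ranking`.
#' @param posthoc optional [test_candidates()] result.
#' @param dir output directory (created if needed).
#' @param analysis named list describing the analysis; entries `cancer`,
#'   `parameter`, `group`, `n_samples` are used for the file stem and the
#'   summary block.
#' @return invisibly, the paths of the two files written.
#' @export
export_candidates <- function(ranking, posthoc = NULL, dir,
                              analysis = list(cancer = "SYNTH",
                                              parameter = "outcome",
                                              group = "gene",
                                              n_samples = NA_integer_)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- paste(analysis$cancer, analysis$parameter, analysis$group,
                "candidates", sep = "_")
  feats <- attr(ranking, "features")
  df <- as.data.frame(ranking)
  platdir <- vapply(df$entity, function(e) {
    rows <- feats[feats$entity == e, , drop = FALSE]
    if (!nrow(rows)) return("")
    rows <- rows[order(rows$platform), , drop = FALSE]
    paste(sprintf("%s:%s", rows$platform,
                  ifelse(rows$direction >= 0, "+", "-")), collapse = ";")
  }, "")
  minp <- rep(NA_real_, nrow(df))
  if (!is.null(posthoc) && nrow(posthoc)) {
    agg <- tapply(posthoc$corrected_p, posthoc$entity, min)
    minp <- as.numeric(agg[df$entity])
  }
  tab <- data.frame(rank = df$rank, entity = df$entity,
                    score = fmt6(df$score),
                    selection_frequency = fmt6(df$selection_frequency),
                    score_variance = fmt6(df$score_variance),
                    platforms = platdir,
                    min_corrected_p = fmt6(minp),
                    stringsAsFactors = FALSE)
  tsv <- file.path(dir, paste0(stem, ".tsv"))
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  cand <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    list(entity = row$entity,
         min_corrected_p = row$min_corrected_p,
         platforms = row$platforms,
         rank = df$rank[i],
         score = row$score,
         score_variance = row$score_variance,
         selection_frequency = row$selection_frequency)
  })
  payload <- list(analysis = analysis[order(names(analysis))],
                  candidates = cand,
                  n_candidates = nrow(tab),
                  n_samples = analysis$n_samples)
  payload <- payload[order(names(payload))]
  json <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", na = "null")
  invisible(c(tsv = tsv, json = json))
}
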