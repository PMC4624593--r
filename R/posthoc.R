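# Per-candidate significance testing with Bonferroni correction.

#' Split encoded samples into two clinical groups
#'
#' Post-hoc testing compares a molecular feature between two groups
#' defined by the clinical parameter. The default rule for ordinal
#' parameters splits encoded levels \{1,2\} against the higher levels
#' (early- vs advanced-stage for a four-level stage parameter); binary
#' and one-vs-rest outcomes split 0 against 1. A custom partition of the
#' encoded levels can be supplied as `list(a = ..., b = ...)`.
#'
#' @param outcome an [encode_outcome()] result.
#' @param rule optional list with integer level sets `a` and `b`.
#' @return list with sample-id vectors `a` and `b` and a `description`.
#' @export
dichotomize_outcome <- function(outcome, rule = NULL) {
  stopifnot(inherits(outcome, "outcome_vector"))
  v <- outcome$values
  if (is.null(rule)) {
    if (outcome$kind == "ordinal") {
      rule <- list(a = c(1, 2), b = setdiff(sort(unique(v)), c(1, 2)))
      desc <- sprintf("%s: levels 1-2 vs higher", outcome$parameter)
    } else {
      rule <- list(a = 0, b = 1)
      desc <- sprintf("%s: 0 vs 1", outcome$parameter)
    }
  } else {
    stopifnot(is.list(rule), all(c("a", "b") %in% names(rule)))
    desc <- sprintf("%s: {%s} vs {%s}", outcome$parameter,
                    paste(rule$a, collapse = ","),
                    paste(rule$b, collapse = ","))
  }
  a <- names(v)[v %in% rule$a]
  b <- names(v)[v %in% rule$b]
  if (!length(a) || !length(b))
    stop("dichotomization produced an empty group")
  list(a = a, b = b, description = desc)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided P-value sums the hypergeometric probabilities, under
#' fixed margins, of every table at most as probable as the observed one
#' (within relative tolerance 1e-7). Used for mutation and copy-number
#' candidates.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the raw two-sided P-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0)) stop("negative cell count")
  if (sum(table) == 0) stop("at least one margin must be positive")
  stats::fisher.test(table)$p.value
}

#' Two-sided Mann-Whitney-Wilcoxon test
#'
#' Used for continuous-platform candidates (expression, methylation,
#' miR-Seq, RPPA). The exact null distribution is used when both groups
#' have at most 8 observations and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections applies.
#'
#' @param a,b numeric value vectors for the two clinical groups.
#' @return the raw two-sided P-value.
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- max(length(a), length(b)) <= 8 && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
}

#' Test each elastic-net candidate individually
#'
#' Implements the post-hoc workflow: every candidate entity is tested on
#' each platform that measures it, against the two clinical groups.
#' Mutation indicators use Fisher's exact test on (altered vs not) x
#' (group A vs group B), with altered = value 1. Copy-number calls use
#' Fisher's exact test with altered = amplified (call > 0) when the
#' candidate's copy-number direction is non-negative, or deleted
#' (call < 0) otherwise. Continuous platforms use the
#' Mann-Whitney-Wilcoxon test. Raw P-values are Bonferroni-corrected by
#' `m`, the number of candidates in this analysis (corrected P =
#' `min(1, raw * m)`); a candidate is retained when its corrected P falls
#' below `threshold`.
#'
#' @param ranking a `gene_ranking` (see [bootstrap_rank()]); its entities
#'   are the candidates.
#' @param matrices list of raw (pre-normalization) [platform_matrix()]
#'   objects.
#' @param outcome an [encode_outcome()] result.
#' @param threshold corrected-P cutoff (default 0.01).
#' @param rule optional dichotomization rule (see
#'   [dichotomize_outcome()]).
#' @return data frame with one row per candidate x matching feature x
#'   platform: `entity`, `platform`, `feature`, `test`, `grouping`,
#'   `n11`..`n22` (the 2x2 table, `NA` for rank tests), `raw_p`,
#'   `corrected_p`, `retained`; attributes `m` and `threshold`.
#' @export
test_candidates <- function(ranking, matrices, outcome, threshold = 0.01,
                            rule = NULL) {
  stopifnot(nrow(ranking) >= 1)
  groups <- dichotomize_outcome(outcome, rule)
  m <- nrow(ranking)
  feats <- attr(ranking, "features")
  out <- data.frame(entity = character(0), platform = character(0),
                    feature = character(0), test = character(0),
                    grouping = character(0),
                    n11 = integer(0), n12 = integer(0),
                    n21 = integer(0), n22 = integer(0),
                    raw_p = numeric(0), stringsAsFactors = FALSE)
  for (ent in ranking$entity) {
    found <- FALSE
    for (mat in matrices) {
      rows <- which(unname(mat$entity) == ent)
      if (!length(rows)) next
      found <- TRUE
      smp <- samples_of(mat)
      ga <- intersect(groups$a, smp)
      gb <- intersect(groups$b, smp)
      if (!length(ga) || !length(gb)) next
      for (i in rows) {
        va <- mat$values[i, ga]
        vb <- mat$values[i, gb]
        va <- va[!is.na(va)]
        vb <- vb[!is.na(vb)]
        if (!length(va) || !length(vb)) next
        if (mat$tag %in% c("MUT", "CNV")) {
          if (mat$tag == "MUT") {
            alt_a <- sum(va == 1); alt_b <- sum(vb == 1)
            test <- "fisher-exact"
          } else {
            dirs <- feats$direction[feats$entity == ent &
                                      feats$platform == "CNV"]
            amplified <- !length(dirs) || sign(sum(dirs)) >= 0
            if (amplified) {
              alt_a <- sum(va > 0); alt_b <- sum(vb > 0)
            } else {
              alt_a <- sum(va < 0); alt_b <- sum(vb < 0)
            }
            test <- "fisher-exact"
          }
          tab <- matrix(c(alt_a, length(va) - alt_a,
                          alt_b, length(vb) - alt_b), 2, 2)
          p <- fisher_exact_2x2(tab)
          out[nrow(out) + 1L, ] <- list(ent, mat$tag, features_of(mat)[i],
                                        test, groups$description,
                                        tab[1, 1], tab[1, 2],
                                        tab[2, 1], tab[2, 2], p)
        } else {
          p <- mann_whitney_u(va, vb)
          out[nrow(out) + 1L, ] <- list(ent, mat$tag, features_of(mat)[i],
                                        "mann-whitney", groups$description,
                                        NA_integer_, NA_integer_,
                                        NA_integer_, NA_integer_, p)
        }
      }
    }
    if (!found) stop("candidate absent from all matrices: ", ent)
  }
  out$corrected_p <- pmin(1, out$raw_p * m)
  out$retained <- out$corrected_p < threshold
  attr(out, "m") <- m
  attr(out, "threshold") <- threshold
  out
}
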