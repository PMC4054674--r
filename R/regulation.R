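# Expression entropy and rank tests over gene groups.
#
# Expression entropy is the Shannon entropy (base 2) of a gene's
# normalized expression profile across conditions: low entropy means the
# gene's transcripts concentrate in few conditions (strong regulation),
# the maximum log2(n_conditions) means uniform expression everywhere.

#' Shannon expression entropy of one gene
#'
#' `p_i = x_i / sum(x)`, `H = -sum(p_i log2 p_i)` with `0 log 0 = 0`.
#' A gene with zero total expression has no defined profile and is flagged
#' invalid (`entropy = NA`).
#'
#' @param x non-negative expression vector across >= 2 conditions.
#' @return list: `entropy` (bits), `n_conditions`, `valid`.
#' @export
expression_entropy <- function(x) {
  if (length(x) < 2) stop("need expression in at least 2 conditions")
  if (any(x < 0)) stop("expression values must be non-negative")
  tot <- sum(x)
  if (tot == 0)
    return(list(entropy = NA_real_, n_conditions = length(x),
                valid = FALSE))
  p <- x / tot
  p <- p[p > 0]
  list(entropy = -sum(p * log2(p)), n_conditions = length(x), valid = TRUE)
}

#' Expression entropy for every gene of a matrix
#'
#' @param expression gene x condition matrix with gene rownames.
#' @return data.table: `gene_id`, `entropy`, `n_conditions`, `valid`.
#' @export
entropy_table <- function(expression) {
  res <- apply(expression, 1, expression_entropy)
  data.table(gene_id = rownames(expression),
             entropy = vapply(res, `[[`, 0, "entropy"),
             n_conditions = ncol(expression),
             valid = vapply(res, `[[`, TRUE, "valid"))
}

#' Wilcoxon rank-sum test between two independent samples
#'
#' Exact enumeration when both samples have at most 25 observations and no
#' ties; tie-corrected normal approximation otherwise. Two identical
#' constant samples give p = 1 by convention.
#'
#' @param sample_a,sample_b numeric vectors.
#' @param alternative `"less"`, `"greater"` or `"two_sided"`, stated for
#'   `sample_a` relative to `sample_b`.
#' @return list: `statistic` (Mann-Whitney W for sample_a), `p_value`,
#'   `exact` (whether enumeration was used).
#' @export
wilcoxon_rank_test <- function(sample_a, sample_b,
                               alternative = c("two_sided", "less",
                                               "greater")) {
  alternative <- match.arg(alternative)
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty")
  alt <- sub("two_sided", "two.sided", alternative)
  pooled <- c(sample_a, sample_b)
  if (max(pooled) == min(pooled))
    return(list(statistic = length(sample_a) * length(sample_b) / 2,
                p_value = 1, exact = FALSE))
  use_exact <- max(length(sample_a), length(sample_b)) <= 25 &&
    !anyDuplicated(pooled)
  wt <- suppressWarnings(
    wilcox.test(sample_a, sample_b, alternative = alt, exact = use_exact,
                correct = !use_exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = use_exact)
}

#' Per-category medians and one-tail tests against all genes
#'
#' For each gene category, reports n, the median of the values, the
#' direction of its deviation from the all-genes median, and the one-tail
#' Wilcoxon rank-sum p-value against the all-genes distribution in that
#' direction.
#'
#' @param values named numeric vector (names = gene ids), e.g. entropies
#'   or expression summaries; NAs dropped.
#' @param categories data.table with `gene_id` and `category` (from
#'   [gene_h33_categories()]) or a named character vector.
#' @return data.table: `category`, `n`, `median`, `direction`, `p_value`;
#'   first row is the all-genes reference.
#' @export
group_comparison_report <- function(values, categories) {
  if (is.data.frame(categories)) {
    cat_vec <- setNames(categories$category, categories$gene_id)
  } else cat_vec <- categories
  values <- values[!is.na(values)]
  all_med <- median(values)
  rows <- list(data.table(category = "all", n = length(values),
                          median = all_med, direction = NA_character_,
                          p_value = NA_real_))
  for (lab in unique(cat_vec)) {
    ids <- names(cat_vec)[cat_vec == lab]
    v <- values[names(values) %in% ids]
    if (!length(v)) next
    dir <- if (median(v) <= all_med) "less" else "greater"
    p <- wilcoxon_rank_test(v, values, alternative = dir)$p_value
    rows[[length(rows) + 1]] <-
      data.table(category = lab, n = length(v), median = median(v),
                 direction = dir, p_value = p)
  }
  rbindlist(rows)
}
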