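# Module enrichment between genome groups. Each module's occurrence
# (completeness at or above a presence threshold) is modelled as binomial
# per group; the Rao score statistic for equality of group proportions has
# the closed form
#   score = sum_g n_g (p_g - p_hat)^2 / (p_hat (1 - p_hat))
# with p_hat the pooled proportion, chi-square with (G - 1) degrees of
# freedom under the null. For two groups this equals the Pearson chi-square
# statistic of the 2x2 occurrence table.

#' Criteria defining module occurrence and enrichment
#'
#' @param q_max Modules are enriched only when their BH-corrected q-value is
#'   strictly below this. Default 0.05.
#' @param min_completeness Minimum mean completeness of the module within
#'   its associated group. Default 0.75.
#' @param min_group_presence Minimum fraction of the associated group's
#'   members in which the module occurs. Default 0.50.
#' @param presence_threshold Completeness at or above this value counts as
#'   "occurrence" of the module in a genome. Default 0.75.
#' @return An `enrichment_criteria` list.
#' @export
enrichment_criteria <- function(q_max = 0.05, min_completeness = 0.75,
                                min_group_presence = 0.50,
                                presence_threshold = 0.75) {
  vals <- c(q_max, min_completeness, min_group_presence, presence_threshold)
  stopifnot(all(vals >= 0), all(vals <= 1))
  structure(list(q_max = q_max, min_completeness = min_completeness,
                 min_group_presence = min_group_presence,
                 presence_threshold = presence_threshold),
            class = "enrichment_criteria")
}

check_groups <- function(matrix, groups) {
  genomes <- rownames(matrix)
  missing <- setdiff(genomes, names(groups))
  if (length(missing) > 0L) {
    stop("genome(s) without group assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.character(groups[genomes])
}

#' Per-group occurrence counts of each module
#'
#' @param matrix Genome-by-module completeness matrix.
#' @param groups Named character vector mapping genome id to group.
#' @param criteria An [enrichment_criteria]; occurrence means completeness
#'   at or above `presence_threshold` (inclusive).
#' @return Data frame with columns `module_id`, `group`, `n_present`,
#'   `n_total`.
#' @export
module_occurrence <- function(matrix, groups,
                              criteria = enrichment_criteria()) {
  grp <- check_groups(matrix, groups)
  levels <- sort(unique(grp))
  present <- matrix >= criteria$presence_threshold
  out <- do.call(rbind, lapply(levels, function(g) {
    rows <- present[grp == g, , drop = FALSE]
    data.frame(module_id = colnames(matrix), group = g,
               n_present = as.integer(colSums(rows)),
               n_total = nrow(rows), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rao score test for equal occurrence proportions across groups
#'
#' @param n_present Integer vector of occurrence counts, one per group.
#' @param n_total Integer vector of group sizes (>= 1), same length.
#' @return List with `score`, `p_value` and `df`. When the pooled
#'   proportion is 0 or 1 (zero variance) the score is 0 and p is 1.
#' @examples
#' rao_score_test(c(10, 0), c(10, 10))
#' @export
rao_score_test <- function(n_present, n_total) {
  stopifnot(length(n_present) == length(n_total))
  if (length(n_present) < 2L) {
    stop("the score test needs at least 2 groups", call. = FALSE)
  }
  if (any(n_total < 1)) {
    stop("every group must contain at least one genome", call. = FALSE)
  }
  if (any(n_present < 0) || any(n_present > n_total)) {
    stop("occurrence counts must satisfy 0 <= n_present <= n_total",
         call. = FALSE)
  }
  df <- length(n_present) - 1L
  p_hat <- sum(n_present) / sum(n_total)
  if (p_hat <= 0 || p_hat >= 1) {
    return(list(score = 0, p_value = 1, df = df))
  }
  p_g <- n_present / n_total
  score <- sum(n_total * (p_g - p_hat)^2) / (p_hat * (1 - p_hat))
  list(score = score,
       p_value = stats::pchisq(score, df = df, lower.tail = FALSE),
       df = df)
}

#' Benjamini-Hochberg step-up false discovery rate correction
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order, each at least its p-value.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment test for every module between genome groups
#'
#' Runs the Rao score test per module on group occurrence counts, corrects
#' p-values with BH, identifies the associated group (highest occurrence
#' proportion; ties report every tied group), and applies the enrichment
#' criteria: q below `q_max`, mean completeness within the associated group
#' at least `min_completeness`, and occurrence in at least
#' `min_group_presence` of that group's members.
#'
#' @param matrix Genome-by-module completeness matrix.
#' @param groups Named character vector mapping genome id to group.
#' @param criteria An [enrichment_criteria].
#' @return Data frame with one row per module: `module_id`,
#'   `enrichment_score`, `p_value`, `q_value`, `associated_groups`,
#'   one `proportion_<group>` and one `mean_completeness_<group>` column
#'   per group, and logical `enriched`.
#' @export
enrichment_test <- function(matrix, groups,
                            criteria = enrichment_criteria()) {
  grp <- check_groups(matrix, groups)
  levels <- sort(unique(grp))
  if (length(levels) < 2L) {
    stop("enrichment needs at least 2 groups", call. = FALSE)
  }
  occ <- module_occurrence(matrix, groups, criteria)
  modules <- colnames(matrix)
  props <- matrix(0, nrow = length(modules), ncol = length(levels),
                  dimnames = list(modules, levels))
  means <- props
  for (g in levels) {
    sub <- matrix[grp == g, , drop = FALSE]
    props[, g] <- colMeans(sub >= criteria$presence_threshold)
    means[, g] <- colMeans(sub)
  }
  tests <- lapply(modules, function(m) {
    rows <- occ[occ$module_id == m, ]
    rows <- rows[match(levels, rows$group), ]
    rao_score_test(rows$n_present, rows$n_total)
  })
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  q <- bh_fdr(p)
  assoc <- vapply(seq_along(modules), function(i) {
    pr <- props[i, ]
    paste(levels[pr == max(pr)], collapse = ",")
  }, character(1))
  enriched <- vapply(seq_along(modules), function(i) {
    if (q[i] >= criteria$q_max) return(FALSE)
    any(vapply(strsplit(assoc[i], ",")[[1]], function(g) {
      means[i, g] >= criteria$min_completeness &&
        props[i, g] >= criteria$min_group_presence
    }, logical(1)))
  }, logical(1))
  out <- data.frame(module_id = modules,
                    enrichment_score = vapply(tests, `[[`, numeric(1),
                                              "score"),
                    p_value = p, q_value = q,
                    associated_groups = assoc,
                    stringsAsFactors = FALSE)
  for (g in levels) out[[paste0("proportion_", g)]] <- props[, g]
  for (g in levels) out[[paste0("mean_completeness_", g)]] <- means[, g]
  out$enriched <- enriched
  rownames(out) <- NULL
  out
}

#' Enriched module sets per group
#'
#' @param rows Output of [enrichment_test] for the same matrix and groups.
#' @param matrix Genome-by-module completeness matrix.
#' @param groups Named character vector mapping genome id to group.
#' @param criteria An [enrichment_criteria].
#' @return Named list: for each group, the character vector of module ids
#'   enriched in it.
#' @export
enriched_modules <- function(rows, matrix, groups,
                             criteria = enrichment_criteria()) {
  grp <- check_groups(matrix, groups)
  levels <- sort(unique(grp))
  out <- lapply(levels, function(g) {
    hits <- character(0)
    for (i in seq_len(nrow(rows))) {
      if (rows$q_value[i] >= criteria$q_max) next
      assoc <- strsplit(rows$associated_groups[i], ",")[[1]]
      if (!g %in% assoc) next
      if (rows[[paste0("mean_completeness_", g)]][i] >=
            criteria$min_completeness &&
          rows[[paste0("proportion_", g)]][i] >=
            criteria$min_group_presence) {
        hits <- c(hits, rows$module_id[i])
      }
    }
    hits
  })
  names(out) <- levels
  out
}
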