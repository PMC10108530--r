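# Metabolic independence: the aggregate pathwise completeness of a fixed
# set of biosynthetic modules (those enriched in good colonizers) in one
# genome. Genomes at or above a threshold fraction of the maximum
# attainable score are classified as high metabolic independence (HMI),
# the rest as low (LMI).

#' Define the module set used for metabolic-independence scoring
#'
#' @param module_ids Ordered character vector of unique module ids.
#' @param categories Optional named list mapping module id to a character
#'   vector of category strings (a module may carry several, e.g.
#'   "Amino acid metabolism").
#' @return A `module_set` object.
#' @export
module_set <- function(module_ids, categories = NULL) {
  module_ids <- as.character(module_ids)
  if (anyDuplicated(module_ids)) {
    stop("module ids must be unique", call. = FALSE)
  }
  if (!is.null(categories)) {
    stopifnot(is.list(categories))
    extra <- setdiff(names(categories), module_ids)
    if (length(extra) > 0L) {
      stop("categories for unknown module(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(module_ids = module_ids, categories = categories),
            class = "module_set")
}

#' Configuration for HMI/LMI classification
#'
#' @param threshold_fraction Fraction of the maximum attainable score (the
#'   number of modules in the set) at or above which a genome is classified
#'   HMI. Default 0.8; the threshold in use is always reported alongside
#'   the score.
#' @return A `mi_config` list.
#' @export
mi_config <- function(threshold_fraction = 0.8) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  structure(list(threshold_fraction = threshold_fraction),
            class = "mi_config")
}

#' Metabolic-independence score and HMI/LMI classification
#'
#' The score is the sum of pathwise completeness over the module set, in
#' `[0, |set|]`; a genome is HMI when its score is at least
#' `threshold_fraction * |set|`.
#'
#' @param matrix Genome-by-module completeness matrix containing every
#'   module of the set.
#' @param genome_ids Genomes to score; defaults to all rows.
#' @param set A [module_set].
#' @param config A [mi_config].
#' @return Data frame with columns `genome_id`, `score`, `classification`
#'   (`HMI`/`LMI`) and `threshold_used`.
#' @export
mi_score <- function(matrix, genome_ids = NULL, set, config = mi_config()) {
  stopifnot(inherits(set, "module_set"))
  missing <- setdiff(set$module_ids, colnames(matrix))
  if (length(missing) > 0L) {
    stop("completeness matrix lacks module column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(genome_ids)) genome_ids <- rownames(matrix)
  bad <- setdiff(genome_ids, rownames(matrix))
  if (length(bad) > 0L) {
    stop("completeness matrix lacks genome row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  threshold <- config$threshold_fraction * length(set$module_ids)
  scores <- rowSums(matrix[genome_ids, set$module_ids, drop = FALSE])
  data.frame(genome_id = genome_ids,
             score = unname(scores),
             classification = ifelse(scores >= threshold, "HMI", "LMI"),
             threshold_used = threshold,
             stringsAsFactors = FALSE)
}

#' Wilcoxon comparison of two score distributions
#'
#' Unpaired comparisons use the rank-sum statistic; paired comparisons the
#' signed-rank statistic V (sum of positive ranks, zero differences
#' dropped). By default p-values come from the normal approximation with
#' continuity correction; `exact = TRUE` uses the exact distribution (no
#' ties), which for small samples equals brute-force permutation
#' enumeration.
#'
#' @param values_a,values_b Numeric vectors (each length >= 3; equal
#'   lengths when paired).
#' @param paired Logical.
#' @param exact Logical; exact p-value instead of the corrected normal
#'   approximation.
#' @return List with `statistic`, `p_value` and `method`.
#' @export
group_compare <- function(values_a, values_b, paired = FALSE,
                          exact = FALSE) {
  if (length(values_a) < 3L || length(values_b) < 3L) {
    stop("each group needs at least 3 values", call. = FALSE)
  }
  if (paired && length(values_a) != length(values_b)) {
    stop("paired comparison needs equal-length vectors", call. = FALSE)
  }
  if (paired) {
    d <- values_a - values_b
    if (all(d == 0)) {
      stop("zero variance: all paired differences are zero", call. = FALSE)
    }
  } else if (length(unique(c(values_a, values_b))) == 1L) {
    stop("zero variance: all values tied", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, paired = paired,
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}

#' Category composition of a module set
#'
#' @param set A [module_set] with categories. A module may carry several
#'   categories, so percentages are computed against the set size and may
#'   sum to more than 100.
#' @return Data frame with columns `category`, `n`, `percent`.
#' @export
category_summary <- function(set) {
  stopifnot(inherits(set, "module_set"))
  if (is.null(set$categories) || length(set$categories) == 0L) {
    return(data.frame(category = character(0), n = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  }
  cats <- unlist(set$categories, use.names = FALSE)
  tab <- sort(table(cats), decreasing = TRUE)
  data.frame(category = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(set$module_ids),
             stringsAsFactors = FALSE)
}

#' Per-group completeness distributions over a module set
#'
#' Summarizes, for each genome group (and optionally each individual), the
#' distribution of module completeness values over the module set: the
#' kind of summary behind group-level comparisons of FMT donor genomes,
#' genomes from healthy individuals, and genomes from IBD patients.
#'
#' @param matrix Genome-by-module completeness matrix.
#' @param set A [module_set].
#' @param genome_groups Named character vector mapping genome id to group.
#' @param individuals Optional named character vector mapping genome id to
#'   individual (subject) id for per-individual summaries.
#' @return List with `per_group` (group, n_genomes, mean, median) and, when
#'   individuals are given, `per_individual` (individual, group, n_genomes,
#'   mean, median) data frames.
#' @export
group_profile <- function(matrix, set, genome_groups, individuals = NULL) {
  stopifnot(inherits(set, "module_set"))
  sub <- matrix[, set$module_ids, drop = FALSE]
  grp <- check_groups(sub, genome_groups)
  levels <- sort(unique(grp))
  per_group <- do.call(rbind, lapply(levels, function(g) {
    vals <- sub[grp == g, , drop = FALSE]
    data.frame(group = g, n_genomes = nrow(vals),
               mean = mean(vals), median = stats::median(vals),
               stringsAsFactors = FALSE)
  }))
  out <- list(per_group = per_group)
  if (!is.null(individuals)) {
    ind <- individuals[rownames(sub)]
    ids <- sort(unique(ind))
    out$per_individual <- do.call(rbind, lapply(ids, function(i) {
      sel <- which(ind == i)
      vals <- sub[sel, , drop = FALSE]
      data.frame(individual = i, group = unique(grp[sel])[1],
                 n_genomes = length(sel), mean = mean(vals),
                 median = stats::median(vals), stringsAsFactors = FALSE)
    }))
  }
  out
}
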