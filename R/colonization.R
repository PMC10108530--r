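# Colonization phenotyping for genome/recipient pairs after fecal
# microbiota transplantation. A pair is in scope only when the genome is
# detected in the donor stool used for that recipient's transplant; the
# phenotype then depends on post-FMT detection and on strain-level
# subpopulation evidence that discriminates donor-derived populations from
# anything the recipient already carried.

#' Rules for colonization phenotyping and good/poor classification
#'
#' @param post_fmt_min_days A recipient sample counts as post-FMT evidence
#'   only when collected strictly more than this many days after transplant.
#'   Default 7.
#' @param subpop_min_proportion Subpopulations making up less than this
#'   proportion of the population explained by a genome are removed as
#'   likely non-specific mapping noise. Default 0.01 (the comparison is
#'   "less than": exactly 1\% is retained).
#' @param scg_coverage_min Subpopulation evidence is used only for
#'   genome/sample cells whose mean non-outlier single-copy core gene
#'   coverage is at least this value. Default 10.
#' @param good_requires_all_recipients Number of recipients in which a
#'   genome must be donor-detected and post-FMT-detected to be a good
#'   colonizer. Default 5 (all recipients of a donor).
#' @param poor_min_recipients Minimum number of recipients in which a
#'   genome must be donor-detected but absent post-FMT to be a poor
#'   colonizer. Default 3.
#' @return A `colonization_rules` list.
#' @export
colonization_rules <- function(post_fmt_min_days = 7,
                               subpop_min_proportion = 0.01,
                               scg_coverage_min = 10,
                               good_requires_all_recipients = 5,
                               poor_min_recipients = 3) {
  stopifnot(post_fmt_min_days > 0, subpop_min_proportion > 0,
            scg_coverage_min > 0, good_requires_all_recipients > 0,
            poor_min_recipients > 0)
  structure(list(post_fmt_min_days = post_fmt_min_days,
                 subpop_min_proportion = subpop_min_proportion,
                 scg_coverage_min = scg_coverage_min,
                 good_requires_all_recipients = good_requires_all_recipients,
                 poor_min_recipients = poor_min_recipients),
            class = "colonization_rules")
}

validate_sample_meta <- function(meta) {
  req <- c("sample_id", "subject_id", "role", "day_relative_to_fmt",
           "donor_subject", "transplant_sample")
  missing <- setdiff(req, names(meta))
  if (length(missing) > 0L) {
    stop("sample metadata is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(meta$role %in% c("donor", "recipient"))) {
    stop("sample roles must be 'donor' or 'recipient'", call. = FALSE)
  }
  rec <- meta[meta$role == "recipient", ]
  if (any(is.na(rec$donor_subject)) || any(is.na(rec$transplant_sample))) {
    stop("recipient samples must carry donor_subject and transplant_sample",
         call. = FALSE)
  }
  invisible(meta)
}

#' Validate a subpopulation proportion table
#'
#' @param profiles Data frame with columns `genome_id`, `subpop_id`,
#'   `sample_id`, `proportion`; per (genome, sample) the proportions must
#'   sum to at most 1 (tolerance 1e-6).
#' @return The validated data frame, invisibly.
#' @export
validate_subpopulations <- function(profiles) {
  req <- c("genome_id", "subpop_id", "sample_id", "proportion")
  missing <- setdiff(req, names(profiles))
  if (length(missing) > 0L) {
    stop("subpopulation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(profiles$proportion < 0) || any(profiles$proportion > 1)) {
    stop("subpopulation proportions must be in [0, 1]", call. = FALSE)
  }
  if (nrow(profiles) > 0L) {
    sums <- tapply(profiles$proportion,
                   paste(profiles$genome_id, profiles$sample_id, sep = "\r"),
                   sum)
    if (any(sums > 1 + 1e-6)) {
      stop("subpopulation proportions exceed 1 for some (genome, sample)",
           call. = FALSE)
    }
  }
  invisible(profiles)
}

#' Filter subpopulation profiles for noise and low coverage
#'
#' Removes subpopulations below the minimum proportion (non-specific
#' mapping) and drops every subpopulation row of (genome, sample) cells
#' whose single-copy core gene coverage is insufficient (low-coverage
#' noise).
#'
#' @param profiles Subpopulation table (see [validate_subpopulations]).
#' @param rules A [colonization_rules].
#' @param coverage_ok Optional logical matrix (genomes x samples) marking
#'   cells with adequate coverage; cells absent from the matrix are treated
#'   as inadequate. `NULL` keeps all cells.
#' @return The filtered data frame.
#' @export
filter_subpopulations <- function(profiles, rules = colonization_rules(),
                                  coverage_ok = NULL) {
  validate_subpopulations(profiles)
  keep <- profiles$proportion >= rules$subpop_min_proportion
  if (!is.null(coverage_ok)) {
    stopifnot(is.matrix(coverage_ok), is.logical(coverage_ok))
    cell_ok <- mapply(function(g, s) {
      g %in% rownames(coverage_ok) && s %in% colnames(coverage_ok) &&
        isTRUE(coverage_ok[g, s])
    }, profiles$genome_id, profiles$sample_id, USE.NAMES = FALSE)
    keep <- keep & cell_ok
  }
  profiles[keep, , drop = FALSE]
}

recipient_samples <- function(meta, recipient_id, rules) {
  rec <- meta[meta$subject_id == recipient_id & meta$role == "recipient", ,
              drop = FALSE]
  if (nrow(rec) == 0L) {
    stop("no samples for recipient '", recipient_id, "'", call. = FALSE)
  }
  pre <- rec$sample_id[rec$day_relative_to_fmt < 0]
  post7 <- rec$sample_id[rec$day_relative_to_fmt > rules$post_fmt_min_days]
  if (length(pre) == 0L) {
    stop("recipient '", recipient_id, "' has no pre-FMT sample",
         call. = FALSE)
  }
  if (length(post7) == 0L) {
    stop("recipient '", recipient_id, "' has no post-FMT sample more than ",
         rules$post_fmt_min_days, " days after transplant", call. = FALSE)
  }
  transplant <- unique(rec$transplant_sample)
  transplant <- transplant[!is.na(transplant)]
  if (length(transplant) != 1L) {
    stop("recipient '", recipient_id,
         "' must reference exactly one transplant sample", call. = FALSE)
  }
  list(pre = pre, post7 = post7, transplant = transplant)
}

subpops_in <- function(subpops, genome_id, sample_ids) {
  unique(subpops$subpop_id[subpops$genome_id == genome_id &
                             subpops$sample_id %in% sample_ids])
}

#' Assign a colonization phenotype to one genome/recipient pair
#'
#' Implements the decision tree: (1) a genome not detected in the donor
#' stool used for this recipient's transplant is out of scope
#' (`not_applicable`); (2) donor-detected but never detected in a recipient
#' sample taken more than `post_fmt_min_days` days post-FMT is
#' `not_colonized`; (3) detected post-FMT with a filtered subpopulation
#' present in the transplant sample, absent from every pre-FMT recipient
#' sample, and present post-FMT is `colonized` (a genome entirely absent
#' pre-FMT satisfies this vacuously); (4) detected post-FMT with no such
#' discriminating subpopulation (including pairs whose subpopulation
#' evidence did not survive the coverage filter) is `undetermined`.
#'
#' @param genome_id,recipient_id The pair to phenotype.
#' @param detection A [detection_table] or detection matrix.
#' @param subpops Filtered subpopulation table (see
#'   [filter_subpopulations]).
#' @param meta Sample metadata (see [validate_sample_meta]).
#' @param rules A [colonization_rules].
#' @param thresholds A [detection_thresholds].
#' @return A one-row data frame: `genome_id`, `recipient_id`, `outcome`
#'   (one of `colonized`, `not_colonized`, `undetermined`,
#'   `not_applicable`) and `evidence` (which rule fired).
#' @export
assign_phenotype <- function(genome_id, recipient_id, detection, subpops,
                             meta, rules = colonization_rules(),
                             thresholds = detection_thresholds()) {
  validate_sample_meta(meta)
  ss <- recipient_samples(meta, recipient_id, rules)
  call_row <- function(outcome, evidence) {
    data.frame(genome_id = genome_id, recipient_id = recipient_id,
               outcome = outcome, evidence = evidence,
               stringsAsFactors = FALSE)
  }
  donor_det <- is_detected(det_lookup(detection, genome_id, ss$transplant),
                           thresholds)
  if (!donor_det) {
    return(call_row("not_applicable", "not_detected_in_transplant_sample"))
  }
  post_det <- any(is_detected(det_lookup(detection, genome_id, ss$post7),
                              thresholds))
  if (!post_det) {
    return(call_row("not_colonized", "no_post_fmt_detection"))
  }
  pre_det <- any(is_detected(det_lookup(detection, genome_id, ss$pre),
                             thresholds))
  if (!pre_det) {
    # nothing of this population existed pre-FMT: every donor
    # subpopulation is vacuously absent before transplant
    return(call_row("colonized", "absent_pre_fmt"))
  }
  donor_subpops <- subpops_in(subpops, genome_id, ss$transplant)
  pre_subpops <- subpops_in(subpops, genome_id, ss$pre)
  post_subpops <- subpops_in(subpops, genome_id, ss$post7)
  discriminating <- setdiff(donor_subpops, pre_subpops)
  discriminating <- intersect(discriminating, post_subpops)
  if (length(discriminating) > 0L) {
    return(call_row("colonized",
                    paste0("discriminating_subpopulation:",
                           paste(sort(discriminating), collapse = "+"))))
  }
  call_row("undetermined", "no_discriminating_subpopulation")
}

#' Phenotype every genome/recipient pair of a cohort
#'
#' @inheritParams assign_phenotype
#' @param genomes Genomes to phenotype; defaults to all rows of the
#'   detection table.
#' @return Data frame of colonization calls, one row per pair.
#' @export
colonization_calls <- function(detection, subpops, meta,
                               rules = colonization_rules(),
                               thresholds = detection_thresholds(),
                               genomes = NULL) {
  validate_sample_meta(meta)
  det <- if (inherits(detection, "detection_table")) detection$detection
         else detection
  if (is.null(genomes)) genomes <- rownames(det)
  recipients <- unique(meta$subject_id[meta$role == "recipient"])
  out <- list()
  for (g in genomes) {
    for (r in recipients) {
      out[[length(out) + 1L]] <-
        assign_phenotype(g, r, detection, subpops, meta, rules, thresholds)
    }
  }
  do.call(rbind, out)
}

#' Classify a genome as a good or poor colonizer
#'
#' A good colonizer is detected in the donor stool used for transplantation
#' and in the recipient more than 7 days post-FMT, in all recipients. A
#' poor colonizer is donor-detected but absent post-FMT in at least
#' `poor_min_recipients` recipients. The two labels are mutually exclusive
#' by construction.
#'
#' @param summary Data frame with one row per recipient and logical columns
#'   `donor_detected` and `post7_detected`.
#' @param rules A [colonization_rules].
#' @return `"good"`, `"poor"` or `"neither"`.
#' @export
classify_good_poor <- function(summary, rules = colonization_rules()) {
  stopifnot(is.data.frame(summary),
            all(c("donor_detected", "post7_detected") %in% names(summary)))
  if (nrow(summary) < rules$good_requires_all_recipients) {
    stop("good/poor classification needs summaries for at least ",
         rules$good_requires_all_recipients, " recipients, got ",
         nrow(summary), call. = FALSE)
  }
  n_fail <- sum(summary$donor_detected & !summary$post7_detected)
  good <- all(summary$donor_detected & summary$post7_detected)
  poor <- n_fail >= rules$poor_min_recipients
  if (good && poor) {
    stop("internal error: genome classified both good and poor",
         call. = FALSE) # unreachable: good forbids any failure
  }
  if (good) "good" else if (poor) "poor" else "neither"
}

#' Per-recipient detection summary for one genome
#'
#' @param genome_id Genome to summarize.
#' @param detection A [detection_table] or detection matrix.
#' @param meta Sample metadata.
#' @param rules A [colonization_rules].
#' @param thresholds A [detection_thresholds].
#' @return Data frame with columns `recipient_id`, `donor_detected`,
#'   `post7_detected` (one row per recipient).
#' @export
good_poor_summary <- function(genome_id, detection, meta,
                              rules = colonization_rules(),
                              thresholds = detection_thresholds()) {
  validate_sample_meta(meta)
  recipients <- unique(meta$subject_id[meta$role == "recipient"])
  rows <- lapply(recipients, function(r) {
    ss <- recipient_samples(meta, r, rules)
    data.frame(
      recipient_id = r,
      donor_detected = is_detected(
        det_lookup(detection, genome_id, ss$transplant), thresholds),
      post7_detected = any(is_detected(
        det_lookup(detection, genome_id, ss$post7), thresholds)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify every genome of a cohort as good/poor/neither
#'
#' @inheritParams good_poor_summary
#' @param genomes Genomes to classify; defaults to all rows of the
#'   detection table.
#' @return Data frame with columns `genome_id`, `label`.
#' @export
classify_cohort <- function(detection, meta, rules = colonization_rules(),
                            thresholds = detection_thresholds(),
                            genomes = NULL) {
  det <- if (inherits(detection, "detection_table")) detection$detection
         else detection
  if (is.null(genomes)) genomes <- rownames(det)
  labels <- vapply(genomes, function(g) {
    classify_good_poor(good_poor_summary(g, detection, meta, rules,
                                         thresholds), rules)
  }, character(1))
  data.frame(genome_id = genomes, label = unname(labels),
             stringsAsFactors = FALSE)
}

#' Select the most prevalent representatives of a genome set
#'
#' Used to reduce the good-colonizer set to the size of the poor-colonizer
#' set before enrichment, keeping the genomes most prevalent in a reference
#' metagenome collection. Ties at the cutoff are broken by lexicographic
#' genome id.
#'
#' @param good_set Character vector of genome ids.
#' @param prevalence_ref Named numeric vector of prevalences covering
#'   `good_set`.
#' @param n_target Number of genomes to retain.
#' @return Character vector of `n_target` genome ids, most prevalent first.
#' @export
select_representatives <- function(good_set, prevalence_ref, n_target) {
  if (n_target > length(good_set)) {
    stop("n_target (", n_target, ") exceeds the number of candidate ",
         "genomes (", length(good_set), ")", call. = FALSE)
  }
  missing <- setdiff(good_set, names(prevalence_ref))
  if (length(missing) > 0L) {
    stop("no prevalence for genome(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(-prevalence_ref[good_set], good_set)
  good_set[ord][seq_len(n_target)]
}

#' Logistic regression of colonization outcome on prevalence and dose
#'
#' Fits one joint binomial GLM of the binary colonization outcome on all
#' supplied predictors (standardized to unit variance) and reports a Wald
#' test per predictor.
#'
#' @param outcomes Binary vector (0/1 or logical), one per
#'   genome/recipient pair.
#' @param predictors Data frame of numeric predictors (e.g. `prevalence`,
#'   `donor_dose`), same length as `outcomes`.
#' @return Data frame with columns `predictor`, `slope`, `se`, `z`,
#'   `p_value`.
#' @export
colonization_regression <- function(outcomes, predictors) {
  y <- as.numeric(outcomes)
  stopifnot(is.data.frame(predictors), nrow(predictors) == length(y))
  if (!all(y %in% c(0, 1))) {
    stop("outcomes must be binary (0/1)", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("outcomes must include both classes", call. = FALSE)
  }
  if (!all(vapply(predictors, is.numeric, logical(1))) ||
      !all(vapply(predictors, function(p) all(is.finite(p)), logical(1)))) {
    stop("predictors must be finite numeric", call. = FALSE)
  }
  sds <- vapply(predictors, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant predictor(s): ",
         paste(names(predictors)[sds == 0], collapse = ", "), call. = FALSE)
  }
  dat <- as.data.frame(scale(predictors))
  dat$.y <- y
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  coefs <- summary(fit)$coefficients
  slopes <- coefs[-1, 1]
  if (!fit$converged || (sep_warning && max(abs(slopes)) > 10)) {
    stop(structure(
      class = c("mindep_separation_error", "error", "condition"),
      list(message = paste0(
        "complete or quasi-complete separation detected; Wald estimates ",
        "are not reliable"), call = NULL)))
  }
  data.frame(predictor = rownames(coefs)[-1],
             slope = coefs[-1, 1],
             se = coefs[-1, 2],
             z = coefs[-1, 3],
             p_value = coefs[-1, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}
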