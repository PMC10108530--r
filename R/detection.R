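# Read-recruitment detection: the fraction of a genome's nucleotide
# positions covered by at least one mapped read. Mean coverage alone cannot
# separate low-abundance populations from non-target read recruitment to
# conserved regions, so presence calls use detection with an inclusive
# threshold (default 0.25, where the bimodal present/absent pattern of real
# read-recruitment results separates cleanly).

#' Detection and coverage thresholds
#'
#' @param detection_min Minimum detection value (inclusive) for a genome to
#'   count as detected in a metagenome. Default 0.25.
#' @param scg_coverage_min Minimum mean non-outlier coverage of single-copy
#'   core genes (inclusive) for strain-level subpopulation evidence to be
#'   considered reliable. Default 10.
#' @return A `detection_thresholds` list.
#' @export
detection_thresholds <- function(detection_min = 0.25, scg_coverage_min = 10) {
  stopifnot(is.numeric(detection_min), detection_min >= 0, detection_min <= 1,
            is.numeric(scg_coverage_min), scg_coverage_min >= 0)
  structure(list(detection_min = detection_min,
                 scg_coverage_min = scg_coverage_min),
            class = "detection_thresholds")
}

#' Detection value of a per-nucleotide coverage vector
#'
#' @param cov Integer/numeric vector of per-nucleotide coverages (>= 0).
#' @return Proportion of positions covered by at least one read, in `[0, 1]`.
#' @examples
#' detection_value(c(0, 0, 1, 2))
#' @export
detection_value <- function(cov) {
  if (length(cov) == 0L) {
    stop("coverage vector must be non-empty", call. = FALSE)
  }
  if (!is.numeric(cov) || any(is.na(cov)) || any(cov < 0)) {
    stop("coverage values must be non-negative numbers", call. = FALSE)
  }
  mean(cov >= 1)
}

#' Is a genome detected in a metagenome?
#'
#' @param d Detection value(s) in `[0, 1]`.
#' @param thresholds A [detection_thresholds]; the comparison is inclusive
#'   ("at least").
#' @return Logical vector.
#' @export
is_detected <- function(d, thresholds = detection_thresholds()) {
  if (any(is.na(d)) || any(d < 0) || any(d > 1)) {
    stop("detection values must be in [0, 1]", call. = FALSE)
  }
  d >= thresholds$detection_min
}

#' Mean coverage in the 2nd and 3rd quartiles (interquartile mean)
#'
#' Sorts the values and drops the `floor(n/4)` lowest and `floor(n/4)`
#' highest before averaging; a deterministic, outlier-robust coverage
#' summary.
#'
#' @param values Numeric vector of coverage values, length >= 4.
#' @return Mean of the central half.
#' @examples
#' q2q3_mean(1:8) # 4.5
#' @export
q2q3_mean <- function(values) {
  n <- length(values)
  if (n < 4L) {
    stop("q2q3_mean needs at least 4 values, got ", n, call. = FALSE)
  }
  if (!is.numeric(values) || any(is.na(values))) {
    stop("coverage values must be numeric and non-missing", call. = FALSE)
  }
  k <- floor(n / 4)
  s <- sort(values)
  mean(s[(k + 1L):(n - k)])
}

#' Assemble a detection table
#'
#' @param detection Numeric matrix of detection values in `[0, 1]`; rows are
#'   genomes, columns are samples (both with dimnames).
#' @param q2q3_mean_coverage Optional matrix (same shape) of interquartile
#'   mean coverages.
#' @param scg_coverage Optional matrix (same shape) of mean non-outlier
#'   single-copy core gene coverages.
#' @return A `detection_table` list.
#' @export
detection_table <- function(detection, q2q3_mean_coverage = NULL,
                            scg_coverage = NULL) {
  stopifnot(is.matrix(detection), !is.null(rownames(detection)),
            !is.null(colnames(detection)))
  if (any(is.na(detection)) || any(detection < 0) || any(detection > 1)) {
    stop("detection values must be in [0, 1]", call. = FALSE)
  }
  check_shape <- function(m, what) {
    if (!is.null(m)) {
      stopifnot(is.matrix(m))
      if (!identical(dimnames(m), dimnames(detection))) {
        stop(what, " matrix must share the detection matrix dimnames",
             call. = FALSE)
      }
      if (any(is.na(m)) || any(m < 0)) {
        stop(what, " values must be non-negative", call. = FALSE)
      }
    }
    m
  }
  structure(list(detection = detection,
                 q2q3_mean_coverage = check_shape(q2q3_mean_coverage,
                                                  "q2q3 coverage"),
                 scg_coverage = check_shape(scg_coverage, "SCG coverage")),
            class = "detection_table")
}

det_lookup <- function(table, genome_id, sample_id) {
  det <- if (inherits(table, "detection_table")) table$detection else table
  if (!genome_id %in% rownames(det)) {
    stop("genome '", genome_id, "' not in detection table", call. = FALSE)
  }
  missing <- setdiff(sample_id, colnames(det))
  if (length(missing) > 0L) {
    stop("sample(s) not in detection table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  det[genome_id, sample_id]
}

#' Prevalence of a genome across a sample collection
#'
#' @param genome_id Genome identifier (row of the detection table).
#' @param group Character vector of sample ids forming the collection
#'   (e.g. all healthy adult metagenomes from one country).
#' @param table A [detection_table] or a genomes-by-samples detection matrix.
#' @param thresholds A [detection_thresholds].
#' @return Fraction of the group's samples in which the genome is detected,
#'   in `[0, 1]`.
#' @export
prevalence <- function(genome_id, group, table,
                       thresholds = detection_thresholds()) {
  if (length(group) == 0L) {
    stop("sample group must be non-empty", call. = FALSE)
  }
  mean(is_detected(det_lookup(table, genome_id, group), thresholds))
}
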