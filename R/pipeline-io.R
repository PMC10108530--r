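# Readers, writers and end-to-end orchestration. All tables are
# tab-separated UTF-8 with a header row; output files carry '# '-prefixed
# comment lines recording the tool version, seed and a config fingerprint,
# and every reader skips such lines.

mindep_version <- function() {
  as.character(utils::packageVersion("mindep"))
}

config_fingerprint <- function(config) {
  s <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(cumsum(as.numeric(utf8ToInt(s)))) %% 2^31)
}

tsv_header_comment <- function(seed = NA, config = NULL) {
  c(paste0("# mindep ", mindep_version()),
    paste0("# seed: ", seed),
    paste0("# config_hash: ",
           if (is.null(config)) "none" else config_fingerprint(config)))
}

#' Write a data frame as a commented TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @param seed,config Run provenance recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, seed = NA, config = NULL) {
  is_num <- vapply(x, is.numeric, logical(1)) &
    !vapply(x, is.integer, logical(1))
  x[is_num] <- lapply(x[is_num], function(v) sprintf("%.4f", v))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(tsv_header_comment(seed, config), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a (possibly commented) TSV into a data frame
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a genomes-by-samples (or genomes-by-modules) matrix as TSV
#'
#' Row names go into a leading `item` column; numeric cells use a fixed
#' 4-decimal rendering.
#'
#' @inheritParams write_tsv
#' @param mat Numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(mat, path, seed = NA, config = NULL) {
  df <- data.frame(item = rownames(mat),
                   as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, seed = seed, config = config)
}

#' Read a matrix written by [write_matrix_tsv]
#'
#' @param path Input path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mode(mat) <- "numeric"
  mat
}

#' Read module definitions from a KEGG-style flat file
#'
#' Records are separated by `///` lines; each record needs `ENTRY` and
#' `DEFINITION` keys (continuation lines indented with spaces are folded
#' into the preceding key). `CLASS` strings are split on `"; "` into
#' category lists.
#'
#' @param path Flat-file path.
#' @return Data frame with columns `module_id`, `name`, `definition`,
#'   `class`; the `categories` attribute holds the split class lists.
#' @export
read_module_flatfile <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(trimws(lines)) == 0L || all(trimws(lines) == "")) {
    stop("empty module flat file: ", path, call. = FALSE)
  }
  records <- list()
  current <- character(0)
  current_start <- 1L
  flush <- function(rec, start_line) {
    if (length(rec) == 0L) return(NULL)
    keys <- list()
    last_key <- NULL
    for (k in seq_along(rec)) {
      line <- rec[k]
      if (grepl("^\\s", line)) {
        if (is.null(last_key)) {
          stop("malformed record starting at line ", start_line,
               ": continuation line without a key", call. = FALSE)
        }
        keys[[last_key]] <- paste(keys[[last_key]], trimws(line))
      } else {
        key <- sub("\\s.*$", "", line)
        val <- trimws(sub("^\\S+\\s*", "", line))
        keys[[key]] <- if (is.null(keys[[key]])) val
                       else paste(keys[[key]], val)
        last_key <- key
      }
    }
    if (is.null(keys$ENTRY)) {
      stop("record starting at line ", start_line, " has no ENTRY",
           call. = FALSE)
    }
    entry <- strsplit(keys$ENTRY, "\\s+")[[1]][1]
    if (is.null(keys$DEFINITION)) {
      stop("record '", entry, "' (line ", start_line,
           ") has no DEFINITION", call. = FALSE)
    }
    data.frame(module_id = entry,
               name = if (is.null(keys$NAME)) NA_character_ else keys$NAME,
               definition = keys$DEFINITION,
               class = if (is.null(keys$CLASS)) NA_character_
                       else keys$CLASS,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_along(lines)) {
    if (trimws(lines[i]) == "///") {
      rec <- flush(current, current_start)
      if (!is.null(rec)) out[[length(out) + 1L]] <- rec
      current <- character(0)
      current_start <- i + 1L
    } else if (nzchar(trimws(lines[i])) || length(current) > 0L) {
      current <- c(current, lines[i])
    }
  }
  rec <- flush(current, current_start)
  if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  if (length(out) == 0L) {
    stop("no module records in ", path, call. = FALSE)
  }
  df <- do.call(rbind, out)
  attr(df, "categories") <- lapply(stats::setNames(df$class, df$module_id),
                                   function(cl) {
                                     if (is.na(cl)) character(0)
                                     else trimws(strsplit(cl, ";")[[1]])
                                   })
  df
}

#' Write module definitions as a KEGG-style flat file
#'
#' @param definitions Data frame with `module_id`, `definition` and
#'   optionally `name` and `class` columns.
#' @param path Output path.
#' @export
write_module_flatfile <- function(definitions, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(definitions))) {
    writeLines(c(
      sprintf("ENTRY       %s", definitions$module_id[i]),
      if (!is.null(definitions$name))
        sprintf("NAME        %s", definitions$name[i]),
      sprintf("DEFINITION  %s", definitions$definition[i]),
      if (!is.null(definitions$class))
        sprintf("CLASS       %s", definitions$class[i]),
      "///"), con)
  }
  invisible(path)
}

#' Read a two-column module definition TSV
#'
#' @param path TSV with columns `module_id` and `definition`.
#' @return Data frame.
#' @export
read_module_tsv <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(c("module_id", "definition"), names(df))
  if (length(missing) > 0L) {
    stop("module TSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a genome KO-annotation TSV
#'
#' @param path TSV with a header including `genome` and `ko` (extra
#'   columns such as `gene_callers_id` or `e_value` are carried along but
#'   unused).
#' @return Data frame.
#' @export
read_ko_annotations <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(c("genome", "ko"), names(df))
  if (length(missing) > 0L) {
    stop("KO annotation TSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

parse_definitions_df <- function(definitions) {
  parsed <- lapply(seq_len(nrow(definitions)), function(i) {
    parse_definition(definitions$module_id[i], definitions$definition[i])
  })
  stats::setNames(parsed, definitions$module_id)
}

#' Run the full FMT colonization / enrichment / metabolic-independence
#' analysis
#'
#' Stages, in order: detection-based colonization phenotyping of every
#' genome/recipient pair; good/poor colonizer classification; reduction of
#' the good set to the size of the poor set by reference prevalence;
#' genome-by-module pathwise completeness; module enrichment between good
#' and poor representatives; metabolic-independence scoring of every
#' genome over the enriched module set; and a logistic regression of
#' colonization outcome on reference prevalence and donor dose.
#'
#' @param cohort A cohort as produced by [gen_fmt_cohort] (detection table
#'   with SCG/interquartile coverages, subpopulation table, sample
#'   metadata, reference detection matrix).
#' @param annotations Long KO annotation table (`genome`, `ko`).
#' @param definitions Module definition table (`module_id`, `definition`,
#'   optional `category`).
#' @param rules A [colonization_rules].
#' @param thresholds A [detection_thresholds].
#' @param criteria An [enrichment_criteria].
#' @param config A [mi_config].
#' @param policy A [moddef_policy].
#' @return List with `calls`, `classification`, `representatives`,
#'   `completeness`, `enrichment`, `enriched`, `module_set`, `mi_scores`,
#'   `group_test`, `regression` and a `summary` list echoing thresholds
#'   and per-stage counts.
#' @export
run_fmt_analysis <- function(cohort, annotations, definitions,
                             rules = colonization_rules(),
                             thresholds = detection_thresholds(),
                             criteria = enrichment_criteria(),
                             config = mi_config(),
                             policy = moddef_policy()) {
  coverage_ok <- cohort$detection$scg_coverage >= rules$scg_coverage_min
  subpops <- filter_subpopulations(cohort$subpops, rules, coverage_ok)
  calls <- colonization_calls(cohort$detection, subpops, cohort$meta,
                              rules, thresholds)
  classification <- classify_cohort(cohort$detection, cohort$meta, rules,
                                    thresholds)
  good <- classification$genome_id[classification$label == "good"]
  poor <- classification$genome_id[classification$label == "poor"]
  if (length(good) == 0L || length(poor) == 0L) {
    stop("stage good/poor classification: need both good and poor ",
         "colonizers (got ", length(good), " good, ", length(poor),
         " poor)", call. = FALSE)
  }
  prev <- vapply(rownames(cohort$ref_detection), function(g) {
    prevalence(g, colnames(cohort$ref_detection), cohort$ref_detection,
               thresholds)
  }, numeric(1))
  representatives <- select_representatives(
    good, prev, min(length(good), length(poor)))

  registry <- parse_definitions_df(definitions)
  keep <- c(representatives, poor)
  ann <- annotations[annotations$genome %in% keep, , drop = FALSE]
  missing <- setdiff(keep, unique(ann$genome))
  if (length(missing) > 0L) {
    stop("stage completeness: no KO annotations for genome(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  genomes <- annotations_from_table(ann)[keep]
  completeness <- completeness_matrix(genomes, registry[definitions$module_id],
                                      registry, policy)
  groups <- stats::setNames(ifelse(keep %in% representatives, "good",
                                   "poor"), keep)
  enrichment <- enrichment_test(completeness, groups, criteria)
  enriched <- enriched_modules(enrichment, completeness, groups, criteria)

  categories <- if ("category" %in% names(definitions)) {
    lapply(stats::setNames(definitions$category, definitions$module_id),
           function(x) x)
  } else NULL
  good_set_ids <- enriched[["good"]]
  mset <- module_set(good_set_ids,
                     categories = if (!is.null(categories) &&
                                        length(good_set_ids) > 0L) {
                       categories[good_set_ids]
                     } else NULL)
  scores <- if (length(good_set_ids) > 0L) {
    mi_score(completeness, set = mset, config = config)
  } else NULL
  group_test <- if (!is.null(scores)) {
    group_compare(scores$score[groups[scores$genome_id] == "good"],
                  scores$score[groups[scores$genome_id] == "poor"])
  } else NULL

  usable <- calls[calls$outcome %in% c("colonized", "not_colonized"), ]
  meta_rec <- cohort$meta[cohort$meta$role == "recipient", ]
  transplant_of <- stats::setNames(meta_rec$transplant_sample,
                                   meta_rec$subject_id)[
                                     !duplicated(meta_rec$subject_id)]
  dose <- mapply(function(g, r) {
    cohort$detection$q2q3_mean_coverage[g, transplant_of[[r]]]
  }, usable$genome_id, usable$recipient_id)
  regression <- colonization_regression(
    usable$outcome == "colonized",
    data.frame(prevalence = unname(prev[usable$genome_id]),
               donor_dose = unname(dose)))

  list(calls = calls, classification = classification,
       representatives = representatives, completeness = completeness,
       enrichment = enrichment, enriched = enriched, module_set = mset,
       mi_scores = scores, group_test = group_test,
       regression = regression,
       summary = list(
         n_pairs = nrow(calls),
         n_outcomes = as.list(table(calls$outcome)),
         n_good = length(good), n_poor = length(poor),
         n_representatives = length(representatives),
         n_modules = nrow(definitions),
         n_enriched_good = length(good_set_ids),
         thresholds = thresholds, rules = rules, criteria = criteria,
         mi_config = config))
}

map_columns <- function(df, column_map) {
  if (is.null(column_map)) return(df)
  for (std in names(column_map)) {
    if (std %in% names(df)) next # already using the standard header
    actual <- column_map[[std]]
    if (!actual %in% names(df)) {
      stop("mapped column '", actual, "' (for '", std,
           "') not found", call. = FALSE)
    }
    names(df)[names(df) == actual] <- std
  }
  df
}

long_to_matrix <- function(df) {
  genomes <- unique(df$genome)
  modules <- unique(df$module)
  mat <- matrix(NA_real_, length(genomes), length(modules),
                dimnames = list(genomes, modules))
  mat[cbind(match(df$genome, genomes), match(df$module, modules))] <-
    df$completeness
  if (any(is.na(mat))) {
    stop("module completeness table does not cover the full ",
         "genome x module grid", call. = FALSE)
  }
  mat
}

#' Recompute headline group statistics from supplementary-style tables
#'
#' Takes two long-format tables (tab-separated, `#` comments allowed). The
#' first describes the FMT-derived high/low metabolic independence (HMI /
#' LMI) genomes, the second genomes from healthy and IBD individuals.
#' Required columns (renameable via `column_map`): `genome`, `group`,
#' `module`, `completeness`, and optionally `genome_length_bp`,
#' `completion_pct`, `category`. Recomputed quantities: per-group genome
#' counts, mean genome size (Mbp) and completion, the number of enriched
#' modules between the first table's two groups, category percentages of
#' the enriched set, per-group mean module completeness, and Wilcoxon
#' rank-sum comparisons of per-module group mean completeness (first
#' group of table 1 vs each group of table 2).
#'
#' @param supp_fmt_path,supp_ibd_path Paths to the two tables.
#' @param criteria An [enrichment_criteria].
#' @param column_map Optional named character vector mapping the standard
#'   column names above to the actual headers.
#' @return List with `report` (data frame `quantity`, `value`) and
#'   `enrichment` (the full per-module test table).
#' @export
run_supplementary_reproduction <- function(supp_fmt_path, supp_ibd_path,
                                           criteria = enrichment_criteria(),
                                           column_map = NULL) {
  fmt <- map_columns(read_tsv(supp_fmt_path), column_map)
  ibd <- map_columns(read_tsv(supp_ibd_path), column_map)
  for (nm in c("genome", "group", "module", "completeness")) {
    if (!nm %in% names(fmt) || !nm %in% names(ibd)) {
      stop("supplementary table is missing column '", nm, "'",
           call. = FALSE)
    }
  }
  report <- list()
  add <- function(quantity, value) {
    report[[length(report) + 1L]] <<-
      data.frame(quantity = quantity, value = value,
                 stringsAsFactors = FALSE)
  }
  per_genome <- function(df) df[!duplicated(df$genome), , drop = FALSE]
  for (tab in list(list(df = fmt, tag = "fmt"),
                   list(df = ibd, tag = "ibd"))) {
    info <- per_genome(tab$df)
    for (g in sort(unique(info$group))) {
      sel <- info[info$group == g, ]
      add(paste0(tab$tag, "_n_genomes_", g), nrow(sel))
      if ("genome_length_bp" %in% names(sel)) {
        add(paste0(tab$tag, "_mean_genome_size_mbp_", g),
            mean(sel$genome_length_bp) / 1e6)
      }
      if ("completion_pct" %in% names(sel)) {
        add(paste0(tab$tag, "_mean_completion_pct_", g),
            mean(sel$completion_pct))
      }
    }
  }
  mat <- long_to_matrix(fmt)
  groups <- stats::setNames(per_genome(fmt)$group, per_genome(fmt)$genome)
  enr <- enrichment_test(mat, groups, criteria)
  sets <- enriched_modules(enr, mat, groups, criteria)
  for (g in names(sets)) add(paste0("fmt_n_enriched_", g), length(sets[[g]]))
  top_group <- names(sets)[which.max(vapply(sets, length, integer(1)))]
  enriched_ids <- sets[[top_group]]
  if ("category" %in% names(fmt) && length(enriched_ids) > 0L) {
    cats <- fmt$category[match(enriched_ids, fmt$module)]
    for (ct in sort(unique(cats))) {
      add(paste0("enriched_pct_", gsub("[^A-Za-z0-9]+", "_", tolower(ct))),
          100 * sum(cats == ct) / length(enriched_ids))
    }
  }
  # per-module group means over the enriched set (falls back to every
  # shared module when no module passes enrichment)
  mod_ids <- if (length(enriched_ids) > 0L) enriched_ids
             else colnames(mat)
  mat_ibd <- long_to_matrix(ibd)
  shared <- intersect(mod_ids, colnames(mat_ibd))
  groups_ibd <- stats::setNames(per_genome(ibd)$group,
                                per_genome(ibd)$genome)
  mean_by_group <- function(m, grp, g) {
    colMeans(m[names(grp)[grp == g], , drop = FALSE])
  }
  ref <- mean_by_group(mat[, shared, drop = FALSE], groups, top_group)
  add(paste0("fmt_mean_module_completeness_", top_group), mean(ref))
  for (g in sort(unique(groups_ibd))) {
    other <- mean_by_group(mat_ibd[, shared, drop = FALSE], groups_ibd, g)
    add(paste0("ibd_mean_module_completeness_", g), mean(other))
    ht <- group_compare(ref, other)
    add(paste0("wilcoxon_p_", top_group, "_vs_", g), ht$p_value)
    add(paste0("wilcoxon_W_", top_group, "_vs_", g), ht$statistic)
  }
  list(report = do.call(rbind, report), enrichment = enr)
}

#' Write a synthetic cohort to a self-contained directory
#'
#' @param cohort Output of [gen_fmt_cohort].
#' @param dir Output directory (created if needed).
#' @param definitions Optional module definition table to include as a
#'   flat file.
#' @param annotations Optional KO annotation table.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, definitions = NULL,
                         annotations = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- cohort$config
  seed <- cfg$seed
  write_matrix_tsv(cohort$detection$detection,
                   file.path(dir, "detection.tsv"), seed, cfg)
  write_matrix_tsv(cohort$detection$scg_coverage,
                   file.path(dir, "scg_coverage.tsv"), seed, cfg)
  write_matrix_tsv(cohort$detection$q2q3_mean_coverage,
                   file.path(dir, "q2q3_coverage.tsv"), seed, cfg)
  write_matrix_tsv(cohort$ref_detection,
                   file.path(dir, "reference_detection.tsv"), seed, cfg)
  write_tsv(cohort$subpops, file.path(dir, "subpopulations.tsv"), seed, cfg)
  write_tsv(cohort$meta, file.path(dir, "sample_metadata.tsv"), seed, cfg)
  if (!is.null(definitions)) {
    write_module_flatfile(definitions,
                          file.path(dir, "module_definitions.txt"))
  }
  if (!is.null(annotations)) {
    write_tsv(annotations, file.path(dir, "ko_annotations.tsv"), seed, cfg)
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
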