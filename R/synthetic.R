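# Deterministic synthetic inputs with the statistical structure the
# analysis assumes: module definitions exercising the full grammar, genome
# annotations with group-differential planted modules, and an FMT cohort
# with planted colonization outcomes, bimodal detection, and strain-level
# subpopulation structure. Each generator re-seeds its own RNG stream from
# the config seed, so outputs are byte-identical across runs and platforms.

#' Configuration of the synthetic-data generators
#'
#' Defaults mirror the study conditions the analysis is built for: 443
#' modules of which 33 are planted with a group-differential occurrence
#' (0.95 in good colonizers vs 0.10 in poor colonizers), 20 genomes per
#' group, five FMT recipients sampled before transplant and at days 7, 30,
#' 90 and 180 after it.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_modules Total module count. Default 443.
#' @param n_planted Number of planted (group-differential) modules.
#'   Default 33.
#' @param n_genomes_per_group Genomes per group for annotation generation.
#'   Default 20.
#' @param occurrence_probs Named probabilities `good` and `poor` that a
#'   group member carries a full path of a planted module.
#'   Defaults `c(good = 0.95, poor = 0.10)`.
#' @param background_prob Shared full-path probability for non-planted
#'   modules in both groups. Default 0.5.
#' @param kos_per_module Range (min, max) of distinct KOs per module.
#'   Default `c(3, 8)`.
#' @param detection_mixture List with `present_mean`, `absent_mean` and
#'   `concentration`: detection values are Beta draws around the present
#'   (default 0.9) or absent (default 0.02) mode. Absence is sampled near
#'   but not exactly 0, so the 0.25 threshold is genuinely exercised;
#'   concentration 150 keeps the two modes well separated (sd ~ 0.03).
#' @param n_recipients Recipients per donor. Default 5.
#' @param pre_fmt_day Day of the baseline recipient sample. Default -1.
#' @param post_fmt_days Post-FMT sampling days. Default
#'   `c(7, 30, 90, 180)`; day 7 deliberately sits on the "more than 7
#'   days" boundary and never counts as post-FMT evidence.
#' @param n_good_colonizers,n_poor_colonizers,n_neither Planted genome
#'   counts per colonization class. Defaults 20, 20, 6.
#' @param n_special Genomes per special decision branch (discriminating
#'   subpopulation, pre-FMT presence, low coverage, sub-1\%
#'   subpopulation, not in donor). Default 2.
#' @param n_reference_samples Size of the reference (global) metagenome
#'   collection used for prevalence. Default 50.
#' @param reference_prevalence Named probabilities that a genome of each
#'   class is present in a reference sample.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_modules = 443L,
                       n_planted = 33L,
                       n_genomes_per_group = 20L,
                       occurrence_probs = c(good = 0.95, poor = 0.10),
                       background_prob = 0.5,
                       kos_per_module = c(3L, 8L),
                       detection_mixture = list(present_mean = 0.9,
                                                absent_mean = 0.02,
                                                concentration = 150),
                       n_recipients = 5L,
                       pre_fmt_day = -1L,
                       post_fmt_days = c(7L, 30L, 90L, 180L),
                       n_good_colonizers = 20L,
                       n_poor_colonizers = 20L,
                       n_neither = 6L,
                       n_special = 2L,
                       n_reference_samples = 50L,
                       reference_prevalence = c(good = 0.8, poor = 0.15,
                                                other = 0.4)) {
  stopifnot(seed == as.integer(seed), n_modules >= 1,
            n_planted >= 0, n_planted <= n_modules,
            n_genomes_per_group >= 1,
            all(occurrence_probs >= 0), all(occurrence_probs <= 1),
            background_prob >= 0, background_prob <= 1,
            length(kos_per_module) == 2, kos_per_module[1] >= 1,
            kos_per_module[2] >= kos_per_module[1],
            detection_mixture$present_mean > detection_mixture$absent_mean,
            n_recipients >= 1, pre_fmt_day < 0,
            all(post_fmt_days >= 0))
  structure(as.list(environment()), class = "sim_config")
}

beta_draw <- function(n, mean, concentration) {
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

# KO accessions are allocated from disjoint per-module pools so module
# completeness signals never bleed into each other.
ko_pool <- function(start, n) sprintf("K%05d", seq.int(start, length.out = n))

random_definition <- function(kos, allow_gap, nest_id = NULL) {
  # consume the module's KO pool across 2-4 steps covering the grammar
  steps <- character(0)
  i <- 1L
  while (i <= length(kos)) {
    remaining <- length(kos) - i + 1L
    kind <- sample(c("atom", "alts", "complex"), 1L,
                   prob = c(0.45, 0.3, 0.25))
    if (kind == "alts" && remaining >= 2L) {
      take <- min(remaining, sample(2:3, 1L))
      branch_kos <- kos[seq.int(i, length.out = take)]
      if (take == 3L && stats::runif(1) < 0.5) {
        # one branch is a two-step sequence
        steps <- c(steps, paste0("(", branch_kos[1], ",(", branch_kos[2],
                                 " ", branch_kos[3], "))"))
      } else {
        steps <- c(steps, paste0("(", paste(branch_kos, collapse = ","),
                                 ")"))
      }
      i <- i + take
    } else if (kind == "complex" && remaining >= 2L) {
      take <- min(remaining, sample(2:3, 1L))
      comp_kos <- kos[seq.int(i, length.out = take)]
      ops <- c("", ifelse(stats::runif(take - 1L) < 0.25, "-", "+"))
      steps <- c(steps, paste0(paste0(ops, comp_kos), collapse = ""))
      i <- i + take
    } else {
      steps <- c(steps, kos[i])
      i <- i + 1L
    }
  }
  if (allow_gap && stats::runif(1) < 0.15) steps <- c(steps, "--")
  if (!is.null(nest_id)) steps <- c(nest_id, steps)
  paste(steps, collapse = " ")
}

#' Generate synthetic module definitions
#'
#' Definitions exercise every grammar feature: sequential steps,
#' alternatives (including branches that are multi-step sequences), enzyme
#' complexes with essential and non-essential subunits, `--` gap steps, and
#' one level of nested module references. Planted (group-differential)
#' modules are generated without gaps or nesting so a fully annotated path
#' reaches completeness 1 under the conservative gap policy.
#'
#' @param cfg A [sim_config].
#' @return Data frame with columns `module_id`, `definition`, `class`
#'   (a `"Pathway modules; <category>"` string), `category` and `planted`.
#' @export
gen_module_definitions <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_modules
  ids <- sprintf("M%05d", seq_len(n))
  planted <- rep(FALSE, n)
  planted[sample.int(n, cfg$n_planted)] <- TRUE
  categories <- c("Amino acid metabolism", "Vitamin and cofactor metabolism",
                  "Carbohydrate metabolism", "Nucleotide metabolism",
                  "Lipid metabolism", "Energy metabolism")
  # planted modules skew toward biosynthesis of amino acids and cofactors,
  # the signature of metabolically independent genomes
  cat_of <- ifelse(planted,
                   sample(categories, n, replace = TRUE,
                          prob = c(0.45, 0.22, 0.09, 0.12, 0.06, 0.06)),
                   sample(categories, n, replace = TRUE))
  n_kos <- sample(seq.int(cfg$kos_per_module[1], cfg$kos_per_module[2]),
                  n, replace = TRUE)
  start <- cumsum(c(1L, n_kos[-n]))
  defs <- character(n)
  # a few non-planted modules nest a reference to an earlier non-planted,
  # gap-free plain module (one level of nesting)
  nest_candidates <- which(!planted)
  nested_hosts <- if (length(nest_candidates) > 40L) {
    sample(nest_candidates[nest_candidates > min(nest_candidates) + 5L], 20L)
  } else integer(0)
  for (i in seq_len(n)) {
    nest_id <- NULL
    if (i %in% nested_hosts) {
      target <- sample(nest_candidates[nest_candidates < i &
                                         !nest_candidates %in% nested_hosts],
                       1L)
      nest_id <- ids[target]
    }
    defs[i] <- random_definition(ko_pool(start[i], n_kos[i]),
                                 allow_gap = !planted[i], nest_id = nest_id)
  }
  data.frame(module_id = ids, definition = defs,
             class = paste("Pathway modules", cat_of, sep = "; "),
             category = cat_of, planted = planted,
             stringsAsFactors = FALSE)
}

module_path_kos <- function(defn, registry, policy = moddef_policy()) {
  paths <- enumerate_paths(defn, registry, policy)
  lapply(paths, function(path) {
    unique(unlist(lapply(path, function(step) {
      switch(step$type,
        atom = step$ko,
        complex = step$components$ko[step$components$essential],
        gap = character(0))
    })))
  })
}

#' Generate genome KO annotations with planted group structure
#'
#' For planted modules a genome receives the complete KO set of one random
#' path with its group's occurrence probability, otherwise a random strict
#' subset (at most half the path's KOs, keeping completeness below the
#' presence threshold). Non-planted modules use a shared background
#' probability in both groups.
#'
#' @param cfg A [sim_config].
#' @param definitions Output of [gen_module_definitions].
#' @param groups Optional named character vector mapping genome id to
#'   group (`"good"`, `"poor"`, or any other label). Genomes outside the
#'   good/poor groups draw planted modules at the background probability.
#'   Defaults to `n_genomes_per_group` genomes per group named
#'   `good_01`, ..., `poor_01`, ...
#' @return List with `annotations` (data frame: `genome`,
#'   `gene_callers_id`, `ko`), `groups` (named character vector genome ->
#'   group) and `truth` (the `definitions` frame, i.e. which modules are
#'   planted).
#' @export
gen_genome_annotations <- function(cfg = sim_config(),
                                   definitions = gen_module_definitions(cfg),
                                   groups = NULL) {
  set.seed(cfg$seed + 1L)
  parsed <- lapply(seq_len(nrow(definitions)), function(i) {
    parse_definition(definitions$module_id[i], definitions$definition[i])
  })
  registry <- stats::setNames(parsed, definitions$module_id)
  path_kos <- lapply(parsed, module_path_kos, registry = registry)
  if (is.null(groups)) {
    genomes <- c(sprintf("good_%02d", seq_len(cfg$n_genomes_per_group)),
                 sprintf("poor_%02d", seq_len(cfg$n_genomes_per_group)))
    groups <- stats::setNames(rep(c("good", "poor"),
                                  each = cfg$n_genomes_per_group), genomes)
  }
  genomes <- names(groups)
  rows <- vector("list", length(genomes))
  for (gi in seq_along(genomes)) {
    group <- groups[[gi]]
    kos <- character(0)
    for (mi in seq_len(nrow(definitions))) {
      p <- if (definitions$planted[mi] &&
                 group %in% names(cfg$occurrence_probs)) {
        unname(cfg$occurrence_probs[group])
      } else cfg$background_prob
      paths <- path_kos[[mi]]
      chosen <- paths[[sample.int(length(paths), 1L)]]
      if (length(chosen) == 0L) next
      if (stats::runif(1) < p) {
        kos <- c(kos, chosen)
      } else {
        keep <- floor(length(chosen) / 2)
        if (keep > 0L) kos <- c(kos, sample(chosen, keep))
      }
    }
    kos <- unique(kos)
    rows[[gi]] <- data.frame(genome = genomes[gi],
                             gene_callers_id = seq_along(kos),
                             ko = kos, stringsAsFactors = FALSE)
  }
  list(annotations = do.call(rbind, rows), groups = groups,
       truth = definitions)
}

#' Generate a synthetic FMT cohort with planted colonization outcomes
#'
#' Builds sample metadata for one donor and `n_recipients` recipients
#' (baseline sample pre-FMT, follow-up at the configured post-FMT days),
#' a genomes-by-samples detection table drawn from the bimodal
#' present/absent mixture, strain-level subpopulation profiles, single-copy
#' core gene coverages, a reference metagenome collection for prevalence,
#' and a truth table recording each genome's planted colonizer label and
#' each pair's expected phenotype. Every decision branch (donor absence,
#' post-FMT absence, vacuous pre-FMT absence, discriminating
#' subpopulation, shared pre-FMT subpopulation, sub-coverage evidence,
#' sub-1\% subpopulation) is planted at least once.
#'
#' @param cfg A [sim_config].
#' @return List with `detection` (a [detection_table] including SCG and
#'   interquartile mean coverages), `subpops`, `meta`, `ref_detection`,
#'   and `truth` (list of `labels` and `pairs` data frames).
#' @export
gen_fmt_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 2L)
  mix <- cfg$detection_mixture
  nr <- cfg$n_recipients
  recipients <- sprintf("R%02d", seq_len(nr))
  donor_samples <- sprintf("DA_S%02d", seq_len(nr))
  rec_meta <- do.call(rbind, lapply(seq_len(nr), function(i) {
    days <- c(cfg$pre_fmt_day, cfg$post_fmt_days)
    data.frame(sample_id = sprintf("%s_d%+04d", recipients[i], days),
               subject_id = recipients[i], role = "recipient",
               day_relative_to_fmt = days,
               donor_subject = "DA", transplant_sample = donor_samples[i],
               delivery = ifelse(i %% 2 == 0, "pill", "colonoscopy"),
               stringsAsFactors = FALSE)
  }))
  donor_meta <- data.frame(sample_id = donor_samples, subject_id = "DA",
                           role = "donor",
                           day_relative_to_fmt = seq(0, by = 30,
                                                     length.out = nr),
                           donor_subject = NA_character_,
                           transplant_sample = NA_character_,
                           delivery = NA_character_,
                           stringsAsFactors = FALSE)
  meta <- rbind(donor_meta, rec_meta)
  samples <- meta$sample_id
  pre_of <- function(r) rec_meta$sample_id[rec_meta$subject_id == r &
                                             rec_meta$day_relative_to_fmt < 0]
  post7_of <- function(r) {
    rec_meta$sample_id[rec_meta$subject_id == r &
                         rec_meta$day_relative_to_fmt > 7]
  }

  classes <- c(rep("good", cfg$n_good_colonizers),
               rep("poor", cfg$n_poor_colonizers),
               rep("neither", cfg$n_neither),
               rep("strain_colonizer", cfg$n_special),
               rep("und_pre", cfg$n_special),
               rep("und_cov", cfg$n_special),
               rep("und_sub", cfg$n_special),
               rep("not_in_donor", cfg$n_special))
  genomes <- sprintf("MAG_%03d", seq_along(classes))
  names(classes) <- genomes

  # presence[g, s]: whether the population truly exists in that sample
  presence <- matrix(FALSE, length(genomes), length(samples),
                     dimnames = list(genomes, samples))
  pair_truth <- list()
  for (g in genomes) {
    cls <- classes[[g]]
    if (cls != "not_in_donor") presence[g, donor_samples] <- TRUE
    fail_recipients <- switch(cls,
      poor = recipients,
      neither = sample(recipients, sample(1:2, 1L)),
      character(0))
    for (i in seq_len(nr)) {
      r <- recipients[i]
      pre <- pre_of(r)
      post <- rec_meta$sample_id[rec_meta$subject_id == r &
                                   rec_meta$day_relative_to_fmt >= 0]
      outcome <- "undetermined"
      if (cls == "not_in_donor") {
        outcome <- "not_applicable"
      } else if (r %in% fail_recipients) {
        outcome <- "not_colonized"
      } else if (cls %in% c("good", "poor", "neither")) {
        presence[g, post] <- TRUE # pre-FMT absent: vacuous colonization
        outcome <- "colonized"
      } else {
        presence[g, c(pre, post)] <- TRUE
        outcome <- switch(cls, strain_colonizer = "colonized",
                          "undetermined")
      }
      pair_truth[[length(pair_truth) + 1L]] <-
        data.frame(genome_id = g, recipient_id = r, outcome = outcome,
                   stringsAsFactors = FALSE)
    }
  }
  pair_truth <- do.call(rbind, pair_truth)

  draw <- function(present) {
    ifelse(present,
           beta_draw(length(present), mix$present_mean, mix$concentration),
           beta_draw(length(present), mix$absent_mean, mix$concentration))
  }
  detection <- matrix(draw(as.vector(presence)), nrow = nrow(presence),
                      dimnames = dimnames(presence))
  scg <- matrix(ifelse(as.vector(presence), stats::runif(length(presence),
                                                         20, 80),
                       stats::runif(length(presence), 0, 3)),
                nrow = nrow(presence), dimnames = dimnames(presence))
  scg[classes == "und_cov", ] <- 5 # below the 10X evidence floor
  q2q3 <- matrix(ifelse(as.vector(presence),
                        stats::rlnorm(length(presence), log(30), 0.5),
                        stats::runif(length(presence), 0, 0.5)),
                 nrow = nrow(presence), dimnames = dimnames(presence))

  # strain-level subpopulation profiles for cells where the population
  # exists; structure depends on the planted decision branch
  sp_rows <- list()
  add_sp <- function(g, s, ids, props) {
    sp_rows[[length(sp_rows) + 1L]] <<-
      data.frame(genome_id = g, subpop_id = ids, sample_id = s,
                 proportion = props, stringsAsFactors = FALSE)
  }
  for (g in genomes) {
    cls <- classes[[g]]
    for (s in samples[presence[g, ]]) {
      is_donor <- s %in% donor_samples
      is_pre <- s %in% rec_meta$sample_id[rec_meta$day_relative_to_fmt < 0]
      if (cls == "und_pre") {
        add_sp(g, s, paste0(g, "_s1"), 1)
      } else if (cls == "und_sub") {
        if (is_donor) {
          add_sp(g, s, paste0(g, c("_s1", "_s2")), c(0.995, 0.005))
        } else add_sp(g, s, paste0(g, "_s1"), 1)
      } else if (cls %in% c("strain_colonizer", "und_cov")) {
        if (is_pre) add_sp(g, s, paste0(g, "_s1"), 1)
        else add_sp(g, s, paste0(g, c("_s1", "_s2")), c(0.6, 0.4))
      } else {
        k <- sample(1:3, 1L)
        props <- stats::rgamma(k, shape = 2)
        add_sp(g, s, paste0(g, "_s", seq_len(k)), props / sum(props))
      }
    }
  }
  subpops <- do.call(rbind, sp_rows)

  ref_samples <- sprintf("REF_%03d", seq_len(cfg$n_reference_samples))
  ref_prob <- ifelse(classes %in% names(cfg$reference_prevalence),
                     cfg$reference_prevalence[classes],
                     cfg$reference_prevalence[["other"]])
  ref_presence <- matrix(stats::runif(length(genomes) *
                                        length(ref_samples)) <
                           rep(ref_prob, times = length(ref_samples)),
                         nrow = length(genomes),
                         dimnames = list(genomes, ref_samples))
  ref_detection <- matrix(draw(as.vector(ref_presence)),
                          nrow = nrow(ref_presence),
                          dimnames = dimnames(ref_presence))

  labels <- data.frame(
    genome_id = genomes,
    class = unname(classes),
    label = unname(ifelse(classes == "good", "good",
                   ifelse(classes == "poor", "poor",
                   ifelse(classes %in% c("neither", "not_in_donor"),
                          "neither", "good")))),
    stringsAsFactors = FALSE)
  # special-branch genomes are detected everywhere post-FMT, so their raw
  # detection-based label is "good"; their pair phenotypes differ

  list(detection = detection_table(detection, q2q3_mean_coverage = q2q3,
                                   scg_coverage = scg),
       subpops = subpops, meta = meta, ref_detection = ref_detection,
       ref_samples = ref_samples,
       truth = list(labels = labels, pairs = pair_truth),
       config = cfg)
}
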