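# Pathwise completeness: a module definition is unrolled into every
# alternative route ("path") through its steps; a genome's completeness for
# the module is the best path's mean per-step completeness.

#' Evaluation policy for module completeness
#'
#' @param gap How `--` gap steps (reactions with no KO) contribute:
#'   `"zero"` (default) counts them as always-absent steps, which caps the
#'   attainable completeness of modules containing them; `"exclude"` drops
#'   them from the path before averaging.
#' @param complex How enzyme complexes are scored: `"fractional"` (default)
#'   scores the fraction of essential subunits annotated; `"strict"` requires
#'   all essential subunits (all-or-nothing).
#' @param path_cap Maximum number of enumerated paths per definition before
#'   an explicit capacity error is raised (never silent truncation).
#' @param max_depth Maximum nesting depth when expanding nested module
#'   references.
#' @return A `moddef_policy` list.
#' @export
moddef_policy <- function(gap = c("zero", "exclude"),
                          complex = c("fractional", "strict"),
                          path_cap = 100000L,
                          max_depth = 10L) {
  gap <- match.arg(gap)
  complex <- match.arg(complex)
  stopifnot(path_cap >= 1, max_depth >= 1)
  structure(list(gap = gap, complex = complex,
                 path_cap = as.integer(path_cap),
                 max_depth = as.integer(max_depth)),
            class = "moddef_policy")
}

expand_step <- function(step, registry, path_cap, visiting, depth, max_depth) {
  if (is_atomic_step(step)) return(list(list(step)))
  if (step$type == "alts") {
    out <- list()
    for (branch in step$branches) {
      out <- c(out, expand_steps(branch, registry, path_cap, visiting, depth,
                                 max_depth))
      if (length(out) > path_cap) {
        stop(path_cap_error(length(out), path_cap))
      }
    }
    return(out)
  }
  if (step$type == "module") {
    id <- step$module_id
    if (id %in% visiting) {
      stop(structure(class = c("mindep_cycle_error", "error", "condition"),
                     list(message = paste0(
                       "cyclic nested module reference: ",
                       paste(c(visiting, id), collapse = " -> ")),
                       call = NULL)))
    }
    if (depth + 1L > max_depth) {
      stop("nested module expansion exceeds depth cap (", max_depth, ") at ",
           id, call. = FALSE)
    }
    nested <- registry[[id]]
    if (is.null(nested)) {
      stop("nested module ", id, " not found in registry", call. = FALSE)
    }
    return(expand_steps(nested$steps, registry, path_cap, c(visiting, id),
                        depth + 1L, max_depth))
  }
  stop("unknown step type: ", step$type, call. = FALSE)
}

expand_steps <- function(steps, registry, path_cap, visiting, depth,
                         max_depth) {
  paths <- list(list())
  for (step in steps) {
    step_paths <- expand_step(step, registry, path_cap, visiting, depth,
                              max_depth)
    n <- length(paths) * length(step_paths)
    if (n > path_cap) stop(path_cap_error(n, path_cap))
    paths <- unlist(lapply(paths, function(prefix) {
      lapply(step_paths, function(suffix) c(prefix, suffix))
    }), recursive = FALSE)
  }
  paths
}

path_cap_error <- function(n, cap) {
  structure(class = c("mindep_path_cap_error", "error", "condition"),
            list(message = paste0("path enumeration exceeds cap: ", n, " > ",
                                  cap, " paths"),
                 call = NULL))
}

#' Enumerate every alternative route through a module definition
#'
#' Every combination of alternative branches yields exactly one path; nested
#' module references are expanded in place (with cycle detection and a depth
#' cap). Paths are ordered lists of atomic steps (atoms, complexes, gaps).
#'
#' @param defn A [module_definition].
#' @param registry Named list of `module_definition` objects resolving nested
#'   module references.
#' @param policy A [moddef_policy] (supplies `path_cap` and `max_depth`).
#' @return List of paths; each path is a list of atomic steps.
#' @export
enumerate_paths <- function(defn, registry = NULL, policy = moddef_policy()) {
  stopifnot(inherits(defn, "module_definition"))
  expand_steps(defn$steps, registry, policy$path_cap,
               visiting = defn$module_id, depth = 0L,
               max_depth = policy$max_depth)
}

#' Completeness of a single atomic step given a genome's KO set
#'
#' An atom scores 1 if its KO is annotated, else 0. A complex scores the
#' fraction of its essential subunits annotated (non-essential `-`
#' components are ignored), or all-or-nothing under the `"strict"` policy.
#' A gap step scores 0 under the default policy.
#'
#' @param step An atomic step (atom, complex or gap).
#' @param kos Character vector of annotated KO accessions.
#' @param policy A [moddef_policy].
#' @return A value in `[0, 1]`.
#' @export
step_completeness <- function(step, kos, policy = moddef_policy()) {
  if (!is_atomic_step(step)) {
    stop("step_completeness expects an atomic step (atom, complex or gap), ",
         "got '", step$type, "'", call. = FALSE)
  }
  switch(step$type,
    atom = as.numeric(step$ko %in% kos),
    gap = 0,
    complex = {
      ess <- step$components$ko[step$components$essential]
      frac <- mean(ess %in% kos)
      if (policy$complex == "strict") as.numeric(frac == 1) else frac
    })
}

path_completeness <- function(path, kos, policy) {
  if (policy$gap == "exclude") {
    path <- Filter(function(s) s$type != "gap", path)
  }
  if (length(path) == 0L) return(0)
  mean(vapply(path, step_completeness, numeric(1), kos = kos,
              policy = policy))
}

#' Pathwise completeness of a module in one genome
#'
#' The maximum, over all enumerated paths, of the mean per-step completeness
#' along the path. An empty KO set yields 0.
#'
#' @inheritParams enumerate_paths
#' @param kos Character vector of KO accessions annotated in the genome.
#' @return A value in `[0, 1]`.
#' @examples
#' d <- parse_definition("M00001", "(K00001,K00002) K00003")
#' pathwise_completeness(d, c("K00002", "K00003"))
#' @export
pathwise_completeness <- function(defn, kos, registry = NULL,
                                  policy = moddef_policy()) {
  paths <- enumerate_paths(defn, registry, policy)
  if (length(kos) > 0L) kos <- ko_id(kos)
  max(vapply(paths, path_completeness, numeric(1), kos = kos,
             policy = policy))
}

#' Bundle one genome's KO annotations
#'
#' @param genome_id Genome identifier (opaque string).
#' @param kos Character vector of KO accessions (deduplicated, validated).
#' @param genome_length_bp Optional genome length in base pairs.
#' @param completion_pct Optional single-copy core gene completion estimate
#'   in `[0, 100]`.
#' @return A `genome_annotations` object.
#' @export
genome_annotations <- function(genome_id, kos, genome_length_bp = NULL,
                               completion_pct = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            nchar(genome_id) > 0L)
  kos <- if (length(kos) > 0L) ko_id(kos) else character(0)
  if (!is.null(genome_length_bp)) {
    stopifnot(is.numeric(genome_length_bp), genome_length_bp >= 0)
  }
  if (!is.null(completion_pct)) {
    stopifnot(is.numeric(completion_pct), completion_pct >= 0,
              completion_pct <= 100)
  }
  structure(list(genome_id = genome_id, kos = kos,
                 genome_length_bp = genome_length_bp,
                 completion_pct = completion_pct),
            class = "genome_annotations")
}

#' Convert a long genome/KO annotation table to genome_annotations objects
#'
#' @param tab Data frame with columns `genome` and `ko` (extra columns such
#'   as `gene_callers_id` or `e_value` are ignored).
#' @return Named list of [genome_annotations] objects.
#' @export
annotations_from_table <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("genome", "ko") %in% names(tab)))
  ids <- unique(as.character(tab$genome))
  out <- lapply(ids, function(g) {
    genome_annotations(g, unique(as.character(tab$ko[tab$genome == g])))
  })
  names(out) <- ids
  out
}

#' Genome-by-module pathwise completeness matrix
#'
#' @param genomes List of [genome_annotations] (unique genome ids).
#' @param modules List of [module_definition] (unique module ids).
#' @param registry Optional registry for nested module references; defaults
#'   to the supplied modules themselves.
#' @param policy A [moddef_policy].
#' @return Numeric matrix, rows = genomes, columns = modules, values in
#'   `[0, 1]`.
#' @export
completeness_matrix <- function(genomes, modules, registry = NULL,
                                policy = moddef_policy()) {
  genome_ids <- vapply(genomes, function(g) g$genome_id, character(1))
  module_ids <- vapply(modules, function(m) m$module_id, character(1))
  if (anyDuplicated(genome_ids)) {
    stop("duplicate genome ids: ",
         paste(unique(genome_ids[duplicated(genome_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(module_ids)) {
    stop("duplicate module ids: ",
         paste(unique(module_ids[duplicated(module_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(registry)) {
    registry <- stats::setNames(modules, module_ids)
  }
  mat <- matrix(0, nrow = length(genomes), ncol = length(modules),
                dimnames = list(genome_ids, module_ids))
  if (length(modules) == 0L || length(genomes) == 0L) return(mat)
  # enumerate each module's paths once, evaluate against every genome
  for (j in seq_along(modules)) {
    paths <- enumerate_paths(modules[[j]], registry, policy)
    for (i in seq_along(genomes)) {
      mat[i, j] <- max(vapply(paths, path_completeness, numeric(1),
                              kos = genomes[[i]]$kos, policy = policy))
    }
  }
  mat
}
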