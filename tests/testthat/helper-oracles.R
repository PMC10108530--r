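# Independent oracles and small fixture builders used across the suite.

# Brute-force pathwise completeness: recursively accumulate (score, length)
# pairs for every route through the step sequence and take the best mean.
# Decomposition is deliberately different from the package's explicit path
# enumeration.
oracle_routes <- function(steps, kos, registry = NULL) {
  acc <- list(c(score = 0, len = 0))
  for (step in steps) {
    opts <- switch(step$type,
      atom = list(c(as.numeric(step$ko %in% kos), 1)),
      gap = list(c(0, 1)),
      complex = {
        ess <- step$components$ko[step$components$essential]
        list(c(mean(ess %in% kos), 1))
      },
      alts = do.call(c, lapply(step$branches, oracle_routes, kos = kos,
                               registry = registry)),
      module = oracle_routes(registry[[step$module_id]]$steps, kos,
                             registry))
    acc <- do.call(c, lapply(acc, function(a) {
      lapply(opts, function(o) a + o)
    }))
  }
  acc
}

oracle_pathwise <- function(defn, kos, registry = NULL) {
  routes <- oracle_routes(defn$steps, kos, registry)
  max(vapply(routes, function(r) if (r[2] == 0) 0 else r[1] / r[2],
             numeric(1)))
}

# Random definition over a fixed KO alphabet, exercising atoms, small
# alternatives and complexes; path counts stay modest.
random_def_text <- function(ko_alphabet, n_steps = sample(2:4, 1)) {
  steps <- vapply(seq_len(n_steps), function(i) {
    kind <- sample(c("atom", "alts", "complex"), 1)
    pick <- function(n) sample(ko_alphabet, n)
    switch(kind,
      atom = pick(1),
      alts = paste0("(", paste(pick(sample(2:3, 1)), collapse = ","), ")"),
      complex = paste(pick(2), collapse = sample(c("+", "-"), 1)))
  }, character(1))
  paste(steps, collapse = " ")
}

random_ko_subset <- function(ko_alphabet, p = 0.5) {
  ko_alphabet[stats::runif(length(ko_alphabet)) < p]
}

# Minimal single-recipient cohort for decision-tree tests: donor sample
# DS1, recipient R1 with pre-FMT day -1 and post-FMT days 7 and 30. Day 7
# sits on the "more than 7 days" boundary and must never count.
toy_meta <- function() {
  data.frame(
    sample_id = c("DS1", "R1_pre", "R1_d007", "R1_d030"),
    subject_id = c("DA", "R1", "R1", "R1"),
    role = c("donor", "recipient", "recipient", "recipient"),
    day_relative_to_fmt = c(0, -1, 7, 30),
    donor_subject = c(NA, "DA", "DA", "DA"),
    transplant_sample = c(NA, "DS1", "DS1", "DS1"),
    delivery = c(NA, "pill", "pill", "pill"),
    stringsAsFactors = FALSE)
}

toy_detection <- function(donor = 0.9, pre = 0.02, d007 = 0.02,
                          d030 = 0.02, genome = "G1") {
  m <- matrix(c(donor, pre, d007, d030), nrow = 1,
              dimnames = list(genome, c("DS1", "R1_pre", "R1_d007",
                                        "R1_d030")))
  m
}

empty_subpops <- function() {
  data.frame(genome_id = character(0), subpop_id = character(0),
             sample_id = character(0), proportion = numeric(0),
             stringsAsFactors = FALSE)
}

# Exact rank-sum p-value by enumeration of all group assignments.
perm_ranksum_p <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  w_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n * (n + 1) / 2
  })
  mu <- n * length(b) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
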