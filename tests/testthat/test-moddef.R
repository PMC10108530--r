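test_that("definitions parse into the expected step structures", {
  d <- parse_definition("M00001", "K00001 K00002")
  expect_length(d$steps, 2)
  expect_equal(vapply(d$steps, `[[`, "", "type"), c("atom", "atom"))

  d <- parse_definition("M00002", "(K00001,K00002) K00003")
  expect_equal(d$steps[[1]]$type, "alts")
  expect_length(d$steps[[1]]$branches, 2)
  expect_equal(d$steps[[1]]$branches[[1]][[1]]$ko, "K00001")
  expect_equal(d$steps[[2]], list(type = "atom", ko = "K00003"))

  d <- parse_definition("M00003", "K00001+K00002-K00003 K00004")
  expect_equal(d$steps[[1]]$type, "complex")
  expect_equal(d$steps[[1]]$components$ko, c("K00001", "K00002", "K00003"))
  expect_equal(d$steps[[1]]$components$essential, c(TRUE, TRUE, FALSE))

  # lowercase input is normalized; redundant grouping is spliced away
  d <- parse_definition("m00004", "(k00001 k00002) k00003")
  expect_equal(d$module_id, "M00004")
  expect_length(d$steps, 3)
})

test_that("malformed definitions fail with positioned errors", {
  expect_error(parse_definition("M00001", "(K00001 K00002"),
               "unbalanced parentheses")
  expect_error(parse_definition("M00001", "K00001) K00002"),
               "unbalanced parentheses")
  expect_error(parse_definition("M00001", "K00001 X99 K00002"),
               "unknown token at position")
  expect_error(parse_definition("M00001", ""), "non-empty")
  expect_error(parse_definition("M00001", "K00001+(K00002,K00003)"),
               "complex components")
  expect_error(parse_definition("BAD1", "K00001"), "invalid module id")
})

test_that("rendering a parsed definition re-parses to the same structure", {
  cases <- c("K00001 K00002",
             "(K00001,K00002) K00003",
             "K00001+K00002-K00003 K00004",
             "(K00001,(K00002 K00003))",
             "K00001 -- K00002",
             "(K00001+K00002,K00003) (K00004,K00005,K00006)")
  for (txt in cases) {
    d1 <- parse_definition("M00001", txt)
    d2 <- parse_definition("M00001", render_definition(d1))
    expect_identical(d1$steps, d2$steps, label = txt)
  }
  set.seed(42)
  alphabet <- sprintf("K%05d", 1:12)
  for (i in 1:100) {
    txt <- random_def_text(alphabet)
    d1 <- parse_definition("M00001", txt)
    d2 <- parse_definition("M00001", render_definition(d1))
    expect_identical(d1$steps, d2$steps, label = txt)
  }
})

test_that("path enumeration multiplies alternative branches", {
  n_paths <- function(txt) {
    length(enumerate_paths(parse_definition("M00001", txt)))
  }
  expect_equal(n_paths("K00001 K00002"), 1)
  expect_equal(n_paths("(K00001,K00002) (K00003,K00004)"), 4)
  paths <- enumerate_paths(parse_definition("M00001",
                                            "(K00001,(K00002 K00003))"))
  expect_length(paths, 2)
  expect_setequal(vapply(paths, length, integer(1)), c(1L, 2L))
})

test_that("nested modules expand in place with cycle and cap protection", {
  inner <- parse_definition("M00002", "(K00010,K00011)")
  outer <- parse_definition("M00001", "M00002 K00001")
  reg <- list(M00001 = outer, M00002 = inner)
  paths <- enumerate_paths(outer, reg)
  expect_length(paths, 2)
  expect_equal(vapply(paths, length, integer(1)), c(2L, 2L))
  expect_equal(pathwise_completeness(outer, c("K00011", "K00001"), reg), 1)

  a <- parse_definition("M00001", "M00002 K00001")
  b <- parse_definition("M00002", "M00001 K00002")
  expect_error(enumerate_paths(a, list(M00001 = a, M00002 = b)),
               class = "mindep_cycle_error")
  expect_error(enumerate_paths(a, list()), "not found in registry")

  wide <- parse_definition("M00003",
                           paste(rep("(K00001,K00002,K00003)", 4),
                                 collapse = " "))
  expect_error(enumerate_paths(wide, policy = moddef_policy(path_cap = 80)),
               class = "mindep_path_cap_error")
  expect_length(enumerate_paths(wide, policy = moddef_policy(path_cap = 81)),
                81)
})

test_that("atomic step completeness follows the step rules", {
  atom <- parse_definition("M00001", "K00001")$steps[[1]]
  expect_equal(step_completeness(atom, "K00001"), 1)
  expect_equal(step_completeness(atom, "K00099"), 0)

  cpx <- parse_definition("M00001", "K00001+K00002")$steps[[1]]
  expect_equal(step_completeness(cpx, "K00001"), 0.5)
  expect_equal(step_completeness(cpx, "K00001",
                                 moddef_policy(complex = "strict")), 0)
  expect_equal(step_completeness(cpx, c("K00001", "K00002"),
                                 moddef_policy(complex = "strict")), 1)

  # non-essential "minus" components are ignored
  cpx2 <- parse_definition("M00001", "K00001+K00002-K00003")$steps[[1]]
  expect_equal(step_completeness(cpx2, c("K00001", "K00002")), 1)

  gap <- parse_definition("M00001", "--")$steps[[1]]
  expect_equal(step_completeness(gap, c("K00001")), 0)

  alts <- parse_definition("M00001", "(K00001,K00002)")$steps[[1]]
  expect_error(step_completeness(alts, "K00001"), "atomic")
})

test_that("pathwise completeness is the best path's mean step score", {
  d <- parse_definition("M00001", "(K00001,K00002) K00003")
  expect_equal(pathwise_completeness(d, "K00002"), 0.5)
  expect_equal(pathwise_completeness(d, c("K00002", "K00003")), 1)
  expect_equal(pathwise_completeness(d, character(0)), 0)

  d2 <- parse_definition("M00002", "K00001+K00002 K00003")
  expect_equal(pathwise_completeness(d2, c("K00001", "K00003")), 0.75)

  # gap steps cap completeness by default but can be excluded
  d3 <- parse_definition("M00003", "K00001 --")
  expect_equal(pathwise_completeness(d3, "K00001"), 0.5)
  expect_equal(pathwise_completeness(d3, "K00001",
                                     policy = moddef_policy(gap = "exclude")),
               1)
})

test_that("pathwise completeness matches the brute-force route oracle", {
  set.seed(101)
  alphabet <- sprintf("K%05d", 1:10)
  for (i in 1:200) {
    d <- parse_definition("M00001", random_def_text(alphabet))
    kos <- random_ko_subset(alphabet)
    expect_equal(pathwise_completeness(d, kos), oracle_pathwise(d, kos),
                 tolerance = 1e-12, label = d$raw_text)
  }
})

test_that("completeness is monotone under KO-set growth and added branches", {
  set.seed(202)
  alphabet <- sprintf("K%05d", 1:10)
  for (i in 1:200) {
    d <- parse_definition("M00001", random_def_text(alphabet))
    small <- random_ko_subset(alphabet, 0.3)
    big <- unique(c(small, random_ko_subset(alphabet, 0.3)))
    expect_lte(pathwise_completeness(d, small),
               pathwise_completeness(d, big))
  }
  # adding an alternative branch never decreases completeness
  for (i in 1:50) {
    base <- random_def_text(alphabet, n_steps = 2)
    wider <- paste0("(", base, ",K00011)")
    kos <- random_ko_subset(alphabet)
    expect_lte(pathwise_completeness(parse_definition("M00001", base), kos),
               pathwise_completeness(parse_definition("M00001", wider), kos))
  }
})

test_that("completeness matrices cover the genome x module grid", {
  m1 <- parse_definition("M00001", "K00001 K00002")
  m2 <- parse_definition("M00002", "K00011+K00012")
  g1 <- genome_annotations("g1", c("K00001", "K00002"))
  g2 <- genome_annotations("g2", c("K00011", "K00012"))
  mat <- completeness_matrix(list(g1, g2), list(m1, m2))
  expect_equal(mat, matrix(c(1, 0, 0, 1), 2,
                           dimnames = list(c("g1", "g2"),
                                           c("M00001", "M00002"))))
  expect_equal(dim(completeness_matrix(list(g1), list())), c(1, 0))
  expect_error(completeness_matrix(list(g1, g1), list(m1)),
               "duplicate genome ids")
  expect_error(completeness_matrix(list(g1), list(m1, m1)),
               "duplicate module ids")
})

test_that("genome annotation containers validate and deduplicate", {
  g <- genome_annotations("g1", c("k00001", "K00001", "K00002"),
                          genome_length_bp = 2.8e6, completion_pct = 91)
  expect_equal(g$kos, c("K00001", "K00002"))
  expect_error(genome_annotations("g1", "K1"), "invalid KO")
  expect_error(genome_annotations("g1", "K00001", completion_pct = 101))
  tab <- data.frame(genome = c("a", "a", "b"),
                    ko = c("K00001", "K00001", "K00002"))
  anns <- annotations_from_table(tab)
  expect_equal(anns$a$kos, "K00001")
  expect_equal(anns$b$kos, "K00002")
})
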