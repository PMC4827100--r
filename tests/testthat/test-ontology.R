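test_that("OBO parsing keeps is-a edges, drops obsolete terms, maps alt_ids", {
  obo <- c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: T:0001",
    "name: root",
    "",
    "[Term]",
    "id: T:0002",
    "name: branch A",
    "alt_id: T:9999",
    "is_a: T:0001 ! root",
    "",
    "[Term]",
    "id: T:0003",
    "name: leaf B",
    "is_a: T:0002 ! branch A",
    "",
    "[Term]",
    "id: T:0004",
    "name: gone",
    "is_a: T:0001",
    "is_obsolete: true",
    "",
    "[Typedef]",
    "id: part_of")
  path <- withr::local_tempfile(lines = obo, fileext = ".obo")
  ont <- read_obo(path)
  expect_setequal(ont$id, c("T:0001", "T:0002", "T:0003"))
  expect_equal(ont$root, "T:0001")
  expect_equal(ont$parents[["T:0003"]], "T:0002")
  expect_equal(ont$parents[["T:0002"]], "T:0001")
  expect_false("T:0004" %in% ont$id)
  # alt_id resolution applies to annotations
  expect_equal(minimal_set(ont, c("T:9999", "T:0003")), "T:0003")
  expect_equal(term_ancestors(ont, "T:9999"),
               term_ancestors(ont, "T:0002"))
})

test_that("cycles and multiple roots are fatal; a named root restricts", {
  expect_error(phe_ontology(list(root = character(0), A = "B", B = "A")),
               "cycle")
  expect_error(phe_ontology(list(r1 = character(0), r2 = character(0),
                                 A = "r1")),
               "multiple root")
  ont <- phe_ontology(list(r1 = character(0), r2 = character(0), A = "r1"),
                      root = "r1")
  expect_setequal(ont$id, c("r1", "A"))
})

test_that("ancestors returns the term plus transitive closure incl. root", {
  ont <- toy_ontology()
  expect_setequal(term_ancestors(ont, "B"), c("B", "A", "root"))
  expect_equal(term_ancestors(ont, "root"), "root")
  expect_setequal(term_ancestors(diamond_ontology(), "C"),
                  c("C", "A", "B", "root"))
  expect_error(term_ancestors(ont, "nope"), "nope")
})

test_that("ancestors agree with brute-force closure on random DAGs", {
  for (seed in 1:5) {
    ont <- random_ontology(25, seed = seed)
    for (t in sample(ont$id, 8))
      expect_setequal(term_ancestors(ont, t),
                      brute_ancestors(ont$parents, t))
  }
})

test_that("minimal_set strips implied terms, deduplicates, and is canonical", {
  ont <- toy_ontology()
  # an implied (ancestral) term is dropped in favour of the specific one
  expect_equal(minimal_set(ont, c("A", "B")), "B")
  expect_equal(minimal_set(ont, c("A", "A")), "A")
  expect_equal(minimal_set(ont, c("A", "B", "root")), "B")
  expect_setequal(minimal_set(ont, c("B", "C")), c("B", "C"))
  expect_equal(minimal_set(ont, character(0)), character(0))
})

test_that("minimal_set is idempotent and permutation-invariant", {
  for (seed in 1:6) {
    ont <- random_ontology(20, seed = seed)
    set.seed(seed + 100)
    for (rep in 1:5) {
      v <- sample(ont$id, sample(1:6, 1), replace = TRUE)
      m <- minimal_set(ont, v)
      expect_setequal(m, brute_minimal(ont$parents, v))
      expect_equal(minimal_set(ont, m), m)
      expect_equal(minimal_set(ont, sample(v)), m)
      # antichain property
      for (t in m)
        expect_false(any(setdiff(m, t) %in% setdiff(term_ancestors(ont, t), t)))
    }
  }
})

test_that("information content propagates annotations and is monotone", {
  ont <- toy_ontology()
  ic <- information_content(ont, toy_phenotypes())
  expect_equal(ic[["root"]], 0)
  expect_equal(ic[["A"]], log(2))          # B-annotation implies A
  expect_equal(ic[["B"]], log(4))
  expect_equal(ic[["C"]], log(2))
  # a term never annotated has infinite IC and is excluded from the usable set
  ont2 <- phe_ontology(list(root = character(0), A = "root", B = "A",
                            C = "root", D = "root"))
  ic2 <- information_content(ont2, toy_phenotypes())
  expect_equal(ic2[["D"]], Inf)
  expect_setequal(usable_terms(ont2, ic2), c("A", "B", "C"))
  # smoothing gives finite IC everywhere
  ic3 <- information_content(ont2, toy_phenotypes(), smooth = TRUE)
  expect_true(all(is.finite(ic3)))
  # monotone along every edge on random instances
  for (seed in 1:3) {
    ont <- random_ontology(30, seed = seed)
    set.seed(seed)
    phen <- replicate(12, sample(ont$id, sample(1:4, 1)), simplify = FALSE)
    ic <- information_content(ont, phen)
    for (t in ont$id) for (p in ont$parents[[t]])
      expect_gte(ic[[t]], ic[[p]])
  }
})

test_that("empty phenotypes contribute only to the denominator", {
  ont <- toy_ontology()
  ic <- information_content(ont, list("A", character(0)))
  expect_equal(ic[["A"]], log(2))
  expect_equal(ic[["root"]], log(2))  # root not implied by the empty subject
})

test_that("count_preimage matches enumeration and the stated examples", {
  ont <- toy_ontology()
  terms <- c("A", "B", "C")
  expect_equal(count_preimage(ont, "B", 2, terms), 3)       # (B,B),(A,B),(B,A)
  expect_equal(count_preimage(ont, c("A", "C"), 2, terms), 2)
  expect_equal(count_preimage(ont, "A", 1, terms), 1)
  expect_error(count_preimage(ont, c("A", "C"), 1, terms), "exceeds")
  expect_error(count_preimage(ont, c("A", "B"), 2, terms), "not a minimal set")
  for (seed in 1:4) {
    ont <- random_ontology(8, seed = seed)
    terms <- setdiff(ont$id, ont$root)
    for (k in 1:3) {
      sets <- enumerate_min_sets(ont, k, terms)
      counts <- vapply(sets, count_preimage, 1, ontology = ont, k = k,
                       terms = terms)
      brute <- vapply(sets, brute_preimage, 1, ont = ont, k = k,
                      terms = terms)
      expect_equal(counts, brute)
      # every k-vector maps to exactly one minimal set
      expect_equal(sum(counts), length(terms)^k)
    }
  }
})

test_that("count_min_sets agrees with enumeration", {
  ont <- toy_ontology()
  terms <- c("A", "B", "C")
  # Phi(2) = {A},{B},{C},{A,C},{B,C}
  expect_equal(count_min_sets(ont, 2, terms), 5)
  expect_equal(count_min_sets(ont, 1, terms), 3)
  for (seed in 1:5) {
    ont <- random_ontology(14, seed = seed)
    terms <- setdiff(ont$id, ont$root)
    for (k in 1:3)
      expect_equal(count_min_sets(ont, k, terms),
                   length(enumerate_min_sets(ont, k, terms)))
  }
})
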