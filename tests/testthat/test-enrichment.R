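# GO universe construction, hypergeometric enrichment, semantic collapse
# and the OBO round trip.

toy_universe <- function() {
  terms <- data.frame(id = c("root", "A", "B", "A1", "A2", "B1"),
                      name = paste("term", 1:6),
                      namespace = "BP")
  parents <- list(root = character(), A = "root", B = "root",
                  A1 = "A", A2 = "A", B1 = "B")
  ann <- data.frame(gene = c(paste0("g", 1:5), paste0("g", 1:5),
                             paste0("g", 6:10)),
                    term = c(rep("A1", 5), rep("A2", 5), rep("B1", 5)))
  go_universe(terms, parents, ann)
}

test_that("annotation is closed under ancestors and cycles are rejected", {
  u <- toy_universe()
  g1 <- u$gene2terms[["g1"]]
  expect_true(all(c("A1", "A2", "A", "root") %in% g1))
  expect_false("B" %in% g1)
  bad_parents <- list(root = character(), A = "B", B = "A")
  expect_error(go_universe(
    data.frame(id = c("root", "A", "B"), name = 1:3, namespace = "BP"),
    bad_parents, data.frame(gene = "g", term = "A")), "cycle")
})

test_that("hypergeometric p equals exact combinatorial enumeration", {
  # one term covering all 5 foreground genes among N = 20:
  # p = 1 / choose(20, 5)
  terms <- data.frame(id = c("root", "T"), name = c("r", "t"),
                      namespace = "BP")
  parents <- list(root = character(), T = "root")
  genes <- paste0("g", 1:20)
  ann <- rbind(data.frame(gene = genes, term = "root"),
               data.frame(gene = genes[1:5], term = "T"))
  u <- go_universe(terms, parents, ann)
  res <- hypergeom_enrich(genes[1:5], genes, u)
  expect_equal(res$p[res$term == "T"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$ratio[res$term == "T"], 1)
  expect_error(hypergeom_enrich(c("zzz"), genes, u), "subset")
})

test_that("the term capturing the whole foreground has the smallest p", {
  set.seed(2)
  sim <- simulate_go_universe(n_genes = 300, n_terms = 30,
                              enrichment_fold = 10, seed = 7)
  res <- hypergeom_enrich(sim$foreground, sim$background, sim$universe)
  expect_lt(which(res$term == sim$truth$planted_term), 4)
  # BH q-values monotone in p-rank, stable under permuted term order
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-15))
  res2 <- hypergeom_enrich(sim$foreground, sim$background, sim$universe)
  expect_equal(res[order(res$term), ], res2[order(res2$term), ],
               ignore_attr = TRUE)
})

test_that("identical annotation means similarity 1; disjoint branches near 0", {
  u <- toy_universe()
  s <- term_similarity(c("A1", "A2", "B1"), u)
  expect_equal(s["A1", "A2"], 1)           # identical gene sets
  expect_lt(s["A1", "B1"], 0.01)           # only the root in common
})

test_that("semantic collapse merges duplicates and keeps separated clusters", {
  u <- toy_universe()
  results <- data.frame(term = c("A1", "A2", "B1"),
                        name = c("a1", "a2", "b1"), namespace = "BP",
                        ratio = c(0.5, 0.8, 0.4), q = c(1e-4, 1e-3, 1e-2))
  reps <- semantic_collapse(results, u, similarity_min = 0.5)
  expect_equal(nrow(reps), 2)              # A1+A2 collapse, B1 separate
  expect_true("A2" %in% reps$term)         # max ratio represents the group
  expect_equal(reps$minq[reps$term == "A2"], 1e-4)
  expect_lte(nrow(reps), nrow(results))    # collapsing never adds terms
  # unknown terms are excluded with a message
  results2 <- rbind(results, data.frame(term = "nope", name = "x",
                                        namespace = "BP", ratio = 1, q = 1))
  expect_message(semantic_collapse(results2, u), "absent")
})

test_that("OBO files round-trip through the reader", {
  sim <- simulate_go_universe(n_genes = 100, n_terms = 15, seed = 9)
  path <- tempfile(fileext = ".obo")
  write_obo(sim$universe, path)
  back <- read_obo(path)
  expect_equal(sort(back$terms$id), sort(sim$universe$terms$id))
  expect_equal(back$parents[["T0005"]], sim$universe$parents[["T0005"]])
})
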