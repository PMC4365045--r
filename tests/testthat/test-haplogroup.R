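toy_hv9_tree <- function() {
  load_tree(c(
    "root: T16311C",
    "  HV9: C4080T",
    "    HV9c: T6248C,@16311",
    "      HV9c1: G5471A"))
}

u7a4_nest_text <- c(
  "U7a4: T146C,T16126C",
  "  U7a4a: C16148T",
  "    U7a4a1: T195C,T6221C",
  "      U7a4a1a: A16318C",
  "        U7a4a1a1: C8574T",
  "          U7a4a1a1a: G16213A",
  "        U7a4a1b: T143C,C12063T,A15322G")

test_that("indented tree text loads with parsed defining variants", {
  tr <- toy_hv9_tree()
  expect_equal(tr$name, "root")
  hv9c <- tr$children[[1]]$children[[1]]
  expect_equal(hv9c$name, "HV9c")
  expect_equal(hv9c$variants$kind, c("transition", "back_mutation"))
  expect_equal(hv9c$variants$position, c(6248L, 16311L))

  expect_error(load_tree(" \n "), "empty")
  expect_error(load_tree(c("A: T73C", "  B: T152C", "  B: T195C")),
               "duplicate")
})

test_that("the U7a4 nest loads and accumulates state down the path", {
  tr <- load_tree(u7a4_nest_text)
  idx <- tree_index(tr)
  expect_equal(nrow(idx$table), 7L)
  deep <- idx$states[["U7a4a1a1a"]]
  # root-to-tip state holds all defining variants of the path
  expect_setequal(names(deep),
                  paste0(c(146, 16126, 16148, 195, 6221, 16318, 8574,
                           16213), ".0"))
  # sibling branch variants are absent
  expect_false("143.0" %in% names(deep))
})

test_that("back mutations revert ancestral state in the index", {
  idx <- tree_index(toy_hv9_tree())
  expect_true("16311.0" %in% names(idx$states[["HV9"]]))
  expect_false("16311.0" %in% names(idx$states[["HV9c"]]))
})

test_that("a perfect-path profile classifies to its node with score 1", {
  idx <- tree_index(toy_hv9_tree())
  full <- haplotype_profile("x", c("C4080T", "T6248C", "G5471A"))
  cl <- classify(full, idx)
  expect_equal(cl$node[1], "HV9c1")
  expect_equal(cl$score[1], 1)
  expect_length(attr(cl, "private"), 0)
  expect_length(attr(cl, "missing"), 0)
})

test_that("extra variants are reported as private for the best node", {
  idx <- tree_index(toy_hv9_tree())
  p <- haplotype_profile("x", c("C4080T", "T6248C", "A5000G"))
  cl <- classify(p, idx)
  expect_equal(cl$node[1], "HV9c")
  expect_equal(attr(cl, "private"), "A5000G")
})

test_that("score decreases monotonically as path variants are removed", {
  tr <- load_tree(u7a4_nest_text)
  idx <- tree_index(tr)
  toks <- c("T146C", "T16126C", "C16148T", "T195C", "T6221C", "A16318C")
  scores <- vapply(length(toks):2, function(k) {
    cl <- classify(haplotype_profile("x", toks[1:k]), idx)
    cl$score[cl$node == "U7a4a1a"]
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("empty trees are rejected and ties prefer the deeper node", {
  expect_error(classify(haplotype_profile("x"),
                        list(table = data.frame(), states = list(),
                             paths = list())), "empty")
  # two nodes with identical cumulative state: child wins on depth
  tr <- load_tree(c("A: T73C", "  B:"))
  cl <- classify(haplotype_profile("x", "T73C"), tr)
  expect_equal(cl$node[1], "B")
})

test_that("simulated profiles classify to their generating node or deeper", {
  set.seed(42)
  tree <- toy_haplogroup_tree()
  idx <- tree_index(tree)
  nodes <- idx$table$name
  pol <- exclusion_policy("phylogeny")
  n_ok <- 0L
  for (i in 1:200) {
    nd <- sample(nodes, 1)
    root <- node_profile(idx, nd)
    sim <- simulate_clade(
      simulation_config(seed = NULL, n_samples = 1L, topology = "star",
                        clade_age_years = 1500),
      root_profile = root)
    cl <- classify(apply_exclusions(sim$profiles[[1]], pol), idx)
    n_ok <- n_ok + (nd %in% idx$paths[[cl$node[1]]])
  }
  expect_gte(n_ok / 200, 0.95)
})

test_that("two genomes sharing a stable derived variant found a sub-clade", {
  parent <- haplotype_profile("HV9c", c("C4080T", "T6248C"))
  m1 <- haplotype_profile("t1", c("C4080T", "T6248C", "G5471A"))
  m2 <- haplotype_profile("t2", c("C4080T", "T6248C", "G5471A", "A750G"))
  props <- discover_subclades(list(m1, m2), parent, parent_name = "HV9c")
  expect_equal(nrow(props), 1L)
  expect_equal(props$name, "HV9c1")
  expect_match(props$defining, "G5471A")
  expect_equal(props$n_members, 2L)
})

test_that("hotspot-only sharing proposes nothing; <2 members yield nothing", {
  parent <- haplotype_profile("P", "T6248C")
  m1 <- haplotype_profile("t1", c("T6248C", "T16519C"))
  m2 <- haplotype_profile("t2", c("T6248C", "T16519C"))
  expect_equal(nrow(discover_subclades(list(m1, m2), parent)), 0L)
  expect_equal(nrow(discover_subclades(list(m1), parent)), 0L)
})

test_that("discovery is invariant under member permutation", {
  set.seed(3)
  parent <- haplotype_profile("P", "T6248C")
  members <- lapply(1:5, function(i) {
    extra <- sample(c("A750G", "T1438C", "G3010A"), sample(1:2, 1))
    haplotype_profile(paste0("m", i), c("T6248C", extra))
  })
  a <- discover_subclades(members, parent, parent_name = "P")
  b <- discover_subclades(members[c(3, 1, 5, 2, 4)], parent,
                          parent_name = "P")
  norm <- function(x) {
    x$members <- vapply(strsplit(x$members, ","), function(m)
      paste(sort(m), collapse = ","), character(1))
    x[order(x$defining), c("defining", "members", "n_members")]
  }
  expect_equal(norm(a), norm(b), ignore_attr = TRUE)
})

test_that("discovery agrees with brute-force shared-variant enumeration", {
  set.seed(9)
  parent <- haplotype_profile("P", character(0))
  vars <- c("A750G", "T1438C", "G3010A", "C7028T")
  members <- lapply(1:5, function(i)
    haplotype_profile(paste0("m", i),
                      sample(vars, sample(0:3, 1))))
  props <- discover_subclades(members, parent, parent_name = "P")
  # brute force: for every variant, list carriers; carrier sets of >= 2
  # distinct genomes must appear among proposals (grouped by carrier set)
  carrier_sets <- unique(Filter(function(s) length(s) >= 2,
    lapply(vars, function(v)
      sort(which(vapply(members, function(m)
        v %in% variant_tokens(m$variants), logical(1)))))))
  got_sets <- unique(lapply(strsplit(props$members, ","), function(ids)
    sort(match(ids, paste0("m", 1:5)))))
  expect_setequal(lapply(carrier_sets, paste, collapse = ","),
                  lapply(got_sets, paste, collapse = ","))
})

test_that("motif search finds exact and one-step matches with region tallies", {
  j1d <- "A73G-T152C-A263G-C295T-C462T-T489C-C16069T-T16126C-C16193T"
  db <- motif_database(data.frame(
    motif = c(j1d, "A73G-T152C", paste0(j1d, "-T16311C")),
    population = c("Baghdad", "Rome", "Dubai"),
    region = c("Iraq", "Europe", "Near East"),
    source = "fixture", stringsAsFactors = FALSE), range = c(1L, 16569L))
  res <- motif_search(j1d, db, max_steps = 0L)
  expect_equal(nrow(res$matches), 1L)
  expect_equal(res$matches$region, "Iraq")
  expect_equal(unname(res$region_tally["Iraq"]), 1L)

  res1 <- motif_search(j1d, db, max_steps = 1L)
  expect_setequal(res1$matches$region, c("Iraq", "Near East"))
})

test_that("alternative query alleles match either database state", {
  u7a4 <- "T16126C-A16309G-A16318T/A16318C"
  db <- motif_database(data.frame(
    motif = c("T16126C-A16309G-A16318T", "T16126C-A16309G-A16318C",
              "T16126C-A16309G"),
    population = c("Tehran", "Baku", "Rome"),
    region = c("Iran", "Azerbaijan", "Europe"),
    source = "fixture", stringsAsFactors = FALSE))
  res <- motif_search(u7a4, db, max_steps = 0L)
  expect_setequal(res$matches$region, c("Iran", "Azerbaijan"))
  res1 <- motif_search(u7a4, db, max_steps = 1L)
  expect_setequal(res1$matches$region, c("Iran", "Azerbaijan", "Europe"))
})

test_that("indexed motif search agrees with a brute-force difference scan", {
  set.seed(21)
  pool <- setdiff(16024:16365, unstable_positions())
  profs <- lapply(1:50, function(i)
    restrict_range(random_profile(paste0("db", i), sample(1:6, 1),
                                  positions = pool), 16024, 16365))
  db <- motif_database(data.frame(
    motif = vapply(profs, render_motif, character(1)),
    population = "pop", region = sample(c("A", "B"), 50, TRUE),
    source = "sim", stringsAsFactors = FALSE))
  q <- profs[[7]]
  for (steps in c(0L, 1L)) {
    res <- motif_search(render_motif(q), db, max_steps = steps)
    brute <- which(vapply(profs, function(p)
      naive_distance(q, p) <= steps, logical(1)))
    expect_setequal(rownames(res$matches), as.character(brute))
  }
})

test_that("range-mismatched queries are refused", {
  db <- motif_database(data.frame(
    motif = "T16126C", population = "p", region = "r", source = "s"),
    range = c(16024L, 16365L))
  full <- haplotype_profile("q", "T16126C")   # full-molecule range
  expect_error(motif_search(full, db), "range")
  expect_error(motif_search("A73G", db), "outside")
})

test_that("clade origin flags follow the non-home majority rule", {
  expect_equal(
    flag_clade_origin("U7a4",
                      c("Near East" = 6, "South Caucasus" = 3),
                      home_region = "Tuscany", threshold = 0.5),
    "Near East")
  expect_equal(flag_clade_origin("X", c(Europe = 10)), "Europe")
  expect_equal(flag_clade_origin("X", c(A = 1, B = 1), threshold = 0.6),
               "unresolved")
  expect_equal(flag_clade_origin("X", integer(0)), "unresolved")
  # home-region members are excluded before the vote
  expect_equal(
    flag_clade_origin("X", c(Tuscany = 50, Iran = 2),
                      home_region = "Tuscany"), "Iran")
})

test_that("the ancestry component counts flagged clades and descendants", {
  tree <- toy_haplogroup_tree()
  nodes <- c(rep("H1", 101), "T2d2a", "J1b1a3a", "T2n1", "J1d6",
             "HV9c1", "HV9c", "U7a4a1a", "H92", "H97")
  cls <- data.frame(sample_id = sprintf("s%03d", 1:110), node = nodes,
                    stringsAsFactors = FALSE)
  comp <- ancestry_component(cls, flagged_near_east_clades(), tree)
  expect_equal(comp, 100 * 9 / 110)
  expect_equal(round(comp, 1), 8.2)
  expect_equal(ancestry_component(cls, character(0), tree), 0)
  expect_equal(ancestry_component(cls, "mtMRCA", tree), 100)
  expect_error(ancestry_component(cls[0, ], "H1", tree), "no classified")
})
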