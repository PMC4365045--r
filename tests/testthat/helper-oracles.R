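# Independent brute-force oracles used across test files. These
# deliberately avoid the package's internal bookkeeping: states are
# recomputed from rendered motif strings, path sums by explicit
# recursion over an adjacency list.

# token-set state of a profile, recomputed from its rendered motif
naive_state <- function(profile) {
  toks <- strsplit(render_motif(profile), "-", fixed = TRUE)[[1]]
  toks <- toks[toks != "" & !startsWith(toks, "@")]
  # key by position+insertion, value = full token
  key <- sub("^[ACGT]?([0-9]+.*)$", "\\1", toks)
  stats::setNames(toks, key)
}

# naive pairwise difference count between two profiles
naive_distance <- function(p1, p2) {
  a <- naive_state(p1); b <- naive_state(p2)
  shared <- intersect(names(a), names(b))
  sum(a[shared] != b[shared]) +
    sum(!(names(a) %in% shared)) + sum(!(names(b) %in% shared))
}

# explicit recursion: list every root -> leaf mutation path sum
naive_leaf_sums <- function(edges, root) {
  kids <- split(seq_len(nrow(edges)), edges$parent)
  sums <- c()
  walk <- function(node, acc) {
    es <- kids[[node]]
    if (is.null(es)) { sums[node] <<- acc; return(invisible()) }
    for (e in es) walk(edges$child[e], acc + edges$mutations[e])
  }
  walk(root, 0)
  sums
}

# leaves below each edge's child, by listing descendant leaves directly
naive_subtended <- function(edges, root) {
  kids <- split(edges$child, edges$parent)
  leaves_below <- function(node) {
    ch <- kids[[node]]
    if (is.null(ch)) return(node)
    unlist(lapply(ch, leaves_below))
  }
  vapply(edges$child, function(ch) length(leaves_below(ch)), numeric(1))
}

# random genealogy: grow a tree by attaching each new node to a random
# existing node, then ensure >= 2 leaves
random_genealogy <- function(n_nodes = 12, max_m = 4) {
  nodes <- "root"
  edges <- data.frame(parent = character(0), child = character(0),
                      mutations = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(n_nodes)) {
    edges <- rbind(edges, data.frame(
      parent = sample(nodes, 1), child = paste0("n", i),
      mutations = sample(0:max_m, 1), stringsAsFactors = FALSE))
    nodes <- c(nodes, paste0("n", i))
  }
  clade_genealogy(edges)
}

# random haplotype profile of substitutions at distinct positions
random_profile <- function(id = "r", n_var = 8,
                           positions = setdiff(1:16569,
                                               unstable_positions())) {
  pos <- sample(positions, n_var)
  ref <- synthetic_reference()[pos]
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  haplotype_profile(id, paste0(ref, pos, alt))
}

hvs1_range <- c(16024L, 16365L)

# independent haversine distance matrix (km)
geo_dist_km_test <- function(lon, lat) {
  n <- length(lon)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- geosphere::distHaversine(c(lon[i], lat[i]),
                                        c(lon[j], lat[j])) / 1000
  d
}
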