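# Seeded synthetic-mitogenome generator: haplotypes evolved down known
# trees under a Poisson clock, structured and admixed study populations,
# and writers for VCF / motif-database fixtures. All randomness flows
# from the configuration seed.

the_cache <- new.env(parent = emptyenv())

#' Synthetic 16,569-bp reference sequence
#'
#' A deterministically generated stand-in for the rCRS used to give the
#' simulator and its VCF fixtures internally consistent REF/ALT fields.
#' It is synthetic: positions and exclusion masks follow the real rCRS
#' coordinate system, but the base composition is random (fixed internal
#' seed), so it must not be used to annotate real sequence data.
#'
#' @return character vector of 16,569 single bases.
#' @export
synthetic_reference <- function() {
  if (!is.null(the_cache$ref)) return(the_cache$ref)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(16569L)
  the_cache$ref <- sample(c("A", "C", "G", "T"), MT_LENGTH, replace = TRUE,
                          prob = c(0.31, 0.31, 0.13, 0.25))
  the_cache$ref
}

#' Per-position mutation weights
#'
#' Relative probabilities that a simulated mutation event lands on each
#' rCRS position. Mutational hotspots and poly-C tracts (the
#' [unstable_positions()] set) get 50x weight so that the hotspot
#' exclusion filters are exercised by simulated data.
#'
#' @param hotspot_weight weight multiplier for unstable positions.
#' @param lo,hi restrict events to this positional window (e.g. HVS-I).
#' @return numeric vector of length 16,569 (zero outside `lo..hi`).
#' @export
position_weights <- function(hotspot_weight = 50, lo = 1L, hi = MT_LENGTH) {
  w <- rep(1, MT_LENGTH)
  w[unstable_positions()] <- hotspot_weight
  w[-seq.int(lo, hi)] <- 0
  w
}

#' Simulation configuration
#'
#' Bundles the generator's study conditions. Defaults follow the study
#' design being emulated: a complete-mitogenome clock of one mutation
#' per 3,624 years, Yule clade topologies (real clades are non-star),
#' clades of about 10 sampled members, a transition:transversion mix of
#' 0.95:0.05 with 2% indels, and an admixed study population of 110
#' samples carrying an 8.2% source-region component.
#'
#' @param seed integer RNG seed (`NULL` to continue the caller's stream).
#' @param years_per_mutation clock calibration, years per counted
#'   mutation.
#' @param clade_age_years true clade age for [simulate_clade()].
#' @param n_samples leaves per simulated clade.
#' @param topology `"yule"` or `"star"`.
#' @param hvs1_only restrict mutation events and the covered range to
#'   HVS-I (16024-16365).
#' @param ts_prob probability a substitution event is a transition.
#' @param indel_prob probability an event is an indel.
#' @param n_study samples in the admixed study population.
#' @param admixture_fraction probability a study sample draws its
#'   haplogroup from the source-region pool.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = NULL, years_per_mutation = 3624,
                              clade_age_years = 8000, n_samples = 10L,
                              topology = c("yule", "star"),
                              hvs1_only = FALSE, ts_prob = 0.95,
                              indel_prob = 0.02, n_study = 110L,
                              admixture_fraction = 0.082) {
  structure(list(
    seed = seed, years_per_mutation = years_per_mutation,
    clade_age_years = clade_age_years, n_samples = as.integer(n_samples),
    topology = match.arg(topology), hvs1_only = hvs1_only,
    ts_prob = ts_prob, indel_prob = indel_prob,
    n_study = as.integer(n_study),
    admixture_fraction = admixture_fraction),
    class = "simulation_config")
}

# one mutation event applied to a state environment (key -> variant row)
apply_mutation_event <- function(state, pos, cfg, ref) {
  key <- paste0(pos, ".0")
  if (!is.null(state[[key]])) {      # recurrent hit reverts the site
    rm(list = key, envir = state)
    return(invisible())
  }
  u <- stats::runif(1)
  if (u < cfg$indel_prob / 2) {
    v <- data.frame(position = pos, ref = "", alt = "", kind = "deletion",
                    insert_index = 0L, stringsAsFactors = FALSE)
  } else if (u < cfg$indel_prob) {
    b <- sample(c("A", "C", "G", "T"), 1)
    v <- data.frame(position = pos, ref = "", alt = b, kind = "insertion",
                    insert_index = 1L, stringsAsFactors = FALSE)
    key <- paste0(pos, ".1")
    if (!is.null(state[[key]])) return(invisible())
  } else {
    rb <- ref[pos]
    alt <- if (stats::runif(1) < cfg$ts_prob) TRANSITION_PARTNER[[rb]]
           else sample(setdiff(setdiff(c("A", "C", "G", "T"), rb),
                               TRANSITION_PARTNER[[rb]]), 1)
    v <- data.frame(position = pos, ref = rb, alt = alt,
                    kind = substitution_kind(rb, alt),
                    insert_index = 0L, stringsAsFactors = FALSE)
  }
  state[[key]] <- v
  invisible()
}

state_to_profile <- function(state, sample_id, covered_range) {
  rows <- as.list(state)
  vars <- if (length(rows)) do.call(rbind, unname(rows)) else
    empty_variants()
  haplotype_profile(sample_id, vars, covered_range)
}

#' Simulate a clade of mitogenomes under a Poisson clock
#'
#' Generates a rooted genealogy of the configured age (Yule topology
#' with exponential waiting times rescaled to the clade age, or a star),
#' draws each branch's mutation count from
#' `Poisson(branch_years / years_per_mutation)`, places the events at
#' positions drawn from [position_weights()] (hotspots overweighted;
#' recurrent hits revert), and accumulates leaf haplotypes from the
#' supplied root state.
#'
#' @param cfg a [simulation_config()].
#' @param root_profile `haplotype_profile` of the clade root (defaults
#'   to the reference state).
#' @param id_prefix prefix for leaf sample ids.
#' @return list with `genealogy` (a [clade_genealogy()]), `profiles`
#'   (list of leaf `haplotype_profile`s) and `truth` (the generating
#'   parameters).
#' @export
simulate_clade <- function(cfg = simulation_config(),
                           root_profile = NULL, id_prefix = "s") {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$clade_age_years < 0 || cfg$years_per_mutation <= 0)
    stop("clade age must be >= 0 and the clock positive", call. = FALSE)
  n <- cfg$n_samples
  ref <- synthetic_reference()
  rng <- if (cfg$hvs1_only) c(16024L, 16365L) else c(1L, MT_LENGTH)
  wts <- position_weights(lo = rng[1], hi = rng[2])
  positions <- which(wts > 0)
  wts <- wts[positions]

  leaf_ids <- paste0(id_prefix, seq_len(n))
  if (cfg$topology == "star" || n == 1L) {
    edges <- data.frame(parent = "root", child = leaf_ids,
                        duration = cfg$clade_age_years,
                        stringsAsFactors = FALSE)
  } else {
    phy <- ape::rphylo(n, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(phy))
    scale <- if (depth > 0) cfg$clade_age_years / depth else 0
    lab <- character(n + phy$Nnode)
    lab[seq_len(n)] <- leaf_ids
    lab[n + seq_len(phy$Nnode)] <- paste0(id_prefix, "node",
                                          seq_len(phy$Nnode))
    lab[n + 1L] <- "root"
    edges <- data.frame(parent = lab[phy$edge[, 1]],
                        child = lab[phy$edge[, 2]],
                        duration = phy$edge.length * scale,
                        stringsAsFactors = FALSE)
  }
  edges$mutations <- stats::rpois(nrow(edges),
                                  edges$duration / cfg$years_per_mutation)

  root_state <- new.env(parent = emptyenv())
  if (!is.null(root_profile)) {
    v <- root_profile$variants
    v <- v[v$kind != "back_mutation", , drop = FALSE]
    for (i in seq_len(nrow(v)))
      assign(paste0(v$position[i], ".", v$insert_index[i]),
             v[i, , drop = FALSE], envir = root_state)
  }

  # walk the genealogy root-down, mutating a copied state per branch
  kids <- split(seq_len(nrow(edges)), edges$parent)
  profiles <- vector("list", n); names(profiles) <- leaf_ids
  walk <- function(node, state) {
    for (e in kids[[node]]) {
      st <- as.environment(as.list(state))
      m <- edges$mutations[e]
      if (m > 0) for (pos in sample(positions, m, replace = TRUE,
                                    prob = wts))
        apply_mutation_event(st, pos, cfg, ref)
      child <- edges$child[e]
      if (is.null(kids[[child]])) {
        profiles[[child]] <<- state_to_profile(st, child, rng)
      } else walk(child, st)
    }
  }
  walk("root", root_state)

  list(
    genealogy = clade_genealogy(edges[, c("parent", "child", "mutations")]),
    profiles = unname(profiles),
    truth = list(age_years = cfg$clade_age_years,
                 years_per_mutation = cfg$years_per_mutation,
                 expected_rho = cfg$clade_age_years / cfg$years_per_mutation))
}

#' Bundled toy haplogroup tree
#'
#' A small PhyloTree-style tree holding the clades relevant to a
#' Near-East-vs-Europe study design: the HV9c nest (defined by T6248C
#' and the 16311 reversion, with the nested HV9c1), the U7a4 nest with
#' its published defining variants, the other flagged clades (T2d2a,
#' J1b1a3a, T2n1, J1d6, H92, H97), the sub-Saharan L1b1a5, and common
#' West-European background haplogroups. Defining variants of nodes
#' that the published record does not spell out are synthetic stand-ins
#' at stable positions.
#'
#' @return the root `haplo_node`.
#' @export
toy_haplogroup_tree <- function() {
  load_tree(c(
    "mtMRCA:",
    "  L1b1a: G3666A,C6548T",
    "    L1b1a5: C14812T",
    "  R: A12705G",
    "    HV: T14766C",
    "      H: G2706A,T7028C",
    "        H1: G3010A",
    "        H92: T9497C",
    "        H97: A111G,T152C,T195C,T16209C,C16261T",
    "      HV9: C4080T,T16311C",
    "        HV9c: T6248C,@16311",
    "          HV9c1: G5471A",
    "    U: A11467G,G12308A",
    "      U5: C16270T",
    "      U7: C5360T,A14070G",
    "        U7a4: T146C,T16126C",
    "          U7a4a: C16148T",
    "            U7a4a1: T195C,T6221C",
    "              U7a4a1a: A16318C",
    "                U7a4a1a1: C8574T",
    "                  U7a4a1a1a: G16213A",
    "                U7a4a1b: T143C,C12063T,A15322G",
    "    JT: G11719A",
    "      J: C295T,T489C,C16069T",
    "        J1b1a3a: G8269A,T9899C",
    "        J1d: C462T,T16126C,C16193T",
    "          J1d6: G7789A",
    "      T: T16126C,C16294T",
    "        T2d2: G1888A,C16292T",
    "          T2d2a: A6881G",
    "        T2n: A11812G",
    "          T2n1: T4823C",
    "    K: G9055A,C14167T"))
}

#' Flagged Near-East clades of the toy tree
#'
#' The clade set treated as recently introduced from the source region
#' in the emulated study design: HV9c, U7a4a1a, T2d2a, J1b1a3a, T2n1,
#' J1d6, H92 and H97 (descendants included via the tree).
#'
#' @return character vector of node names.
#' @export
flagged_near_east_clades <- function() {
  c("HV9c", "U7a4a1a", "T2d2a", "J1b1a3a", "T2n1", "J1d6", "H92", "H97")
}

#' Simulate an admixed study population with known source fraction
#'
#' Each of `cfg$n_study` samples draws its haplogroup from the
#' source-region pool with probability `cfg$admixture_fraction`, and
#' from the local (background) pool otherwise; its haplotype is the
#' haplogroup's cumulative state plus private mutations accumulated
#' over `private_age_years` under the clock.
#'
#' @param cfg a [simulation_config()].
#' @param tree haplogroup tree (default [toy_haplogroup_tree()]).
#' @param source_pool haplogroup names forming the source-region pool.
#' @param local_pool background haplogroup names.
#' @param private_age_years depth of private variation per sample.
#' @return list with `population` (a [population_set()]), `truth`
#'   (data frame: sample_id, haplogroup, origin) and `tree`.
#' @export
simulate_admixed_study <- function(cfg = simulation_config(),
                                   tree = toy_haplogroup_tree(),
                                   source_pool = flagged_near_east_clades(),
                                   local_pool = c("H1", "H", "U5", "K",
                                                  "J", "T", "HV"),
                                   private_age_years = 2000) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (length(source_pool) == 0L || length(local_pool) == 0L)
    stop("empty haplogroup pool", call. = FALSE)
  idx <- tree_index(tree)
  bad <- setdiff(c(source_pool, local_pool), idx$table$name)
  if (length(bad)) stop("haplogroup(s) not in tree: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  n <- cfg$n_study
  from_source <- stats::runif(n) < cfg$admixture_fraction
  hg <- ifelse(from_source,
               sample(source_pool, n, replace = TRUE),
               sample(local_pool, n, replace = TRUE))
  # samples of one haplogroup descend from a shared genealogy of the
  # configured depth, so they carry shared derived variants the way real
  # co-classified genomes do (this is what sub-clade discovery sees)
  profiles <- vector("list", n)
  for (h in unique(hg)) {
    members <- which(hg == h)
    root_prof <- haplotype_profile("hgroot", state_rows(idx$states[[h]]))
    clade <- simulate_clade(
      modify_config(cfg, seed = NULL, n_samples = length(members),
                    clade_age_years = private_age_years),
      root_profile = root_prof, id_prefix = paste0(h, "_"))
    for (j in seq_along(members)) {
      prof <- clade$profiles[[j]]
      prof$sample_id <- sprintf("TSC%03d", members[j])
      profiles[[members[j]]] <- prof
    }
  }
  list(
    population = population_set("study", profiles, region = "study"),
    truth = data.frame(
      sample_id = sprintf("TSC%03d", seq_len(n)), haplogroup = hg,
      origin = ifelse(from_source, "source", "local"),
      stringsAsFactors = FALSE),
    tree = tree)
}

modify_config <- function(cfg, ...) {
  upd <- list(...)
  cfg[names(upd)] <- upd
  cfg
}

# turn a cumulative state vector back into variant rows; substitution
# ref bases come from the synthetic reference
state_rows <- function(state) {
  if (length(state) == 0L) return(empty_variants())
  ref <- synthetic_reference()
  do.call(rbind, lapply(seq_along(state), function(i) {
    key <- strsplit(names(state)[i], ".", fixed = TRUE)[[1]]
    pos <- as.integer(key[1]); idx <- as.integer(key[2]); val <- state[[i]]
    if (val == "d")
      data.frame(position = pos, ref = "", alt = "", kind = "deletion",
                 insert_index = 0L, stringsAsFactors = FALSE)
    else if (idx > 0L)
      data.frame(position = pos, ref = "", alt = val, kind = "insertion",
                 insert_index = idx, stringsAsFactors = FALSE)
    else {
      rb <- ref[pos]
      if (rb == val) rb <- TRANSITION_PARTNER[[val]]
      data.frame(position = pos, ref = rb, alt = val,
                 kind = substitution_kind(rb, val),
                 insert_index = 0L, stringsAsFactors = FALSE)
    }
  }))
}

#' Write haplotype profiles as a multi-sample VCF fixture
#'
#' Emits VCF v4.2 text against a 16,569-bp contig (`chrM`). SNPs are
#' written directly; deletions are re-anchored to the preceding base
#' (`POS=p-1, REF=xy, ALT=x`); insertions to their anchor position.
#' Round-tripping through [vcf_to_profile()] reproduces the profiles.
#'
#' @param profiles list of `haplotype_profile` objects.
#' @param path output path (plain text `.vcf`).
#' @export
write_fixture_vcf <- function(profiles, path) {
  ref <- synthetic_reference()
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  # collect unique variant records across samples
  recs <- list()
  for (k in seq_along(profiles)) {
    v <- profiles[[k]]$variants
    v <- v[v$kind != "back_mutation", , drop = FALSE]
    for (i in seq_len(nrow(v))) {
      r <- v[i, ]
      key <- paste(r$position, r$insert_index, r$alt, r$kind)
      if (is.null(recs[[key]])) {
        rec <- vcf_record_fields(r, ref)
        rec$carriers <- logical(length(profiles))
        recs[[key]] <- rec
      }
      recs[[key]]$carriers[k] <- TRUE
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=chrM,length=", MT_LENGTH, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", ids), collapse = "\t"))
  body <- character(0)
  if (length(recs)) {
    ord <- order(vapply(recs, function(r) r$pos, numeric(1)))
    body <- vapply(recs[ord], function(r)
      paste(c("chrM", r$pos, ".", r$ref, r$alt, ".", "PASS", ".", "GT",
              ifelse(r$carriers, "1", "0")), collapse = "\t"),
      character(1))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

vcf_record_fields <- function(r, ref) {
  if (r$kind == "deletion") {
    if (r$position < 2L) stop("cannot anchor a deletion at position 1",
                              call. = FALSE)
    anchor <- ref[r$position - 1L]
    list(pos = r$position - 1L,
         ref = paste0(anchor, ref[r$position]), alt = anchor)
  } else if (r$kind == "insertion") {
    list(pos = r$position, ref = ref[r$position],
         alt = paste0(ref[r$position], r$alt))
  } else {
    list(pos = r$position, ref = r$ref, alt = r$alt)
  }
}

#' Write a motif-database TSV from profiles and metadata
#'
#' @param profiles list of `haplotype_profile` objects.
#' @param population,region,source character vectors (recycled).
#' @param path output TSV path.
#' @export
write_motif_db <- function(profiles, population, region,
                           source = "synthetic", path) {
  df <- data.frame(
    motif = vapply(profiles, render_motif, character(1)),
    population = rep_len(population, length(profiles)),
    region = rep_len(region, length(profiles)),
    source = rep_len(source, length(profiles)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Simulate diverged populations for PhiST / MDS analyses
#'
#' Populations descend from founder haplotypes separated by independent
#' Poisson(divergence_years / clock) mutation sets; within-population
#' variation accumulates over `within_age_years`. Larger divergence
#' times therefore produce larger expected PhiST.
#'
#' @param cfg a [simulation_config()].
#' @param labels population labels.
#' @param divergence_years per-population founder depth (recycled).
#' @param within_age_years clade age within each population.
#' @param n_per_pop samples per population (recycled).
#' @return list of [population_set()] objects.
#' @export
simulate_structured_populations <- function(cfg = simulation_config(),
                                            labels = c("A", "B", "C"),
                                            divergence_years = 8000,
                                            within_age_years = 3000,
                                            n_per_pop = 12L) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  divergence_years <- rep_len(divergence_years, length(labels))
  n_per_pop <- rep_len(as.integer(n_per_pop), length(labels))
  lapply(seq_along(labels), function(k) {
    founder <- simulate_clade(
      modify_config(cfg, seed = NULL, n_samples = 1L, topology = "star",
                    clade_age_years = divergence_years[k]),
      id_prefix = paste0(labels[k], "f"))
    clade <- simulate_clade(
      modify_config(cfg, seed = NULL, n_samples = n_per_pop[k],
                    clade_age_years = within_age_years),
      root_profile = founder$profiles[[1]],
      id_prefix = paste0(labels[k], "_"))
    population_set(labels[k], clade$profiles, region = labels[k])
  })
}
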