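# End-to-end study pipeline: convert -> classify -> discover -> flag ->
# component -> date -> diversity -> fst -> mds -> krige. Each stage is a
# pure function of its inputs and writes one artifact under the output
# directory, so a run can be resumed from any stage.

#' Pipeline run configuration
#'
#' @param vcf path to a multi-sample VCF of mtDNA calls (or `NULL` if
#'   `haplotypes` is given).
#' @param haplotypes path to a `sample_id<TAB>motif` haplotype table
#'   (used instead of the VCF when supplied).
#' @param metadata path to a TSV with columns `sample_id`, `population`,
#'   `region`, `lon`, `lat`.
#' @param tree path to a haplogroup tree file, or a `haplo_node`.
#' @param flagged_nodes clade names treated as introduced from the
#'   source region.
#' @param target_clade clade whose per-population frequency is kriged.
#' @param clock a [clock_model()] or label for one.
#' @param range HVS-I range used for diversity comparisons.
#' @param outdir output directory (created if absent).
#' @param seed integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, haplotypes = NULL, metadata, tree,
                       flagged_nodes = flagged_near_east_clades(),
                       target_clade = flagged_nodes[1],
                       clock = clock_model("complete"),
                       range = c(16024L, 16365L),
                       outdir = "pipeline_out", seed = 1L) {
  if (is.character(clock)) clock <- clock_model(clock)
  cfg <- structure(list(
    vcf = vcf, haplotypes = haplotypes, metadata = metadata, tree = tree,
    flagged_nodes = flagged_nodes, target_clade = target_clade,
    clock = clock, range = as.integer(range), outdir = outdir,
    seed = as.integer(seed)), class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$vcf) && is.null(cfg$haplotypes))
    stop("either a VCF or a haplotype table must be supplied",
         call. = FALSE)
  paths <- c(cfg$vcf, cfg$haplotypes, cfg$metadata,
             if (is.character(cfg$tree)) cfg$tree)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(cfg)
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %-10s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg))
}

# star genealogy over clade members: each member's branch carries its
# post-exclusion private mutation count relative to the clade root state
genealogy_from_members <- function(members, root_state_profile) {
  root_state <- profile_state(root_state_profile)
  m <- vapply(members, function(p) {
    s <- profile_state(apply_exclusions(p, exclusion_policy("phylogeny")))
    shared <- intersect(names(s), names(root_state))
    sum(s[shared] != root_state[shared]) +
      sum(!(names(s) %in% shared)) + sum(!(names(root_state) %in% shared))
  }, numeric(1))
  clade_genealogy(data.frame(
    parent = "root",
    child = vapply(members, function(p) p$sample_id, character(1)),
    mutations = m, stringsAsFactors = FALSE))
}

#' Run the full phylogeographic pipeline
#'
#' Executes the stages in order, writes one artifact per stage under
#' `cfg$outdir`, and returns a run report summarising sample counts,
#' haplogroup tallies, proposed new clades, the ancestry component,
#' clade ages, diversity tables, the PhiST matrix and the MDS embedding.
#'
#' @param cfg a [run_config()].
#' @param stages subset of stages to (re)run, in pipeline order.
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(cfg,
                         stages = c("convert", "classify", "discover",
                                    "component", "date", "diversity",
                                    "fst", "mds", "krige")) {
  validate_run_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  tree <- if (is.character(cfg$tree)) load_tree(cfg$tree) else cfg$tree
  idx <- tree_index(tree)
  meta <- utils::read.table(cfg$metadata, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  report <- list(outdir = cfg$outdir, stages_run = stages)
  art <- function(f) file.path(cfg$outdir, f)

  profiles <- NULL
  load_profiles <- function() {
    if (!is.null(profiles)) return(profiles)
    if (file.exists(art("haplotypes.tsv")))
      return(read_haplotype_table(art("haplotypes.tsv")))
    stop("convert stage has not produced haplotypes.tsv", call. = FALSE)
  }

  if ("convert" %in% stages) {
    stage_log("convert", "reading input calls")
    profiles <- if (!is.null(cfg$haplotypes)) {
      read_haplotype_table(cfg$haplotypes)
    } else {
      v <- vcfR::read.vcfR(cfg$vcf, verbose = FALSE)
      lapply(colnames(v@gt)[-1], function(s) vcf_to_profile(v, s))
    }
    write_haplotype_table(profiles, art("haplotypes.tsv"))
    stage_log("convert", paste(length(profiles), "haplotypes written"))
  }

  cls <- NULL
  load_cls <- function() {
    if (!is.null(cls)) return(cls)
    if (file.exists(art("classifications.tsv")))
      return(utils::read.table(art("classifications.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE))
    stop("classify stage has not produced classifications.tsv",
         call. = FALSE)
  }

  if ("classify" %in% stages) {
    profiles <- load_profiles()
    stage_log("classify", paste("classifying", length(profiles),
                                "profiles"))
    pol <- exclusion_policy("phylogeny")
    filt <- lapply(profiles, apply_exclusions, policy = pol)
    cls <- classify_all(filt, idx)
    utils::write.table(cls, art("classifications.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$haplogroup_tally <- sort(table(cls$node), decreasing = TRUE)
    stage_log("classify", "done")
  }

  if ("discover" %in% stages) {
    profiles <- load_profiles(); cls <- load_cls()
    stage_log("discover", "searching shared derived variants")
    pol <- exclusion_policy("phylogeny")
    props <- list()
    for (nd in unique(cls$node[duplicated(cls$node)])) {
      member_ids <- cls$sample_id[cls$node == nd]
      members <- lapply(
        profiles[match(member_ids,
                       vapply(profiles, `[[`, character(1), "sample_id"))],
        apply_exclusions, policy = pol)
      root_prof <- haplotype_profile(nd, state_rows(idx$states[[nd]]))
      p <- discover_subclades(members, root_prof, parent_name = nd)
      if (nrow(p)) props[[nd]] <- p
    }
    proposals <- if (length(props)) do.call(rbind, props) else
      data.frame(name = character(0), parent = character(0),
                 defining = character(0), members = character(0),
                 n_members = integer(0))
    utils::write.table(proposals, art("new_clades.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$new_clades <- proposals
    stage_log("discover", paste(nrow(proposals), "proposed sub-clades"))
  }

  if ("component" %in% stages) {
    cls <- load_cls()
    comp <- ancestry_component(cls, cfg$flagged_nodes, idx)
    report$component_pct <- round(comp, 1)
    writeLines(sprintf("ancestry_component_pct\t%.1f", comp),
               art("component.tsv"))
    stage_log("component", sprintf("source-region component %.1f%%", comp))
  }

  if ("date" %in% stages) {
    profiles <- load_profiles(); cls <- load_cls()
    stage_log("date", "dating flagged clades (rho and ML)")
    ids <- vapply(profiles, `[[`, character(1), "sample_id")
    rows <- list()
    for (nd in cfg$flagged_nodes) {
      in_clade <- vapply(cls$node, function(x) {
        p <- idx$paths[[x]]; !is.null(p) && nd %in% p
      }, logical(1))
      member_ids <- cls$sample_id[in_clade]
      if (length(member_ids) < 2L) next
      members <- profiles[match(member_ids, ids)]
      root_prof <- haplotype_profile(nd, state_rows(idx$states[[nd]]))
      gen <- genealogy_from_members(members, root_prof)
      a_rho <- age_from_rho(gen, cfg$clock)
      a_ml <- ml_tmrca(gen, cfg$clock)
      rows[[nd]] <- data.frame(
        clade = nd, n = gen$n, rho = a_rho$rho_or_ml, sigma = a_rho$sigma,
        rho_age = a_rho$age_years, rho_lo = a_rho$ci95_low,
        rho_hi = a_rho$ci95_high, ml_age = a_ml$age_years,
        ml_lo = a_ml$ci95_low, ml_hi = a_ml$ci95_high,
        stringsAsFactors = FALSE)
    }
    ages <- if (length(rows)) do.call(rbind, rows) else
      data.frame(clade = character(0))
    utils::write.table(ages, art("clade_ages.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$clade_ages <- ages
    stage_log("date", paste(nrow(ages), "clades dated"))
  }

  pops <- NULL
  load_pops <- function() {
    profiles <- load_profiles()
    ids <- vapply(profiles, `[[`, character(1), "sample_id")
    pol <- exclusion_policy("diversity")
    by_pop <- split(meta$sample_id, meta$population)
    by_pop <- by_pop[lengths(by_pop) >= 2L]
    lapply(names(by_pop), function(lbl) {
      prf <- lapply(profiles[match(by_pop[[lbl]], ids)], function(p)
        restrict_range(apply_exclusions(p, pol),
                       cfg$range[1], cfg$range[2]))
      population_set(lbl, prf,
                     region = meta$region[match(lbl, meta$population)])
    })
  }

  if ("diversity" %in% stages) {
    pops <- load_pops()
    stage_log("diversity", paste("diversity over", length(pops),
                                 "populations"))
    div <- do.call(rbind, lapply(pops, function(p) {
      d <- diversity(p)
      data.frame(population = p$label, n = d$n, L = d$L, HD = d$HD,
                 M = d$M, pi = d$pi, stringsAsFactors = FALSE)
    }))
    utils::write.table(div, art("diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$diversity <- div
  }

  if ("fst" %in% stages) {
    if (is.null(pops)) pops <- load_pops()
    stage_log("fst", "pairwise PhiST")
    fst <- fst_matrix(pops)
    write_dist_matrix(fst, art("phist_matrix.tsv"))
    report$phist <- fst
  }

  if ("mds" %in% stages) {
    fst <- if (!is.null(report$phist)) report$phist else
      read_dist_matrix(art("phist_matrix.tsv"))
    if (nrow(fst) >= 3L) {
      if (all(fst == 0))
        stage_log("mds", "degenerate all-zero distance matrix")
      mds <- suppressWarnings(classical_mds(fst, k = 2L))
      coords <- data.frame(population = rownames(mds$coordinates),
                           dim1 = mds$coordinates[, 1],
                           dim2 = mds$coordinates[, 2])
      con <- file(art("mds_coordinates.tsv"), "w")
      writeLines(sprintf("# variance fractions: %s",
                         paste(sprintf("%.3f", mds$variance_fraction),
                               collapse = " ")), con)
      utils::write.table(coords, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
      report$mds <- mds
      stage_log("mds", sprintf("dim1 %.0f%%, dim2 %.0f%%",
                               100 * mds$variance_fraction[1],
                               100 * mds$variance_fraction[2]))
    } else stage_log("mds", "skipped: fewer than 3 populations")
  }

  if ("krige" %in% stages) {
    cls <- load_cls()
    stage_log("krige", paste("kriging frequency of", cfg$target_clade))
    by_pop <- split(meta, meta$population)
    freq <- vapply(by_pop, function(mm) {
      nodes <- cls$node[match(mm$sample_id, cls$sample_id)]
      mean(vapply(nodes, function(x) {
        p <- idx$paths[[x]]; !is.null(p) && cfg$target_clade %in% p
      }, logical(1)), na.rm = TRUE)
    }, numeric(1))
    sites <- geo_samples(
      lon = vapply(by_pop, function(mm) mean(mm$lon), numeric(1)),
      lat = vapply(by_pop, function(mm) mean(mm$lat), numeric(1)),
      value = freq, label = names(by_pop), is_frequency = TRUE)
    if (stats::var(sites$value) == 0) {
      # constant field: kriging is the identity, no variogram to fit
      stage_log("krige", "constant frequency field; writing flat surface")
      grid <- make_grid(sites)
      surf <- structure(list(
        lon = grid$lon, lat = grid$lat,
        values = matrix(sites$value[1], length(grid$lon),
                        length(grid$lat)),
        variance = matrix(0, length(grid$lon), length(grid$lat)),
        max_weight_error = 0, model = NULL), class = "geo_surface")
    } else {
      emp <- empirical_variogram(sites,
                                 n_bins = min(8L, nrow(sites) - 1L))
      model <- fit_variogram(emp, "exponential")
      surf <- ordinary_krige(sites, model, clip_frequency = TRUE)
    }
    write_surface(surf, art("surface.tsv"))
    report$surface <- surf
  }

  report$n_samples <- if (!is.null(cls)) nrow(cls) else
    length(load_profiles())
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$n_samples, "samples; stages:",
      paste(x$stages_run, collapse = ", "), "\n")
  if (!is.null(x$component_pct))
    cat("  source-region component:", x$component_pct, "%\n")
  if (!is.null(x$new_clades))
    cat("  proposed sub-clades:", nrow(x$new_clades), "\n")
  invisible(x)
}
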