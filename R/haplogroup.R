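# Haplogroup tree handling, classification, sub-clade discovery and
# motif-database searching.

#' Load a haplogroup tree from indented text
#'
#' The format mirrors a PhyloTree export: one node per line,
#' `name: variant,variant`, with children indented relative to their
#' parent (any consistent step of spaces or tabs). The root may have an
#' empty defining-variant list. Back mutations (`@`-prefixed) in a
#' defining list revert the corresponding ancestral variant.
#'
#' @param text the tree as a single string, a character vector of lines,
#'   or a file path.
#' @return the root `haplo_node`: a nested list with elements `name`,
#'   `variants` (parsed defining variants), `children` and `annotations`.
#' @examples
#' tree <- load_tree(c(
#'   "HV9:",
#'   "  HV9c: T6248C,@16311",
#'   "    HV9c1: C8460T"))
#' @export
load_tree <- function(text) {
  if (length(text) == 1L && file.exists(text)) text <- readLines(text)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- text[trimws(text) != ""]
  if (length(lines) == 0L) stop("empty tree text", call. = FALSE)
  indents <- nchar(sub("[^ \t].*$", "", lines))
  steps <- sort(unique(indents))
  depth <- match(indents, steps) - 1L
  if (depth[1] != 0L) stop("first tree line must be the root", call. = FALSE)
  if (sum(depth == 0L) > 1L)
    stop("tree text contains more than one root", call. = FALSE)

  parse_line <- function(ln) {
    ln <- trimws(ln)
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    name <- trimws(parts[1])
    toks <- if (length(parts) > 1L && trimws(parts[2]) != "")
      trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]]) else character(0)
    list(name = name, variants = parse_variant_token(toks),
         children = list(), annotations = list())
  }

  nodes <- lapply(lines, parse_line)
  names_seen <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(names_seen))
    stop("duplicate node name(s): ",
         paste(unique(names_seen[duplicated(names_seen)]), collapse = ", "),
         call. = FALSE)
  build <- function(i) {
    node <- nodes[[i]]
    j <- i + 1L
    while (j <= length(nodes) && depth[j] > depth[i]) {
      if (depth[j] == depth[i] + 1L) {
        node$children[[length(node$children) + 1L]] <- build(j)
      } else if (depth[j] > depth[i] + 1L && depth[j - 1L] < depth[j] - 1L) {
        stop("indentation jumps more than one level at line ", j,
             call. = FALSE)
      }
      j <- j + 1L
    }
    structure(node, class = "haplo_node")
  }
  build(1L)
}

#' @export
print.haplo_node <- function(x, ...) {
  idx <- tree_index(x)
  cat("<haplo_node> tree with", nrow(idx$table), "nodes, root '",
      x$name, "'\n", sep = "")
  invisible(x)
}

# State bookkeeping: a cumulative haplotype state is a named character
# vector, key "<pos>.<insert_index>" -> derived allele ("" for deletions,
# encoded "d"). Back mutations in a defining list delete the key.
state_key <- function(variants) {
  if (nrow(variants) == 0L) return(character(0))
  paste0(variants$position, ".", variants$insert_index)
}

state_value <- function(variants) {
  if (nrow(variants) == 0L) return(character(0))
  ifelse(variants$kind == "deletion", "d", variants$alt)
}

apply_variants_to_state <- function(state, variants) {
  if (nrow(variants) == 0L) return(state)
  back <- variants$kind == "back_mutation"
  if (any(back)) {
    drop_keys <- state_key(variants[back, , drop = FALSE])
    state <- state[setdiff(names(state), drop_keys)]
  }
  fwd <- variants[!back, , drop = FALSE]
  if (nrow(fwd)) state[state_key(fwd)] <- state_value(fwd)
  state
}

profile_state <- function(profile) {
  v <- profile$variants
  v <- v[v$kind != "back_mutation", , drop = FALSE]
  s <- state_value(v)
  names(s) <- state_key(v)
  s
}

#' Flatten a haplogroup tree into a classification index
#'
#' Computes, for every node, its depth, its ancestor path and its
#' cumulative variant state (parent state edited by the node's defining
#' variants, with back mutations reverting). Building the index once and
#' passing it to [classify()] amortises the traversal over many samples.
#'
#' @param tree root `haplo_node`.
#' @return a list with `table` (data frame: name, depth, parent) and
#'   per-node `states` and `paths`.
#' @export
tree_index <- function(tree) {
  rows <- list(); states <- list(); paths <- list()
  walk <- function(node, depth, parent, state, path) {
    state <- apply_variants_to_state(state, node$variants)
    path <- c(path, node$name)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = node$name, depth = depth, parent = parent,
      stringsAsFactors = FALSE)
    states[[node$name]] <<- state
    paths[[node$name]] <<- path
    for (ch in node$children) walk(ch, depth + 1L, node$name, state, path)
  }
  walk(tree, 0L, NA_character_, character(0), character(0))
  list(table = do.call(rbind, rows), states = states, paths = paths)
}

#' Classify a haplotype profile against a haplogroup tree
#'
#' Every node is scored by the symmetric (Kulczynski-style) average of
#' expected-variant recall and profile precision: with `E` the node's
#' cumulative variants inside the profile's covered range and `P` the
#' profile's informative variants, `score = (|E∩P|/|E| + |E∩P|/|P|)/2`
#' (an empty set contributes 1). An expected variant countered by an
#' observed `@` reversion counts as missing. Ties prefer the deeper node,
#' then the lexicographically smaller name. The profile should already be
#' filtered with the `phylogeny` exclusion policy.
#'
#' @param profile a `haplotype_profile`.
#' @param tree root `haplo_node`, or a prebuilt [tree_index()].
#' @param top how many ranked nodes to return.
#' @return a data frame (class `haplogroup_classification`) ranked by
#'   score with columns `sample_id`, `node`, `score`, `depth`,
#'   `n_matched`, `n_missing`, `n_private`; attributes `matched`,
#'   `missing` and `private` give token vectors for the best node.
#' @export
classify <- function(profile, tree, top = Inf) {
  idx <- if (is.list(tree) && !inherits(tree, "haplo_node")) tree
         else tree_index(tree)
  if (nrow(idx$table) == 0L) stop("empty haplogroup tree", call. = FALSE)
  p_state <- profile_state(profile)
  p_pos <- as.numeric(sub("\\..*$", "", names(p_state)))
  keep <- position_in_ranges(p_pos, profile$covered_range)
  p_state <- p_state[keep]

  nm <- idx$table$name
  score <- n_matched <- n_missing <- n_private <- numeric(length(nm))
  for (i in seq_along(nm)) {
    e_state <- idx$states[[nm[i]]]
    e_pos <- as.numeric(sub("\\..*$", "", names(e_state)))
    e_state <- e_state[position_in_ranges(e_pos, profile$covered_range)]
    common <- intersect(names(e_state), names(p_state))
    m <- sum(e_state[common] == p_state[common])
    recall <- if (length(e_state) == 0L) 1 else m / length(e_state)
    precision <- if (length(p_state) == 0L) 1 else m / length(p_state)
    score[i] <- (recall + precision) / 2
    n_matched[i] <- m
    n_missing[i] <- length(e_state) - m
    n_private[i] <- length(p_state) - m
  }
  out <- data.frame(sample_id = profile$sample_id, node = nm,
                    score = score, depth = idx$table$depth,
                    n_matched = n_matched, n_missing = n_missing,
                    n_private = n_private, stringsAsFactors = FALSE)
  ord <- order(-out$score, -out$depth, out$node)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (is.finite(top)) out <- utils::head(out, top)

  best_state <- idx$states[[out$node[1]]]
  b_pos <- as.numeric(sub("\\..*$", "", names(best_state)))
  best_state <- best_state[position_in_ranges(b_pos, profile$covered_range)]
  common <- intersect(names(best_state), names(p_state))
  hit <- common[best_state[common] == p_state[common]]
  attr(out, "matched") <- state_tokens(best_state[hit])
  attr(out, "missing") <- state_tokens(
    best_state[setdiff(names(best_state), hit)])
  attr(out, "private") <- state_tokens(
    p_state[setdiff(names(p_state), hit)])
  class(out) <- c("haplogroup_classification", "data.frame")
  out
}

# render a state vector back into display tokens (ref base unknown for
# substitutions coming from a bare state, so the transition partner is
# implied; deletions print "<pos>d", insertions "<pos>.<idx><alt>")
state_tokens <- function(state) {
  if (length(state) == 0L) return(character(0))
  ks <- strsplit(names(state), ".", fixed = TRUE)
  vapply(seq_along(state), function(i) {
    pos <- ks[[i]][1]; idx <- ks[[i]][2]; val <- state[[i]]
    if (val == "d") paste0(pos, "d")
    else if (idx != "0") paste0(pos, ".", idx, val)
    else paste0(TRANSITION_PARTNER[[val]], pos, val)
  }, character(1))
}

#' Write a haplogroup tree back to indented text
#'
#' Inverse of [load_tree()]: one node per line, children indented two
#' spaces per level, defining variants comma-joined after the name.
#'
#' @param tree root `haplo_node`.
#' @param path output path; omit to return the lines invisibly only.
#' @return the text lines, invisibly.
#' @export
write_tree_text <- function(tree, path = NULL) {
  lines <- character(0)
  walk <- function(node, depth) {
    toks <- paste(variant_tokens(node$variants), collapse = ",")
    lines[[length(lines) + 1L]] <<- paste0(
      strrep("  ", depth), node$name, ": ", toks)
    for (ch in node$children) walk(ch, depth + 1L)
  }
  walk(tree, 0L)
  lines <- unlist(lines)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Cumulative state of a tree node as a haplotype profile
#'
#' @param tree root `haplo_node` or a [tree_index()].
#' @param name node name.
#' @return a `haplotype_profile` carrying the node's root-path variants.
#' @export
node_profile <- function(tree, name) {
  idx <- if (is.list(tree) && !inherits(tree, "haplo_node")) tree
         else tree_index(tree)
  st <- idx$states[[name]]
  if (is.null(st)) stop("node '", name, "' not in tree", call. = FALSE)
  haplotype_profile(name, state_rows(st))
}

#' Classify many profiles at once
#'
#' @param profiles list of `haplotype_profile` objects.
#' @param tree root `haplo_node` or [tree_index()].
#' @return data frame of best hits, one row per profile.
#' @export
classify_all <- function(profiles, tree) {
  idx <- if (is.list(tree) && !inherits(tree, "haplo_node")) tree
         else tree_index(tree)
  do.call(rbind, lapply(profiles, function(p) classify(p, idx, top = 1L)))
}

#' Propose new sub-haplogroups from shared derived variants
#'
#' Implements the discovery rule used when extending the worldwide
#' phylogeny: a new sub-clade is proposed for every maximal set of at
#' least two distinct genomes that share at least one derived variant
#' (relative to the parent node's state) at a mutationally stable
#' position. Nested proposals (a clade within a clade) are allowed, and
#' names follow the PhyloTree letter/number alternation under the parent
#' name.
#'
#' @param members list of `haplotype_profile` objects classified to the
#'   parent node.
#' @param parent_state `haplotype_profile` holding the parent node's
#'   cumulative state.
#' @param stable_positions integer positions considered mutationally
#'   stable; defaults to [stable_positions()].
#' @param parent_name name used as the prefix for proposals.
#' @return a data frame with one row per proposed node: `name`,
#'   `parent`, `defining` (comma-joined tokens), `members`
#'   (comma-joined sample ids) and `n_members`.
#' @export
discover_subclades <- function(members, parent_state,
                               stable_positions = NULL,
                               parent_name = "X") {
  empty <- data.frame(name = character(0), parent = character(0),
                      defining = character(0), members = character(0),
                      n_members = integer(0), stringsAsFactors = FALSE)
  if (length(members) < 2L) return(empty)
  if (is.null(stable_positions)) stable_positions <- stable_positions()
  par_state <- profile_state(parent_state)
  ids <- vapply(members, function(p) p$sample_id, character(1))

  derived <- lapply(members, function(p) {
    s <- profile_state(p)
    new_keys <- names(s)[is.na(match(names(s), names(par_state))) |
                           s[names(s)] != par_state[names(s)]]
    gained <- if (length(new_keys)) paste0(new_keys, "=", s[new_keys])
              else character(0)
    lost <- setdiff(names(par_state), names(s))      # reversions
    c(gained, if (length(lost)) paste0(lost, "=@") else character(0))
  })
  # keep only variants at stable positions
  derived <- lapply(derived, function(d) {
    pos <- as.integer(sub("\\..*$", "", d))
    d[pos %in% stable_positions]
  })
  all_vars <- unique(unlist(derived))
  if (length(all_vars) == 0L) return(empty)
  carriers <- lapply(all_vars, function(v)
    sort(which(vapply(derived, function(d) v %in% d, logical(1)))))
  sizes <- lengths(carriers)
  ok <- sizes >= 2L
  if (!any(ok)) return(empty)
  all_vars <- all_vars[ok]; carriers <- carriers[ok]
  # group variants with identical carrier sets -> one proposed node each
  grp_key <- vapply(carriers, paste, character(1), collapse = ",")
  groups <- split(seq_along(all_vars), grp_key)
  prop <- lapply(groups, function(g) list(
    variants = all_vars[g], carriers = carriers[[g[1]]]))
  prop <- prop[order(-vapply(prop, function(p) length(p$carriers), numeric(1)),
                     vapply(prop, function(p) p$variants[1], character(1)))]

  # nesting: a proposal nests under the smallest earlier proposal whose
  # carrier set strictly contains it
  parent_of <- integer(length(prop))
  for (i in seq_along(prop)) {
    parent_of[i] <- 0L
    if (i > 1L) for (j in (i - 1L):1L) {
      if (length(prop[[j]]$carriers) > length(prop[[i]]$carriers) &&
          all(prop[[i]]$carriers %in% prop[[j]]$carriers)) {
        parent_of[i] <- j; break
      }
    }
  }
  nms <- character(length(prop))
  counter <- new.env()
  next_name <- function(parent) {
    k <- (get0(parent, envir = counter, ifnotfound = 0L)) + 1L
    assign(parent, k, envir = counter)
    if (grepl("[0-9]$", parent)) paste0(parent, letters[k])
    else paste0(parent, k)
  }
  parents <- character(length(prop))
  for (i in seq_along(prop)) {
    parents[i] <- if (parent_of[i] == 0L) parent_name else nms[parent_of[i]]
    nms[i] <- next_name(parents[i])
  }
  data.frame(
    name = nms, parent = parents,
    defining = vapply(prop, function(p)
      paste(derived_tokens(p$variants), collapse = ","), character(1)),
    members = vapply(prop, function(p)
      paste(ids[p$carriers], collapse = ","), character(1)),
    n_members = vapply(prop, function(p) length(p$carriers), integer(1)),
    stringsAsFactors = FALSE)
}

derived_tokens <- function(enc) {
  vapply(enc, function(e) {
    parts <- strsplit(e, "=", fixed = TRUE)[[1]]
    key <- strsplit(parts[1], ".", fixed = TRUE)[[1]]
    val <- parts[2]
    if (val == "@") paste0("@", key[1])
    else if (val == "d") paste0(key[1], "d")
    else if (key[2] != "0") paste0(key[1], ".", key[2], val)
    else paste0(TRANSITION_PARTNER[[val]], key[1], val)
  }, character(1), USE.NAMES = FALSE)
}

#' Positions considered mutationally stable
#'
#' The bundled default marks as unstable the classic control-region
#' hotspots (16182, 16183, 16189, 16193, 16519), the poly-C stretches
#' around positions 310 (302-316) and 16184-16193, and the 515-524
#' repeat — the same sites the phylogeny exclusion mask targets. All
#' other rCRS positions are treated as stable.
#'
#' @param unstable override the unstable position set.
#' @return integer vector of stable positions.
#' @export
stable_positions <- function(unstable = unstable_positions()) {
  setdiff(seq_len(MT_LENGTH), unstable)
}

#' @rdname stable_positions
#' @export
unstable_positions <- function() {
  sort(unique(c(16182L, 16183L, 16189L, 16519L,
                302L:316L, 16184L:16193L, 515L:524L)))
}

#' Build or load a control-region motif database
#'
#' @param records data frame with columns `motif`, `population`,
#'   `region`, `source`, or a path to such a TSV.
#' @param range covered positions (lo, hi); records are restricted to it.
#' @return object of class `motif_db`.
#' @export
motif_database <- function(records, range = c(16024L, 16365L)) {
  if (is.character(records) && length(records) == 1L)
    records <- utils::read.table(records, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE,
                                 colClasses = "character")
  needed <- c("motif", "population", "region", "source")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("motif database lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  profiles <- lapply(seq_len(nrow(records)), function(i)
    restrict_range(parse_motif(records$motif[i], paste0("db", i)),
                   range[1], range[2]))
  records$motif <- vapply(profiles, render_motif, character(1))
  structure(list(records = records, profiles = profiles,
                 range = as.integer(range)),
            class = "motif_db")
}

#' @export
print.motif_db <- function(x, ...) {
  cat("<motif_db>", nrow(x$records), "profiles over range",
      x$range[1], "-", x$range[2], "\n")
  invisible(x)
}

# parse a query motif allowing per-site alternative alleles written
# "A16318T/A16318C"; returns list of per-site allowed state values
parse_motif_query <- function(motif) {
  toks <- if (motif == "") character(0) else
    strsplit(motif, "-", fixed = TRUE)[[1]]
  sites <- list()
  for (tok in toks) {
    alts <- strsplit(tok, "/", fixed = TRUE)[[1]]
    v <- parse_variant_token(alts)
    keys <- unique(state_key(v))
    if (length(keys) != 1L)
      stop("alternative alleles in '", tok,
           "' must share one position", call. = FALSE)
    sites[[keys]] <- state_value(v)
  }
  sites
}

#' Search a motif database for exact or one-step-mutation matches
#'
#' With `max_steps = 0` only records whose state on the shared range is
#' identical to the query are returned; with `max_steps = 1`, records
#' differing by exactly one variant (an extra variant, a missing variant,
#' or a different allele at one site) are returned as well. Query tokens
#' may carry per-site alternative alleles (`"A16318T/A16318C"` matches
#' either state).
#'
#' @param query motif string, or a `haplotype_profile` (converted with
#'   its rendered motif).
#' @param db a [motif_database()].
#' @param max_steps 0 (exact) or 1 (one mutational step).
#' @return list with `matches` (records data frame plus `steps` column)
#'   and `region_tally` (named counts per region).
#' @export
motif_search <- function(query, db, max_steps = 0L) {
  stopifnot(max_steps %in% c(0L, 1L))
  if (inherits(query, "haplotype_profile")) {
    if (!identical(as.integer(query$covered_range[1, ]), db$range))
      stop("query range (", paste(query$covered_range[1, ], collapse = "-"),
           ") does not match database range (",
           paste(db$range, collapse = "-"), ")", call. = FALSE)
    query <- render_motif(query)
  }
  q <- parse_motif_query(query)
  q_pos <- as.integer(sub("\\..*$", "", names(q)))
  if (length(q_pos) && (any(q_pos < db$range[1]) || any(q_pos > db$range[2])))
    stop("query contains positions outside the database range",
         call. = FALSE)
  # steps = substituted sites + query sites absent + record sites extra
  steps <- vapply(db$profiles, function(p) {
    s <- profile_state(p)
    shared <- intersect(names(q), names(s))
    substituted <- sum(!vapply(shared, function(k) s[[k]] %in% q[[k]],
                               logical(1)))
    absent <- sum(!(names(q) %in% names(s)))
    extra <- sum(!(names(s) %in% names(q)))
    substituted + absent + extra
  }, numeric(1))
  hit <- steps <= max_steps
  matches <- db$records[hit, , drop = FALSE]
  matches$steps <- steps[hit]
  tally <- if (nrow(matches)) table(matches$region) else
    table(character(0))
  list(matches = matches, region_tally = c(tally))
}

#' Assign a geographic origin to a clade from member sampling regions
#'
#' @param node clade name (used for reporting only).
#' @param member_regions named integer vector of member counts per
#'   region, excluding the study's own (home-region) samples.
#' @param home_region the study region, removed from the counts if
#'   present.
#' @param threshold minimum fraction of non-home members a region must
#'   hold to be called the origin.
#' @return the winning region label, or `"unresolved"`.
#' @export
flag_clade_origin <- function(node, member_regions, home_region = NULL,
                              threshold = 0.5) {
  if (!is.null(home_region))
    member_regions <- member_regions[setdiff(names(member_regions),
                                             home_region)]
  if (length(member_regions) == 0L || sum(member_regions) == 0L)
    return("unresolved")
  frac <- member_regions / sum(member_regions)
  best <- which.max(frac)
  if (frac[best] >= threshold) names(member_regions)[best] else "unresolved"
}

#' Fraction of samples classified into flagged clades
#'
#' Computes the ancestry component: the percentage of samples whose best
#' haplogroup assignment is one of the flagged nodes or a descendant of
#' one (descent is taken from the tree when supplied, otherwise flagged
#' names must match exactly).
#'
#' @param classifications data frame of best hits (from [classify_all()]
#'   or equivalent) with columns `sample_id` and `node`.
#' @param flagged_nodes character vector of flagged clade names.
#' @param tree optional `haplo_node` or [tree_index()] used to resolve
#'   descendants of flagged nodes.
#' @return the component as a percentage in [0, 100].
#' @export
ancestry_component <- function(classifications, flagged_nodes, tree = NULL) {
  n <- nrow(classifications)
  if (is.null(n) || n == 0L) stop("no classified samples", call. = FALSE)
  flagged_set <- flagged_nodes
  in_flagged <- if (!is.null(tree)) {
    idx <- if (is.list(tree) && !inherits(tree, "haplo_node")) tree
           else tree_index(tree)
    vapply(classifications$node, function(nd) {
      path <- idx$paths[[nd]]
      if (is.null(path)) nd %in% flagged_set
      else any(path %in% flagged_set)
    }, logical(1))
  } else {
    classifications$node %in% flagged_set
  }
  100 * sum(in_flagged) / n
}
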