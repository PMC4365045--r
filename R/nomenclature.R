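#' @keywords internal
"_PACKAGE"

MT_LENGTH <- 16569L

# transition partners: A<->G, C<->T
TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

empty_variants <- function() {
  data.frame(
    position = integer(0), ref = character(0), alt = character(0),
    kind = character(0), insert_index = integer(0),
    stringsAsFactors = FALSE
  )
}

#' Parse mtDNA variant tokens in standard rCRS-relative nomenclature
#'
#' Tokens follow the conventional mtDNA grammar: an optional `@` prefix
#' (back/missing mutation), an optional reference base, the 1-based rCRS
#' position, and a suffix that is either a single base (substitution),
#' `d` (deletion of that rCRS position), or `.<index><bases>` (insertion
#' after that position). Substitutions written without an explicit
#' reference base are transitions by convention, so the reference is the
#' transition partner of the written allele (e.g. `"16182C"` is `T16182C`).
#'
#' @param tokens character vector of variant tokens, e.g.
#'   `c("A263G", "T6248C", "@16311", "15322d", "309.1C")`.
#' @return A data frame with one row per token and columns `position`,
#'   `ref`, `alt`, `kind` (one of `transition`, `transversion`,
#'   `insertion`, `deletion`, `back_mutation`) and `insert_index`
#'   (0 unless the variant is an insertion).
#' @examples
#' parse_variant_token(c("T6248C", "A16318C", "@16311"))
#' @export
parse_variant_token <- function(tokens) {
  tokens <- as.character(tokens)
  n <- length(tokens)
  out <- data.frame(
    position = integer(n), ref = character(n), alt = character(n),
    kind = character(n), insert_index = integer(n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    tok <- tokens[i]
    body <- tok
    back <- startsWith(body, "@")
    if (back) body <- substring(body, 2L)
    m <- regmatches(body, regexec(
      "^([ACGT]?)([0-9]+)(\\.([0-9]+)([ACGT]+)|d|[ACGT])?$", body))[[1]]
    if (length(m) == 0L || (m[4] == "" && !back))
      stop("malformed variant token: '", tok, "'", call. = FALSE)
    pos <- as.integer(m[3])
    if (is.na(pos) || pos < 1L || pos > MT_LENGTH)
      stop("position out of rCRS range (1..", MT_LENGTH, ") in token '",
           tok, "'", call. = FALSE)
    ref <- m[2]
    suf <- m[4]
    ins_idx <- 0L
    if (suf == "") {            # bare "@<pos>" back mutation
      alt <- ""
      kind <- "back_mutation"
    } else if (suf == "d") {
      alt <- ""
      kind <- "deletion"
      ref <- ""                  # canonical deletion carries no ref base
    } else if (startsWith(suf, ".")) {
      ins_idx <- as.integer(m[5])
      if (is.na(ins_idx) || ins_idx < 1L)
        stop("malformed insertion index in token '", tok, "'", call. = FALSE)
      alt <- m[6]
      kind <- "insertion"
      ref <- ""
    } else {
      alt <- suf
      if (ref == "") ref <- TRANSITION_PARTNER[[alt]]
      if (ref == alt)
        stop("reference and alternate allele identical in token '", tok, "'",
             call. = FALSE)
      kind <- substitution_kind(ref, alt)
    }
    if (back) kind <- "back_mutation"
    out$position[i] <- pos
    out$ref[i] <- ref
    out$alt[i] <- alt
    out$kind[i] <- kind
    out$insert_index[i] <- ins_idx
  }
  out
}

substitution_kind <- function(ref, alt) {
  purines <- c("A", "G")
  same_class <- (ref %in% purines) == (alt %in% purines)
  if (same_class) "transition" else "transversion"
}

#' Render variants back to nomenclature tokens
#'
#' Inverse of [parse_variant_token()]: substitutions print with an explicit
#' reference base, deletions as `<pos>d`, insertions as `<pos>.<idx><bases>`,
#' back mutations with the `@` prefix.
#'
#' @param variants a variant data frame as returned by
#'   [parse_variant_token()].
#' @return character vector of tokens.
#' @export
variant_tokens <- function(variants) {
  if (nrow(variants) == 0L) return(character(0))
  vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    body <- if (v$kind == "deletion") {
      paste0(v$position, "d")
    } else if (v$kind == "insertion") {
      paste0(v$position, ".", v$insert_index, v$alt)
    } else if (v$kind == "back_mutation" && v$alt == "") {
      as.character(v$position)
    } else {
      paste0(v$ref, v$position, v$alt)
    }
    if (v$kind == "back_mutation") paste0("@", body) else body
  }, character(1))
}

sort_variants <- function(variants) {
  variants <- variants[order(variants$position, variants$insert_index), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  variants
}

#' Construct a haplotype profile
#'
#' A haplotype profile is one sample's set of differences from the rCRS,
#' sorted by position, together with the sequencing range it covers
#' (defaults to the full molecule). At most one state per
#' (position, insertion index) is allowed, and every variant must lie
#' inside the covered range.
#'
#' @param sample_id sample identifier.
#' @param variants variant data frame ([parse_variant_token()]) or a
#'   character vector of tokens.
#' @param covered_range two-column matrix (or length-2 vector) of 1-based
#'   inclusive position intervals covered by the sequence.
#' @return An object of class `haplotype_profile`.
#' @examples
#' haplotype_profile("TSI-001", c("A73G", "A263G", "T16126C"))
#' @export
haplotype_profile <- function(sample_id, variants = character(0),
                              covered_range = c(1L, MT_LENGTH)) {
  if (is.character(variants)) variants <- parse_variant_token(variants)
  if (is.null(dim(covered_range)))
    covered_range <- matrix(as.integer(covered_range), ncol = 2)
  colnames(covered_range) <- c("lo", "hi")
  variants <- sort_variants(variants)
  key <- paste(variants$position, variants$insert_index)
  if (anyDuplicated(key))
    stop("profile '", sample_id, "' carries two states at position(s) ",
         paste(unique(variants$position[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  inside <- position_in_ranges(variants$position, covered_range)
  if (!all(inside))
    stop("variant(s) at ", paste(variants$position[!inside], collapse = ", "),
         " fall outside the covered range", call. = FALSE)
  structure(
    list(sample_id = sample_id, variants = variants,
         covered_range = covered_range),
    class = "haplotype_profile"
  )
}

position_in_ranges <- function(pos, ranges) {
  if (length(pos) == 0L) return(logical(0))
  Reduce(`|`, lapply(seq_len(nrow(ranges)), function(i)
    pos >= ranges[i, 1] & pos <= ranges[i, 2]))
}

#' @export
print.haplotype_profile <- function(x, ...) {
  cat("<haplotype_profile> ", x$sample_id, ": ",
      if (nrow(x$variants)) render_motif(x) else "(rCRS)",
      "\n", sep = "")
  invisible(x)
}

#' Parse a hyphen-joined haplotype motif into a profile
#'
#' @param motif motif string such as `"A73G-T152C-A263G"`; the empty
#'   string yields an empty profile.
#' @param sample_id sample identifier for the resulting profile.
#' @param covered_range passed to [haplotype_profile()].
#' @return a `haplotype_profile`.
#' @export
parse_motif <- function(motif, sample_id = "motif",
                        covered_range = c(1L, MT_LENGTH)) {
  toks <- if (is.na(motif) || motif == "") character(0) else
    strsplit(motif, "-", fixed = TRUE)[[1]]
  haplotype_profile(sample_id, toks, covered_range)
}

#' Render a profile as a hyphen-joined motif string
#'
#' Tokens are emitted in ascending position order; `parse_motif()` of the
#' result reproduces the profile.
#'
#' @param profile a `haplotype_profile`.
#' @return a single motif string (empty string for an empty profile).
#' @export
render_motif <- function(profile) {
  paste(variant_tokens(profile$variants), collapse = "-")
}

#' Exclusion policies for unstable mtDNA variation
#'
#' Two contexts are provided. The `phylogeny` policy removes the classic
#' mutational hotspots used in tree building: transitions at 16182, 16183
#' and 16519, indels within 515-524, insertions at 16193, and the
#' length-unstable poly-C variation around position 310 (interval 302-316,
#' restricted to indels and C-involving substitutions). The `diversity`
#' policy removes only the length-heteroplasmy-associated states near
#' 16189, i.e. the 16182C and 16183C tokens, as is usual for HVS-I
#' diversity statistics.
#'
#' @param context `"phylogeny"` or `"diversity"`.
#' @param drop_positions extra positions to drop entirely.
#' @param drop_tokens extra rendered tokens to drop.
#' @return an object of class `exclusion_policy`.
#' @export
exclusion_policy <- function(context = c("phylogeny", "diversity"),
                             drop_positions = integer(0),
                             drop_tokens = character(0)) {
  context <- match.arg(context)
  if (context == "phylogeny") {
    drop_positions <- union(drop_positions, c(16182L, 16183L, 16519L))
  } else {
    drop_tokens <- union(drop_tokens, c("T16182C", "T16183C"))
  }
  structure(
    list(context = context,
         drop_positions = as.integer(drop_positions),
         drop_tokens = drop_tokens),
    class = "exclusion_policy"
  )
}

#' Apply an exclusion policy to a profile
#'
#' Returns a copy of the profile with matching variants removed; the
#' operation is idempotent and never touches its input.
#'
#' @param profile a `haplotype_profile`.
#' @param policy an [exclusion_policy()].
#' @return the filtered `haplotype_profile`.
#' @export
apply_exclusions <- function(profile, policy) {
  v <- profile$variants
  if (nrow(v) == 0L) return(profile)
  drop <- v$position %in% policy$drop_positions |
    variant_tokens(v) %in% policy$drop_tokens
  if (policy$context == "phylogeny") {
    indel <- v$kind %in% c("insertion", "deletion")
    drop <- drop |
      (indel & v$position >= 515L & v$position <= 524L) |
      (v$kind == "insertion" & v$position == 16193L) |
      (v$position >= 302L & v$position <= 316L &
         (indel | v$ref == "C" | v$alt == "C"))
  }
  profile$variants <- v[!drop, , drop = FALSE]
  profile
}

#' Restrict a profile to a positional range
#'
#' Keeps only variants with `lo <= position <= hi` and sets the covered
#' range accordingly. The default HVS-I range used for inter-population
#' control-region comparisons is 16024-16365.
#'
#' @param profile a `haplotype_profile`.
#' @param lo,hi inclusive 1-based rCRS bounds.
#' @return the restricted `haplotype_profile`.
#' @export
restrict_range <- function(profile, lo = 16024L, hi = 16365L) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo > hi) stop("inverted range bounds: ", lo, " > ", hi, call. = FALSE)
  if (lo < 1L || hi > MT_LENGTH) stop("range outside 1..", MT_LENGTH,
                                      call. = FALSE)
  keep <- profile$variants$position >= lo & profile$variants$position <= hi
  profile$variants <- profile$variants[keep, , drop = FALSE]
  profile$covered_range <- matrix(c(lo, hi), ncol = 2,
                                  dimnames = list(NULL, c("lo", "hi")))
  profile
}

#' Convert a VCF of mtDNA calls into a haplotype profile
#'
#' Reads the sample's called non-reference alleles from a VCF aligned to
#' the rCRS (16,569 bp contig) and re-expresses them in the standard
#' mtDNA nomenclature: SNPs become `<ref><pos><alt>` tokens, left-aligned
#' VCF deletions are reported per deleted rCRS position with suffix `d`,
#' and insertions are anchored to the preceding rCRS position as
#' `<pos>.<index><bases>`. Heterozygous (heteroplasmic) genotypes resolve
#' to the major allele by allele depth when `AD` is present, otherwise to
#' the alternate allele, with a warning.
#'
#' @param vcf path to a VCF file, or a `vcfR` object.
#' @param sample_id sample column to extract; defaults to the first
#'   sample in the VCF.
#' @param het_policy `"major"` (default) resolves heteroplasmies to the
#'   major allele; `"alt"` always takes the alternate.
#' @return a `haplotype_profile` for the sample.
#' @export
vcf_to_profile <- function(vcf, sample_id = NULL,
                           het_policy = c("major", "alt")) {
  het_policy <- match.arg(het_policy)
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  if (is.null(sample_id)) sample_id <- samples[1]
  if (!sample_id %in% samples)
    stop("sample '", sample_id, "' not present in VCF", call. = FALSE)
  ctg_len <- vcf_contig_length(vcf)
  if (!is.na(ctg_len) && ctg_len != MT_LENGTH)
    stop("VCF contig length ", ctg_len, " does not match the rCRS (",
         MT_LENGTH, " bp)", call. = FALSE)

  vars <- empty_variants()
  if (nrow(fix) > 0L) {
    fmt <- gt[, 1]
    calls <- gt[, sample_id]
    for (i in seq_len(nrow(fix))) {
      alt_field <- fix[i, "ALT"]
      if (is.na(alt_field) || alt_field == "" || alt_field == ".") next
      alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
      allele <- select_allele(fmt[i], calls[i], length(alts), het_policy,
                              fix[i, "POS"])
      if (allele == 0L) next
      vars <- rbind(vars, expand_vcf_allele(
        as.integer(fix[i, "POS"]), fix[i, "REF"], alts[allele]))
    }
  }
  # record order must not matter; also collapse exact duplicates
  vars <- sort_variants(vars)
  vars <- vars[!duplicated(paste(vars$position, vars$insert_index)), ,
               drop = FALSE]
  haplotype_profile(sample_id, vars)
}

vcf_contig_length <- function(vcf) {
  meta <- vcf@meta
  ln <- grep("^##contig=", meta, value = TRUE)
  if (length(ln) == 0L) return(NA_integer_)
  m <- regmatches(ln[1], regexec("length=([0-9]+)", ln[1]))[[1]]
  if (length(m) < 2L) NA_integer_ else as.integer(m[2])
}

select_allele <- function(fmt, call, n_alt, het_policy, pos) {
  if (is.na(call) || call == ".") return(0L)
  keys <- strsplit(fmt, ":", fixed = TRUE)[[1]]
  vals <- strsplit(call, ":", fixed = TRUE)[[1]]
  gt <- vals[match("GT", keys)]
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(0L)
  alleles <- suppressWarnings(
    as.integer(strsplit(gt, "[/|]")[[1]]))
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0L) return(0L)
  u <- unique(alleles)
  if (length(u) == 1L) return(u[1])
  # heteroplasmic call
  ad_i <- match("AD", keys)
  chosen <- if (!is.na(ad_i) && het_policy == "major") {
    ad <- as.numeric(strsplit(vals[ad_i], ",", fixed = TRUE)[[1]])
    which.max(ad) - 1L
  } else {
    max(u)
  }
  warning("heteroplasmic genotype at position ", pos,
          "; resolved to allele ", chosen, call. = FALSE)
  chosen
}

# Re-express one VCF REF/ALT pair in mtDNA convention.
expand_vcf_allele <- function(pos, ref, alt) {
  ref_b <- strsplit(ref, "")[[1]]
  alt_b <- strsplit(alt, "")[[1]]
  if (length(ref_b) == length(alt_b)) {
    diff <- which(ref_b != alt_b)
    if (length(diff) == 0L) return(empty_variants())
    return(do.call(rbind, lapply(diff, function(k)
      data.frame(position = pos + k - 1L, ref = ref_b[k], alt = alt_b[k],
                 kind = substitution_kind(ref_b[k], alt_b[k]),
                 insert_index = 0L, stringsAsFactors = FALSE))))
  }
  # strip the shared left-anchor base(s)
  n_shared <- 0L
  while (n_shared < min(length(ref_b), length(alt_b)) &&
         ref_b[n_shared + 1L] == alt_b[n_shared + 1L]) n_shared <- n_shared + 1L
  if (length(ref_b) > length(alt_b)) {         # deletion
    deleted <- seq.int(pos + n_shared, pos + length(ref_b) - 1L)
    return(do.call(rbind, lapply(deleted, function(p)
      data.frame(position = p, ref = "", alt = "", kind = "deletion",
                 insert_index = 0L, stringsAsFactors = FALSE))))
  }
  ins <- alt_b[(n_shared + 1L):length(alt_b)]  # insertion
  data.frame(position = pos + n_shared - 1L, ref = "",
             alt = paste(ins, collapse = ""), kind = "insertion",
             insert_index = 1L, stringsAsFactors = FALSE)
}

#' Write a one-line-per-sample haplotype table
#'
#' @param profiles list of `haplotype_profile` objects.
#' @param path output path; tab-separated `sample_id<TAB>motif`.
#' @export
write_haplotype_table <- function(profiles, path) {
  df <- data.frame(
    sample_id = vapply(profiles, function(p) p$sample_id, character(1)),
    motif = vapply(profiles, render_motif, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a haplotype table back into profiles
#'
#' @param path TSV with columns `sample_id` and `motif` (extra columns are
#'   kept as attributes).
#' @return list of `haplotype_profile` objects.
#' @export
read_haplotype_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(motif = "character"))
  lapply(seq_len(nrow(df)), function(i)
    parse_motif(df$motif[i], df$sample_id[i]))
}
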