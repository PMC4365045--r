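test_that("variant tokens parse with the correct chemistry", {
  v <- parse_variant_token("T6248C")
  expect_equal(v$position, 6248L)
  expect_equal(v$ref, "T"); expect_equal(v$alt, "C")
  expect_equal(v$kind, "transition")

  v <- parse_variant_token("A16318C")
  expect_equal(v$kind, "transversion")

  v <- parse_variant_token("@16311")
  expect_equal(v$position, 16311L)
  expect_equal(v$kind, "back_mutation")

  v <- parse_variant_token("15322d")
  expect_equal(v$kind, "deletion")
  expect_equal(v$alt, "")

  v <- parse_variant_token("309.1CC")
  expect_equal(v$kind, "insertion")
  expect_equal(v$insert_index, 1L)
  expect_equal(v$alt, "CC")

  # bare-alt tokens imply the transition partner as reference
  v <- parse_variant_token("16182C")
  expect_equal(v$ref, "T")
  expect_equal(v$kind, "transition")
})

test_that("every published clade-defining token parses", {
  toks <- c("T6248C", "T146C", "T16126C", "C16148T", "T195C", "T6221C",
            "A16318C", "C8574T", "G16213A", "T143C", "C12063T",
            "A15322G", "C14812T", "T9497C", "T16368C")
  v <- parse_variant_token(toks)
  expect_equal(nrow(v), length(toks))
  expect_true(all(v$kind %in% c("transition", "transversion")))
})

test_that("malformed and out-of-range tokens are rejected by name", {
  expect_error(parse_variant_token("notatoken"), "notatoken")
  expect_error(parse_variant_token("T123"), "T123")
  expect_error(parse_variant_token("A99999G"), "range")
  expect_error(parse_variant_token("A100A"), "identical")
})

test_that("profiles enforce one state per site and range containment", {
  expect_error(haplotype_profile("x", c("A73G", "73d")), "position")
  expect_error(
    haplotype_profile("x", "A73G", covered_range = c(16024L, 16365L)),
    "outside")
  p <- haplotype_profile("x", c("T16126C", "A73G"))
  expect_equal(p$variants$position, c(73L, 16126L))  # sorted
})

test_that("parse and render round-trip over random profiles", {
  set.seed(101)
  for (i in 1:300) {
    p <- random_profile(n_var = sample(0:12, 1))
    motif <- render_motif(p)
    p2 <- parse_motif(motif, p$sample_id)
    expect_identical(p2$variants, p$variants)
    expect_identical(render_motif(p2), motif)
  }
})

test_that("published control-region motifs survive a round trip", {
  h97 <- "A111G-T152C-T195C-A263G-T16209C-C16261T"
  expect_identical(render_motif(parse_motif(h97)), h97)
  expect_identical(render_motif(haplotype_profile("e")), "")
})

test_that("phylogeny exclusions drop hotspots, poly-C and 16193 insertions", {
  pol <- exclusion_policy("phylogeny")
  p <- haplotype_profile("x", c("T16519C", "T6248C"))
  expect_equal(render_motif(apply_exclusions(p, pol)), "T6248C")

  p <- haplotype_profile("x", c("T310C", "309.1C", "522d", "16193.1C",
                                "A73G"))
  expect_equal(render_motif(apply_exclusions(p, pol)), "A73G")

  # non-C substitution inside 302-316 but outside the C-tract rule stays
  p <- haplotype_profile("x", "A302G")
  expect_equal(render_motif(apply_exclusions(p, pol)), "A302G")

  # idempotence
  p <- haplotype_profile("x", c("T16182C", "T16519C", "T6248C", "A73G"))
  once <- apply_exclusions(p, pol)
  twice <- apply_exclusions(once, pol)
  expect_identical(once$variants, twice$variants)
  # original untouched
  expect_equal(nrow(p$variants), 4L)
})

test_that("diversity exclusions remove only the 16182C/16183C states", {
  pol <- exclusion_policy("diversity")
  p <- haplotype_profile("x", c("T16182C", "T16183C", "T16189C", "A73G"))
  expect_equal(render_motif(apply_exclusions(p, pol)), "A73G-T16189C")
  e <- haplotype_profile("e")
  expect_equal(nrow(apply_exclusions(e, pol)$variants), 0L)
})

test_that("range restriction keeps HVS-I variants and sets the range", {
  p <- haplotype_profile("x", c("A73G", "T16126C", "A16309G"))
  r <- restrict_range(p, 16024, 16365)
  expect_equal(render_motif(r), "T16126C-A16309G")
  expect_equal(as.integer(r$covered_range), c(16024L, 16365L))
  expect_error(restrict_range(p, 200, 100), "inverted")
  # identity on the full molecule
  expect_identical(restrict_range(p, 1, 16569)$variants, p$variants)
})

test_that("VCF records convert to standard nomenclature", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16569>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1"), collapse = "\t"),
    "chrM\t263\t.\tA\tG\t.\tPASS\t.\tGT\t1",
    "chrM\t15321\t.\tGA\tG\t.\tPASS\t.\tGT\t1",
    "chrM\t309\t.\tC\tCCT\t.\tPASS\t.\tGT\t1",
    "chrM\t5000\t.\tT\tA\t.\tPASS\t.\tGT\t0"), vcf)
  p <- vcf_to_profile(vcf, "S1")
  expect_equal(render_motif(p), "A263G-309.1CT-15322d")
})

test_that("VCF deletion re-expression matches an alignment oracle", {
  # independent route: align the two local haplotype strings and read
  # off which reference position is deleted
  ref_local <- "TTGATT"   # stands for positions 15319..15324
  alt_local <- "TTGTT"    # REF=GA ALT=G applied at offset 3
  al <- Biostrings::pairwiseAlignment(alt_local, ref_local,
                                      type = "global")
  del <- Biostrings::deletion(al)[[1]]
  deleted_pos <- 15319 + BiocGenerics::start(del) - 1
  expect_equal(deleted_pos, 15322)
})

test_that("VCF conversion ignores record order and empty call sets", {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16569>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1"), collapse = "\t"))
  recs <- c("chrM\t750\t.\tA\tG\t.\tPASS\t.\tGT\t1",
            "chrM\t73\t.\tA\tG\t.\tPASS\t.\tGT\t1")
  f1 <- tempfile(fileext = ".vcf"); writeLines(c(header, recs), f1)
  f2 <- tempfile(fileext = ".vcf"); writeLines(c(header, rev(recs)), f2)
  expect_identical(render_motif(vcf_to_profile(f1, "S1")),
                   render_motif(vcf_to_profile(f2, "S1")))

  f3 <- tempfile(fileext = ".vcf")
  writeLines(c(header, "chrM\t73\t.\tA\tG\t.\tPASS\t.\tGT\t0"), f3)
  expect_equal(nrow(vcf_to_profile(f3, "S1")$variants), 0L)
})

test_that("a wrong reference length is a reference-mismatch error", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16571>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1"), collapse = "\t"),
    "chrM\t73\t.\tA\tG\t.\tPASS\t.\tGT\t1"), vcf)
  expect_error(vcf_to_profile(vcf, "S1"), "16569")
})

test_that("heteroplasmic genotypes resolve to the major allele with warning", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16569>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1"), collapse = "\t"),
    "chrM\t73\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:10,90"), vcf)
  expect_warning(p <- vcf_to_profile(vcf, "S1"), "heteroplasmic")
  expect_equal(render_motif(p), "A73G")

  vcf2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16569>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1"), collapse = "\t"),
    "chrM\t750\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:95,5"), vcf2)
  expect_warning(p2 <- vcf_to_profile(vcf2, "S1"), "heteroplasmic")
  expect_equal(nrow(p2$variants), 0L)   # major allele is the reference
})

test_that("haplotype tables round-trip through disk", {
  set.seed(7)
  profs <- lapply(1:5, function(i) random_profile(paste0("s", i), 4))
  path <- tempfile(fileext = ".tsv")
  write_haplotype_table(profs, path)
  back <- read_haplotype_table(path)
  expect_equal(vapply(back, render_motif, character(1)),
               vapply(profs, render_motif, character(1)))
})
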