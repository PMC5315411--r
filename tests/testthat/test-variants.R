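chr10_pattern <- c(affected_collie_1 = "het", affected_collie_2 = "het",
                   affected_collie_3 = "hom", affected_sheltie = "hom")

test_that("interval restriction keeps boundaries inclusively", {
  df <- data.frame(chrom = "chr10", pos = c(1, 1333693, 1333694, 500),
                   id = paste0("v", 1:4), ref = "A", alt = "T",
                   gt_s1 = "het", stringsAsFactors = FALSE)
  v <- variant_set(df, "s1")
  kept <- restrict_to_interval(v, "chr10:1-1,333,693")
  expect_setequal(kept$id, c("v1", "v2", "v4"))
  expect_equal(unname(attr(kept, "excluded")["out_of_interval"]), 1L)
  # disjoint interval
  expect_equal(nrow(restrict_to_interval(v, "chr31:1-100")), 0)
})

test_that("segregation filter retains exactly the planted variants", {
  sim <- simulate_variant_vcf("chr10:1-1333693", chr10_pattern,
                              n_total = 100, n_matching = 20, seed = 81)
  kept <- segregation_filter(sim$variants, chr10_pattern)
  expect_equal(nrow(kept), 20)
  expect_setequal(kept$id, sim$truth$id[sim$truth$matches])
  # the empty pattern is the identity filter
  all_kept <- segregation_filter(sim$variants, character(0))
  expect_equal(nrow(all_kept), nrow(sim$variants))
  # a missing call at a required sample drops the variant, counted apart
  v <- sim$variants
  match_id <- sim$truth$id[sim$truth$matches][1]
  v$gt_affected_collie_1[v$id == match_id] <- "missing"
  kept2 <- segregation_filter(v, chr10_pattern)
  expect_equal(nrow(kept2), 19)
  expect_gte(unname(attr(kept2, "excluded")["missing"]), 1)
  # unknown sample names are fatal
  expect_error(segregation_filter(v, c(nobody = "het")), "absent")
  # "hom" accepts either homozygote; hom_alt does not accept hom_ref
  df <- data.frame(chrom = "1", pos = 1:2, id = c("a", "b"), ref = "A",
                   alt = "T", gt_s1 = c("hom_ref", "hom_alt"),
                   stringsAsFactors = FALSE)
  vs <- variant_set(df, "s1")
  expect_equal(nrow(segregation_filter(vs, c(s1 = "hom"))), 2)
  expect_equal(segregation_filter(vs, c(s1 = "hom_alt"))$id, "b")
})

test_that("exon filter keeps variants within 10 bp of exons, not 11", {
  exons <- data.frame(chrom = "chr10", start = c(1000, 5000),
                      end = c(1100, 5200))
  df <- data.frame(chrom = "chr10",
                   pos = c(989, 990, 1110, 1111, 3000, 5100),
                   id = paste0("v", 1:6), ref = "A", alt = "T",
                   gt_s1 = "het", stringsAsFactors = FALSE)
  v <- variant_set(df, "s1")
  kept <- exonic_splice_filter(v, exons)
  expect_setequal(kept$id, c("v2", "v3", "v6"))
  # BED round trip (0-based half-open on disk)
  bed <- tempfile(fileext = ".bed")
  write.table(data.frame("chr10", exons$start - 1L, exons$end), bed,
              sep = "\t", col.names = FALSE, row.names = FALSE,
              quote = FALSE)
  expect_setequal(exonic_splice_filter(v, bed)$id, c("v2", "v3", "v6"))
})

test_that("uniqueness filter drops variants seen in other breeds or catalogs", {
  set.seed(91)
  df <- data.frame(chrom = "chr31", pos = sort(sample(1e6, 50)),
                   id = sprintf("v%02d", 1:50), ref = "G", alt = "C",
                   gt_s1 = "hom_alt", stringsAsFactors = FALSE)
  v <- variant_set(df, "s1")
  planted_unique <- df$id[1:7]
  other <- df[8:30, c("chrom", "pos", "alt")]
  catalog <- df[31:50, c("chrom", "pos", "alt")]
  kept <- uniqueness_filter(v, other, catalog)
  expect_setequal(kept$id, planted_unique)
  excl <- attr(kept, "excluded")
  expect_equal(unname(excl["in_panel"] + excl["in_catalog"]), 43L)
})

test_that("filters commute as set operations and report conserved counts", {
  sim <- simulate_variant_vcf("chr10:1-2000000", chr10_pattern,
                              n_total = 120, n_matching = 35, seed = 83)
  v <- sim$variants
  exons <- data.frame(chrom = "chr10",
                      start = seq(1e5, 1.9e6, by = 2e5),
                      end = seq(1e5, 1.9e6, by = 2e5) + 5e4)
  interval <- "chr10:200000-1500000"
  a <- exonic_splice_filter(segregation_filter(
    restrict_to_interval(v, interval), chr10_pattern), exons)
  b <- restrict_to_interval(segregation_filter(
    exonic_splice_filter(v, exons), chr10_pattern), interval)
  expect_setequal(a$id, b$id)
  res <- filter_variants(v, interval = interval, pattern = chr10_pattern,
                         exons = exons)
  expect_setequal(res$retained$id, a$id)
  expect_equal(sum(res$report$excluded) + nrow(res$retained), nrow(v))
})

test_that("VCF writing and parsing round-trips genotype states", {
  sim <- simulate_variant_vcf("chr10:1-500000", chr10_pattern,
                              n_total = 30, n_matching = 10, seed = 85,
                              path = tempfile(fileext = ".vcf"))
  back <- read_variants_vcf(sim$path)
  expect_equal(nrow(back), 30)
  expect_equal(back$pos, sim$variants$pos)
  for (cl in attr(sim$variants, "gt_cols")) {
    expect_equal(back[[cl]], sim$variants[[cl]])
  }
  # multi-allelic records split into biallelic ones
  multi <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chr1\t100\t.\tA\tC,G\t.\tPASS\t.\tGT\t1/2"), multi)
  vm <- read_variants_vcf(multi)
  expect_equal(nrow(vm), 2)
  expect_equal(vm$alt, c("C", "G"))
  expect_equal(vm$gt_s1, c("het", "het"))
})
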