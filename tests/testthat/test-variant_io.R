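make_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", lines), path)
  path
}

test_that("read_snvs keeps biallelic PASS SNVs and splits multiallelics", {
  p <- make_vcf(c("chr1\t1000\t.\tC\tT\t.\tPASS\t.",
                  "chr1\t2000\t.\tC\tT,G\t.\tPASS\t.",
                  "chr1\t3000\t.\tCA\tC\t.\tPASS\t.",     # indel
                  "chr1\t4000\t.\tC\t<DEL>\t.\tPASS\t.",  # symbolic
                  "chr1\t5000\t.\tC\tT\t.\tlowqual\t."))
  rec <- read_snvs(p, "s1")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$pos, c(1000L, 2000L, 2000L))
  expect_setequal(rec$alt[rec$pos == 2000], c("T", "G"))
  expect_equal(attr(rec, "n_skipped"), 3)
  rec_all <- read_snvs(p, "s1", pass_only = FALSE)
  expect_equal(nrow(rec_all), 4)
})

test_that("a VCF with no variant lines yields an empty record set", {
  rec <- read_snvs(make_vcf(character(0)), "s1")
  expect_equal(nrow(rec), 0)
})

test_that("simulator VCFs round-trip with identical keys", {
  sim <- generate_positioned_cohort(
    n_samples = 2, chrom_lengths = c(chr1 = 2e5, chr2 = 2e5),
    background_rate = 2e-4,
    signatures = sigcraft:::random_sparse_signatures(2, seed = 3),
    seed = 5, out_dir = tempfile("rt"))
  for (sid in names(sim$files$vcfs)) {
    got <- read_snvs(sim$files$vcfs[[sid]], sid)
    want <- sim$mutations[sim$mutations$sample_id == sid, ]
    expect_equal(nrow(got), nrow(want))
    key <- function(d) sort(paste(sigcraft:::norm_chrom(d$chrom), d$pos,
                                  d$ref, d$alt))
    expect_identical(key(got), key(want))
  }
})

test_that("consensus keeps variants seen by enough callers", {
  base <- random_snv_records(20, seed = 2, sample_ids = "s1")
  base <- base[!duplicated(base[c("chrom", "pos")]), ]
  cs <- list(base[1:10, ], base[5:15, ], base[8:18, ], base[10, , drop = FALSE])
  twoplus <- consensus_calls(cs, 2)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  # a variant in exactly 2 of 4 callsets is retained
  only_in_1_and_2 <- setdiff(intersect(key(cs[[1]]), key(cs[[2]])), key(cs[[3]]))
  expect_true(all(only_in_1_and_2 %in% key(twoplus)))
  # a variant private to one caller is dropped
  private <- setdiff(key(cs[[1]]), c(key(cs[[2]]), key(cs[[3]]), key(cs[[4]])))
  expect_false(any(private %in% key(twoplus)))
  # union / intersection limits and monotonicity
  expect_setequal(key(consensus_calls(cs, 1)), unique(unlist(lapply(cs, key))))
  expect_setequal(key(consensus_calls(cs, 4)),
                  Reduce(intersect, lapply(cs, key)))
  sizes <- sapply(1:4, function(k) nrow(consensus_calls(cs, k)))
  expect_true(all(diff(sizes) <= 0))
  expect_error(consensus_calls(cs, 0), ">= 1")
  expect_error(consensus_calls(cs, 5), "exceeds")
})

test_that("fetch_context returns the trinucleotide around a position", {
  g <- Biostrings::DNAStringSet(c(chrZ = "ACGTA"))
  expect_identical(fetch_context(g, "chrZ", 3), "CGT")
  expect_identical(fetch_context(g, "Z", 2), "ACG")  # chr prefix stripped
  expect_error(fetch_context(g, "Z", 1), "edge")
  expect_error(fetch_context(g, "Z", 5), "edge")
  expect_error(fetch_context(g, "nope", 3), "absent")
})

test_that("signature tables round-trip and are order-normalized", {
  set.seed(9)
  S <- matrix(rgamma(96 * 2, 1), 96, 2)
  S <- sweep(S, 2, colSums(S), "/")
  dimnames(S) <- list(sbs96_channels(), c("sigA", "sigB"))
  p <- tempfile(fileext = ".tsv")
  write_matrix(S, p)
  S2 <- read_signature_table(p)
  expect_matrix_equal(S, S2, tol = 1e-9)

  # shuffled rows read back identically
  df <- read.table(p, header = TRUE, sep = "\t", check.names = FALSE)
  df <- df[sample(96), ]
  p2 <- tempfile(fileext = ".tsv")
  write.table(df, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_matrix_equal(S, read_signature_table(p2), tol = 1e-9)

  # format errors are named
  expect_error(read_signature_table(p2, renormalize = TRUE), NA)
  df_bad <- df[-1, ]
  write.table(df_bad, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_table(p2), "96 data rows")
  df_neg <- df; df_neg[1, 2] <- -1
  write.table(df_neg, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_table(p2), "negative")
  df_lab <- df; df_lab[1, 1] <- "A[C>U]A"
  write.table(df_lab, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_table(p2), "unknown channel")
})

test_that("BED intervals convert to 1-based inclusive coordinates", {
  p <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200", p)
  r <- read_bed_regions(p)
  expect_equal(r$start, 100)
  expect_equal(r$end, 200)
  m <- data.frame(sample_id = "s", chrom = "chr1", pos = c(99, 100, 200, 201),
                  ref = "C", alt = "T", context = NA_character_)
  kept <- restrict_to_regions(m, r)
  expect_equal(kept$pos, c(100, 200))
})
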