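# reading, filtering, merging, polarization and spectra of TE/SNP tables

snp_info <- function(QD = 20, FS = 5, SOR = 1, MQ = 55, MQRS = 0, RPRS = 0) {
  sprintf("VC=SNP;QD=%g;FS=%g;SOR=%g;MQ=%g;MQRankSum=%g;ReadPosRankSum=%g",
          QD, FS, SOR, MQ, MQRS, RPRS)
}

test_that("VCF + age table join produces one record per site and logs misses", {
  samples <- c("a1", "a2", "c1")
  rows <- list(
    list(chrom = "chr1", pos = 100, id = "v1", ref = "A", alt = "T",
         info = snp_info(), gts = c("0/0", "1/1", "0/0")),
    list(chrom = "chr1", pos = 200, id = "v2", ref = "G", alt = "C",
         info = snp_info(), gts = c("1/1", "1/1", "0/0")),
    list(chrom = "chr2", pos = 50, id = "t1", ref = "A", alt = "<INS>",
         info = "VC=TE;TC=retrotransposon;FAM=fam1", gts = c("1/1", "0/0", "0/0")))
  vcf <- toy_vcf_file(rows, samples)
  ages <- tibble::tibble(variant_id = c("v1", "v2", "t1"), clade = "A",
                         age_generations = c(100, 200, 300))

  pd <- suppressMessages(read_polymorphism_table(vcf, toy_age_file(ages)))
  expect_equal(nrow(pd$records), 3)
  expect_equal(sort(pd$records$variant_id), c("t1", "v1", "v2"))
  expect_equal(pd$records$var_class[pd$records$variant_id == "t1"], "TE")
  expect_equal(pd$records$te_class[pd$records$variant_id == "t1"], "retrotransposon")
  expect_true(all(is.na(pd$records$te_class[pd$records$var_class == "SNP"])))
  expect_equal(nrow(pd$ages), 3)

  # age table missing one variant: records retained, warning emitted
  expect_warning(
    pd2 <- suppressMessages(read_polymorphism_table(vcf, toy_age_file(ages[-1, ]))),
    "no age estimate")
  expect_equal(nrow(pd2$records), 3)
  expect_equal(nrow(pd2$ages), 2)
})

test_that("row order does not affect the joined record set", {
  samples <- c("a1", "a2")
  rows <- lapply(1:6, function(i) {
    list(chrom = "chr1", pos = i * 10, id = paste0("v", i), ref = "A",
         alt = "T", info = snp_info(QD = i), gts = c("0/0", "1/1"))
  })
  v1 <- suppressMessages(read_polymorphism_table(toy_vcf_file(rows, samples)))
  v2 <- suppressMessages(read_polymorphism_table(
    toy_vcf_file(rev(rows), samples)))
  o1 <- dplyr::arrange(v1$records, variant_id)
  o2 <- dplyr::arrange(v2$records, variant_id)
  expect_equal(o1, o2)
})

test_that("duplicate variant ids are a hard error naming the id", {
  samples <- "a1"
  rows <- list(
    list(chrom = "chr1", pos = 1, id = "dup", ref = "A", alt = "T",
         info = snp_info(), gts = "0/0"),
    list(chrom = "chr1", pos = 2, id = "dup", ref = "A", alt = "T",
         info = snp_info(), gts = "0/0"))
  expect_error(read_polymorphism_table(toy_vcf_file(rows, samples)), "dup")
})

test_that("hard filters remove failing SNPs and spare boundaries and TEs", {
  rec <- make_records(3)
  rec$QD <- c(4.9, 5.0, 20)           # first fails QD < 5
  rec$FS <- c(5, 20.0, 5); rec$SOR <- c(1, 3.0, 1)
  rec$MQ <- c(55, 50.0, 55)
  rec$MQRankSum <- c(0, 0, 0); rec$ReadPosRankSum <- c(0, 0, 0)
  out <- suppressMessages(apply_snp_hard_filters(rec))
  expect_equal(out$variant_id, c("v002", "v003"))  # boundary values retained

  te <- make_records(1, var_class = "TE")
  te$QD <- 0.1  # would fail as a SNP; TEs pass through
  expect_equal(nrow(apply_snp_hard_filters(te)), 1)
})

test_that("hard-filter survivors equal brute-force evaluation of all eight conditions", {
  rec <- make_records(40, seed = 7)
  keep <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    fails <- c(rec$QD[i] < 5.0, rec$FS[i] > 20.0, rec$SOR[i] > 3.0,
               rec$MQ[i] < 50.0, rec$MQRankSum[i] > 2.5,
               rec$MQRankSum[i] < -2.5, rec$ReadPosRankSum[i] > 2.0,
               rec$ReadPosRankSum[i] < -2.0)
    keep[i] <- !any(fails, na.rm = TRUE)
  }
  out <- suppressMessages(apply_snp_hard_filters(rec))
  expect_equal(out$variant_id, rec$variant_id[keep])
  # idempotent
  expect_equal(suppressMessages(apply_snp_hard_filters(out)), out)
})

test_that("heterozygote and multiallelic cleaning matches defined behaviour", {
  rec <- make_records(3)
  rec$calls[[1]] <- c(s1 = "0/1", s2 = "1/1", s3 = "0/0")
  rec$alt[2] <- "T,G"                       # triallelic -> dropped
  rec$calls[[3]] <- c(s1 = "0|1", s2 = "0/0")
  out <- suppressMessages(remove_het_and_multiallelic(rec))
  expect_equal(out$variant_id, c("v001", "v003"))
  expect_true(is.na(out$calls[[1]][["s1"]]))
  expect_equal(out$calls[[1]][["s2"]], "1/1")
  expect_true(is.na(out$calls[[2]][["s1"]]))

  # TE calls recoded homozygous
  te <- make_records(1, var_class = "TE")
  te$calls[[1]] <- c(s1 = "0/1", s2 = "1", s3 = "0", s4 = NA)
  out_te <- remove_het_and_multiallelic(te)
  expect_equal(unname(out_te$calls[[1]][1:3]), c("1/1", "1/1", "0/0"))
  expect_true(is.na(out_te$calls[[1]][[4]]))
  # idempotent
  expect_equal(remove_het_and_multiallelic(out_te), out_te)
})

make_te_records <- function(pos, family, calls_list = NULL) {
  n <- length(pos)
  tb <- make_records(n, var_class = "TE")
  tb$pos <- pos
  tb$family <- family
  if (!is.null(calls_list)) tb$calls <- calls_list
  tb
}

test_that("TIP merging follows the strict <100 bp single-linkage rule", {
  # 99 bp apart: merged
  te <- make_te_records(c(100L, 199L), c("f1", "f1"))
  out <- suppressMessages(merge_tips(te))
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 100L)

  # exactly 100 bp apart: NOT merged
  te2 <- make_te_records(c(100L, 200L), c("f1", "f1"))
  expect_equal(nrow(merge_tips(te2)), 2)

  # chain 100/180/260 collapses by single linkage
  te3 <- make_te_records(c(100L, 180L, 260L), c("f1", "f1", "f1"))
  out3 <- suppressMessages(merge_tips(te3))
  expect_equal(nrow(out3), 1)
  expect_setequal(out3$merged_ids[[1]], te3$variant_id)

  # different families never merge
  te4 <- make_te_records(c(100L, 150L), c("f1", "f2"))
  expect_equal(nrow(merge_tips(te4)), 2)

  # presence calls are unioned
  te5 <- make_te_records(
    c(100L, 150L), c("f1", "f1"),
    list(c(s1 = "1/1", s2 = "0/0", s3 = NA),
         c(s1 = "0/0", s2 = "1/1", s3 = "0/0")))
  out5 <- suppressMessages(merge_tips(te5))
  g <- out5$calls[[1]]
  expect_equal(unname(g[c("s1", "s2", "s3")]), c("1/1", "1/1", "0/0"))
})

test_that("TIP merging equals brute-force transitive closure on random inputs", {
  set.seed(11)
  n <- 60
  te <- make_te_records(sort(sample.int(3000, n)),
                        sample(c("fA", "fB"), n, replace = TRUE))
  out <- suppressMessages(merge_tips(te))

  # oracle: transitive closure of the pairwise <100 bp same-family relation
  groups <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (te$family[i] == te$family[j] && abs(te$pos[i] - te$pos[j]) < 100 &&
          groups[i] != groups[j]) {
        groups[groups == groups[j]] <- groups[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  expect_equal(nrow(out), length(unique(groups)))
  expect_true(nrow(out) <= n)
  # merged sets partition the input
  expect_setequal(unlist(out$merged_ids), te$variant_id)
  # idempotent
  expect_equal(nrow(suppressMessages(merge_tips(out))), nrow(out))
})

test_that("polarization against a fixed outgroup assigns the derived allele", {
  rec <- make_records(3)
  clades <- tibble::tibble(sample = c("f1", "f2", "f3", "o1", "o2"),
                           clade = c("A", "A", "A", "C", "C"))
  # outgroup fixed REF -> derived = ALT, focal ALT freq 1/3
  rec$calls[[1]] <- c(f1 = "1/1", f2 = "0/0", f3 = "0/0", o1 = "0/0", o2 = "0/0")
  # outgroup fixed ALT -> derived = REF, focal REF freq 1/3 -> derived 2/3... use same calls
  rec$calls[[2]] <- c(f1 = "1/1", f2 = "0/0", f3 = "0/0", o1 = "1/1", o2 = "1/1")
  # outgroup segregating -> excluded
  rec$calls[[3]] <- c(f1 = "1/1", f2 = "0/0", f3 = "0/0", o1 = "0/0", o2 = "1/1")
  sites <- suppressMessages(polarize(rec, clades))
  expect_equal(nrow(sites), 2)
  expect_equal(sites$derived_freq[sites$variant_id == "v001"], 1 / 3)
  expect_equal(sites$derived_freq[sites$variant_id == "v002"], 2 / 3)
  expect_equal(sites$minor_freq, pmin(sites$derived_freq, 1 - sites$derived_freq))
  excl <- attr(sites, "exclusions")
  expect_equal(excl$n[excl$reason == "outgroup_polymorphic"], 1L)
})

test_that("folded SFS folds frequencies and conserves total mass", {
  sites <- tibble::tibble(minor_freq = pmin(c(0.1, 0.9, 0.5), 1 - c(0.1, 0.9, 0.5)))
  expect_equal(sites$minor_freq, c(0.1, 0.1, 0.5))
  sfs <- folded_sfs(sites)
  expect_equal(sum(sfs$n), 3)

  # random panel vs brute-force histogram
  set.seed(3)
  p <- runif(500)
  mf <- pmin(p, 1 - p)
  sfs2 <- folded_sfs(tibble::tibble(minor_freq = mf))
  brk <- seq(0, 0.5, by = 0.05)
  oracle <- as.vector(table(cut(mf, brk, include.lowest = TRUE)))
  expect_equal(sfs2$n, oracle)
  expect_equal(sum(sfs2$n), 500)

  expect_error(folded_sfs(tibble::tibble(minor_freq = 0.6)), "0.5")
})

test_that("gene-distance categories follow the inclusive 1 kb / 5 kb edges", {
  genes <- tibble::tibble(chrom = "chr1", start = 10000L, end = 20000L, id = "g1")
  gff <- toy_gff3_file(genes)
  sites <- tibble::tibble(
    variant_id = paste0("v", 1:5), chrom = "chr1",
    pos = c(15000L,    # inside
            21000L,    # 1000 bp from end -> genic_to_1kb
            21001L,    # 1001 bp -> 1kb_to_5kb
            25000L,    # 5000 bp -> 1kb_to_5kb
            26000L))   # 6000 bp -> over_5kb
  out <- classify_gene_distance(sites, gff)
  expect_equal(out$gene_distance, c(0, 1000, 1001, 5000, 6000))
  expect_equal(out$gene_distance_category,
               c("genic_to_1kb", "genic_to_1kb", "1kb_to_5kb", "1kb_to_5kb",
                 "over_5kb"))

  # chromosome absent from the annotation -> NA with warning
  off <- tibble::tibble(variant_id = "x", chrom = "chrZ", pos = 5L)
  expect_warning(out2 <- classify_gene_distance(off, gff), "absent")
  expect_true(is.na(out2$gene_distance_category))
})

test_that("gene distances equal a brute-force nearest-edge scan", {
  set.seed(5)
  genes <- tibble::tibble(chrom = "chr1",
                          start = sort(sample.int(9e4, 8)), id = paste0("g", 1:8))
  genes$end <- genes$start + sample(500:3000, 8)
  sites <- tibble::tibble(variant_id = paste0("v", 1:50), chrom = "chr1",
                          pos = sample.int(1e5, 50))
  out <- classify_gene_distance(sites, toy_gff3_file(genes))
  oracle <- vapply(sites$pos, function(p) {
    d <- pmax(0, genes$start - p, p - genes$end)
    min(d)
  }, numeric(1))
  expect_equal(out$gene_distance, oracle)
})
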