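# programmatic fixtures: toy VCF / GFF3 / TSV inputs and records tibbles

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=VC,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=TC,Number=1,Type=String,Description=\"TE class\">",
    "##INFO=<ID=SF,Number=1,Type=String,Description=\"TE superfamily\">",
    "##INFO=<ID=FAM,Number=1,Type=String,Description=\"TE family\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# rows: list of lists with chrom, pos, id, ref, alt, info, gts (character
# vector, one per sample)
toy_vcf_file <- function(rows, samples, path = tempfile(fileext = ".vcf")) {
  body <- vapply(rows, function(r) {
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", r$info, "GT",
            r$gts), collapse = "\t")
  }, character(1))
  writeLines(c(vcf_header(samples), body), path)
  path
}

toy_gff3_file <- function(genes, path = tempfile(fileext = ".gff3")) {
  # genes: tibble with chrom, start, end, id
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$id))
  writeLines(lines, path)
  path
}

toy_age_file <- function(ages, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(ages, path)
  path
}

toy_clade_file <- function(clades, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(clades, path)
  path
}

# records tibble in the shape produced by read_polymorphism_table(),
# built directly for ops that do not need VCF parsing
make_records <- function(n, seed = 1, var_class = "SNP", chrom = "chr1",
                         samples = paste0("s", 1:6)) {
  set.seed(seed)
  tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(n)),
    chrom = chrom,
    pos = sort(sample.int(1e5, n)),
    ref = "A", alt = "T",
    var_class = var_class,
    te_class = ifelse(var_class == "TE", "retrotransposon", NA_character_),
    superfamily = NA_character_,
    family = NA_character_,
    effect = NA_character_,
    QD = runif(n, 0, 40), FS = runif(n, 0, 40), SOR = runif(n, 0, 6),
    MQ = runif(n, 20, 60), MQRankSum = runif(n, -5, 5),
    ReadPosRankSum = runif(n, -4, 4),
    calls = lapply(seq_len(n), function(i) {
      g <- sample(c("0/0", "1/1", NA), length(samples), replace = TRUE)
      stats::setNames(g, samples)
    })
  )
}

# quick neutral/focal synthetic site pair for pipeline tests
toy_site_pair <- function(n_focal = 300, n_neutral = 3000, r = 1, S = 0,
                          seed = 1, ...) {
  cfg <- synth_config(n_sites_focal = n_focal, n_sites_neutral = n_neutral,
                      neutral_ratio_r = r, scaled_S = S, seed = seed, ...)
  sites <- generate_dataset(cfg)
  list(focal = sites[sites$class == "focal", ],
       neutral = sites[sites$class == "neutral", ])
}
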