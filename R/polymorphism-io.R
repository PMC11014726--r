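#' Read a combined TE/SNP polymorphism table
#'
#' Reads a VCF holding both SNPs and TE presence/absence polymorphisms,
#' together with an optional per-variant allele-age table (as produced by an
#' external age estimator, e.g. GEVA) and an optional sample-to-clade
#' assignment table.
#'
#' Variant class annotations are taken from the INFO column: `VC` (values
#' `SNP` or `TE`), `TC` (TE class: `retrotransposon`, `DNA_transposon`,
#' `unclassified`), `SF` (superfamily), `FAM` (family) and `EFF` (SnpEff-style
#' effect label: `synonymous`, `non_synonymous`, `high_effect`). SNP records
#' additionally carry the standard GATK site annotations `QD`, `FS`, `SOR`,
#' `MQ`, `MQRankSum` and `ReadPosRankSum` used by [apply_snp_hard_filters()].
#'
#' @param variant_file path to a VCF (v4.x, plain text or gzipped).
#' @param age_file optional path to a tab-separated table with columns
#'   `variant_id`, `clade`, `age_generations`; ages are point estimates of
#'   allele age in generations and must be positive.
#' @param clade_file optional path to a tab-separated table with columns
#'   `sample`, `clade` and optionally `coverage` (mean mapping coverage).
#' @param min_coverage if not `NULL`, restrict genotype calls to samples with
#'   `coverage >= min_coverage` (the clade table must then carry a
#'   `coverage` column).
#'
#' @return A list with components `records` (a tibble, one row per variant,
#'   with a `calls` list-column of named per-sample genotype strings),
#'   `ages` (a tibble or `NULL`) and `clades` (a tibble or `NULL`).
#' @export
read_polymorphism_table <- function(variant_file, age_file = NULL,
                                    clade_file = NULL, min_coverage = NULL) {
  if (!file.exists(variant_file)) {
    abort(paste0("variant file not found: ", variant_file))
  }
  v <- vcfR::read.vcfR(variant_file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)

  ids <- fix$ID
  auto <- is.na(ids) | ids == "."
  ids[auto] <- paste0(fix$CHROM[auto], "_", fix$POS[auto])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(paste0("duplicate variant_id in variant file: ", dup))
  }
  v@fix[, "ID"] <- ids  # ensure unique row names for genotype extraction
  gt <- vcfR::extract.gt(v, element = "GT")

  info_chr <- function(key) {
    out <- suppressWarnings(vcfR::extract.info(v, element = key))
    if (is.null(out)) rep(NA_character_, nrow(fix)) else as.character(out)
  }
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }

  var_class <- info_chr("VC")
  var_class[is.na(var_class)] <- "SNP"
  te_class <- info_chr("TC")
  te_class[var_class == "TE" & is.na(te_class)] <- "unclassified"
  te_class[var_class == "SNP"] <- NA_character_

  calls <- lapply(seq_len(nrow(gt)), function(i) {
    gi <- gt[i, , drop = TRUE]
    gi[gi %in% c(".", "./.", ".|.")] <- NA_character_
    gi
  })

  records <- tibble(
    variant_id = ids,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    var_class = var_class,
    te_class = te_class,
    superfamily = info_chr("SF"),
    family = info_chr("FAM"),
    effect = info_chr("EFF"),
    QD = info_num("QD"),
    FS = info_num("FS"),
    SOR = info_num("SOR"),
    MQ = info_num("MQ"),
    MQRankSum = info_num("MQRankSum"),
    ReadPosRankSum = info_num("ReadPosRankSum"),
    calls = calls
  )
  if (any(records$pos < 1, na.rm = TRUE)) abort("VCF positions must be >= 1")

  ages <- NULL
  if (!is.null(age_file)) {
    ages <- readr::read_tsv(age_file, show_col_types = FALSE)
    need <- c("variant_id", "clade", "age_generations")
    if (!all(need %in% names(ages))) {
      abort(paste0("age table must have columns: ", paste(need, collapse = ", ")))
    }
    bad <- !is.finite(ages$age_generations) | ages$age_generations <= 0
    if (any(bad)) {
      warn(paste0("dropping ", sum(bad), " age rows with non-positive or missing age"))
      ages <- ages[!bad, , drop = FALSE]
    }
    n_aged <- sum(records$variant_id %in% unique(ages$variant_id))
    n_missing <- nrow(records) - n_aged
    if (n_missing > 0) {
      warn(paste0(n_missing, " of ", nrow(records),
                  " variants have no age estimate; they are retained in the",
                  " records but excluded from age-based analyses"))
    }
    inform(paste0("joined ages for ", n_aged, " of ", nrow(records), " variants"))
  }

  clades <- NULL
  if (!is.null(clade_file)) {
    clades <- readr::read_tsv(clade_file, show_col_types = FALSE)
    if (!all(c("sample", "clade") %in% names(clades))) {
      abort("clade table must have columns: sample, clade")
    }
    if (!is.null(min_coverage)) {
      if (!"coverage" %in% names(clades)) {
        abort("min_coverage requested but clade table has no coverage column")
      }
      keep <- clades$sample[!is.na(clades$coverage) & clades$coverage >= min_coverage]
      inform(paste0("coverage filter >= ", min_coverage, "x keeps ",
                    length(keep), " of ", nrow(clades), " samples"))
      records$calls <- lapply(records$calls, function(g) g[names(g) %in% keep])
      clades <- clades[clades$sample %in% keep, , drop = FALSE]
    }
  }

  list(records = records, ages = ages, clades = clades)
}

#' Hard-filter SNP records on GATK site annotations
#'
#' A SNP is removed when any of its site annotations falls in the failing
#' range: `QD < 5`, `FS > 20`, `SOR > 3`, `MQ < 50`, `|MQRankSum| > 2.5` or
#' `|ReadPosRankSum| > 2` (all strict). A missing annotation never fails its
#' condition, so SNPs lacking an annotation are retained for that condition.
#' TE records pass through untouched.
#'
#' @param records a records tibble from [read_polymorphism_table()].
#' @return The surviving records tibble.
#' @export
apply_snp_hard_filters <- function(records) {
  f <- function(x) !is.na(x) & x  # missing annotation -> condition not met
  fails <- f(records$QD < 5.0) |
    f(records$FS > 20.0) |
    f(records$SOR > 3.0) |
    f(records$MQ < 50.0) |
    f(records$MQRankSum > 2.5) |
    f(records$MQRankSum < -2.5) |
    f(records$ReadPosRankSum > 2.0) |
    f(records$ReadPosRankSum < -2.0)
  fails <- fails & records$var_class == "SNP"
  if (any(fails)) {
    inform(paste0("hard filters removed ", sum(fails), " of ",
                  sum(records$var_class == "SNP"), " SNPs"))
  }
  records[!fails, , drop = FALSE]
}

is_het <- function(g) {
  a <- strsplit(g, "[/|]")
  vapply(a, function(x) length(unique(x[x != "."])) > 1, logical(1))
}

#' Remove heterozygous calls and multiallelic sites
#'
#' Heterozygous SNP genotypes are set to missing (the target system is highly
#' selfing, so heterozygous calls are treated as likely errors); any site with
#' more than two alleles is dropped; TE calls are recoded homozygous
#' (presence `1/1`, absence `0/0`).
#'
#' @inheritParams apply_snp_hard_filters
#' @return The cleaned records tibble.
#' @export
remove_het_and_multiallelic <- function(records) {
  multi <- !is.na(records$alt) & grepl(",", records$alt, fixed = TRUE)
  if (any(multi)) {
    inform(paste0("dropped ", sum(multi), " multiallelic sites"))
  }
  records <- records[!multi, , drop = FALSE]

  te <- records$var_class == "TE"
  records$calls <- lapply(seq_len(nrow(records)), function(i) {
    g <- records$calls[[i]]
    if (te[i]) {
      # any evidence of presence counts as a homozygous presence call
      out <- ifelse(is.na(g), NA_character_,
                    ifelse(grepl("1", g, fixed = TRUE), "1/1", "0/0"))
      setNames(out, names(g))
    } else {
      g[!is.na(g) & is_het(g)] <- NA_character_
      g
    }
  })
  records
}

#' Merge nearby same-family TE insertion polymorphisms
#'
#' TE insertions called at slightly different positions in different samples
#' often represent one insertion event. Same-family TE records on the same
#' chromosome whose consecutive positions are less than `max_gap` bp apart
#' are merged by single-linkage chaining; the merged record keeps the
#' leftmost position and the per-sample union of presence calls. Records
#' without a family assignment, and all SNP records, pass through untouched.
#'
#' @inheritParams apply_snp_hard_filters
#' @param max_gap merge when consecutive positions differ by strictly less
#'   than this many bp (default 100).
#' @return The records tibble with merged TE rows; merged rows gain a
#'   `merged_ids` list-column naming their members.
#' @export
merge_tips <- function(records, max_gap = 100) {
  is_mergeable <- records$var_class == "TE" & !is.na(records$family)
  keep <- records[!is_mergeable, , drop = FALSE]
  te <- records[is_mergeable, , drop = FALSE]
  if (nrow(te) == 0) {
    records$merged_ids <- as.list(records$variant_id)
    return(records)
  }

  te <- dplyr::arrange(te, .data$chrom, .data$family, .data$pos)
  gap_break <- c(TRUE, diff(te$pos) >= max_gap) |
    c(TRUE, te$chrom[-1] != te$chrom[-nrow(te)]) |
    c(TRUE, te$family[-1] != te$family[-nrow(te)])
  te$.cluster <- cumsum(gap_break)

  merged <- te |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::group_modify(function(d, key) {
      first <- d[1, , drop = FALSE]
      if (nrow(d) > 1) {
        samples <- unique(unlist(lapply(d$calls, names)))
        g <- rep(NA_character_, length(samples))
        names(g) <- samples
        for (ci in d$calls) {
          present <- names(ci)[!is.na(ci) & ci == "1/1"]
          absent <- names(ci)[!is.na(ci) & ci == "0/0"]
          g[present] <- "1/1"
          g[absent[is.na(g[absent])]] <- "0/0"
        }
        first$calls <- list(g)
        first$pos <- min(d$pos)
      }
      first$merged_ids <- list(d$variant_id)
      first
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-".cluster")

  n_merged <- nrow(te) - nrow(merged)
  if (n_merged > 0) {
    inform(paste0("merged ", nrow(te), " TE records into ", nrow(merged),
                  " (", n_merged, " collapsed)"))
  }
  keep$merged_ids <- as.list(keep$variant_id)
  out <- dplyr::bind_rows(merged, keep)
  dplyr::arrange(out, .data$chrom, .data$pos)
}

allele_counts <- function(g) {
  # g: genotype strings, hets already removed/recoded; count allele copies
  g <- g[!is.na(g)]
  n1 <- sum(g == "1/1")
  n0 <- sum(g == "0/0")
  c(ref = n0, alt = n1)
}

#' Polarize variants against an outgroup clade
#'
#' Assigns the derived allele per site using the calls of an outgroup clade:
#' when the outgroup is fixed for one allele, the other allele is derived.
#' Sites whose outgroup calls are polymorphic or entirely missing cannot be
#' polarized and are excluded (and counted in the exclusion log). Derived
#' allele frequencies are computed per focal clade over non-missing calls.
#'
#' @inheritParams apply_snp_hard_filters
#' @param clades a tibble with columns `sample` and `clade`.
#' @param outgroup name of the outgroup clade (default `"C"`).
#' @param focal_clades clades to compute frequencies for; defaults to all
#'   clades except the outgroup.
#' @return A sites tibble with one row per (variant, focal clade):
#'   `variant_id`, `clade`, `derived_freq`, `minor_freq`, `n_calls` plus the
#'   variant annotation columns. Carries an `exclusions` attribute tibble.
#' @export
polarize <- function(records, clades, outgroup = "C", focal_clades = NULL) {
  stopifnot(all(c("sample", "clade") %in% names(clades)))
  og_samples <- clades$sample[clades$clade == outgroup]
  if (length(og_samples) == 0) abort(paste0("no samples in outgroup clade ", outgroup))
  focal_clades <- focal_clades %||% setdiff(unique(clades$clade), outgroup)

  excl <- character(0)
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    g <- records$calls[[i]]
    og <- allele_counts(g[names(g) %in% og_samples])
    if (sum(og) == 0) { excl <- c(excl, "outgroup_missing"); next }
    if (og["ref"] > 0 && og["alt"] > 0) { excl <- c(excl, "outgroup_polymorphic"); next }
    derived_is_alt <- og["alt"] == 0
    per_clade <- lapply(focal_clades, function(cl) {
      cs <- clades$sample[clades$clade == cl]
      cc <- allele_counts(g[names(g) %in% cs])
      n <- sum(cc)
      if (n == 0) return(NULL)
      df <- if (derived_is_alt) cc["alt"] / n else cc["ref"] / n
      tibble(variant_id = records$variant_id[i], clade = cl,
             derived_freq = unname(df),
             minor_freq = min(unname(df), 1 - unname(df)),
             n_calls = n)
    })
    rows[[i]] <- dplyr::bind_rows(per_clade)
  }
  sites <- dplyr::bind_rows(rows)
  ann <- dplyr::select(records, "variant_id", "chrom", "pos", "var_class",
                       "te_class", "superfamily", "family", "effect")
  sites <- dplyr::left_join(sites, ann, by = "variant_id")

  excl_tbl <- if (length(excl)) dplyr::count(tibble(reason = excl), .data$reason) else
    tibble(reason = character(0), n = integer(0))
  if (nrow(excl_tbl)) {
    inform(paste0("excluded ", sum(excl_tbl$n),
                  " sites from polarization (",
                  paste(paste0(excl_tbl$reason, ": ", excl_tbl$n), collapse = "; "),
                  ")"))
  }
  attr(sites, "exclusions") <- excl_tbl
  sites
}

#' Attach allele-age estimates to polarized sites
#'
#' @param sites a sites tibble from [polarize()] (or any tibble with
#'   `variant_id` and, if the age table has per-clade ages, `clade`).
#' @param ages age tibble with columns `variant_id`, `clade`,
#'   `age_generations`.
#' @return `sites` with an `age` column; rows lacking an age keep `NA` and
#'   are excluded from age-based analyses downstream.
#' @export
annotate_ages <- function(sites, ages) {
  by <- intersect(c("variant_id", "clade"), intersect(names(sites), names(ages)))
  out <- dplyr::left_join(sites, dplyr::rename(ages, age = "age_generations"), by = by)
  n_na <- sum(is.na(out$age))
  if (n_na > 0) {
    warn(paste0(n_na, " of ", nrow(out), " sites lack an age estimate"))
  }
  out
}

#' Folded site frequency spectrum
#'
#' Histogram of minor allele frequencies; total mass equals the number of
#' input (segregating) sites.
#'
#' @param sites a tibble with a `minor_freq` column in \[0, 0.5\].
#' @param breaks histogram break points on \[0, 0.5\].
#' @return A tibble with columns `lower`, `upper`, `n`.
#' @export
folded_sfs <- function(sites, breaks = seq(0, 0.5, by = 0.05)) {
  mf <- sites$minor_freq
  if (any(is.na(mf)) || any(mf < 0) || any(mf > 0.5)) {
    abort("minor_freq must lie in [0, 0.5] for all sites")
  }
  bin <- cut(mf, breaks = breaks, include.lowest = TRUE, right = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  tibble(lower = head(breaks, -1), upper = tail(breaks, -1), n = counts)
}

#' Classify variants by distance to the nearest gene
#'
#' Distance is measured in bp from the variant position to the nearest gene
#' body edge (0 if the variant lies inside a gene). Categories:
#' `genic_to_1kb` (distance <= 1000 bp, inclusive), `1kb_to_5kb`
#' (1000 < d <= 5000) and `over_5kb` (d > 5000). Variants on chromosomes
#' absent from the annotation get `NA` with a warning.
#'
#' @param sites a tibble with `chrom` and `pos` columns.
#' @param gff3 path to a GFF3 file, or a `GRanges` of gene features.
#' @return `sites` with `gene_distance` and `gene_distance_category` columns.
#' @export
classify_gene_distance <- function(sites, gff3) {
  genes <- if (is.character(gff3)) {
    gr <- rtracklayer::import(gff3)
    gr[!is.na(gr$type) & gr$type == "gene"]
  } else gff3
  if (length(genes) == 0) abort("no gene features found in annotation")

  d <- rep(NA_real_, nrow(sites))
  on_chr <- sites$chrom %in% as.character(GenomicRanges::seqnames(genes))
  if (any(!on_chr)) {
    warn(paste0(sum(!on_chr), " variants on chromosomes absent from the ",
                "gene annotation; gene_distance_category set to NA"))
  }
  if (any(on_chr)) {
    q <- GenomicRanges::GRanges(
      seqnames = sites$chrom[on_chr],
      ranges = IRanges::IRanges(start = sites$pos[on_chr], width = 1))
    inside <- IRanges::overlapsAny(q, genes, ignore.strand = TRUE)
    hits <- GenomicRanges::distanceToNearest(q, genes, ignore.strand = TRUE)
    dn <- rep(NA_real_, length(q))
    dn[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    # GRanges distance counts positions strictly between the ranges; the
    # closed-interval edge distance is one more, except inside a gene
    edge <- ifelse(inside, 0, dn + 1)
    d[on_chr] <- edge
  }
  sites$gene_distance <- d
  sites$gene_distance_category <- dplyr::case_when(
    is.na(d) ~ NA_character_,
    d <= 1000 ~ "genic_to_1kb",
    d <= 5000 ~ "1kb_to_5kb",
    TRUE ~ "over_5kb"
  )
  sites
}
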