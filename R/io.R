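#' Read region-grouped genotypes from a VCF
#'
#' Extracts biallelic variants in a 1-based inclusive interval, codes them as
#' minor-allele counts on the analysed samples, and applies the rare-variant
#' frequency filter.  "Minor" is decided per variant within the analysed
#' samples: if the ALT allele frequency exceeds 0.5 the counts are flipped so
#' the column encodes the (rarer) REF allele.
#'
#' Missing genotypes are imputed to zero minor-allele copies (the most likely
#' value for rare variants); variants with more than `max_missing` missing
#' calls are dropped, and per-variant missingness is reported.
#'
#' @param vcf_path Path to a VCF (plain or bgzipped); the whole file is read
#'   and filtered in memory, so per-gene or per-chromosome files are expected.
#' @param chrom,start,end Region, 1-based inclusive.
#' @param sample_ids Optional ordered subset of samples; all must exist.
#' @param maf_max Keep variants with post-filter sample MAF in (0, maf_max].
#' @param region_id Label for the returned region.
#' @param max_missing Per-variant missing-call fraction above which the
#'   variant is dropped.
#' @return A [genotype_region()], or `NULL` (with a warning) when no variant
#'   passes the filters.
#' @export
read_region_genotypes <- function(vcf_path, chrom, start, end,
                                  sample_ids = NULL, maf_max = 0.01,
                                  region_id = NULL, max_missing = 0.1) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  pos <- as.integer(fix[, "POS"])
  keep <- fix[, "CHROM"] == as.character(chrom) &
    pos >= start & pos <= end & vcfR::is.biallelic(v)
  if (is.null(region_id)) {
    region_id <- sprintf("%s:%d-%d", chrom, start, end)
  }
  if (!any(keep)) {
    warn(sprintf("region %s: no biallelic variants in interval", region_id))
    return(NULL)
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  ids <- fix[keep, "ID"]
  pos <- pos[keep]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- sprintf("%s_%d", chrom, pos[no_id])

  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, colnames(gt))
    if (length(missing) > 0L) {
      abort(paste0("samples absent from VCF: ",
                   paste(missing, collapse = ", ")))
    }
    gt <- gt[, sample_ids, drop = FALSE]
  }

  counts <- alt_allele_counts(gt)          # variants x samples, NA = missing
  miss_rate <- rowMeans(is.na(counts))
  if (any(miss_rate > max_missing)) {
    inform(sprintf("region %s: dropping %d variant(s) with >%.0f%% missing calls",
                   region_id, sum(miss_rate > max_missing), 100 * max_missing))
  }
  keep_v <- miss_rate <= max_missing
  counts <- counts[keep_v, , drop = FALSE]
  ids <- ids[keep_v]
  pos <- pos[keep_v]
  if (any(miss_rate[keep_v] > 0)) {
    counts[is.na(counts)] <- 0
  }

  counts <- t(counts)                       # samples x variants
  if (ncol(counts) > 0L) {
    freq <- colMeans(counts) / 2
    flip <- freq > 0.5
    counts[, flip] <- 2 - counts[, flip]
    maf <- colMeans(counts) / 2
    keep_v <- maf > 0 & maf <= maf_max
    counts <- counts[, keep_v, drop = FALSE]
    ids <- ids[keep_v]
    pos <- pos[keep_v]
  }
  if (ncol(counts) == 0L) {
    warn(sprintf("region %s: no variant passes the rare-variant filters",
                 region_id))
    return(NULL)
  }
  genotype_region(counts, variant_ids = ids, positions = pos,
                  region_id = region_id, chrom = chrom,
                  start = as.integer(start), end = as.integer(end))
}

# "0/1"-style GT strings -> ALT allele counts; NA for missing calls
alt_allele_counts <- function(gt) {
  count_one <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }
  out <- vapply(gt, count_one, numeric(1))
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Read a per-sample phenotype/covariate table
#'
#' Reads a TSV with a header and one row per sample, checks for required
#' columns and duplicated ids, and (when `sample_ids` is given) reorders the
#' rows to the analysis sample order, erroring on absent samples and dropping
#' extra ones with a warning.
#'
#' @param path TSV path.
#' @param sample_ids Optional ordered analysis samples.
#' @param required_columns Columns that must be present and complete; rows
#'   with missing values there are flagged in the `exclude` column.
#' @param id_col Name of the sample-id column (default `"sample_id"`).
#' @return A tibble in analysis order with an added logical `exclude` column.
#' @export
read_sample_table <- function(path, sample_ids = NULL,
                              required_columns = NULL,
                              id_col = "sample_id") {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!id_col %in% names(tab)) {
    abort(sprintf("column '%s' not found in %s", id_col, path))
  }
  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  missing_cols <- setdiff(required_columns, names(tab))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, ids)
    if (length(absent) > 0L) {
      abort(paste0("samples missing from table: ",
                   paste(absent, collapse = ", ")))
    }
    extra <- setdiff(ids, sample_ids)
    if (length(extra) > 0L) {
      warn(sprintf("ignoring %d sample(s) not in the analysis set",
                   length(extra)))
    }
    tab <- tab[match(sample_ids, ids), , drop = FALSE]
  }
  flag <- if (is.null(required_columns)) {
    rep(FALSE, nrow(tab))
  } else {
    rowSums(is.na(tab[, required_columns, drop = FALSE])) > 0
  }
  dplyr::mutate(tab, exclude = flag)
}

#' Read a region/gene interval table
#'
#' BED-like TSV with header columns `chrom`, `start`, `end`, `region_id` —
#' but with 1-based inclusive coordinates (unlike BED proper, which is
#' 0-based half-open).
#'
#' @param path TSV path.
#' @return A tibble with columns `chrom`, `start`, `end`, `region_id`.
#' @export
read_region_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "end", "region_id")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    abort(paste0("region table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  dplyr::mutate(tab[, need], chrom = as.character(.data$chrom),
                start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Standardize a numeric vector
#'
#' Mean 0, unit sample standard deviation (the preprocessing applied to
#' phenotypes and continuous covariates before analysis).
#'
#' @param x Numeric vector, length >= 2, nonzero variance.
#' @return The standardized vector.
#' @export
standardize <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) abort("need at least two values to standardize")
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("cannot standardize a constant vector")
  (x - mean(x)) / s
}

#' Flag extreme outliers
#'
#' Marks values more than `k` standard deviations from the mean; an optional
#' preprocessing utility for excluding implausible phenotype or covariate
#' values before analysis.
#'
#' @param x Numeric vector.
#' @param k Threshold in standard deviations (default 5).
#' @return Logical vector, `TRUE` for outliers.
#' @export
flag_outliers <- function(x, k = 5) {
  abs(x - mean(x)) > k * sd(x)
}

#' Adjust blood pressure for antihypertensive medication
#'
#' Adds the conventional offsets (+10 mm Hg systolic, +5 mm Hg diastolic) to
#' treated individuals; an optional phenotype-preprocessing utility, off the
#' statistical core.
#'
#' @param sbp,dbp Numeric blood pressures (mm Hg).
#' @param on_medication Logical, `TRUE` for treated individuals.
#' @return A tibble with adjusted `sbp` and `dbp`.
#' @export
adjust_bp_medication <- function(sbp, dbp, on_medication) {
  tibble(sbp = sbp + 10 * as.numeric(on_medication),
         dbp = dbp + 5 * as.numeric(on_medication))
}

#' Write per-region GEI results to TSV
#'
#' One row per region with a `p_<kernel>` column per tested kernel;
#' deterministic column order, round-trip readable, p-values at full
#' precision.
#'
#' @param results A tibble as returned by [gei_test()] (possibly row-bound
#'   over regions).
#' @param path Output TSV path.
#' @return The written wide tibble, invisibly.
#' @export
write_gei_results <- function(results, path) {
  base_cols <- c("region_id", "chrom", "start", "end", "m_variants")
  if (nrow(results) == 0L) {
    wide <- tibble(region_id = character(), chrom = character(),
                   start = integer(), end = integer(),
                   m_variants = integer())
  } else {
    kern_order <- unique(results$kernel)
    wide <- results |>
      dplyr::select(dplyr::all_of(base_cols), "kernel", "p_value",
                    "p_method") |>
      tidyr::pivot_wider(names_from = "kernel",
                         values_from = c("p_value", "p_method"),
                         names_glue = "{.value}_{kernel}") |>
      dplyr::select(dplyr::all_of(base_cols),
                    dplyr::all_of(paste0("p_value_", kern_order)),
                    dplyr::all_of(paste0("p_method_", kern_order)))
  }
  readr::write_tsv(wide, path)
  invisible(wide)
}

#' Write a genotype region as a plain-text VCF
#'
#' Fixture/interchange writer for simulated regions: emits a minimal VCF 4.2
#' with GT-only genotype columns in which the ALT allele is the minor allele
#' (heterozygotes `0/1`, minor homozygotes `1/1`).
#'
#' @param geno A [genotype_region()].
#' @param path Output path (`.vcf`).
#' @param sample_ids Sample names (default `S1..Sn`).
#' @return `path`, invisibly.
#' @export
write_region_vcf <- function(geno, path, sample_ids = NULL) {
  stopifnot(inherits(geno, "genotype_region"))
  n <- nrow(geno$counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  stopifnot(length(sample_ids) == n)
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s>", geno$chrom),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(geno$counts)), function(j) {
    paste(c(geno$chrom, geno$positions[j], geno$variant_ids[j], "A", "T",
            ".", "PASS", ".", "GT",
            gt_code[geno$counts[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write per-sample simulation tables
#'
#' Companion writer to [write_region_vcf()]: phenotypes and covariates of a
#' simulated dataset as a single TSV keyed by `sample_id`, so the simulator
#' doubles as a fixture generator for the file-based pipeline.
#'
#' @param sim A [simulate_phenotypes()] result.
#' @param path Output TSV path.
#' @param sample_ids Sample names (default `S1..Sn`).
#' @return The written tibble, invisibly.
#' @export
write_sim_tables <- function(sim, path, sample_ids = NULL) {
  stopifnot(inherits(sim, "gei_sim"))
  n <- nrow(sim$pheno)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  tab <- dplyr::bind_cols(tibble(sample_id = sample_ids),
                          sim$covariates, sim$pheno)
  readr::write_tsv(tab, path)
  invisible(tab)
}
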