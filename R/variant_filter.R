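# Hard-filter cascade for annotated somatic variant calls.
#
# Eleven criteria remove a record when:
#  1  the upstream caller's own filter did not pass;
#  2  alternative-read fraction <= 5%;
#  3  total depth <= 5 or alternative depth <= 3;
#  4  QUAL < 30;
#  5  dbNSFP impact is "low";
#  6  the site is a common SNP (dbSNP);
#  7  any population allele frequency (ExAC AF, ESP global AF, ESP6500
#     MAF_EA) exceeds 0.001;
#  8  MAPQ < 40 for variants with >= 100 COSMIC cases or on breast-cancer
#     hotspot genes;
#  9  MAPQ < 55 for variants on all other genes (the hotspot/COSMIC-heavy
#     branch is exempt from this stricter tier);
#  10 the variant recurs in more than one sample while having < 100 COSMIC
#     cases;
#  11 the variant has zero COSMIC cases and only "moderate" dbNSFP impact.
# All criteria are evaluated exhaustively (no short-circuiting) so the
# audit trail records every rule that would have removed each record.

#' Default breast-cancer hotspot gene set
#' @return character vector.
#' @export
hotspot_genes_default <- function() c("TP53", "PIK3CA", "GATA3", "MAP3K1",
                                      "KMT2C")

#' Build an annotated variant record table
#'
#' @param df data.frame with columns `sample_id`, `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `caller_pass`, `alt_fraction`, `total_depth`,
#'   `alt_depth`, `qual`, `mapq`, `dbnsfp_impact`, `is_common_snp`,
#'   `af_exac`, `af_esp_global`, `maf_ea`, `cosmic_case_count`.
#'   `n_samples_with_variant` is recomputed internally.
#' @return validated data.frame.
#' @export
variant_records <- function(df) {
  req <- c("sample_id", "gene", "chrom", "pos", "ref", "alt", "caller_pass",
           "alt_fraction", "total_depth", "alt_depth", "qual", "mapq",
           "dbnsfp_impact", "is_common_snp", "af_exac", "af_esp_global",
           "maf_ea", "cosmic_case_count")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop(sprintf("missing annotation field(s): %s",
                 paste(missing, collapse = ", ")))
  for (f in req) {
    if (any(is.na(df[[f]])))
      stop(sprintf("missing annotation value in field '%s'", f))
  }
  if (!all(df$dbnsfp_impact %in% c("high", "moderate", "low", "modifier")))
    stop("dbnsfp_impact must be high/moderate/low/modifier")
  if (any(df$alt_depth > df$total_depth))
    stop("alt_depth exceeds total_depth")
  if (any(df$total_depth < 0) || any(df$alt_depth < 0))
    stop("depths must be non-negative")
  df
}

#' Apply the 11-criterion filter cascade to one annotated record
#'
#' @param record a one-row data.frame (or list) with the fields of
#'   [variant_records()] plus `n_samples_with_variant`.
#' @param hotspot_genes hotspot gene set for the two-tier MAPQ rule.
#' @return A list with `passed` (logical) and `failed_criteria` (integer
#'   vector of criterion ids 1-11, empty when passed).
#' @export
apply_filters <- function(record, hotspot_genes = hotspot_genes_default()) {
  req <- c("caller_pass", "alt_fraction", "total_depth", "alt_depth", "qual",
           "mapq", "dbnsfp_impact", "is_common_snp", "af_exac",
           "af_esp_global", "maf_ea", "cosmic_case_count",
           "n_samples_with_variant", "gene")
  for (f in req) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop(sprintf("missing annotation field '%s'", f))
  }
  heavy <- record$cosmic_case_count >= 100 || record$gene %in% hotspot_genes
  failed <- c(
    if (!record$caller_pass) 1L,
    if (record$alt_fraction <= 0.05) 2L,
    if (record$total_depth <= 5 || record$alt_depth <= 3) 3L,
    if (record$qual < 30) 4L,
    if (record$dbnsfp_impact == "low") 5L,
    if (record$is_common_snp) 6L,
    if (record$af_exac > 0.001 || record$af_esp_global > 0.001 ||
        record$maf_ea > 0.001) 7L,
    if (record$mapq < 40 && heavy) 8L,
    if (record$mapq < 55 && !heavy) 9L,
    if (record$n_samples_with_variant > 1 && record$cosmic_case_count < 100)
      10L,
    if (record$cosmic_case_count == 0 && record$dbnsfp_impact == "moderate")
      11L
  )
  list(passed = length(failed) == 0L, failed_criteria = as.integer(failed))
}

#' Filter a variant table and produce an audit trail
#'
#' Recomputes `n_samples_with_variant` over the whole table (distinct
#' samples sharing chrom/pos/ref/alt), applies [apply_filters()] to every
#' record, and splits the table into kept records and a full audit table.
#' Verdicts are order-independent: the cross-sample recurrence count is
#' table-global.
#'
#' @param records a data.frame accepted by [variant_records()].
#' @param hotspot_genes hotspot gene set.
#' @return list with `kept` (passing records), `audit` (all records plus
#'   `passed` and `failed_criteria` columns, criteria comma-joined).
#' @export
filter_table <- function(records, hotspot_genes = hotspot_genes_default()) {
  if (nrow(records) == 0L) {
    empty <- cbind(records, data.frame(n_samples_with_variant = integer(0),
                                       passed = logical(0),
                                       failed_criteria = character(0)))
    return(list(kept = empty[0, ], audit = empty))
  }
  records <- variant_records(records)
  key <- paste(records$chrom, records$pos, records$ref, records$alt,
               sep = ":")
  nsamp <- vapply(key, function(k) {
    length(unique(records$sample_id[key == k]))
  }, integer(1))
  records$n_samples_with_variant <- unname(nsamp)
  verdicts <- lapply(seq_len(nrow(records)), function(i) {
    apply_filters(records[i, ], hotspot_genes)
  })
  records$passed <- vapply(verdicts, `[[`, logical(1), "passed")
  records$failed_criteria <- vapply(verdicts, function(v) {
    paste(v$failed_criteria, collapse = ",")
  }, character(1))
  list(kept = records[records$passed, , drop = FALSE], audit = records)
}

#' Read a VCF plus annotation sidecar into a variant record table
#'
#' The VCF supplies chrom/pos/ref/alt and the caller's FILTER status; the
#' tab-separated sidecar supplies everything else, keyed by
#' chrom/pos/ref/alt/sample_id. Requires the vcfR package.
#'
#' @param vcf_path VCF file path.
#' @param annotation_path sidecar TSV path with the remaining
#'   [variant_records()] fields.
#' @return data.frame ready for [filter_table()].
#' @export
read_variant_table <- function(vcf_path, annotation_path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the vcfR package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  vcf_df <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                       ref = fix$REF, alt = fix$ALT,
                       caller_pass = fix$FILTER %in% c("PASS", "."),
                       stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  out <- merge(ann, vcf_df, by = c("chrom", "pos", "ref", "alt"))
  if (nrow(out) == 0L) stop("no annotation records match the VCF sites")
  variant_records(out)
}
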