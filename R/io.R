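# Readers/writers: annotated multi-sample VCF and the TSV annotation sidecar.
#
# Reading is delegated to VariantAnnotation (readVcf + expand for
# multi-allelic decomposition); this file maps its containers onto the
# package's variant_cohort and applies the configurable annotation key map.

#' Default annotation key map
#'
#' Names the VCF INFO keys (site-level annotations) and FORMAT keys
#' (per-sample read evidence) that carry each annotation-bundle field.
#' Override individual entries to match the upstream annotator, e.g.
#' `default_key_map(cadd_phred = "CADD13_PHRED")`.
#'
#' INFO keys must be declared `Number=1` (replicated across decomposed alt
#' alleles) or `Number=A` (one value per alt allele); FORMAT keys `Number=1`
#' or `Number=A`. Predictor calls are `D`/`T` (or
#' `deleterious`/`tolerated`); HaploReg flags are a `|`-separated tag list.
#'
#' @param ... named overrides of individual entries
#' @return named list mapping bundle fields to VCF keys
#' @export
default_key_map <- function(...) {
  km <- list(region = "REGION",
             maf_1kg = "MAF1KG", maf_exac = "MAFEXAC",
             cadd_phred = "CADD", gerp = "GERP", phastcons = "PHC",
             mutation_taster = "MT", polyphen2 = "PP2",
             provean = "PROVEAN", sift = "SIFT",
             intol_inhouse = "ITINH", intol_esp = "ITESP",
             intol_exac = "ITEXAC",
             regulome_rank = "REGDB", haploreg_flags = "HAPLOREG",
             mirsvr = "MIRSVR",
             depth = "DP", alt_fwd = "ADF", alt_rev = "ADR")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(km))
  if (length(unknown) > 0L)
    stop("unknown key map entries: ", paste(unknown, collapse = ", "))
  km[names(dots)] <- dots
  km
}

CHAR_ANNOTATION_FIELDS <- c(PREDICTOR_KEYS, "regulome_rank", "haploreg_flags")

normalise_predictor <- function(x) {
  x <- as.character(x)
  x[x %in% c("D", "d")] <- "deleterious"
  x[x %in% c("T", "t")] <- "tolerated"
  x[x %in% c(".", "")] <- NA
  x
}

info_field <- function(info, key, n) {
  if (is.null(key) || !key %in% names(info)) return(rep(NA, n))
  v <- info[[key]]
  if (is(v, "List") || is.list(v)) {
    v <- vapply(as.list(v),
                function(e) if (length(e) == 0L) NA else e[[1L]],
                vector(class(unlist(v, use.names = FALSE))[1L] %||% "character",
                       1L))
  }
  v
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

# GT strings ("0/1", "1|2", "./.") -> dosage of the alt allele with 1-based
# index alt_idx[row]; any missing allele makes the genotype missing.
gt_to_dosage <- function(gtmat, alt_idx) {
  n <- nrow(gtmat); m <- ncol(gtmat)
  alleles <- strsplit(as.vector(gtmat), "[/|]")
  idx <- rep(alt_idx, times = m)
  dos <- mapply(function(al, k) {
    if (length(al) == 0L || any(al %in% c(".", ""))) return(NA_real_)
    sum(suppressWarnings(as.integer(al)) == k)
  }, alleles, idx, USE.NAMES = FALSE)
  matrix(dos, n, m, dimnames = dimnames(gtmat))
}

#' Read an annotated multi-sample VCF into a variant cohort
#'
#' Multi-allelic sites are decomposed into one record per alt allele; the
#' per-sample genotype of each decomposed record is the dosage of that alt
#' allele only. Missing annotation keys yield missing fields, never
#' defaults. An optional TSV annotation sidecar (keyed chrom:pos:ref:alt)
#' is merged over the VCF-borne annotations.
#'
#' @param path VCF v4.x file (plain or bgzipped)
#' @param key_map see [default_key_map()]
#' @param annotation_tsv optional path to a sidecar TSV (see
#'   [read_annotation_tsv()])
#' @return a [variant_cohort()]
#' @export
read_annotated_vcf <- function(path, key_map = default_key_map(),
                               annotation_tsv = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (ncol(vcf) == 0L)
    stop("configuration error: VCF has no sample columns: ", path)
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  evcf <- VariantAnnotation::expand(vcf)
  alt_idx <- sequence(nalt)
  n <- length(alt_idx)

  rr <- SummarizedExperiment::rowRanges(evcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(evcf))
  alt <- as.character(VariantAnnotation::alt(evcf))
  qual <- as.numeric(rr$QUAL)
  filt <- as.character(rr$FILTER)
  filt[!is.na(filt) & filt == "."] <- NA

  info <- VariantAnnotation::info(evcf)
  region <- as.character(info_field(info, key_map$region, n))
  region[is.na(region)] <- "other"
  vclass <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL")
  vid <- variant_key(chrom, pos, ref, alt)
  variants <- data.frame(variant_id = vid, chrom = chrom, pos = pos,
                         ref = ref, alt = alt, vclass = vclass,
                         region = region, qual = qual, filter = filt,
                         stringsAsFactors = FALSE)

  ann <- empty_annotations(vid)
  for (f in setdiff(ANNOTATION_COLS, CHAR_ANNOTATION_FIELDS))
    ann[[f]] <- as.numeric(info_field(info, key_map[[f]], n))
  for (f in PREDICTOR_KEYS)
    ann[[f]] <- normalise_predictor(info_field(info, key_map[[f]], n))
  ann$regulome_rank <- as.character(info_field(info, key_map$regulome_rank, n))
  hap <- as.character(info_field(info, key_map$haploreg_flags, n))
  hap[!is.na(hap) & hap == "."] <- NA
  ann$haploreg_flags <- hap

  gmats <- VariantAnnotation::geno(evcf)
  samples <- colnames(evcf)
  if (!"GT" %in% names(gmats)) stop("VCF has no GT FORMAT field: ", path)
  gt <- gt_to_dosage(gmats$GT, alt_idx)
  num_fmt <- function(key) {
    if (is.null(key) || !key %in% names(gmats)) return(NULL)
    v <- gmats[[key]]
    if (is.list(v))
      v <- matrix(vapply(v, function(e) if (length(e) == 0L) NA_real_
                         else as.numeric(e[[1L]]), numeric(1L)),
                  nrow(gt), ncol(gt), dimnames = dimnames(gt))
    storage.mode(v) <- "double"
    v
  }
  geno <- list(gt = gt, dp = num_fmt(key_map$depth),
               adf = num_fmt(key_map$alt_fwd),
               adr = num_fmt(key_map$alt_rev))

  cohort <- variant_cohort(variants, samples, geno, ann)
  if (!is.null(annotation_tsv)) {
    sidecar <- read_annotation_tsv(annotation_tsv, key_map)
    cohort <- merge_annotations(cohort, sidecar)
  }
  cohort
}

#' Read a TSV annotation sidecar
#'
#' Alternative annotation transport: a tab-separated table with key columns
#' `chrom`, `pos`, `ref`, `alt` and annotation columns named by the key map.
#'
#' @param path TSV file path
#' @param key_map see [default_key_map()]
#' @return data.frame of annotations keyed by `variant_id`
#' @export
read_annotation_tsv <- function(path, key_map = default_key_map()) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("annotation sidecar needs columns chrom, pos, ref, alt")
  ann <- empty_annotations(variant_key(tab$chrom, tab$pos, tab$ref, tab$alt))
  for (f in ANNOTATION_COLS) {
    key <- key_map[[f]]
    if (is.null(key) || !key %in% names(tab)) next
    v <- tab[[key]]
    ann[[f]] <- if (f %in% PREDICTOR_KEYS) normalise_predictor(v)
                else if (f %in% CHAR_ANNOTATION_FIELDS) as.character(v)
                else as.numeric(v)
  }
  ann
}

#' Merge sidecar annotations into a cohort
#'
#' Sidecar values override VCF-borne values where present; variants absent
#' from the sidecar keep their existing annotations.
#'
#' @param cohort a [variant_cohort()]
#' @param annotations data.frame keyed by `variant_id` (e.g. from
#'   [read_annotation_tsv()])
#' @return the cohort with merged annotations
#' @export
merge_annotations <- function(cohort, annotations) {
  idx <- match(cohort$annotations$variant_id, annotations$variant_id)
  for (f in ANNOTATION_COLS) {
    if (!f %in% names(annotations)) next
    v <- annotations[[f]][idx]
    take <- !is.na(idx) & !is.na(v)
    cohort$annotations[[f]][take] <- v[take]
  }
  validate_annotations(cohort$annotations)
  cohort
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "." else sprintf("%.17g", v)
  }, character(1L))
  # integers print clean
  ix <- !is.na(x) & x == round(x) & abs(x) < 1e15
  out[ix] <- sprintf("%d", as.integer(x[ix]))
  out
}

#' Write a variant cohort to a VCF file
#'
#' Emits a VCF v4.2 whose INFO/FORMAT keys follow the key map, so that
#' [read_annotated_vcf()] round-trips genotypes and annotations exactly.
#' Output is deterministic (byte-identical across runs on equal input).
#'
#' @param cohort a [variant_cohort()]
#' @param path output path
#' @param key_map see [default_key_map()]
#' @return invisibly, `path`
#' @export
write_cohort_vcf <- function(cohort, path, key_map = default_key_map()) {
  v <- cohort$variants
  ann <- cohort$annotations
  num_info <- setdiff(ANNOTATION_COLS, CHAR_ANNOTATION_FIELDS)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Region class">',
            key_map$region),
    vapply(num_info, function(f) sprintf(
      '##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
      key_map[[f]], f), character(1L)),
    vapply(CHAR_ANNOTATION_FIELDS, function(f) sprintf(
      '##INFO=<ID=%s,Number=1,Type=String,Description="%s">',
      key_map[[f]], f), character(1L)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf('##FORMAT=<ID=%s,Number=1,Type=Integer,Description="Read depth">',
            key_map$depth),
    sprintf('##FORMAT=<ID=%s,Number=1,Type=Integer,Description="Alt forward reads">',
            key_map$alt_fwd),
    sprintf('##FORMAT=<ID=%s,Number=1,Type=Integer,Description="Alt reverse reads">',
            key_map$alt_rev),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )

  n <- nrow(v)
  info_parts <- matrix("", n, 1 + length(ANNOTATION_COLS))
  info_parts[, 1] <- paste0(key_map$region, "=", v$region)
  ci <- 2L
  for (f in ANNOTATION_COLS) {
    val <- ann[[f]]
    if (f %in% PREDICTOR_KEYS)
      val <- c(deleterious = "D", tolerated = "T")[val]
    txt <- if (is.numeric(val)) fmt_num(val) else as.character(val)
    present <- !is.na(val)
    info_parts[, ci] <- ifelse(present, paste0(key_map[[f]], "=", txt), "")
    ci <- ci + 1L
  }
  info_str <- apply(info_parts, 1L, function(r) {
    r <- r[r != ""]
    if (length(r) == 0L) "." else paste(r, collapse = ";")
  })

  gt_str <- matrix(".", n, length(cohort$samples))
  gt <- cohort$geno$gt
  gt_str[] <- c("0/0", "0/1", "1/1")[gt + 1L]
  gt_str[is.na(gt)] <- "./."
  fmt_cell <- function(mat) {
    matrix(fmt_num(as.vector(mat)), n, length(cohort$samples))
  }
  dp_s <- fmt_cell(cohort$geno$dp)
  adf_s <- fmt_cell(cohort$geno$adf)
  adr_s <- fmt_cell(cohort$geno$adr)
  sample_str <- matrix(paste(gt_str, dp_s, adf_s, adr_s, sep = ":"),
                       n, length(cohort$samples))

  lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt,
                 fmt_num(v$qual), ifelse(is.na(v$filter), ".", v$filter),
                 info_str,
                 paste("GT", key_map$depth, key_map$alt_fwd, key_map$alt_rev,
                       sep = ":"),
                 apply(sample_str, 1L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a full simulated cohort to disk
#'
#' Emits the standard file set — VCF, PED, status sidecar and annotation
#' TSV — so that fixtures exercise the real readers.
#'
#' @param cohort a [variant_cohort()]
#' @param ped a [pedigree()]
#' @param dir output directory (created if needed)
#' @param key_map see [default_key_map()]
#' @return named character vector of the written paths
#' @export
write_cohort <- function(cohort, ped, dir, key_map = default_key_map()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ped = file.path(dir, "family.ped"),
             statuses = file.path(dir, "statuses.tsv"),
             annotations = file.path(dir, "annotations.tsv"))
  write_cohort_vcf(cohort, paths["vcf"], key_map)
  write_pedigree(ped, paths["ped"], paths["statuses"])
  ann <- cohort$annotations
  out <- data.frame(chrom = cohort$variants$chrom, pos = cohort$variants$pos,
                    ref = cohort$variants$ref, alt = cohort$variants$alt)
  for (f in ANNOTATION_COLS) {
    val <- ann[[f]]
    out[[key_map[[f]]]] <- if (is.numeric(val)) fmt_num(val)
                           else ifelse(is.na(val), ".", as.character(val))
  }
  utils::write.table(out, paths["annotations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
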