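#' Construct a genotype matrix object
#'
#' Container for a samples x variants matrix of alternate-allele dosages
#' together with per-variant metadata. Dosages are integers in \{0, 1, 2\}
#' (number of copies of the alternate allele carried by a diploid genotype);
#' missing calls are \code{NA}. Phase is not represented: all downstream
#' tests are allelic.
#'
#' @param genotypes integer matrix, samples in rows, variants in columns.
#'   Entries must be 0, 1, 2 or \code{NA}.
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{id}, \code{ref}, \code{alt} and optionally \code{gene}; one row
#'   per column of \code{genotypes}.
#' @param samples character vector of sample identifiers, one per row of
#'   \code{genotypes}.
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{genotypes}, \code{variants}, \code{samples}.
#' @export
genotype_matrix <- function(genotypes, variants, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != length(samples))
    stop("genotypes must have one row per sample")
  if (ncol(genotypes) != nrow(variants))
    stop("genotypes must have one column per variant row")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("non-missing genotypes must be alt-allele dosages in {0,1,2}")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  if (!"gene" %in% names(variants)) variants$gene <- NA_character_
  if (any(is.na(variants$id) | variants$id == ""))
    stop("every variant needs a non-empty id")
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ")
  if (any(variants$pos < 1)) stop("positions are 1-based and must be >= 1")
  rownames(genotypes) <- samples
  colnames(genotypes) <- variants$id
  structure(list(genotypes = genotypes, variants = variants,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Construct a cohort design
#'
#' Assigns every sample to a cohort and to one of the four analysis groups:
#' the three extreme constitution groups V (Vata), P (Pitta), K (Kapha) and
#' the unstratified background control group C.
#'
#' @param sample character vector of sample identifiers.
#' @param cohort character vector of cohort labels (recycled if length 1).
#' @param group character vector of group labels, each in
#'   \code{c("V","P","K","C")}.
#' @return data.frame of class \code{cohort_design} with columns
#'   \code{sample}, \code{cohort}, \code{group}.
#' @export
cohort_design <- function(sample, cohort, group) {
  if (length(cohort) == 1L) cohort <- rep(cohort, length(sample))
  if (length(sample) != length(cohort) || length(sample) != length(group))
    stop("sample, cohort and group must have matching lengths")
  bad <- setdiff(unique(group), c("V", "P", "K", "C"))
  if (length(bad))
    stop("group labels must be in {V,P,K,C}; found: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(sample))
    stop("duplicated sample identifiers in design")
  structure(data.frame(sample = as.character(sample),
                       cohort = as.character(cohort),
                       group = as.character(group),
                       stringsAsFactors = FALSE),
            class = c("cohort_design", "data.frame"))
}

#' Samples belonging to a group (optionally within one cohort)
#'
#' @param design a \code{cohort_design}.
#' @param group group label, one of V/P/K/C.
#' @param cohort optional cohort label to restrict to.
#' @return character vector of sample ids.
#' @export
group_samples <- function(design, group, cohort = NULL) {
  sel <- design$group == group
  if (!is.null(cohort)) sel <- sel & design$cohort == cohort
  design$sample[sel]
}

## parse a character vector of VCF GT strings into dosages of alt allele j
.gt_dosage <- function(gt, alt_index) {
  u <- unique(gt)
  tok <- as.character(alt_index)
  dos <- vapply(u, function(g) {
    if (is.na(g) || g == "" || g == ".") return(NA_integer_)
    al <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (length(al) != 2L)
      stop("non-diploid genotype encountered: '", g, "'")
    # a half-call (one missing allele) is treated as fully missing
    if (any(al == ".")) return(NA_integer_)
    as.integer(sum(al == tok))
  }, integer(1))
  dos[match(gt, u)]
}

#' Read genotypes and sample metadata
#'
#' Reads a multi-sample diploid VCF and a sample sheet into the internal
#' dosage representation. Multi-allelic sites are split into one biallelic
#' record per alternate allele; within each split record the other alternate
#' alleles count as reference (the allelic 2x2 tables downstream only ever
#' oppose one alternate allele to everything else). Phased and unphased
#' genotypes are treated identically and genotypes containing any missing
#' allele are treated as fully missing. Variants without an rsID (ID field
#' \code{"."}) are named \code{chrom:pos}, with the alternate allele appended
#' when splitting would otherwise produce duplicate ids.
#'
#' @param vcf_path path to a VCF 4.x file (plain or gzipped).
#' @param sheet_path path to a tab-separated sample sheet with header
#'   \code{sample<TAB>cohort<TAB>group}.
#' @return list with elements \code{matrix} (a \code{genotype_matrix}) and
#'   \code{design} (a \code{cohort_design}). VCF samples absent from the
#'   sheet are dropped with a warning; sheet samples absent from the VCF are
#'   an error.
#' @export
read_genotypes <- function(vcf_path, sheet_path) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  if (!file.exists(sheet_path)) stop("sample sheet not found: ", sheet_path)
  sheet <- utils::read.table(sheet_path, header = TRUE, sep = "\t",
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  if (!all(c("sample", "cohort", "group") %in% names(sheet)))
    stop("sample sheet must have columns sample, cohort, group")
  design <- cohort_design(sheet$sample, sheet$cohort, sheet$group)

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))                 # single-record VCF drops dims
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(vcf@gt) == 0L) stop("VCF contains no genotype records")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  vcf_samples <- colnames(gt)

  absent <- setdiff(design$sample, vcf_samples)
  if (length(absent))
    stop("sample(s) in sheet absent from VCF: ", paste(absent, collapse = ", "))
  extra <- setdiff(vcf_samples, design$sample)
  if (length(extra))
    warning(length(extra), " VCF sample(s) not in sheet were dropped: ",
            paste(extra, collapse = ", "))
  keep_samples <- design$sample
  gt <- gt[, keep_samples, drop = FALSE]

  gene <- tryCatch(vcfR::extract.info(vcf, "GENE"),
                   error = function(e) rep(NA_character_, nrow(fix)))
  if (is.null(gene)) gene <- rep(NA_character_, nrow(fix))

  alts <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  rec_site <- rep(seq_along(alts), lengths(alts))
  rec_aidx <- unlist(lapply(lengths(alts), seq_len), use.names = FALSE)

  n_rec <- length(rec_site)
  dosage <- matrix(NA_integer_, nrow = length(keep_samples), ncol = n_rec)
  for (r in seq_len(n_rec)) {
    dosage[, r] <- .gt_dosage(gt[rec_site[r], ], rec_aidx[r])
  }

  chrom <- as.character(fix[rec_site, "CHROM"])
  pos <- as.integer(fix[rec_site, "POS"])
  id <- as.character(fix[rec_site, "ID"])
  novel <- is.na(id) | id == "." | id == ""
  id[novel] <- paste0(chrom[novel], ":", pos[novel])
  multi <- rec_site %in% rec_site[duplicated(rec_site)]
  alt <- unlist(alts, use.names = FALSE)
  fixdup <- novel & multi
  id[fixdup] <- paste0(id[fixdup], ":", alt[fixdup])

  variants <- data.frame(chrom = chrom, pos = pos, id = id,
                         ref = as.character(fix[rec_site, "REF"]),
                         alt = alt, gene = as.character(gene[rec_site]),
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(dosage, variants, keep_samples)
  list(matrix = gm, design = design)
}

#' Write genotypes (and optionally the design) back to disk
#'
#' Emits a minimal plain-text VCF 4.2 with dosages re-encoded as unphased
#' genotypes (0/0, 0/1, 1/1, ./.) and a GENE INFO tag where gene annotation
#' is present, plus an optional sample sheet TSV. Round-tripping through
#' \code{read_genotypes} reproduces dosages and missingness exactly.
#'
#' @param gm a \code{genotype_matrix}.
#' @param vcf_path output VCF path.
#' @param design optional \code{cohort_design}.
#' @param sheet_path output sample sheet path (required when \code{design}
#'   is given).
#' @return invisibly, \code{vcf_path}.
#' @export
write_genotypes <- function(gm, vcf_path, design = NULL, sheet_path = NULL) {
  v <- gm$variants
  gt_code <- c("0/0", "0/1", "1/1")
  G <- gm$genotypes
  body <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    s <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    info <- if (!is.na(v$gene[j]) && nzchar(v$gene[j]))
      paste0("GENE=", v$gene[j]) else "."
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            info, "GT", s), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  writeLines(c(header, body), vcf_path)
  if (!is.null(design)) {
    if (is.null(sheet_path))
      stop("sheet_path is required when design is given")
    utils::write.table(as.data.frame(design), sheet_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(vcf_path)
}

#' Write the dosage matrix as a TSV table
#'
#' One row per variant: \code{variant_id} followed by one dosage column per
#' sample (\code{NA} for missing).
#'
#' @param gm a \code{genotype_matrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_dosage_tsv <- function(gm, path) {
  out <- data.frame(variant_id = gm$variants$id,
                    t(gm$genotypes), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotyping call rate of one variant over a sample subset
#'
#' @param gm a \code{genotype_matrix}.
#' @param variant_index column index of the variant.
#' @param sample_subset character vector of sample ids.
#' @return fraction of samples in the subset with a non-missing genotype.
#' @export
call_rate <- function(gm, variant_index, sample_subset) {
  if (length(sample_subset) == 0L) stop("sample subset is empty")
  g <- gm$genotypes[sample_subset, variant_index]
  mean(!is.na(g))
}

#' Per-comparison call-rate filter
#'
#' Keeps a variant for a pairwise comparison iff its call rate over the
#' union of the two compared groups' samples is at least \code{threshold}.
#' Variants with less than the threshold (strictly) are removed, so a call
#' rate of exactly 0.5 passes the default filter. The filter is recomputed
#' independently for every pairwise comparison.
#'
#' @param gm a \code{genotype_matrix}.
#' @param pair_samples character vector: the union of the two groups'
#'   samples.
#' @param threshold minimum call rate in [0,1]; default 0.5.
#' @return integer vector of surviving variant column indices.
#' @export
filter_by_call_rate <- function(gm, pair_samples, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
  if (length(pair_samples) == 0L) stop("sample subset is empty")
  rate <- colMeans(!is.na(gm$genotypes[pair_samples, , drop = FALSE]))
  which(rate >= threshold)
}

#' Alternate-allele frequency of one variant in a sample group
#'
#' Computed over non-missing diploid genotypes: summed alt dosage divided by
#' twice the non-missing count.
#'
#' @param gm a \code{genotype_matrix}.
#' @param variant_index column index of the variant.
#' @param group_samples character vector of sample ids.
#' @return frequency in [0,1], or \code{NA} when every genotype in the
#'   group is missing (undefined frequency).
#' @export
alt_allele_frequency <- function(gm, variant_index, group_samples) {
  g <- gm$genotypes[group_samples, variant_index]
  n <- sum(!is.na(g))
  if (n == 0L) return(NA_real_)
  sum(g, na.rm = TRUE) / (2 * n)
}
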