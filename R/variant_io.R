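# Reading/writing the standard formats and shared-variant intersections.
#
# Only diploid biallelic SNPs enter the ancestry computations; multi-allelic
# records and indels are skipped on read with a logged count.  Chromosome
# names are taken verbatim (no alias mapping), and allele mismatches at a
# shared genomic location are dropped, not flipped: strand or allele
# flipping is out of scope here.

#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and keeps biallelic SNP records
#' with a GT FORMAT field.  Multi-allelic and non-SNP records are skipped
#' with a message reporting the count; `./.` genotypes become missing.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("VCF '", path, "' contains no variant records")
  if (!"GT" %in% unlist(strsplit(v@gt[, "FORMAT"], ":"))) {
    stop("VCF '", path, "' has no GT FORMAT field")
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp)) {
    message(sum(!snp), " multi-allelic or non-SNP record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- gt[snp, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt == "0/0"] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt == "1/1"] <- 2L
  unknown <- !is.na(gt) & is.na(code) & gt != "./."
  if (any(unknown)) {
    stop("unparseable GT value(s) in '", path, "', e.g. ",
         gt[which(unknown)[1]])
  }
  sites <- data.frame(chrom = fix[snp, "CHROM"],
                      pos = as.integer(fix[snp, "POS"]),
                      ref = ref[snp], alt = alt[snp],
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, colnames(v@gt)[-1], code)
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Emits a minimal GT-only VCF that [read_vcf()] round-trips exactly.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt <- matrix("./.", nrow(g$sites), length(g$animals))
  gt[!is.na(g$calls)] <- c("0/0", "0/1", "1/1")[g$calls[!is.na(g$calls)] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$animals), collapse = "\t"))
  body <- paste(g$sites$chrom, g$sites$pos, ".", g$sites$ref, g$sites$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Compute per-site alternate-allele frequencies from a cohort
#'
#' `af = (het + 2 hom-alt) / (2 x non-missing animals)` per site; sites at
#' which every call is missing are dropped.
#'
#' @param g A [genotype_matrix()].
#' @return A [freq_table()].
#' @export
compute_allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_obs <- rowSums(!is.na(g$calls))
  ac <- rowSums(g$calls, na.rm = TRUE)
  keep <- n_obs > 0
  if (any(!keep)) message(sum(!keep), " all-missing site(s) dropped")
  freq_table(g$sites$chrom[keep], g$sites$pos[keep], g$sites$ref[keep],
             g$sites$alt[keep], ac[keep] / (2 * n_obs[keep]))
}

#' Three-way shared-variant intersection counts
#'
#' Counts the seven Venn regions of three variant sets keyed by
#' (chrom, pos, ref, alt).
#'
#' @param a,b,c Site sets: [genotype_matrix()], [freq_table()] or any data
#'   frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @param labels Length-3 character vector naming the sets.
#' @return A data frame with one row per Venn region (`region`, `count`).
#'   The counts partition each input set exactly.
#' @export
intersect_variant_sets <- function(a, b, c,
                                   labels = c("a", "b", "c")) {
  ka <- unique(site_key(a)); kb <- unique(site_key(b)); kc <- unique(site_key(c))
  all_keys <- unique(c(ka, kb, kc))
  ina <- all_keys %in% ka
  inb <- all_keys %in% kb
  inc <- all_keys %in% kc
  region <- c(paste(labels[1], "only", sep = "_"),
              paste(labels[2], "only", sep = "_"),
              paste(labels[3], "only", sep = "_"),
              paste(labels[1], labels[2], sep = "_"),
              paste(labels[1], labels[3], sep = "_"),
              paste(labels[2], labels[3], sep = "_"),
              paste(labels, collapse = "_"))
  count <- c(sum(ina & !inb & !inc),
             sum(!ina & inb & !inc),
             sum(!ina & !inb & inc),
             sum(ina & inb & !inc),
             sum(ina & !inb & inc),
             sum(!ina & inb & inc),
             sum(ina & inb & inc))
  data.frame(region = region, count = count, stringsAsFactors = FALSE)
}

#' Align a genotype matrix with a reference frequency table
#'
#' Inner join on (chrom, pos), i.e. on shared genomic location; sites whose
#' ref/alt alleles disagree between the two inputs are dropped with a
#' logged count.
#'
#' @param g A [genotype_matrix()].
#' @param f A [freq_table()].
#' @return A list with the aligned `genotypes` and `freqs` (equal row
#'   counts, matching coordinates).
#' @export
join_on_sites <- function(g, f) {
  stopifnot(inherits(g, "genotype_matrix"))
  ig <- match(pos_key(g), pos_key(f))
  hit <- !is.na(ig)
  if (!any(hit)) {
    warning("no shared genomic locations between genotypes and frequencies")
    return(list(genotypes = subset_sites(g, integer(0)),
                freqs = f[integer(0), , drop = FALSE]))
  }
  same_allele <- hit
  same_allele[hit] <- g$sites$ref[hit] == f$ref[ig[hit]] &
    g$sites$alt[hit] == f$alt[ig[hit]]
  n_mismatch <- sum(hit & !same_allele)
  if (n_mismatch > 0) {
    message(n_mismatch, " shared location(s) dropped for ref/alt mismatch")
  }
  keep <- which(same_allele)
  fr <- f[ig[keep], , drop = FALSE]
  rownames(fr) <- NULL
  class(fr) <- c("freq_table", "data.frame")
  list(genotypes = subset_sites(g, keep), freqs = fr)
}
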