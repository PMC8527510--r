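# Tabulation of microbiome reads overlapping SNPs into genotype-category
# count tables: 3 x 2 for one genomic DNA sample (genotype x read allele),
# 3 x 3 x 2 for a pair of genomic DNA samples (joint genotypes x read
# allele). These tables are the sufficient statistics for both the
# discordance distance and the mixture model.

ALLELE_LABELS <- c("A", "B")

#' Construct a per-sample SNP allele count table
#'
#' @param snp_id Character vector of SNP ids.
#' @param n_major,n_minor Non-negative integer read counts of the major (A)
#'   and minor (B) allele at each SNP.
#' @param sample_id Microbiome sample id.
#' @return Data frame of class `snp_allele_counts` with attribute
#'   `sample_id`. SNPs absent from the table are implicitly zero-count.
#' @export
snp_allele_counts <- function(snp_id, n_major, n_minor, sample_id) {
    if (any(n_major < 0) || any(n_minor < 0)) {
        stop("allele counts must be non-negative")
    }
    out <- data.frame(snp_id = as.character(snp_id),
                      n_major = as.integer(round(n_major)),
                      n_minor = as.integer(round(n_minor)),
                      stringsAsFactors = FALSE)
    attr(out, "sample_id") <- sample_id
    class(out) <- c("snp_allele_counts", "data.frame")
    out
}

#' Read per-sample allele counts from TSV
#'
#' Columns `snp_id`, `n_major`, `n_minor`; gzip handled transparently.
#'
#' @param file Path to the TSV.
#' @param sample_id Sample id; defaults to the file name stripped of
#'   `.tsv`/`.tsv.gz`.
#' @return A `snp_allele_counts` object.
#' @export
read_allele_counts <- function(file, sample_id = NULL) {
    if (is.null(sample_id)) {
        sample_id <- sub("\\.tsv(\\.gz)?$", "", basename(file))
    }
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("snp_id", "n_major", "n_minor")
    if (!all(need %in% colnames(df))) {
        stop("allele-count TSV must have columns ",
             paste(need, collapse = ", "))
    }
    snp_allele_counts(df$snp_id, df$n_major, df$n_minor, sample_id)
}

#' Write per-sample allele counts to TSV
#'
#' @param counts A `snp_allele_counts` object.
#' @param file Output path (`.gz` suffix writes gzip).
#' @export
write_allele_counts <- function(counts, file) {
    con <- if (grepl("\\.gz$", file)) gzfile(file, "w") else file(file, "w")
    on.exit(close(con))
    utils::write.table(as.data.frame(counts)[c("snp_id", "n_major", "n_minor")],
                       con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Total reads in an allele count table
#'
#' @param counts A `snp_allele_counts` object.
#' @return Total read count (major + minor over all SNPs).
#' @export
total_reads <- function(counts) sum(counts$n_major) + sum(counts$n_minor)

new_category_table <- function(counts, microbiome_id = NA, genomic_id = NA) {
    stopifnot(identical(dim(counts), c(3L, 2L)))
    dimnames(counts) <- list(genotype = GENO_LABELS, allele = ALLELE_LABELS)
    attr(counts, "microbiome_id") <- microbiome_id
    attr(counts, "genomic_id") <- genomic_id
    class(counts) <- c("category_table", "matrix")
    counts
}

#' Build a 3 x 2 category table from explicit counts
#'
#' Rows are the genomic DNA sample's genotype (AA, AB, BB), columns the
#' allele carried by the read (A = major, B = minor). Useful for desk
#' calculations from published marginal counts.
#'
#' @param counts 3 x 2 numeric matrix, rows AA/AB/BB, columns A/B.
#' @param microbiome_id,genomic_id Optional sample ids.
#' @return A `category_table`.
#' @export
category_table <- function(counts, microbiome_id = NA, genomic_id = NA) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("category counts must be non-negative")
    new_category_table(counts, microbiome_id, genomic_id)
}

#' Tabulate reads against one genomic DNA sample's genotypes
#'
#' Reads at each SNP are placed in the cell indexed by the genomic sample's
#' genotype at that SNP and the allele on the read. SNPs with a missing
#' genotype are excluded.
#'
#' @param reads A `snp_allele_counts` object.
#' @param geno Genotype matrix (samples x SNPs, dosage coding).
#' @param genomic_id Row of `geno` to tabulate against.
#' @return A 3 x 2 `category_table`.
#' @export
tabulate_single <- function(reads, geno, genomic_id) {
    if (!genomic_id %in% rownames(geno)) {
        stop("unknown genomic sample: ", genomic_id)
    }
    g <- geno[genomic_id, ][reads$snp_id]
    keep <- !is.na(g)
    tab <- matrix(0, 3, 2)
    if (any(keep)) {
        gf <- factor(g[keep], levels = 0:2)
        tab[, 1] <- tapply(reads$n_major[keep], gf, sum, default = 0)
        tab[, 2] <- tapply(reads$n_minor[keep], gf, sum, default = 0)
    }
    new_category_table(tab, attr(reads, "sample_id"), genomic_id)
}

#' Tabulate reads against the joint genotypes of a pair of samples
#'
#' Reads are split by the allele on the read and the joint SNP genotypes of
#' the nominally correct sample (`id_self`) and a candidate contaminant
#' (`id_other`). SNPs where either genotype is missing are excluded.
#'
#' @param reads A `snp_allele_counts` object.
#' @param geno Genotype matrix (samples x SNPs, dosage coding).
#' @param id_self,id_other Rows of `geno`; must differ.
#' @return 3 x 3 x 2 array of class `joint_category_table`, dimensions
#'   (genotype of self) x (genotype of other) x (read allele).
#' @export
tabulate_pair <- function(reads, geno, id_self, id_other) {
    if (id_self == id_other) stop("id_self and id_other must differ")
    for (id in c(id_self, id_other)) {
        if (!id %in% rownames(geno)) stop("unknown genomic sample: ", id)
    }
    g1 <- geno[id_self, ][reads$snp_id]
    g2 <- geno[id_other, ][reads$snp_id]
    keep <- !is.na(g1) & !is.na(g2)
    tab <- array(0, c(3, 3, 2),
                 dimnames = list(self = GENO_LABELS, other = GENO_LABELS,
                                 allele = ALLELE_LABELS))
    if (any(keep)) {
        cell <- g1[keep] * 3L + g2[keep]  # 0..8
        cf <- factor(cell, levels = 0:8)
        tab[, , 1] <- matrix(tapply(reads$n_major[keep], cf, sum, default = 0),
                             3, 3, byrow = TRUE)
        tab[, , 2] <- matrix(tapply(reads$n_minor[keep], cf, sum, default = 0),
                             3, 3, byrow = TRUE)
    }
    attr(tab, "microbiome_id") <- attr(reads, "sample_id")
    attr(tab, "genomic_id_self") <- id_self
    attr(tab, "genomic_id_other") <- id_other
    class(tab) <- c("joint_category_table", "array")
    tab
}

#' Build a 3 x 3 x 2 joint category table from explicit counts
#'
#' @param counts 3 x 3 x 2 numeric array (self genotype x other genotype x
#'   read allele, genotype order AA/AB/BB, allele order A/B).
#' @param microbiome_id,genomic_id_self,genomic_id_other Optional ids.
#' @return A `joint_category_table`.
#' @export
joint_category_table <- function(counts, microbiome_id = NA,
                                 genomic_id_self = NA,
                                 genomic_id_other = NA) {
    counts <- as.array(counts)
    if (!identical(dim(counts), c(3L, 3L, 2L))) {
        stop("joint category table must be 3 x 3 x 2")
    }
    if (any(counts < 0)) stop("category counts must be non-negative")
    dimnames(counts) <- list(self = GENO_LABELS, other = GENO_LABELS,
                             allele = ALLELE_LABELS)
    attr(counts, "microbiome_id") <- microbiome_id
    attr(counts, "genomic_id_self") <- genomic_id_self
    attr(counts, "genomic_id_other") <- genomic_id_other
    class(counts) <- c("joint_category_table", "array")
    counts
}

#' Marginalize a joint category table over the second sample's genotype
#'
#' @param t A `joint_category_table`.
#' @return The implied 3 x 2 `category_table` for the self sample,
#'   restricted to SNPs where both genotypes were non-missing.
#' @export
marginal_category_table <- function(t) {
    new_category_table(apply(unclass(t), c(1, 3), sum),
                       attr(t, "microbiome_id"),
                       attr(t, "genomic_id_self"))
}

#' Serialize a category table as a flat CSV
#'
#' Writes one row per cell with explicit category labels, for auditability.
#'
#' @param t A `category_table` or `joint_category_table`.
#' @param file Output path.
#' @export
write_category_table <- function(t, file) {
    if (inherits(t, "joint_category_table")) {
        df <- expand.grid(g_self = GENO_LABELS, g_other = GENO_LABELS,
                          allele = ALLELE_LABELS, stringsAsFactors = FALSE)
        df$count <- as.vector(unclass(t))
    } else {
        df <- expand.grid(g_self = GENO_LABELS, allele = ALLELE_LABELS,
                          stringsAsFactors = FALSE)
        df$count <- as.vector(unclass(t))
    }
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
}

#' Count major/minor alleles at SNP sites from a coordinate-sorted BAM
#'
#' Pileup-level counting: each aligned read segment contributes once per
#' overlapped site; paired-end mates count independently. Bases matching
#' neither the major nor the minor allele are discarded and reported in a
#' message. Requires the Rsamtools and GenomicRanges packages.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param sites Data frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `major`, `minor` (e.g. a biallelic founder table merged with its allele
#'   coding).
#' @param sample_id Sample id for the result.
#' @param min_base_quality Minimum base quality (default 20).
#' @param min_mapq Minimum mapping quality (default 0).
#' @return A `snp_allele_counts` object covering every site (zero counts
#'   where no read overlapped).
#' @export
extract_allele_counts <- function(bam, sites, sample_id,
                                  min_base_quality = 20, min_mapq = 0) {
    if (!requireNamespace("Rsamtools", quietly = TRUE) ||
        !requireNamespace("GenomicRanges", quietly = TRUE)) {
        stop("extract_allele_counts requires Rsamtools and GenomicRanges")
    }
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam))) {
        stop("BAM index not found for ", bam)
    }
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    unmatched <- setdiff(unique(sites$chrom), names(hdr))
    if (length(unmatched) > 0) {
        stop("contig name(s) absent from BAM header: ",
             paste(unmatched, collapse = ", "))
    }
    gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos, sites$pos))
    pp <- Rsamtools::PileupParam(min_base_quality = min_base_quality,
                                 min_mapq = min_mapq,
                                 min_nucleotide_depth = 1,
                                 distinguish_strands = FALSE,
                                 max_depth = .Machine$integer.max,
                                 include_deletions = FALSE,
                                 include_insertions = FALSE)
    sb <- Rsamtools::ScanBamParam(which = gr)
    p <- Rsamtools::pileup(bam, scanBamParam = sb, pileupParam = pp)

    key_sites <- paste(sites$chrom, sites$pos)
    idx <- match(paste(p$seqnames, p$pos), key_sites)
    nmaj <- nmin <- integer(nrow(sites))
    base <- as.character(p$nucleotide)
    is_maj <- base == sites$major[idx]
    is_min <- base == sites$minor[idx]
    for (w in which(is_maj)) nmaj[idx[w]] <- nmaj[idx[w]] + p$count[w]
    for (w in which(is_min)) nmin[idx[w]] <- nmin[idx[w]] + p$count[w]
    n_other <- sum(p$count[!is_maj & !is_min])
    if (n_other > 0) {
        message(n_other, " read base(s) matched neither allele and were discarded")
    }
    out <- snp_allele_counts(sites$snp_id, nmaj, nmin, sample_id)
    attr(out, "n_other") <- n_other
    out
}
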