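# Read-count tabulation into 3x2 and 3x3x2 genotype-category tables, and
# pileup extraction from BAM.

test_that("allele-count TSV round-trips, including gzip", {
    ct <- snp_allele_counts(c("snp1", "snp2"), c(3L, 0L), c(1L, 5L), "mb1")
    for (ext in c(".tsv", ".tsv.gz")) {
        f <- tempfile(fileext = ext)
        write_allele_counts(ct, f)
        back <- read_allele_counts(f)
        expect_equal(as.data.frame(back), as.data.frame(ct),
                     ignore_attr = TRUE)
        expect_identical(attr(back, "sample_id"),
                         sub("\\.tsv(\\.gz)?$", "", basename(f)))
        unlink(f)
    }
    expect_error(snp_allele_counts("s", -1, 0, "x"), "non-negative")
    expect_identical(total_reads(ct), 9L)
})

test_that("single-sample tabulation places counts by genotype and allele", {
    geno <- rbind(g1 = c(snpA = 0L, snpB = NA, snpC = 2L))
    reads <- snp_allele_counts(c("snpA", "snpB", "snpC"),
                               c(3L, 7L, 0L), c(1L, 2L, 4L), "mb1")
    tab <- tabulate_single(reads, geno, "g1")
    expect_equal(tab["AA", "A"], 3)
    expect_equal(tab["AA", "B"], 1)
    expect_equal(tab["BB", "B"], 4)
    expect_equal(sum(tab), 8)  # snpB excluded: missing genotype
    expect_error(tabulate_single(reads, geno, "nope"), "unknown")

    # all genotypes missing -> all-zero table
    geno_na <- rbind(g1 = c(snpA = NA_integer_))
    tab0 <- tabulate_single(snp_allele_counts("snpA", 5L, 2L, "mb1"),
                            geno_na, "g1")
    expect_true(all(tab0 == 0))
})

test_that("tabulations match naive per-SNP oracles on simulated data", {
    geno <- simulate_genotypes(3, 1000, seed = 21)
    geno[1, sample(1000, 50)] <- NA  # sprinkle missing genotypes
    geno[2, sample(1000, 30)] <- NA
    reads <- simulate_read_counts(geno, "S03", scenario("correct"),
                                  mean_depth = 5, eps = 0.01, seed = 22)
    attr(reads, "sample_id") <- "mb"
    tab <- tabulate_single(reads, geno, "S01")
    expect_equal(unclass(tab)[, ], naive_tabulate_single(reads, geno, "S01"),
                 ignore_attr = TRUE)
    jt <- tabulate_pair(reads, geno, "S01", "S02")
    expect_equal(as.vector(unclass(jt)),
                 as.vector(naive_tabulate_pair(reads, geno, "S01", "S02")))

    # total tabulated reads <= total reads, equal iff no missing genotype
    expect_lt(sum(tab), total_reads(reads))
    full <- tabulate_single(reads, geno, "S03")
    expect_equal(sum(full), total_reads(reads))

    # invariance to SNP ordering
    perm <- reads[sample(nrow(reads)), ]
    attr(perm, "sample_id") <- "mb"
    expect_equal(unclass(tabulate_single(perm, geno, "S01")), unclass(tab))
})

test_that("pair tabulation excludes missing, transposes, marginalizes", {
    geno <- rbind(x = c(s1 = 0L, s2 = 1L, s3 = 0L),
                  y = c(s1 = 2L, s2 = NA, s3 = 1L))
    reads <- snp_allele_counts(c("s1", "s2", "s3"),
                               c(0L, 9L, 2L), c(4L, 1L, 2L), "mb")
    jt <- tabulate_pair(reads, geno, "x", "y")
    expect_equal(jt["AA", "BB", "B"], 4)  # s1: (self AA, other BB), 4 B reads
    expect_equal(sum(jt), 8)  # s2's 10 reads excluded: other genotype missing
    expect_error(tabulate_pair(reads, geno, "x", "x"), "must differ")

    # swapping the pair transposes the two genotype axes
    jt_rev <- tabulate_pair(reads, geno, "y", "x")
    expect_equal(unclass(jt_rev)[, , 1], t(unclass(jt)[, , 1]),
                 ignore_attr = TRUE)
    expect_equal(unclass(jt_rev)[, , 2], t(unclass(jt)[, , 2]),
                 ignore_attr = TRUE)

    # marginal over the other sample's genotype = single-sample table on
    # the SNPs where both genotypes are known
    marg <- marginal_category_table(jt)
    both <- c("s1", "s3")
    sub <- reads[reads$snp_id %in% both, ]
    attr(sub, "sample_id") <- "mb"
    expect_equal(unclass(marg), unclass(tabulate_single(sub, geno, "x")),
                 ignore_attr = TRUE)
})

test_that("category tables serialize to labeled flat CSV", {
    tab <- category_table(matrix(1:6, 3, 2), "mb", "g")
    f <- tempfile(fileext = ".csv")
    write_category_table(tab, f)
    df <- read.csv(f, stringsAsFactors = FALSE)
    expect_identical(nrow(df), 6L)
    expect_equal(df$count[df$g_self == "AA" & df$allele == "A"], 1)
    jt <- joint_category_table(array(1:18, c(3, 3, 2)))
    write_category_table(jt, f)
    expect_identical(nrow(read.csv(f)), 18L)
    unlink(f)
})

# --- BAM pileup extraction ---------------------------------------------

# build a text SAM, convert to sorted/indexed BAM, return the BAM path
write_test_bam <- function(reads, dir, name) {
    sam <- file.path(dir, paste0(name, ".sam"))
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 "@SQ\tSN:chr1\tLN:1000",
                 reads), sam)
    Rsamtools::asBam(sam, file.path(dir, name), overwrite = TRUE)
}

sam_read <- function(name, pos, seq, qual, mapq = 60) {
    paste(name, 0, "chr1", pos, mapq, paste0(nchar(seq), "M"), "*", 0, 0,
          seq, qual, sep = "\t")
}

# naive per-read scan over the SAM records (the independent oracle)
naive_pileup <- function(reads, sites, min_bq = 20, min_mapq = 0) {
    nmaj <- nmin <- integer(nrow(sites))
    for (r in reads) {
        f <- strsplit(r, "\t")[[1]]
        pos <- as.integer(f[4]); mapq <- as.integer(f[5])
        seq <- f[10]; qual <- f[11]
        if (mapq < min_mapq) next
        for (s in seq_len(nrow(sites))) {
            off <- sites$pos[s] - pos + 1
            if (off < 1 || off > nchar(seq)) next
            if (utf8ToInt(substr(qual, off, off)) - 33 < min_bq) next
            base <- substr(seq, off, off)
            if (base == sites$major[s]) nmaj[s] <- nmaj[s] + 1L
            else if (base == sites$minor[s]) nmin[s] <- nmin[s] + 1L
        }
    }
    list(n_major = nmaj, n_minor = nmin)
}

test_that("BAM pileup counting matches a naive per-read scan", {
    skip_if_not_installed("Rsamtools")
    skip_if_not_installed("GenomicRanges")
    sites <- data.frame(snp_id = c("m1", "m2", "m3"), chrom = "chr1",
                        pos = c(100L, 105L, 200L),
                        major = c("A", "C", "G"), minor = c("C", "A", "T"),
                        stringsAsFactors = FALSE)
    hand <- c(
        sam_read("r1", 96, "TTTTATTTTC", "IIIIIIIIII"),      # A@100, C@105
        sam_read("r2", 100, "CTTTTATTTT", "IIIIIIIIII"),     # C@100, A@105
        sam_read("r3", 100, "ATTTTTTTTT", "#IIIIIIIII"),     # low qual @100
        sam_read("r4", 198, "TTCTT", "IIIII"),               # C@200: neither
        sam_read("r5", 199, "TGTTT", "IIIII", mapq = 0))     # G@200, mapq 0
    dir <- tempfile(); dir.create(dir)
    bam <- write_test_bam(hand, dir, "hand")
    got <- suppressMessages(extract_allele_counts(bam, sites, "mb1"))
    expect_identical(got$n_major, c(1L, 1L, 1L))
    expect_identical(got$n_minor, c(1L, 1L, 0L))
    expect_equal(attr(got, "n_other"), 1)  # the C@200 base

    # mapping-quality threshold drops the mapq-0 read
    got10 <- suppressMessages(
        extract_allele_counts(bam, sites, "mb1", min_mapq = 10))
    expect_identical(got10$n_major[3], 0L)

    # 50 random reads: agreement with the brute-force oracle
    set.seed(99)
    rnd <- vapply(1:50, function(i) {
        len <- sample(8:20, 1)
        sam_read(paste0("q", i), sample(85:215, 1),
                 paste(sample(c("A", "C", "G", "T"), len, TRUE),
                       collapse = ""),
                 paste(sample(c("I", "5", "#"), len, TRUE), collapse = ""))
    }, "")
    bam2 <- write_test_bam(rnd, dir, "rand")
    got2 <- suppressMessages(extract_allele_counts(bam2, sites, "mb1"))
    want <- naive_pileup(rnd, sites)
    expect_identical(got2$n_major, want$n_major)
    expect_identical(got2$n_minor, want$n_minor)

    # error paths: missing index, unknown contig
    file.remove(paste0(bam2, ".bai"))
    expect_error(extract_allele_counts(bam2, sites, "mb1"), "index")
    bad_sites <- sites; bad_sites$chrom <- "chrX"
    expect_error(extract_allele_counts(bam, bad_sites, "mb1"), "chrX")
    unlink(dir, recursive = TRUE)
})
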