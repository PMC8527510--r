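# Genotype preparation: biallelic filtering, allele coding, and collapse
# of diplotype probabilities to 3-state SNP calls.

test_that("biallelic filtering keeps exactly-two-allele SNPs, in order", {
    tab <- founder_fixture()
    kept <- filter_biallelic(tab)
    # m2 has three alleles, m3 is monomorphic, m6 has a missing allele
    expect_identical(kept$snp_id, c("m1", "m4", "m5"))
    expect_error(filter_biallelic(tab[0, ]), "empty")
})

test_that("allele coding follows founder frequency with lexicographic ties", {
    kept <- filter_biallelic(founder_fixture())
    cod <- code_alleles(kept)
    expect_identical(cod$major, c("A", "G", "C"))  # 3v1, 2v2 tie, 3v1
    expect_identical(cod$minor, c("C", "T", "A"))
    # determinism: permuting founder columns must not change the coding
    perm <- kept[, c("snp_id", "chrom", "pos", "F4", "F2", "F3", "F1")]
    cod_perm <- code_alleles(perm)
    expect_identical(cod, cod_perm)
    expect_error(code_alleles(founder_fixture()), "biallelic")
})

# two-founder fixture: states F1F1, F1F2, F2F2 map to dosage 0, 1, 2 at a
# SNP where F1 carries the major and F2 the minor allele
two_founder_setup <- function() {
    tab <- data.frame(snp_id = "m1", chrom = "1", pos = 100,
                      F1 = "A", F2 = "C", stringsAsFactors = FALSE)
    list(tab = tab, coding = code_alleles(tab))
}

test_that("diplotype collapse calls by maximum marginal above threshold", {
    s <- two_founder_setup()
    dip <- array(c(0.97, 0.50, 0.00,
                   0.02, 0.30, 1.00,
                   0.01, 0.20, 0.00),
                 c(3, 3, 1),
                 dimnames = list(c("a", "b", "c"), NULL, "m1"))
    g <- impute_snp_genotypes(dip, s$tab, s$coding)
    expect_identical(g["a", "m1"], 0L)          # P(AA) = 0.97 > 0.95
    expect_true(is.na(g["b", "m1"]))            # max marginal 0.5 <= 0.95
    expect_identical(g["c", "m1"], 1L)          # all mass on the het state
})

test_that("collapse validates inputs", {
    s <- two_founder_setup()
    bad <- array(c(0.5, 0.2, 0.2), c(1, 3, 1),
                 dimnames = list("a", NULL, "m1"))
    expect_error(impute_snp_genotypes(bad, s$tab, s$coding), "sum to 1")
    unknown <- array(c(1, 0, 0), c(1, 3, 1),
                     dimnames = list("a", NULL, "mX"))
    expect_error(impute_snp_genotypes(unknown, s$tab, s$coding),
                 "absent from founder table")
})

test_that("deterministic diplotypes reproduce the founder-implied genotype", {
    # three founders, six states; place all mass on one random state per
    # (sample, SNP) and check the call against a direct allele lookup
    set.seed(42)
    k <- 3
    founders <- c("F1", "F2", "F3")
    n_snps <- 40; n_samp <- 8
    alleles <- t(replicate(n_snps, {
        a <- sample(c("A", "C", "G", "T"), 2)
        a[sample(1:2, k, replace = TRUE)]  # may be monomorphic: filter below
    }))
    tab <- data.frame(snp_id = sprintf("m%02d", 1:n_snps), chrom = "1",
                      pos = 1:n_snps * 100, stringsAsFactors = FALSE)
    tab[founders] <- as.data.frame(alleles, stringsAsFactors = FALSE)
    tab <- filter_biallelic(tab)
    cod <- code_alleles(tab)
    st <- diplotype_states(founders)
    dip <- array(0, c(n_samp, nrow(st), nrow(tab)),
                 dimnames = list(paste0("s", 1:n_samp), NULL, tab$snp_id))
    chosen <- matrix(sample(nrow(st), n_samp * nrow(tab), replace = TRUE),
                     n_samp, nrow(tab))
    for (i in 1:n_samp) for (j in seq_len(nrow(tab))) {
        dip[i, chosen[i, j], j] <- 1
    }
    g <- impute_snp_genotypes(dip, tab, cod, threshold = 0)
    for (i in 1:n_samp) for (j in seq_len(nrow(tab))) {
        a1 <- tab[j, founders][[st$f1[chosen[i, j]]]]
        a2 <- tab[j, founders][[st$f2[chosen[i, j]]]]
        expected <- (a1 == cod$minor[j]) + (a2 == cod$minor[j])
        expect_identical(g[i, j], as.integer(expected))
    }
})

test_that("raising the call threshold only introduces missingness", {
    set.seed(7)
    s <- two_founder_setup()
    n_samp <- 50
    pr <- matrix(stats::rgamma(n_samp * 3, 1), n_samp, 3)
    pr <- pr / rowSums(pr)
    dip <- array(pr, c(n_samp, 3, 1),
                 dimnames = list(paste0("s", 1:n_samp), NULL, "m1"))
    prev <- NULL
    for (th in c(0, 0.5, 0.95, 0.99)) {
        g <- impute_snp_genotypes(dip, s$tab, s$coding, threshold = th)
        if (!is.null(prev)) {
            both <- !is.na(prev) & !is.na(g)
            expect_identical(prev[both], g[both])
            expect_true(all(is.na(g[is.na(prev)])))
        }
        prev <- g
    }
})

test_that("interval averaging takes the mean of endpoint probabilities", {
    l <- matrix(c(1, 0, 0, 0.5, 0.5, 0), 2, 3, byrow = TRUE)
    r <- matrix(c(0, 1, 0, 0.5, 0.1, 0.4), 2, 3, byrow = TRUE)
    av <- average_diplotype_probs(l, r)
    expect_equal(av, (l + r) / 2)
    expect_equal(rowSums(av), c(1, 1))
    expect_error(average_diplotype_probs(l, r[1, , drop = FALSE]),
                 "identical dimensions")
})

test_that("genotype CSV round-trips in both encodings", {
    set.seed(11)
    geno <- simulate_genotypes(5, 12, seed = 3)
    geno[2, 4] <- NA
    for (enc in c("letters", "dosage")) {
        f <- tempfile(fileext = ".csv")
        write_genotypes(geno, f, encoding = enc)
        back <- read_genotypes(f)
        expect_identical(back, structure(geno, maf = NULL))
        unlink(f)
    }
})

test_that("dosage/letter conversion is a bijection and validates input", {
    expect_identical(geno2dosage(c("AA", "AB", "BB", NA)),
                     c(0L, 1L, 2L, NA))
    expect_identical(dosage2geno(geno2dosage(c("BB", "AA"))), c("BB", "AA"))
    expect_error(geno2dosage("AC"), "unrecognized")
    expect_error(geno2dosage(3), "dosage")
})

test_that("VCF genotypes map to dosage and mismatched sites are dropped", {
    skip_if_not_installed("vcfR")
    coding <- data.frame(snp_id = c("m1", "m2", "m3"),
                         major = c("A", "G", "C"),
                         minor = c("C", "T", "A"), stringsAsFactors = FALSE)
    vcf <- c("##fileformat=VCFv4.2",
             "##contig=<ID=1>",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2", sep = "\t"),
             # REF = major: dosage = ALT count
             paste("1", "100", "m1", "A", "C", ".", "PASS", ".", "GT",
                   "0/0", "0/1", sep = "\t"),
             # REF = minor: dosage flipped
             paste("1", "200", "m2", "T", "G", ".", "PASS", ".", "GT",
                   "1/1", "./.", sep = "\t"),
             # REF/ALT disagree with the coding: dropped with a warning
             paste("1", "300", "m3", "G", "T", ".", "PASS", ".", "GT",
                   "0/1", "0/0", sep = "\t"))
    f <- tempfile(fileext = ".vcf")
    writeLines(vcf, f)
    expect_warning(g <- read_genotypes_vcf(f, coding), "dropped")
    expect_identical(colnames(g), c("m1", "m2"))
    expect_identical(g["s1", "m1"], 0L)
    expect_identical(g["s2", "m1"], 1L)
    expect_identical(g["s1", "m2"], 0L)  # 1/1 on flipped site = no minor
    expect_true(is.na(g["s2", "m2"]))
    unlink(f)
})
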