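# Host SNP genotype preparation: biallelic filtering of a founder allele
# table, major/minor coding by founder allele frequency, and collapse of
# multi-founder diplotype probabilities to 3-state SNP genotype calls.
#
# Genotypes are held internally as minor-allele dosage {0, 1, 2} (0 = AA,
# 1 = AB, 2 = BB) in an integer matrix with samples as rows and SNPs as
# columns; NA marks a missing call.

GENO_LABELS <- c("AA", "AB", "BB")

#' Convert genotype labels to minor-allele dosage
#'
#' @param x Character vector of calls in `{AA, AB, BB}` (NA allowed), or a
#'   numeric vector of dosages 0/1/2 which is returned as integer unchanged.
#' @return Integer vector of minor-allele dosages (0, 1, 2, or NA).
#' @export
geno2dosage <- function(x) {
    if (is.numeric(x)) {
        bad <- !is.na(x) & !(x %in% 0:2)
        if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
        return(as.integer(x))
    }
    m <- match(as.character(x), GENO_LABELS) - 1L
    bad <- !is.na(x) & x != "NA" & is.na(m)
    if (any(bad)) {
        stop("unrecognized genotype call(s): ",
             paste(unique(x[bad]), collapse = ", "))
    }
    m
}

#' Convert minor-allele dosage to genotype labels
#'
#' @param d Integer vector of dosages (0, 1, 2, NA).
#' @return Character vector of `AA`/`AB`/`BB` calls (NA preserved).
#' @export
dosage2geno <- function(d) GENO_LABELS[as.integer(d) + 1L]

# founder allele columns = everything except the coordinate columns
founder_columns <- function(tab) {
    setdiff(colnames(tab), c("snp_id", "chrom", "pos"))
}

#' Read a founder SNP allele table
#'
#' Tab-delimited, columns `snp_id`, `chrom`, `pos` (1-based), then one
#' single-nucleotide allele column per founder strain. Founder strains are
#' assumed fully inbred, so each contributes one allele per SNP.
#'
#' @param file Path to the TSV (gzip transparently supported).
#' @return Data frame with one row per SNP.
#' @export
read_founder_table <- function(file) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                             na.strings = c("NA", "", "N", "."))
    need <- c("snp_id", "chrom", "pos")
    if (!all(need %in% colnames(tab))) {
        stop("founder table must have columns ", paste(need, collapse = ", "))
    }
    if (length(founder_columns(tab)) < 2) {
        stop("founder table needs at least two founder allele columns")
    }
    tab
}

#' Filter a founder table to strictly biallelic SNPs
#'
#' Keeps SNPs whose founder alleles comprise exactly two distinct
#' nucleotides. SNPs with three or more alleles are uninformative under a
#' two-allele coding and are removed; monomorphic SNPs carry no identity
#' information and are removed as well. SNPs with a missing founder allele
#' are dropped because the diplotype-to-genotype map is undefined for them.
#'
#' @param tab Founder table as from [read_founder_table()].
#' @return The filtered table, row order preserved.
#' @export
filter_biallelic <- function(tab) {
    if (nrow(tab) == 0) stop("empty founder table")
    fc <- founder_columns(tab)
    al <- as.matrix(tab[, fc, drop = FALSE])
    keep <- apply(al, 1, function(a) {
        !anyNA(a) && length(unique(a)) == 2L
    })
    tab[keep, , drop = FALSE]
}

#' Code SNP alleles as major/minor by founder frequency
#'
#' The major allele is the one carried by more founder strains; at a
#' frequency tie the lexicographically smaller nucleotide is taken as major,
#' so the coding does not depend on founder ordering.
#'
#' @param tab Biallelic founder table (see [filter_biallelic()]).
#' @return Data frame with columns `snp_id`, `major`, `minor`.
#' @export
code_alleles <- function(tab) {
    fc <- founder_columns(tab)
    al <- as.matrix(tab[, fc, drop = FALSE])
    maj <- character(nrow(tab))
    mnr <- character(nrow(tab))
    for (i in seq_len(nrow(tab))) {
        cnt <- table(al[i, ])
        if (length(cnt) != 2L || anyNA(al[i, ])) {
            stop("SNP ", tab$snp_id[i], " is not strictly biallelic")
        }
        alleles <- names(cnt)[order(-as.integer(cnt), names(cnt))]
        maj[i] <- alleles[1]
        mnr[i] <- alleles[2]
    }
    data.frame(snp_id = tab$snp_id, major = maj, minor = mnr,
               stringsAsFactors = FALSE)
}

#' Enumerate diplotype states for a set of founders
#'
#' The d = k(k+1)/2 unordered founder pairs (36 for eight founders), in the
#' order (1,1), (1,2), (2,2), (1,3), ... matching upper-triangle traversal
#' by column.
#'
#' @param founders Character vector of founder codes (column names of the
#'   founder table).
#' @return Data frame with columns `state`, `f1`, `f2`.
#' @export
diplotype_states <- function(founders) {
    k <- length(founders)
    f1 <- f2 <- integer(0)
    for (j in seq_len(k)) {
        f1 <- c(f1, seq_len(j))
        f2 <- c(f2, rep(j, j))
    }
    data.frame(state = paste0(founders[f1], founders[f2]),
               f1 = f1, f2 = f2, stringsAsFactors = FALSE)
}

#' Average diplotype probabilities at two flanking markers
#'
#' For SNPs lying between two genotyped array markers, the diplotype
#' probabilities may be taken as constant within the interval; this helper
#' returns the arithmetic mean of the endpoint probabilities.
#'
#' @param left,right Numeric matrices (samples x diplotype states) of equal
#'   dimension.
#' @return Matrix of the same shape.
#' @export
average_diplotype_probs <- function(left, right) {
    if (!identical(dim(left), dim(right))) {
        stop("endpoint probability matrices must have identical dimensions")
    }
    (left + right) / 2
}

#' Collapse diplotype probabilities to 3-state SNP genotype calls
#'
#' For each SNP the founder alleles map every diplotype state to a
#' minor-allele dosage 0/1/2; the marginal probability of each dosage is the
#' sum of the probabilities of the states yielding it. The call is the
#' dosage with maximum marginal probability, provided that probability
#' exceeds `threshold`; otherwise the call is missing.
#'
#' @param dip 3-d array of diplotype probabilities, dimensions
#'   samples x states x SNPs, with dimnames; state order must follow
#'   [diplotype_states()] of the founder table's founder columns.
#' @param tab Founder table restricted to biallelic SNPs.
#' @param coding Allele coding from [code_alleles()].
#' @param threshold Minimum marginal probability for a non-missing call
#'   (strictly greater than; default 0.95).
#' @param tol Tolerance for each state vector summing to 1.
#' @return Integer genotype matrix (samples x SNPs, minor-allele dosage).
#' @export
impute_snp_genotypes <- function(dip, tab, coding, threshold = 0.95,
                                 tol = 1e-6) {
    founders <- founder_columns(tab)
    st <- diplotype_states(founders)
    if (dim(dip)[2] != nrow(st)) {
        stop("diplotype array has ", dim(dip)[2], " states; expected ",
             nrow(st), " for ", length(founders), " founders")
    }
    snp_ids <- dimnames(dip)[[3]]
    if (is.null(snp_ids)) stop("diplotype array must name its SNPs")
    miss <- setdiff(snp_ids, tab$snp_id)
    if (length(miss) > 0) {
        stop("SNP(s) absent from founder table: ",
             paste(utils::head(miss, 5), collapse = ", "))
    }

    n_samp <- dim(dip)[1]
    geno <- matrix(NA_integer_, n_samp, length(snp_ids),
                   dimnames = list(dimnames(dip)[[1]], snp_ids))
    tab_idx <- match(snp_ids, tab$snp_id)
    cod_idx <- match(snp_ids, coding$snp_id)
    if (anyNA(cod_idx)) stop("SNP(s) absent from allele coding")

    for (s in seq_along(snp_ids)) {
        alleles <- unlist(tab[tab_idx[s], founders])
        if (anyNA(alleles)) {
            stop("missing founder allele at SNP ", snp_ids[s])
        }
        dos_founder <- as.integer(alleles == coding$minor[cod_idx[s]])
        state_dos <- dos_founder[st$f1] + dos_founder[st$f2]
        pr <- dip[, , s, drop = FALSE]
        dim(pr) <- dim(dip)[1:2]
        bad <- abs(rowSums(pr) - 1) > tol
        if (any(bad)) {
            stop("diplotype probabilities do not sum to 1 at SNP ",
                 snp_ids[s], " for sample(s) ",
                 paste(which(bad), collapse = ", "))
        }
        marg <- cbind(rowSums(pr[, state_dos == 0L, drop = FALSE]),
                      rowSums(pr[, state_dos == 1L, drop = FALSE]),
                      rowSums(pr[, state_dos == 2L, drop = FALSE]))
        top <- max.col(marg, ties.method = "first")
        pmax_val <- marg[cbind(seq_len(n_samp), top)]
        call <- ifelse(pmax_val > threshold, top - 1L, NA_integer_)
        geno[, s] <- as.integer(call)
    }
    geno
}

#' Write a genotype matrix to CSV
#'
#' One row per sample: `sample_id` then calls. Calls are written as
#' `AA`/`AB`/`BB` by default, or as minor-allele dosage 0/1/2.
#'
#' @param geno Genotype matrix (samples x SNPs, dosage coding).
#' @param file Output path.
#' @param encoding `"letters"` or `"dosage"`.
#' @export
write_genotypes <- function(geno, file, encoding = c("letters", "dosage")) {
    encoding <- match.arg(encoding)
    vals <- if (encoding == "letters") {
        matrix(dosage2geno(geno), nrow(geno), ncol(geno))
    } else geno
    df <- data.frame(sample_id = rownames(geno), vals,
                     stringsAsFactors = FALSE, check.names = FALSE)
    colnames(df) <- c("sample_id", colnames(geno))
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "NA")
}

#' Read a genotype matrix from CSV
#'
#' Accepts both letter (`AA`/`AB`/`BB`) and dosage (0/1/2) encodings.
#'
#' @param file Path to CSV as written by [write_genotypes()].
#' @return Integer genotype matrix (samples x SNPs, dosage coding).
#' @export
read_genotypes <- function(file) {
    df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
    if (colnames(df)[1] != "sample_id") {
        stop("genotype CSV must start with a sample_id column")
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    geno <- matrix(geno2dosage(m), nrow(m), ncol(m),
                   dimnames = list(df$sample_id, colnames(df)[-1]))
    geno
}

#' Read genotypes from a VCF
#'
#' GT fields 0/0, 0/1, 1/1 (or phased equivalents) are mapped to minor-allele
#' dosage using the supplied allele coding. Sites whose REF/ALT pair does not
#' match the coding's major/minor alleles are dropped with a warning.
#'
#' @param file Path to a VCF (may be bgzipped).
#' @param coding Allele coding from [code_alleles()]; SNP ids are matched
#'   against the VCF ID column.
#' @return Integer genotype matrix (samples x SNPs, dosage coding).
#' @export
read_genotypes_vcf <- function(file, coding) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
        stop("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gt <- vcfR::extract.gt(v, element = "GT")
    ids <- fix[, "ID"]
    idx <- match(ids, coding$snp_id)
    ok <- !is.na(idx)
    flip <- logical(length(ids))
    for (i in which(ok)) {
        j <- idx[i]
        if (fix[i, "REF"] == coding$major[j] &&
            fix[i, "ALT"] == coding$minor[j]) {
            flip[i] <- FALSE
        } else if (fix[i, "REF"] == coding$minor[j] &&
                   fix[i, "ALT"] == coding$major[j]) {
            flip[i] <- TRUE
        } else ok[i] <- FALSE
    }
    if (any(!ok)) {
        warning(sum(!ok), " VCF site(s) dropped: ID or REF/ALT does not ",
                "match the allele coding")
    }
    gt <- gt[ok, , drop = FALSE]
    flip <- flip[ok]
    alt_count <- function(g) {
        if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
        sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0L)
    }
    dos <- apply(gt, c(1, 2), alt_count)
    dos[flip, ] <- 2L - dos[flip, , drop = FALSE]
    t(dos)
}
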