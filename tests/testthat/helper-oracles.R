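# Independent brute-force oracles used across the test files. These
# deliberately avoid the package's own accumulation and optimization code
# paths: tabulations are naive per-SNP loops, the likelihood goes through
# stats::dbinom, and the mixture MLE is an exhaustive staged grid search.

naive_tabulate_single <- function(reads, geno, genomic_id) {
    tab <- matrix(0, 3, 2, dimnames = list(c("AA", "AB", "BB"), c("A", "B")))
    for (i in seq_len(nrow(reads))) {
        snp <- reads$snp_id[i]
        if (!snp %in% colnames(geno)) next
        g <- geno[genomic_id, snp]
        if (is.na(g)) next
        tab[g + 1, 1] <- tab[g + 1, 1] + reads$n_major[i]
        tab[g + 1, 2] <- tab[g + 1, 2] + reads$n_minor[i]
    }
    tab
}

naive_tabulate_pair <- function(reads, geno, id_self, id_other) {
    tab <- array(0, c(3, 3, 2))
    for (i in seq_len(nrow(reads))) {
        snp <- reads$snp_id[i]
        if (!snp %in% colnames(geno)) next
        g1 <- geno[id_self, snp]
        g2 <- geno[id_other, snp]
        if (is.na(g1) || is.na(g2)) next
        tab[g1 + 1, g2 + 1, 1] <- tab[g1 + 1, g2 + 1, 1] + reads$n_major[i]
        tab[g1 + 1, g2 + 1, 2] <- tab[g1 + 1, g2 + 1, 2] + reads$n_minor[i]
    }
    tab
}

# binomial log-likelihood through stats::dbinom, with the combinatorial
# constant subtracted so it matches the package's constant-free form
dbinom_loglik <- function(t, p, eps) {
    t <- unclass(t)
    ll <- 0
    f <- c(0, 0.5, 1)
    for (i in 1:3) for (j in 1:3) {
        nA <- t[i, j, 1]; nB <- t[i, j, 2]; n <- nA + nB
        if (n == 0) next
        q <- eps + ((1 - p) * f[i] + p * f[j]) * (1 - 2 * eps)
        if ((q <= 0 && nB > 0) || (q >= 1 && nA > 0)) return(-1e300)
        ll <- ll + stats::dbinom(nB, n, q, log = TRUE) - lchoose(n, nB)
    }
    ll
}

# staged exhaustive grid search for the mixture MLE: a coarse global pass
# then repeated zooming around the argmax, down to ~1e-7 resolution
grid_fit <- function(t, n_p = 101, n_eps = 51, stages = 4) {
    lo_p <- 0; hi_p <- 1
    lo_e <- 0; hi_e <- 0.499
    best <- NULL
    for (s in seq_len(stages)) {
        ps <- seq(lo_p, hi_p, length.out = n_p)
        es <- seq(lo_e, hi_e, length.out = n_eps)
        grid <- expand.grid(p = ps, eps = es)
        ll <- vapply(seq_len(nrow(grid)), function(i) {
            mixture_loglik(t, grid$p[i], grid$eps[i])
        }, 0)
        k <- which.max(ll)
        best <- list(p = grid$p[k], eps = grid$eps[k], loglik = ll[k])
        dp <- (hi_p - lo_p) / (n_p - 1)
        de <- (hi_e - lo_e) / (n_eps - 1)
        lo_p <- max(0, best$p - dp); hi_p <- min(1, best$p + dp)
        lo_e <- max(0, best$eps - de); hi_e <- min(0.499, best$eps + de)
    }
    best
}

# 1-d grid for the null (p = 0) error-rate estimate
grid_null_eps <- function(t, n_eps = 2001) {
    es <- seq(0, 0.499, length.out = n_eps)
    ll <- vapply(es, function(e) mixture_loglik(t, 0, e), 0)
    list(eps = es[which.max(ll)], loglik = max(ll))
}

# a random joint category table with reads in identifiable cells,
# simulated through the package's own generator at a random (p, eps)
random_joint_table <- function(seed, mean_depth = 30) {
    set.seed(seed)
    p <- stats::runif(1)
    eps <- stats::runif(1, 0.0005, 0.02)
    geno <- simulate_genotypes(2, 500, seed = seed + 1000L)
    reads <- simulate_read_counts(geno, "S01",
                                  scenario("mixture", "S02", p),
                                  mean_depth = mean_depth, eps = eps,
                                  seed = seed + 2000L)
    list(table = tabulate_pair(reads, geno, "S01", "S02"),
         p = p, eps = eps)
}

# small founder allele table used by the genotype tests
founder_fixture <- function() {
    data.frame(
        snp_id = paste0("m", 1:6),
        chrom = "1", pos = c(100, 200, 300, 400, 500, 600),
        F1 = c("A", "A", "T", "G", "A", NA),
        F2 = c("A", "C", "T", "G", "C", "C"),
        F3 = c("A", "G", "T", "T", "C", "C"),
        F4 = c("C", "A", "T", "T", "C", "C"),
        stringsAsFactors = FALSE)
}
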