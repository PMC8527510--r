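# Two-sample mixture model for a microbiome sample's host-derived reads.
#
# The sample is modeled as a proportion (1 - p) from the correctly labeled
# mouse and p from one contaminant mouse, with per-read sequencing error
# rate eps. Writing f(g) for the minor-allele frequency implied by a
# genotype (0, 1/2, or 1 for AA, AB, BB), the template minor-allele
# frequency in a joint-genotype cell is
#     f* = (1 - p) f(g_self) + p f(g_other)
# and the probability that a read shows the minor allele is
#     q = eps + f* (1 - 2 eps),
# i.e. a true minor read survives with probability 1 - eps and a true major
# read errs to minor with probability eps. Conditional on the cell totals
# the 18-category multinomial factorizes into 9 independent binomials, so
# the binomial form is used throughout (identical MLEs, simpler numerics).

LOGLIK_FLOOR <- -1e300  # representable stand-in for log(0) likelihoods

check_mixture_params <- function(p, eps) {
    if (is.na(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
    if (is.na(eps) || eps < 0 || eps >= 0.5) stop("eps must be in [0, 0.5)")
}

dosage_frequency <- function(g) {
    if (is.character(g) || is.factor(g)) geno2dosage(g) / 2 else g / 2
}

#' Expected minor-allele read probability in a joint-genotype cell
#'
#' @param g_self Genotype of the correctly labeled sample: `"AA"`, `"AB"`,
#'   `"BB"` or dosage 0/1/2 (vectorized).
#' @param g_other Genotype of the candidate contaminant, same encodings.
#' @param p Contaminant proportion in \[0, 1\].
#' @param eps Sequencing error rate in \[0, 0.5).
#' @return Probability that a read from this cell carries the minor (B)
#'   allele.
#' @export
expected_minor_prob <- function(g_self, g_other, p, eps) {
    check_mixture_params(p, eps)
    fstar <- (1 - p) * dosage_frequency(g_self) +
        p * dosage_frequency(g_other)
    eps + fstar * (1 - 2 * eps)
}

# internal: cell minor-allele frequencies for the 9 joint-genotype cells,
# in the array layout of a joint_category_table (self varies fastest)
cell_freqs <- function() {
    f1 <- rep(c(0, 0.5, 1), 3)
    f2 <- rep(c(0, 0.5, 1), each = 3)
    list(f1 = f1, f2 = f2)
}

#' Log-likelihood of a joint category table under the mixture model
#'
#' Sum over the nine joint-genotype cells of the binomial log-likelihood of
#' the minor-read count given the cell total and the expected minor
#' probability. Binomial coefficients are omitted (they cancel in every
#' likelihood ratio). A cell whose expected probability is exactly 0 or 1
#' but whose counts contradict it yields a large negative sentinel value.
#'
#' @param t A `joint_category_table`.
#' @param p Contaminant proportion.
#' @param eps Sequencing error rate.
#' @return Log-likelihood (0 for an empty table).
#' @export
mixture_loglik <- function(t, p, eps) {
    check_mixture_params(p, eps)
    nA <- as.vector(unclass(t)[, , 1])
    nB <- as.vector(unclass(t)[, , 2])
    fr <- cell_freqs()
    q <- eps + ((1 - p) * fr$f1 + p * fr$f2) * (1 - 2 * eps)
    ll_terms(nA, nB, q)
}

# shared kernel: sum nB log q + nA log(1-q) with 0 * log(0) := 0
ll_terms <- function(nA, nB, q) {
    ll <- 0
    bad <- (nB > 0 & q <= 0) | (nA > 0 & q >= 1)
    if (any(bad)) return(LOGLIK_FLOOR)
    use_b <- nB > 0
    use_a <- nA > 0
    sum(nB[use_b] * log(q[use_b])) + sum(nA[use_a] * log(1 - q[use_a]))
}

# vectorized over a parameter grid: p, eps equal-length vectors
loglik_grid <- function(t, p, eps) {
    nA <- as.vector(unclass(t)[, , 1])
    nB <- as.vector(unclass(t)[, , 2])
    fr <- cell_freqs()
    vapply(seq_along(p), function(i) {
        q <- eps[i] + ((1 - p[i]) * fr$f1 + p[i] * fr$f2) * (1 - 2 * eps[i])
        ll_terms(nA, nB, q)
    }, 0)
}

# moment starting values: p from the discordant homozygous-opposite cells,
# eps from the concordant homozygous cells
moment_estimates <- function(t) {
    t <- unclass(t)
    n_eps <- t["AA", "AA", "B"] + t["BB", "BB", "A"]
    d_eps <- sum(t["AA", "AA", ]) + sum(t["BB", "BB", ])
    eps_m <- if (d_eps > 0) n_eps / d_eps else 0.005
    n_p <- t["AA", "BB", "B"] + t["BB", "AA", "A"]
    d_p <- sum(t["AA", "BB", ]) + sum(t["BB", "AA", ])
    p_m <- if (d_p > 0) n_p / d_p else 0.01
    c(p = min(max(p_m, 1e-4), 1 - 1e-4),
      eps = min(max(eps_m, 1e-5), 0.49))
}

EPS_MAX <- 0.5 - 1e-9

fit_null_eps <- function(t) {
    # p = 0: the contaminant genotype is irrelevant; 1-d maximization in eps
    opt <- stats::optimize(function(e) mixture_loglik(t, 0, e),
                           interval = c(0, EPS_MAX), maximum = TRUE,
                           tol = 1e-10)
    # optimize() cannot return the boundary exactly; check eps = 0 too
    ll0 <- mixture_loglik(t, 0, 0)
    if (ll0 > opt$objective) list(eps = 0, loglik = ll0)
    else list(eps = opt$maximum, loglik = opt$objective)
}

#' Fit the two-parameter mixture model to a joint category table
#'
#' Maximum likelihood estimates of the contaminant proportion p and the
#' sequencing error rate eps, by multi-start derivative-free optimization
#' on a logit-transformed scale, together with the null fit (p = 0, eps
#' free) and the likelihood ratio test statistic
#' LRT = 2 (loglik_alt - loglik_null) for no contamination.
#'
#' p is unidentifiable when every read sits in a cell where the two
#' genotypes imply the same allele frequency; such fits are returned with
#' `identifiable = FALSE`, `p_hat = NA` and LRT 0.
#'
#' @param t A `joint_category_table`.
#' @return Object of class `mixture_fit`: list with `p_hat`, `eps_hat`,
#'   `eps0_hat`, `loglik_alt`, `loglik_null`, `lrt`, `n_reads`,
#'   `identifiable`.
#' @export
fit_mixture <- function(t) {
    n_reads <- sum(t)
    null_fit <- if (n_reads > 0) fit_null_eps(t) else list(eps = 0, loglik = 0)

    fr <- cell_freqs()
    informative <- abs(fr$f1 - fr$f2) > 0
    n_informative <- sum(apply(unclass(t), c(1, 2), sum)[informative])
    if (n_reads == 0 || n_informative == 0) {
        out <- list(p_hat = NA_real_, eps_hat = null_fit$eps,
                    eps0_hat = null_fit$eps, loglik_alt = null_fit$loglik,
                    loglik_null = null_fit$loglik, lrt = 0,
                    n_reads = n_reads, identifiable = FALSE)
        class(out) <- "mixture_fit"
        return(out)
    }

    # unconstrained scale: theta = (logit p, logit 2 eps)
    to_par <- function(theta) {
        c(p = unname(stats::plogis(theta[1])),
          eps = unname(stats::plogis(theta[2])) / 2)
    }
    negll <- function(theta) {
        pa <- to_par(theta)
        -mixture_loglik(t, pa[["p"]], min(pa[["eps"]], EPS_MAX))
    }
    mom <- moment_estimates(t)
    starts <- rbind(c(mom[["p"]], mom[["eps"]]),
                    c(0.01, 0.005),
                    c(0.5, 0.01),
                    c(0.95, 0.002),
                    c(0.2, 0.05))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
        th0 <- c(stats::qlogis(starts[s, 1]),
                 stats::qlogis(min(2 * starts[s, 2], 1 - 1e-8)))
        o <- tryCatch(stats::optim(th0, negll, method = "Nelder-Mead",
                                   control = list(maxit = 2000,
                                                  reltol = 1e-12)),
                      error = function(e) NULL)
        if (is.null(o)) next
        if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) stop("mixture optimization failed from all starts")

    pa <- to_par(best$par)
    p_hat <- pa[["p"]]
    eps_hat <- min(pa[["eps"]], EPS_MAX)
    ll_alt <- mixture_loglik(t, p_hat, eps_hat)
    # the boundary p = 0 is outside the open logit scale; the null optimum
    # is a feasible alternative-model point, so never report less than it
    if (ll_alt < null_fit$loglik) {
        p_hat <- 0
        eps_hat <- null_fit$eps
        ll_alt <- null_fit$loglik
    }
    lrt <- 2 * (ll_alt - null_fit$loglik)
    if (lrt < -1e-6) stop("negative LRT beyond numerical floor")
    out <- list(p_hat = p_hat, eps_hat = eps_hat, eps0_hat = null_fit$eps,
                loglik_alt = ll_alt, loglik_null = null_fit$loglik,
                lrt = max(lrt, 0), n_reads = n_reads, identifiable = TRUE)
    class(out) <- "mixture_fit"
    out
}

#' @export
print.mixture_fit <- function(x, ...) {
    cat("Mixture model fit (", format(x$n_reads, big.mark = ","),
        " reads)\n", sep = "")
    if (!x$identifiable) {
        cat("  contaminant proportion not identifiable from these counts\n")
    } else {
        cat(sprintf("  p-hat   = %.4f   (contaminant proportion)\n", x$p_hat))
    }
    cat(sprintf("  eps-hat = %.4f   (sequencing error rate)\n", x$eps_hat))
    cat(sprintf("  LRT (p = 0) = %.4g\n", x$lrt))
    invisible(x)
}

#' Scan every candidate contaminant for one microbiome sample
#'
#' Fits the mixture model with each other genomic sample as the single
#' candidate contaminant, via [tabulate_pair()] and [fit_mixture()].
#'
#' @param reads A `snp_allele_counts` object for the microbiome sample.
#' @param geno Genotype matrix (samples x SNPs, dosage coding).
#' @param id_self The microbiome sample's own genomic id.
#' @param candidates Candidate contaminant ids (default: all other rows of
#'   `geno`).
#' @return Data frame of class `contaminant_scan`, one row per candidate:
#'   `candidate_id`, `p_hat`, `eps_hat`, `lrt`, `n_reads`, `identifiable`,
#'   sorted by decreasing LRT, with attribute `microbiome_id`.
#' @export
scan_contaminants <- function(reads, geno, id_self,
                              candidates = setdiff(rownames(geno), id_self)) {
    if (!id_self %in% rownames(geno)) {
        stop("unknown genomic sample: ", id_self)
    }
    fits <- lapply(candidates, function(id) {
        fit_mixture(tabulate_pair(reads, geno, id_self, id))
    })
    out <- data.frame(candidate_id = candidates,
                      p_hat = vapply(fits, `[[`, 0, "p_hat"),
                      eps_hat = vapply(fits, `[[`, 0, "eps_hat"),
                      lrt = vapply(fits, `[[`, 0, "lrt"),
                      n_reads = vapply(fits, `[[`, 0, "n_reads"),
                      identifiable = vapply(fits, `[[`, TRUE, "identifiable"),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$lrt), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "microbiome_id") <- attr(reads, "sample_id")
    attr(out, "genomic_id_self") <- id_self
    class(out) <- c("contaminant_scan", "data.frame")
    out
}

#' Detect a separated contaminant in a scan
#'
#' The LRT statistics in a real scan are nominally significant throughout
#' (the binomial model is only an approximation), so a contaminant is
#' called by separation, not by calibrated significance: the top candidate
#' is flagged when its LRT exceeds the runner-up's by at least
#' `gap_factor`. A small absolute floor `min_lrt` guards the rule in clean
#' data, where many LRTs are exactly zero at the p = 0 boundary and the
#' top-to-runner-up ratio of near-zero statistics is meaningless noise.
#'
#' The default gap factor sits between the two regimes a scan exhibits:
#' candidates other than the contaminant separate from one another by
#' factors of only 1-2, while the runner-up trails a true contaminant by
#' a factor of about 10, because it captures roughly a tenth of the
#' mixture signal through minor-allele-frequency confounding (cells where
#' a candidate is BB enrich for high-frequency SNPs, which also carry
#' more contaminant minor alleles). See the package vignette for the
#' calibration analysis.
#'
#' @param scan A `contaminant_scan` with at least two candidates.
#' @param gap_factor Required ratio of the top LRT to the second (default
#'   4).
#' @param min_lrt Minimum top LRT for a flag (default 25).
#' @return List with `flagged_contaminant` (id or NA), `separation`
#'   (top LRT / second LRT; Inf when the runner-up is 0), and the top
#'   candidate's `p_hat`, `eps_hat`, `lrt`.
#' @export
detect_contaminant <- function(scan, gap_factor = 4, min_lrt = 25) {
    if (nrow(scan) < 2) stop("scan needs at least two candidates")
    l <- sort(scan$lrt, decreasing = TRUE)
    sep <- if (l[2] > 0) l[1] / l[2] else if (l[1] > 0) Inf else NA_real_
    top <- scan[which.max(scan$lrt), ]
    flagged <- if (!is.na(sep) && sep >= gap_factor && l[1] >= min_lrt) {
        top$candidate_id
    } else NA_character_
    list(flagged_contaminant = flagged, separation = sep,
         p_hat = top$p_hat, eps_hat = top$eps_hat, lrt = top$lrt)
}

#' Plot a contaminant scan: LRT vs estimated proportion
#'
#' One point per candidate contaminant; a separated point in the upper
#' part of the plot indicates a mixture.
#'
#' @param scan A `contaminant_scan`.
#' @param log Use a log y-axis (default TRUE; zero LRTs are floored at the
#'   smallest positive value shown).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_scan <- function(scan, log = TRUE, ...) {
    y <- scan$lrt
    logarg <- ""
    if (log) {
        floor_y <- if (any(y > 0)) min(y[y > 0]) else 1e-2
        y <- pmax(y, floor_y)
        logarg <- "y"
    }
    graphics::plot(scan$p_hat, y, xlab = "estimated contaminant proportion",
                   ylab = "LRT statistic", log = logarg, pch = 16,
                   col = "grey30", las = 1, xlim = c(0, 1),
                   main = attr(scan, "microbiome_id"), ...)
}
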