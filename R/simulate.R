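# Synthetic-cohort generator: genotype matrices under Hardy-Weinberg
# equilibrium and per-sample SNP allele counts under the read model, with
# planted swaps and mixtures, so the full pipeline is testable without
# external data.
#
# The identity and mixture statistics depend only on genotype frequencies
# and read counts, not on pedigree structure, so genotypes are drawn under
# Hardy-Weinberg at a per-SNP minor-allele frequency rather than from a
# multi-founder pedigree (the founder-diplotype path is exercised with
# hand-built probability fixtures instead).

#' Describe a planted scenario for one microbiome sample
#'
#' @param type `"correct"`, `"swap"`, or `"mixture"`.
#' @param with For `swap`/`mixture`: the genomic id the sample is swapped
#'   with, or the contaminant id.
#' @param p For `mixture`: the true contaminant proportion in \[0, 1\].
#' @return A scenario list usable in [simulate_cohort()].
#' @export
scenario <- function(type = c("correct", "swap", "mixture"), with = NULL,
                     p = NULL) {
    type <- match.arg(type)
    if (type != "correct" && is.null(with)) {
        stop("scenario '", type, "' needs a partner sample id")
    }
    if (type == "mixture") {
        if (is.null(p) || p < 0 || p > 1) stop("mixture needs p in [0, 1]")
    }
    list(type = type, with = with, p = p)
}

#' Simulate a genotype matrix under Hardy-Weinberg equilibrium
#'
#' Each SNP gets a minor-allele frequency drawn uniformly from `maf_range`
#' (or a fixed value if the two endpoints coincide); each sample's dosage
#' is then Binomial(2, maf).
#'
#' @param n_samples,n_snps Cohort dimensions.
#' @param maf_range Minor-allele-frequency range (default c(0.05, 0.5)).
#' @param seed Random seed (mandatory, for reproducibility).
#' @return Integer genotype matrix (samples x SNPs, dosage coding), sample
#'   ids `S01`, `S02`, ... and SNP ids `snp00001`, ..., with the realized
#'   per-SNP frequencies in attribute `maf`.
#' @export
simulate_genotypes <- function(n_samples, n_snps,
                               maf_range = c(0.05, 0.5), seed) {
    if (missing(seed)) stop("seed is required")
    set.seed(seed)
    maf <- if (maf_range[1] == maf_range[2]) rep(maf_range[1], n_snps)
           else stats::runif(n_snps, maf_range[1], maf_range[2])
    geno <- vapply(seq_len(n_snps),
                   function(s) stats::rbinom(n_samples, 2, maf[s]),
                   integer(n_samples))
    geno <- matrix(as.integer(geno), n_samples, n_snps)
    wid <- max(2, nchar(n_samples))
    rownames(geno) <- sprintf(paste0("S%0", wid, "d"), seq_len(n_samples))
    colnames(geno) <- sprintf("snp%05d", seq_len(n_snps))
    attr(geno, "maf") <- maf
    geno
}

#' Simulate host-read allele counts for one microbiome sample
#'
#' Per SNP the total read count is Poisson(`mean_depth`); the minor-read
#' count is Binomial(total, eps + f* (1 - 2 eps)) where f* is the mixture
#' minor-allele frequency implied by the scenario: the sample's own
#' genotype for `correct`, the partner's genotype for `swap`, and
#' (1 - p) self + p contaminant for `mixture`.
#'
#' @param geno Genotype matrix (samples x SNPs, dosage coding).
#' @param sample_id The microbiome sample's label (a row of `geno`).
#' @param scen A [scenario()] (default: correct).
#' @param mean_depth Mean reads per SNP (default 50).
#' @param eps True sequencing error rate (default 0.005).
#' @param seed Random seed (mandatory).
#' @return A `snp_allele_counts` object.
#' @export
simulate_read_counts <- function(geno, sample_id, scen = scenario(),
                                 mean_depth = 50, eps = 0.005, seed) {
    if (missing(seed)) stop("seed is required")
    ids <- c(sample_id, scen$with)
    if (!all(ids %in% rownames(geno))) {
        stop("scenario names sample(s) absent from the genotype matrix")
    }
    set.seed(seed)
    f_self <- geno[sample_id, ] / 2
    fstar <- switch(scen$type,
                    correct = f_self,
                    swap = geno[scen$with, ] / 2,
                    mixture = (1 - scen$p) * f_self +
                        scen$p * geno[scen$with, ] / 2)
    n_snps <- ncol(geno)
    total <- stats::rpois(n_snps, mean_depth)
    q <- eps + fstar * (1 - 2 * eps)
    n_minor <- stats::rbinom(n_snps, total, q)
    snp_allele_counts(colnames(geno), total - n_minor, n_minor, sample_id)
}

#' Simulate allele counts for a whole cohort
#'
#' @param geno Genotype matrix.
#' @param scenarios Named list of [scenario()]s; names are the microbiome
#'   ids to simulate (default: every row of `geno`, all correct).
#' @param mean_depth Mean reads per SNP before the per-sample multiplier.
#' @param eps True sequencing error rate.
#' @param depth_multiplier_range Per-sample depth multiplier drawn
#'   log-uniformly from this range (default c(1, 1), i.e. homogeneous);
#'   widen it to emulate the large sample-to-sample variation in
#'   host-read yield seen in real fecal shotgun data.
#' @param seed Random seed (mandatory).
#' @return Named list of `snp_allele_counts`, plus attribute `truth`: a
#'   data frame with each sample's scenario, source id and true p.
#' @export
simulate_cohort <- function(geno, scenarios = NULL, mean_depth = 50,
                            eps = 0.005, depth_multiplier_range = c(1, 1),
                            seed) {
    if (missing(seed)) stop("seed is required")
    if (is.null(scenarios)) {
        scenarios <- stats::setNames(
            rep(list(scenario("correct")), nrow(geno)), rownames(geno))
    }
    set.seed(seed)
    mult <- exp(stats::runif(length(scenarios),
                             log(depth_multiplier_range[1]),
                             log(depth_multiplier_range[2])))
    sub_seeds <- sample.int(.Machine$integer.max, length(scenarios))
    counts <- vector("list", length(scenarios))
    names(counts) <- names(scenarios)
    for (i in seq_along(scenarios)) {
        counts[[i]] <- simulate_read_counts(
            geno, names(scenarios)[i], scenarios[[i]],
            mean_depth = mean_depth * mult[i], eps = eps,
            seed = sub_seeds[i])
    }
    truth <- data.frame(
        microbiome_id = names(scenarios),
        scenario = vapply(scenarios, `[[`, "", "type"),
        source_id = vapply(scenarios, function(s)
            if (is.null(s$with)) NA_character_ else s$with, ""),
        p_true = vapply(scenarios, function(s)
            if (is.null(s$p)) NA_real_ else s$p, 0),
        stringsAsFactors = FALSE, row.names = NULL)
    attr(counts, "truth") <- truth
    attr(counts, "eps_true") <- eps
    counts
}

#' Write a complete benchmark cohort to disk
#'
#' Emits the exact file formats the command-line interface consumes: a
#' genotype CSV, one allele-count TSV per microbiome sample under
#' `counts/`, and a `truth.json` with the planted scenarios for
#' downstream scoring.
#'
#' @param dir Output directory (created if needed).
#' @param n_samples,n_snps Cohort dimensions (defaults 20 x 2000).
#' @param scenarios Named list of [scenario()]s (default all correct).
#' @param mean_depth,eps,depth_multiplier_range As [simulate_cohort()].
#' @param maf_range As [simulate_genotypes()].
#' @param seed Random seed (mandatory).
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless TRUE.
#' @return Invisibly, a list with the genotype matrix, counts list and
#'   truth data frame.
#' @export
make_benchmark_cohort <- function(dir, n_samples = 20, n_snps = 2000,
                                  scenarios = NULL, mean_depth = 50,
                                  eps = 0.005,
                                  depth_multiplier_range = c(1, 1),
                                  maf_range = c(0.05, 0.5), seed,
                                  overwrite = FALSE) {
    if (missing(seed)) stop("seed is required")
    if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
        stop("directory ", dir, " is not empty; use overwrite = TRUE")
    }
    dir.create(file.path(dir, "counts"), recursive = TRUE,
               showWarnings = FALSE)
    geno <- simulate_genotypes(n_samples, n_snps, maf_range, seed = seed)
    counts <- simulate_cohort(geno, scenarios, mean_depth, eps,
                              depth_multiplier_range, seed = seed + 1L)
    write_genotypes(geno, file.path(dir, "genotypes.csv"))
    for (id in names(counts)) {
        write_allele_counts(counts[[id]],
                            file.path(dir, "counts", paste0(id, ".tsv")))
    }
    truth <- attr(counts, "truth")
    jsonlite::write_json(
        list(eps_true = eps, mean_depth = mean_depth, seed = seed,
             samples = truth),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
    invisible(list(geno = geno, counts = counts, truth = truth))
}
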