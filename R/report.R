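# End-to-end orchestration: distance matrix -> sample classification ->
# contaminant scans -> per-sample verdicts, plus report serialization.

#' Configuration for a full study run
#'
#' All thresholds of the pipeline in one place.
#'
#' @param self_high,match_low,mixture_gray,low_reads_floor,low_quality_dna
#'   See [classify_samples()].
#' @param gap_factor,min_lrt See [detect_contaminant()].
#' @param scan_all Scan every microbiome sample for contaminants, not only
#'   the ones the distance analysis flags. Subtle mixtures can look clean
#'   in the single-sample distance analysis, so this defaults to TRUE for
#'   cohorts of up to `scan_all_max` samples.
#' @param scan_all_max Cohort size above which `scan_all` falls back to
#'   scanning only flagged samples (default 500).
#' @return A list of class `study_config`.
#' @export
study_config <- function(self_high = 0.15, match_low = 0.01,
                         mixture_gray = 0.05, low_reads_floor = 1e5,
                         low_quality_dna = character(),
                         gap_factor = 4, min_lrt = 25,
                         scan_all = TRUE, scan_all_max = 500) {
    out <- list(self_high = self_high, match_low = match_low,
                mixture_gray = mixture_gray,
                low_reads_floor = low_reads_floor,
                low_quality_dna = low_quality_dna,
                gap_factor = gap_factor, min_lrt = min_lrt,
                scan_all = scan_all, scan_all_max = scan_all_max)
    class(out) <- "study_config"
    out
}

#' Run the full mix-up and mixture analysis
#'
#' Computes the distance matrix, classifies every microbiome sample, scans
#' candidate contaminants (all samples by default; at least every sample
#' not labeled `correct`), and merges the results into one verdict per
#' sample. Verdict precedence is swap > mixture > low_reads: a sample
#' called a swap by the distance analysis is never simultaneously reported
#' as a mixture (a pure swap is the p = 1 corner of the mixture model).
#'
#' @param geno Genotype matrix (samples x SNPs, dosage coding).
#' @param counts_list Named list of `snp_allele_counts`.
#' @param config A [study_config()].
#' @return Object of class `study_report`: list with `verdicts` (data
#'   frame), `calls`, `distances`, `scans` (named list), and `config`.
#' @export
run_study <- function(geno, counts_list, config = study_config()) {
    if (is.null(names(counts_list))) {
        names(counts_list) <- vapply(counts_list, attr, "", "sample_id")
    }
    overlap <- intersect(names(counts_list), rownames(geno))
    if (length(overlap) == 0) {
        stop("no sample-id overlap between counts and genotypes")
    }
    m <- distance_matrix(counts_list, geno)
    calls <- classify_samples(m, self_high = config$self_high,
                              match_low = config$match_low,
                              mixture_gray = config$mixture_gray,
                              low_reads_floor = config$low_reads_floor,
                              low_quality_dna = config$low_quality_dna)

    scan_all <- config$scan_all && nrow(calls) <= config$scan_all_max
    to_scan <- calls$microbiome_id[calls$microbiome_id %in% rownames(geno) &
                                   (scan_all | calls$label != "correct")]
    scans <- list()
    detections <- list()
    for (id in to_scan) {
        sc <- tryCatch(scan_contaminants(counts_list[[id]], geno, id),
                       error = function(e) e)
        if (inherits(sc, "error")) {
            warning("scan failed for ", id, ": ", conditionMessage(sc))
            next
        }
        scans[[id]] <- sc
        if (nrow(sc) >= 2) {
            detections[[id]] <- detect_contaminant(
                sc, gap_factor = config$gap_factor, min_lrt = config$min_lrt)
        }
    }

    verdicts <- data.frame(
        microbiome_id = calls$microbiome_id, verdict = NA_character_,
        source_id = NA_character_, p_hat = NA_real_, eps_hat = NA_real_,
        lrt = NA_real_, self_distance = calls$self_distance,
        min_distance = calls$min_distance, total_reads = calls$total_reads,
        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(verdicts))) {
        id <- verdicts$microbiome_id[i]
        det <- detections[[id]]
        flagged <- !is.null(det) && !is.na(det$flagged_contaminant)
        if (calls$label[i] == "swap") {
            verdicts$verdict[i] <- "swap"
            verdicts$source_id[i] <- calls$argmin_id[i]
        } else if (flagged) {
            verdicts$verdict[i] <- "mixture"
            verdicts$source_id[i] <- det$flagged_contaminant
            verdicts$p_hat[i] <- det$p_hat
            verdicts$eps_hat[i] <- det$eps_hat
            verdicts$lrt[i] <- det$lrt
        } else if (calls$label[i] %in%
                   c("correct", "low_reads", "low_quality_dna")) {
            verdicts$verdict[i] <- calls$label[i]
        } else {
            verdicts$verdict[i] <- "unresolved"
        }
    }
    out <- list(verdicts = verdicts, calls = calls, distances = m,
                scans = scans, config = config)
    class(out) <- "study_report"
    out
}

#' @export
print.study_report <- function(x, ...) {
    cat("Study report:", nrow(x$verdicts), "microbiome samples vs",
        ncol(x$distances), "genomic DNA samples\n")
    print(table(verdict = x$verdicts$verdict))
    anom <- x$verdicts[x$verdicts$verdict %in% c("swap", "mixture"), ]
    if (nrow(anom) > 0) {
        cat("\nFlagged samples:\n")
        print(anom[, c("microbiome_id", "verdict", "source_id", "p_hat",
                       "lrt")], row.names = FALSE, digits = 4)
    }
    invisible(x)
}

#' Write a study report to disk
#'
#' Emits `verdicts.csv`, `sample_calls.csv`, `distance_matrix.csv`, one
#' scan CSV per scanned sample under `scans/`, a text `summary.txt`, and
#' (optionally) the distance and LRT overview figures as PNG files.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @param figures Also write PNG figures (default TRUE; skipped with a
#'   warning if no graphics device is available).
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless TRUE.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, figures = TRUE, overwrite = FALSE) {
    if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
        stop("directory ", dir, " is not empty; use overwrite = TRUE")
    }
    dir.create(file.path(dir, "scans"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- character()
    wr <- function(df, name) {
        p <- file.path(dir, name)
        utils::write.csv(df, p, row.names = FALSE, quote = FALSE, na = "NA")
        paths <<- c(paths, p)
    }
    wr(report$verdicts, "verdicts.csv")
    wr(as.data.frame(report$calls), "sample_calls.csv")
    dm <- data.frame(microbiome_id = rownames(report$distances),
                     as.data.frame(unclass(report$distances)),
                     check.names = FALSE)
    wr(dm, "distance_matrix.csv")
    for (id in names(report$scans)) {
        wr(as.data.frame(report$scans[[id]]),
           file.path("scans", paste0(id, "_scan.csv")))
    }

    sp <- file.path(dir, "summary.txt")
    con <- file(sp, "w")
    sink(con); print(report); sink()
    close(con)
    paths <- c(paths, sp)

    if (figures) {
        ok <- tryCatch({
            grDevices::png(file.path(dir, "fig_distance.png"), 900, 700,
                           res = 110)
            plot_distance_summary(report$distances, report$calls)
            grDevices::dev.off()
            if (length(report$scans) > 0) {
                grDevices::png(file.path(dir, "fig_max_lrt.png"), 900, 700,
                               res = 110)
                plot_cohort_lrt(report)
                grDevices::dev.off()
            }
            TRUE
        }, error = function(e) {
            warning("figure output skipped: ", conditionMessage(e))
            FALSE
        })
        if (ok) {
            paths <- c(paths, file.path(dir, "fig_distance.png"))
        }
    }
    invisible(paths)
}

#' Cohort-level plot: maximum scan LRT vs its estimated proportion
#'
#' One point per scanned microbiome sample, at the candidate contaminant
#' with the largest LRT; swaps sit near p = 1, mixtures in between.
#'
#' @param report A `study_report` with non-empty `scans`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_cohort_lrt <- function(report, ...) {
    if (length(report$scans) == 0) stop("report has no scans")
    top <- t(vapply(report$scans, function(sc) {
        i <- which.max(sc$lrt)
        c(sc$p_hat[i], sc$lrt[i])
    }, c(0, 0)))
    v <- report$verdicts$verdict[match(names(report$scans),
                                       report$verdicts$microbiome_id)]
    cols <- c(correct = "slateblue", swap = "darkorchid4",
              mixture = "darkgreen", low_reads = "orchid1",
              low_quality_dna = "salmon", unresolved = "grey40")
    y <- pmax(top[, 2], if (any(top[, 2] > 0)) min(top[top[, 2] > 0, 2])
              else 1e-2)
    graphics::plot(top[, 1], y, log = "y", xlim = c(0, 1), pch = 16,
                   col = cols[v],
                   xlab = "estimated contaminant proportion (top candidate)",
                   ylab = "maximum LRT statistic", las = 1, ...)
    graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                     bg = "white", cex = 0.8)
}

#' Read a verdicts CSV back into a data frame
#'
#' Inverse of the `verdicts.csv` written by [write_report()].
#'
#' @param file Path to `verdicts.csv`.
#' @return Data frame with the same columns and types as
#'   `study_report$verdicts`.
#' @export
read_verdicts <- function(file) {
    df <- utils::read.csv(file, stringsAsFactors = FALSE,
                          colClasses = c(microbiome_id = "character",
                                         verdict = "character",
                                         source_id = "character"))
    df
}
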