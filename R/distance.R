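# Genotype-discordance distance between microbiome samples and genomic DNA
# samples, closest-match ranking, and sample classification.
#
# The distance is the proportion of discordant reads among reads that
# overlap a SNP where the genomic DNA sample is homozygous: a B read at an
# AA SNP or an A read at a BB SNP is discordant. Heterozygous SNPs are
# uninformative for identity (either allele is expected) and are ignored.

#' Discordance distance from a category table
#'
#' d = (n(AA,B) + n(BB,A)) / (n(AA,A) + n(AA,B) + n(BB,A) + n(BB,B)).
#' The heterozygous row is ignored. When no reads fall in a homozygous
#' row the distance is undefined and NA is returned with a warning.
#'
#' @param t A 3 x 2 `category_table`.
#' @return Proportion in \[0, 1\], or NA if undefined.
#' @export
discordance_distance <- function(t) {
    denom <- t["AA", "A"] + t["AA", "B"] + t["BB", "A"] + t["BB", "B"]
    if (denom == 0) {
        warning("no reads at homozygous SNPs; distance undefined")
        return(NA_real_)
    }
    unname((t["AA", "B"] + t["BB", "A"]) / denom)
}

#' Distance matrix between microbiome and genomic DNA samples
#'
#' @param counts_list Named list of `snp_allele_counts`, one per microbiome
#'   sample (names are the microbiome ids).
#' @param geno Genotype matrix (samples x SNPs, dosage coding).
#' @param genomic_ids Genomic samples to compare against (default: all rows
#'   of `geno`).
#' @return Numeric matrix (microbiome rows x genomic columns) of class
#'   `distance_matrix`, with attribute `total_reads`: per-microbiome total
#'   read counts over scored SNPs. Undefined distances are NA.
#' @export
distance_matrix <- function(counts_list, geno,
                            genomic_ids = rownames(geno)) {
    if (length(counts_list) == 0 || length(genomic_ids) == 0) {
        stop("empty sample collection")
    }
    if (is.null(names(counts_list))) {
        names(counts_list) <- vapply(counts_list, attr, "", "sample_id")
    }
    m <- matrix(NA_real_, length(counts_list), length(genomic_ids),
                dimnames = list(names(counts_list), genomic_ids))
    for (i in seq_along(counts_list)) {
        for (j in seq_along(genomic_ids)) {
            tab <- tabulate_single(counts_list[[i]], geno, genomic_ids[j])
            m[i, j] <- suppressWarnings(discordance_distance(tab))
        }
    }
    attr(m, "total_reads") <- vapply(counts_list, total_reads, 0)
    class(m) <- c("distance_matrix", "matrix")
    m
}

#' Classify microbiome samples from the distance matrix
#'
#' Labels, in precedence order:
#' * `correct`: self-distance below `match_low` and self is the closest
#'   genomic sample.
#' * `swap`: self-distance above `self_high` but some other genomic sample
#'   is closer than `match_low`.
#' * `low_quality_dna`: id listed by the caller (DNA quality is known from
#'   external evidence, never inferred from the distances).
#' * `mixture_candidate`: closest distance in the gray zone
#'   \[`match_low`, `self_high`), or self is closest but at distance in
#'   \[`mixture_gray`, `self_high`) — close to nothing, or suspiciously far
#'   from itself.
#' * `low_reads`: fewer scored reads than `low_reads_floor`.
#' * `unresolved`: anything else, including samples without a same-named
#'   genomic column or with no defined distances.
#'
#' @param m A `distance_matrix`.
#' @param self_high Self-distance above which a sample cannot be its own
#'   (default 0.15).
#' @param match_low Distance below which a genomic sample is called a match
#'   (default 0.01).
#' @param mixture_gray Lower edge of the self-distance gray zone for
#'   mixture candidates (default 0.05).
#' @param low_reads_floor Minimum scored reads (default 1e5).
#' @param low_quality_dna Character vector of microbiome ids whose genomic
#'   DNA is known to be of low quality.
#' @return Data frame of class `sample_calls`: one row per microbiome
#'   sample with self/min distances, closest and second-closest genomic
#'   ids, total reads, and label.
#' @export
classify_samples <- function(m, self_high = 0.15, match_low = 0.01,
                             mixture_gray = 0.05, low_reads_floor = 1e5,
                             low_quality_dna = character()) {
    reads <- attr(m, "total_reads")
    if (is.null(reads)) reads <- rep(NA_real_, nrow(m))
    out <- data.frame(microbiome_id = rownames(m),
                      self_distance = NA_real_, min_distance = NA_real_,
                      argmin_id = NA_character_,
                      second_argmin_id = NA_character_,
                      total_reads = as.numeric(reads),
                      label = "unresolved", stringsAsFactors = FALSE)
    for (i in seq_len(nrow(m))) {
        id <- rownames(m)[i]
        row <- m[i, ]
        def <- which(!is.na(row))
        if (length(def) == 0) next
        ord <- def[order(row[def])]  # stable: ties by column order
        if (length(def) > 1 && row[ord[1]] == row[ord[2]]) {
            warning("tie for closest genomic sample to ", id,
                    "; broken by column order")
        }
        out$min_distance[i] <- row[ord[1]]
        out$argmin_id[i] <- colnames(m)[ord[1]]
        if (length(ord) > 1) out$second_argmin_id[i] <- colnames(m)[ord[2]]
        has_self <- id %in% colnames(m) && !is.na(row[id])
        if (has_self) out$self_distance[i] <- row[id]

        d_self <- out$self_distance[i]
        d_min <- out$min_distance[i]
        amin <- out$argmin_id[i]
        label <-
            if (!has_self) "unresolved"
            else if (d_self < match_low && amin == id) "correct"
            else if (d_self > self_high && d_min < match_low && amin != id)
                "swap"
            else if (id %in% low_quality_dna) "low_quality_dna"
            else if ((d_min >= match_low && d_min < self_high) ||
                     (amin == id && d_self >= mixture_gray &&
                      d_self < self_high)) "mixture_candidate"
            else if (!is.na(reads[i]) && reads[i] < low_reads_floor)
                "low_reads"
            else "unresolved"
        out$label[i] <- label
    }
    class(out) <- c("sample_calls", "data.frame")
    out
}

#' Ranked genomic matches for one microbiome sample
#'
#' @param m A `distance_matrix`.
#' @param microbiome_id Row of `m`.
#' @return Data frame `genomic_id`, `distance`, `rank`, sorted by ascending
#'   distance; ties keep column order. Undefined distances are placed last
#'   with rank NA.
#' @export
match_table <- function(m, microbiome_id) {
    if (!microbiome_id %in% rownames(m)) {
        stop("unknown microbiome sample: ", microbiome_id)
    }
    row <- m[microbiome_id, ]
    ord <- order(row, na.last = TRUE)  # stable sort, ties by column index
    d <- row[ord]
    data.frame(genomic_id = colnames(m)[ord], distance = as.numeric(d),
               rank = ifelse(is.na(d), NA_integer_, seq_along(d)),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Scatterplot of minimum distance vs distance to self
#'
#' One point per microbiome sample, colored by its classification label.
#'
#' @param m A `distance_matrix`.
#' @param calls Optional `sample_calls` from [classify_samples()]; computed
#'   with defaults if omitted.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_distance_summary <- function(m, calls = NULL, ...) {
    if (is.null(calls)) calls <- classify_samples(m)
    cols <- c(correct = "slateblue", swap = "darkorchid4",
              mixture_candidate = "darkgreen", low_reads = "orchid1",
              low_quality_dna = "salmon", unresolved = "grey40")
    graphics::plot(calls$self_distance, calls$min_distance,
                   xlab = "distance to self", ylab = "minimum distance",
                   col = cols[calls$label], pch = 16, xlim = c(0, 1),
                   las = 1, ...)
    graphics::abline(0, 1, col = "grey80", lty = 2)
    graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                     bg = "white", cex = 0.8)
}

#' Per-sample plot of distances to every genomic sample
#'
#' @param m A `distance_matrix`.
#' @param microbiome_id Row of `m`; the same-named genomic sample is
#'   highlighted.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_sample_distances <- function(m, microbiome_id, ...) {
    row <- m[microbiome_id, ]
    graphics::plot(seq_along(row), row, xlab = "genomic sample index",
                   ylab = "distance", main = microbiome_id, pch = 16,
                   col = "grey30", las = 1, ...)
    self <- match(microbiome_id, colnames(m))
    if (!is.na(self)) {
        graphics::points(self, row[self], col = "deeppink3", pch = 16,
                         cex = 1.4)
    }
}
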