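# 5'-isomiR application helpers: nomenclature, RPM normalisation, the
# cumulative-expression filter, AGO2 weighting and target-change
# classification around the pairwise z-test.

#' Parse 5'-isomiR identifiers
#'
#' The standard 5'-isomiR nomenclature appends "|shift" to the miRNA name,
#' where the signed integer is the offset of the isoform's 5' end from the
#' canonical one in 5'-3' direction ("hsa-miR-192-5p|+1" lacks the first
#' nucleotide; shift 0 is the canonical molecule).  Only 5' shifts are
#' encoded; a second "|" field (3'-end shift) is rejected.
#'
#' @param text character vector of identifiers of the form `name|shift`.
#' @return a data.frame with columns `mirna` (character) and `shift`
#'   (integer).
#' @examples
#' parseIsomir(c("hsa-miR-192-5p|+1", "hsa-miR-93-5p|0"))
#' @export
parseIsomir <- function(text) {
    text <- as.character(text)
    m <- regmatches(text, regexec("^(.+)\\|([+-]?[0-9]+)$", text))
    bad <- lengths(m) != 3L | grepl("\\|.*\\|", text)
    if (any(bad))
        stop("malformed isomiR identifier(s): ",
             paste(text[bad], collapse = ", "),
             " (expected 'name|signed-integer')")
    data.frame(mirna = vapply(m, `[`, "", 2L),
               shift = as.integer(vapply(m, `[`, "", 3L)))
}

#' @rdname parseIsomir
#' @param mirna character vector of miRNA names.
#' @param shift integer vector of 5' shifts.
#' @return `formatIsomir` returns the canonical text form, with an explicit
#'   sign for nonzero shifts and `"|0"` for the canonical isoform;
#'   `formatIsomir(parseIsomir(x))` round-trips every canonical identifier.
#' @examples
#' formatIsomir("hsa-miR-192-5p", 1)    # "hsa-miR-192-5p|+1"
#' @export
formatIsomir <- function(mirna, shift) {
    if (is.data.frame(mirna)) {
        shift <- mirna$shift
        mirna <- mirna$mirna
    }
    shift <- as.integer(shift)
    sprintf("%s|%s", mirna,
            ifelse(shift > 0L, paste0("+", shift), as.character(shift)))
}

#' Reads-per-million normalisation
#'
#' Divides each count by its sample's library size and scales to one million
#' mapped reads, so each value is the share (in ppm) of the sample's reads
#' assigned to that molecule.
#'
#' @param counts nonnegative count matrix, molecules in rows, samples in
#'   columns.
#' @param librarySizes per-sample library sizes; defaults to the column sums
#'   of `counts`.  May exceed the column sums when rows have been filtered
#'   out upstream.
#' @return matrix of RPM values, same dimensions as `counts`.
#' @examples
#' rpmNormalize(matrix(c(5, 5), 2, 1), librarySizes = 10)  # 5e5 each
#' @export
rpmNormalize <- function(counts, librarySizes = NULL) {
    counts <- as.matrix(counts)
    if (any(counts < 0))
        stop("counts must be nonnegative")
    if (is.null(librarySizes))
        librarySizes <- colSums(counts)
    if (length(librarySizes) != ncol(counts))
        stop("one library size per sample is required")
    if (any(librarySizes <= 0))
        stop("zero or negative library size for sample(s): ",
             paste(colnames(counts)[librarySizes <= 0], collapse = ", "))
    sweep(counts, 2L, librarySizes, "/") * 1e6
}

#' Minimal highly-expressed set covering a read-share fraction
#'
#' Ranks molecules by their total read share pooled across all samples
#' (descending, ties broken by identifier) and returns the shortest prefix
#' whose cumulative share reaches `fraction`.  miRNA sequencing reads are
#' dominated by a few dozen isomiRs, so a 95% cut typically retains a small
#' fraction of the annotated molecules.
#'
#' @param x matrix of counts or RPM values, molecules in rows (rownames
#'   required).
#' @param fraction cumulative read-share target in (0, 1]; at `fraction = 1`
#'   all molecules with nonzero reads are returned.
#' @return character vector of molecule identifiers, in decreasing
#'   read-share order.
#' @examples
#' m <- matrix(c(90, 6, 4), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
#' highlyExpressedSet(m, 0.95)   # A, B
#' @export
highlyExpressedSet <- function(x, fraction = 0.95) {
    x <- as.matrix(x)
    if (nrow(x) == 0L)
        stop("empty matrix: no molecules to rank")
    if (is.null(rownames(x)))
        stop("rownames (molecule identifiers) are required")
    if (fraction <= 0 || fraction > 1)
        stop("fraction must lie in (0, 1]")
    share <- rowSums(x) / sum(x)
    ord <- order(-share, rownames(x))
    cum <- cumsum(share[ord])
    nkeep <- which(cum >= fraction - 1e-12)[1L]
    keep <- ord[seq_len(nkeep)]
    keep <- keep[share[keep] > 0]
    rownames(x)[keep]
}

#' AGO2-loading weight for isomiR expression
#'
#' Multiplies an isomiR's per-sample RPM values by the sample's AGO2 (the
#' catalytic RISC Argonaute) expression as a proxy for the RISC-loaded
#' abundance, then log2-transforms with a pseudocount for downstream
#' correlation analysis.  The proportionality constant is irrelevant:
#' correlations with any target are computed within one isomiR, and for rank
#' correlations a constant AGO2 vector is an exact no-op.
#'
#' @param rpm per-sample RPM values of one isomiR (vector) or of several
#'   (matrix with samples in columns).
#' @param ago2 per-sample AGO2 expression on the linear scale, same samples.
#' @param log2transform apply `log2(x + pseudocount)` (default `TRUE`).
#' @param pseudocount added before the log (default 1).
#' @return weighted (and by default log2-transformed) expression values with
#'   the shape of `rpm`.
#' @examples
#' ago2Weight(c(1, 2), c(3, 4), log2transform = FALSE)  # 3 8
#' @export
ago2Weight <- function(rpm, ago2, log2transform = TRUE, pseudocount = 1) {
    if (any(ago2 < 0) || any(rpm < 0))
        stop("RPM and AGO2 values must be nonnegative")
    if (is.matrix(rpm)) {
        if (length(ago2) != ncol(rpm))
            stop("AGO2 vector must have one value per sample (",
                 ncol(rpm), " columns, got ", length(ago2), ")")
        w <- sweep(rpm, 2L, ago2, "*")
    } else {
        if (length(ago2) != length(rpm))
            stop("AGO2 vector must have one value per sample (",
                 length(rpm), " values, got ", length(ago2), ")")
        w <- rpm * ago2
    }
    if (log2transform) log2(w + pseudocount) else w
}

#' Keep the pairs anticorrelated below a threshold in one group
#'
#' Filters a pairwise result table down to the interactions whose
#' correlation in the chosen group is strictly below the threshold
#' (default -0.3, the conventional cut for miRNA-target anticorrelation),
#' returning them as a network.  A correlation exactly at the threshold is
#' excluded.
#'
#' @param results a [PairTestResults-class].
#' @param group one of the two group labels of the run.
#' @param threshold correlation cut (default -0.3; strict `<`).
#' @return an [InteractionNetwork-class] of the retained pairs (may be
#'   empty).
#' @export
buildCorrelationNetwork <- function(results, group, threshold = -0.3) {
    md <- metadata(results)
    if (!group %in% c(md$groupA, md$groupB))
        stop("unknown group label '", group, "'; run groups are '",
             md$groupA, "' and '", md$groupB, "'")
    r <- results[[paste0("r_", group)]]
    keep <- which(r < threshold)
    new("InteractionNetwork",
        source = as.character(results$source[keep]),
        target = as.character(results$target[keep]))
}

#' Classify significant jumps over the anticorrelation threshold
#'
#' Labels each tested (source, target) pair by how its correlation moved
#' relative to the threshold (default -0.3) between the two groups, counting
#' only statistically significant changes (BH-adjusted p < alpha):
#' `lost` -- anticorrelated in group A (r below the threshold) but not in
#' group B; `gained` -- the reverse; everything else `unchanged`.  The three
#' statuses partition the result set.
#'
#' @param results a [PairTestResults-class] (group A in the role of
#'   "Normal").
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param threshold correlation cut (default -0.3; strict `<` below it).
#' @return a [S4Vectors::DataFrame] with columns `source`, `target`,
#'   `r_<groupA>`, `r_<groupB>`, `adjusted_pvalue`, `status` (factor
#'   lost/gained/unchanged).
#' @export
classifyTargetChanges <- function(results, alpha = 0.05, threshold = -0.3) {
    md <- metadata(results)
    padj <- results$adjusted_pvalue
    if (is.null(padj) || anyNA(padj))
        stop("results must carry adjusted p-values")
    rA <- results[[paste0("r_", md$groupA)]]
    rB <- results[[paste0("r_", md$groupB)]]
    sig <- padj < alpha
    status <- rep("unchanged", nrow(results))
    status[sig & rA < threshold & rB >= threshold] <- "lost"
    status[sig & rB < threshold & rA >= threshold] <- "gained"
    out <- DataFrame(
        source = results$source, target = results$target,
        rA = rA, rB = rB, adjusted_pvalue = padj,
        status = factor(status, levels = c("lost", "gained", "unchanged")))
    colnames(out)[3:4] <- paste0("r_", c(md$groupA, md$groupB))
    metadata(out) <- list(alpha = alpha, threshold = threshold,
                          groupA = md$groupA, groupB = md$groupB)
    out
}

#' Per-source summary of lost and gained targets
#'
#' Tabulates, for every source molecule, the number of significantly lost
#' and gained anticorrelated targets, the number of targets in the group A
#' ("Normal") state (correlation below the threshold), and the lost/gained
#' counts normalised by that target number.
#'
#' @param changes output of [classifyTargetChanges()].
#' @return a data.frame with columns `source`, `lost`, `gained`,
#'   `n_targets_groupA`, `lost_norm`, `gained_norm`.
#' @export
summariseTargetChanges <- function(changes) {
    md <- metadata(changes)
    src <- factor(changes$source, levels = unique(changes$source))
    rA <- changes[[paste0("r_", md$groupA)]]
    lost <- as.integer(tapply(changes$status == "lost", src, sum))
    gained <- as.integer(tapply(changes$status == "gained", src, sum))
    nA <- as.integer(tapply(rA < md$threshold, src, sum))
    data.frame(source = levels(src), lost = lost, gained = gained,
               n_targets_groupA = nA,
               lost_norm = ifelse(nA > 0, lost / nA, NA_real_),
               gained_norm = ifelse(nA > 0, gained / nA, NA_real_))
}
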