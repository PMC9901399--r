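# Readers, writers, the run configuration and the mode dispatcher behind the
# command-line entry point (exec/dcoex).

#' Read a molecules-by-samples expression table
#'
#' Tab-separated text: a header row of sample identifiers, first column
#' molecule identifiers, decimal point ".".  Duplicate identifiers, missing
#' cells and non-numeric cells are hard errors reported with coordinates.
#'
#' @param path path to the file.
#' @return a numeric matrix with molecule rownames and sample colnames.
#' @export
readExpressionMatrix <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            quote = "", comment.char = "")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate molecule identifier(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    samples <- colnames(df)[-1L]
    if (anyDuplicated(samples))
        stop("duplicate sample identifier(s): ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    vals <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
    bad <- which(is.na(num) | vals == "", arr.ind = TRUE)
    if (nrow(bad)) {
        i <- bad[1L, 1L]; j <- bad[1L, 2L]
        stop(sprintf(
            "missing or non-numeric cell at molecule '%s', sample '%s' (value '%s')",
            ids[i], samples[j], vals[i, j]))
    }
    dimnames(num) <- list(ids, samples)
    num
}

#' Read a sample-to-group assignment table
#'
#' Tab-separated with header `sample<TAB>group`; every sample on one line,
#' exactly two distinct group labels overall.
#'
#' @param path path to the file.
#' @return a named character vector, names = sample identifiers.
#' @export
readGroupAssignment <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            quote = "", comment.char = "")
    if (ncol(df) < 2L)
        stop("group file needs two columns: sample, group")
    if (anyDuplicated(df[[1L]]))
        stop("duplicate sample(s) in group file: ",
             paste(unique(df[[1L]][duplicated(df[[1L]])]), collapse = ", "))
    stats::setNames(df[[2L]], df[[1L]])
}

#' Read a (source, target) interaction table
#'
#' Tab-separated with header `source<TAB>target`.
#'
#' @param path path to the file.
#' @return an [InteractionNetwork-class].
#' @export
readInteractionNetwork <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            quote = "", comment.char = "")
    if (ncol(df) < 2L)
        stop("interaction file needs two columns: source, target")
    InteractionNetwork(df[[1L]], df[[2L]])
}

.CONFIG_KEYS <- c("data_path", "description_path", "interaction_path",
                  "output_dir", "correlation", "score_kinds", "alpha",
                  "permutations", "seed", "workers")

#' Read a run configuration file
#'
#' A flat text file of `key = value` lines (one per line, `#` comments and
#' blank lines allowed).  Recognised keys: `data_path`, `description_path`,
#' `interaction_path` (optional; absent means exhaustive mode),
#' `output_dir`, `correlation` (`pearson`/`spearman`), `score_kinds`
#' (comma-separated among mean/median/quantile), `alpha`, `permutations`
#' (integer or `auto`), `seed`, `workers`.  Unknown keys are errors.
#'
#' @param path path to the file.
#' @return a named list with all keys present (defaults filled in).
#' @export
readRunConfig <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
    if (any(lengths(kv) != 3L))
        stop("malformed config line(s): ",
             paste(lines[lengths(kv) != 3L], collapse = "; "))
    keys <- vapply(kv, `[`, "", 2L)
    vals <- trimws(vapply(kv, `[`, "", 3L))
    unknown <- setdiff(keys, .CONFIG_KEYS)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    if (anyDuplicated(keys))
        stop("duplicated config key(s): ",
             paste(unique(keys[duplicated(keys)]), collapse = ", "))
    cfg <- list(data_path = NULL, description_path = NULL,
                interaction_path = NULL, output_dir = ".",
                correlation = "spearman", score_kinds = "mean",
                alpha = 0.05, permutations = "auto", seed = 1L,
                workers = 1L)
    cfg[keys] <- as.list(vals)
    for (k in c("data_path", "description_path"))
        if (is.null(cfg[[k]]))
            stop("config key '", k, "' is required")
    cfg$alpha <- as.numeric(cfg$alpha)
    if (!is.finite(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
        stop("alpha must lie in (0, 1)")
    if (!identical(cfg$permutations, "auto")) {
        cfg$permutations <- as.integer(cfg$permutations)
        if (is.na(cfg$permutations) || cfg$permutations < 1L)
            stop("permutations must be a positive integer or 'auto'")
    }
    cfg$seed <- as.integer(cfg$seed)
    cfg$workers <- as.integer(cfg$workers)
    cfg$correlation <- match.arg(cfg$correlation, c("spearman", "pearson"))
    cfg$score_kinds <- trimws(strsplit(cfg$score_kinds, ",")[[1L]])
    cfg
}

#' Write a pairwise result table
#'
#' Tab-separated, columns `source`, `target`, `r_<groupA>`, `r_<groupB>`,
#' `statistic`, `pvalue`, `adjusted_pvalue`, rows in network order.
#'
#' @param results a [PairTestResults-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePairResults <- function(results, path) {
    utils::write.table(as.data.frame(results), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a source-aggregation table
#'
#' Tab-separated, columns `source`, `n_G`, `s_G`, `hypergeom_pvalue`,
#' `hypergeom_adjusted`, `score_kind`, `score_value`, `score_pvalue`,
#' `score_adjusted`.
#'
#' @param aggregates a [SourceAggregates-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSourceAggregates <- function(aggregates, path) {
    utils::write.table(as.data.frame(aggregates), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

.MODES <- c("network.ztest", "exhaustive.ztest",
            "network.hypergeom", "exhaustive.hypergeom",
            "network.zscore", "exhaustive.zscore")

#' Run one usage mode end to end
#'
#' Dispatches one of the six usage modes -- pairwise z-test, hypergeometric
#' aggregation, or z-score aggregation, each over a predefined network or
#' exhaustively over all molecule pairs -- from a configuration (a file path
#' or the list returned by [readRunConfig()]), writes the result table(s)
#' into `output_dir` and a run log recording R (hypothesis count), B, alpha,
#' seed, correlation kind, group sizes and wall time.  Outputs are
#' byte-identical across repeated runs with the same config and seed,
#' independent of `workers` (the engine is deterministic and single-threaded;
#' the key is accepted for interface compatibility).
#'
#' @param mode one of `network.ztest`, `exhaustive.ztest`,
#'   `network.hypergeom`, `exhaustive.hypergeom`, `network.zscore`,
#'   `exhaustive.zscore`.
#' @param config a config file path or a config list.
#' @param seed,permutations,alpha optional overrides of the config values.
#' @return named character vector of written file paths, invisibly.
#' @export
runMode <- function(mode, config, seed = NULL, permutations = NULL,
                    alpha = NULL) {
    mode <- match.arg(mode, .MODES)
    if (is.character(config))
        config <- readRunConfig(config)
    if (!is.null(seed)) config$seed <- as.integer(seed)
    if (!is.null(permutations)) config$permutations <- permutations
    if (!is.null(alpha)) config$alpha <- as.numeric(alpha)
    t0 <- proc.time()[["elapsed"]]

    exhaustive <- startsWith(mode, "exhaustive")
    if (!exhaustive && is.null(config$interaction_path))
        stop("network.* modes require 'interaction_path' in the config")
    if (exhaustive && !is.null(config$interaction_path))
        stop("exhaustive.* modes must not set 'interaction_path'")

    exprs <- readExpressionMatrix(config$data_path)
    groups <- readGroupAssignment(config$description_path)
    ce <- CoexExperiment(exprs, groups)
    analysis <- sub("^[a-z]+\\.", "", mode)
    if (analysis == "ztest") {
        network <- if (exhaustive) exhaustiveNetwork(ce) else
            readInteractionNetwork(config$interaction_path)
        R <- length(network)
    } else if (exhaustive) {
        network <- NULL
        R <- nrow(ce) * (nrow(ce) - 1L)   # every molecule vs all others
    } else {
        network <- readInteractionNetwork(config$interaction_path)
        R <- length(network)
    }
    B <- if (identical(config$permutations, "auto"))
        minPermutations(R, config$alpha) else config$permutations

    if (!dir.exists(config$output_dir))
        dir.create(config$output_dir, recursive = TRUE)
    outfile <- file.path(config$output_dir, paste0(mode, "_results.tsv"))
    if (analysis == "ztest") {
        res <- runZtest(ce, network, kind = config$correlation,
                        pvalueKind = "analytic", alpha = config$alpha)
        writePairResults(res, outfile)
    } else {
        plan <- PermutationPlan(
            nHypotheses = max(1L, R), alpha = config$alpha,
            nPermutations = B, seed = config$seed)
        agg <- runAggregation(
            ce, network, kind = config$correlation, alpha = config$alpha,
            scoreKinds = if (analysis == "zscore") config$score_kinds
                         else character(0),
            plan = plan)
        writeSourceAggregates(agg, outfile)
    }
    sizes <- groupSizes(ce)
    logfile <- file.path(config$output_dir, paste0(mode, "_run.log"))
    writeLines(c(
        sprintf("mode\t%s", mode),
        sprintf("correlation\t%s", config$correlation),
        sprintf("hypotheses_R\t%d", R),
        sprintf("permutations_B\t%d", B),
        sprintf("alpha\t%g", config$alpha),
        sprintf("seed\t%d", config$seed),
        sprintf("group_%s_K\t%d", names(sizes)[1L], sizes[1L]),
        sprintf("group_%s_L\t%d", names(sizes)[2L], sizes[2L]),
        sprintf("wall_time_s\t%.3f", proc.time()[["elapsed"]] - t0)),
        logfile)
    invisible(c(results = outfile, log = logfile))
}
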