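# CSV dialects and report generation.  All tabular files are plain CSV with
# a block of '#'-prefixed key: value metadata lines (provenance: generator
# version, parameters, seed) before the header.  Numbers are written with 17
# significant digits so that write -> read round-trips are value-exact.

.fmtNum <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
}

.writeCSVWithMeta <- function(df, path, meta = list()) {
    meta <- c(list(generator = paste0("NTRkinetics ",
                                      as.character(packageVersion("NTRkinetics")))),
              meta)
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(meta))
        writeLines(sprintf("# %s: %s", nm,
                           paste(format(meta[[nm]], digits = 17),
                                 collapse = " ")), con)
    isNum <- vapply(df, is.numeric, logical(1))
    df[isNum] <- lapply(df[isNum], .fmtNum)
    writeLines(paste(names(df), collapse = ","), con)
    writeLines(do.call(paste, c(df, sep = ",")), con)
    invisible(path)
}

.readCSVWithMeta <- function(path) {
    lines <- readLines(path)
    isMeta <- grepl("^#", lines)
    metaLines <- lines[isMeta]
    meta <- list()
    for (ln in metaLines) {
        kv <- sub("^#\\s*", "", ln)
        key <- sub(":.*$", "", kv)
        meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
    }
    body <- lines[!isMeta]
    if (!length(body)) stop("no data rows in ", path, call. = FALSE)
    df <- read.table(text = body, header = TRUE, sep = ",",
                     stringsAsFactors = FALSE)
    # all quantities in these dialects are physically continuous
    df[] <- lapply(df, function(x) if (is.integer(x)) as.numeric(x) else x)
    attr(df, "meta") <- meta
    df
}

#' Write steady-state datasets as CSV
#'
#' Columns: dataset_id, varied_substrate, conc_uM, cosubstrate_uM,
#' inhibitor_uM, enzyme_nM, rate_per_s, preceded by '#'-prefixed provenance
#' metadata.
#'
#' @param datasets list of [SteadyStateDataset-class] (or a single one)
#' @param path output file
#' @param meta named list of extra provenance entries (e.g. seed, parameters)
#' @return the path, invisibly
#' @export
writeRatesCSV <- function(datasets, path, meta = list()) {
    if (is(datasets, "SteadyStateDataset")) datasets <- list(datasets)
    rows <- lapply(datasets, function(d)
        data.frame(dataset_id = d@id, varied_substrate = d@variedSubstrate,
                   conc_uM = d@conc, cosubstrate_uM = d@cosubstrate,
                   inhibitor_uM = d@inhibitor, enzyme_nM = d@enzymeConc,
                   rate_per_s = d@rates))
    .writeCSVWithMeta(do.call(rbind, rows), path, meta)
}

#' Read steady-state datasets from CSV
#'
#' Inverse of [writeRatesCSV()]; rows are grouped by dataset_id.  Schema
#' violations are reported with the offending column.
#'
#' @param path input file
#' @return list of [SteadyStateDataset-class]; attribute \code{"meta"} holds
#'   the metadata block
#' @export
readRatesCSV <- function(path) {
    df <- .readCSVWithMeta(path)
    need <- c("dataset_id", "varied_substrate", "conc_uM", "cosubstrate_uM",
              "inhibitor_uM", "enzyme_nM", "rate_per_s")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("rates CSV is missing column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    out <- lapply(split(df, df$dataset_id), function(g)
        steadyStateDataset(conc = g$conc_uM, rates = g$rate_per_s,
                           variedSubstrate = g$varied_substrate[1],
                           cosubstrate = g$cosubstrate_uM[1],
                           inhibitor = g$inhibitor_uM[1],
                           enzymeConc = g$enzyme_nM[1],
                           id = g$dataset_id[1]))
    out <- out[order(names(out))]
    attr(out, "meta") <- attr(df, "meta")
    out
}

#' Write a stopped-flow trace as CSV
#'
#' Columns time_s, absorbance; metadata keys wavelength_nm, pathlength_cm,
#' dead_time_s (plus any extras such as substrate_uM).
#'
#' @param trace an [AbsorbanceTrace-class]
#' @param path output file
#' @param meta named list of extra metadata (e.g. \code{substrate_uM})
#' @export
writeTraceCSV <- function(trace, path, meta = list()) {
    stopifnot(is(trace, "AbsorbanceTrace"))
    meta <- c(list(wavelength_nm = trace@wavelength,
                   pathlength_cm = trace@pathlength,
                   dead_time_s = trace@deadTime), meta)
    .writeCSVWithMeta(data.frame(time_s = trace@time,
                                 absorbance = trace@absorbance), path, meta)
}

#' Read a stopped-flow trace from CSV
#' @param path input file
#' @return an [AbsorbanceTrace-class]; attribute \code{"meta"} holds the
#'   metadata block (e.g. substrate_uM)
#' @export
readTraceCSV <- function(path) {
    df <- .readCSVWithMeta(path)
    if (!all(c("time_s", "absorbance") %in% names(df)))
        stop("trace CSV needs columns time_s, absorbance", call. = FALSE)
    meta <- attr(df, "meta")
    num <- function(key, default) {
        if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else default
    }
    tr <- absorbanceTrace(df$time_s, df$absorbance,
                          wavelength = num("wavelength_nm", NA_real_),
                          pathlength = num("pathlength_cm", 1),
                          deadTime = num("dead_time_s", 0))
    attr(tr, "meta") <- meta
    tr
}

#' Write a kobs table as CSV
#' @param S substrate concentrations, uM
#' @param kobs observed rate constants, 1/s
#' @param se standard errors, 1/s (optional)
#' @param path output file
#' @param meta extra metadata entries
#' @export
writeKobsCSV <- function(S, kobs, se = NA_real_, path, meta = list()) {
    .writeCSVWithMeta(data.frame(substrate_uM = S, kobs_per_s = kobs,
                                 se_per_s = se), path, meta)
}

#' Read a kobs table from CSV
#' @param path input file
#' @return data.frame with substrate_uM, kobs_per_s, se_per_s
#' @export
readKobsCSV <- function(path) {
    df <- .readCSVWithMeta(path)
    if (!all(c("substrate_uM", "kobs_per_s") %in% names(df)))
        stop("kobs CSV needs columns substrate_uM, kobs_per_s",
             call. = FALSE)
    df
}

#' Write a progress curve as CSV
#' @param pc a [ProgressCurve-class]
#' @param path output file
#' @param meta extra metadata entries
#' @export
writeProgressCSV <- function(pc, path, meta = list()) {
    stopifnot(is(pc, "ProgressCurve"))
    df <- data.frame(time_s = pc@time, pc@concentrations,
                     check.names = FALSE)
    .writeCSVWithMeta(df, path, meta)
}

#' Tabular fit report
#'
#' Parameter table in the conventional layout (parameter, estimate, SE, t,
#' P) with model-level statistics (n, p, RSS, AIC, AICc) and all quality
#' flags appended, mirroring how commercial regression reports print their
#' results.
#'
#' @param fit a [FitResult-class]
#' @return data.frame
#' @export
fitReport <- function(fit) {
    stopifnot(is(fit, "FitResult"))
    tab <- fit@coefficients
    tab$model <- fit@model
    tab[, c("model", "parameter", "estimate", "se", "t", "p")]
}

#' Write a fit report (CSV table plus human-readable text)
#'
#' Writes \code{<path>} as CSV and \code{<path>.txt} with the printed
#' summary; warnings and flags always appear in both.
#'
#' @param fit a [FitResult-class]
#' @param path output CSV path
#' @param meta extra metadata entries
#' @return the CSV path, invisibly
#' @export
writeFitReport <- function(fit, path, meta = list()) {
    tab <- fitReport(fit)
    meta <- c(meta, list(model = fit@model, n = fit@n, p = fit@p,
                         rss = fit@rss, aic = fit@aic, aicc = fit@aicc))
    if (length(fit@flags)) meta$flags <- paste(fit@flags, collapse = "; ")
    .writeCSVWithMeta(tab, path, meta)
    txt <- c(utils::capture.output(show(fit)),
             if (length(fit@flags))
                 paste("WARNING:", fit@flags))
    writeLines(txt, paste0(path, ".txt"))
    invisible(path)
}

#' Write a model-comparison report
#'
#' AIC/AICc table across the fitted inhibition variants with the delta-AICc
#' column, the selected model and the selection rule.
#'
#' @param comparison a [ModelComparison-class]
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writeComparisonReport <- function(comparison, path) {
    stopifnot(is(comparison, "ModelComparison"))
    tab <- comparison@table
    tab$selected <- tab$model == comparison@selected
    .writeCSVWithMeta(tab, path,
                      list(selected = comparison@selected,
                           rule = comparison@rule))
    invisible(path)
}

#' Generate a design and optionally write it out
#'
#' One-call driver for the simulate step of the pipeline: generates the
#' steady-state datasets of a design and, when \code{path} is given, writes
#' them with full provenance (parameters and seed) to CSV.
#'
#' @param params a [KineticParameters-class]
#' @param design an [ExperimentDesign-class]
#' @param path optional output CSV
#' @return list of [SteadyStateDataset-class], invisibly when writing
#' @export
simulateExperiment <- function(params, design, path = NULL) {
    datasets <- generateSteadyState(params, design)
    if (!is.null(path)) {
        meta <- list(kcat = params@kcat, KmA = params@KmA, KmB = params@KmB,
                     KiA = params@KiA, KiB = params@KiB,
                     noise_sd = design@noiseSd, seed = design@seed)
        writeRatesCSV(datasets, path, meta)
        return(invisible(datasets))
    }
    datasets
}

#' Parameter-recovery experiment
#'
#' Generate -> fit -> compare-to-truth over seeded replicates: reports
#' per-parameter bias, RMSE and 95\% Wald confidence-interval coverage.  The
#' core guarantee of the synthetic-data module (noiseless generation
#' followed by the matching fit is the identity on parameters) corresponds
#' to \code{nrep = 1, noiseSd = 0}, where bias is 0 to optimizer tolerance.
#'
#' @param params generating [KineticParameters-class]
#' @param design an [ExperimentDesign-class] of kind "two_sided_inhibition" (its
#'   \code{noiseSd} is used for every replicate)
#' @param model inhibition variant fitted to each replicate
#' @param nrep number of replicates
#' @param seed base seed; replicate r uses seed + r - 1
#' @return data.frame: parameter, truth, meanEstimate, bias, rmse, coverage
#' @export
recoverParameters <- function(params, design, model = "mixed", nrep = 1L,
                              seed = 1L) {
    truth <- c(kcat = params@kcat, KmA = params@KmA, KmB = params@KmB,
               KiA = params@KiA, KiB = params@KiB)[.modelParams(model)]
    est <- matrix(NA_real_, nrep, length(truth),
                  dimnames = list(NULL, names(truth)))
    cover <- matrix(NA, nrep, length(truth),
                    dimnames = list(NULL, names(truth)))
    for (r in seq_len(nrep)) {
        d <- design
        d@seed <- as.integer(seed + r - 1L)
        fit <- fitGlobalInhibition(generateSteadyState(params, d), model)
        cf <- fit@coefficients
        est[r, cf$parameter] <- cf$estimate
        half <- qt(0.975, fit@n - fit@p) * cf$se
        cover[r, cf$parameter] <- abs(cf$estimate - truth[cf$parameter]) <=
            half
    }
    data.frame(parameter = names(truth), truth = unname(truth),
               meanEstimate = colMeans(est),
               bias = colMeans(est) - unname(truth),
               rmse = sqrt(colMeans(sweep(est, 2, truth)^2)),
               coverage = colMeans(cover), row.names = NULL)
}
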