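#' Run a reference-design experiment end to end
#'
#' Orchestrates the package's experiment recipes from one declarative config
#' and writes all results (predictions CSV, evaluation JSON, tidy metric
#' CSVs, a log, and a snapshot of the exact config) into an output
#' directory, so every result folder is self-describing and re-runnable.
#'
#' Config keys (a plain named list):
#' \describe{
#'   \item{experiment}{one of \code{"plain"} (single full-reference run),
#'     \code{"bootstrap"} (weighted bootstrap vs full comparison),
#'     \code{"cap_sweep"}, \code{"hvg_sweep"}, \code{"mosaic"},
#'     \code{"calibration"}.}
#'   \item{classifier, classifier_params, seed}{the classifier spec.}
#'   \item{n_hvgs, pseudocount, theta}{preprocessing (defaults 1000, 0.001,
#'     100).}
#'   \item{caps, n_perm}{cap sweep settings (defaults
#'     \code{defaultCapSweep()}, 20).}
#'   \item{n_boot}{bootstrap replicates (default 20).}
#'   \item{hvg_sizes}{HVG sweep sizes (default c(200, 1000, 2000)).}
#' }
#'
#' @param reference labelled reference dataset (for \code{"mosaic"}: a list
#'   of labelled source datasets).
#' @param query labelled query dataset.
#' @param config named list of config keys (see above).
#' @param outdir output directory, created if needed.
#' @return Invisibly, a list of the in-memory results (content depends on
#'   the experiment).
#' @export
runExperiment <- function(reference, query, config, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    cfg <- .fillConfig(config)
    jsonlite::write_json(cfg[!vapply(cfg, is.function, logical(1))],
                         file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    logLines <- c(sprintf("experiment=%s classifier=%s seed=%d start=%s",
                          cfg$experiment, cfg$classifier, cfg$seed,
                          format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
    spec <- classifierSpec(cfg$classifier, cfg$classifier_params, cfg$seed)
    truthDf <- function(q) data.frame(cell_id = cellIds(q),
                                      label = .requireLabels(q),
                                      stringsAsFactors = FALSE)
    result <- switch(cfg$experiment,
        plain = {
            proc <- preprocessPair(reference, query, nHvgs = cfg$n_hvgs,
                                   pseudocount = cfg$pseudocount,
                                   theta = cfg$theta)
            pred <- predictLabels(spec, proc$reference,
                                  .requireLabels(reference), proc$query)
            writePredictionsCsv(pred, file.path(outdir, "predictions.csv"))
            ev <- evaluateLabels(pred, truthDf(query))
            .writeReport(ev, outdir, "evaluation")
            list(predictions = pred, evaluation = ev)
        },
        bootstrap = {
            cmp <- compareBootstrapVsFull(query, reference, spec,
                                          nBoot = cfg$n_boot,
                                          seed = cfg$seed,
                                          nHvgs = cfg$n_hvgs,
                                          pseudocount = cfg$pseudocount,
                                          theta = cfg$theta)
            utils::write.csv(cmp$delta, file.path(outdir, "delta.csv"),
                             row.names = FALSE)
            .writeReport(cmp$full, outdir, "evaluation_full")
            .writeReport(cmp$bootstrap, outdir, "evaluation_bootstrap")
            cmp
        },
        cap_sweep = {
            tab <- sweepCaps(reference, query, spec, caps = cfg$caps,
                             nPerm = cfg$n_perm, seed = cfg$seed,
                             nHvgs = cfg$n_hvgs,
                             pseudocount = cfg$pseudocount,
                             theta = cfg$theta)
            utils::write.csv(tab, file.path(outdir, "cap_sweep.csv"),
                             row.names = FALSE)
            list(sweep = tab)
        },
        hvg_sweep = {
            tabs <- lapply(cfg$hvg_sizes, function(n) {
                proc <- preprocessPair(reference, query, nHvgs = n,
                                       pseudocount = cfg$pseudocount,
                                       theta = cfg$theta)
                pred <- predictLabels(spec, proc$reference,
                                      .requireLabels(reference), proc$query)
                pc <- perClassMetrics(evaluateLabels(pred, truthDf(query)))
                pc$n_hvgs <- n
                pc
            })
            tab <- do.call(rbind, tabs)
            utils::write.csv(tab, file.path(outdir, "hvg_sweep.csv"),
                             row.names = FALSE)
            list(sweep = tab)
        },
        mosaic = {
            stopifnot(is.list(reference))
            mosaic <- assembleMosaic(reference,
                                     batchNames = paste0("source",
                                                         seq_along(reference)))
            utils::write.csv(
                data.frame(cell_type = names(typeAbundances(mosaic)),
                           abundance = as.integer(typeAbundances(mosaic))),
                file.path(outdir, "mosaic_abundances.csv"),
                row.names = FALSE)
            cmp <- compareBootstrapVsFull(query, mosaic, spec,
                                          nBoot = cfg$n_boot,
                                          seed = cfg$seed,
                                          nHvgs = cfg$n_hvgs,
                                          pseudocount = cfg$pseudocount,
                                          theta = cfg$theta)
            .writeReport(cmp$bootstrap, outdir, "evaluation_bootstrap")
            c(cmp, list(mosaic = mosaic))
        },
        calibration = {
            proc <- preprocessPair(reference, query, nHvgs = cfg$n_hvgs,
                                   pseudocount = cfg$pseudocount,
                                   theta = cfg$theta)
            pred <- predictLabels(spec, proc$reference,
                                  .requireLabels(reference), proc$query)
            cal <- confidenceCalibration(pred, truthDf(query))
            utils::write.csv(cal, file.path(outdir, "calibration.csv"),
                             row.names = FALSE)
            list(predictions = pred, calibration = cal)
        },
        stop(sprintf("unknown experiment '%s'", cfg$experiment)))
    logLines <- c(logLines, sprintf("end=%s",
                                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
    writeLines(logLines, file.path(outdir, "run.log"))
    invisible(result)
}

.fillConfig <- function(config) {
    defaults <- list(experiment = "plain", classifier = "centroid",
                     classifier_params = list(), seed = 1L,
                     n_hvgs = 1000, pseudocount = 0.001, theta = 100,
                     caps = defaultCapSweep(), n_perm = 20L, n_boot = 20L,
                     hvg_sizes = c(200L, 1000L, 2000L))
    bad <- setdiff(names(config), names(defaults))
    if (length(bad))
        stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
    defaults[names(config)] <- config
    defaults$seed <- as.integer(defaults$seed)
    defaults
}

.writeReport <- function(ev, outdir, stem) {
    utils::write.csv(perClassMetrics(ev),
                     file.path(outdir, paste0(stem, "_per_class.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
        list(macro_f1 = macroF1(ev), micro_f1 = microF1(ev),
             per_class = perClassMetrics(ev),
             confusion = as.data.frame(as.table(confusionMatrix(ev)))),
        file.path(outdir, paste0(stem, ".json")),
        auto_unbox = TRUE, digits = NA)
    invisible(NULL)
}
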