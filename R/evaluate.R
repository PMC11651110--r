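#' Absolute relative bias of a coefficient estimate
#'
#' The benchmark's accuracy metric: the median, over coefficients whose true
#' value is nonzero, of `|estimate - truth| / |truth|`. Coefficients with
#' zero truth carry no relative scale and are excluded.
#'
#' @param estimate numeric vector of estimates.
#' @param truth numeric vector of true values, same length.
#' @return scalar ARB.
#' @examples
#' absoluteRelativeBias(c(1.5, 1), c(1, 2))  # 0.5
#' @export
absoluteRelativeBias <- function(estimate, truth) {
  if (length(estimate) != length(truth))
    stop("'estimate' and 'truth' must have the same length")
  keep <- truth != 0
  if (!any(keep))
    stop("'truth' has no nonzero entries; ARB is undefined")
  stats::median(abs(estimate[keep] - truth[keep]) / abs(truth[keep]))
}

#' Run the model-comparison benchmark
#'
#' For every scenario cell and replicate: simulate a covariate table and a
#' ZINB count response, fit each requested model variant, and record the
#' absolute relative bias of its non-intercept coefficients (the intercept's
#' truth depends on the mean-scale normalization, so it is excluded by
#' default) together with the estimated overdispersion. Model failures —
#' sampler degeneracy or structural impossibility on a degenerate draw — are
#' recorded as `NA` rows with `failed = TRUE`, never raised. The whole run
#' is determined by `seed`; when `outFile` is given, rows are appended after
#' each cell so long runs are resumable by inspection.
#'
#' @param grid `data.frame` of scenario cells from [scenarioGrid()] (columns
#'   `n`, `effect`, `phi`, `invTheta`).
#' @param models character vector of variant names.
#' @param replicates replicates per cell.
#' @param spec template [ZinbModelSpec-class] supplying priors and the MCMC
#'   schedule; its variant and seed are set per fit.
#' @param zeroMech zero-inflation mechanism passed to [simulateCounts()].
#' @param seed master integer seed.
#' @param includeIntercept include the intercept in ARB?
#' @param outFile optional CSV path for incremental results.
#' @return `data.frame` with columns `n`, `effect`, `phi`, `invTheta`,
#'   `model`, `replicate`, `arb`, `invThetaEst`, `failed`.
#' @export
runBenchmark <- function(grid, models, replicates = 10,
                         spec = zinbModelSpec(), zeroMech = "tau", seed = 1,
                         includeIntercept = FALSE, outFile = NULL) {
  stopifnot(replicates >= 1, nrow(grid) >= 1)
  rows <- vector("list", nrow(grid) * replicates * length(models))
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    cellRows <- list()
    for (r in seq_len(replicates)) {
      simSeed <- (as.integer(seed) * 1009L + i * 797L + r * 13L) %% 2147483629L
      cov <- generateCovariates(cell$n, seed = simSeed)
      B <- simulationDesign(cov)
      truth <- simulationCoefficients(B, cell$effect)
      y <- simulateCounts(cov, truth, list(phi = cell$phi, invTheta = cell$invTheta),
                          zeroMech = zeroMech, seed = simSeed + 1L)
      idx <- if (includeIntercept) seq_along(truth) else -1L
      for (m in seq_along(models)) {
        fitSpec <- spec
        fitSpec@seed <- (simSeed + 100L * m) %% 2147483629L
        fit <- tryCatch(fitVariant(models[m], B, y, spec = fitSpec),
                        error = function(e)
                          .failedFit(models[m], names(truth), fitSpec,
                                     conditionMessage(e)))
        if (isFailed(fit)) {
          arb <- NA_real_; invThetaEst <- NA_real_
        } else {
          arb <- absoluteRelativeBias(unname(coef(fit))[idx], truth[idx])
          dr <- posteriorDraws(fit)
          invThetaEst <- if ("theta" %in% colnames(dr)) mean(1 / dr[, "theta"])
            else if (fit@variant == "HURDLE")
              1 / fit@summary$mean[fit@summary$parameter == "theta"]
            else NA_real_
        }
        k <- k + 1L
        row <- data.frame(n = cell$n, effect = cell$effect, phi = cell$phi,
                          invTheta = cell$invTheta, model = models[m],
                          replicate = r, arb = arb, invThetaEst = invThetaEst,
                          failed = isFailed(fit), stringsAsFactors = FALSE)
        rows[[k]] <- row
        cellRows <- c(cellRows, list(row))
      }
    }
    if (!is.null(outFile)) {
      out <- do.call(rbind, cellRows)
      utils::write.table(out, outFile, sep = ",", row.names = FALSE,
                         col.names = !file.exists(outFile), append = file.exists(outFile))
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Summarize a benchmark run
#'
#' Two aggregate shapes: per model, the median ARB across all cells and
#' replicates (the box-plot-style headline), and per cell and model, the
#' mean ARB with its standard deviation (the tolerance-table style
#' "ARB (sd)"). Failed fits are excluded from the aggregates and counted.
#'
#' @param result output of [runBenchmark()].
#' @return list with `perModel` (`model`, `medianArb`, `naCount`, `fits`) and
#'   `perCell` (`n`, `effect`, `phi`, `invTheta`, `model`, `meanArb`, `sdArb`,
#'   `meanInvThetaEst`, `naCount`).
#' @export
summarizeArb <- function(result) {
  if (nrow(result) == 0) stop("empty benchmark result")
  perModel <- do.call(rbind, lapply(split(result, result$model), function(d) {
    data.frame(model = d$model[1],
               medianArb = if (all(is.na(d$arb))) NA_real_
                           else stats::median(d$arb, na.rm = TRUE),
               naCount = sum(is.na(d$arb)), fits = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(perModel) <- NULL
  key <- interaction(result$n, result$effect, result$phi, result$invTheta,
                     result$model, drop = TRUE)
  perCell <- do.call(rbind, lapply(split(result, key), function(d) {
    data.frame(n = d$n[1], effect = d$effect[1], phi = d$phi[1],
               invTheta = d$invTheta[1], model = d$model[1],
               meanArb = if (all(is.na(d$arb))) NA_real_
                         else mean(d$arb, na.rm = TRUE),
               sdArb = if (sum(!is.na(d$arb)) < 2) NA_real_
                       else stats::sd(d$arb, na.rm = TRUE),
               meanInvThetaEst = if (all(is.na(d$invThetaEst))) NA_real_
                                 else mean(d$invThetaEst, na.rm = TRUE),
               naCount = sum(is.na(d$arb)), stringsAsFactors = FALSE)
  }))
  rownames(perCell) <- NULL
  list(perModel = perModel, perCell = perCell)
}
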