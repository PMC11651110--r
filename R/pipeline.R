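#' Differential-abundance result
#'
#' Output of [runDaPipeline()]. `effects` holds one row per taxon and
#' monitored covariate with the posterior-mean effect size on the log-mean
#' scale, its sd and equal-tailed 95 percent credible interval, the
#' `discriminatory` flag (interval excludes zero — no p-values exist
#' anywhere in this workflow) and the `highlight` flag (absolute effect above
#' the configured threshold, default 0.35). `taxa` carries per-taxon
#' moment characterization and relative abundance; `interactions` the
#' ethnic-by-geography combination effects against the reference cell.
#'
#' @slot effects per taxon-by-covariate data.frame.
#' @slot taxa per-taxon data.frame.
#' @slot interactions per taxon-by-combination data.frame.
#' @slot config the resolved configuration list.
#' @export
setClass("DaResult",
  representation(effects = "data.frame", taxa = "data.frame",
                 interactions = "data.frame", config = "list"))

setValidity("DaResult", function(object) {
  need <- c("taxon", "covariate", "effect", "sd", "q2.5", "q97.5",
            "discriminatory", "highlight", "failed")
  if (!all(need %in% names(object@effects)))
    return(paste("effects must have columns:", paste(need, collapse = ", ")))
  bad <- object@effects$failed &
    (object@effects$discriminatory | object@effects$highlight)
  if (any(bad, na.rm = TRUE)) return("failed taxa must not carry flags")
  TRUE
})

setMethod("show", "DaResult", function(object) {
  ok <- !object@effects$failed
  cat("DaResult:", length(unique(object@effects$taxon)), "taxa,",
      sum(object@effects$discriminatory[ok]), "discriminatory flags,",
      sum(object@effects$failed[!duplicated(object@effects$taxon)]),
      "failed fits\n")
  invisible(object)
})

#' @describeIn DaResult-class per taxon-by-covariate effect table.
#' @param object a `DaResult`.
#' @export
setGeneric("daEffects", function(object) standardGeneric("daEffects"))

#' @rdname DaResult-class
#' @export
setMethod("daEffects", "DaResult", function(object) object@effects)

#' @describeIn DaResult-class per-taxon characterization table.
#' @export
setGeneric("daTaxa", function(object) standardGeneric("daTaxa"))

#' @rdname DaResult-class
#' @export
setMethod("daTaxa", "DaResult", function(object) object@taxa)

.daDefaults <- function() {
  list(variant = "ZINB_tau", minTotal = 30, highlightThreshold = 0.35,
       referenceEthnic = "U", referenceGeography = "H", interaction = TRUE,
       adapt = 1000, burnin = 1000, samples = 1000, chains = 1, seed = 1)
}

#' Per-taxon Bayesian differential-abundance pipeline
#'
#' The end-to-end workflow: align counts with metadata, drop taxa with a
#' cohort total below `minTotal` (default 30 — rarer taxa provoke sampler
#' degeneracy), build the design (centered age, BMI-for-age z-score,
#' ethnicity and geography with their observed interaction cells, treatment
#' coding against the configured reference), then fit the chosen model
#' variant to every taxon. Age and BMI-z effects are flagged
#' `discriminatory` when the 95 percent credible interval excludes zero and
#' `highlight` when the absolute posterior mean exceeds the threshold.
#' Per-taxon sampler failures are flagged, never fatal; the whole run is
#' reproducible from `config$seed`.
#'
#' @param counts taxa-by-samples integer matrix (see [readAsvTable()]).
#' @param metadata sample metadata with a `bmiaz` column (see
#'   [readMetadata()], [growthZscore()]).
#' @param taxonomy optional taxonomy table; carried into the result.
#' @param config named list overriding any of: `variant`, `minTotal`,
#'   `highlightThreshold`, `referenceEthnic`, `referenceGeography`,
#'   `interaction`, `adapt`, `burnin`, `samples`, `chains`, `seed`.
#' @return a [DaResult-class].
#' @export
runDaPipeline <- function(counts, metadata, taxonomy = NULL, config = list()) {
  cfg <- utils::modifyList(.daDefaults(), config)
  if (!cfg$variant %in% .zinbVariants)
    stop("unknown variant '", cfg$variant, "'; valid names: ",
         paste(.zinbVariants, collapse = ", "))
  counts <- .checkCountMatrix(counts)
  if (!"bmiaz" %in% names(metadata))
    stop("metadata lacks 'bmiaz'; compute it with growthZscore()")
  if (!setequal(colnames(counts), metadata$sample_id))
    stop("sample ids of counts and metadata do not match")
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]

  nIn <- nrow(counts)
  counts <- filterLowAbundance(counts, cfg$minTotal)
  nFiltered <- length(attr(counts, "removed"))
  stopifnot(nIn == nrow(counts) + nFiltered)
  message("taxa in: ", nIn, "; retained: ", nrow(counts),
          "; filtered (< ", cfg$minTotal, " total): ", nFiltered)
  if (nrow(counts) == 0) stop("no taxon passes the abundance filter")

  dm <- buildDesignMatrix(metadata, cfg$referenceEthnic,
                          cfg$referenceGeography, cfg$interaction)
  B <- dm$design
  spec <- zinbModelSpec(cfg$variant, adapt = cfg$adapt, burnin = cfg$burnin,
                        samples = cfg$samples, chains = cfg$chains,
                        seed = cfg$seed)
  monitored <- c("age_c", "bmiaz")
  total <- sum(counts)
  combos <- .observedCombos(metadata, cfg$referenceEthnic,
                            cfg$referenceGeography)

  effectRows <- list(); taxonRows <- list(); interRows <- list()
  for (t in seq_len(nrow(counts))) {
    taxon <- rownames(counts)[t]
    y <- counts[t, ]
    fitSpec <- spec
    fitSpec@seed <- (spec@seed + 7919L * t) %% 2147483629L
    fit <- tryCatch(fitVariant(cfg$variant, B, y, spec = fitSpec),
                    error = function(e)
                      .failedFit(cfg$variant, .paramNames(cfg$variant, B, B),
                                 fitSpec, conditionMessage(e)))
    mom <- tryCatch(estimateZinbMoments(y), error = function(e) NULL)
    taxonRows[[t]] <- data.frame(
      taxon = taxon,
      phiHat = if (is.null(mom)) NA_real_ else mom$phiHat,
      invThetaHat = if (is.null(mom)) NA_real_ else mom$invThetaHat,
      relAbundance = sum(y) / total,
      failed = isFailed(fit), stringsAsFactors = FALSE)
    s <- posteriorSummary(fit)
    for (cv in monitored) {
      row <- s[s$parameter == paste0("beta[", cv, "]"), ]
      failed <- isFailed(fit) || nrow(row) == 0
      effectRows[[length(effectRows) + 1L]] <- data.frame(
        taxon = taxon, covariate = cv,
        effect = if (failed) NA_real_ else row$mean,
        sd = if (failed) NA_real_ else row$sd,
        q2.5 = if (failed) NA_real_ else row$q2.5,
        q97.5 = if (failed) NA_real_ else row$q97.5,
        discriminatory = if (failed) FALSE else (row$q2.5 > 0 || row$q97.5 < 0),
        highlight = if (failed) FALSE else
          abs(row$mean) > cfg$highlightThreshold,
        failed = failed, stringsAsFactors = FALSE)
    }
    if (!isFailed(fit) && nrow(combos) && nrow(posteriorDraws(fit)) > 0)
      interRows[[length(interRows) + 1L]] <-
        cbind(taxon = taxon, .comboEffects(fit, combos),
              stringsAsFactors = FALSE)
  }
  new("DaResult",
      effects = do.call(rbind, effectRows),
      taxa = do.call(rbind, taxonRows),
      interactions = if (length(interRows)) do.call(rbind, interRows)
                     else data.frame(taxon = character(), ethnic = character(),
                                     geography = character(), effect = numeric(),
                                     q2.5 = numeric(), q97.5 = numeric()),
      config = c(cfg, list(nTaxaIn = nIn, nTaxaFiltered = nFiltered,
                           taxonomy = taxonomy)))
}

.observedCombos <- function(metadata, refEthnic, refGeo) {
  tab <- unique(metadata[, c("ethnic", "geography")])
  tab <- tab[!(tab$ethnic == refEthnic & tab$geography == refGeo), ,
             drop = FALSE]
  tab[order(tab$ethnic, tab$geography), , drop = FALSE]
}

# posterior draws of each (ethnic, geography) cell's total effect relative
# to the reference cell: main effects plus the matching interaction column
.comboEffects <- function(fit, combos) {
  dr <- posteriorDraws(fit)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    e <- combos$ethnic[i]; g <- combos$geography[i]
    cols <- c(paste0("beta[ethnic", e, "]"),
              paste0("beta[geography", g, "]"),
              paste0("beta[ethnic", e, ":geography", g, "]"))
    cols <- cols[cols %in% colnames(dr)]
    draws <- if (length(cols)) rowSums(dr[, cols, drop = FALSE]) else
      rep(0, nrow(dr))
    data.frame(ethnic = e, geography = g, effect = mean(draws),
               q2.5 = unname(stats::quantile(draws, 0.025)),
               q97.5 = unname(stats::quantile(draws, 0.975)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Ethnic-by-geography interaction effect report
#'
#' For every taxon, lists each observed (ethnic, geography) combination's
#' effect size and 95 percent credible interval relative to the reference
#' cell, and flags taxa for which at least one pair of combinations has
#' non-overlapping intervals — the signature of a real ethnogeographic
#' interaction rather than a shared shift.
#'
#' @param da a [DaResult-class] from [runDaPipeline()].
#' @return list with `combos` (the per-taxon table) and `flags` (`taxon`,
#'   `nonOverlap`).
#' @export
interactionEffectReport <- function(da) {
  combos <- da@interactions
  flags <- do.call(rbind, lapply(split(combos, combos$taxon), function(d) {
    non <- FALSE
    if (nrow(d) >= 2)
      for (i in seq_len(nrow(d) - 1)) for (j in (i + 1):nrow(d))
        if (d$q2.5[i] > d$q97.5[j] || d$q2.5[j] > d$q97.5[i]) non <- TRUE
    data.frame(taxon = d$taxon[1], nonOverlap = non, stringsAsFactors = FALSE)
  }))
  if (is.null(flags))
    flags <- data.frame(taxon = character(), nonOverlap = logical())
  rownames(flags) <- NULL
  list(combos = combos, flags = flags)
}
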