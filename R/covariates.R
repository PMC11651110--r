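# Covariate engineering: LMS growth-reference z-scores, z-BMI classes,
# cohort design matrices, and GVIF collinearity screening.

#' LMS z-score transformation
#'
#' The LMS method normalizes a skewed anthropometric measurement against
#' reference curves: power `L`, median `M` and coefficient of variation `S`,
#' giving `z = ((x/M)^L - 1) / (L * S)` for `L != 0` and `z = log(x/M) / S`
#' in the `L = 0` limit. Strictly increasing in `x`.
#'
#' @param x positive measurement (e.g. BMI in kg/m^2).
#' @param L,M,S reference parameters; `M > 0`, `S > 0`.
#' @return z-score.
#' @examples
#' lmsZscore(16.0, L = 1, M = 16.0, S = 0.1)  # 0
#' @export
lmsZscore <- function(x, L, M, S) {
  if (any(x <= 0)) stop("'x' must be positive")
  stopifnot(all(M > 0), all(S > 0))
  ifelse(L == 0, log(x / M) / S, ((x / M)^L - 1) / (L * S))
}

#' Read an LMS growth-reference table
#'
#' Expects a CSV with columns `measure` (e.g. `bmi`, `height`, `weight`),
#' `sex` (`F`/`M`), `age_months`, `L`, `M`, `S`, with `M, S > 0` and ages
#' strictly increasing within each (measure, sex). A small synthetic table
#' for tests ships at
#' `system.file("extdata", "lms_reference_synthetic.csv", package = "zinbiome")`;
#' real WHO reference tables in this layout are supplied by the user.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
readLmsReference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("measure", "sex", "age_months", "L", "M", "S")
  if (!all(need %in% names(ref)))
    stop("LMS reference must have columns: ", paste(need, collapse = ", "))
  if (any(ref$M <= 0) || any(ref$S <= 0)) stop("M and S must be positive")
  for (key in split(ref, interaction(ref$measure, ref$sex, drop = TRUE)))
    if (is.unsorted(key$age_months, strictly = TRUE))
      stop("age_months must be strictly increasing within each measure/sex")
  ref
}

#' Growth-reference z-score at an interpolated age
#'
#' Looks up `L`, `M`, `S` for the requested measure and sex, linearly
#' interpolating each parameter between the bracketing reference ages
#' (constant extension beyond the table range), then applies [lmsZscore()].
#'
#' @param x measurement values.
#' @param ageMonths age in months, same length as `x` (or scalar).
#' @param sex `"F"`/`"M"`, recycled.
#' @param reference table from [readLmsReference()].
#' @param measure reference measure name (default `"bmi"`).
#' @return z-scores.
#' @export
growthZscore <- function(x, ageMonths, sex, reference, measure = "bmi") {
  k <- max(length(x), length(ageMonths), length(sex))
  x <- rep_len(x, k); ageMonths <- rep_len(ageMonths, k)
  sex <- rep_len(sex, k)
  out <- numeric(k)
  for (s in unique(sex)) {
    sel <- sex == s
    tab <- reference[reference$measure == measure & reference$sex == s, ]
    if (nrow(tab) < 2)
      stop("no usable reference rows for measure '", measure,
           "', sex '", s, "'")
    L <- stats::approx(tab$age_months, tab$L, ageMonths[sel], rule = 2)$y
    M <- stats::approx(tab$age_months, tab$M, ageMonths[sel], rule = 2)$y
    S <- stats::approx(tab$age_months, tab$S, ageMonths[sel], rule = 2)$y
    out[sel] <- lmsZscore(x[sel], L, M, S)
  }
  out
}

#' Classify a BMI-for-age z-score
#'
#' Bands: `underweight` below -2; `normal` from -2 to `cutOverweight`
#' (inclusive); `overweight` above `cutOverweight` up to `cutObese`
#' (inclusive); `obese` strictly above `cutObese`. The default cutoffs 2 and
#' 4 follow the workflow this package accompanies; note the common WHO
#' school-age convention uses 2 (overweight) and 3 (obesity) instead — pass
#' `cutObese = 3` for that convention.
#'
#' @param z z-score vector (finite).
#' @param cutOverweight,cutObese band cutoffs, `cutOverweight < cutObese`.
#' @return factor with levels underweight, normal, overweight, obese.
#' @examples
#' classifyZbmi(c(0, 2, 2.5, 5))
#' @export
classifyZbmi <- function(z, cutOverweight = 2, cutObese = 4) {
  if (any(!is.finite(z))) stop("'z' must be finite")
  stopifnot(cutOverweight < cutObese)
  # closures differ per boundary: -2 belongs to normal, the upper cutoffs to
  # the band below them
  lab <- ifelse(z < -2, "underweight",
         ifelse(z <= cutOverweight, "normal",
         ifelse(z <= cutObese, "overweight", "obese")))
  factor(lab, levels = c("underweight", "normal", "overweight", "obese"))
}

#' Cohort design matrix with ethnic-by-geography interaction
#'
#' Treatment coding with user-chosen reference levels (default ethnic `U`,
#' geography `H`); age mean-centered; the BMI-for-age z-score passed through
#' unchanged; interaction columns only for ethnic-geography level pairs
#' actually observed. Returns the column-to-term map needed by [gvif()].
#'
#' @param cov covariate table with columns `age_years`, `bmiaz`, `ethnic`,
#'   `geography` (e.g. from [generateCovariates()]).
#' @param referenceEthnic,referenceGeography reference levels; must occur in
#'   the data.
#' @param interaction include ethnic-by-geography interaction columns?
#' @return list with `design` (numeric matrix), `groups` (character vector
#'   mapping non-intercept columns to term labels) and `ageCenter` (the
#'   subtracted mean age).
#' @export
buildDesignMatrix <- function(cov, referenceEthnic = "U",
                              referenceGeography = "H", interaction = TRUE) {
  for (v in c("ethnic", "geography")) {
    ref <- if (v == "ethnic") referenceEthnic else referenceGeography
    if (!ref %in% cov[[v]])
      stop("reference level '", ref, "' absent from '", v, "'")
  }
  d <- data.frame(
    age_c = cov$age_years - mean(cov$age_years),
    bmiaz = cov$bmiaz,
    ethnic = stats::relevel(factor(cov$ethnic), referenceEthnic),
    geography = stats::relevel(factor(cov$geography), referenceGeography))
  form <- if (interaction) ~ age_c + bmiaz + ethnic * geography
          else ~ age_c + bmiaz + ethnic + geography
  mm <- stats::model.matrix(form, d)
  labels <- c("(Intercept)", attr(stats::terms(form), "term.labels"))
  groups <- labels[attr(mm, "assign") + 1L]
  # interaction cells never observed produce all-zero columns; drop them
  nonzero <- colSums(mm != 0) > 0
  if (interaction) {
    interCols <- groups == "ethnic:geography"
    if (any(interCols) && !any(nonzero & interCols))
      stop("no ethnic-geography interaction cell is populated")
  }
  mm <- mm[, nonzero, drop = FALSE]
  groups <- groups[nonzero]
  names(groups) <- colnames(mm)
  list(design = mm, groups = groups[groups != "(Intercept)"],
       ageCenter = mean(cov$age_years))
}

#' Generalized variance inflation factors
#'
#' Fox-Monette GVIF per term group over the correlation matrix `R` of the
#' non-intercept columns: `GVIF = det(R_g) det(R_-g) / det(R)`, reported
#' together with the df-adjusted scale `GVIF^(1/(2 df))` on which multi-df
#' terms are comparable. A single-df term's GVIF equals the classical
#' `1/(1-R^2)` inflation factor. GVIF is at least 1 for full-rank designs
#' and invariant to affine rescaling of individual columns.
#'
#' @param design numeric design matrix (intercept column allowed; ignored).
#' @param groups character vector mapping non-intercept columns of `design`
#'   to term labels, as produced by [buildDesignMatrix()].
#' @return data.frame with columns `term`, `df`, `gvif`, `gvifScaled`.
#' @export
gvif <- function(design, groups) {
  design <- as.matrix(design)
  drop <- colnames(design) == "(Intercept)" |
    apply(design, 2, function(col) stats::var(col) == 0)
  X <- design[, !drop, drop = FALSE]
  if (length(groups) != ncol(X))
    stop("'groups' must label every non-intercept column")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)) + 1L,
                               qrX$pivot[seq_len(qrX$rank)]) - 1L]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  R <- stats::cor(X)
  detR <- det(R)
  terms <- unique(groups)
  out <- lapply(terms, function(tm) {
    ids <- which(groups == tm)
    detG <- det(R[ids, ids, drop = FALSE])
    rest <- setdiff(seq_len(ncol(X)), ids)
    detRest <- if (length(rest)) det(R[rest, rest, drop = FALSE]) else 1
    g <- detG * detRest / detR
    data.frame(term = tm, df = length(ids), gvif = g,
               gvifScaled = g^(1 / (2 * length(ids))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Screen candidate designs for collinearity
#'
#' Builds each candidate model matrix on `data`, computes its GVIF report,
#' and flags candidates whose maximum df-adjusted GVIF is strictly below 3
#' as acceptable (the naive-independence working threshold). Rank-deficient
#' candidates are flagged rather than raised.
#'
#' @param data data.frame holding every variable the candidate formulas use.
#' @param candidates named list of one-sided formulas, in the order they
#'   should be compared.
#' @return data.frame with columns `candidate`, `maxGvifScaled`,
#'   `acceptable`, `rankDeficient`.
#' @export
screenInteractions <- function(data, candidates) {
  if (length(candidates) < 1) stop("need at least one candidate formula")
  if (is.null(names(candidates)))
    names(candidates) <- vapply(candidates, function(f)
      paste(deparse(f[[length(f)]]), collapse = ""), "")
  out <- lapply(names(candidates), function(nm) {
    mm <- stats::model.matrix(candidates[[nm]], data)
    labels <- c("(Intercept)",
                attr(stats::terms(candidates[[nm]]), "term.labels"))
    groups <- labels[attr(mm, "assign") + 1L]
    names(groups) <- colnames(mm)
    groups <- groups[groups != "(Intercept)"]
    rep <- tryCatch(gvif(mm, groups), error = function(e) NULL)
    if (is.null(rep))
      data.frame(candidate = nm, maxGvifScaled = NA_real_,
                 acceptable = FALSE, rankDeficient = TRUE,
                 stringsAsFactors = FALSE)
    else
      data.frame(candidate = nm, maxGvifScaled = max(rep$gvifScaled),
                 acceptable = max(rep$gvifScaled) < 3, rankDeficient = FALSE,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
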