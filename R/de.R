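#' Parameters of the two-step differential-expression screen
#'
#' @param maxDegree cap on the polynomial time degree (the effective degree
#'   is `min(maxDegree, #distinct timepoints - 1)`).
#' @param globalFDR BH-adjusted cut-off for the step-1 global F-test.
#' @param r2Min minimal coefficient of determination of the stepwise-
#'   selected model for a gene to count as differentially expressed.
#' @param alpha per-coefficient threshold for the stepwise step; `NULL`
#'   (default) applies the `0.05 / n` rule with `n` the number of
#'   coefficients of the full model.
#' @return a validated `DEParams` list.
#' @export
deParams <- function(maxDegree = 3L, globalFDR = 0.01, r2Min = 0.6,
                     alpha = NULL) {
  if (maxDegree < 1L) stop("maxDegree must be >= 1")
  if (globalFDR <= 0 || globalFDR >= 1) stop("globalFDR must be in (0,1)")
  if (r2Min < 0 || r2Min > 1) stop("r2Min must be in [0,1]")
  structure(list(maxDegree = as.integer(maxDegree), globalFDR = globalFDR,
                 r2Min = r2Min, alpha = alpha), class = "DEParams")
}

#' Build the polynomial time-course design matrix
#'
#' Columns: intercept, scaled time raised to powers `1..d` with
#' `d = min(maxDegree, #distinct timepoints - 1)`, and for every
#' non-control dose level present in the samples a group indicator plus its
#' interactions with each time power. Time is rescaled to unit range for
#' numerical conditioning. Dose levels absent from a particular compound
#' (as happens for panels lacking e.g. a low-dose arm) simply contribute no
#' columns.
#'
#' @param samples data.frame (or DataFrame) of sample metadata with at
#'   least `dose` and `time` columns, one row per sample.
#' @param maxDegree polynomial degree cap.
#' @return list with `X` (the model matrix), `groupCols` (logical, which
#'   columns encode treatment-group terms), `degree` and `nCoef`.
#' @export
buildDesign <- function(samples, maxDegree = 3L) {
  samples <- as.data.frame(samples)
  if (!all(c("dose", "time") %in% colnames(samples)))
    stop("samples must have 'dose' and 'time' columns")
  if (!any(samples$dose == "control"))
    stop("no control samples present")
  times <- unique(samples$time)
  if (length(times) < 2L)
    stop("at least two distinct timepoints are required")
  d <- min(as.integer(maxDegree), length(times) - 1L)
  tScaled <- (samples$time - min(times)) / diff(range(times))
  timeCols <- outer(tScaled, seq_len(d), `^`)
  colnames(timeCols) <- paste0("time", seq_len(d))
  X <- cbind(intercept = 1, timeCols)
  groupCols <- rep(FALSE, ncol(X))
  for (lvl in setdiff(doseLevels, "control")) {
    if (!any(samples$dose == lvl)) next
    ind <- as.numeric(samples$dose == lvl)
    block <- cbind(ind, ind * timeCols)
    colnames(block) <- c(lvl, paste0(lvl, ":time", seq_len(d)))
    X <- cbind(X, block)
    groupCols <- c(groupCols, rep(TRUE, ncol(block)))
  }
  list(X = X, groupCols = groupCols, degree = d, nCoef = ncol(X))
}

# OLS fit with per-coefficient t-tests and model F-test vs intercept-only.
# Aliased (rank-deficient) columns are dropped and reported.
fitOLS <- function(y, X) {
  n <- length(y)
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  piv <- fit$qr$pivot[seq_len(r)]
  aliased <- colnames(X)[setdiff(seq_len(ncol(X)), piv)]
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  dfRes <- n - r
  coefP <- rep(NA_real_, ncol(X))
  names(coefP) <- colnames(X)
  if (dfRes > 0 && r > 0) {
    sigma2 <- rss / dfRes
    R <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
    R[lower.tri(R)] <- 0
    xtxInv <- chol2inv(R)
    se <- sqrt(pmax(diag(xtxInv), 0) * sigma2)
    tval <- fit$coefficients[piv] / se
    coefP[piv] <- 2 * stats::pt(abs(tval), dfRes, lower.tail = FALSE)
  }
  r2 <- if (tss > 1e-12) max(0, 1 - rss / tss) else 0
  fP <- modelFPValue(rss, tss, r, n)
  list(coefficients = fit$coefficients, coefP = coefP, rss = rss,
       tss = tss, rank = r, r2 = r2, fPValue = fP, aliased = aliased,
       df.residual = dfRes)
}

modelFPValue <- function(rss, tss, rank, n) {
  df1 <- rank - 1
  df2 <- n - rank
  if (df1 <= 0 || df2 <= 0 || tss <= 1e-12) return(1)
  if (rss <= 1e-12 * tss) return(0)
  f <- ((tss - rss) / df1) / (rss / df2)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Global model fit and F-test for one gene
#'
#' Ordinary least-squares fit of the full polynomial design; the p-value
#' comes from the F-test of the full model against the intercept-only
#' model. A zero-variance response yields p = 1 (no evidence). Aliased
#' design columns are dropped and recorded in the fit.
#'
#' @param y numeric expression vector (one gene across samples).
#' @param design design description from [buildDesign()].
#' @return list with `pValue`, `r2` and the full `fit` (see internals).
#' @export
fitGlobal <- function(y, design) {
  if (length(y) != nrow(design$X))
    stop("length of 'y' must match the design rows")
  fit <- fitOLS(y, design$X)
  list(pValue = fit$fPValue, r2 = fit$r2, fit = fit)
}

# Step-1 F-test p-values for all genes at once (same math as fitGlobal,
# vectorized across the response matrix).
globalFPValues <- function(Y, X) {
  n <- ncol(Y)
  fit <- stats::lm.fit(X, t(Y))
  r <- fit$rank
  res <- fit$residuals
  rss <- colSums(res^2)
  tss <- colSums(t(Y - rowMeans(Y))^2)
  df1 <- r - 1
  df2 <- n - r
  p <- rep(1, nrow(Y))
  ok <- tss > 1e-12
  if (df1 > 0 && df2 > 0) {
    f <- ((tss[ok] - rss[ok]) / df1) / (pmax(rss[ok], 0) / df2)
    pOk <- stats::pf(f, df1, df2, lower.tail = FALSE)
    pOk[rss[ok] <= 1e-12 * tss[ok]] <- 0
    p[ok] <- pOk
  }
  names(p) <- rownames(Y)
  p
}

#' Two-way backward stepwise coefficient selection
#'
#' Starts from the full model and repeatedly removes the coefficient with
#' the largest t-test p-value above `alpha`; after every removal any
#' excluded variable whose re-entry p-value would be at or below `alpha`
#' may re-enter (two-way). The intercept is never removed. Stops when all
#' retained coefficients are significant or only the intercept remains.
#'
#' @param y numeric response vector.
#' @param design design description from [buildDesign()].
#' @param alpha per-coefficient threshold; defaults to `0.05 / nCoef` of
#'   the full model.
#' @return list with `active` (retained column names), `r2`, `fPValue` (of
#'   the selected model vs intercept-only), `coefP` and `hasGroupCoef`
#'   (whether any treatment-group column was retained).
#' @export
backwardStepwise <- function(y, design, alpha = 0.05 / design$nCoef) {
  X <- design$X
  active <- seq_len(ncol(X))
  excluded <- integer(0)
  maxIter <- 4L * ncol(X)
  fit <- fitOLS(y, X)
  if (fit$tss <= 1e-12) {
    active <- 1L
    fit <- fitOLS(y, X[, 1L, drop = FALSE])
  } else {
    for (iter in seq_len(maxIter)) {
      # aliased columns carry no information in this model: exclude them
      al <- which(colnames(X)[active] %in% fit$aliased)
      if (length(al)) {
        excluded <- c(excluded, active[al])
        active <- active[-al]
        fit <- fitOLS(y, X[, active, drop = FALSE])
        next
      }
      pv <- fit$coefP
      pv[1L] <- 0  # intercept is fixed
      worst <- which.max(pv)
      if (length(active) > 1L && is.finite(pv[worst]) &&
          pv[worst] > alpha) {
        excluded <- c(excluded, active[worst])
        active <- active[-worst]
        fit <- fitOLS(y, X[, active, drop = FALSE])
        # two-way: allow the best re-entry candidate back in
        reP <- vapply(excluded, function(e) {
          f <- fitOLS(y, X[, c(active, e), drop = FALSE])
          f$coefP[length(active) + 1L]
        }, numeric(1))
        best <- which.min(reP)
        if (length(best) && is.finite(reP[best]) && reP[best] <= alpha) {
          active <- c(active, excluded[best])
          excluded <- excluded[-best]
          fit <- fitOLS(y, X[, active, drop = FALSE])
        }
      } else break
    }
  }
  nm <- colnames(X)[active]
  list(active = nm, r2 = fit$r2, fPValue = fit$fPValue,
       coefP = stats::setNames(fit$coefP, nm),
       hasGroupCoef = any(nm %in% colnames(X)[design$groupCols]))
}

#' Per-compound two-step differential-expression screen
#'
#' Step 1 fits the full polynomial time/dose model to every gene and
#' BH-adjusts the global F-test p-values across genes; genes at or below
#' `globalFDR` proceed to step 2, a two-way backward stepwise selection at
#' the `0.05 / n` per-coefficient threshold. A gene is `selected` when it
#' passed the global test, its selected model retains at least one
#' treatment-group coefficient, and that model explains at least `r2Min`
#' of the variance.
#'
#' @param panel an [ExpressionPanel-class].
#' @param compound compound to analyse (the panel is restricted to it).
#' @param params a [deParams()] object.
#' @param denoise optional function applied to the compound's gene x sample
#'   matrix before fitting (hook for noise-removal procedures); default
#'   pass-through.
#' @return data.frame with one row per gene and columns `gene_id`,
#'   `passed_global`, `global_q`, `adjusted_p`, `r2`, `n_coef`,
#'   `has_significant_coef`, `selected`.
#' @export
deAnalysis <- function(panel, compound = NULL, params = deParams(),
                       denoise = NULL) {
  stopifnot(is(panel, "ExpressionPanel"))
  cd <- colData(panel)
  if (!is.null(compound)) {
    keep <- cd$compound == compound
    if (!any(keep)) stop("compound not present in panel: ", compound)
    panel <- panel[, keep]
    cd <- colData(panel)
  } else if (length(unique(cd$compound)) > 1L) {
    stop("panel holds several compounds; pass 'compound'")
  }
  grp <- interaction(cd$dose, cd$time, drop = TRUE)
  if (min(table(grp)) < 2L)
    warning("fewer than two replicates in at least one dose-time group")
  Y <- assay(panel, "log2")
  if (!is.null(denoise)) Y <- denoise(Y)
  design <- buildDesign(cd, params$maxDegree)
  alpha <- if (is.null(params$alpha)) 0.05 / design$nCoef else params$alpha

  p1 <- globalFPValues(Y, design$X)
  q1 <- bhFDR(p1)
  passed <- q1 <= params$globalFDR

  n <- nrow(Y)
  adjP <- rep(NA_real_, n); r2 <- rep(NA_real_, n)
  hasCoef <- rep(FALSE, n)
  for (i in which(passed)) {
    sw <- backwardStepwise(Y[i, ], design, alpha)
    adjP[i] <- sw$fPValue
    r2[i] <- sw$r2
    grpActive <- intersect(sw$active, colnames(design$X)[design$groupCols])
    hasCoef[i] <- length(grpActive) > 0L &&
      any(sw$coefP[grpActive] <= alpha, na.rm = TRUE)
  }
  selected <- passed & hasCoef & !is.na(r2) & r2 >= params$r2Min
  data.frame(gene_id = rownames(Y), passed_global = passed,
             global_q = q1, adjusted_p = adjP, r2 = r2,
             n_coef = design$nCoef, has_significant_coef = hasCoef,
             selected = selected, row.names = NULL)
}
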