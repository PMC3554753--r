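#' Logistic grain-filling growth model
#'
#' Grain dry weight over the filling period is modelled with the standard
#' three-parameter logistic
#' \deqn{Y(t) = K / (1 + a e^{-b t})}
#' where `Y` is mean weight per grain (mg), `t` is days after flowering
#' (DAF), `K` the asymptotic grain weight (mg), `a` dimensionless and `b`
#' the rate coefficient (per day).  The filling rate is its derivative
#' \deqn{V(t) = K a b e^{-b t} / (1 + a e^{-b t})^2,}
#' maximal at `t = ln(a)/b` where `V = K b / 4`.
#'
#' @param K,a,b positive model coefficients.
#' @return list of class `"grain_logistic"`.
#' @export
grain_logistic <- function(K, a, b) {
  if (any(c(K, a, b) <= 0)) stop("K, a and b must all be positive")
  structure(list(K = K, a = a, b = b), class = "grain_logistic")
}

#' @describeIn grain_logistic grain weight Y(t) in mg.
#' @param model a `"grain_logistic"` object.
#' @param t days after flowering.
#' @export
logistic_weight <- function(model, t) {
  model$K / (1 + model$a * exp(-model$b * t))
}

#' @describeIn grain_logistic grain filling rate V(t) = dY/dt in mg/day.
#' @export
filling_rate <- function(model, t) {
  e <- model$a * exp(-model$b * t)
  model$K * model$b * e / (1 + e)^2
}

#' @export
print.grain_logistic <- function(x, ...) {
  cat(sprintf("logistic grain-filling model: K = %.4g mg, a = %.4g, b = %.4g /day\n",
              x$K, x$a, x$b))
  cat(sprintf("  inflection at t = %.2f DAF, max rate %.3f mg/day\n",
              log(x$a) / x$b, x$K * x$b / 4))
  invisible(x)
}

#' Fit the logistic grain-filling model by nonlinear least squares
#'
#' Deterministic initialization: `K0 = 1.05 * max(weight)`, then `a0` and
#' `b0` from the ordinary least-squares line of `log((K0 - Y)/Y)` against
#' `t` (intercept `log a`, slope `-b`).  The fit is refined with
#' [stats::nls()] (port algorithm, positive-parameter bounds).
#'
#' @param weights data.frame with columns `daf` and `weight` (mg), at
#'   least 4 points, all weights positive.
#' @return a `"grain_logistic"` model with attributes `fit` (the `nls`
#'   object) and `rss`.
#' @export
fit_logistic <- function(weights) {
  stopifnot(is.data.frame(weights), all(c("daf", "weight") %in% names(weights)))
  if (nrow(weights) < 4) stop("need at least 4 time points")
  if (any(weights$weight <= 0)) stop("weights must be positive")
  t <- weights$daf; y <- weights$weight
  K0 <- 1.05 * max(y)
  z <- log(pmax(K0 - y, 1e-9) / y)
  lf <- stats::lm.fit(cbind(1, t), z)
  a0 <- exp(lf$coefficients[1]); b0 <- -lf$coefficients[2]
  if (!is.finite(a0) || !is.finite(b0) || b0 <= 0) {
    stop("logistic fit failed: initial slope non-positive ",
         "(weights not increasing?)")
  }
  fit <- tryCatch(
    stats::nls(weight ~ K / (1 + a * exp(-b * daf)), data = weights,
               start = list(K = K0, a = a0, b = b0),
               lower = c(K = 1e-8, a = 1e-8, b = 1e-8),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stop("logistic fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  if (cf[["b"]] <= 1e-8) stop("logistic fit rejected: b <= 0")
  model <- grain_logistic(cf[["K"]], cf[["a"]], cf[["b"]])
  attr(model, "fit") <- fit
  attr(model, "rss") <- sum(stats::residuals(fit)^2)
  model
}

#' Filter expression profiles by a strict TPM threshold
#'
#' Keeps profiles whose maximum over the stages is strictly greater than
#' `threshold` (default 10 TPM, the "higher than 10 TPM in one of our
#' datasets" rule; a profile peaking at exactly 10 is excluded).
#'
#' @param tpm TPM matrix (rows = profiles, columns = stages).
#' @param threshold strict lower bound on the per-profile maximum.
#' @return the retained rows of `tpm`.
#' @export
filter_expressed <- function(tpm, threshold = 10) {
  tpm <- as.matrix(tpm)
  tpm[apply(tpm, 1, max) > threshold, , drop = FALSE]
}

#' Hierarchically cluster expression profiles
#'
#' Profiles are log2(TPM + 1) transformed, distances are 1 - Pearson
#' correlation, linkage is average (UPGMA), and the tree is cut into `k`
#' clusters.  Rows are processed in lexicographic id order so the
#' partition does not depend on input row order.  Constant profiles have
#' no defined correlation; they are treated as mutually identical and
#' maximally distant from everything else.
#'
#' @param tpm TPM matrix with rownames.
#' @param k number of clusters (default 10).
#' @return list of class `"cluster_result"`: `assignment` (named integer),
#'   `means` (k x stages matrix of mean log2 profiles), `k`, and the
#'   transformed matrix `logmat`.
#' @export
cluster_profiles <- function(tpm, k = 10L) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm))) rownames(tpm) <- paste0("p", seq_len(nrow(tpm)))
  if (k > nrow(tpm)) stop("k exceeds the number of profiles")
  tpm <- tpm[order(rownames(tpm)), , drop = FALSE]
  lm2 <- log2(tpm + 1)
  sds <- apply(lm2, 1, stats::sd)
  if (any(sds == 0)) {
    # correlation is undefined for flat profiles; treat them as mutually
    # identical and maximally distant from everything else
    cm <- suppressWarnings(stats::cor(t(lm2)))
    cm[is.na(cm)] <- 0
    flat <- which(sds == 0)
    cm[flat, flat] <- 1
  } else {
    cm <- stats::cor(t(lm2))
  }
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = k)
  # canonical labels: clusters numbered by first member in id order
  lab <- match(raw, unique(raw))
  names(lab) <- rownames(tpm)
  means <- t(vapply(seq_len(k), function(g) colMeans(lm2[lab == g, , drop = FALSE]),
                    numeric(ncol(lm2))))
  rownames(means) <- paste0("cluster", seq_len(k))
  structure(list(assignment = lab, means = means, k = k, logmat = lm2),
            class = "cluster_result")
}

#' Pearson correlation of an expression profile with the filling rate
#'
#' @param profile numeric vector of expression values over the stages.
#' @param model a `"grain_logistic"` model.
#' @param stage_days DAF of each stage (defaults to 10, 15, 21, 27, 35).
#' @return PCC between the profile and `V(stage_days)`; `NA` when the
#'   profile is constant.
#' @export
correlate_with_rate <- function(profile, model, stage_days = STAGE_DAYS) {
  v <- filling_rate(model, stage_days)
  if (stats::sd(profile) == 0 || stats::sd(v) == 0) return(NA_real_)
  stats::cor(profile, v)
}

#' Correlate miRNAs with their predicted targets across stages
#'
#' @param mirna_tpm,gene_tpm TPM matrices sharing column (stage) order.
#' @param pairs data.frame with columns `mirna`, `gene`.
#' @return data.frame per pair: `pcc` and `sign_class` (`"negative"` iff
#'   PCC < 0, `"positive"` otherwise, `"not_classifiable"` when either
#'   profile is constant).
#' @export
mirna_target_correlation <- function(mirna_tpm, gene_tpm, pairs) {
  stopifnot(all(c("mirna", "gene") %in% names(pairs)))
  pcc <- numeric(nrow(pairs)); cls <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (!pairs$mirna[i] %in% rownames(mirna_tpm) ||
        !pairs$gene[i] %in% rownames(gene_tpm)) {
      pcc[i] <- NA_real_; cls[i] <- "not_classifiable"; next
    }
    mp <- as.numeric(mirna_tpm[pairs$mirna[i], ])
    gp <- as.numeric(gene_tpm[pairs$gene[i], ])
    if (stats::sd(mp) == 0 || stats::sd(gp) == 0) {
      pcc[i] <- NA_real_; cls[i] <- "not_classifiable"
    } else {
      pcc[i] <- stats::cor(mp, gp)
      cls[i] <- if (pcc[i] < 0) "negative" else "positive"
    }
  }
  data.frame(mirna = pairs$mirna, gene = pairs$gene, pcc = pcc,
             sign_class = cls, stringsAsFactors = FALSE)
}
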