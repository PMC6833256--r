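#' Median-of-ratios size factors
#'
#' For every gene with all-positive counts, compute the ratio of each
#' sample's count to the gene's geometric mean across samples; a sample's
#' size factor is the median of its ratios over those genes.
#'
#' @param cm a [count_matrix()].
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  k <- cm$counts
  pos <- rowSums(k > 0) == ncol(k)
  if (!any(pos))
    stop("size_factors: no gene with all-positive counts; ",
         "median-of-ratios normalization is undefined")
  kp <- k[pos, , drop = FALSE]
  gm <- exp(rowMeans(log(kp)))
  ratios <- kp / gm
  apply(ratios, 2, median)
}

#' Dispersion model with a mean-dependent trend
#'
#' Estimates gene-wise dispersions by method of moments on normalized
#' counts (floored at 1e-8), a common dispersion by maximizing the pooled
#' negative-binomial profile likelihood, empirical-Bayes-style shrunken
#' per-gene values (weighted combination with `prior_df` pseudo-degrees of
#' freedom toward the common value), and a linear trend
#' `alpha(mu) = a1 + a0/mu` fit by least squares of the gene-wise estimates
#' on `1/mu` (coefficients clipped at zero).
#'
#' @param cm a [count_matrix()].
#' @param sf per-sample size factors.
#' @param prior_df prior weight (pseudo residual df) pulling gene-wise
#'   dispersions toward the common one.
#' @return a `dispersion_model`: list with `a0`, `a1`, `per_gene_dispersion`,
#'   `common_dispersion`, `genewise_dispersion`, `fitted_mean`,
#'   `size_factors`.
#' @export
estimate_dispersion <- function(cm, sf, prior_df = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  k <- cm$counts
  gA <- cm$groups == "A"; gB <- cm$groups == "B"
  nA <- sum(gA); nB <- sum(gB)
  if (nA < 2 || nB < 2)
    stop("estimate_dispersion: need >= 2 samples per group ",
         "(dispersion is unidentifiable otherwise)")
  q <- sweep(k, 2, sf, "/")
  muA <- rowMeans(q[, gA, drop = FALSE]); muB <- rowMeans(q[, gB, drop = FALSE])
  mu <- rowMeans(q)

  # method-of-moments gene-wise dispersion, pooled over the two groups;
  # Var(k_ij/s_j) = mu/s_j + alpha * mu^2  =>  subtract the Poisson part
  mom_group <- function(idx, mug) {
    v <- apply(q[, idx, drop = FALSE], 1, var)
    shot <- mug * mean(1 / sf[idx])
    (v - shot) / mug^2
  }
  aA <- mom_group(gA, muA); aB <- mom_group(gB, muB)
  dfA <- nA - 1; dfB <- nB - 1
  genewise <- (dfA * aA + dfB * aB) / (dfA + dfB)
  genewise[!is.finite(genewise)] <- 0
  genewise <- pmax(genewise, 1e-8)

  # common dispersion: pooled NB profile likelihood over a log-alpha grid
  mu_fit <- k
  mu_fit[, gA] <- outer(muA, sf[gA]); mu_fit[, gB] <- outer(muB, sf[gB])
  keep <- mu > 0
  kv <- as.vector(k[keep, , drop = FALSE])
  mv <- as.vector(mu_fit[keep, , drop = FALSE])
  nz <- mv > 0
  kv <- kv[nz]; mv <- mv[nz]
  ll <- function(log_a) sum(dnbinom(kv, mu = mv, size = exp(-log_a), log = TRUE))
  opt <- optimize(ll, interval = log(c(1e-6, 10)), maximum = TRUE, tol = 1e-4)
  common <- exp(opt$maximum)

  d <- nA + nB - 2
  shrunk <- pmax((d * genewise + prior_df * common) / (d + prior_df), 1e-8)

  # least-squares trend of gene-wise alpha on 1/mu
  sel <- mu >= 1 & is.finite(genewise)
  x <- 1 / mu[sel]; y <- genewise[sel]
  fit_ls <- function() {
    xb <- mean(x); yb <- mean(y)
    b <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
    a <- yb - b * xb
    c(a0 = b, a1 = a)
  }
  cf <- fit_ls()
  if (cf["a0"] < 0 || cf["a1"] < 0) {
    # constrained refits on the boundary; keep the better SSE
    a1_only <- max(mean(y), 0)
    a0_only <- max(sum(x * y) / sum(x * x), 0)
    sse1 <- sum((y - a1_only)^2)
    sse0 <- sum((y - a0_only * x)^2)
    cf <- if (sse1 <= sse0) c(a0 = 0, a1 = a1_only) else c(a0 = a0_only, a1 = 0)
  }
  names(mu) <- names(genewise) <- names(shrunk) <- rownames(k)
  structure(list(a0 = unname(cf["a0"]), a1 = unname(cf["a1"]),
                 per_gene_dispersion = shrunk,
                 genewise_dispersion = genewise,
                 common_dispersion = common,
                 fitted_mean = mu, size_factors = sf),
            class = "dispersion_model")
}

#' Trend dispersion at a given mean
#' @param model a `dispersion_model`.
#' @param mu mean(s) on the normalized-count scale.
#' @return `a1 + a0/mu`.
#' @export
trend_dispersion <- function(model, mu) model$a1 + model$a0 / mu

#' Conditional negative-binomial exact test
#'
#' Tests whether the count sums of the two conditions are compatible with a
#' common mean. Conditional on the overall sum `k_a + k_b`, the p-value is
#' the total probability of all splits `(a, b)` whose probability does not
#' exceed that of the observed split, where the probability of a split is
#' the product of the NB masses of the two group sums (group sum of `n`
#' samples with per-sample mean `mu` and dispersion `alpha` is NB with mean
#' `n * mu` and size `n / alpha`). `dispersion <= 0` uses the Poisson limit,
#' which for equal group sizes reduces to a two-sided exact binomial test.
#'
#' @param k_a,k_b observed count sums in conditions A and B (on a common
#'   library scale).
#' @param n_a,n_b number of samples in each condition.
#' @param dispersion NB dispersion `alpha` (variance `mu + alpha mu^2`).
#' @return p-value in (0, 1].
#' @export
nb_exact_test <- function(k_a, k_b, n_a, n_b, dispersion) {
  if (k_a < 0 || k_b < 0) stop("nb_exact_test: negative counts")
  if (n_a < 1 || n_b < 1) stop("nb_exact_test: need samples in both groups")
  ks <- k_a + k_b
  if (ks == 0) return(1)
  mu_hat <- ks / (n_a + n_b)
  a <- 0:ks
  b <- ks - a
  if (dispersion <= 1e-12) {
    lp <- dpois(a, n_a * mu_hat, log = TRUE) + dpois(b, n_b * mu_hat, log = TRUE)
  } else {
    lp <- dnbinom(a, size = n_a / dispersion, mu = n_a * mu_hat, log = TRUE) +
      dnbinom(b, size = n_b / dispersion, mu = n_b * mu_hat, log = TRUE)
  }
  lobs <- lp[k_a + 1L]
  keep <- lp <= lobs + 1e-7
  m <- max(lp)
  p <- sum(exp(lp[keep] - m)) / sum(exp(lp - m))
  min(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (same order as input), capped at 1 and monotone
#'   non-decreasing in raw-p rank order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

.de_result <- function(gene, log2fc, p, method) {
  res <- data.frame(gene = gene, log2fc = log2fc, p_value = p,
                    adj_p_value = bh_adjust(p), stringsAsFactors = FALSE)
  attr(res, "method_name") <- method
  class(res) <- c("de_result", "data.frame")
  res
}

# shared exact-test loop over genes on rescaled counts
.exact_test_all <- function(cm, sf, disp_per_gene) {
  k <- cm$counts
  gA <- cm$groups == "A"; gB <- cm$groups == "B"
  q <- round(sweep(k, 2, sf, "/"))
  kA <- rowSums(q[, gA, drop = FALSE]); kB <- rowSums(q[, gB, drop = FALSE])
  nA <- sum(gA); nB <- sum(gB)
  p <- rep(1, nrow(k))
  nzero <- kA + kB > 0
  p[nzero] <- vapply(which(nzero), function(i)
    nb_exact_test(kA[i], kB[i], nA, nB, disp_per_gene[i]), numeric(1))
  qn <- sweep(k, 2, sf, "/")
  mA <- rowMeans(qn[, gA, drop = FALSE]); mB <- rowMeans(qn[, gB, drop = FALSE])
  lfc <- log2((mB + 0.5) / (mA + 0.5))
  lfc[!nzero] <- 0
  list(p = p, lfc = lfc)
}

#' DESeq-like differential expression
#'
#' Median-of-ratios size factors, mean-dispersion trend, and the
#' conditional NB exact test with the trend dispersion evaluated at each
#' gene's fitted normalized mean; BH-adjusted p-values.
#'
#' @param cm a [count_matrix()].
#' @return a `de_result` data.frame (gene, log2fc, p_value, adj_p_value).
#' @export
run_deseq_like <- function(cm) {
  sf <- size_factors(cm)
  dm <- estimate_dispersion(cm, sf)
  mu <- pmax(dm$fitted_mean, 1e-8)
  disp <- pmax(trend_dispersion(dm, mu), 1e-8)
  et <- .exact_test_all(cm, sf, disp)
  .de_result(rownames(cm$counts), et$lfc, et$p, "deseq_like")
}

#' edgeR-like differential expression
#'
#' Total-count normalization to the geometric-mean library size, gene-wise
#' dispersions shrunk toward the common dispersion (prior weight
#' `prior_df`), and the same conditional NB exact test; BH-adjusted.
#'
#' @param cm a [count_matrix()].
#' @param prior_df shrinkage weight toward the common dispersion.
#' @return a `de_result` data.frame.
#' @export
run_edger_like <- function(cm, prior_df = 10) {
  lib <- colSums(cm$counts)
  if (any(lib == 0)) stop("run_edger_like: sample with zero library size")
  sf <- lib / geometric_mean(lib)
  dm <- estimate_dispersion(cm, sf, prior_df = prior_df)
  et <- .exact_test_all(cm, sf, dm$per_gene_dispersion)
  .de_result(rownames(cm$counts), et$lfc, et$p, "edger_like")
}

#' Variance-stabilizing transformation
#'
#' With the variance-mean dependence `w(q) = q + alpha(q) q^2` and the trend
#' `alpha(q) = a1 + a0/q`, i.e. `w(q) = (1 + a0) q + a1 q^2`, the transform
#' integrates `dtau/dq = 1/sqrt(w(q))` in closed form:
#' `tau(q) = 2/sqrt(a1) * asinh(sqrt(a1 q / (1 + a0)))`, falling back to
#' `2 sqrt(q / (1 + a0))` when `a1 = 0`. Applied to size-factor-normalized
#' counts.
#'
#' @param cm a [count_matrix()].
#' @param model a `dispersion_model` (supplies `a0`, `a1`, size factors).
#' @return a `transformed_matrix` (values, no weights, transform "vst").
#' @export
vst_transform <- function(cm, model) {
  stopifnot(inherits(cm, "count_matrix"), inherits(model, "dispersion_model"))
  a0 <- model$a0; a1 <- model$a1
  cc <- 1 + a0
  if (!is.finite(cc) || cc <= 0 || a1 < 0)
    stop("vst_transform: fitted variance function is not monotone increasing")
  q <- sweep(cm$counts, 2, model$size_factors, "/")
  vals <- if (a1 <= 0) 2 * sqrt(q / cc) else
    (2 / sqrt(a1)) * asinh(sqrt(a1 * q / cc))
  transformed_matrix(vals, weights = NULL, transform_name = "vst",
                     groups = cm$groups)
}

#' Transformed expression matrix
#'
#' @param values numeric matrix (genes x samples).
#' @param weights optional positive observation weights, same shape.
#' @param transform_name "vst" or "logcpm".
#' @param groups two-group factor per sample.
#' @return an object of class `transformed_matrix`.
#' @export
transformed_matrix <- function(values, weights = NULL,
                               transform_name = c("vst", "logcpm"), groups) {
  transform_name <- match.arg(transform_name)
  if (!is.null(weights)) stopifnot(all(dim(weights) == dim(values)))
  if (transform_name == "logcpm" && is.null(weights))
    stop("transformed_matrix: logcpm (voom) requires weights")
  if (transform_name == "vst" && !is.null(weights))
    stop("transformed_matrix: vst carries no weights")
  structure(list(values = values, weights = weights,
                 transform_name = transform_name,
                 groups = factor(groups, levels = c("A", "B"))),
            class = "transformed_matrix")
}

#' voom-style log-cpm transform with precision weights
#'
#' Computes `log2((count + 0.5) / (libsize + 1) * 1e6)`, fits the residual
#' standard deviation of the two-group model against average log2 count
#' size with a deterministic binned-median smoother on the `sqrt(sd)` scale
#' (20 equal-count bins, linear interpolation, flat extrapolation), and
#' assigns each observation the weight `trend(predicted log-count)^-4`.
#'
#' @param cm a [count_matrix()].
#' @return a `transformed_matrix` (values, weights, transform "logcpm").
#' @export
voom_transform <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  k <- cm$counts
  if (nrow(k) < 10)
    stop("voom_transform: need >= 10 genes to fit the variance trend")
  lib <- colSums(k)
  logcpm <- log2(sweep(k + 0.5, 2, lib + 1, "/") * 1e6)
  gA <- cm$groups == "A"; gB <- cm$groups == "B"
  fitA <- rowMeans(logcpm[, gA, drop = FALSE])
  fitB <- rowMeans(logcpm[, gB, drop = FALSE])
  fitted <- logcpm
  fitted[, gA] <- fitA; fitted[, gB] <- fitB
  d <- ncol(k) - 2
  sdres <- sqrt(rowSums((logcpm - fitted)^2) / d)
  # x-axis: average log2 count size
  xbar <- rowMeans(logcpm) + mean(log2(lib + 1)) - log2(1e6)
  s4 <- sqrt(sdres)
  nb <- min(20L, max(2L, floor(nrow(k) / 5)))
  br <- quantile(xbar, probs = seq(0, 1, length.out = nb + 1), names = FALSE)
  bin <- cut(xbar, breaks = unique(br), include.lowest = TRUE)
  bx <- tapply(xbar, bin, median)
  by <- tapply(s4, bin, median)
  ok <- is.finite(bx) & is.finite(by)
  bx <- bx[ok]; by <- by[ok]
  trend <- if (length(bx) >= 2)
    stats::approxfun(bx, by, rule = 2) else function(x) rep(by[1], length(x))
  pred_logcount <- sweep(fitted, 2, log2(lib + 1) - log2(1e6), "+")
  pred_sd4 <- pmax(trend(pred_logcount), 1e-6)
  w <- matrix(pred_sd4^-4, nrow = nrow(k), dimnames = dimnames(k))
  transformed_matrix(logcpm, weights = w, transform_name = "logcpm",
                     groups = cm$groups)
}

# Newton solver for trigamma(x) = y (limma-style closed-form EB route)
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Moderated two-group t-test
#'
#' Per-gene (weighted) two-group linear model; residual variances are
#' shrunk toward a common prior `s0^2` with prior degrees of freedom `d0`
#' estimated by matching moments of `log s^2` to a scaled F distribution
#' (digamma/trigamma closed forms); moderated t with `d0 + d` degrees of
#' freedom and BH adjustment. `d0` is capped at 1e6 to represent infinity.
#'
#' @param tm a `transformed_matrix`.
#' @param method_name label stored in the result.
#' @param prior_df optional override of the estimated `d0` (0 gives the
#'   ordinary t-test; `Inf` replaces every gene variance by `s0^2`).
#' @return a `de_result` data.frame; `log2fc` is the (weighted) group-mean
#'   difference on the transformed scale.
#' @export
moderated_t <- function(tm, method_name = "moderated_t", prior_df = NULL) {
  stopifnot(inherits(tm, "transformed_matrix"))
  x <- tm$values
  w <- tm$weights
  if (is.null(w)) w <- matrix(1, nrow(x), ncol(x))
  gA <- tm$groups == "A"; gB <- tm$groups == "B"
  n <- ncol(x); d <- n - 2
  if (d <= 0) stop("moderated_t: zero residual degrees of freedom")
  WA <- rowSums(w[, gA, drop = FALSE]); WB <- rowSums(w[, gB, drop = FALSE])
  mA <- rowSums((w * x)[, gA, drop = FALSE]) / WA
  mB <- rowSums((w * x)[, gB, drop = FALSE]) / WB
  fitted <- x
  fitted[, gA] <- mA; fitted[, gB] <- mB
  s2 <- rowSums(w * (x - fitted)^2) / d
  beta <- mB - mA
  u2 <- 1 / WA + 1 / WB

  pos <- s2 > 0
  z <- log(s2[pos])
  e <- z - digamma(d / 2) + log(d / 2)
  if (length(e) >= 2) {
    evar <- var(e) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * .trigamma_inverse(evar)
    } else d0 <- Inf
    s02 <- exp(mean(e) + (if (is.finite(d0)) digamma(d0 / 2) - log(d0 / 2) else 0))
  } else { d0 <- Inf; s02 <- mean(s2) }
  if (!is.null(prior_df)) d0 <- prior_df
  d0 <- min(d0, 1e6)
  s2_post <- if (d0 == 0) s2 else (d0 * s02 + d * s2) / (d0 + d)
  df_total <- min(d0 + d, 1e6)
  tstat <- beta / sqrt(s2_post * u2)
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[!is.finite(p)] <- 1
  .de_result(rownames(x), beta, p, method_name)
}

#' VST + moderated-t differential expression
#'
#' Size factors, dispersion trend, [vst_transform()], then [moderated_t()].
#' The reported `log2fc` is recomputed on size-factor-normalized counts
#' (`log2((meanB + 0.5) / (meanA + 0.5))`) so it is comparable across
#' methods.
#'
#' @param cm a [count_matrix()].
#' @return a `de_result` data.frame.
#' @export
run_vst_like <- function(cm) {
  sf <- size_factors(cm)
  dm <- estimate_dispersion(cm, sf)
  tm <- vst_transform(cm, dm)
  res <- moderated_t(tm, method_name = "vst_like")
  q <- sweep(cm$counts, 2, sf, "/")
  gA <- cm$groups == "A"; gB <- cm$groups == "B"
  res$log2fc <- log2((rowMeans(q[, gB, drop = FALSE]) + 0.5) /
                     (rowMeans(q[, gA, drop = FALSE]) + 0.5))
  res
}

#' voom + moderated-t differential expression
#'
#' [voom_transform()] followed by the weighted [moderated_t()]; `log2fc` is
#' the difference in group-mean log-cpm.
#'
#' @param cm a [count_matrix()].
#' @return a `de_result` data.frame.
#' @export
run_voom_like <- function(cm) {
  tm <- voom_transform(cm)
  moderated_t(tm, method_name = "voom_like")
}

#' The four implemented DE methods
#' @export
DE_METHODS <- c("deseq_like", "edger_like", "vst_like", "voom_like")

#' Run one DE method by name
#' @param cm a [count_matrix()].
#' @param method one of `DE_METHODS`.
#' @return a `de_result` data.frame.
#' @export
run_de_method <- function(cm, method = DE_METHODS) {
  method <- match.arg(method)
  switch(method,
         deseq_like = run_deseq_like(cm),
         edger_like = run_edger_like(cm),
         vst_like = run_vst_like(cm),
         voom_like = run_voom_like(cm))
}

#' Threshold a DE result into a gene set
#'
#' Strict inequality: `adj_p < alpha`.
#'
#' @param res a `de_result`.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return a `de_gene_set`: list with `method_name`, `genes`, `alpha`.
#' @export
significant_genes <- function(res, alpha = 0.05) {
  stopifnot(inherits(res, "de_result"))
  de_gene_set(attr(res, "method_name"),
              res$gene[res$adj_p_value < alpha], alpha)
}

#' Construct a DE gene set
#' @param method_name method label.
#' @param genes character vector of significant gene ids.
#' @param alpha threshold used.
#' @return an object of class `de_gene_set`.
#' @export
de_gene_set <- function(method_name, genes, alpha = 0.05) {
  structure(list(method_name = method_name,
                 genes = unique(as.character(genes)), alpha = alpha),
            class = "de_gene_set")
}
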