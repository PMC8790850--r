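#' Per-OTU occurrence frequency and mean relative abundance
#'
#' The two statistics the Sloan neutral community model relates: each OTU's
#' mean relative abundance across samples (its stand-in for metacommunity
#' abundance) and its detection frequency (fraction of samples with at
#' least one read). Requires a rarefied table so that the detection limit
#' is the same in every sample.
#'
#' @param table rarefied OTU count matrix (equal row sums).
#' @return data.frame with `otu_id`, `p` (mean relative abundance), `f`
#'   (occurrence frequency).
#' @export
occurrence_abundance <- function(table) {
  validate_otu_table(table)
  depths <- unique(rowSums(table))
  if (length(depths) != 1L)
    stop("table is not rarefied: row sums range ",
         min(depths), "-", max(depths))
  data.frame(otu_id = colnames(table),
             p = colMeans(table / depths),
             f = colMeans(table > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Neutral-model occurrence frequency prediction
#'
#' Under the Sloan model, the long-run relative abundance of a taxon in a
#' local community of size N with migration parameter Nm follows
#' Beta(Nm p, Nm (1 - p)), where p is its metacommunity relative abundance.
#' The predicted occurrence frequency is the probability of exceeding the
#' detection limit d = 1/N:
#' f_hat = 1 - pbeta(d, Nm p, Nm (1 - p)).
#'
#' @param p metacommunity relative abundance(s) in \[0, 1\].
#' @param Nm migration parameter (metacommunity size x migration rate).
#' @param N local community size (reads per sample after rarefaction).
#' @return predicted frequency in \[0, 1\], vectorized over `p`.
#' @export
predict_frequency <- function(p, Nm, N) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (Nm <= 0) stop("Nm must be positive")
  if (N <= 0) stop("N must be positive")
  d <- 1 / N
  out <- 1 - stats::pbeta(d, Nm * p, Nm * (1 - p))
  out[p == 0] <- 0
  out[p == 1] <- 1
  out
}

#' Fit the Sloan neutral community model
#'
#' Estimates Nm by bounded nonlinear least squares of the predicted
#' occurrence frequency against the observed one over all OTUs with
#' nonzero mean abundance, using a multi-start over Nm in
#' \{1e2, 1e3, 1e4, 1e5\} on the log scale. Reports R2 (may be negative:
#' worse than the constant mean-frequency model; not clamped), the 99%
#' prediction envelope per OTU, and each OTU's category relative to the
#' envelope (within / above / below).
#'
#' The envelope is the 0.5% and 99.5% quantile band of the sampling
#' distribution of observed frequency given the fitted per-OTU detection
#' probability f_hat and the number of samples n: detections are iid
#' Bernoulli(f_hat) across samples, so the band is Binomial(n, f_hat)
#' quantiles divided by n (`envelope = "binomial"`, default), or the Wilson
#' score interval at the same level (`envelope = "wilson"`). Bounds are
#' clamped to contain f_hat (binomial discreteness can otherwise push a
#' quantile marginally past the mean).
#'
#' @param table rarefied OTU count matrix.
#' @param ci_level envelope coverage level (default 0.99).
#' @param envelope `"binomial"` or `"wilson"`.
#' @return object of class `neutral_fit`: list with `Nm`, `m`, `N`, `R2`,
#'   `detection_limit`, `ci_level`, `envelope`, `n_samples`, and `otu`
#'   (data.frame: otu_id, p, f, f_hat, envelope_low, envelope_high,
#'   category).
#' @export
fit_sloan <- function(table, ci_level = 0.99,
                      envelope = c("binomial", "wilson")) {
  envelope <- match.arg(envelope)
  oa <- occurrence_abundance(table)
  n <- nrow(table)
  if (n < 10L)
    warning("only ", n, " samples; the neutral fit is unstable below 10")
  N <- unique(rowSums(table))
  d <- 1 / N
  fit_dat <- oa[oa$p > 0, , drop = FALSE]
  if (nrow(fit_dat) < 3L) stop("too few OTUs with nonzero abundance to fit")

  nls_fit <- sloan_nls(fit_dat$p, fit_dat$f, N)
  Nm <- nls_fit$Nm

  f_hat <- predict_frequency(fit_dat$p, Nm, N)
  sst <- sum((fit_dat$f - mean(fit_dat$f))^2)
  r2 <- 1 - nls_fit$sse / sst

  env <- sloan_envelope(f_hat, n, ci_level, envelope)
  lo <- env$lo
  hi <- env$hi
  category <- ifelse(fit_dat$f > hi, "above",
                     ifelse(fit_dat$f < lo, "below", "within"))

  structure(list(
    Nm = Nm, N = N, m = Nm / N, R2 = r2, detection_limit = d,
    ci_level = ci_level, envelope = envelope, n_samples = n,
    otu = data.frame(otu_id = fit_dat$otu_id, p = fit_dat$p, f = fit_dat$f,
                     f_hat = f_hat, envelope_low = lo, envelope_high = hi,
                     category = category, row.names = NULL,
                     stringsAsFactors = FALSE)
  ), class = "neutral_fit")
}

# bounded NLS of the Sloan occurrence model on (p, f) pairs, multi-start on
# log(Nm) from 1e2..1e5
sloan_nls <- function(p, f, N) {
  sse <- function(log_nm)
    sum((f - predict_frequency(p, exp(log_nm), N))^2)
  starts <- log(c(1e2, 1e3, 1e4, 1e5))
  fits <- lapply(starts, function(s)
    tryCatch(stats::nlminb(s, sse, lower = log(1e-2), upper = log(1e10)),
             error = function(e) NULL))
  fits <- Filter(function(x) !is.null(x) && is.finite(x$objective), fits)
  if (!length(fits))
    stop("neutral-model fit failed to converge from all starting points")
  best <- fits[[which.min(vapply(fits, `[[`, 0, "objective"))]]
  list(Nm = exp(best$par), sse = best$objective)
}

# quantile band of the sampling distribution of observed frequency given a
# per-OTU detection probability f_hat over n samples
sloan_envelope <- function(f_hat, n, ci_level = 0.99,
                           method = c("binomial", "wilson")) {
  method <- match.arg(method)
  alpha <- (1 - ci_level) / 2
  if (method == "binomial") {
    lo <- stats::qbinom(alpha, n, f_hat) / n
    hi <- stats::qbinom(1 - alpha, n, f_hat) / n
  } else {
    z <- stats::qnorm(1 - alpha)
    centre <- (f_hat + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(f_hat * (1 - f_hat) / n + z^2 / (4 * n^2)) /
      (1 + z^2 / n)
    lo <- pmax(0, centre - half)
    hi <- pmin(1, centre + half)
  }
  # discreteness can push a quantile marginally past the mean; the band
  # must contain the prediction itself
  list(lo = pmin(lo, f_hat), hi = pmax(hi, f_hat))
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  Nm = %.1f (m = %.4g, N = %d), R2 = %.3f\n",
              x$Nm, x$m, as.integer(x$N), x$R2))
  cat(sprintf("  %d OTUs over %d samples; %s %d%% envelope\n",
              nrow(x$otu), x$n_samples, x$envelope,
              round(100 * x$ci_level)))
  print(table(x$otu$category))
  invisible(x)
}

#' Envelope categories of high-abundance OTUs
#'
#' Proportions of OTUs above the abundance threshold (default mean relative
#' abundance > 1e-3, the high-abundance cut used for the pie-chart
#' summaries) falling within, above, and below the neutral prediction
#' envelope.
#'
#' @param fit a `neutral_fit`.
#' @param min_mean_abundance strict abundance threshold.
#' @return named list of three fractions summing to 1, plus `n_otus`.
#' @export
abundant_otu_categories <- function(fit, min_mean_abundance = 0.001) {
  stopifnot(inherits(fit, "neutral_fit"))
  sub <- fit$otu[fit$otu$p > min_mean_abundance, , drop = FALSE]
  if (!nrow(sub))
    stop("no OTU exceeds mean abundance ", min_mean_abundance)
  list(within = mean(sub$category == "within"),
       above = mean(sub$category == "above"),
       below = mean(sub$category == "below"),
       n_otus = nrow(sub))
}

#' Write the per-OTU neutral-fit table as TSV
#'
#' @param fit a `neutral_fit`.
#' @param path output path.
#' @export
write_neutral_fit_table <- function(fit, path) {
  stopifnot(inherits(fit, "neutral_fit"))
  utils::write.table(fit$otu, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
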