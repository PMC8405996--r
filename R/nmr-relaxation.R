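# NMR spin relaxation: exponential fitting with replicate-based
# uncertainties, NOE ratios, the R1R2 product, combined chemical shift
# perturbations, and trimmed-mean outlier calling with Spearman rho.

#' Pooled intensity noise from duplicate relaxation delays
#'
#' Replicate spectra at duplicate delays estimate the peak-height noise:
#' `sigma_I = sd(replicate differences pooled across residues) / sqrt(2)`,
#' since the difference of two equal-noise measurements has variance
#' `2 * sigma_I^2`.
#'
#' @param series a T1/T2 [RelaxationSeries-class] containing replicate rows.
#' @return estimated intensity noise (same units as intensity), or NA if no
#'   duplicate delays are present.
#' @export
replicateNoiseSd <- function(series) {
  r <- series@records
  rep2 <- r[r$replicate == 2L, ]
  if (nrow(rep2) == 0) return(NA_real_)
  diffs <- vapply(seq_len(nrow(rep2)), function(i) {
    prim <- r$intensity[r$replicate == 1L &
                        r$residue == rep2$residue[i] &
                        r$delay_s == rep2$delay_s[i]]
    if (length(prim) == 0) return(NA_real_)
    rep2$intensity[i] - prim[1]
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2) return(NA_real_)
  sqrt(mean(diffs^2)) / sqrt(2)
}

#' Fit a single-exponential decay
#'
#' Nonlinear least squares fit of `I(t) = I0 * exp(-R * t)` over `(I0, R)`,
#' started from a log-linear regression. The rate uncertainty comes from the
#' fit covariance; when the per-point intensity noise `sigmaI` is supplied
#' (e.g. from [replicateNoiseSd()]) the covariance uses that known noise
#' instead of the residual variance estimate, which keeps per-residue
#' uncertainties stable for short delay schedules.
#'
#' @param delay numeric delays, seconds (>= 3 distinct values).
#' @param intensity peak heights at those delays.
#' @param sigmaI known intensity noise (single value) or NA to estimate from
#'   residuals.
#' @return list with `rate` (s^-1), `rateSd`, `I0`, `I0Sd`, and `negative`
#'   (TRUE when the fitted rate is negative; flagged, never clamped).
#' @export
fitExponentialDecay <- function(delay, intensity, sigmaI = NA) {
  if (length(unique(delay)) < 3)
    stop("need at least 3 distinct delays")
  if (all(intensity == 0)) stop("intensities are all zero")
  # start values: log-linear fit on positive intensities, fallback flat
  pos <- intensity > 0
  start <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(intensity[pos]) ~ delay[pos]))
    list(I0 = exp(cf[[1]]), R = -cf[[2]])
  } else list(I0 = max(abs(intensity)), R = 1)
  if (!is.finite(start$R)) start$R <- 1

  df <- data.frame(t = delay, I = intensity)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ I0 * exp(-R * t), data = df,
                      start = list(I0 = start$I0, R = start$R),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  # covariance of (I0, R): J'J scaled by known noise if available
  J <- cbind(exp(-cf["R"] * delay),
             -cf["I0"] * delay * exp(-cf["R"] * delay))
  s2 <- if (is.finite(sigmaI) && !is.na(sigmaI) && sigmaI > 0) sigmaI^2
        else sum(stats::resid(fit)^2) / max(length(delay) - 2, 1)
  covm <- tryCatch(s2 * solve(crossprod(J)), error = function(e)
    matrix(NA_real_, 2, 2))
  list(rate = unname(cf["R"]), rateSd = sqrt(covm[2, 2]),
       I0 = unname(cf["I0"]), I0Sd = sqrt(covm[1, 1]),
       negative = unname(cf["R"]) < 0)
}

#' Fit relaxation rates for every residue of a series
#'
#' Fits each residue's decay with [fitExponentialDecay()], using the pooled
#' replicate noise of the whole series for the per-residue rate
#' uncertainties. Non-converging residues are reported (warning) and
#' returned with NA rates rather than dropped silently.
#'
#' @param series a T1/T2 [RelaxationSeries-class].
#' @return data.frame: `residue`, `rate` (s^-1), `rateSd`, `I0`,
#'   `negative`.
#' @export
fitRelaxationRates <- function(series) {
  stopifnot(series@kind %in% c("T1", "T2"))
  r <- series@records
  sigmaI <- replicateNoiseSd(series)
  out <- lapply(split(r, r$residue), function(rr) {
    fit <- tryCatch(
      fitExponentialDecay(rr$delay_s, rr$intensity, sigmaI = sigmaI),
      error = function(e) {
        warning("residue ", rr$residue[1], ": ", conditionMessage(e))
        list(rate = NA_real_, rateSd = NA_real_, I0 = NA_real_,
             negative = NA)
      })
    data.frame(residue = rr$residue[1], rate = fit$rate,
               rateSd = fit$rateSd, I0 = fit$I0, negative = fit$negative)
  })
  res <- do.call(rbind, out)
  res <- res[order(suppressWarnings(as.numeric(res$residue)),
                   res$residue), ]
  rownames(res) <- NULL
  res
}

#' Heteronuclear NOE from saturated/reference peak heights
#'
#' @param saturated,reference peak heights (vectors align elementwise).
#' @param saturatedSd,referenceSd optional peak-height noise for first-order
#'   uncertainty propagation.
#' @return data.frame with `noe` and `noeSd` (NA when noise not given).
#'   Negative NOEs are preserved. Zero reference heights are an error.
#' @export
computeNOE <- function(saturated, reference, saturatedSd = NA,
                       referenceSd = NA) {
  if (any(reference == 0))
    stop("zero reference intensity at index ",
         which(reference == 0)[1])
  noe <- saturated / reference
  noeSd <- if (all(is.na(saturatedSd))) rep(NA_real_, length(noe))
    else abs(noe) * sqrt((saturatedSd / saturated)^2 +
                         (referenceSd / reference)^2)
  data.frame(noe = noe, noeSd = noeSd)
}

#' R1R2 product with first-order uncertainty propagation
#'
#' The elementwise product `R1 * R2` suppresses contributions from
#' anisotropic molecular tumbling, highlighting chemical-exchange effects.
#' Residues missing either rate are dropped and reported via the
#' `"skipped"` attribute.
#'
#' @param r1,r2 data.frames from [fitRelaxationRates()] (columns `residue`,
#'   `rate`, `rateSd`).
#' @return data.frame: `residue`, `r1`, `r2`, `r1r2` (s^-2), `r1r2Sd`.
#' @export
r1r2Product <- function(r1, r2) {
  m <- merge(r1, r2, by = "residue", suffixes = c(".1", ".2"))
  ok <- !is.na(m$rate.1) & !is.na(m$rate.2)
  skipped <- m$residue[!ok]
  m <- m[ok, ]
  out <- data.frame(
    residue = m$residue, r1 = m$rate.1, r2 = m$rate.2,
    r1r2 = m$rate.1 * m$rate.2,
    r1r2Sd = sqrt((m$rateSd.1 * m$rate.2)^2 + (m$rate.1 * m$rateSd.2)^2))
  out <- out[order(suppressWarnings(as.numeric(out$residue)),
                   out$residue), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Combined 1H-15N chemical shift perturbation
#'
#' `ddelta = sqrt(ddeltaH^2 + (w * ddeltaN)^2)` with the community-standard
#' nitrogen scaling `w = 0.14` by default.
#'
#' @param dH,dN proton and nitrogen shift differences, ppm (vectors).
#' @param w nitrogen weight.
#' @return combined perturbation, ppm (>= 0; 0 iff both components are 0).
#' @export
#' @examples
#' combinedCSP(0.05, 0.5)  # 0.0860 ppm
combinedCSP <- function(dH, dN, w = 0.14) {
  sqrt(dH^2 + (w * dN)^2)
}

#' Chemical shift perturbations between two peak lists
#'
#' Pairs residues by id; residues present in the reference but missing in
#' the variant are reported as broadened (line-broadening annotations are
#' input facts, not inferred from intensities).
#'
#' @param reference,variant data.frames with columns `residue`, `dH`, `dN`
#'   (peak positions, ppm).
#' @param w nitrogen weight for [combinedCSP()].
#' @return data.frame: `residue`, `dH`, `dN` (differences), `csp`,
#'   `broadened`.
#' @export
shiftPerturbations <- function(reference, variant, w = 0.14) {
  m <- merge(reference, variant, by = "residue",
             suffixes = c(".ref", ".var"), all.x = TRUE)
  broad <- is.na(m$dH.var)
  ddH <- m$dH.var - m$dH.ref
  ddN <- m$dN.var - m$dN.ref
  out <- data.frame(residue = m$residue, dH = ddH, dN = ddN,
                    csp = ifelse(broad, NA_real_, combinedCSP(ddH, ddN, w)),
                    broadened = broad)
  out[order(suppressWarnings(as.numeric(out$residue)), out$residue), ]
}

#' Trimmed-mean / sigma significance threshold on a residue profile
#'
#' The "10 percent trimmed mean" removes the lowest 5 percent and highest
#' 5 percent of values; sigma is the standard deviation of the full
#' (untrimmed) profile. Values above `trimmedMean + nSigma * sigma` are
#' significant.
#'
#' @param values named numeric per-residue profile (>= 10 values).
#' @param trim total trimmed fraction (default 0.10, i.e. 0.05 per tail).
#' @param nSigma threshold multiplier (default 1.5).
#' @return list with `trimmedMean`, `sigma`, `threshold`, `significant`
#'   (names or indices of significant values).
#' @export
thresholdProfile <- function(values, trim = 0.10, nSigma = 1.5) {
  vals <- values[!is.na(values)]
  if (length(vals) < 10) stop("need at least 10 residues")
  tm <- mean(vals, trim = trim / 2)
  s <- stats::sd(vals)
  thr <- tm + nSigma * s
  sig <- if (!is.null(names(vals))) names(vals)[vals > thr]
         else which(values %in% vals[vals > thr] & !is.na(values))
  list(trimmedMean = tm, sigma = s, threshold = thr, significant = sig)
}

#' Outlier calling on a wt-versus-variant correlation diagram
#'
#' For per-residue profiles of a reference (wild type) and a variant (e.g.
#' R1R2 products or NOE values), the deviation of each residue from the
#' perfect-correlation line x = y is `variant - reference` (the
#' perpendicular offset up to a sqrt(2) factor; set
#' `perpendicular = TRUE` to divide by sqrt(2)). Residues whose deviation
#' falls outside `nSigma` times the untrimmed sigma of the 10 percent
#' trimmed mean of the deviations are flagged; Spearman rho is computed over
#' all paired residues.
#'
#' @param reference,variant named numeric per-residue profiles (>= 10 common
#'   residues).
#' @param nSigma flag threshold multiplier (default 1.5).
#' @param trim total trimmed fraction for the deviation mean (default 0.10).
#' @param perpendicular report perpendicular distances instead of simple
#'   differences.
#' @return an [OutlierReport-class].
#' @export
correlationOutliers <- function(reference, variant, nSigma = 1.5,
                                trim = 0.10, perpendicular = FALSE) {
  if (is.null(names(reference)) || is.null(names(variant)))
    stop("profiles must be named by residue")
  common <- intersect(names(reference), names(variant))
  common <- common[!is.na(reference[common]) & !is.na(variant[common])]
  if (length(common) < 10)
    stop("insufficient overlap: only ", length(common),
         " residues present in both profiles")
  dev <- variant[common] - reference[common]
  if (perpendicular) dev <- dev / sqrt(2)
  tm <- mean(dev, trim = trim / 2)
  s <- stats::sd(dev)
  flagged <- if (s == 0) rep(FALSE, length(dev))
             else abs(dev - tm) > nSigma * s
  rho <- stats::cor(reference[common], variant[common],
                    method = "spearman")
  new("OutlierReport", residue = common, deviation = unname(dev),
      trimmedMean = tm, sigma = s, flagged = unname(flagged), rho = rho,
      nSigma = nSigma)
}

#' Read a relaxation table from CSV
#'
#' Expected columns: `residue`, `delay_s`, `intensity`, `replicate`.
#'
#' @param path CSV file.
#' @param kind "T1" or "T2".
#' @return a [RelaxationSeries-class].
#' @export
readRelaxationCSV <- function(path, kind = c("T1", "T2")) {
  kind <- match.arg(kind)
  r <- utils::read.csv(path)
  new("RelaxationSeries", kind = kind, records = r,
      metadata = list(source = path))
}

#' Write a relaxation series to CSV
#'
#' @param series a [RelaxationSeries-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRelaxationCSV <- function(series, path) {
  utils::write.csv(series@records, path, row.names = FALSE)
  invisible(path)
}

#' Read a Sparky-style peak list
#'
#' Tab- or whitespace-delimited with a header line: assignment (e.g.
#' `S62N-H`), w1 (ppm, 15N), w2 (ppm, 1H) and optionally height. Residue
#' numbers are extracted from the assignment.
#'
#' @param path peak-list file.
#' @return data.frame: `residue` (integer), `dN`, `dH`, `height` (NA when
#'   absent).
#' @export
readSparkyPeaks <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  ln <- ln[-1]                          # header
  toks <- lapply(ln, function(l) scan(text = l, what = "", quiet = TRUE))
  data.frame(
    residue = vapply(toks, function(t)
      as.integer(gsub("[^0-9]", "", sub("-.*$", "", t[1]))), integer(1)),
    dN = vapply(toks, function(t) as.numeric(t[2]), numeric(1)),
    dH = vapply(toks, function(t) as.numeric(t[3]), numeric(1)),
    height = vapply(toks, function(t)
      if (length(t) >= 4) as.numeric(t[4]) else NA_real_, numeric(1)))
}
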