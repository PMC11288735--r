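# Fiber-FISH quantitation: micrometer measurements on stretched DNA fibers
# convert to kilobases by a calibration rate (default 3.21 kb/um).

#' Convert a fiber-FISH length from micrometers to kilobases
#'
#' @param lengthUm Measurement(s) in micrometers (>= 0).
#' @param rate Conversion rate in kb per micrometer (default 3.21).
#' @return Length(s) in kb.
#' @examples
#' umToKb(215.1)  # 690.5 kb at 1-decimal reporting
#' @export
umToKb <- function(lengthUm, rate = 3.21) {
  if (rate <= 0) stop("rate must be positive")
  if (any(lengthUm < 0)) stop("negative length")
  lengthUm * rate
}

#' Summarize a set of fiber-FISH signal measurements
#'
#' Mean and sample (n - 1) standard deviation in micrometers and, after
#' conversion, in kilobases.
#'
#' @param lengthsUm Measurements in micrometers (n >= 2).
#' @param rate kb per micrometer.
#' @return A one-row data.frame with columns \code{n}, \code{mean_um},
#'   \code{sd_um}, \code{mean_kb}, \code{sd_kb}.
#' @export
fiberSummary <- function(lengthsUm, rate = 3.21) {
  if (length(lengthsUm) < 2L) stop("need at least 2 measurements")
  if (any(lengthsUm < 0)) stop("negative length")
  data.frame(n = length(lengthsUm),
             mean_um = mean(lengthsUm),
             sd_um = stats::sd(lengthsUm),
             mean_kb = umToKb(mean(lengthsUm), rate),
             sd_kb = umToKb(stats::sd(lengthsUm), rate))
}

#' Genome-wide centromere-size extrapolation
#'
#' Multiplies the mean centromere size (kb) by the chromosome number and
#' reports megabases.
#'
#' @param meanKb Mean centromere size in kb (> 0).
#' @param nChromosomes Number of chromosomes (> 0).
#' @return Total in Mb.
#' @export
genomeTotalEstimate <- function(meanKb, nChromosomes) {
  if (meanKb <= 0 || nChromosomes <= 0)
    stop("inputs must be positive")
  meanKb * nChromosomes / 1000
}
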