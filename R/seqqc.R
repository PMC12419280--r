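#' Per-position FASTQ quality, base-composition and error-rate profiles
#'
#' Reads a FASTQ file (Phred+33, optionally gzipped; reads must share one
#' length) and computes, per read position, the mean Phred quality, the
#' A/C/G/T/N base fractions (summing to 1) and the mean sequencing error rate
#' `mean(10^(-Q/10))`.
#'
#' @param path FASTQ file path.
#' @return Data frame with columns `position`, `mean_qual`, `frac_a`,
#'   `frac_c`, `frac_g`, `frac_t`, `frac_n`, `error_rate`.
#' @export
fastq_profiles <- function(path) {
  reads <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = "phred")),
    error = function(e) stop("malformed FASTQ at ", path, ": ",
                             conditionMessage(e)))
  if (length(reads) == 0) stop("no reads in ", path)
  widths <- Biostrings::width(reads)
  if (length(unique(widths)) != 1)
    stop("reads must share one length (pad variable-length reads); found ",
         length(unique(widths)), " distinct lengths")
  w <- widths[1]
  cm <- Biostrings::consensusMatrix(reads, as.prob = TRUE)
  pick <- function(b) if (b %in% rownames(cm)) cm[b, ] else rep(0, w)
  ql <- methods::as(Biostrings::quality(reads), "IntegerList")
  qm <- matrix(unlist(ql), nrow = length(reads), byrow = TRUE)
  data.frame(position = seq_len(w),
             mean_qual = colMeans(qm),
             frac_a = pick("A"), frac_c = pick("C"),
             frac_g = pick("G"), frac_t = pick("T"),
             frac_n = pick("N"),
             error_rate = colMeans(10^(-qm / 10)))
}

#' Per-sample sequencing QC gate
#'
#' A sample passes when raw yield is at least 6 gigabases, the Q30 base
#' fraction at least 0.80, mean target-region depth at least 50x and the
#' fraction of target bases covered at 10x or more at least 0.90 (all bounds
#' inclusive). Failures list each violated gate; the gate is reported, not
#' enforced.
#'
#' @param raw_gigabases Raw sequencing yield in gigabases.
#' @param q30_fraction Proportion of bases with Phred quality >= 30.
#' @param mean_target_depth Mean fold-coverage of the target region.
#' @param frac_ge_10x Proportion of target bases covered at >= 10x.
#' @param thresholds Named list overriding any of `raw_gigabases`,
#'   `q30_fraction`, `mean_target_depth`, `frac_ge_10x`.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   violated gates, empty on pass).
#' @export
#' @examples
#' qc_gate(6.5, 0.85, 60, 0.92)$pass   # TRUE
#' qc_gate(5.9, 0.85, 60, 0.92)$reasons
qc_gate <- function(raw_gigabases, q30_fraction, mean_target_depth,
                    frac_ge_10x, thresholds = list()) {
  th <- utils::modifyList(list(raw_gigabases = 6, q30_fraction = 0.80,
                               mean_target_depth = 50, frac_ge_10x = 0.90),
                          thresholds)
  stopifnot(q30_fraction >= 0, q30_fraction <= 1,
            frac_ge_10x >= 0, frac_ge_10x <= 1, mean_target_depth >= 0)
  reasons <- character(0)
  if (raw_gigabases < th$raw_gigabases)
    reasons <- c(reasons, sprintf("raw volume %.2f Gb < %.2f Gb",
                                  raw_gigabases, th$raw_gigabases))
  if (q30_fraction < th$q30_fraction)
    reasons <- c(reasons, sprintf("Q30 fraction %.3f < %.3f",
                                  q30_fraction, th$q30_fraction))
  if (mean_target_depth < th$mean_target_depth)
    reasons <- c(reasons, sprintf("mean depth %.1fx < %.1fx",
                                  mean_target_depth, th$mean_target_depth))
  if (frac_ge_10x < th$frac_ge_10x)
    reasons <- c(reasons, sprintf("fraction >=10x %.3f < %.3f",
                                  frac_ge_10x, th$frac_ge_10x))
  list(pass = length(reasons) == 0, reasons = reasons)
}
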