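#' qPCR replicate averaging
#'
#' Averages the duplicate cycle-quantification (Cq) values of a PNA-clamp
#' qPCR measurement. Samples are run in duplicate with and without the PNA
#' clamp; when only one +PNA replicate amplified, that replicate is used,
#' and when neither amplified the +PNA Cq is undefined (no mutant signal).
#' Total cfDNA always amplifies, so at least one -PNA replicate is required.
#'
#' @param cq_plus_pna numeric vector (length <= 2) of +PNA Cq values; `NA`
#'   encodes no amplification.
#' @param cq_minus_pna numeric vector (length <= 2) of -PNA Cq values.
#' @return list with `cq_plus` (`NA` if no +PNA amplification) and `cq_minus`.
#' @export
average_replicates <- function(cq_plus_pna, cq_minus_pna) {
  minus <- cq_minus_pna[!is.na(cq_minus_pna)]
  if (length(minus) == 0)
    stop("invalid measurement: no -PNA replicate amplified")
  check_cq_range(minus)
  plus <- cq_plus_pna[!is.na(cq_plus_pna)]
  check_cq_range(plus)
  if (length(plus) == 2 && abs(plus[1] - plus[2]) > 2)
    warning("replicate disagreement > 2 cycles (+PNA); mean still used")
  if (length(minus) == 2 && abs(minus[1] - minus[2]) > 2)
    warning("replicate disagreement > 2 cycles (-PNA); mean still used")
  list(cq_plus = if (length(plus)) mean(plus) else NA_real_,
       cq_minus = mean(minus))
}

check_cq_range <- function(x) {
  bad <- x[!is.na(x) & (x <= 0 | x >= 50)]
  if (length(bad))
    stop("Cq value outside instrument cycle range (0, 50): ",
         paste(format(bad), collapse = ", "))
  invisible(x)
}

#' Compute the sample delta-Cq
#'
#' `ddCq = Cq(+PNA) - Cq(-PNA)`: the cycle difference between the clamped
#' (mutant-enriched) and unclamped (total cfDNA) reactions. Undefined when
#' the +PNA reaction never amplified.
#'
#' @param cq_plus averaged +PNA Cq (or `NA`).
#' @param cq_minus averaged -PNA Cq.
#' @return delta-Cq in cycles, or `NA`.
#' @export
compute_delta_cq <- function(cq_plus, cq_minus) {
  if (is.na(cq_minus)) stop("cq_minus must be defined")
  if (is.na(cq_plus)) return(NA_real_)
  cq_plus - cq_minus
}

#' Derive the wild-type detection cutoff from a control panel
#'
#' The detection cutoff is the minimum delta-Cq observed among non-cancer
#' control plasma samples: any patient sample with a smaller delta-Cq shows
#' more mutant-specific amplification than any control ever did.
#'
#' @param delta_cq_values numeric vector of control delta-Cq values (cycles).
#' @return list of class `ctmon_control_panel` with `delta_cq_values` and
#'   `cutoff`.
#' @export
derive_cutoff <- function(delta_cq_values) {
  delta_cq_values <- as.numeric(delta_cq_values)
  delta_cq_values <- delta_cq_values[!is.na(delta_cq_values)]
  if (length(delta_cq_values) == 0) stop("empty control panel")
  structure(list(delta_cq_values = delta_cq_values,
                 cutoff = min(delta_cq_values)),
            class = "ctmon_control_panel")
}

#' Compute the ddCq ctDNA level and detection call
#'
#' `ddCq = cutoff - delta_cq`, floored at 0; a sample is called detected when
#' the raw value is strictly positive. A ddCq difference of 1 cycle
#' corresponds to a 2-fold change in relative mutant abundance.
#'
#' @param delta_cq sample delta-Cq (cycles) or `NA` (no +PNA amplification).
#' @param panel a `ctmon_control_panel` from [derive_cutoff()].
#' @return list with `delta_cq`, `ddcq` (>= 0) and `detected` (logical).
#' @export
compute_ddcq <- function(delta_cq, panel) {
  stopifnot(inherits(panel, "ctmon_control_panel"))
  if (is.na(delta_cq))
    return(list(delta_cq = NA_real_, ddcq = 0, detected = FALSE))
  raw <- panel$cutoff - delta_cq
  list(delta_cq = delta_cq, ddcq = max(raw, 0), detected = raw > 0)
}

#' Quantify a table of raw qPCR measurements
#'
#' Applies replicate averaging, delta-Cq and ddCq computation to every row of
#' a samples table (columns `sample_id`, `patient_id`, `draw_day`,
#' `cq_pna_1`, `cq_pna_2`, `cq_nopna_1`, `cq_nopna_2`). Missing amplification
#' may be encoded as an empty field, `NA`, or the sentinel string `"ND"`.
#'
#' @param samples data frame of raw measurements.
#' @param panel a `ctmon_control_panel`.
#' @return data frame with `sample_id`, `patient_id`, `draw_day`, `delta_cq`,
#'   `ddcq`, `detected`.
#' @export
quantify_samples <- function(samples, panel) {
  need <- c("sample_id", "patient_id", "draw_day",
            "cq_pna_1", "cq_pna_2", "cq_nopna_1", "cq_nopna_2")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("samples table missing column(s): ",
                         paste(miss, collapse = ", "))
  parse_cq <- function(x) {
    x[x %in% c("", "ND", "nd")] <- NA
    suppressWarnings(as.numeric(x))
  }
  n <- nrow(samples)
  delta <- ddcq <- numeric(n)
  det <- logical(n)
  for (i in seq_len(n)) {
    avg <- average_replicates(
      parse_cq(c(samples$cq_pna_1[i], samples$cq_pna_2[i])),
      parse_cq(c(samples$cq_nopna_1[i], samples$cq_nopna_2[i])))
    d <- compute_delta_cq(avg$cq_plus, avg$cq_minus)
    lev <- compute_ddcq(d, panel)
    delta[i] <- if (is.na(lev$delta_cq)) NA_real_ else lev$delta_cq
    ddcq[i] <- lev$ddcq
    det[i] <- lev$detected
  }
  data.frame(sample_id = samples$sample_id,
             patient_id = samples$patient_id,
             draw_day = samples$draw_day,
             delta_cq = delta, ddcq = ddcq, detected = det,
             stringsAsFactors = FALSE)
}
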