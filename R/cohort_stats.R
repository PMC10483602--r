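#' Cross-classify a baseline characteristic by ctDNA status
#'
#' Builds the contingency table of one baseline variable against baseline
#' ctDNA detection. Patients without a baseline sample are excluded.
#' "Unknown"-type categories (`unknown`, `Tx`, `Nx`, ...) can be kept as rows
#' (as in published baseline tables, where they are counted) or dropped
#' before testing.
#'
#' @param patients patients table.
#' @param levels quantified levels table (from [quantify_samples()]) or a
#'   samples table with a `ddcq` column; baseline = `draw_day == 0`.
#' @param variable name of the patient column to tabulate.
#' @param include_unknown keep unknown/unstaged categories as rows.
#' @param unknown_labels labels treated as unknown.
#' @return object of class `ctmon_ctable`: list with `counts` (matrix,
#'   categories x detected/not detected), `variable`.
#' @export
build_table <- function(patients, levels, variable, include_unknown = TRUE,
                        unknown_labels = c("unknown", "Unknown", "Tx", "Nx")) {
  if (!variable %in% names(patients))
    stop("variable '", variable, "' not found in patients table")
  base <- levels[levels$draw_day == 0, ]
  detected <- setNames(base$ddcq > 0, base$patient_id)
  idx <- patients$patient_id %in% names(detected)
  v <- patients[[variable]][idx]
  d <- detected[patients$patient_id[idx]]
  if (!include_unknown) {
    keep <- !(v %in% unknown_labels)
    v <- v[keep]; d <- d[keep]
  }
  counts <- table(factor(v), factor(ifelse(d, "detected", "not_detected"),
                                    levels = c("detected", "not_detected")))
  counts <- unclass(counts)
  structure(list(counts = counts, variable = variable),
            class = "ctmon_ctable")
}

#' Construct a contingency table object from counts
#'
#' @param counts non-negative integer matrix (at least 2x2).
#' @param variable optional label.
#' @return a `ctmon_ctable`.
#' @export
as_ctable <- function(counts, variable = "") {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least 2 rows and 2 columns")
  structure(list(counts = counts, variable = variable),
            class = "ctmon_ctable")
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration over all tables
#' with the observed margins: the p-value is the sum of probabilities of all
#' tables whose probability does not exceed that of the observed table
#' (with a relative tolerance of 1e-7 on the comparison, so ties are kept).
#'
#' @param t a `ctmon_ctable` or 2x2 matrix.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(t) {
  m <- if (inherits(t, "ctmon_ctable")) t$counts else as.matrix(t)
  if (!all(dim(m) == c(2, 2))) stop("fisher_exact_2x2 requires a 2x2 table")
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  x <- m[1, 1]
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- dhyper(x, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Freeman-Halton exact test for an r x c table
#'
#' Generalization of Fisher's exact test: enumerates all non-negative
#' integer tables with the observed row and column margins (depth-first with
#' margin pruning), computes each table's multivariate hypergeometric
#' probability, and sums the probabilities of tables at least as extreme as
#' the observed one (probability <= observed, relative tolerance 1e-7).
#' Guarded to total counts <= 200 to keep the enumeration exact and fast.
#'
#' @param t a `ctmon_ctable` or integer matrix, r >= 2, c >= 2.
#' @return two-sided p-value.
#' @export
fisher_exact_rxc <- function(t) {
  m <- if (inherits(t, "ctmon_ctable")) t$counts else as.matrix(t)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2x2 table")
  n <- sum(m)
  if (n > 200)
    stop("table total ", n, " exceeds the exact-enumeration guard (200); ",
         "a Monte-Carlo approximation would be needed")
  row_m <- rowSums(m); col_m <- colSums(m)
  if (any(row_m == 0) || any(col_m == 0)) return(1)
  # log-probability of a table given fixed margins
  log_const <- sum(lgamma(row_m + 1)) + sum(lgamma(col_m + 1)) - lgamma(n + 1)
  logp_table <- function(cells) log_const - sum(lgamma(cells + 1))
  logp_obs <- logp_table(as.vector(m))
  thresh <- logp_obs + log1p(1e-7)
  r <- nrow(m); cc <- ncol(m)
  p_total <- 0; p_extreme <- 0
  # depth-first over rows; within a row, over cells, with remaining-margin
  # bounds
  recurse_row <- function(i, col_rem, logp_acc) {
    if (i == r) {
      lp <- logp_acc - sum(lgamma(col_rem + 1))
      pr <- exp(lp)
      p_total <<- p_total + pr
      if (lp <= thresh) p_extreme <<- p_extreme + pr
      return(invisible())
    }
    cells <- integer(cc)
    fill_cell <- function(j, rem_row, col_rem, logp_acc) {
      if (j == cc) {
        if (rem_row > col_rem[cc]) return(invisible())
        cells[cc] <<- rem_row
        recurse_row(i + 1,
                    col_rem - cells,
                    logp_acc - lgamma(rem_row + 1))
        return(invisible())
      }
      rest_cap <- sum(col_rem[(j + 1):cc])
      lo <- max(0, rem_row - rest_cap)
      hi <- min(rem_row, col_rem[j])
      if (lo > hi) return(invisible())
      for (x in lo:hi) {
        cells[j] <<- x
        fill_cell(j + 1, rem_row - x, col_rem, logp_acc - lgamma(x + 1))
      }
      invisible()
    }
    fill_cell(1, row_m[i], col_rem, logp_acc)
    invisible()
  }
  recurse_row(1, col_m, log_const)
  if (abs(p_total - 1) > 1e-6)
    warning("enumerated probabilities sum to ", format(p_total))
  min(p_extreme, 1)
}

#' Exact test dispatch
#'
#' Uses the 2x2 hypergeometric enumeration when the table is 2x2 and the
#' Freeman-Halton enumeration otherwise.
#'
#' @param t a `ctmon_ctable` or matrix.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(t) {
  m <- if (inherits(t, "ctmon_ctable")) t$counts else as.matrix(t)
  if (all(dim(m) == c(2, 2))) fisher_exact_2x2(m) else fisher_exact_rxc(m)
}

#' Baseline characteristics table with exact tests
#'
#' Emits counts, within-group percentages and the exact p-value for each
#' requested baseline variable, compared between patients with and without
#' ctDNA detected at baseline.
#'
#' @param patients patients table.
#' @param levels quantified levels (see [build_table()]).
#' @param variables character vector of patient columns.
#' @param include_unknown passed to [build_table()].
#' @return data frame with one row per variable category plus the exact p.
#' @export
baseline_stats <- function(patients, levels,
                           variables = c("sex", "ecog", "treatment",
                                         "metastasis_location",
                                         "tumour_location", "site"),
                           include_unknown = TRUE) {
  rows <- lapply(variables, function(v) {
    tb <- build_table(patients, levels, v, include_unknown = include_unknown)
    p <- fisher_exact(tb)
    cnt <- tb$counts
    pct <- sweep(cnt, 2, pmax(colSums(cnt), 1), "/")
    data.frame(variable = v, category = rownames(cnt),
               detected = cnt[, "detected"],
               not_detected = cnt[, "not_detected"],
               pct_detected = round(100 * pct[, "detected"], 1),
               pct_not_detected = round(100 * pct[, "not_detected"], 1),
               p_value = c(p, rep(NA, nrow(cnt) - 1)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
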