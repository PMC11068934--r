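#' Cell-population doubling time
#'
#' `Td = (T2 - T1) * ln(2) / ln(N2 / N1)`: the time for an exponentially
#' growing population to double, from counts `n1` at time `t1` and `n2` at
#' time `t2`. A shrinking population (`n2 < n1`) returns a negative doubling
#' time with a warning; `n2 == n1` is undefined.
#'
#' @param t1,t2 Measurement times (same units, `t2 > t1`), e.g. days.
#' @param n1,n2 Positive cell counts at `t1` and `t2`.
#' @return Doubling time in the units of `t1`/`t2`.
#' @examples
#' doubling_time(0, 1, 1e4, 2e4)  # 1
#' @export
doubling_time <- function(t1, t2, n1, n2) {
  stopifnot(t2 > t1, n1 > 0, n2 > 0)
  if (n2 == n1) stop("doubling time undefined: no change in cell number")
  if (n2 < n1) warning("population shrank; doubling time is negative")
  (t2 - t1) * log(2) / log(n2 / n1)
}

#' Mitochondrial stress-test OCR trace
#'
#' A trace of twelve oxygen-consumption-rate (OCR) measurements from the
#' standard mitochondrial stress test, already normalized per cell:
#' timepoints 1--3 under basal conditions (condition A), 4--6 after the ATP
#' synthase inhibitor oligomycin (B), 7--9 after the uncoupler FCCP (C), and
#' 10--12 after rotenone/antimycin A (D).
#'
#' @param ocr Numeric vector of exactly 12 finite OCR values in timepoint
#'   order.
#' @return An `ocr_trace` with per-condition means `A`, `B`, `C`, `D`.
#' @export
ocr_trace <- function(ocr) {
  ocr <- as.numeric(ocr)
  if (length(ocr) != 12L || anyNA(ocr) || any(!is.finite(ocr)))
    stop("an OCR trace needs exactly 12 finite timepoint values")
  structure(list(ocr = ocr,
                 A = mean(ocr[1:3]), B = mean(ocr[4:6]),
                 C = mean(ocr[7:9]), D = mean(ocr[10:12])),
            class = "ocr_trace")
}

#' Mitochondrial respiration phenotypes from an OCR trace
#'
#' The three timepoints per condition are technical replicates and are
#' averaged; the derived phenotypes are then: non-mitochondrial respiration
#' D, basal respiration A - D, ATP-linked respiration A - B, proton leak
#' B - D, maximal respiratory capacity C - D, and reserve capacity C - A.
#' By construction basal = ATP-linked + proton leak.
#'
#' @param trace An [ocr_trace()] (or numeric vector of 12 OCR values).
#' @return A `mito_phenotypes` list: `non_mito`, `basal`, `atp_linked`,
#'   `proton_leak`, `max_capacity`, `reserve_capacity` (OCR units).
#' @examples
#' seahorse_phenotypes(c(100, 100, 100, 60, 60, 60, 150, 150, 150, 20, 20, 20))
#' @export
seahorse_phenotypes <- function(trace) {
  if (!inherits(trace, "ocr_trace")) trace <- ocr_trace(trace)
  structure(list(non_mito = trace$D,
                 basal = trace$A - trace$D,
                 atp_linked = trace$A - trace$B,
                 proton_leak = trace$B - trace$D,
                 max_capacity = trace$C - trace$D,
                 reserve_capacity = trace$C - trace$A),
            class = "mito_phenotypes")
}

#' @export
print.mito_phenotypes <- function(x, ...) {
  cat("mito_phenotypes (OCR units)\n")
  for (f in names(x)) cat(sprintf("  %-17s %g\n", f, x[[f]]))
  invisible(x)
}

#' Per-group mitochondrial phenotypes from a long assay table
#'
#' Reads tab-delimited assay data with columns `well`, `timepoint`, `value`
#' and `group` (values already normalized per cell), averages wells within
#' each group at each timepoint, and derives the [seahorse_phenotypes()]
#' per group.
#'
#' @param path Tab-delimited file, or a data frame with the same columns.
#' @return Data frame with one row per group and one column per phenotype.
#' @export
seahorse_group_summary <- function(path) {
  df <- if (is.data.frame(path)) path
  else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("well", "timepoint", "value", "group")
  if (!all(need %in% names(df)))
    stop("assay table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$group), function(d) {
    tp <- tapply(d$value, d$timepoint, mean)
    if (!all(as.character(1:12) %in% names(tp)))
      stop("group '", d$group[1], "' is missing timepoints")
    unlist(seahorse_phenotypes(as.numeric(tp[as.character(1:12)])))
  })
  res <- data.frame(group = names(out), do.call(rbind, out),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
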