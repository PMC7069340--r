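`%||%` <- function(x, y) if (is.null(x)) y else x

.datatable.aware <- TRUE

BASES <- c("A", "C", "G", "T")

#' @importFrom stats complete.cases cor p.adjust pnorm rbeta rbinom runif setNames
#' @importFrom utils read.delim write.table head combn
NULL

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0

#' Complement of nucleotide bases
#' @param b character vector of single bases
#' @return complemented bases
#' @keywords internal
comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

# 12 substitution classes (ref != alt), fixed ordering used in spectra
SUB_CLASSES <- {
  cls <- as.vector(outer(BASES, BASES, paste0))
  cls[substr(cls, 1, 1) != substr(cls, 2, 2)]
}
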