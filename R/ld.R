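#' Build a pairwise LD (r-squared) lookup
#'
#' Stores precomputed linkage-disequilibrium r-squared values between variant
#' pairs, as produced from a reference panel. The lookup is symmetric,
#' r²(a, a) = 1 by definition, and any pair absent from the table is treated
#' as unlinked (r² = 0) — genotype-level LD computation is out of scope.
#'
#' @param pairs data.frame with columns `rsid_a`, `rsid_b`, `r2`
#'   (0 <= r2 <= 1). May be empty.
#' @return An object of class `"ld_ref"`.
#' @export
ld_reference <- function(pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- data.frame(rsid_a = character(), rsid_b = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("rsid_a", "rsid_b", "r2") %in% names(pairs)))
  r2 <- as.numeric(pairs$r2)
  if (any(is.na(r2) | r2 < 0 | r2 > 1)) {
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  }
  a <- as.character(pairs$rsid_a)
  b <- as.character(pairs$rsid_b)
  keys <- c(paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  vals <- c(r2, r2)
  dup <- duplicated(keys)
  structure(list(r2 = stats::setNames(vals[!dup], keys[!dup])),
            class = "ld_ref")
}

#' Read an LD reference from a three-column delimited file
#'
#' @param path file with header columns `rsid_a`, `rsid_b`, `r2`.
#' @param sep field separator; `NULL` auto-detects tab vs comma.
#' @return An `"ld_ref"` object.
#' @export
read_ld <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  ld_reference(utils::read.table(path, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE))
}

#' Look up pairwise r-squared values
#'
#' Vectorized over `b`. Pairs absent from the reference return 0 (documented
#' missing-equals-unlinked convention); `ld_r2(ld, a, a)` returns 1.
#'
#' @param ld an `"ld_ref"` object.
#' @param a single query rsid.
#' @param b character vector of rsids.
#' @return numeric vector of r² values, same length as `b`.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_ref"), length(a) == 1L)
  out <- unname(ld$r2[paste(a, b, sep = "\r")])
  out[is.na(out)] <- 0
  out[b == a] <- 1
  out
}

#' @export
print.ld_ref <- function(x, ...) {
  cat(sprintf("LD reference: %d stored pair value(s)\n", length(x$r2) / 2L))
  invisible(x)
}
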