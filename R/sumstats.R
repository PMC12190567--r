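#' Construct a validated GWAS summary-statistics table
#'
#' The canonical per-trait container used throughout the package. Each row is
#' one SNP's association record: identifier, genomic coordinates, allele pair,
#' effect-allele frequency, additive effect (SD units for quantitative traits,
#' log-odds for binary traits), standard error, p-value and sample size. Rows
#' violating the data contract are dropped and reported, not silently fixed.
#'
#' Row-level requirements: single-base alleles in A/C/G/T with
#' `effect_allele != other_allele`; `0 < eaf < 1`; `se > 0`; `0 < pval <= 1`;
#' `n >= 2`. A row whose p-value disagrees with its `|beta/se|` z-score by
#' more than 10% (on the z scale, two-sided normal) is retained but counted as
#' a consistency warning. Indels and multi-allelic records are out of scope
#' and rejected.
#'
#' @param data data.frame with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_id character label for the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_cases,n_controls case/control counts, required for binary traits.
#' @return An object of class `"sumstats"`: a list with elements `trait_id`,
#'   `trait_type`, `n_cases`, `n_controls`, `data` (the retained rows),
#'   `rejects` (data.frame of rsid + reason) and `n_warnings`.
#' @examples
#' df <- data.frame(rsid = "rs1", chrom = "1", pos = 1000L,
#'                  effect_allele = "A", other_allele = "G", eaf = 0.3,
#'                  beta = 0.2, se = 0.04, pval = 5.7e-7, n = 1539)
#' sumstats(df, trait_id = "genus_x", trait_type = "quantitative")
#' @export
sumstats <- function(data, trait_id, trait_type = c("quantitative", "binary"),
                     n_cases = NA_integer_, n_controls = NA_integer_) {
  trait_type <- match.arg(trait_type)
  required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (trait_type == "binary" && (is.na(n_cases) || is.na(n_controls))) {
    stop("binary traits require `n_cases` and `n_controls`", call. = FALSE)
  }
  data <- data[, required, drop = FALSE]
  data$rsid <- as.character(data$rsid)
  data$chrom <- as.character(data$chrom)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }

  chk <- validate_variant_rows(data)
  dup <- duplicated(data$rsid)
  chk$reason[dup & is.na(chk$reason)] <- "duplicate_rsid"
  keep <- is.na(chk$reason)

  structure(list(
    trait_id = as.character(trait_id),
    trait_type = trait_type,
    n_cases = n_cases,
    n_controls = n_controls,
    data = data[keep, , drop = FALSE],
    rejects = data.frame(rsid = data$rsid[!keep],
                         reason = chk$reason[!keep],
                         stringsAsFactors = FALSE),
    n_warnings = sum(chk$warn[keep])
  ), class = "sumstats")
}

# Row validation: returns reason (NA = accepted) and a z/p consistency flag.
validate_variant_rows <- function(data) {
  n_row <- nrow(data)
  reason <- rep(NA_character_, n_row)
  bases <- c("A", "C", "G", "T")

  bad_allele <- !(data$effect_allele %in% bases) |
    !(data$other_allele %in% bases)
  same_allele <- !bad_allele & data$effect_allele == data$other_allele
  num_bad <- is.na(data$pos) | is.na(data$beta)
  eaf_bad <- is.na(data$eaf) | data$eaf <= 0 | data$eaf >= 1
  se_bad <- is.na(data$se) | data$se <= 0
  p_bad <- is.na(data$pval) | data$pval <= 0 | data$pval > 1
  n_bad <- is.na(data$n) | data$n < 2

  reason[n_bad] <- "invalid_n"
  reason[p_bad] <- "invalid_pval"
  reason[se_bad] <- "invalid_se"
  reason[eaf_bad] <- "invalid_eaf"
  reason[num_bad] <- "unparsable_numeric"
  reason[same_allele] <- "identical_alleles"
  reason[bad_allele] <- "non_single_base_allele"

  warn <- rep(FALSE, n_row)
  ok <- is.na(reason)
  if (any(ok)) {
    z_obs <- abs(data$beta[ok] / data$se[ok])
    z_p <- stats::qnorm(pmax(data$pval[ok], 1e-300) / 2, lower.tail = FALSE)
    denom <- pmax(z_obs, z_p, 1)
    warn[ok] <- abs(z_obs - z_p) / denom > 0.10
  }
  list(reason = reason, warn = warn)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited file with a header, renames columns via an
#' explicit mapping (no dialect guessing), and validates rows through
#' [sumstats()]. Row order is preserved; rejected rows are listed in the
#' returned object's `rejects` element.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names
#'   (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`, `n`) to the file's column names. Canonical names absent
#'   from the map are assumed to appear verbatim in the file.
#' @param trait_id,trait_type,n_cases,n_controls passed to [sumstats()].
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma from
#'   the header line.
#' @return A `"sumstats"` object.
#' @export
read_sumstats <- function(path, trait_id, trait_type = c("quantitative", "binary"),
                          column_map = NULL, n_cases = NA_integer_,
                          n_controls = NA_integer_, sep = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  canonical <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canonical)
    if (length(bad)) {
      stop("unknown canonical name(s) in column_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  missing_cols <- map[!(map %in% names(raw))]
  if (length(missing_cols)) {
    stop("input is missing required column(s): ",
         paste(sprintf("%s (expected as '%s')", names(missing_cols), missing_cols),
               collapse = ", "), call. = FALSE)
  }
  df <- stats::setNames(raw[, map, drop = FALSE], canonical)
  sumstats(df, trait_id = trait_id, trait_type = trait_type,
           n_cases = n_cases, n_controls = n_controls)
}

#' Write a summary-statistics table to delimited text
#'
#' Emits the retained rows of a `"sumstats"` object as a tab-delimited file
#' with numeric fields formatted to 6 significant digits, so that
#' `read_sumstats(write_sumstats(x))` reproduces every retained field to that
#' precision.
#'
#' @param x a `"sumstats"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  df <- x$data
  num_cols <- c("eaf", "beta", "se", "pval", "n")
  out <- df
  for (col in num_cols) out[[col]] <- fmt_num(df[[col]])
  out$pos <- sprintf("%.0f", df$pos)
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(paste, c(unname(as.list(out)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s)\n", x$trait_id, x$trait_type))
  if (x$trait_type == "binary") {
    cat(sprintf("  cases/controls: %s / %s\n", x$n_cases, x$n_controls))
  }
  cat(sprintf("  %d variants retained, %d rejected, %d consistency warning(s)\n",
              nrow(x$data), nrow(x$rejects), x$n_warnings))
  invisible(x)
}
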