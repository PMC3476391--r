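#' Write SNP calls as minimal VCF 4.2
#'
#' One data line per call: CHROM is the isotig id, POS the 1-based position,
#' REF the major allele and ALT the minor allele. INFO carries the read
#' depth (`DP`), minor-allele count (`MC`), isogroup id (`IG`) and the
#' post-deduplication unique flag (`UNIQ`, 0/1).
#'
#' @param calls A SNP call set as returned by [call_snps()] /
#'   [dedup_calls()] (the `unique` and `isogroup_id` columns are optional
#'   and default to 1 / ".").
#' @param path Output path.
#' @export
write_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=postasm",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Non-gap read depth\">",
    "##INFO=<ID=MC,Number=1,Type=Integer,Description=\"Minor allele read count\">",
    "##INFO=<ID=IG,Number=1,Type=String,Description=\"Isogroup id\">",
    "##INFO=<ID=UNIQ,Number=1,Type=Integer,Description=\"1 if the call is the unique representative of its redundancy class\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(calls)) {
    uniq <- if (is.null(calls$unique)) rep(1L, nrow(calls)) else
      as.integer(calls$unique)
    ig <- if (is.null(calls$isogroup_id)) rep(".", nrow(calls)) else
      calls$isogroup_id
    info <- sprintf("DP=%d;MC=%d;IG=%s;UNIQ=%d",
                    as.integer(calls$depth), as.integer(calls$minor_count),
                    ig, uniq)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                       calls$isotig_id, as.integer(calls$position),
                       calls$major, calls$minor, info), con)
  }
  invisible(path)
}

#' Read a minimal VCF written by [write_vcf()]
#'
#' @param path Path to the VCF file.
#' @return A data.frame with the same columns [write_vcf()] consumed.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  empty <- data.frame(
    isotig_id = character(0), isogroup_id = character(0),
    position = integer(0), major = character(0), minor = character(0),
    minor_count = integer(0), depth = integer(0), minor_freq = numeric(0),
    unique = logical(0), stringsAsFactors = FALSE
  )
  if (!length(body)) return(empty)
  fields <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  if (ncol(fields) < 8L) stop("malformed VCF data line", call. = FALSE)
  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    sub(paste0("^;?", key, "="), "", m)
  }
  depth <- as.integer(info_field(fields[, 8], "DP"))
  mc <- as.integer(info_field(fields[, 8], "MC"))
  data.frame(
    isotig_id = fields[, 1],
    isogroup_id = info_field(fields[, 8], "IG"),
    position = as.integer(fields[, 2]),
    major = fields[, 4],
    minor = fields[, 5],
    minor_count = mc,
    depth = depth,
    minor_freq = mc / depth,
    unique = info_field(fields[, 8], "UNIQ") == "1",
    stringsAsFactors = FALSE
  )
}
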