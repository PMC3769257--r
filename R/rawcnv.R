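#' Read PennCNV `.rawcnv` CNV calls
#'
#' Parses the standard PennCNV per-sample CNV call lines, e.g.
#' `chr22:17000000-17100000 numsnp=10 length=100001 state2,cn=1 sample_7
#' startsnp=rs1 endsnp=rs10`. Positions are 1-based and inclusive, as in
#' PennCNV output; only variant segments (copy number 0, 1, 3 or 4) are
#' listed, unlisted positions carry the normal two copies. Extra whitespace
#' between fields and thousands separators in `length=` are tolerated.
#'
#' @param path Path to a `.rawcnv` text file.
#' @return Data frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `cn`, `num_snps`, `length`, `state`, `start_snp`, `end_snp`; zero rows
#'   for an empty file.
#' @export
read_rawcnv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(), cn = integer(),
                      num_snps = integer(), length = integer(),
                      state = character(), start_snp = character(),
                      end_snp = character(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parse_line <- function(line, lineno) {
    f <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    fail <- function(what) {
      stop(sprintf("malformed .rawcnv line %d (%s): %s", lineno, what, line))
    }
    if (length(f) < 7L) fail("expected 7 fields")
    loc <- regmatches(f[1], regexec("^(chr[^:]+):([0-9,]+)-([0-9,]+)$", f[1]))[[1]]
    if (length(loc) != 4L) fail("bad locus field")
    num <- function(x) as.integer(gsub(",", "", x))
    if (!grepl("^numsnp=", f[2])) fail("bad numsnp field")
    if (!grepl("^length=", f[3])) fail("bad length field")
    st <- regmatches(f[4], regexec("^state([0-9]+),cn=([0-9]+)$", f[4]))[[1]]
    if (length(st) != 3L) fail("bad state/cn field")
    cn <- num(st[3])
    if (!cn %in% c(0L, 1L, 3L, 4L)) fail("cn must be 0, 1, 3 or 4")
    if (!grepl("^startsnp=", f[6])) fail("bad startsnp field")
    if (!grepl("^endsnp=", f[7])) fail("bad endsnp field")
    start <- num(loc[3]); end <- num(loc[4])
    if (is.na(start) || is.na(end) || start > end) fail("start > end")
    data.frame(sample_id = f[5], chrom = loc[2], start = start, end = end,
               cn = cn, num_snps = num(sub("numsnp=", "", f[2])),
               length = num(sub("length=", "", f[3])), state = st[2],
               start_snp = sub("startsnp=", "", f[6]),
               end_snp = sub("endsnp=", "", f[7]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, mapply(parse_line, lines, seq_along(lines),
                               SIMPLIFY = FALSE, USE.NAMES = FALSE))
  rownames(out) <- NULL
  out
}

#' Write CNV calls in PennCNV `.rawcnv` format
#'
#' Inverse of [read_rawcnv()]: a write/read round trip preserves all fields.
#'
#' @param calls Data frame as returned by [read_rawcnv()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_rawcnv <- function(calls, path) {
  lines <- sprintf("%s:%d-%d numsnp=%d length=%d state%s,cn=%d %s startsnp=%s endsnp=%s",
                   calls$chrom, calls$start, calls$end, calls$num_snps,
                   calls$length, calls$state, calls$cn, calls$sample_id,
                   calls$start_snp, calls$end_snp)
  writeLines(lines, path)
  invisible(path)
}
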