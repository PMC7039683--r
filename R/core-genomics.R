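## Shared coordinate conventions, sequence utilities, and plain-text readers
## and writers.  All intervals are 0-based, half-open (BED convention),
## everywhere; 1-based inputs (SNP tables) are converted at the reader
## boundary.  Genomes are named character vectors of DNA strings in which
## lowercase letters mark repeat-masked (soft-masked) bases.

#' Construct a table of genomic intervals
#'
#' The universal coordinate unit of the package: a data frame with columns
#' `chrom`, `start`, `end` (0-based, half-open) and optionally `strand`
#' plus arbitrary annotation columns.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end` is enforced.
#' @param strand optional vector over `+`, `-`, `.`.
#' @param ... further annotation columns, recycled by `data.frame()`.
#' @return a `data.frame` of intervals.
#' @export
gintervals <- function(chrom, start, end, strand = NULL, ...) {
  start <- as.integer(start)
  end <- as.integer(end)
  bad <- which(!(start >= 0L & start < end))
  if (length(bad) > 0)
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    if (!all(strand %in% c("+", "-", ".")))
      stop("strand must be one of '+', '-', '.'")
    df$strand <- strand
  }
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

#' Read a (soft-masked) FASTA file into a genome
#'
#' Case is preserved so that lowercase bases can be interpreted as
#' repeat-masked sequence; `N` is allowed.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (class `genome`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) return(structure(character(0), class = "genome"))
  hdr <- grepl("^>", lines)
  if (!hdr[1]) {
    bad <- which(!grepl("^[A-Za-z*.-]*$", lines))[1]
    stop("malformed FASTA: line 1 is not a header")
  }
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids))
    stop("duplicate FASTA record name: ", ids[duplicated(ids)][1])
  grp <- cumsum(hdr)
  body <- lines[!hdr]
  bad <- which(!grepl("^[ACGTUNRYSWKMBDHVacgtunryswkmbdhv]*$", body))
  if (length(bad) > 0) {
    lineno <- which(!hdr)[bad[1]]
    stop("malformed FASTA sequence at line ", lineno, " of ", path)
  }
  seqs <- vapply(split(body, factor(grp[!hdr], levels = seq_along(ids))),
                 paste0, character(1), collapse = "")
  structure(stats::setNames(unname(seqs), ids), class = "genome")
}

#' Write a genome (or any named set of sequences) as FASTA
#'
#' @param genome named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    s <- genome[[nm]]
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = width)
    writeLines(c(paste0(">", nm), substring(s, starts, pmin(starts + width - 1L, n))),
               con)
  }
  invisible(path)
}

#' @export
print.genome <- function(x, ...) {
  cat("genome with", length(x), "sequence(s);",
      format(sum(nchar(x)), big.mark = ","), "bp total\n")
  for (nm in utils::head(names(x), 10))
    cat(" ", nm, ":", nchar(x[[nm]]), "bp\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome named character vector of sequences.
#' @return named integer vector.
#' @export
genome_lengths <- function(genome) vapply(genome, nchar, integer(1))

#' Extract the sequence of intervals from a genome
#'
#' @param genome named character vector.
#' @param intervals interval data frame (0-based half-open).
#' @return character vector of sequences, case preserved.
#' @export
get_seq <- function(genome, intervals) {
  lens <- genome_lengths(genome)
  miss <- setdiff(unique(intervals$chrom), names(lens))
  if (length(miss) > 0) stop("chromosome(s) absent from genome: ",
                             paste(miss, collapse = ", "))
  if (any(intervals$end > lens[intervals$chrom]))
    stop("interval(s) extend past chromosome end")
  unname(substring(genome[intervals$chrom], intervals$start + 1L, intervals$end))
}

#' Read a BED3+ / narrowPeak file
#'
#' Standard BED columns are mapped to `chrom`, `start`, `end`, `name`,
#' `score`, `strand`; a 10-column narrowPeak additionally yields
#' `signal`, `pvalue`, `qvalue`, `summit`.  Extra columns beyond those are
#' kept as `V<i>`.
#'
#' @param path BED file (no header).
#' @return interval data frame in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0)
    return(gintervals(character(0), integer(0), integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3))
    stop("BED line ", which(ncols < 3)[1], " has fewer than 3 columns")
  nc <- min(ncols)
  m <- matrix(unlist(lapply(parts, `[`, seq_len(nc))), ncol = nc, byrow = TRUE)
  start <- as.integer(m[, 2])
  end <- as.integer(m[, 3])
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad) > 0)
    stop("invalid BED interval at line ", bad[1], ": start must satisfy 0 <= start < end")
  df <- data.frame(chrom = m[, 1], start = start, end = end, stringsAsFactors = FALSE)
  nm <- c("name", "score", "strand", "signal", "pvalue", "qvalue", "summit")
  for (i in seq_len(nc - 3)) {
    col <- m[, i + 3]
    label <- if (i <= length(nm)) nm[i] else paste0("V", i + 3)
    num <- suppressWarnings(as.numeric(col))
    df[[label]] <- if (label %in% c("chrom", "name", "strand") || anyNA(num)) col else num
  }
  df
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` plus any of `name`, `score`, `strand`
#' present, in that order.  `read_bed(write_bed(x))` round-trips
#' coordinates bit-exactly.
#'
#' @param intervals interval data frame.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand"))
    if (extra %in% names(intervals)) cols <- c(cols, extra)
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' GC fraction of a sequence
#'
#' `(G + C) / (A + C + G + T)`, case-insensitive; `N` (and other ambiguity
#' codes) are excluded from the denominator.  An all-`N` sequence returns 0.
#'
#' @param seq character vector of DNA sequences.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  if (any(!nzchar(seq))) stop("empty sequence")
  up <- toupper(seq)
  gc <- nchar(gsub("[^GC]", "", up))
  at <- nchar(gsub("[^AT]", "", up))
  ifelse(gc + at == 0, 0, gc / (gc + at))
}

#' Repeat (soft-masked) fraction of a sequence
#'
#' Lowercase bases are the repeat representation: the value is the
#' lowercase count divided by total length.
#'
#' @param seq character vector.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
repeat_fraction <- function(seq) {
  if (any(!nzchar(seq))) stop("empty sequence")
  nchar(gsub("[^a-z]", "", seq)) / nchar(seq)
}

#' Reverse complement, preserving case
#'
#' @param seq character vector over `ACGTN` (either case).
#' @return reverse-complemented sequences; `rc(rc(s)) == s`.
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTNacgtn]", seq))) stop("non-DNA character in sequence")
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Read a SNP table
#'
#' Tab-separated with header and columns `chrom`, `pos` (1-based), `ref`,
#' `alt`, `id` and optionally `assoc_p` (GWAS association p) or further
#' annotations.  Positions are converted to 0-based `pos0` internally.
#'
#' @param path TSV file.
#' @return data frame with an additional `pos0` column.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("SNP table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$ref == df$alt)) stop("SNP with ref == alt: ", df$id[df$ref == df$alt][1])
  if (any(!df$ref %in% c("A", "C", "G", "T")) || any(!df$alt %in% c("A", "C", "G", "T")))
    stop("ref/alt must be single A/C/G/T bases")
  df$pos0 <- as.integer(df$pos) - 1L
  df
}

#' Read an ATAC fragment table
#'
#' Tab-separated with header: `chrom`, `start`, `end` (0-based half-open),
#' `strand`, `sample`.
#'
#' @param path TSV file.
#' @return fragment data frame with a derived `length` column.
#' @export
read_fragments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "sample")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("fragment table lacks column(s): ", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$end - df$start < 1)) stop("fragment with length < 1")
  df$length <- df$end - df$start
  df
}

## ---- interval helpers (internal but exported for composability) ----

#' Merge overlapping or book-ended intervals
#' @param intervals interval data frame.
#' @return merged, sorted interval data frame.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals[, c("chrom", "start", "end")])
  o <- order(intervals$chrom, intervals$start, intervals$end)
  x <- intervals[o, , drop = FALSE]
  out <- list()
  cur <- x[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(x))[-1]) {
    if (x$chrom[i] == cur$chrom && x$start[i] <= cur$end) {
      cur$end <- max(cur$end, x$end[i])
    } else {
      out[[length(out) + 1]] <- cur
      cur <- x[i, c("chrom", "start", "end")]
    }
  }
  out[[length(out) + 1]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Indices of query intervals overlapping any subject interval (>= 1 bp)
#' @param query,subject interval data frames.
#' @return logical vector along `query`.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  res <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    s <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) next
    for (i in qi)
      res[i] <- any(query$start[i] < s$end & s$start < query$end[i])
  }
  res
}
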