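#' Load a two-column contig coverage table
#'
#' Reads the TAB-separated `contig_id<TAB>mean_depth` table that accompanies
#' an assembly (no header required; a header line whose second field is not
#' numeric is rejected as non-numeric).
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of mean depths, one entry per contig.
#' @export
load_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("coverage table must have two TAB-separated columns")
  ids <- tab[[1L]]
  depth <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(depth)) {
    stop("non-numeric depth for contig(s): ",
         paste(ids[is.na(depth)], collapse = ", "))
  }
  if (any(depth < 0)) stop("negative depth in coverage table")
  if (any(duplicated(ids))) {
    stop("repeated contig id(s) in coverage table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(depth, ids)
}

#' Coverage-ratio compatibility of two contigs
#'
#' A candidate contig is coverage-compatible with the query when the ratio
#' `cov_candidate / cov_query` lies inside the inclusive window. A zero-depth
#' query is compatible only with a zero-depth candidate.
#'
#' @param cov_query Mean depth of the query contig.
#' @param cov_candidate Mean depth of the candidate contig.
#' @param window Numeric `(lo, hi)` with `lo <= 1 <= hi`; default `c(0.5, 2)`.
#' @return Logical.
#' @export
coverage_compatible <- function(cov_query, cov_candidate, window = c(0.5, 2)) {
  if (cov_query == 0) return(cov_candidate == 0)
  r <- cov_candidate / cov_query
  window[1] <= r && r <= window[2]
}

#' Count read pairs spanning pairs of contigs
#'
#' Parses a SAM or BAM file of the read set mapped to the assembly and counts,
#' for every unordered contig pair, the read pairs whose two mates map (as
#' primary alignments) to the two different contigs with at most `mm_max`
#' mismatches each (NM tag). Unmapped, secondary and supplementary alignments
#' are ignored; soft-clipped bases are not mismatches because only NM is
#' consulted.
#'
#' @param alignment_path Path to a SAM (`.sam`) or BAM file.
#' @param mm_max Maximum mismatches per mapped read (default 2).
#' @param missing_nm What to do with a mapped read lacking an NM tag:
#'   `"fail"` (default; that read fails the mismatch filter) or `"pass"`.
#' @return A `linkage_evidence` object: environment-backed counter queryable
#'   with [spanning_pairs()].
#' @export
collect_spanning_pairs <- function(alignment_path, mm_max = 2L,
                                   missing_nm = c("fail", "pass")) {
  missing_nm <- match.arg(missing_nm)
  bam <- as_bam(alignment_path)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname"),
                               tag = "NM", flag = flags)
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  qname <- res$qname
  rname <- as.character(res$rname)
  flag <- res$flag
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(qname))
  keep <- if (missing_nm == "fail") !is.na(nm) & nm <= mm_max else
    is.na(nm) | nm <= mm_max
  qname <- qname[keep]; rname <- rname[keep]; flag <- flag[keep]
  first <- bitwAnd(flag, 64L) > 0L
  second <- bitwAnd(flag, 128L) > 0L
  d1 <- data.frame(qname = qname[first], r1 = rname[first],
                   stringsAsFactors = FALSE)
  d2 <- data.frame(qname = qname[second], r2 = rname[second],
                   stringsAsFactors = FALSE)
  d1 <- d1[!duplicated(d1$qname), , drop = FALSE]
  d2 <- d2[!duplicated(d2$qname), , drop = FALSE]
  m <- merge(d1, d2, by = "qname")
  m <- m[m$r1 != m$r2, , drop = FALSE]
  key <- paste(pmin(m$r1, m$r2), pmax(m$r1, m$r2), sep = "\r")
  counts <- table(key)
  ev <- new.env(parent = emptyenv())
  for (k in names(counts)) assign(k, as.integer(counts[[k]]), envir = ev)
  structure(list(counts = ev, n_pairs = nrow(m)), class = "linkage_evidence")
}

#' Number of read pairs spanning two contigs
#'
#' @param linkage A `linkage_evidence` from [collect_spanning_pairs()].
#' @param id_a,id_b Contig ids (unordered).
#' @return Integer count (0 when the pair was never spanned, or `id_a == id_b`).
#' @export
spanning_pairs <- function(linkage, id_a, id_b) {
  if (id_a == id_b) return(0L)
  key <- paste(min(id_a, id_b), max(id_a, id_b), sep = "\r")
  if (exists(key, envir = linkage$counts, inherits = FALSE)) {
    get(key, envir = linkage$counts, inherits = FALSE)
  } else 0L
}

#' Build linkage evidence from precomputed pair counts
#'
#' @param pairs Data frame with columns `a`, `b` (contig ids) and `count`
#'   (spanning read pairs); pairs are unordered and `a == b` is rejected.
#' @return A `linkage_evidence` object.
#' @export
linkage_from_pairs <- function(pairs) {
  stopifnot(all(c("a", "b", "count") %in% names(pairs)))
  if (any(pairs$a == pairs$b)) stop("self-pair (a == a) is not a linkage")
  ev <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pairs))) {
    key <- paste(min(pairs$a[i], pairs$b[i]),
                 max(pairs$a[i], pairs$b[i]), sep = "\r")
    prev <- if (exists(key, envir = ev, inherits = FALSE))
      get(key, envir = ev, inherits = FALSE) else 0L
    assign(key, prev + as.integer(pairs$count[i]), envir = ev)
  }
  structure(list(counts = ev, n_pairs = sum(pairs$count)),
            class = "linkage_evidence")
}

# SAM text is converted to BAM on the fly; BAM passes through.
as_bam <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
    paste0(dest, ".bam")
  } else {
    path
  }
}
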