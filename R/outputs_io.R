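#' Write the category FASTA files and summaries
#'
#' Writes five FASTA files (one per category) plus two TSV summaries. Joined
#' sequences carry ids `<query_id>_extended`, `<query_id>_extended_circular`
#' or `<query_id>_self_circular`; extended_failed and orphan_end files carry
#' the original query sequences under their original ids. The joining-detail
#' file lists each walk with member orientations.
#'
#' @param result A `cobra_result` from [run_cobra()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_outputs <- function(result, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", outdir)
  contigs <- result$contigs
  cats <- c("self_circular", "extended_circular", "extended_partial",
            "extended_failed", "orphan_end")
  paths <- character()
  for (cat in cats) {
    rs <- Filter(function(r) r$category == cat, result$results)
    seqs <- vapply(rs, function(r) {
      if (!is.null(r$joined_seq)) r$joined_seq else
        contigs$seq[match(r$query_id, contigs$id)]
    }, character(1L))
    ids <- vapply(rs, joined_id_for, character(1L))
    path <- file.path(outdir, paste0("query.", cat, ".fasta"))
    x <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
    Biostrings::writeXStringSet(x, path, width = 80L)
    paths[cat] <- path
  }
  sp <- file.path(outdir, "joining_summary.tsv")
  utils::write.table(result$summary, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["summary"] <- sp
  detail <- do.call(rbind, lapply(result$results, function(r) {
    if (length(r$walk) == 0L) return(NULL)
    data.frame(query_id = r$query_id,
               position = seq_along(r$walk),
               contig_id = vapply(r$walk, `[[`, character(1L), "id"),
               orientation = vapply(r$walk, function(w)
                 if (w$forward) "+" else "-", character(1L)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(detail)) {
    detail <- data.frame(query_id = character(), position = integer(),
                         contig_id = character(), orientation = character())
  }
  rownames(detail) <- NULL
  dp <- file.path(outdir, "joining_detail.tsv")
  utils::write.table(detail, dp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["detail"] <- dp
  invisible(paths)
}

#' Mask zero-coverage regions of joined sequences
#'
#' Recomputes per-base coverage of each sequence from mapped reads with at
#' most `mm_max` mismatches (NM tag; unmapped/secondary/supplementary
#' alignments and reads without NM are excluded) and replaces every maximal
#' zero-coverage interval by exactly 10 `N` characters, regardless of the
#' interval's length. Intervals touching a sequence end are replaced too and
#' flagged in the report.
#'
#' @param fasta_path FASTA of the joined sequences.
#' @param alignment_path SAM/BAM of reads mapped to those sequences; every
#'   FASTA sequence must appear in the alignment header.
#' @param mm_max Maximum mismatches per read (default 2).
#' @param out_fasta Optional path for the corrected FASTA.
#' @return List with `seqs` (named character vector of corrected sequences)
#'   and `report` (data frame: seq_id, interval_start, interval_end in
#'   0-based half-open coordinates on the input sequence, at_end flag).
#' @export
gap_check <- function(fasta_path, alignment_path, mm_max = 2L,
                      out_fasta = NULL) {
  contigs <- load_contigs(fasta_path)
  bam <- as_bam(alignment_path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  missing <- setdiff(contigs$id, names(hdr))
  if (length(missing) > 0L) {
    stop("sequence(s) absent from alignment header: ",
         paste(missing, collapse = ", "))
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(tag = "NM", flag = flags, what = character())
  gal <- GenomicAlignments::readGAlignments(bam, param = p)
  nm <- S4Vectors::mcols(gal)$NM
  gal <- gal[!is.na(nm) & nm <= mm_max]
  covs <- GenomicAlignments::coverage(gal)
  marker <- strrep("N", 10L)
  report <- list()
  out <- stats::setNames(contigs$seq, contigs$id)
  for (sid in contigs$id) {
    len <- contigs$length[match(sid, contigs$id)]
    cov <- if (sid %in% names(covs)) covs[[sid]] else
      S4Vectors::Rle(0L, len)
    if (length(cov) < len) {
      cov <- c(cov, S4Vectors::Rle(0L, len - length(cov)))
    }
    z <- as.integer(cov) == 0L
    r <- rle(z)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0L) next
    seq <- out[[sid]]
    # replace right-to-left so earlier coordinates stay valid
    for (i in rev(seq_along(starts))) {
      seq <- paste0(substr(seq, 1L, starts[i] - 1L), marker,
                    substr(seq, ends[i] + 1L, nchar(seq)))
    }
    out[[sid]] <- seq
    report[[sid]] <- data.frame(
      seq_id = sid,
      interval_start = starts - 1L,        # 0-based half-open
      interval_end = ends,
      at_end = starts == 1L | ends == len,
      stringsAsFactors = FALSE)
  }
  report <- if (length(report) > 0L) do.call(rbind, report) else
    data.frame(seq_id = character(), interval_start = integer(),
               interval_end = integer(), at_end = logical())
  rownames(report) <- NULL
  if (!is.null(out_fasta)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(out), out_fasta,
                                width = 80L)
  }
  list(seqs = out, report = report)
}
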